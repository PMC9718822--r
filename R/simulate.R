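#' Simulation configuration for the three-species stress study
#'
#' Builds and validates the configuration driving [simulate_study()]. The
#' defaults emulate a small three-species brain RNA-seq design: human
#' control/disease pairs (n = 3), rat control/stress/stress+drug (n = 3) and
#' zebrafish control/stress/stress+drug (n = 6), negative-binomial counts
#' whose log2 means combine a shared per-gene baseline, a per-species
#' per-gene offset large enough to dominate overall variance, and planted
#' group effects: a fraction of genes differentially expressed with the same
#' sign in all three species (the conserved signal) and per-species-only
#' signals. In the stress+drug group a configurable fraction of the
#' conserved effects is reverted to baseline, emulating antidepressant
#' rescue.
#'
#' @param n_genes number of ortholog groups simulated.
#' @param samples_per_group named list `species -> c(control, stress,
#'   stress_drug)`.
#' @param baseline_logmean_mu,baseline_logmean_sigma log2-scale mean and sd
#'   of per-gene baseline expression.
#' @param nb_dispersion NB dispersion alpha (variance `mu + alpha mu^2`).
#' @param frac_conserved_de fraction of genes with a conserved stress effect.
#' @param conserved_l2fc_magnitude absolute log2 fold change of conserved
#'   effects.
#' @param frac_species_de per-species fraction of additional species-specific
#'   DE genes.
#' @param species_l2fc_magnitude absolute log2 fold change of
#'   species-specific effects.
#' @param species_offset_sd sd (log2) of the per-species per-gene offset.
#' @param drug_rescue_frac fraction of conserved-DE genes whose effect is
#'   reverted in the stress_drug group.
#' @param paralog_dup_frac fraction of groups given a second, less similar
#'   zebrafish candidate.
#' @param seed integer seed; every sub-generator derives its own stream from
#'   it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 600,
                       samples_per_group = list(
                         human = c(control = 3, stress = 3, stress_drug = 0),
                         rat = c(control = 3, stress = 3, stress_drug = 3),
                         zebrafish = c(control = 6, stress = 6, stress_drug = 6)
                       ),
                       baseline_logmean_mu = 5,
                       baseline_logmean_sigma = 1.5,
                       nb_dispersion = 0.05,
                       frac_conserved_de = 0.05,
                       conserved_l2fc_magnitude = 2,
                       frac_species_de = 0.01,
                       species_l2fc_magnitude = 2,
                       species_offset_sd = 2,
                       drug_rescue_frac = 1,
                       paralog_dup_frac = 0.1,
                       seed = 1L) {
  cfg <- list(
    n_genes = n_genes, samples_per_group = samples_per_group,
    baseline_logmean_mu = baseline_logmean_mu,
    baseline_logmean_sigma = baseline_logmean_sigma,
    nb_dispersion = nb_dispersion,
    frac_conserved_de = frac_conserved_de,
    conserved_l2fc_magnitude = conserved_l2fc_magnitude,
    frac_species_de = frac_species_de,
    species_l2fc_magnitude = species_l2fc_magnitude,
    species_offset_sd = species_offset_sd,
    drug_rescue_frac = drug_rescue_frac,
    paralog_dup_frac = paralog_dup_frac,
    seed = as.integer(seed)
  )
  for (f in c("frac_conserved_de", "frac_species_de", "drug_rescue_frac",
              "paralog_dup_frac")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      rlang::abort(sprintf("configuration error: `%s` must lie in [0, 1]", f))
    }
  }
  if (cfg$nb_dispersion <= 0) {
    rlang::abort("configuration error: `nb_dispersion` must be > 0")
  }
  if (cfg$n_genes < 10) rlang::abort("configuration error: `n_genes` must be >= 10")
  if (!setequal(names(samples_per_group), c("human", "rat", "zebrafish"))) {
    rlang::abort("configuration error: `samples_per_group` needs human, rat, zebrafish")
  }
  for (sp in names(samples_per_group)) {
    n <- samples_per_group[[sp]]
    if (!all(c("control", "stress") %in% names(n)) ||
        n[["control"]] < 2 || n[["stress"]] < 2) {
      rlang::abort(sprintf(
        "configuration error: `samples_per_group$%s` needs >= 2 control and stress samples", sp))
    }
  }
  structure(cfg, class = "sim_config")
}

species_prefix <- c(human = "HG", rat = "RG", zebrafish = "ZG")

#' Simulate the full three-species count study
#'
#' Draws the ortholog map, the planted truth and negative-binomial count
#' matrices for all species/groups. Log2 means are additive: baseline +
#' species offset + group effect; conserved-DE genes shift by plus/minus
#' `conserved_l2fc_magnitude` in stress in all species with a shared sign
#' (through the ortholog map), species-specific DE genes shift only in their
#' species, and in stress_drug the rescued fraction of conserved effects is
#' reverted to baseline. Fully reproducible from the seed; each
#' sub-generator uses its own derived stream so downstream draws do not
#' shift when another stage's size changes.
#'
#' @param config a [sim_config()].
#' @return A `study_bundle` list: `counts` (named list of count tibbles),
#'   `metadata` (tibble `sample`, `species`, `group`), `ortholog_raw` (raw
#'   records tibble), `truth` (planted ground truth), `log2_mu` (the exact
#'   per-gene log2 means used per species and group, for verifying the
#'   sampler's moments) and `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  ng <- config$n_genes
  species <- c("human", "rat", "zebrafish")
  ids <- lapply(species, function(sp) sprintf("%s%05d", species_prefix[[sp]], seq_len(ng)))
  names(ids) <- species

  ortholog_raw <- with_stream(config$seed, "orthologs", {
    rows <- list(
      tibble::tibble(group_id = sprintf("GRP%05d", seq_len(ng)),
                     species = "human", gene_id = ids$human, similarity = 1),
      tibble::tibble(group_id = sprintf("GRP%05d", seq_len(ng)),
                     species = "rat", gene_id = ids$rat,
                     similarity = round(runif(ng, 0.7, 0.99), 4)),
      tibble::tibble(group_id = sprintf("GRP%05d", seq_len(ng)),
                     species = "zebrafish", gene_id = ids$zebrafish,
                     similarity = round(runif(ng, 0.7, 0.99), 4))
    )
    n_dup <- round(config$paralog_dup_frac * ng)
    if (n_dup > 0) {
      di <- sample.int(ng, n_dup)
      # the duplicate is strictly less similar than the primary candidate
      prim <- rows[[3]]$similarity[di]
      rows[[4]] <- tibble::tibble(
        group_id = sprintf("GRP%05d", di),
        species = "zebrafish",
        gene_id = paste0(ids$zebrafish[di], "b"),
        similarity = round(prim - runif(n_dup, 0.05, 0.2), 4)
      )
    }
    dplyr::arrange(dplyr::bind_rows(rows), .data$group_id, .data$species,
                   .data$gene_id)
  })

  truth <- with_stream(config$seed, "truth", {
    n_cons <- round(config$frac_conserved_de * ng)
    cons_idx <- if (n_cons > 0) sort(sample.int(ng, n_cons)) else integer()
    cons_sign <- if (n_cons > 0) sample(c(-1, 1), n_cons, replace = TRUE) else integer()
    rescued <- if (n_cons > 0) {
      cons_idx[seq_len(round(config$drug_rescue_frac * n_cons))]
    } else integer()
    remaining <- setdiff(seq_len(ng), cons_idx)
    species_de <- list()
    for (sp in species) {
      n_sp <- round(config$frac_species_de * ng)
      pick <- if (n_sp > 0 && length(remaining)) {
        sort(sample(remaining, min(n_sp, length(remaining))))
      } else integer()
      species_de[[sp]] <- tibble::tibble(
        gene = ids[[sp]][pick],
        index = pick,
        sign = if (length(pick)) sample(c(-1, 1), length(pick), replace = TRUE) else integer()
      )
    }
    list(
      conserved_de = tibble::tibble(
        gene = ids$human[cons_idx], index = cons_idx, sign = cons_sign,
        rescued = cons_idx %in% rescued),
      species_de = species_de
    )
  })

  counts <- list()
  metadata <- list()
  log2_mu <- list()
  with_stream(config$seed, "counts", {
    baseline <- rnorm(ng, config$baseline_logmean_mu, config$baseline_logmean_sigma)
    for (sp in species) {
      offset <- rnorm(ng, 0, config$species_offset_sd)
      eff <- numeric(ng)
      if (nrow(truth$conserved_de)) {
        eff[truth$conserved_de$index] <-
          truth$conserved_de$sign * config$conserved_l2fc_magnitude
      }
      sde <- truth$species_de[[sp]]
      if (nrow(sde)) eff[sde$index] <- sde$sign * config$species_l2fc_magnitude
      drug_eff <- eff
      if (nrow(truth$conserved_de)) {
        resc <- truth$conserved_de$index[truth$conserved_de$rescued]
        drug_eff[resc] <- 0
      }
      grp_n <- config$samples_per_group[[sp]]
      cols <- list()
      meta_rows <- list()
      log2_mu[[sp]] <- list()
      for (grp in c("control", "stress", "stress_drug")) {
        n <- if (grp %in% names(grp_n)) grp_n[[grp]] else 0
        if (n == 0) next
        lmu <- baseline + offset +
          switch(grp, control = 0, stress = eff, stress_drug = drug_eff)
        log2_mu[[sp]][[grp]] <- setNames(lmu, ids[[sp]])
        mu <- 2^lmu
        for (j in seq_len(n)) {
          nm <- sprintf("%s_%s_%d", sp, grp, j)
          cols[[nm]] <- rnbinom(ng, mu = mu, size = 1 / config$nb_dispersion)
          meta_rows[[nm]] <- tibble::tibble(sample = nm, species = sp, group = grp)
        }
      }
      counts[[sp]] <- tibble::tibble(gene = ids[[sp]], !!!cols)
      metadata[[sp]] <- dplyr::bind_rows(meta_rows)
    }
  })

  structure(list(
    counts = counts,
    metadata = dplyr::bind_rows(metadata),
    ortholog_raw = ortholog_raw,
    truth = truth,
    log2_mu = log2_mu,
    config = config
  ), class = "study_bundle")
}

#' Simulate a scored PPI network with planted cliques
#'
#' Planted cliques are fully connected; every remaining vertex pair receives
#' an edge independently with probability `p_background`. Edge scores are
#' uniform on \[0.15, 1\]. Cliques flagged ribosomal are named with RPS*/RPL*
#' prefixes unless explicit members are given.
#'
#' @param n_nodes number of background vertices (planted members beyond the
#'   provided node set are added on top).
#' @param planted_cliques list of specs, each `list(size =, ribosomal =)` or
#'   `list(members = c(...), ribosomal =)`.
#' @param p_background background edge probability in \[0, 1).
#' @param seed integer seed.
#' @param node_ids optional vertex names to use (length `n_nodes`).
#' @return List with `edges` (tibble `protein_a`, `protein_b`,
#'   `combined_score`) and `truth` (list with `planted_cliques` tibble).
#' @export
simulate_ppi <- function(n_nodes, planted_cliques = list(),
                         p_background = 0.02, seed = 1L, node_ids = NULL) {
  if (p_background < 0 || p_background >= 1) {
    rlang::abort("`p_background` must lie in [0, 1)")
  }
  with_stream(seed, "ppi", {
    if (is.null(node_ids)) node_ids <- sprintf("P%05d", seq_len(n_nodes))
    stopifnot(length(node_ids) == n_nodes)
    ribo_counter <- 0L
    planted <- purrr::imap(planted_cliques, function(spec, k) {
      ribo <- isTRUE(spec$ribosomal)
      if (!is.null(spec$members)) {
        members <- spec$members
      } else {
        size <- spec$size
        if (size > n_nodes) rlang::abort("planted clique larger than node set")
        if (ribo) {
          members <- sprintf("%s%d", rep(c("RPS", "RPL"), length.out = size),
                             ribo_counter + seq_len(size))
          ribo_counter <<- ribo_counter + size
        } else {
          members <- node_ids[sample.int(n_nodes, size)]
        }
      }
      list(members = sort(members), is_ribosomal = ribo)
    })
    all_members <- unlist(lapply(planted, `[[`, "members"))
    if (anyDuplicated(all_members)) {
      rlang::abort("planted cliques overlap: a vertex may belong to one planted clique only")
    }
    nodes <- union(node_ids, all_members)

    edges <- list()
    for (pc in planted) {
      m <- pc$members
      if (length(m) >= 2) {
        cmb <- utils::combn(m, 2)
        edges[[length(edges) + 1]] <- tibble::tibble(
          protein_a = cmb[1, ], protein_b = cmb[2, ])
      }
    }
    if (p_background > 0 && length(nodes) >= 2) {
      cmb <- utils::combn(nodes, 2)
      keep <- runif(ncol(cmb)) < p_background
      if (any(keep)) {
        edges[[length(edges) + 1]] <- tibble::tibble(
          protein_a = cmb[1, keep], protein_b = cmb[2, keep])
      }
    }
    if (!length(edges)) rlang::abort("simulated network has no edges")
    e <- dplyr::distinct(dplyr::bind_rows(edges))
    e$combined_score <- round(runif(nrow(e), 0.15, 1), 3)
    e <- clean_edges(e, 0)
    list(
      edges = e,
      truth = list(planted_cliques = tibble::tibble(
        members = lapply(planted, `[[`, "members"),
        is_ribosomal = vapply(planted, `[[`, logical(1), "is_ribosomal")
      ))
    )
  })
}

#' Simulate promoter sequences with planted motif sites
#'
#' Background sequence is i.i.d. uniform over ACGT. For genes in
#' `enriched_gene_ids`, `insert_rate` consensus copies per PFM (the
#' per-column majority base) are written at uniform random non-overlapping
#' positions on a uniformly chosen strand, so every planted copy is
#' recoverable by a scanner at any threshold; positions are recorded in the
#' truth.
#'
#' @param gene_ids character vector of promoter identifiers.
#' @param length promoter length in bp (must fit the longest motif).
#' @param pfms named list of [pfm()] objects to plant.
#' @param enriched_gene_ids genes that receive planted sites.
#' @param insert_rate planted copies per enriched gene per PFM.
#' @param seed integer seed.
#' @return List with `sequences` (tibble `gene`, `sequence`) and `truth`
#'   (tibble `gene`, `pfm`, `position`, `strand`).
#' @export
simulate_promoters <- function(gene_ids, length = 500, pfms = list(),
                               enriched_gene_ids = character(),
                               insert_rate = 0, seed = 1L) {
  if (insert_rate < 0) rlang::abort("`insert_rate` must be >= 0")
  widths <- vapply(pfms, `[[`, numeric(1), "width")
  if (base::length(widths) && base::length(enriched_gene_ids) && insert_rate > 0 &&
      max(widths) > length) {
    rlang::abort("motif longer than the promoter sequence")
  }
  with_stream(seed, "promoters", {
    bases <- c("A", "C", "G", "T")
    seqs <- vapply(gene_ids, function(g) {
      paste(sample(bases, length, replace = TRUE), collapse = "")
    }, character(1))
    truth <- list()
    for (g in intersect(enriched_gene_ids, gene_ids)) {
      used <- integer()                       # occupied positions in this promoter
      for (p in pfms) {
        if (insert_rate == 0) next
        consensus <- paste(bases[apply(p$matrix, 2, which.max)], collapse = "")
        for (r in seq_len(insert_rate)) {
          strand <- sample(c("+", "-"), 1)
          site <- if (strand == "-") revcomp(consensus) else consensus
          for (try in 1:50) {
            pos <- sample.int(length - p$width + 1, 1)
            span <- pos:(pos + p$width - 1)
            if (!any(span %in% used)) break
          }
          used <- c(used, span)
          substr(seqs[[g]], pos, pos + p$width - 1) <- site
          truth[[base::length(truth) + 1]] <- tibble::tibble(
            gene = g, pfm = p$id, position = pos, strand = strand)
        }
      }
    }
    list(
      sequences = tibble::tibble(gene = gene_ids, sequence = unname(seqs)),
      truth = if (base::length(truth)) dplyr::bind_rows(truth) else
        tibble::tibble(gene = character(), pfm = character(),
                       position = integer(), strand = character())
    )
  })
}

#' Simulate a small near-consensus PFM library
#'
#' Each motif is a random consensus with heavy majority counts and light
#' off-consensus counts, so that permissive scan thresholds detect planted
#' copies while random background matches stay rare.
#'
#' @param n number of motifs.
#' @param width motif width.
#' @param seed integer seed.
#' @return Named list of [pfm()] objects with ids `PFM1`, `PFM2`, ...
#' @export
simulate_pfms <- function(n = 3, width = 8, seed = 1L) {
  with_stream(seed, "pfms", {
    out <- lapply(seq_len(n), function(k) {
      cons <- sample(1:4, width, replace = TRUE)
      m <- matrix(1, nrow = 4, ncol = width)
      m[cbind(cons, seq_len(width))] <- 17
      rownames(m) <- c("A", "C", "G", "T")
      pfm(sprintf("PFM%d", k), m, name = sprintf("motif_%d", k))
    })
    setNames(out, vapply(out, `[[`, character(1), "id"))
  })
}

#' Simulate a gene-set catalog with planted enriched sets
#'
#' Enriched sets draw most members from the planted conserved-DE genes (so a
#' genuine group shift exists), topped up with random genes; neutral sets
#' are random draws from the universe.
#'
#' @param universe gene identifiers to draw from (human-keyed).
#' @param enriched_pool genes carrying a planted effect.
#' @param n_sets total number of sets.
#' @param n_enriched how many sets are planted as enriched.
#' @param set_size members per set.
#' @param seed integer seed.
#' @return List with `catalog` (tibble `set`, `description`, `genes`) and
#'   `truth` (tibble `set`, `enriched`).
#' @export
simulate_catalog <- function(universe, enriched_pool, n_sets = 20,
                             n_enriched = 5, set_size = 20, seed = 1L) {
  stopifnot(n_enriched <= n_sets, set_size <= length(universe))
  with_stream(seed, "catalog", {
    sets <- lapply(seq_len(n_sets), function(k) {
      if (k <= n_enriched && length(enriched_pool)) {
        core <- sample(enriched_pool, min(length(enriched_pool), ceiling(set_size * 0.75)))
        fill <- sample(setdiff(universe, core), set_size - length(core))
        sort(c(core, fill))
      } else {
        sort(sample(universe, set_size))
      }
    })
    catalog <- tibble::tibble(
      set = sprintf("SET%03d", seq_len(n_sets)),
      description = ifelse(seq_len(n_sets) <= n_enriched,
                           "planted enriched set", "neutral set"),
      genes = sets
    )
    list(catalog = catalog,
         truth = tibble::tibble(set = catalog$set,
                                enriched = seq_len(n_sets) <= n_enriched))
  })
}

#' Assemble every synthetic input the four experiments need
#'
#' Convenience wrapper: simulates the count study, a gene-set catalog with
#' planted enriched sets, a PFM library, per-species promoters with the
#' first PFM planted in DE-gene promoters, and a PPI network over the human
#' gene universe with a planted "responsive" clique made of conserved-DE
#' genes, one ribosomal clique and one neutral clique.
#'
#' @param config a [sim_config()].
#' @param p_background PPI background edge probability.
#' @param promoter_length synthetic promoter length (bp).
#' @param insert_rate planted motif copies per enriched promoter.
#' @return List `bundle`, `catalog`, `pfms`, `promoters` (named list per
#'   species), `ppi` plus the sub-generators' truth records.
#' @export
simulate_inputs <- function(config = sim_config(), p_background = 0.02,
                            promoter_length = 500, insert_rate = 3) {
  bundle <- simulate_study(config)
  table <- resolve_one_to_one(bundle$ortholog_raw)
  universe <- table$human

  cat_sim <- simulate_catalog(
    universe = universe,
    enriched_pool = bundle$truth$conserved_de$gene,
    seed = config$seed
  )

  pfms <- simulate_pfms(n = 3, width = 8, seed = config$seed)
  promoters <- list()
  for (sp in names(bundle$counts)) {
    sp_genes <- bundle$counts[[sp]]$gene
    cons_idx <- bundle$truth$conserved_de$index
    sp_de <- unique(c(sp_genes[cons_idx], bundle$truth$species_de[[sp]]$gene))
    sim <- simulate_promoters(
      gene_ids = sp_genes, length = promoter_length,
      pfms = pfms[1],               # only the first motif is planted
      enriched_gene_ids = sp_de,
      insert_rate = insert_rate,
      seed = stream_seed(config$seed, "promoters") + match(sp, names(bundle$counts))
    )
    promoters[[sp]] <- sim$sequences
  }

  cons <- bundle$truth$conserved_de$gene
  planted <- list()
  if (length(cons) >= 5) {
    planted[[length(planted) + 1]] <- list(
      members = cons[seq_len(min(8, length(cons)))], ribosomal = FALSE)
  }
  planted[[length(planted) + 1]] <- list(size = 10, ribosomal = TRUE)
  planted[[length(planted) + 1]] <- list(size = 6, ribosomal = FALSE)
  ppi <- simulate_ppi(
    n_nodes = length(universe), planted_cliques = planted,
    p_background = p_background, seed = config$seed, node_ids = universe
  )

  list(
    bundle = bundle,
    ortholog_table = table,
    catalog = cat_sim$catalog,
    catalog_truth = cat_sim$truth,
    pfms = pfms,
    promoters = promoters,
    ppi = ppi
  )
}

#' Write a study bundle's inputs to disk in the standard formats
#'
#' Counts and metadata as TSV, raw ortholog records as TSV, truth as JSON.
#'
#' @param bundle a `study_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(bundle$counts)) {
    write_counts(bundle$counts[[sp]], file.path(dir, paste0("counts_", sp, ".tsv")))
  }
  readr::write_tsv(bundle$metadata, file.path(dir, "metadata.tsv"), progress = FALSE)
  readr::write_tsv(bundle$ortholog_raw, file.path(dir, "orthologs.tsv"),
                   progress = FALSE)
  truth <- list(
    conserved_de = bundle$truth$conserved_de,
    species_de = bundle$truth$species_de
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"), dataframe = "rows")
  invisible(dir)
}
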