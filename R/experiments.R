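#' Venn-style overlap counts for per-species item lists
#'
#' @param lists named list of character vectors (one per species).
#' @return Tibble of region counts: per-species totals, pairwise
#'   intersections and the triple intersection.
#' @export
overlap_counts <- function(lists) {
  sp <- names(lists)
  rows <- list()
  for (s in sp) {
    rows[[length(rows) + 1]] <- tibble::tibble(region = s, n = length(unique(lists[[s]])))
  }
  if (length(sp) >= 2) {
    prs <- utils::combn(sp, 2, simplify = FALSE)
    for (pr in prs) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        region = paste(pr, collapse = "&"),
        n = length(intersect(lists[[pr[1]]], lists[[pr[2]]])))
    }
  }
  if (length(sp) >= 3) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      region = paste(sp, collapse = "&"),
      n = length(purrr::reduce(lists, intersect)))
  }
  dplyr::bind_rows(rows)
}

species_counts_groups <- function(bundle, sp, groups = c("control", "stress")) {
  meta <- dplyr::filter(bundle$metadata, .data$species == sp,
                        .data$group %in% groups)
  counts <- bundle$counts[[sp]][, c("gene", meta$sample), drop = FALSE]
  list(counts = counts, meta = meta[, c("sample", "group")])
}

#' Experiment 1: direct per-species comparisons
#'
#' For each species independently: low-count filter, NB-Wald differential
#' expression (stress vs control), gene-set enrichment in up/down/both
#' modes, and the TFBS high- versus low-variability contrast. DE gene lists
#' are translated to the human ortholog namespace and compared by Venn
#' counts, as are significant set names and significant TFBS identifiers.
#'
#' @param bundle `study_bundle` from [simulate_study()].
#' @param catalog human-keyed gene-set catalog.
#' @param pfms named PFM list.
#' @param promoters named list (per species) of promoter tibbles.
#' @param fdr significance threshold on adjusted p-values.
#' @param use_adjusted call DE genes on `padj` (default) or raw `p`.
#' @param min_counts low-count filter threshold.
#' @param ... passed to [tfbs_run()].
#' @return An `experiment_report` list.
#' @export
experiment1 <- function(bundle, catalog = NULL, pfms = NULL, promoters = NULL,
                        fdr = 0.05, use_adjusted = TRUE, min_counts = 10, ...) {
  table <- resolve_one_to_one(bundle$ortholog_raw)
  species <- names(bundle$counts)
  de <- list(); gsea <- list(); tfbs <- list()
  de_human <- list(); sig_sets <- list(); sig_tfbs <- list()
  for (sp in species) {
    cg <- species_counts_groups(bundle, sp)
    counts <- filter_low_counts(cg$counts, min_counts)
    de[[sp]] <- nb_wald(counts, cg$meta, reference = "control")
    crit <- if (use_adjusted) de[[sp]]$padj else de[[sp]]$p
    sig_genes <- de[[sp]]$gene[crit < fdr]
    de_human[[sp]] <- map_gene_ids(sig_genes, table, sp)

    if (!is.null(catalog)) {
      sp_catalog <- translate_catalog(catalog, table, sp)
      gsea[[sp]] <- run_catalog(counts, cg$meta, sp_catalog)
      sig_sets[[sp]] <- unique(gsea[[sp]]$set[gsea[[sp]]$padj < fdr])
    }
    if (!is.null(pfms) && !is.null(promoters)) {
      tfbs[[sp]] <- tfbs_run(de[[sp]], promoters[[sp]], pfms, ...)
      sig_tfbs[[sp]] <- tfbs[[sp]]$pfm[tfbs[[sp]]$significant]
    }
  }
  structure(list(
    experiment = 1L,
    de = de,
    gsea = if (length(gsea)) gsea else NULL,
    tfbs = if (length(tfbs)) tfbs else NULL,
    de_genes_human = de_human,
    venn = list(
      de_genes = overlap_counts(de_human),
      sets = if (length(sig_sets)) overlap_counts(sig_sets) else NULL,
      tfbs = if (length(sig_tfbs)) overlap_counts(sig_tfbs) else NULL
    ),
    config = bundle$config
  ), class = "experiment_report")
}

# translate significant species gene ids to human anchors (unmapped dropped)
map_gene_ids <- function(genes, table, species) {
  idx <- match(genes, table[[species]])
  table$human[idx[!is.na(idx)]]
}

# re-key a human catalog into a species' gene namespace
translate_catalog <- function(catalog, table, species) {
  if (species == "human") return(catalog)
  lut <- setNames(table[[species]], table$human)
  out <- catalog
  out$genes <- lapply(catalog$genes, function(g) {
    m <- lut[g]
    unname(m[!is.na(m)])
  })
  out
}

#' Experiment 2: pooled cross-species analysis
#'
#' Maps every species' counts to the human ortholog namespace, concatenates
#' the samples into one matrix, and contrasts the pooled stress/disease
#' samples against the pooled controls with the same DE and enrichment
#' machinery. Also returns the PCA of the samples on centered log2
#' normalized counts, which exposes the species-dominated variance
#' structure.
#'
#' @inheritParams experiment1
#' @param catalog optional human-keyed catalog for pooled enrichment.
#' @return An `experiment_report` list with `de`, `gsea`, `pca`.
#' @export
experiment2 <- function(bundle, catalog = NULL, fdr = 0.05, min_counts = 10) {
  table <- resolve_one_to_one(bundle$ortholog_raw)
  mapped <- lapply(names(bundle$counts), function(sp) {
    cg <- species_counts_groups(bundle, sp)
    map_to_human(cg$counts, table, sp)
  })
  names(mapped) <- names(bundle$counts)
  common <- purrr::reduce(lapply(mapped, function(m) m$gene), intersect)
  if (!length(common)) rlang::abort("empty ortholog intersection across species")
  pooled <- purrr::reduce(
    lapply(mapped, function(m) m[match(common, m$gene), , drop = FALSE]),
    function(a, b) dplyr::bind_cols(a, b[, -1, drop = FALSE]))
  meta <- dplyr::filter(bundle$metadata, .data$sample %in% sample_names(pooled))
  meta$group <- ifelse(meta$group == "control", "control", "stress")

  pooled_f <- filter_low_counts(pooled, min_counts)
  de <- nb_wald(pooled_f, meta[, c("sample", "group")], reference = "control")
  gsea <- if (!is.null(catalog)) {
    run_catalog(pooled_f, meta[, c("sample", "group")], catalog)
  } else NULL

  ly <- t(log2(normalize_counts(pooled_f) + 1))
  pc <- stats::prcomp(ly, center = TRUE, scale. = FALSE)
  var_expl <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- tibble::as_tibble(pc$x[, 1:2, drop = FALSE], rownames = "sample") |>
    dplyr::left_join(bundle$metadata, by = "sample")

  structure(list(
    experiment = 2L,
    de = de, gsea = gsea,
    pca = list(scores = scores, var_explained = var_expl[1:2]),
    n_genes = nrow(pooled_f),
    config = bundle$config
  ), class = "experiment_report")
}

#' Experiment 3: per-species analyses combined by Fisher meta-analysis
#'
#' Maps counts to the human namespace, runs the per-species DE (and
#' optionally set enrichment) on the ortholog-restricted matrices, then
#' combines per-species p-values per gene (and per set) with Fisher's
#' method, flagging direction-concordant items. When PPI edges are supplied,
#' a hub table is computed on the subgraph induced by meta-significant genes
#' after excluding genes with mixed expression direction, keeping vertices
#' highly ranked by at least two hub metrics.
#'
#' @inheritParams experiment2
#' @param ppi_edges optional edge tibble for the hub analysis.
#' @param min_score PPI score threshold.
#' @return An `experiment_report` list with `de`, `meta_genes`,
#'   `concordant_genes`, optional `gsea`/`meta_sets` and `hubs`.
#' @export
experiment3 <- function(bundle, catalog = NULL, ppi_edges = NULL, fdr = 0.05,
                        min_counts = 10, min_score = 0.15) {
  table <- resolve_one_to_one(bundle$ortholog_raw)
  species <- names(bundle$counts)
  de <- list(); gsea <- list()
  for (sp in species) {
    cg <- species_counts_groups(bundle, sp)
    counts <- filter_low_counts(map_to_human(cg$counts, table, sp), min_counts)
    de[[sp]] <- nb_wald(counts, cg$meta, reference = "control")
    if (!is.null(catalog)) {
      gsea[[sp]] <- run_catalog(counts, cg$meta, catalog)
    }
  }
  meta_genes <- meta_table(de, join_key = "gene", effect_col = "l2fc")
  concordant <- meta_genes$gene[meta_genes$padj < fdr & meta_genes$concordant]

  meta_sets <- NULL
  if (!is.null(catalog)) {
    both <- lapply(gsea, function(g) dplyr::filter(g, .data$mode == "both"))
    meta_sets <- meta_table(both, join_key = "set", effect_col = "mean_stat")
  }

  hubs <- NULL
  if (!is.null(ppi_edges)) {
    sig <- meta_genes$gene[meta_genes$padj < fdr]
    keep <- setdiff(sig, meta_genes$gene[!meta_genes$concordant])
    g <- build_graph(ppi_edges, min_score)
    keep <- intersect(keep, igraph::V(g)$name)
    if (length(keep) >= 4) {
      sub <- igraph::induced_subgraph(g, keep)
      sc <- hub_scores(sub)
      hubs <- hub_consensus(sc, top_n = 10, min_methods = 2)
    }
  }

  structure(list(
    experiment = 3L,
    de = de, gsea = if (length(gsea)) gsea else NULL,
    meta_genes = meta_genes,
    concordant_genes = concordant,
    meta_sets = meta_sets,
    hubs = hubs,
    config = bundle$config
  ), class = "experiment_report")
}

#' Experiment 4: maximal-clique gene sets and hub proteins
#'
#' Builds the PPI graph over the ortholog universe, enumerates maximal
#' cliques, drops ribosomal cliques, and uses the survivors as gene sets for
#' per-species bidirectional enrichment on human-mapped counts. Per-clique
#' p-values are combined across species by Fisher's method; members of the
#' meta-significant cliques form the "conserved set", which is then (a)
#' tested as a whole per species in the stress and antidepressant contrasts,
#' (b) reduced to genes with strictly concordant fold-change direction in
#' all species, over which hub scores and the DMNC-then-MNC double screen
#' are computed, and (c) ranked by fold change, intersecting each species'
#' top over- and under-expressed members.
#'
#' @inheritParams experiment3
#' @param ppi_edges edge tibble covering the ortholog gene universe.
#' @param min_size minimal clique size used as a gene set.
#' @param top_l2fc how many over- and under-expressed genes per species
#'   enter the conserved top-gene intersection.
#' @return An `experiment_report` list.
#' @export
experiment4 <- function(bundle, ppi_edges, fdr = 0.05, min_counts = 10,
                        min_score = 0.15, min_size = 3, top_l2fc = 10) {
  table <- resolve_one_to_one(bundle$ortholog_raw)
  species <- names(bundle$counts)

  g <- build_graph(ppi_edges, min_score)
  cliques <- maximal_cliques(g, min_size = min_size)
  kept <- filter_ribosomal(cliques)
  fractions <- clique_fraction_summary(nrow(cliques), nrow(kept))
  catalog <- cliques_to_catalog(kept)

  mapped <- list(); meta_sp <- list(); de <- list(); gsea <- list()
  for (sp in species) {
    cg <- species_counts_groups(bundle, sp, groups = c("control", "stress", "stress_drug"))
    mc <- filter_low_counts(map_to_human(cg$counts, table, sp), min_counts)
    mapped[[sp]] <- mc
    meta_sp[[sp]] <- cg$meta
    stress <- dplyr::filter(cg$meta, .data$group %in% c("control", "stress"))
    sub <- mc[, c("gene", stress$sample), drop = FALSE]
    de[[sp]] <- nb_wald(sub, stress, reference = "control")
    gsea[[sp]] <- run_catalog(sub, stress, catalog, modes = "both")
  }

  meta_cliques <- meta_table(gsea, join_key = "set", effect_col = "mean_stat")
  sig_cliques <- meta_cliques$set[meta_cliques$padj < fdr]
  if (!length(sig_cliques)) {
    rlang::warn("no meta-significant clique; downstream sections are empty")
  }
  conserved_set <- sort(unique(unlist(
    catalog$genes[catalog$set %in% sig_cliques])))

  # proof of concept: the conserved set as one gene set, per species,
  # in the stress contrast and (where a drug group exists) drug vs stress
  # `direction` is the contrast's alignment with each member gene's own
  # stress-response direction: +1 when the contrast moves the set the same
  # way stress did, -1 when it reverses it. A mixed-sign set has no single
  # up/down direction, so alignment is the meaningful signed summary.
  poc <- list()
  if (length(conserved_set) >= 3) {
    for (sp in species) {
      mc <- mapped[[sp]]
      meta <- meta_sp[[sp]]
      stress <- dplyr::filter(meta, .data$group %in% c("control", "stress"))
      s_stat <- per_gene_stat(mc[, c("gene", stress$sample)], stress)
      inset <- s_stat$gene %in% conserved_set
      ref_sign <- sign(s_stat$stat[inset])
      row <- set_test(s_stat, conserved_set, mode = "both")
      row$contrast <- "stress_vs_control"
      row$direction <- sign(sum(s_stat$stat[inset] * ref_sign))
      poc[[length(poc) + 1]] <- dplyr::mutate(row, species = sp)
      drug <- dplyr::filter(meta, .data$group %in% c("stress", "stress_drug"))
      if (dplyr::n_distinct(drug$group) == 2 && all(table(drug$group) >= 2)) {
        d_stat <- per_gene_stat(mc[, c("gene", drug$sample)], drug,
                                reference = "stress")
        drow <- set_test(d_stat, conserved_set, mode = "both")
        drow$contrast <- "drug_vs_stress"
        drow$direction <- sign(sum(d_stat$stat[inset] * ref_sign))
        poc[[length(poc) + 1]] <- dplyr::mutate(drow, species = sp)
      }
    }
  }
  poc <- if (length(poc)) dplyr::bind_rows(poc) else NULL

  # unidirectional filter: strictly same-sign l2fc in all species
  uni <- character()
  if (length(conserved_set)) {
    l2 <- vapply(de, function(d) {
      d$l2fc[match(conserved_set, d$gene)]
    }, numeric(length(conserved_set)))
    if (is.null(dim(l2))) l2 <- matrix(l2, nrow = length(conserved_set))
    ok <- apply(l2, 1, function(x) all(!is.na(x)) && (all(x > 0) || all(x < 0)))
    uni <- conserved_set[ok]
  }

  hubs <- NULL
  if (length(uni) >= 4) {
    members <- intersect(uni, igraph::V(g)$name)
    if (length(members) >= 4) {
      sub <- igraph::induced_subgraph(g, members)
      hubs <- hub_scores(sub)
    }
  }

  # conserved top fold-change genes across species
  top_genes <- NULL
  if (length(uni)) {
    per_sp <- lapply(de, function(d) {
      dd <- d[d$gene %in% uni, , drop = FALSE]
      dd <- dd[order(dd$l2fc), ]
      up <- utils::tail(dd$gene, top_l2fc)
      dn <- utils::head(dd$gene, top_l2fc)
      union(up, dn)
    })
    top_genes <- sort(purrr::reduce(per_sp, intersect))
  }

  structure(list(
    experiment = 4L,
    clique_summary = fractions,
    n_cliques_total = nrow(cliques),
    n_cliques_kept = nrow(kept),
    cliques = kept,
    de = de, gsea = gsea,
    meta_cliques = meta_cliques,
    significant_cliques = sig_cliques,
    conserved_set = conserved_set,
    proof_of_concept = poc,
    unidirectional_genes = uni,
    hubs = hubs,
    top_l2fc_genes = top_genes,
    config = bundle$config
  ), class = "experiment_report")
}

#' Run the full four-experiment study on synthetic inputs
#'
#' @param config a [sim_config()].
#' @param ... passed to [simulate_inputs()].
#' @return Named list `inputs`, `exp1`, `exp2`, `exp3`, `exp4`.
#' @export
run_study <- function(config = sim_config(), ...) {
  inputs <- simulate_inputs(config, ...)
  list(
    inputs = inputs,
    exp1 = experiment1(inputs$bundle, inputs$catalog, inputs$pfms,
                       inputs$promoters),
    exp2 = experiment2(inputs$bundle, catalog = inputs$catalog),
    exp3 = experiment3(inputs$bundle, catalog = inputs$catalog,
                       ppi_edges = inputs$ppi$edges),
    exp4 = experiment4(inputs$bundle, inputs$ppi$edges)
  )
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> experiment %d\n", x$experiment))
  for (nm in setdiff(names(x), c("experiment", "config"))) {
    obj <- x[[nm]]
    desc <- if (is.data.frame(obj)) sprintf("%d rows" , nrow(obj))
    else if (is.list(obj)) sprintf("%d elements", length(obj))
    else if (is.character(obj)) sprintf("%d items", length(obj))
    else class(obj)[1]
    cat(sprintf("  $%s: %s\n", nm, desc))
  }
  invisible(x)
}
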