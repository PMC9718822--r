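# one moderately sized default study reused across blocks
study <- NULL
get_study <- function() {
  if (is.null(study)) {
    study <<- run_study(sim_config(seed = 51))
  }
  study
}

test_that("per-species reports are internally consistent", {
  st <- get_study()
  e1 <- st$exp1
  # Venn counts equal recomputed intersections of the emitted lists
  lists <- e1$de_genes_human
  v <- e1$venn$de_genes
  expect_equal(v$n[v$region == "human"], length(unique(lists$human)))
  expect_equal(v$n[v$region == "human&rat"],
               length(intersect(lists$human, lists$rat)))
  expect_equal(v$n[v$region == "human&rat&zebrafish"],
               length(Reduce(intersect, lists)))
  # planted conserved sets surface in every species' significant GSEA list
  planted <- st$inputs$catalog_truth$set[st$inputs$catalog_truth$enriched]
  for (sp in names(e1$gsea)) {
    sig <- unique(e1$gsea[[sp]]$set[e1$gsea[[sp]]$padj < 0.05])
    expect_gte(mean(planted %in% sig), 0.8)
  }
})

test_that("null bundles give chance-level three-way DE overlap", {
  hits <- vapply(1:8, function(s) {
    b <- simulate_study(sim_config(n_genes = 200, frac_conserved_de = 0,
                                   frac_species_de = 0, seed = 60 + s))
    e1 <- experiment1(b)
    v <- e1$venn$de_genes
    v$n[v$region == "human&rat&zebrafish"]
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.85)
})

test_that("pooled analysis separates species, not groups, and PCA is sound", {
  skip_if_not_installed("cluster")
  st <- get_study()
  e2 <- st$exp2
  sc <- e2$pca$scores
  d <- dist(as.matrix(sc[, c("PC1", "PC2")]))
  sil_sp <- mean(cluster::silhouette(as.integer(factor(sc$species)), d)[, 3])
  sil_gr <- mean(cluster::silhouette(as.integer(factor(sc$group)), d)[, 3])
  expect_gt(sil_sp, sil_gr)

  # principal component scores are orthogonal
  expect_lt(abs(sum(sc$PC1 * sc$PC2)), 1e-8)

  # with no species offsets and the conserved effect intact, pooled DE
  # recovers the planted genes
  cfg0 <- sim_config(n_genes = 300, species_offset_sd = 0, seed = 52)
  b0 <- simulate_study(cfg0)
  e2b <- experiment2(b0)
  called <- e2b$de$gene[e2b$de$padj < 0.05]
  expect_gte(mean(b0$truth$conserved_de$gene %in% called), 0.7)
})

test_that("meta-analysis experiment recovers truth and applies the hub rule", {
  st <- get_study()
  e3 <- st$exp3
  truth <- st$inputs$bundle$truth$conserved_de$gene
  called <- e3$concordant_genes
  expect_gte(mean(truth %in% called), 0.7)

  # species-specific genes are mostly kept out of the concordant list
  sp_de <- unlist(lapply(st$inputs$bundle$truth$species_de, function(x) x$index))
  sp_human <- st$inputs$bundle$counts$human$gene[sp_de]
  expect_gte(mean(!(sp_human %in% called)), 0.5)

  # hub table only contains nodes top-10 by at least two metrics
  if (!is.null(e3$hubs) && nrow(e3$hubs)) {
    expect_true(all(e3$hubs$n_methods >= 2))
  }
})

test_that("clique experiment obeys its own filters and bookkeeping", {
  st <- get_study()
  e4 <- st$exp4
  # fraction summary consistent with the clique set itself
  expect_equal(e4$clique_summary$kept_pct,
               100 * nrow(e4$cliques) / e4$n_cliques_total)
  expect_equal(e4$clique_summary$kept_pct + e4$clique_summary$removed_pct, 100)
  # no surviving clique touches a ribosomal symbol
  expect_false(any(vapply(e4$cliques$members,
                          function(m) any(grepl("^(RPS|RPL)[0-9]", m)),
                          logical(1))))
  # unidirectional genes are conserved-set members with same-sign l2fc
  expect_true(all(e4$unidirectional_genes %in% e4$conserved_set))
  for (g in e4$unidirectional_genes) {
    l2 <- vapply(e4$de, function(d) d$l2fc[d$gene == g], numeric(1))
    expect_true(all(l2 > 0) || all(l2 < 0))
  }
  # top fold-change genes come from the unidirectional set
  expect_true(all(e4$top_l2fc_genes %in% e4$unidirectional_genes))
  # the planted responsive clique reaches meta-significance
  planted <- st$inputs$ppi$truth$planted_cliques
  resp <- planted$members[[which(!planted$is_ribosomal)[1]]]
  sig_members <- e4$cliques$members[e4$cliques$clique_id %in% e4$significant_cliques]
  hit <- any(vapply(sig_members, function(m) setequal(m, resp), logical(1)))
  expect_true(hit)
})

test_that("experiments are deterministic end to end", {
  cfg <- sim_config(n_genes = 150, seed = 53)
  b <- simulate_study(cfg)
  r1 <- experiment3(b)
  r2 <- experiment3(b)
  expect_equal(r1$meta_genes, r2$meta_genes, tolerance = 1e-12)
  expect_identical(r1$concordant_genes, r2$concordant_genes)
})
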