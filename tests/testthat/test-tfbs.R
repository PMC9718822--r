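one_hot_pfm <- function(consensus, id = "OH") {
  b <- c(A = 1, C = 2, G = 3, T = 4)
  m <- matrix(0, 4, nchar(consensus))
  idx <- b[strsplit(consensus, "")[[1]]]
  m[cbind(idx, seq_len(ncol(m)))] <- 100
  rownames(m) <- names(b)
  pfm(id, m)
}

test_that("gene strata follow the strict p-value thresholds", {
  de <- tibble::tibble(gene = c("g1", "g2", "g3"),
                       p = c(0.005, 0.5, 0.9))
  s <- stratify_genes(de)
  expect_equal(s$foreground, "g1")
  expect_equal(s$background, "g3")
  # boundary exactly at the threshold is excluded
  de2 <- tibble::tibble(gene = c("g1", "g2"), p = c(0.01, 0.9))
  expect_error(stratify_genes(de2), "p < 0.01")
  expect_error(stratify_genes(tibble::tibble(gene = "g", p = 0.5)), "p <")
})

test_that("promoter windows obey coordinates, clipping and strand", {
  set.seed(15)
  contig <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
                  collapse = "")
  genome <- c(chr1 = contig)
  w <- promoter_window(tibble::tibble(gene = "g1", contig = "chr1",
                                      tss = 2000, strand = "+"), genome)
  expect_equal(w$sequence, substr(contig, 501, 2500))
  expect_equal(nchar(w$sequence), 2000)

  # clipped at the contig start
  w2 <- promoter_window(tibble::tibble(gene = "g2", contig = "chr1",
                                       tss = 100, strand = "+"), genome)
  expect_equal(nchar(w2$sequence), 600)
  expect_equal(w2$sequence, substr(contig, 1, 600))

  # minus strand: reverse complement of the mirrored interval
  w3 <- promoter_window(tibble::tibble(gene = "g3", contig = "chr1",
                                       tss = 5000, strand = "-"), genome)
  mirrored <- substr(contig, 5000 - 500 + 2, 5000 + 1500 + 1)
  expect_equal(w3$sequence, orthometa:::revcomp(mirrored))

  expect_error(promoter_window(tibble::tibble(gene = "g", contig = "chr1",
                                              tss = 10000, strand = "+"),
                               genome), "outside")
})

test_that("scanner counts planted and background sites correctly", {
  p <- one_hot_pfm("ACGTACGT")
  expect_gte(scan_pfm(paste0("TTTT", "ACGTACGT", "TTTT"), p, 1), 1)
  expect_equal(scan_pfm("", p, 1), 0)
  expect_equal(scan_pfm("ACG", p, 1), 0)

  # reverse complement invariance
  set.seed(16)
  s <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")
  expect_equal(scan_pfm(s, p, 0.8), scan_pfm(orthometa:::revcomp(s), p, 0.8))

  # background rate of an exact 8-mer on both strands: 2 (L - 7) / 4^8
  set.seed(17)
  L <- 10000
  counts <- replicate(100, {
    seq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    scan_pfm(seq, p, 1)
  })
  n_pos <- 2 * (L - 7) * 100
  expected <- n_pos * 4^-8
  sd3 <- 3 * sqrt(n_pos * 4^-8 * (1 - 4^-8))
  expect_lt(abs(sum(counts) - expected), sd3)
})

test_that("dual-criterion contrast reproduces the hypergeometric worked case", {
  fg <- c(rep(1, 9), 0)        # 9 of 10 covered
  bg <- c(1, rep(0, 9))        # 1 of 10 covered
  res <- tfbs_contrast(fg, bg)
  expect_equal(res$coverage_p, 202 / 184756, tolerance = 1e-10)
  expect_gt(res$log2_enrichment, 0)

  # identical strata: no enrichment, not significant
  same <- c(0, 1, 2, 0, 1)
  res2 <- tfbs_contrast(same, same)
  expect_equal(res2$log2_enrichment, 0)
  expect_false(res2$significant)
  expect_gt(res2$coverage_p, 0.99)

  # swapping strata negates the enrichment, p-values unchanged
  set.seed(18)
  a <- rpois(20, 2); b <- rpois(25, 0.5)
  fwd <- tfbs_contrast(a, b); rev <- tfbs_contrast(b, a)
  expect_equal(fwd$log2_enrichment, -rev$log2_enrichment)
  expect_equal(fwd$coverage_p, rev$coverage_p)
  expect_equal(fwd$distribution_p, rev$distribution_p)

  expect_error(tfbs_contrast(c(1, 2), c(0, 1, 2)), ">= 3")
})

test_that("planted motifs are flagged by the full TFBS contrast", {
  pfms <- simulate_pfms(n = 3, width = 8, seed = 19)
  genes <- sprintf("g%03d", 1:60)
  enriched <- genes[1:20]
  sim <- simulate_promoters(genes, length = 400, pfms = pfms[1],
                            enriched_gene_ids = enriched, insert_rate = 3,
                            seed = 19)
  # scanner finds at least the planted copies at a permissive threshold
  hits <- scan_pfm(sim$sequences$sequence[1], pfms[[1]], 0.8)
  expect_gte(hits, 3)

  de <- tibble::tibble(gene = genes,
                       p = c(rep(0.001, 20), rep(0.9, 40)))
  res <- tfbs_run(de, sim$sequences, pfms)
  planted <- res[res$pfm == "PFM1", ]
  expect_true(planted$significant)
  expect_gt(planted$log2_enrichment, 0)
  # non-planted motifs are not systematically flagged
  expect_lte(sum(res$significant[res$pfm != "PFM1"]), 1)
})
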