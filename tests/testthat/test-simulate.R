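test_that("configuration invariants are enforced with named errors", {
  expect_error(sim_config(frac_conserved_de = 1.2), "frac_conserved_de")
  expect_error(sim_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(sim_config(samples_per_group = list(
    human = c(control = 1, stress = 3, stress_drug = 0),
    rat = c(control = 3, stress = 3, stress_drug = 3),
    zebrafish = c(control = 6, stress = 6, stress_drug = 6))),
    "human")
})

test_that("simulation is deterministic and stream-stable", {
  cfg <- sim_config(n_genes = 60, seed = 41)
  b1 <- simulate_study(cfg)
  b2 <- simulate_study(cfg)
  expect_identical(b1, b2)

  p1 <- simulate_ppi(30, list(list(size = 4, ribosomal = FALSE)),
                     p_background = 0.1, seed = 41)
  p2 <- simulate_ppi(30, list(list(size = 4, ribosomal = FALSE)),
                     p_background = 0.1, seed = 41)
  expect_identical(p1, p2)

  pfms <- simulate_pfms(seed = 41)
  s1 <- simulate_promoters(paste0("g", 1:5), 200, pfms[1], "g1", 2, seed = 41)
  s2 <- simulate_promoters(paste0("g", 1:5), 200, pfms[1], "g1", 2, seed = 41)
  expect_identical(s1, s2)
})

test_that("negative-binomial sampler hits the planted moments", {
  # many samples per group so empirical moments are tight
  cfg <- sim_config(
    n_genes = 200, seed = 42,
    samples_per_group = list(human = c(control = 1500, stress = 2, stress_drug = 0),
                             rat = c(control = 2, stress = 2, stress_drug = 0),
                             zebrafish = c(control = 2, stress = 2, stress_drug = 0)),
    species_offset_sd = 1
  )
  b <- simulate_study(cfg)
  meta <- dplyr::filter(b$metadata, species == "human", group == "control")
  m <- counts_matrix(b$counts$human)[, meta$sample]
  mu <- 2^b$log2_mu$human$control
  a <- cfg$nb_dispersion
  # pick genes with mean near 100 so the relative tolerance is meaningful
  pick <- which(mu > 50 & mu < 500)[1:20]
  emp_mean <- rowMeans(m[pick, ])
  emp_var <- apply(m[pick, ], 1, var)
  expect_true(all(abs(emp_mean - mu[pick]) / mu[pick] < 0.05))
  theo_var <- mu[pick] + a * mu[pick]^2
  expect_true(all(abs(emp_var - theo_var) / theo_var < 0.35))
  expect_lt(abs(mean(emp_var / theo_var) - 1), 0.05)
})

test_that("null configuration yields empty truth and uniform p-values", {
  cfg <- sim_config(n_genes = 300, frac_conserved_de = 0, frac_species_de = 0,
                    seed = 43)
  b <- simulate_study(cfg)
  expect_equal(nrow(b$truth$conserved_de), 0)
  expect_true(all(vapply(b$truth$species_de, nrow, integer(1)) == 0))
  meta <- dplyr::filter(b$metadata, species == "zebrafish",
                        group %in% c("control", "stress"))
  counts <- filter_low_counts(b$counts$zebrafish[, c("gene", meta$sample)])
  de <- nb_wald(counts, meta[, c("sample", "group")])
  expect_gt(stats::ks.test(de$p, "punif")$p.value, 0.001)
})

test_that("every conserved gene is mappable in all three species", {
  b <- simulate_study(sim_config(n_genes = 120, seed = 44))
  tab <- resolve_one_to_one(b$ortholog_raw)
  cons <- b$truth$conserved_de$gene
  expect_true(all(cons %in% tab$human))
  for (sp in c("human", "rat", "zebrafish")) {
    mapped <- map_to_human(b$counts[[sp]], tab, sp)
    expect_true(all(cons %in% mapped$gene))
  }
  # zebrafish paralog duplicates exist and always lose to the primary
  dups <- b$ortholog_raw |>
    dplyr::filter(species == "zebrafish") |>
    dplyr::count(group_id) |>
    dplyr::filter(n > 1)
  expect_gt(nrow(dups), 0)
  expect_false(any(grepl("b$", tab$zebrafish)))
})

test_that("PPI simulation plants cliques and matches the edge budget", {
  sim <- simulate_ppi(30, list(list(size = 5, ribosomal = FALSE)),
                      p_background = 0, seed = 45)
  cl <- maximal_cliques(build_graph(sim$edges, 0), 3)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$size, 5)

  # realized background edges within 3 binomial SDs of expectation
  n_pair <- choose(50, 2)
  counts <- vapply(1:10, function(s) {
    nrow(simulate_ppi(50, list(), p_background = 0.1, seed = s)$edges)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 0.1 * n_pair),
            3 * sqrt(n_pair * 0.1 * 0.9 / 10))

  ribo <- simulate_ppi(20, list(list(size = 6, ribosomal = TRUE)),
                       p_background = 0, seed = 46)
  members <- ribo$truth$planted_cliques$members[[1]]
  expect_true(all(grepl("^(RPS|RPL)", members)))

  expect_error(simulate_ppi(20, list(list(members = c("X", "Y", "Z")),
                                     list(members = c("Z", "W", "V"))),
                            p_background = 0, seed = 1), "overlap")
})

test_that("promoter simulation plants sites and respects the background rate", {
  pfms <- simulate_pfms(seed = 47)
  expect_error(simulate_promoters("g1", length = 5, pfms = pfms[1],
                                  enriched_gene_ids = "g1", insert_rate = 1,
                                  seed = 1), "longer")
  # planted copies recorded in the truth and findable by the scanner
  sim <- simulate_promoters(paste0("g", 1:10), 300, pfms[1], "g3", 3, seed = 48)
  expect_equal(sum(sim$truth$gene == "g3"), 3)
  expect_gte(scan_pfm(sim$sequences$sequence[3], pfms[[1]], 0.85), 3)

  # with no insertions an exact-match one-hot scan stays at the uniform rate
  b <- c(A = 1, C = 2, G = 3, T = 4)
  oh <- matrix(0, 4, 8); oh[cbind(b[strsplit("ACGTTGCA", "")[[1]]], 1:8)] <- 9
  rownames(oh) <- names(b)
  p_oh <- pfm("OH", oh)
  sim0 <- simulate_promoters(paste0("g", 1:200), 500, list(), character(),
                             0, seed = 49)
  total <- sum(vapply(sim0$sequences$sequence, scan_pfm, integer(1),
                      pfm = p_oh, threshold_frac = 1, USE.NAMES = FALSE))
  n_pos <- 2 * (500 - 7) * 200
  expect_lt(abs(total - n_pos * 4^-8), 3 * sqrt(n_pos * 4^-8) + 1)
})
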