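tri_edges <- tibble::tibble(protein_a = c("A", "A", "B"),
                            protein_b = c("B", "C", "C"),
                            combined_score = c(0.5, 0.6, 0.7))

test_that("graph construction thresholds and simplifies", {
  g <- build_graph(tri_edges)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 3)

  e <- tibble::tibble(protein_a = c("A", "A"), protein_b = c("B", "C"),
                      combined_score = c(0.14, 0.15))
  g2 <- build_graph(e, min_score = 0.15)
  expect_equal(igraph::ecount(g2), 1)

  dup <- tibble::tibble(protein_a = c("A", "B"), protein_b = c("B", "A"),
                        combined_score = c(0.3, 0.9))
  g3 <- build_graph(dup, 0.15)
  expect_equal(igraph::ecount(g3), 1)
  expect_error(build_graph(tri_edges[0, ]), "empty")
})

test_that("maximal cliques match definitions on canonical graphs", {
  k5 <- complete_edges(paste0("v", 1:5))
  cs <- maximal_cliques(build_graph(k5), min_size = 3)
  expect_equal(nrow(cs), 1)
  expect_equal(cs$size, 5)

  path <- tibble::tibble(protein_a = c("a", "b"), protein_b = c("b", "c"),
                         combined_score = 1)
  expect_equal(nrow(maximal_cliques(build_graph(path), 3)), 0)
})

test_that("clique enumeration equals a brute-force subset oracle", {
  for (seed in 1:20) {
    n <- sample(5:10, 1)
    edges <- er_edges(n, 0.5, seed)
    if (!nrow(edges)) next
    got <- maximal_cliques(build_graph(edges, 0), min_size = 3)$members
    want <- bf_max_cliques(edges, min_size = 3)
    key <- function(x) sort(vapply(x, paste, character(1), collapse = "|"))
    expect_equal(key(got), key(want))
  }
})

test_that("ribosomal cliques are removed by symbol prefix", {
  cs <- tibble::tibble(
    clique_id = c("MC1", "MC2"), size = c(3, 3),
    members = list(c("RPL3", "ABC1", "XYZ2"), c("GRIA1", "DLG1", "CDH1")))
  class(cs) <- c("clique_set", class(cs))
  expect_message(kept <- filter_ribosomal(cs), "removed 1")
  expect_equal(kept$clique_id, "MC2")

  # counting oracle on a simulated network with one planted ribosomal clique
  sim <- simulate_ppi(40, planted_cliques = list(
    list(size = 6, ribosomal = TRUE), list(size = 5, ribosomal = FALSE)),
    p_background = 0.05, seed = 20)
  cl <- maximal_cliques(build_graph(sim$edges, 0), 3)
  kept2 <- suppressMessages(filter_ribosomal(cl))
  touches <- vapply(cl$members, function(m) any(grepl("^(RPS|RPL)[0-9]", m)),
                    logical(1))
  expect_equal(nrow(kept2), nrow(cl) - sum(touches))
})

test_that("centralities match closed forms on canonical graphs", {
  k4 <- complete_edges(paste0("v", 1:4))
  g4 <- build_graph(k4)
  expect_equal(unname(mnc(g4, "v1")), 3)
  expect_equal(unname(dmnc(g4, "v1")), 3 / 3^1.7, tolerance = 1e-12)

  k5 <- complete_edges(paste0("v", 1:5))
  g5 <- build_graph(k5)
  expect_equal(unname(mnc(g5, "v1")), 4)
  expect_equal(unname(dmnc(g5, "v1")), 6 / 4^1.7, tolerance = 1e-12)
  expect_equal(unname(dmnc(g5, "v1")), 0.5683937124413994, tolerance = 1e-9)

  path <- build_graph(tibble::tibble(protein_a = c("a", "b"),
                                     protein_b = c("b", "c"),
                                     combined_score = 1))
  expect_equal(unname(igraph::betweenness(path, "b")), 1)
  expect_equal(unname(igraph::betweenness(path, "a")), 0)

  star <- build_graph(tibble::tibble(protein_a = rep("hub", 5),
                                     protein_b = paste0("l", 1:5),
                                     combined_score = 1))
  expect_equal(unname(mnc(star, "hub")), 1)
  expect_equal(unname(dmnc(star, "hub")), 0)
  # star center is the subtree carrier from every leaf source
  bn <- bottleneck(star)
  expect_equal(unname(bn["hub"]), 5)
})

test_that("centralities agree with brute force on random small graphs", {
  for (seed in 21:32) {
    n <- sample(5:10, 1)
    edges <- er_edges(n, 0.45, seed)
    if (nrow(edges) < 3) next
    g <- build_graph(edges, 0)
    nodes <- sort(igraph::V(g)$name)
    oracle <- bf_mnc_dmnc(edges)
    expect_equal(mnc(g, nodes), oracle$mnc[nodes])
    expect_equal(dmnc(g, nodes), oracle$dmnc[nodes], tolerance = 1e-12)
    bt <- igraph::betweenness(g, v = nodes, directed = FALSE)
    expect_equal(unname(bt), unname(bf_betweenness(edges)[nodes]),
                 tolerance = 1e-9)
    deg <- table(c(edges$protein_a, edges$protein_b))
    expect_equal(unname(igraph::degree(g, nodes)),
                 as.integer(deg[nodes]))
  }
})

test_that("the double screening scheme applies both stages", {
  sc <- tibble::tibble(
    node = c("A", "B", "C", "D"),
    degree = c(4, 3, 2, 1), betweenness = 0, bottleneck = 0,
    mnc = c(2, 3, 1, 1), dmnc = c(0.9, 0.8, 0.7, 0.6),
    rank_degree = 1:4, rank_betweenness = 1:4, rank_bottleneck = 1:4,
    rank_mnc = c(2, 1, 3, 4), rank_dmnc = 1:4
  )
  # top-2 by DMNC is {A, B}; MNC re-ranking puts B first
  expect_equal(dss_rank(sc, 1), "B")
  expect_error(dss_rank(sc, 3), "exceeds")
  # the selection is always within the top-2n DMNC set
  set.seed(33)
  edges <- er_edges(12, 0.4, 34)
  hs <- hub_scores(build_graph(edges, 0))
  sel <- dss_rank(hs, 3)
  top6 <- hs$node[order(-hs$dmnc, hs$node)][1:6]
  expect_true(all(sel %in% top6))
  expect_equal(sum(hs$dss_selected), min(10, floor(nrow(hs) / 2)))
})

test_that("scores are invariant under vertex relabeling", {
  edges <- er_edges(8, 0.5, 35)
  g1 <- build_graph(edges, 0)
  lut <- setNames(sprintf("Q%02d", seq_len(8)), sprintf("N%02d", seq_len(8)))
  edges2 <- dplyr::mutate(edges, protein_a = unname(lut[protein_a]),
                          protein_b = unname(lut[protein_b]))
  g2 <- build_graph(edges2, 0)
  s1 <- hub_scores(g1); s2 <- hub_scores(g2)
  expect_equal(s1$dmnc, s2$dmnc[match(lut[s1$node], s2$node)])
  expect_equal(s1$mnc, s2$mnc[match(lut[s1$node], s2$node)])
})
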