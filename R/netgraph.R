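#' Build a simple undirected PPI graph from scored edges
#'
#' Edges below `min_score` are excluded (boundary kept); self-loops and
#' parallel edges are collapsed keeping the maximal score. All graph
#' algorithms downstream treat edges as unweighted: scores gate membership
#' only.
#'
#' @param edges tibble `protein_a`, `protein_b`, `combined_score`.
#' @param min_score minimal confidence score.
#' @return An [igraph::igraph] object.
#' @export
build_graph <- function(edges, min_score = 0.15) {
  if (!nrow(edges)) rlang::abort("empty edge set")
  edges <- clean_edges(edges, min_score)
  if (!nrow(edges)) rlang::abort("no edge passes the score threshold")
  igraph::graph_from_data_frame(edges, directed = FALSE)
}

#' Enumerate maximal cliques
#'
#' All maximal cliques of the graph with at least `min_size` members, in a
#' canonical deterministic order (size descending, then lexicographic member
#' tuple). Members within a clique are sorted.
#'
#' @param g an igraph graph.
#' @param min_size minimal clique size reported.
#' @return A `clique_set` tibble: `clique_id`, `size`, list-column
#'   `members`.
#' @export
maximal_cliques <- function(g, min_size = 3) {
  cl <- igraph::max_cliques(g, min = min_size)
  members <- lapply(cl, function(v) sort(names(v)))
  key <- vapply(members, paste, character(1), collapse = "\r")
  ord <- order(-lengths(members), key)
  members <- members[ord]
  out <- tibble::tibble(
    clique_id = sprintf("MC%05d", seq_along(members)),
    size = lengths(members),
    members = members
  )
  class(out) <- c("clique_set", class(out))
  out
}

#' Drop cliques containing ribosomal protein genes
#'
#' A clique is removed when any member symbol starts with one of the given
#' prefixes (case-insensitive, prefix followed by an alphanumeric), the
#' convention for small/large ribosomal subunit protein gene symbols
#' (RPS*/RPL*).
#'
#' @param cliques `clique_set` tibble.
#' @param prefixes symbol prefixes marking ribosomal genes.
#' @return Filtered `clique_set` with an `is_ribosomal` bookkeeping message.
#' @export
filter_ribosomal <- function(cliques, prefixes = c("RPS", "RPL")) {
  pat <- paste0("^(", paste(prefixes, collapse = "|"), ")[A-Za-z0-9]")
  ribo <- vapply(cliques$members, function(m) any(grepl(pat, m, ignore.case = TRUE)),
                 logical(1))
  rlang::inform(sprintf("removed %d ribosomal clique(s), kept %d",
                        sum(ribo), sum(!ribo)))
  out <- cliques[!ribo, , drop = FALSE]
  class(out) <- c("clique_set", class(out))
  out
}

#' Convert a clique set into a gene-set catalog
#'
#' @param cliques `clique_set` tibble.
#' @return Catalog tibble (`set`, `description`, list-column `genes`)
#'   usable with [run_catalog()].
#' @export
cliques_to_catalog <- function(cliques) {
  tibble::tibble(
    set = cliques$clique_id,
    description = sprintf("maximal clique, size %d", cliques$size),
    genes = cliques$members
  )
}

#' Maximum neighborhood component size
#'
#' Size of the largest connected component of the subgraph induced by the
#' neighbors of `v` (`v` itself excluded).
#'
#' @param g an igraph graph.
#' @param v vertex name(s); default all vertices.
#' @return Named integer vector.
#' @export
mnc <- function(g, v = igraph::V(g)$name) {
  vapply(v, function(u) {
    nb <- igraph::neighbors(g, u)
    if (!length(nb)) return(0L)
    sub <- igraph::induced_subgraph(g, nb)
    as.integer(max(igraph::components(sub)$csize))
  }, integer(1))
}

#' Density of the maximum neighborhood component
#'
#' `E / N^eps` where `N` and `E` are the vertex and edge counts of the
#' largest connected component of the neighborhood subgraph of `v`; zero
#' when that component has at most one vertex.
#'
#' @inheritParams mnc
#' @param eps density exponent (1.7 by convention).
#' @return Named numeric vector.
#' @export
dmnc <- function(g, v = igraph::V(g)$name, eps = 1.7) {
  vapply(v, function(u) {
    nb <- igraph::neighbors(g, u)
    if (length(nb) < 2) return(0)
    sub <- igraph::induced_subgraph(g, nb)
    cmp <- igraph::components(sub)
    big <- which.max(cmp$csize)
    n <- cmp$csize[big]
    if (n <= 1) return(0)
    comp_v <- igraph::V(sub)[cmp$membership == big]
    e <- igraph::ecount(igraph::induced_subgraph(sub, comp_v))
    e / n^eps
  }, numeric(1))
}

#' BottleNeck hub score
#'
#' For every source vertex a single-source BFS shortest-path tree is built
#' (each non-source vertex takes, as parent, the lexicographically smallest
#' neighbor one BFS level closer to the source). A vertex scores one point
#' per tree in which its subtree contains more than `|V|/4` vertices and it
#' is not the source. The score counts such trees over all sources.
#'
#' @param g an igraph graph.
#' @return Named numeric vector over all vertices.
#' @export
bottleneck <- function(g) {
  nodes <- sort(igraph::V(g)$name)
  nv <- length(nodes)
  score <- setNames(numeric(nv), nodes)
  adj <- lapply(igraph::adjacent_vertices(g, nodes), function(x) sort(names(x)))
  names(adj) <- nodes
  dmat <- igraph::distances(g, v = nodes, to = nodes)
  for (s in nodes) {
    d <- dmat[s, ]
    reach <- names(d)[is.finite(d)]
    if (length(reach) < 2) next
    parent <- setNames(rep(NA_character_, length(reach)), reach)
    for (u in reach) {
      if (u == s) next
      cand <- adj[[u]][d[adj[[u]]] == d[u] - 1]
      parent[u] <- cand[1]             # adj lists are sorted: lexicographic tie-break
    }
    sub_size <- setNames(rep(1, length(reach)), reach)
    for (u in reach[order(-d[reach])]) {
      if (u == s) next
      sub_size[parent[u]] <- sub_size[parent[u]] + sub_size[u]
    }
    gain <- reach[reach != s & sub_size > nv / 4]
    score[gain] <- score[gain] + 1
  }
  score
}

#' Hub centrality battery for a PPI graph
#'
#' Computes, per vertex: degree, unnormalized shortest-path betweenness,
#' the BottleNeck tree score, MNC, DMNC, per-metric ranks (descending score,
#' ties broken by vertex name for stability) and the double-screening-scheme
#' selection flag.
#'
#' @param g an igraph graph.
#' @param eps DMNC exponent.
#' @param dss_n number of proteins the double screening scheme should
#'   return; `NA` (default) selects `min(10, floor(|V|/2))`.
#' @return A `hub_scores` tibble ordered by node name.
#' @export
hub_scores <- function(g, eps = 1.7, dss_n = NA) {
  nodes <- sort(igraph::V(g)$name)
  deg <- igraph::degree(g, v = nodes)
  btw <- igraph::betweenness(g, v = nodes, directed = FALSE, normalized = FALSE)
  bn <- bottleneck(g)[nodes]
  mn <- mnc(g, nodes)
  dm <- dmnc(g, nodes, eps = eps)
  rk <- function(x) rank(-x, ties.method = "first")
  out <- tibble::tibble(
    node = nodes,
    degree = unname(deg),
    betweenness = unname(btw),
    bottleneck = unname(bn),
    mnc = unname(mn),
    dmnc = unname(dm),
    rank_degree = rk(unname(deg)),
    rank_betweenness = rk(unname(btw)),
    rank_bottleneck = rk(unname(bn)),
    rank_mnc = rk(unname(mn)),
    rank_dmnc = rk(unname(dm))
  )
  if (is.na(dss_n)) dss_n <- max(1, min(10, floor(length(nodes) / 2)))
  out$dss_selected <- out$node %in% dss_rank(out, dss_n)
  class(out) <- c("hub_scores", class(out))
  out
}

#' Double screening scheme (DMNC then MNC)
#'
#' Selects the `2n` vertices with the highest DMNC (ties broken stably by
#' node name), re-ranks those by MNC, and returns the top `n`.
#'
#' @param scores `hub_scores` tibble (needs `node`, `dmnc`, `mnc`).
#' @param n number of proteins to return; `2n` must not exceed the vertex
#'   count.
#' @return Character vector of `n` selected node names.
#' @export
dss_rank <- function(scores, n) {
  if (n < 1) rlang::abort("`n` must be >= 1")
  if (2 * n > nrow(scores)) rlang::abort("`2n` exceeds the number of vertices")
  stage1 <- scores[order(-scores$dmnc, scores$node), ][seq_len(2 * n), ]
  stage2 <- stage1[order(-stage1$mnc, stage1$node), ]
  stage2$node[seq_len(n)]
}

#' Vertices highly ranked by at least `k` hub metrics
#'
#' Flags vertices appearing in the top `top_n` by at least `min_methods` of
#' the degree, betweenness, BottleNeck and DSS (DMNC then MNC) criteria.
#'
#' @param scores `hub_scores` tibble.
#' @param top_n per-metric cut.
#' @param min_methods how many metrics must agree.
#' @return Tibble of selected nodes with a `n_methods` support column.
#' @export
hub_consensus <- function(scores, top_n = 10, min_methods = 2) {
  dssn <- max(1, min(top_n, floor(nrow(scores) / 2)))
  sets <- list(
    degree = scores$node[scores$rank_degree <= top_n],
    betweenness = scores$node[scores$rank_betweenness <= top_n],
    bottleneck = scores$node[scores$rank_bottleneck <= top_n],
    dss = dss_rank(scores, dssn)
  )
  support <- table(unlist(sets))
  keep <- names(support)[support >= min_methods]
  out <- dplyr::filter(scores, .data$node %in% keep)
  out$n_methods <- as.integer(support[out$node])
  dplyr::arrange(out, dplyr::desc(.data$n_methods), .data$node)
}
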