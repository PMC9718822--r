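# Small in-code fixtures and brute-force oracles shared across tests.

# build a count tibble from a plain matrix
make_counts <- function(m, genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(m)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(m)))
  colnames(m) <- samples
  dplyr::bind_cols(tibble::tibble(gene = genes),
                   tibble::as_tibble(m, .name_repair = "minimal"))
}

# complete-graph edge tibble
complete_edges <- function(nodes) {
  cmb <- utils::combn(nodes, 2)
  tibble::tibble(protein_a = cmb[1, ], protein_b = cmb[2, ],
                 combined_score = 1)
}

# random Erdos-Renyi edge tibble over named nodes
er_edges <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n))
  cmb <- utils::combn(nodes, 2)
  keep <- runif(ncol(cmb)) < p
  tibble::tibble(protein_a = cmb[1, keep], protein_b = cmb[2, keep],
                 combined_score = 1)
}

# adjacency lookup from an edge tibble
edge_adj <- function(edges, nodes) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges$protein_a[i]; b <- edges$protein_b[i]
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  adj
}

# brute-force maximal cliques: enumerate all vertex subsets, keep complete
# ones not contained in a larger complete subset
bf_max_cliques <- function(edges, min_size = 3) {
  nodes <- sort(unique(c(edges$protein_a, edges$protein_b)))
  adj <- edge_adj(edges, nodes)
  is_complete <- function(s) {
    if (length(s) < 2) return(TRUE)
    for (i in seq_along(s)) {
      for (j in seq_along(s)) {
        if (i < j && !(s[j] %in% adj[[s[i]]])) return(FALSE)
      }
    }
    TRUE
  }
  n <- length(nodes)
  cliques <- list()
  for (mask in seq_len(2^n - 1)) {
    s <- nodes[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    if (length(s) >= 2 && is_complete(s)) cliques[[length(cliques) + 1]] <- s
  }
  maximal <- Filter(function(s) {
    !any(vapply(cliques, function(t) length(t) > length(s) && all(s %in% t),
                logical(1)))
  }, cliques)
  maximal <- Filter(function(s) length(s) >= min_size, maximal)
  maximal <- lapply(maximal, sort)
  maximal[order(vapply(maximal, paste, character(1), collapse = "|"))]
}

# brute-force unnormalized betweenness by explicit shortest-path counting
bf_betweenness <- function(edges) {
  nodes <- sort(unique(c(edges$protein_a, edges$protein_b)))
  adj <- edge_adj(edges, nodes)
  # all shortest paths between a pair by BFS layer expansion
  all_paths <- function(s, t) {
    if (s == t) return(list())
    paths <- list(c(s))
    found <- list()
    repeat {
      nxt <- list()
      for (p in paths) {
        last <- p[length(p)]
        for (u in adj[[last]]) {
          if (u %in% p) next
          q <- c(p, u)
          if (u == t) found[[length(found) + 1]] <- q else nxt[[length(nxt) + 1]] <- q
        }
      }
      if (length(found)) return(found)
      if (!length(nxt)) return(list())
      paths <- nxt
    }
  }
  bt <- setNames(numeric(length(nodes)), nodes)
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (i >= j) next
      sp <- all_paths(nodes[i], nodes[j])
      if (!length(sp)) next
      for (p in sp) {
        inner <- p[-c(1, length(p))]
        for (v in inner) bt[v] <- bt[v] + 1 / length(sp)
      }
    }
  }
  bt
}

# brute-force MNC / DMNC via connected-component search on neighbor sets
bf_mnc_dmnc <- function(edges, eps = 1.7) {
  nodes <- sort(unique(c(edges$protein_a, edges$protein_b)))
  adj <- edge_adj(edges, nodes)
  comp_of <- function(members) {
    comps <- list()
    left <- members
    while (length(left)) {
      q <- left[1]; comp <- character()
      while (length(q)) {
        v <- q[1]; q <- q[-1]
        if (v %in% comp) next
        comp <- c(comp, v)
        q <- c(q, intersect(adj[[v]], setdiff(members, comp)))
      }
      comps[[length(comps) + 1]] <- comp
      left <- setdiff(left, comp)
    }
    comps
  }
  mnc <- setNames(integer(length(nodes)), nodes)
  dmnc <- setNames(numeric(length(nodes)), nodes)
  for (v in nodes) {
    nb <- adj[[v]]
    if (!length(nb)) next
    comps <- comp_of(nb)
    sizes <- lengths(comps)
    big <- comps[[which.max(sizes)]]
    mnc[v] <- length(big)
    if (length(big) > 1) {
      e <- 0
      for (i in seq_along(big)) for (j in seq_along(big)) {
        if (i < j && big[j] %in% adj[[big[i]]]) e <- e + 1
      }
      dmnc[v] <- e / length(big)^eps
    }
  }
  list(mnc = mnc, dmnc = dmnc)
}

# independent BH step-up
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
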