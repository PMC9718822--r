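#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   inner_join left_join bind_rows bind_cols rename relocate distinct n
#' @importFrom stats median pnorm pchisq p.adjust rnbinom rnorm runif rbinom
#'   t.test fisher.test wilcox.test prcomp lm coef setNames sd quantile
#' @importFrom utils head
NULL

# counts tibble -> integer matrix with gene rownames
counts_matrix <- function(counts) {
  stopifnot(is.data.frame(counts), ncol(counts) >= 2)
  m <- as.matrix(counts[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(counts[[1]])
  m
}

matrix_counts <- function(m) {
  tibble::as_tibble(m, rownames = "gene")
}

sample_names <- function(counts) names(counts)[-1]

#' Percentage bookkeeping for a filtered clique inventory
#'
#' Given the total number of maximal cliques enumerated from a network and the
#' number surviving a filter (for instance the ribosomal-clique exclusion),
#' report the kept and removed percentages. Percentages are on the 0-100
#' scale.
#'
#' @param n_total total cliques before filtering.
#' @param n_kept cliques retained after filtering.
#' @return A one-row tibble with `n_total`, `n_kept`, `n_removed`,
#'   `kept_pct` and `removed_pct`.
#' @examples
#' clique_fraction_summary(121219, 21938)
#' @export
clique_fraction_summary <- function(n_total, n_kept) {
  if (length(n_total) != 1 || length(n_kept) != 1 ||
      is.na(n_total) || is.na(n_kept) || n_total <= 0 || n_kept < 0 ||
      n_kept > n_total) {
    rlang::abort("`n_kept` must lie in [0, n_total] with n_total > 0")
  }
  tibble::tibble(
    n_total = n_total,
    n_kept = n_kept,
    n_removed = n_total - n_kept,
    kept_pct = 100 * n_kept / n_total,
    removed_pct = 100 * (n_total - n_kept) / n_total
  )
}

# deterministic sub-seed per named generator stream so that, e.g., the PPI
# draw does not shift when the count draw consumes more random numbers
stream_seed <- function(seed, stream) {
  offsets <- c(
    genes = 11L, orthologs = 23L, truth = 37L, counts = 53L,
    ppi = 71L, promoters = 89L, catalog = 101L, pfms = 113L
  )
  off <- offsets[[stream]]
  as.integer((as.numeric(seed) * 127 + off) %% 2147483629)
}

with_stream <- function(seed, stream, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, stream))
  force(code)
}

revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}
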