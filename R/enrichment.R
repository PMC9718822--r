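#' Per-gene expression shift statistic
#'
#' The gene-level statistic feeding the set tests: the difference in mean
#' log2(normalized count + 1) between the two groups (treatment minus
#' reference). Counts are size-factor normalized internally.
#'
#' @inheritParams nb_wald
#' @return Tibble `gene`, `stat`.
#' @export
per_gene_stat <- function(counts, groups, reference = "control") {
  g <- group_vector(counts, groups)
  lev <- unique(g)
  if (length(lev) != 2) rlang::abort("exactly two groups are required")
  if (!reference %in% lev) rlang::abort(sprintf("reference group '%s' not present", reference))
  treat <- setdiff(lev, reference)
  if (min(table(g)) < 2) rlang::abort("each group needs >= 2 samples")
  ly <- log2(normalize_counts(counts) + 1)
  s <- rowMeans(ly[, g == treat, drop = FALSE]) -
    rowMeans(ly[, g == reference, drop = FALSE])
  tibble::tibble(gene = rownames(ly), stat = unname(s))
}

#' Set-versus-complement enrichment test
#'
#' A two-sample Welch t-test of the member genes' statistics against all
#' non-member genes. Modes: `"up"` tests one-sided greater, `"down"`
#' one-sided less, and `"both"` tests absolute statistics one-sided greater,
#' capturing sets altered bidirectionally regardless of per-gene direction.
#'
#' @param stats per-gene statistic tibble (`gene`, `stat`) from
#'   [per_gene_stat()], or a named numeric vector.
#' @param members character vector of member gene identifiers.
#' @param mode one of `"up"`, `"down"`, `"both"`.
#' @param min_size minimal member count after intersecting with the measured
#'   universe.
#' @return One-row tibble `set_size`, `mean_stat`, `stat` (t), `p`.
#' @export
set_test <- function(stats, members, mode = c("up", "down", "both"),
                     min_size = 3) {
  mode <- match.arg(mode)
  if (is.data.frame(stats)) stats <- setNames(stats$stat, stats$gene)
  members <- unique(members)
  inset <- names(stats) %in% members
  x <- stats[inset]
  y <- stats[!inset]
  if (length(x) < min_size) {
    rlang::abort(sprintf("only %d member(s) in the measured universe (need >= %d)",
                         length(x), min_size))
  }
  if (!length(y)) rlang::abort("complement of the set is empty")
  if (mode == "both") {
    x <- abs(x); y <- abs(y)
    alt <- "greater"
  } else {
    alt <- if (mode == "up") "greater" else "less"
  }
  tt <- stats::t.test(x, y, alternative = alt, var.equal = FALSE)
  tibble::tibble(
    set_size = length(x),
    mean_stat = mean(x),
    stat = unname(tt$statistic),
    p = unname(tt$p.value)
  )
}

#' Run a gene-set catalog through the enrichment test
#'
#' Applies [set_test()] to every set in a catalog for each requested mode,
#' intersecting members with the measured gene universe, skipping (with a
#' message) sets with fewer than `min_size` usable members, and BH-adjusting
#' p-values within each mode.
#'
#' @inheritParams per_gene_stat
#' @param catalog gene-set tibble (`set`, `description`, list-column
#'   `genes`), e.g. from [read_gmt()] or [cliques_to_catalog()].
#' @param modes subset of `c("up", "down", "both")`.
#' @param min_size minimal usable set size.
#' @return An `enrichment_result` tibble: `set`, `mode`, `set_size`,
#'   `mean_stat`, `stat`, `p`, `padj`, ordered by `padj` then `set`.
#' @export
run_catalog <- function(counts, groups, catalog,
                        modes = c("up", "down", "both"),
                        reference = "control", min_size = 3) {
  if (!nrow(catalog)) rlang::abort("empty gene-set catalog")
  if (anyDuplicated(catalog$set)) rlang::abort("duplicate set names in catalog")
  modes <- match.arg(modes, c("up", "down", "both"), several.ok = TRUE)
  s <- per_gene_stat(counts, groups, reference = reference)
  sv <- setNames(s$stat, s$gene)
  usable <- vapply(catalog$genes, function(g) sum(names(sv) %in% g), integer(1))
  skip <- usable < min_size
  if (any(skip)) {
    rlang::inform(sprintf("skipping %d set(s) with < %d measured members",
                          sum(skip), min_size))
  }
  cat_use <- catalog[!skip, , drop = FALSE]
  if (!nrow(cat_use)) rlang::abort("no set has enough measured members")
  rows <- purrr::map_dfr(modes, function(md) {
    res <- purrr::map_dfr(seq_len(nrow(cat_use)), function(i) {
      set_test(sv, cat_use$genes[[i]], mode = md, min_size = min_size)
    })
    res$set <- cat_use$set
    res$mode <- md
    res$padj <- bh_adjust(res$p)
    res
  })
  out <- dplyr::arrange(
    dplyr::select(rows, "set", "mode", "set_size", "mean_stat",
                  "stat", "p", "padj"),
    .data$padj, .data$set)
  class(out) <- c("enrichment_result", class(out))
  out
}
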