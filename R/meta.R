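#' Fisher combination of per-species p-values with direction
#'
#' Combines k two-sided p-values by Fisher's method on one-sided p-values.
#' Each two-sided p is converted to the "up" one-sided p (`p/2` when the
#' effect sign is positive, `1 - p/2` when negative, `0.5` when zero), giving
#' the statistic `S+ = -2 sum(log p_up)`; the mirrored statistic `S-` uses
#' the "down" one-sided p-values. Both are referred to a chi-squared null
#' with `2k` degrees of freedom, and two-sidedness is recovered as
#' `min(1, 2 min(tail(S+), tail(S-)))`. The reported statistic is the larger
#' of the two.
#'
#' With `raw = TRUE` the plain Fisher combination of the two-sided p-values
#' is returned instead (statistic `-2 sum(log p)` against chi-squared 2k),
#' the convention used by simple cross-study RNA-seq combiners.
#'
#' @param p vector of k >= 2 two-sided p-values in (0, 1].
#' @param signs effect-direction signs in \{-1, 0, 1\} (e.g.
#'   `sign(l2fc)`); ignored when `raw = TRUE`.
#' @param raw combine two-sided p-values directly.
#' @return A one-row tibble `fisher_stat`, `df`, `p`.
#' @export
fisher_combine <- function(p, signs = NULL, raw = FALSE) {
  k <- length(p)
  if (k < 2) rlang::abort("need p-values from at least 2 studies")
  if (anyNA(p) || any(p < 0 | p > 1)) rlang::abort("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    rlang::warn("p-value of 0 clamped to 1e-300")
    p[p == 0] <- 1e-300
  }
  df <- 2 * k
  if (raw) {
    s <- -2 * sum(log(p))
    return(tibble::tibble(fisher_stat = s, df = df,
                          p = stats::pchisq(s, df, lower.tail = FALSE)))
  }
  if (is.null(signs) || length(signs) != k) {
    rlang::abort("`signs` must accompany the p-values (one per study)")
  }
  signs <- sign(signs)
  # both one-sided forms are derived directly from p and the sign:
  # 1 - (1 - p/2) would lose all precision for p below ~1e-16
  p_up <- ifelse(signs > 0, p / 2, ifelse(signs < 0, 1 - p / 2, 0.5))
  p_dn <- ifelse(signs > 0, 1 - p / 2, ifelse(signs < 0, p / 2, 0.5))
  p_up <- pmin(pmax(p_up, 1e-300), 1)
  p_dn <- pmin(pmax(p_dn, 1e-300), 1)
  s_up <- -2 * sum(log(p_up))
  s_dn <- -2 * sum(log(p_dn))
  t_up <- stats::pchisq(s_up, df, lower.tail = FALSE)
  t_dn <- stats::pchisq(s_dn, df, lower.tail = FALSE)
  tibble::tibble(
    fisher_stat = max(s_up, s_dn),
    df = df,
    p = min(1, 2 * min(t_up, t_dn))
  )
}

# vectorized form: p and signs are n x k matrices; returns list of vectors
fisher_combine_matrix <- function(pm, sm, raw = FALSE) {
  k <- ncol(pm)
  df <- 2 * k
  pm <- pmin(pmax(pm, 1e-300), 1)
  if (raw) {
    s <- -2 * rowSums(log(pm))
    return(list(stat = s, df = df,
                p = stats::pchisq(s, df, lower.tail = FALSE)))
  }
  sm <- sign(sm)
  p_up <- ifelse(sm > 0, pm / 2, ifelse(sm < 0, 1 - pm / 2, 0.5))
  p_dn <- ifelse(sm > 0, 1 - pm / 2, ifelse(sm < 0, pm / 2, 0.5))
  p_up <- pmin(pmax(p_up, 1e-300), 1)
  p_dn <- pmin(pmax(p_dn, 1e-300), 1)
  s_up <- -2 * rowSums(log(p_up))
  s_dn <- -2 * rowSums(log(p_dn))
  t_up <- stats::pchisq(s_up, df, lower.tail = FALSE)
  t_dn <- stats::pchisq(s_dn, df, lower.tail = FALSE)
  list(stat = pmax(s_up, s_dn), df = df,
       p = pmin(1, 2 * pmin(t_up, t_dn)))
}

#' Cross-species meta-analysis table
#'
#' Inner-joins per-species result tables on a shared key (human-ortholog gene
#' or set name), combines their p-values per item with [fisher_combine()],
#' BH-adjusts the combined p-values, and flags items whose effect direction
#' is strictly concordant (same nonzero sign in every species).
#'
#' @param per_species named list of per-species tibbles (names become column
#'   suffixes), each carrying the key column plus `p` and an effect column.
#' @param join_key key column name (`"gene"` for DE tables, `"set"` for
#'   enrichment tables).
#' @param effect_col effect-size column used for direction (`"l2fc"` for DE,
#'   `"mean_stat"` for set results).
#' @param raw passed to [fisher_combine()].
#' @return A `meta_result` tibble with per-species `p_*` and `effect_*`
#'   columns plus `fisher_stat`, `df`, `p`, `padj`, `concordant`,
#'   `mean_effect`, ordered by combined `padj`.
#' @export
meta_table <- function(per_species, join_key = "gene", effect_col = "l2fc",
                       raw = FALSE) {
  stopifnot(is.list(per_species), length(per_species) >= 2,
            !is.null(names(per_species)))
  sp <- names(per_species)
  slim <- purrr::imap(per_species, function(d, nm) {
    stopifnot(all(c(join_key, "p", effect_col) %in% names(d)))
    out <- tibble::tibble(
      key = d[[join_key]],
      p = d$p,
      effect = d[[effect_col]]
    )
    names(out) <- c(join_key, paste0("p_", nm), paste0("effect_", nm))
    out
  })
  joined <- purrr::reduce(slim, function(a, b) dplyr::inner_join(a, b, by = join_key))
  if (!nrow(joined)) rlang::abort("no shared items across the input tables")

  pm <- as.matrix(joined[, paste0("p_", sp), drop = FALSE])
  em <- as.matrix(joined[, paste0("effect_", sp), drop = FALSE])
  if (any(pm == 0)) rlang::warn("p-value of 0 clamped to 1e-300")
  comb <- fisher_combine_matrix(pm, em, raw = raw)
  joined$fisher_stat <- comb$stat
  joined$df <- comb$df
  joined$p <- comb$p
  joined$padj <- bh_adjust(comb$p)
  joined$concordant <- apply(em, 1, function(e) all(e > 0) || all(e < 0))
  joined$mean_effect <- rowMeans(em)
  out <- dplyr::arrange(joined, .data$padj, .data[[join_key]])
  class(out) <- c("meta_result", class(out))
  attr(out, "species") <- sp
  out
}
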