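#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname tidiers
#' @title Broom-style accessors for orthometa result objects
#' @description `tidy()` returns the per-item result table; `glance()`
#'   returns a one-row summary.
#' @param x a result object.
#' @param alpha significance threshold used by the summaries.
#' @param ... unused.
#' @export
tidy.de_result <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  out
}

#' @rdname tidiers
#' @export
glance.de_result <- function(x, alpha = 0.05, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_sig = sum(x$padj < alpha),
    n_up = sum(x$padj < alpha & x$l2fc > 0),
    n_down = sum(x$padj < alpha & x$l2fc < 0)
  )
}

#' @rdname tidiers
#' @export
tidy.meta_result <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  out
}

#' @rdname tidiers
#' @export
glance.meta_result <- function(x, alpha = 0.05, ...) {
  tibble::tibble(
    n_items = nrow(x),
    n_sig = sum(x$padj < alpha),
    n_sig_concordant = sum(x$padj < alpha & x$concordant)
  )
}

#' @rdname tidiers
#' @export
tidy.enrichment_result <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  out
}

#' @rdname tidiers
#' @export
glance.enrichment_result <- function(x, alpha = 0.05, ...) {
  tibble::tibble(
    n_tests = nrow(x),
    n_sets = dplyr::n_distinct(x$set),
    n_sig = sum(x$padj < alpha)
  )
}

#' @rdname tidiers
#' @export
tidy.tfbs_result <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  out
}

#' @rdname tidiers
#' @export
glance.tfbs_result <- function(x, ...) {
  tibble::tibble(
    n_pfms = nrow(x),
    n_significant = sum(x$significant)
  )
}
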