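#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_col geom_hline
#'   labs theme_minimal coord_flip
#' @export
ggplot2::autoplot

#' Volcano plot of a differential-expression result
#'
#' @param object a `de_result` tibble.
#' @param alpha adjusted-p threshold used for coloring.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.de_result <- function(object, alpha = 0.05, ...) {
  d <- tidy(object)
  d$significant <- d$padj < alpha
  ggplot(d, aes(x = .data$l2fc, y = -log10(pmax(.data$p, 1e-300)),
                colour = .data$significant)) +
    geom_point(size = 0.8, alpha = 0.7) +
    labs(x = "log2 fold change", y = "-log10 p", colour = paste("padj <", alpha)) +
    theme_minimal()
}

#' Bar chart of the strongest set enrichments
#'
#' @param object an `enrichment_result` tibble.
#' @param n number of sets shown (by adjusted p).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_result <- function(object, n = 15, ...) {
  d <- utils::head(dplyr::arrange(tidy(object), .data$padj), n)
  d$label <- paste(d$set, d$mode, sep = " / ")
  ggplot(d, aes(x = stats::reorder(.data$label, -.data$padj),
                y = -log10(pmax(.data$padj, 1e-300)), fill = .data$mode)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "-log10 adjusted p") +
    theme_minimal()
}

#' Sample scores on the first two principal components
#'
#' Visualizes the pooled-study PCA (samples colored by species, shaped by
#' group), the view that makes the species-dominated variance structure of
#' pooled cross-species counts obvious.
#'
#' @param report an `experiment_report` from [experiment2()], or a tibble of
#'   scores with `PC1`, `PC2`, `species`, `group`.
#' @return A ggplot object.
#' @export
plot_pca <- function(report) {
  scores <- if (is.data.frame(report)) report else report$pca$scores
  ggplot(scores, aes(x = .data$PC1, y = .data$PC2, colour = .data$species,
                     shape = .data$group)) +
    geom_point(size = 2.5) +
    labs(x = "PC1", y = "PC2") +
    theme_minimal()
}

#' Lollipop chart of hub centralities
#'
#' @param scores a `hub_scores` tibble.
#' @param metric which centrality column to display.
#' @param n number of vertices shown.
#' @return A ggplot object.
#' @export
plot_hubs <- function(scores, metric = "dmnc", n = 15) {
  stopifnot(metric %in% c("degree", "betweenness", "bottleneck", "mnc", "dmnc"))
  d <- utils::head(scores[order(-scores[[metric]], scores$node), ], n)
  ggplot(d, aes(x = stats::reorder(.data$node, .data[[metric]]),
                y = .data[[metric]], colour = .data$dss_selected)) +
    geom_point(size = 2.5) +
    coord_flip() +
    labs(x = NULL, y = metric, colour = "DSS selected") +
    theme_minimal()
}
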