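#' Split genes into high- and low-variability strata
#'
#' Foreground = genes with raw DE p-value strictly below `p_high` (strongly
#' group-dependent expression); background = genes with raw p strictly above
#' `p_low` (stable expression). The strata are disjoint by construction.
#'
#' @param de `de_result` tibble.
#' @param p_high foreground threshold on the raw p-value.
#' @param p_low background threshold on the raw p-value.
#' @return List with character vectors `foreground` and `background`.
#' @export
stratify_genes <- function(de, p_high = 0.01, p_low = 0.7) {
  if (!nrow(de)) rlang::abort("empty DE table")
  fg <- de$gene[de$p < p_high]
  bg <- de$gene[de$p > p_low]
  if (!length(fg)) {
    rlang::abort(sprintf("no gene with p < %g; relax `p_high`", p_high))
  }
  if (!length(bg)) {
    rlang::abort(sprintf("no gene with p > %g; relax `p_low`", p_low))
  }
  list(foreground = fg, background = bg)
}

#' Extract promoter windows around transcription start sites
#'
#' Returns, per gene, the sequence spanning `upstream` bases before and
#' `downstream` bases after the TSS (0-based TSS coordinate, half-open
#' window, clipped at contig edges). Minus-strand genes get the reverse
#' complement of the mirrored interval so that "upstream" is always 5' of the
#' gene.
#'
#' @param tss tibble with columns `gene`, `contig`, `tss` (0-based), `strand`
#'   (`"+"`/`"-"`).
#' @param genome named character vector (or tibble from [read_fasta()])
#'   of contig sequences.
#' @param upstream,downstream window extents in bp.
#' @return Tibble `gene`, `sequence`.
#' @export
promoter_window <- function(tss, genome, upstream = 1500, downstream = 500) {
  if (is.data.frame(genome)) genome <- setNames(genome$sequence, genome$gene)
  seqs <- vapply(seq_len(nrow(tss)), function(i) {
    ctg <- tss$contig[i]
    if (!ctg %in% names(genome)) rlang::abort(sprintf("contig '%s' not in genome", ctg))
    len <- nchar(genome[[ctg]])
    pos <- tss$tss[i]
    if (pos < 0 || pos >= len) {
      rlang::abort(sprintf("TSS of '%s' outside contig '%s'", tss$gene[i], ctg))
    }
    if (tss$strand[i] == "+") {
      s <- max(0, pos - upstream)
      e <- min(len, pos + downstream)
      substr(genome[[ctg]], s + 1, e)
    } else {
      s <- max(0, pos - downstream + 1)
      e <- min(len, pos + upstream + 1)
      revcomp(substr(genome[[ctg]], s + 1, e))
    }
  }, character(1))
  tibble::tibble(gene = tss$gene, sequence = seqs)
}

#' Count motif matches in a sequence
#'
#' Scores every position on both strands with the PFM's log2-odds matrix
#' (uniform background) and counts positions scoring at least
#' `threshold_frac` times the maximal achievable score. Sequences shorter
#' than the motif yield zero. Positions overlapping an `N` never match.
#'
#' @param seq a single DNA string.
#' @param pfm a [pfm()] object.
#' @param threshold_frac score threshold as a fraction of the best possible
#'   score, in (0, 1].
#' @return Integer match count.
#' @export
scan_pfm <- function(seq, pfm, threshold_frac = 0.8) {
  stopifnot(inherits(pfm, "pfm"))
  if (threshold_frac <= 0 || threshold_frac > 1) {
    rlang::abort("`threshold_frac` must lie in (0, 1]")
  }
  thr <- threshold_frac * sum(apply(pfm$log_odds, 2, max))
  strand_count(seq, pfm$log_odds, thr) +
    strand_count(revcomp(seq), pfm$log_odds, thr)
}

strand_count <- function(seq, lo, thr) {
  W <- ncol(lo)
  L <- nchar(seq)
  if (L < W) return(0L)
  b <- match(strsplit(seq, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
  n <- L - W + 1
  idx <- outer(seq_len(n) - 1L, seq_len(W), `+`)      # n x W positions
  bm <- matrix(b[idx], nrow = n)
  sc <- rowSums(matrix(lo[bm + rep(4L * (seq_len(W) - 1L), each = n)], nrow = n))
  sum(!is.na(sc) & sc >= thr)
}

#' Scan a promoter collection with a PFM library
#'
#' @param promoters tibble `gene`, `sequence`.
#' @param pfms named list of [pfm()] objects.
#' @param threshold_frac passed to [scan_pfm()].
#' @return Tibble `gene`, `pfm`, `sites`.
#' @export
scan_promoters <- function(promoters, pfms, threshold_frac = 0.8) {
  purrr::map_dfr(pfms, function(p) {
    tibble::tibble(
      gene = promoters$gene,
      pfm = p$id,
      sites = vapply(promoters$sequence, scan_pfm, integer(1),
                     pfm = p, threshold_frac = threshold_frac,
                     USE.NAMES = FALSE)
    )
  })
}

#' Foreground-versus-background TFBS contrast for one motif
#'
#' Compares per-gene site counts between two gene strata with a dual
#' criterion: a two-sided Fisher exact test on gene coverage (genes with at
#' least one site versus none) and a two-sided Mann-Whitney test on the
#' per-gene site-count distributions. The motif is flagged significant only
#' when both p-values fall below their thresholds. The log2 enrichment is the
#' ratio of coverage proportions with Haldane-style pseudocounts:
#' `log2((fg_cov + 0.5)/(fg_n + 1)) - log2((bg_cov + 0.5)/(bg_n + 1))`.
#'
#' @param fg_sites,bg_sites per-gene site counts in the foreground and
#'   background strata.
#' @param coverage_alpha,distribution_alpha significance thresholds for the
#'   two criteria (raw p-values).
#' @return One-row tibble with coverage counts, both p-values,
#'   `log2_enrichment` and `significant`.
#' @export
tfbs_contrast <- function(fg_sites, bg_sites, coverage_alpha = 0.05,
                          distribution_alpha = 0.05) {
  if (length(fg_sites) < 3 || length(bg_sites) < 3) {
    rlang::abort("both strata need >= 3 genes")
  }
  fg_cov <- sum(fg_sites > 0); bg_cov <- sum(bg_sites > 0)
  fg_n <- length(fg_sites); bg_n <- length(bg_sites)
  tab <- matrix(c(fg_cov, fg_n - fg_cov, bg_cov, bg_n - bg_cov), nrow = 2)
  cov_p <- stats::fisher.test(tab)$p.value
  dist_p <- suppressWarnings(
    stats::wilcox.test(fg_sites, bg_sites, exact = FALSE)$p.value)
  if (is.na(dist_p)) dist_p <- 1   # both strata constant
  l2e <- log2((fg_cov + 0.5) / (fg_n + 1)) - log2((bg_cov + 0.5) / (bg_n + 1))
  tibble::tibble(
    fg_covered = fg_cov, fg_total = fg_n,
    bg_covered = bg_cov, bg_total = bg_n,
    coverage_p = cov_p, distribution_p = dist_p,
    log2_enrichment = l2e,
    significant = cov_p < coverage_alpha & dist_p < distribution_alpha
  )
}

#' Full TFBS over/under-representation analysis
#'
#' Stratifies genes by DE p-value, scans both strata's promoters with every
#' PFM, and applies the dual-criterion contrast per motif.
#'
#' @param de `de_result` tibble for the stratification.
#' @param promoters tibble `gene`, `sequence` covering the DE gene universe.
#' @param pfms named list of [pfm()] objects.
#' @param p_high,p_low stratification thresholds (see [stratify_genes()]).
#' @param threshold_frac scanner threshold (see [scan_pfm()]).
#' @param coverage_alpha,distribution_alpha dual-criterion thresholds.
#' @return A `tfbs_result` tibble, one row per PFM, ordered by coverage p.
#' @export
tfbs_run <- function(de, promoters, pfms, p_high = 0.01, p_low = 0.7,
                     threshold_frac = 0.8, coverage_alpha = 0.05,
                     distribution_alpha = 0.05) {
  strata <- stratify_genes(de, p_high = p_high, p_low = p_low)
  fg <- promoters[promoters$gene %in% strata$foreground, , drop = FALSE]
  bg <- promoters[promoters$gene %in% strata$background, , drop = FALSE]
  if (nrow(fg) < 3 || nrow(bg) < 3) {
    rlang::abort("fewer than 3 promoters available in a stratum")
  }
  out <- purrr::map_dfr(pfms, function(p) {
    fg_sites <- vapply(fg$sequence, scan_pfm, integer(1), pfm = p,
                       threshold_frac = threshold_frac, USE.NAMES = FALSE)
    bg_sites <- vapply(bg$sequence, scan_pfm, integer(1), pfm = p,
                       threshold_frac = threshold_frac, USE.NAMES = FALSE)
    res <- tfbs_contrast(fg_sites, bg_sites,
                         coverage_alpha = coverage_alpha,
                         distribution_alpha = distribution_alpha)
    res$pfm <- p$id
    res
  })
  out <- dplyr::arrange(dplyr::relocate(out, "pfm"), .data$coverage_p)
  class(out) <- c("tfbs_result", class(out))
  out
}
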