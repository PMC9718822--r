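#' Resolve raw ortholog records into a strict 1:1:1 human-keyed table
#'
#' Each ortholog group must contribute exactly one gene per species. Groups
#' missing any of the three species are dropped. When a species has several
#' candidates in a group, the candidate with the highest similarity is kept
#' (ties broken by the lexicographically smallest gene identifier, with a
#' message). Groups with more than one human candidate are dropped entirely:
#' the human gene is the anchor of the map, and an ambiguous anchor cannot be
#' resolved by similarity alone.
#'
#' @param raw tibble of records `group_id`, `species`, `gene_id`,
#'   `similarity` (see [read_ortholog_table()]).
#' @param species the three species expected per group.
#' @return A tibble with one row per resolved group: `human`, `rat`,
#'   `zebrafish` gene identifiers plus `rat_similarity` and
#'   `zebrafish_similarity`, ordered by human identifier.
#' @export
resolve_one_to_one <- function(raw,
                               species = c("human", "rat", "zebrafish")) {
  stopifnot(all(c("group_id", "species", "gene_id", "similarity") %in% names(raw)))
  raw <- dplyr::filter(raw, .data$species %in% !!species)

  # drop groups lacking any species or with an ambiguous human anchor
  cover <- raw |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(
      n_species = dplyr::n_distinct(.data$species),
      n_human = sum(.data$species == "human"),
      .groups = "drop"
    )
  keep <- cover$group_id[cover$n_species == length(species) & cover$n_human == 1]
  n_ambig <- sum(cover$n_human > 1 & cover$n_species == length(species))
  if (n_ambig) {
    rlang::inform(sprintf("dropped %d group(s) with >1 human candidate", n_ambig))
  }
  raw <- dplyr::filter(raw, .data$group_id %in% keep)
  if (!nrow(raw)) {
    return(tibble::tibble(human = character(), rat = character(),
                          zebrafish = character(),
                          rat_similarity = double(),
                          zebrafish_similarity = double()))
  }

  picked <- raw |>
    dplyr::group_by(.data$group_id, .data$species) |>
    dplyr::arrange(dplyr::desc(.data$similarity), .data$gene_id, .by_group = TRUE) |>
    dplyr::summarise(
      tie = dplyr::n() > 1 && .data$similarity[2] == .data$similarity[1],
      gene_id = .data$gene_id[1],
      similarity = .data$similarity[1],
      .groups = "drop"
    )
  n_ties <- sum(picked$tie)
  if (n_ties) {
    rlang::inform(sprintf(
      "%d similarity tie(s) broken by lexicographic gene id", n_ties))
  }

  wide <- picked |>
    dplyr::select(-"tie") |>
    tidyr::pivot_wider(names_from = "species",
                       values_from = c("gene_id", "similarity"))
  out <- tibble::tibble(
    human = wide$gene_id_human,
    rat = wide$gene_id_rat,
    zebrafish = wide$gene_id_zebrafish,
    rat_similarity = wide$similarity_rat,
    zebrafish_similarity = wide$similarity_zebrafish
  )
  for (col in c("human", "rat", "zebrafish")) {
    if (anyDuplicated(out[[col]])) {
      dup <- unique(out[[col]][duplicated(out[[col]])])
      rlang::abort(sprintf(
        "gene id(s) claimed by multiple groups (%s): %s",
        col, paste(head(dup, 5), collapse = ", ")))
    }
  }
  dplyr::arrange(out, .data$human)
}

#' Re-key a species count matrix to human ortholog identifiers
#'
#' Rows are renamed to the human anchor of the resolved 1:1:1 table; genes
#' absent from the table are dropped; counts themselves are never altered.
#' Row order follows the table order, so matrices mapped from different
#' species share an identical gene index up to genes missing from a matrix.
#'
#' @param counts count tibble (first column `gene`).
#' @param table resolved ortholog table from [resolve_one_to_one()].
#' @param species which species the matrix belongs to (`"human"`, `"rat"` or
#'   `"zebrafish"`).
#' @return Count tibble keyed by human gene identifiers.
#' @export
map_to_human <- function(counts, table, species) {
  species <- match.arg(species, c("human", "rat", "zebrafish"))
  key <- table[[species]]
  idx <- match(key, counts$gene)
  keep <- !is.na(idx)
  out <- counts[idx[keep], , drop = FALSE]
  out$gene <- table$human[keep]
  if (anyDuplicated(out$gene)) {
    rlang::abort("duplicate mapping target: ortholog table violates 1:1:1 invariants")
  }
  out
}
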