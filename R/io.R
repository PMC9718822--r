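#' Read a gene-by-sample count table
#'
#' Reads a tab-separated count matrix in the featureCounts convention: a
#' header line, a first column of gene identifiers and one integer column per
#' sample. Lines starting with `#` are skipped. Malformed cells are rejected,
#' not coerced.
#'
#' @param path file path.
#' @return A tibble whose first column is `gene` followed by one numeric
#'   column per sample.
#' @export
read_counts <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  if (ncol(x) < 2) rlang::abort("count table needs a gene column plus >= 1 sample")
  names(x)[1] <- "gene"
  x$gene <- as.character(x$gene)
  if (anyDuplicated(x$gene)) {
    dup <- unique(x$gene[duplicated(x$gene)])
    rlang::abort(paste0("duplicate gene IDs in count table: ",
                        paste(head(dup, 5), collapse = ", ")))
  }
  for (s in names(x)[-1]) {
    col <- x[[s]]
    bad <- which(is.na(col) | !is.numeric(col) | col < 0 | col != floor(col))
    if (length(bad)) {
      rlang::abort(sprintf(
        "invalid count for gene '%s', sample '%s': must be a non-negative integer",
        x$gene[bad[1]], s))
    }
  }
  x
}

#' Write a count table
#'
#' @param counts tibble as returned by [read_counts()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Read a GMT gene-set catalog
#'
#' GMT dialect: one set per line, `name TAB description TAB member...`.
#' Duplicate members within a set are dropped with a warning; empty sets and
#' duplicate set names are errors.
#'
#' @param path file path.
#' @return A tibble with columns `set`, `description` and a list-column
#'   `genes`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) rlang::abort("empty GMT file")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 3)
  if (length(bad)) {
    rlang::abort(sprintf("GMT line %d has no members", bad[1]))
  }
  nm <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(nm)) {
    rlang::abort(paste0("duplicate set names in GMT: ",
                        paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  genes <- lapply(parts, function(p) {
    g <- p[-(1:2)]
    g <- g[nzchar(g)]
    if (anyDuplicated(g)) {
      rlang::warn(sprintf("duplicate members in set '%s' deduplicated", p[[1]]))
      g <- unique(g)
    }
    if (!length(g)) rlang::abort(sprintf("set '%s' has no members", p[[1]]))
    g
  })
  tibble::tibble(
    set = nm,
    description = vapply(parts, `[[`, character(1), 2),
    genes = genes
  )
}

#' Write a GMT gene-set catalog
#'
#' @param catalog tibble with `set`, `description`, list-column `genes`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(catalog, path) {
  lines <- vapply(seq_len(nrow(catalog)), function(i) {
    paste(c(catalog$set[i], catalog$description[i], catalog$genes[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a scored interaction edge list
#'
#' Expects a tab-separated table with columns `protein_a`, `protein_b` and
#' `combined_score`, scores already on the 0-1 scale (STRING's 0-1000 scores
#' must be divided by 1000 by the caller). Self-loops are dropped; duplicate
#' undirected pairs are collapsed keeping the maximal score; edges below
#' `min_score` are removed after collapsing.
#'
#' @param path file path.
#' @param min_score minimal confidence score kept (boundary included).
#' @return Tibble `protein_a`, `protein_b`, `combined_score`.
#' @export
read_edges <- function(path, min_score = 0) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  need <- c("protein_a", "protein_b", "combined_score")
  if (!all(need %in% names(x))) {
    names(x)[1:3] <- need
  }
  x <- dplyr::select(x, dplyr::all_of(need))
  if (any(is.na(x$combined_score) | x$combined_score < 0 | x$combined_score > 1)) {
    rlang::abort("edge scores must lie in [0, 1]")
  }
  clean_edges(x, min_score)
}

clean_edges <- function(edges, min_score = 0) {
  edges <- dplyr::filter(edges, .data$protein_a != .data$protein_b)
  a <- pmin(edges$protein_a, edges$protein_b)
  b <- pmax(edges$protein_a, edges$protein_b)
  edges$protein_a <- a
  edges$protein_b <- b
  edges <- edges |>
    dplyr::group_by(.data$protein_a, .data$protein_b) |>
    dplyr::summarise(combined_score = max(.data$combined_score), .groups = "drop") |>
    dplyr::filter(.data$combined_score >= min_score)
  edges
}

#' Write an edge list
#' @param edges tibble `protein_a`, `protein_b`, `combined_score`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(edges, path) {
  readr::write_tsv(edges, path, progress = FALSE)
  invisible(path)
}

#' Read JASPAR-format position frequency matrices
#'
#' Parses the JASPAR text dialect: a `>ID name` header followed by four rows
#' (A, C, G, T) of equal length, with or without surrounding brackets.
#'
#' @param path file path.
#' @return A named list of PFM objects (see [pfm()]).
#' @export
read_pfm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  starts <- which(startsWith(lines, ">"))
  if (!length(starts)) rlang::abort("no PFM records found")
  ends <- c(starts[-1] - 1, length(lines))
  out <- list()
  for (k in seq_along(starts)) {
    hdr <- sub("^>\\s*", "", lines[starts[k]])
    toks <- strsplit(trimws(hdr), "\\s+")[[1]]
    id <- toks[1]
    name <- if (length(toks) > 1) toks[2] else toks[1]
    body <- lines[(starts[k] + 1):ends[k]]
    if (length(body) != 4) rlang::abort(sprintf("PFM '%s': expected 4 base rows", id))
    rows <- lapply(body, function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
      l <- gsub("[\\[\\]]", " ", l, perl = TRUE)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    w <- unique(vapply(rows, length, integer(1)))
    if (length(w) != 1) rlang::abort(sprintf("PFM '%s': ragged rows", id))
    m <- do.call(rbind, rows)
    rownames(m) <- c("A", "C", "G", "T")
    out[[id]] <- pfm(id, m, name = name)
  }
  out
}

#' Write PFMs in JASPAR text format
#' @param pfms list of PFM objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(pfms, path) {
  lines <- unlist(lapply(pfms, function(p) {
    c(sprintf(">%s %s", p$id, p$name),
      vapply(c("A", "C", "G", "T"), function(b) {
        sprintf("%s [ %s ]", b, paste(p$matrix[b, ], collapse = " "))
      }, character(1)))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a position frequency matrix object
#'
#' @param id motif identifier.
#' @param matrix 4-by-W numeric matrix with rows A, C, G, T and positive
#'   column sums.
#' @param name optional display name.
#' @return An object of class `pfm` holding the frequency matrix and its
#'   log2-odds form against a uniform background (pseudocount 0.25 per cell).
#' @export
pfm <- function(id, matrix, name = id) {
  if (!is.matrix(matrix) || nrow(matrix) != 4 || ncol(matrix) < 1) {
    rlang::abort("PFM matrix must be 4 x W")
  }
  if (any(matrix < 0) || any(colSums(matrix) <= 0)) {
    rlang::abort(sprintf("PFM '%s': column sums must be positive", id))
  }
  rownames(matrix) <- c("A", "C", "G", "T")
  pc <- 0.25
  prob <- sweep(matrix + pc, 2, colSums(matrix) + 4 * pc, `/`)
  lo <- log2(prob / 0.25)
  structure(list(id = id, name = name, matrix = matrix, log_odds = lo,
                 width = ncol(matrix)),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("<pfm> %s (%s), width %d\n", x$id, x$name, x$width))
  invisible(x)
}

#' Read a FASTA file into a gene/sequence tibble
#'
#' Sequences are uppercased; anything outside ACGTN after normalization is an
#' error.
#'
#' @param path file path.
#' @return Tibble with columns `gene` and `sequence`.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    rlang::abort(sprintf("sequence '%s' contains non-ACGTN characters",
                         names(seqs)[which(bad)[1]]))
  }
  tibble::tibble(gene = sub("\\s.*$", "", names(seqs)), sequence = unname(seqs))
}

#' Write a gene/sequence tibble as FASTA
#' @param sequences tibble with `gene` and `sequence`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  writeLines(paste0(">", sequences$gene, "\n", sequences$sequence), path)
  invisible(path)
}

#' Read raw ortholog records
#'
#' Tab-separated records with columns `group_id`, `species`, `gene_id` and a
#' numeric `similarity` (required for every row, making "most homologous"
#' operational when a species has several candidates in a group).
#'
#' @param path file path.
#' @return Tibble of raw records ordered by `group_id`.
#' @export
read_ortholog_table <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  need <- c("group_id", "species", "gene_id", "similarity")
  if (!all(need %in% names(x))) {
    rlang::abort(paste("ortholog table must have columns:",
                       paste(need, collapse = ", ")))
  }
  if (any(is.na(x$similarity))) {
    rlang::abort("ortholog records with missing similarity")
  }
  dplyr::arrange(x[, need], .data$group_id, .data$species, .data$gene_id)
}
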