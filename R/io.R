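#' Read an abundance table from delimited text
#'
#' Canonical layout: header row of taxon ids, first column of sample ids,
#' numeric body of non-negative abundances. `orientation = "taxa"` reads a
#' transposed table (taxa in rows) and transposes it back, so a transposed
#' file loads to the identical matrix.
#'
#' @param path path to a TSV/CSV file
#' @param sep field separator; `NULL` guesses from the file extension
#'   (`.csv` -> comma, otherwise tab)
#' @param orientation `"samples"` (rows are samples, default) or `"taxa"`
#' @param metadata optional path to a per-sample metadata table (first
#'   column sample id; recognised columns `context`, `position`, `subject`)
#' @param drop_empty drop zero-total samples with a warning (default)
#' @return an [abundance_matrix()] object
#' @export
read_abundance <- function(path, sep = NULL, orientation = c("samples", "taxa"),
                           metadata = NULL, drop_empty = TRUE) {
  orientation <- match.arg(orientation)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "")
  vals <- as.matrix(raw)
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(apply(raw, 2, as.numeric))), arr.ind = TRUE)
    if (length(bad))
      stop(sprintf("non-numeric cell at row '%s', column '%s'",
                   rownames(raw)[bad[1, 1]], colnames(raw)[bad[1, 2]]))
    stop("non-numeric abundance table body")
  }
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at row '%s', column '%s'",
                 rownames(vals)[bad[1]], colnames(vals)[bad[2]]))
  }
  if (orientation == "taxa") vals <- t(vals)
  if (any(vals < 0)) {
    bad <- which(vals < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance at sample '%s', taxon '%s'",
                 rownames(vals)[bad[1]], colnames(vals)[bad[2]]))
  }
  meta <- list(context = NULL, position = NULL, subject = NULL)
  if (!is.null(metadata)) {
    md <- utils::read.table(metadata, header = TRUE, sep = sep, row.names = 1,
                            check.names = FALSE, stringsAsFactors = FALSE)
    miss <- setdiff(rownames(vals), rownames(md))
    if (length(miss))
      stop("metadata missing samples: ", paste(miss, collapse = ", "))
    md <- md[rownames(vals), , drop = FALSE]
    for (f in names(meta))
      if (f %in% colnames(md)) meta[[f]] <- as.character(md[[f]])
  }
  abundance_matrix(vals, context = meta$context, position = meta$position,
                   subject = meta$subject, drop_empty = drop_empty)
}

#' Write an abundance table (canonical dialect)
#'
#' Tab-separated, samples in rows, taxon-id header, sample ids in the first
#' column named `sample`. `read_abundance()` of the written file round-trips
#' the matrix.
#' @param M an `abund` object
#' @param path output path
#' @export
write_abundance <- function(M, path) {
  stopifnot(inherits(M, "abund"))
  df <- data.frame(sample = rownames(M$values), M$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy map
#'
#' Table with a taxon-id column followed by rank columns
#' (phylum...species). Returns a data.frame keyed by taxon id.
#' @param path TSV path; first column taxon id
#' @export
read_taxonomy <- function(path) {
  tx <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  tx
}

#' Aggregate taxa to a taxonomic rank
#'
#' Sums abundance columns within each group at `level`. With `top_k`, the
#' `top_k` most abundant groups (ranked by total abundance over all samples,
#' ties broken by lexicographic group name) are kept and the rest merged
#' into an `"other"` bin. Per-sample totals — hence the habitat index — are
#' conserved exactly.
#'
#' @param M an `abund` object
#' @param taxonomy data.frame of lineages keyed by taxon id (see
#'   [read_taxonomy()]), or a named character vector taxon -> group
#' @param level rank column name in `taxonomy` (ignored for a vector map)
#' @param top_k optional integer; groups ranked beyond `top_k` are merged
#' @param other name of the catch-all bin; set `NULL` to error on taxa
#'   missing from the taxonomy
#' @return an `abund` object with one column per group
#' @export
aggregate_taxa <- function(M, taxonomy, level = NULL, top_k = NULL,
                           other = "other") {
  stopifnot(inherits(M, "abund"))
  ids <- taxa(M)
  if (is.data.frame(taxonomy)) {
    if (is.null(level) || !level %in% colnames(taxonomy))
      stop("'level' must name a rank column of the taxonomy")
    map <- stats::setNames(as.character(taxonomy[[level]]), rownames(taxonomy))
  } else {
    map <- taxonomy
  }
  grp <- unname(map[ids])
  if (anyNA(grp)) {
    if (is.null(other))
      stop("taxa missing from taxonomy: ",
           paste(ids[is.na(grp)], collapse = ", "))
    grp[is.na(grp)] <- other
  }
  agg <- t(rowsum(t(M$values), group = grp))
  if (!is.null(top_k) && ncol(agg) > top_k) {
    tot <- colSums(agg)
    ord <- order(-tot, colnames(agg))  # ties: lexicographic
    keep <- colnames(agg)[ord][seq_len(top_k)]
    rest <- setdiff(colnames(agg), keep)
    merged <- rowSums(agg[, rest, drop = FALSE])
    agg <- agg[, keep, drop = FALSE]
    if (other %in% colnames(agg)) {
      agg[, other] <- agg[, other] + merged
    } else {
      agg <- cbind(agg, merged)
      colnames(agg)[ncol(agg)] <- other
    }
  }
  abundance_matrix(agg, context = M$context, position = M$position,
                   subject = M$subject, drop_empty = FALSE)
}
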