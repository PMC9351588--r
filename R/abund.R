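#' Abundance matrix with per-sample metadata
#'
#' Container for a samples x taxa abundance matrix plus optional per-sample
#' labels (context, gut position, subject). The row sum of a sample is its
#' habitat index, the quasi-dynamic independent variable used throughout the
#' package; every retained sample must therefore have strictly positive
#' total abundance.
#'
#' @param values numeric matrix, samples in rows, taxa in columns, all
#'   entries non-negative. Row and column names are used as sample and taxon
#'   ids; defaults are generated when absent.
#' @param context,position,subject optional character vectors of length
#'   `nrow(values)` with per-sample labels.
#' @param drop_empty drop samples whose total abundance is zero (with a
#'   warning) instead of erroring.
#' @return an object of class `"abund"`: a list with elements `values`,
#'   `context`, `position`, `subject`.
#' @examples
#' m <- matrix(1, 4, 4, dimnames = list(paste0("s", 1:4), paste0("t", 1:4)))
#' a <- abundance_matrix(m)
#' habitat_index(a)
#' @export
abundance_matrix <- function(values, context = NULL, position = NULL,
                             subject = NULL, drop_empty = TRUE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (samples x taxa)")
  if (anyNA(values))
    stop("abundance matrix contains missing values")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance at sample %s, taxon %s",
                 rownames(values)[bad[1]] %||% bad[1],
                 colnames(values)[bad[2]] %||% bad[2]))
  }
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("S%d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("T%d", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids")
  if (anyDuplicated(colnames(values)))
    stop("duplicate taxon ids")
  chk <- function(x, nm) {
    if (is.null(x)) return(NULL)
    if (length(x) != nrow(values))
      stop(sprintf("'%s' must have one entry per sample", nm))
    as.character(x)
  }
  obj <- structure(list(values = values,
                        context = chk(context, "context"),
                        position = chk(position, "position"),
                        subject = chk(subject, "subject")),
                   class = "abund")
  empty <- rowSums(obj$values) <= 0
  if (any(empty)) {
    if (!drop_empty)
      stop("samples with zero total abundance: ",
           paste(rownames(values)[empty], collapse = ", "))
    warning(sprintf("dropping %d sample(s) with zero total abundance", sum(empty)))
    obj <- obj[!empty, ]
  }
  obj
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
dim.abund <- function(x) dim(x$values)

#' Subset an abundance matrix
#'
#' `x[i, j]` subsets samples (`i`) and taxa (`j`); per-sample metadata is
#' carried along with the samples.
#' @param x an `abund` object
#' @param i,j sample / taxon indices
#' @param ... ignored
#' @export
`[.abund` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  structure(list(values = x$values[i, j, drop = FALSE],
                 context = x$context[i],
                 position = x$position[i],
                 subject = x$subject[i]),
            class = "abund")
}

#' @export
print.abund <- function(x, ...) {
  cat(sprintf("Abundance matrix: %d samples x %d taxa\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("Habitat index range: [%.4g, %.4g]\n",
              min(habitat_index(x)), max(habitat_index(x))))
  for (f in c("context", "position", "subject"))
    if (!is.null(x[[f]]))
      cat(sprintf("%s: %s\n", f,
                  paste(unique(x[[f]]), collapse = ", ")))
  invisible(x)
}

#' Sample and taxon identifiers
#' @param M an `abund` object
#' @return character vector of ids
#' @export
taxa <- function(M) colnames(M$values)

#' @rdname taxa
#' @export
samples <- function(M) rownames(M$values)

#' Habitat index of every sample
#'
#' The habitat index H_i of sample i is the summed abundance of all taxa in
#' that sample — the total carrying capacity of the habitat. It serves as
#' the independent variable of the quasi-dynamic ODE system.
#'
#' @param M an `abund` object
#' @return named numeric vector, one strictly positive value per sample
#' @export
habitat_index <- function(M) {
  stopifnot(inherits(M, "abund"))
  rowSums(M$values)
}
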