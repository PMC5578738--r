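#' Construct an interaction matrix
#'
#' An `interaction_matrix` holds the N x N signal matrix of a bidirectional
#' bait-prey screen. The orientation convention is fixed throughout the
#' package: **rows are prey, columns are bait**, so `X[i, j]` is the signal of
#' prey `i` probed against bait `j`, and the transposed cell `X[j, i]` is the
#' same protein pair assayed in the opposite orientation.
#'
#' @param X numeric N x N matrix of non-negative signal values (arbitrary
#'   units, e.g. median fluorescence intensity). `NA` entries are treated as
#'   masked.
#' @param proteins character vector of N protein names, used for both rows
#'   and columns in the same order. Defaults to `rownames(X)`.
#' @param mask logical N x N matrix marking missing cells. Defaults to
#'   `is.na(X)`. Masked cells are excluded from all downstream resampling and
#'   are never imputed.
#' @param meta named list of provenance (source file, replicate-averaging
#'   rule, bead filter, ...).
#'
#' @return An object of class `interaction_matrix`: a list with elements
#'   `proteins`, `X`, `mask`, `meta`.
#' @examples
#' X <- matrix(c(100, 5000, 120, 90), 2, 2,
#'             dimnames = list(c("A", "B"), c("A", "B")))
#' interaction_matrix(X)
#' @export
interaction_matrix <- function(X, proteins = rownames(X), mask = NULL,
                               meta = list()) {
  X <- as.matrix(X)
  if (nrow(X) != ncol(X)) {
    stop("interaction matrix must be square, got ", nrow(X), " x ", ncol(X))
  }
  if (nrow(X) < 2) stop("interaction matrix needs at least 2 proteins")
  if (is.null(proteins)) stop("protein names are required")
  proteins <- as.character(proteins)
  if (length(proteins) != nrow(X)) {
    stop("length of 'proteins' must equal matrix dimension")
  }
  if (anyDuplicated(proteins)) stop("duplicated protein names")
  if (is.null(mask)) mask <- is.na(X)
  mask <- matrix(as.logical(mask), nrow(X), ncol(X))
  if (any(!mask & is.na(X))) stop("NA signal in an unmasked cell")
  if (any(X[!mask] < 0)) stop("negative signal values are not allowed")
  X[mask] <- NA_real_
  dimnames(X) <- list(proteins, proteins)
  dimnames(mask) <- dimnames(X)
  structure(list(proteins = proteins, X = X, mask = mask, meta = meta),
            class = "interaction_matrix")
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("interaction_matrix: %d proteins (rows = prey, cols = bait)\n",
              length(x$proteins)))
  cat(sprintf("  masked cells: %d / %d\n", sum(x$mask), length(x$mask)))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.interaction_matrix <- function(x) dim(x$X)

#' Write an interaction matrix to TSV
#'
#' Tab-separated, UTF-8; first row and first column carry the protein names
#' (in identical order); masked cells are written as blank fields; values are
#' serialized with 6 significant digits.
#'
#' @param m an [interaction_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_matrix()]
#' @export
write_matrix <- function(m, path) {
  stopifnot(inherits(m, "interaction_matrix"))
  vals <- matrix("", nrow(m$X), ncol(m$X))
  ok <- !m$mask
  vals[ok] <- formatC(signif(m$X[ok], 6), format = "g", digits = 6)
  body <- cbind(m$proteins, vals)
  lines <- c(paste(c("", m$proteins), collapse = "\t"),
             apply(body, 1, paste, collapse = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an interaction matrix from TSV
#'
#' Expects the dialect written by [write_matrix()]: square, header row and
#' first column both carrying the protein names in the same order, blank
#' cells denoting masked entries.
#'
#' @param path file path.
#' @return An [interaction_matrix()].
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, header = TRUE, row.names = 1,
                           check.names = FALSE, colClasses = "character",
                           na.strings = "")
  cols <- colnames(tab)
  rows <- rownames(tab)
  if (length(rows) != length(cols)) {
    stop("matrix file is not square: ", length(rows), " rows vs ",
         length(cols), " columns")
  }
  if (!setequal(rows, cols)) {
    stop("row and column protein name sets differ")
  }
  if (!identical(rows, cols)) {
    stop("row and column protein orders differ; refusing to guess")
  }
  X <- apply(as.matrix(tab), c(1, 2), function(v) {
    if (is.na(v)) NA_real_ else {
      num <- suppressWarnings(as.numeric(v))
      if (is.na(num)) stop("non-numeric cell value: '", v, "'")
      num
    }
  })
  interaction_matrix(X, proteins = rows, meta = list(source = path))
}
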