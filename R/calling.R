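#' Bootstrap-of-the-median location and spread
#'
#' Draws `B` resamples of size `n = length(values)` with replacement, takes
#' the median of each, and returns the mean and population standard deviation
#' of the `B` medians. These are the row/column statistics against which
#' every cell of the interaction matrix is Z-scored: the median is robust to
#' the genuine-binding cells of a row, so no outlier trimming is needed even
#' when a large fraction of the proteins interact.
#'
#' Resampling is done on indices, so the result is exactly equivariant under
#' affine transformation of `values` at a fixed seed.
#'
#' @param values numeric vector with masked entries already removed; must be
#'   non-empty and free of `NA`.
#' @param B number of bootstrap repetitions (default 300).
#' @param seed optional integer seed; identical inputs and seed give
#'   identical results.
#' @return Named numeric vector `c(mu = ..., sigma = ...)`.
#' @examples
#' bootstrap_median_moments(c(7, 7, 7), B = 50, seed = 1)   # (7, 0)
#' bootstrap_median_moments(c(1, 2, 9), B = 1e4, seed = 1)  # near (3.556, 3.247)
#' @export
bootstrap_median_moments <- function(values, B = 300, seed = NULL) {
  if (length(values) == 0) {
    stop("empty vector: row/column is fully masked")
  }
  if (anyNA(values)) stop("values must not contain NA; remove masked entries")
  stopifnot(B >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- length(values)
  idx <- sample.int(n, n * B, replace = TRUE)
  meds <- col_medians(matrix(values[idx], n, B))
  mu <- mean(meds)
  c(mu = mu, sigma = sqrt(mean((meds - mu)^2)))
}

# column medians without per-column dispatch overhead (n is small, B large)
col_medians <- function(m) {
  n <- nrow(m)
  ms <- apply(m, 2, sort, method = "quick")
  if (n %% 2 == 1) {
    ms[(n + 1) %/% 2, ]
  } else {
    (ms[n %/% 2, ] + ms[n %/% 2 + 1, ]) / 2
  }
}

#' Bootstrap-median Z-scoring of an interaction matrix
#'
#' For every column `j`, [bootstrap_median_moments()] of its unmasked values
#' gives `(mu_j, sigma_j)` and `X_zc(i, j) = (X(i, j) - mu_j) / sigma_j`;
#' symmetrically over rows for `X_zr`; `X_zrc` is the elementwise average of
#' the two. Each row and column resamples from an independent child stream
#' derived from the root seed by its role and position, so results do not
#' depend on evaluation order.
#'
#' Rows/columns whose bootstrap medians have zero spread (e.g. constant
#' values) are *degenerate*: their Z contribution is defined as 0 rather than
#' infinite — a constant row carries no evidence of specific binding, and a
#' zero Z makes the downstream geometric mean undefined, correctly
#' suppressing calls. Masked cells are excluded from the resampling pools and
#' stay masked (`NA`) in all three Z matrices.
#'
#' @param m an [interaction_matrix()].
#' @param B bootstrap repetitions per row/column (default 300).
#' @param seed integer root seed.
#' @return An object of class `zscore_result`: list with `proteins`, `X_zr`,
#'   `X_zc`, `X_zrc`, `mask`, `B`, `seed`, `degenerate_rows`,
#'   `degenerate_cols` (integer indices with zero bootstrap-median spread,
#'   including fully masked ones).
#' @export
zscore_matrix <- function(m, B = 300, seed = 1L) {
  stopifnot(inherits(m, "interaction_matrix"))
  N <- length(m$proteins)
  set.seed(seed)
  child <- sample.int(2147483646L, 2L * N)
  X <- m$X
  mask <- m$mask
  Zc <- Zr <- matrix(NA_real_, N, N, dimnames = dimnames(X))
  degenerate_cols <- integer(0)
  degenerate_rows <- integer(0)
  for (j in seq_len(N)) {
    ok <- !mask[, j]
    if (!any(ok)) {
      degenerate_cols <- c(degenerate_cols, j)
      next
    }
    mm <- bootstrap_median_moments(X[ok, j], B = B, seed = child[j])
    if (mm[["sigma"]] == 0) {
      degenerate_cols <- c(degenerate_cols, j)
      Zc[ok, j] <- 0
    } else {
      Zc[ok, j] <- (X[ok, j] - mm[["mu"]]) / mm[["sigma"]]
    }
  }
  for (i in seq_len(N)) {
    ok <- !mask[i, ]
    if (!any(ok)) {
      degenerate_rows <- c(degenerate_rows, i)
      next
    }
    mm <- bootstrap_median_moments(X[i, ok], B = B, seed = child[N + i])
    if (mm[["sigma"]] == 0) {
      degenerate_rows <- c(degenerate_rows, i)
      Zr[i, ok] <- 0
    } else {
      Zr[i, ok] <- (X[i, ok] - mm[["mu"]]) / mm[["sigma"]]
    }
  }
  structure(list(proteins = m$proteins, X_zr = Zr, X_zc = Zc,
                 X_zrc = (Zr + Zc) / 2, mask = mask, B = B, seed = seed,
                 degenerate_rows = degenerate_rows,
                 degenerate_cols = degenerate_cols),
            class = "zscore_result")
}

#' @export
print.zscore_result <- function(x, ...) {
  cat(sprintf("zscore_result: %d proteins, B = %d, seed = %d\n",
              length(x$proteins), x$B, x$seed))
  if (length(x$degenerate_rows) || length(x$degenerate_cols)) {
    cat(sprintf("  degenerate rows: %s; columns: %s\n",
                paste(x$degenerate_rows, collapse = ","),
                paste(x$degenerate_cols, collapse = ",")))
  }
  invisible(x)
}

#' Combine the two assay orientations of every protein pair
#'
#' Every unordered pair `{A, B}` appears twice in the screen: A as prey
#' against B as bait, and the reverse. The two averaged Z-scores are combined
#' by their geometric mean, which is defined only when both are strictly
#' positive (a zero or negative orientation — including the zero produced by
#' a failed-expression bait — makes the pair uncallable). Diagonal
#' (homophilic) pairs use their single cell for both orientations.
#'
#' @param z a [zscore_matrix()] result.
#' @return A `data.frame` (class `pair_scores`) with one row per unordered
#'   pair: `protein_a`, `protein_b`, `z_ab` (A prey / B bait), `z_ba`,
#'   `gmean` (`NA` when undefined).
#' @export
combine_orientations <- function(z) {
  stopifnot(inherits(z, "zscore_result"))
  N <- length(z$proteins)
  idx <- which(upper.tri(matrix(0, N, N), diag = TRUE), arr.ind = TRUE)
  z_ab <- z$X_zrc[idx]                      # row = prey = A, col = bait = B
  z_ba <- z$X_zrc[idx[, c(2, 1), drop = FALSE]]
  gmean <- rep(NA_real_, length(z_ab))
  defined <- !is.na(z_ab) & !is.na(z_ba) & z_ab > 0 & z_ba > 0
  gmean[defined] <- sqrt(z_ab[defined] * z_ba[defined])
  out <- data.frame(protein_a = z$proteins[idx[, 1]],
                    protein_b = z$proteins[idx[, 2]],
                    z_ab = z_ab, z_ba = z_ba, gmean = gmean,
                    stringsAsFactors = FALSE)
  class(out) <- c("pair_scores", "data.frame")
  out
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Call interactions at a strict geometric-mean threshold
#'
#' A pair is scored as a genuine interactor when its geometric-mean Z exceeds
#' the threshold (strictly: `gmean > threshold`), or when it is listed in the
#' explicit curator overrides. Overrides exist for pairs that are very strong
#' in one orientation but just below the cutoff in the other; they are always
#' flagged in the output, never silent.
#'
#' @param scores a [combine_orientations()] result.
#' @param threshold calling threshold on the geometric mean (default 5).
#' @param overrides optional `data.frame` with columns `protein_a`,
#'   `protein_b` and (recommended) `justification`; pair order is ignored.
#'   An override naming a protein absent from `scores` is an error.
#' @return `scores` with logical `called`, logical `override`, and character
#'   `justification` columns added.
#' @export
call_interactions <- function(scores, threshold = 5, overrides = NULL) {
  stopifnot(inherits(scores, "data.frame"), threshold > 0)
  scores$called <- !is.na(scores$gmean) & scores$gmean > threshold
  scores$override <- rep(FALSE, nrow(scores))
  scores$justification <- rep("", nrow(scores))
  if (!is.null(overrides) && nrow(overrides)) {
    if (!all(c("protein_a", "protein_b") %in% names(overrides))) {
      stop("overrides need columns protein_a, protein_b")
    }
    known <- unique(c(scores$protein_a, scores$protein_b))
    bad <- setdiff(unique(c(overrides$protein_a, overrides$protein_b)), known)
    if (length(bad)) {
      stop("override names unknown protein(s): ", paste(bad, collapse = ", "))
    }
    just <- if ("justification" %in% names(overrides)) {
      as.character(overrides$justification)
    } else {
      rep("curator override", nrow(overrides))
    }
    hit <- match(pair_key(scores$protein_a, scores$protein_b),
                 pair_key(overrides$protein_a, overrides$protein_b))
    ov <- !is.na(hit)
    scores$override <- ov
    scores$called <- scores$called | ov
    scores$justification[ov] <- just[hit[ov]]
  }
  attr(scores, "threshold") <- threshold
  scores
}

#' Quantize pair scores into low/mid/high categories
#'
#' Category thresholds are empirical percentiles (linear interpolation
#' between order statistics, `stats::quantile` type 7) of all finite
#' geometric means in the supplied score set; restrict `scores` to a family
#' submatrix first if the percentile population should be a subset. A pair is
#' `low` when its geometric mean is undefined or below the first cutoff,
#' `mid` in `[p_low, p_high)`, and `high` at or above the upper cutoff.
#'
#' @param scores a [combine_orientations()] (optionally called) result.
#' @param cutoffs two strictly increasing percentile cutoffs in (0, 1);
#'   default `c(0.80, 0.90)`.
#' @return `scores` with a `category` factor (`low` < `mid` < `high`) added;
#'   the numeric thresholds and the percentile convention are recorded in
#'   attributes `quantize_thresholds` and `quantize_convention`.
#' @export
quantize_scores <- function(scores, cutoffs = c(0.80, 0.90)) {
  stopifnot(inherits(scores, "data.frame"))
  if (length(cutoffs) != 2 || any(cutoffs <= 0) || any(cutoffs >= 1) ||
      diff(cutoffs) <= 0) {
    stop("cutoffs must be two strictly increasing values in (0, 1)")
  }
  finite <- scores$gmean[is.finite(scores$gmean)]
  lev <- c("low", "mid", "high")
  if (length(finite) < 2) {
    warning("fewer than 2 finite geometric means; all pairs categorized low")
    scores$category <- factor(rep("low", nrow(scores)), levels = lev,
                              ordered = TRUE)
    attr(scores, "quantize_thresholds") <- c(NA_real_, NA_real_)
  } else {
    thr <- stats::quantile(finite, probs = cutoffs, type = 7, names = FALSE)
    cat_chr <- rep("low", nrow(scores))
    ok <- is.finite(scores$gmean)
    cat_chr[ok & scores$gmean >= thr[1]] <- "mid"
    cat_chr[ok & scores$gmean >= thr[2]] <- "high"
    scores$category <- factor(cat_chr, levels = lev, ordered = TRUE)
    attr(scores, "quantize_thresholds") <- thr
  }
  attr(scores, "quantize_cutoffs") <- cutoffs
  attr(scores, "quantize_convention") <-
    "linear interpolation between order statistics (quantile type 7)"
  scores
}

#' Write / read a pair-score (calls) table
#'
#' Plain TSV with one row per unordered pair; `NA` geometric means are
#' written as empty fields. Numbers are serialized at full precision so a
#' rerun with the same seed round-trips bitwise.
#'
#' @param scores pair-score data.frame.
#' @param path file path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_calls <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  if ("category" %in% names(out)) {
    out$category <- factor(out$category, levels = c("low", "mid", "high"),
                           ordered = TRUE)
  }
  if ("justification" %in% names(out)) {
    out$justification[is.na(out$justification)] <- ""
  }
  out
}
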