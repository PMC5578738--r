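# Independent oracles used across the suite. These stay deliberately naive:
# exhaustive enumeration and brute-force grid search, never the package's own
# code path.

# Exact bootstrap-median distribution: enumerate all n^n equiprobable
# resamples of `values` and return the exact mean/population-SD of the
# resample medians (plus the full median vector for standard-error math).
exact_median_moments <- function(values) {
  n <- length(values)
  stopifnot(n <= 6)
  idx <- as.matrix(do.call(expand.grid, rep(list(seq_len(n)), n)))
  meds <- apply(idx, 1, function(r) stats::median(values[r]))
  mu <- mean(meds)
  list(mu = mu, sigma = sqrt(mean((meds - mu)^2)), medians = meds)
}

# Exact Z-score matrix from the enumerated bootstrap distribution.
exact_zscore <- function(X) {
  N <- nrow(X)
  Zc <- Zr <- matrix(0, N, N)
  for (j in seq_len(N)) {
    mm <- exact_median_moments(X[, j])
    Zc[, j] <- if (mm$sigma == 0) 0 else (X[, j] - mm$mu) / mm$sigma
  }
  for (i in seq_len(N)) {
    mm <- exact_median_moments(X[i, ])
    Zr[i, ] <- if (mm$sigma == 0) 0 else (X[i, ] - mm$mu) / mm$sigma
  }
  (Zr + Zc) / 2
}

# Brute-force grid minimizer of the Langmuir sum of squared errors.
grid_search_langmuir <- function(C, R, n_kd = 161, n_rmax = 161) {
  kd_grid <- exp(seq(log(min(C) / 10), log(max(C) * 10), length.out = n_kd))
  rmax_grid <- seq(0.5 * max(R), 2 * max(R), length.out = n_rmax)
  best <- c(kd = NA_real_, rmax = NA_real_, sse = Inf)
  for (rm in rmax_grid) {
    pred <- outer(C, kd_grid, function(cc, kd) rm * cc / (kd + cc))
    sse <- colSums((pred - R)^2)
    k <- which.min(sse)
    if (sse[k] < best[["sse"]]) best <- c(kd = kd_grid[k], rmax = rm,
                                          sse = sse[k])
  }
  c(best, kd_step = kd_grid[2] / kd_grid[1],
    rmax_step = rmax_grid[2] - rmax_grid[1])
}

# Hand-built zscore_result for tests that exercise pair combination without
# running the bootstrap.
fake_zscore_result <- function(Zrc, proteins = NULL) {
  N <- nrow(Zrc)
  if (is.null(proteins)) proteins <- LETTERS[seq_len(N)]
  dimnames(Zrc) <- list(proteins, proteins)
  structure(list(proteins = proteins, X_zr = Zrc, X_zc = Zrc, X_zrc = Zrc,
                 mask = is.na(Zrc), B = 0L, seed = 0L,
                 degenerate_rows = integer(0), degenerate_cols = integer(0)),
            class = "zscore_result")
}

# Small paper-like simulated screen shared by several tests: strong planted
# signal, modest background, no expression failures.
demo_screen <- function(seed = 42, n_a = 6, n_b = 4, n_edges = 3) {
  truth <- generate_truth(n_a, n_b, n_edges = n_edges,
                          kd_range = c(0.5, 10), fail_prob = 0,
                          family_a = "Rec", family_b = "Lig", seed = seed)
  list(truth = truth, matrix = simulate_matrix(truth, seed = seed + 1))
}
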