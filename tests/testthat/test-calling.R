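test_that("bootstrap of the median matches the exhaustive-resample oracle", {
  # constant vector: location is the value, spread is zero
  expect_equal(bootstrap_median_moments(c(7, 7, 7), B = 50, seed = 1),
               c(mu = 7, sigma = 0))

  # [1, 2, 9]: all 3^3 = 27 equiprobable resamples give exactly
  # mu = 96/27 and sigma = 3.2467 (frozen from the enumeration oracle)
  ex <- exact_median_moments(c(1, 2, 9))
  expect_equal(ex$mu, 96 / 27)
  expect_equal(ex$sigma, sqrt(626 / 27 - (96 / 27)^2))  # = 3.24703

  # Monte-Carlo estimate agrees with the enumeration within 3 standard errors
  B <- 1e4
  mc <- bootstrap_median_moments(c(1, 2, 9), B = B, seed = 2)
  se_mu <- ex$sigma / sqrt(B)
  dev2 <- (ex$medians - ex$mu)^2
  se_sigma <- sqrt(mean((dev2 - mean(dev2))^2) / B) / (2 * ex$sigma)
  expect_lt(abs(mc[["mu"]] - ex$mu), 3 * se_mu)
  expect_lt(abs(mc[["sigma"]] - ex$sigma), 3 * se_sigma)
})

test_that("bootstrap moments are deterministic and reject bad input", {
  a <- bootstrap_median_moments(c(3, 1, 4, 1, 5), B = 200, seed = 9)
  b <- bootstrap_median_moments(c(3, 1, 4, 1, 5), B = 200, seed = 9)
  expect_identical(a, b)
  expect_error(bootstrap_median_moments(numeric(0)), "fully masked")
  expect_error(bootstrap_median_moments(c(1, NA)), "NA")
})

test_that("Z-scoring a constant matrix yields all-zero, all-degenerate output", {
  m <- interaction_matrix(matrix(5, 4, 4,
                                 dimnames = list(letters[1:4], letters[1:4])))
  z <- zscore_matrix(m, B = 100, seed = 3)
  expect_true(all(z$X_zrc == 0))
  expect_identical(z$degenerate_rows, 1:4)
  expect_identical(z$degenerate_cols, 1:4)
})

test_that("a planted cell dominates the Z matrix and tracks the exact oracle", {
  set.seed(21)
  X <- matrix(rnorm(16, 100, 5), 4, 4)
  X[2, 3] <- 100 * 100  # planted signal at 100x background
  dimnames(X) <- list(letters[1:4], letters[1:4])
  z <- zscore_matrix(interaction_matrix(X), B = 5e4, seed = 4)
  expect_equal(which.max(z$X_zrc), which.max(X))
  # against enumeration of all 4^4 resamples per row/column
  Zex <- exact_zscore(X)
  expect_equal(unname(z$X_zrc), Zex, tolerance = 0.02)
})

test_that("Z matrices are exactly invariant under affine rescaling at fixed seed", {
  scr <- demo_screen(seed = 31)
  z1 <- zscore_matrix(scr$matrix, B = 150, seed = 7)
  m2 <- scr$matrix
  m2$X <- 3.7 * m2$X + 250
  z2 <- zscore_matrix(m2, B = 150, seed = 7)
  expect_equal(z1$X_zr, z2$X_zr, tolerance = 1e-12)
  expect_equal(z1$X_zc, z2$X_zc, tolerance = 1e-12)
  expect_equal(z1$X_zrc, z2$X_zrc, tolerance = 1e-12)
})

test_that("masked cells are excluded from pools and stay masked downstream", {
  scr <- demo_screen(seed = 33)
  m <- scr$matrix
  m$mask[1, 2] <- TRUE
  m$X[1, 2] <- NA
  z <- zscore_matrix(m, B = 100, seed = 5)
  expect_true(is.na(z$X_zr[1, 2]) && is.na(z$X_zc[1, 2]) &&
                is.na(z$X_zrc[1, 2]))
  sc <- combine_orientations(z)
  a <- m$proteins[1]; b <- m$proteins[2]
  row <- sc[sc$protein_a == a & sc$protein_b == b, ]
  expect_true(is.na(row$gmean))
  # the averaged-Z identity holds on every unmasked cell
  ok <- !is.na(z$X_zrc)
  expect_equal(z$X_zrc[ok], ((z$X_zr + z$X_zc) / 2)[ok])
})

test_that("orientation combination follows the geometric-mean rules", {
  Z <- matrix(0, 2, 2)
  Z[1, 2] <- 4; Z[2, 1] <- 9     # A prey vs B bait = 4; reverse = 9
  sc <- combine_orientations(fake_zscore_result(Z))
  ab <- sc[sc$protein_a == "A" & sc$protein_b == "B", ]
  expect_equal(ab$gmean, 6)

  # one orientation at zero (the failed-bait case) or negative: undefined
  for (bad in c(0, -1)) {
    Z[1, 2] <- bad; Z[2, 1] <- 10
    sc <- combine_orientations(fake_zscore_result(Z))
    ab <- sc[sc$protein_a == "A" & sc$protein_b == "B", ]
    expect_true(is.na(ab$gmean))
    expect_false(call_interactions(sc)$called[is.na(sc$gmean)][1])
  }

  # diagonal pairs use their single cell twice
  Z2 <- diag(c(3, -2))
  sc2 <- combine_orientations(fake_zscore_result(Z2))
  aa <- sc2[sc2$protein_a == "A" & sc2$protein_b == "A", ]
  expect_equal(aa$gmean, 3)
  bb <- sc2[sc2$protein_a == "B" & sc2$protein_b == "B", ]
  expect_true(is.na(bb$gmean))
})

test_that("calling uses a strict threshold and explicit overrides", {
  sc <- data.frame(protein_a = c("A", "A", "B"),
                   protein_b = c("B", "C", "C"),
                   z_ab = c(5, 25.1001, 2), z_ba = c(5, 1, 30),
                   gmean = c(5.0, 5.01, NA))
  called <- call_interactions(sc, threshold = 5)
  expect_identical(called$called, c(FALSE, TRUE, FALSE))

  # strong in one orientation, just below the cutoff combined: preserved
  # only through a logged override
  ov <- data.frame(protein_a = "C", protein_b = "B",
                   justification = "very strong in one orientation")
  called2 <- call_interactions(sc, threshold = 5, overrides = ov)
  expect_identical(called2$called, c(FALSE, TRUE, TRUE))
  expect_identical(called2$override, c(FALSE, FALSE, TRUE))
  expect_match(called2$justification[3], "strong in one orientation")

  expect_error(call_interactions(sc, overrides = data.frame(
    protein_a = "A", protein_b = "Nessie")), "unknown protein")
  empty <- call_interactions(sc[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("the called set shrinks monotonically as the threshold rises", {
  scr <- demo_screen(seed = 55, n_a = 8, n_b = 6, n_edges = 6)
  sc <- combine_orientations(zscore_matrix(scr$matrix, B = 200, seed = 8))
  keys <- function(d) with(d[d$called, ], paste(protein_a, protein_b))
  prev <- keys(call_interactions(sc, threshold = 1))
  for (t in c(2, 5, 10, 20)) {
    cur <- keys(call_interactions(sc, threshold = t))
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("quantization uses linear-interpolation percentiles of finite gmeans", {
  sc <- data.frame(protein_a = sprintf("a%02d", 1:20),
                   protein_b = sprintf("b%02d", 1:20),
                   z_ab = 1, z_ba = 1, gmean = as.numeric(1:20))
  q <- quantize_scores(sc, cutoffs = c(0.8, 0.9))
  expect_identical(as.character(q$category[q$gmean >= 19]), rep("high", 2))
  expect_identical(as.character(q$category[q$gmean %in% 17:18]),
                   rep("mid", 2))
  expect_identical(as.character(q$category[q$gmean <= 16]), rep("low", 16))
  expect_equal(unname(attr(q, "quantize_thresholds")), c(16.2, 18.1))

  sc$gmean <- NA_real_
  expect_warning(q2 <- quantize_scores(sc), "fewer than 2")
  expect_true(all(q2$category == "low"))
})

test_that("identical matrix, B and seed reproduce the Z result bitwise", {
  scr <- demo_screen(seed = 77)
  z1 <- zscore_matrix(scr$matrix, B = 120, seed = 13)
  z2 <- zscore_matrix(scr$matrix, B = 120, seed = 13)
  expect_identical(z1, z2)
  z3 <- zscore_matrix(scr$matrix, B = 120, seed = 14)
  expect_false(identical(z1$X_zrc, z3$X_zrc))
})
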