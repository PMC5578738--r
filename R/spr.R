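#' Construct an equilibrium SPR titration series
#'
#' Holds the steady-state binding responses of one analyte titration over an
#' immobilized ligand. Only equilibrium analysis is supported: when
#' dissociation is too fast to resolve kinetically, the plateau response at
#' each analyte concentration still identifies the affinity through the
#' Langmuir isotherm.
#'
#' @param concentration analyte concentrations (uM), strictly positive and
#'   pairwise distinct within a series.
#' @param response equilibrium responses (RU), non-negative.
#' @param ligand,analyte protein names (immobilized / mobile phase).
#' @param replicate integer series index (>= 1).
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(concentration, response, ligand = "ligand",
                             analyte = "analyte", replicate = 1L) {
  concentration <- as.numeric(concentration)
  response <- as.numeric(response)
  if (length(concentration) != length(response)) {
    stop("concentration and response lengths differ")
  }
  if (length(concentration) == 0) stop("empty titration series")
  if (any(!is.finite(concentration)) || any(concentration <= 0)) {
    stop("concentrations must be strictly positive")
  }
  if (anyDuplicated(concentration)) {
    stop("concentrations must be pairwise distinct within a series")
  }
  if (any(!is.finite(response)) || any(response < 0)) {
    stop("responses must be non-negative")
  }
  structure(list(ligand = ligand, analyte = analyte,
                 replicate = as.integer(replicate),
                 concentration = concentration, response = response),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("titration_series: %s over immobilized %s (replicate %d), %d points, %g-%g uM\n",
              x$analyte, x$ligand, x$replicate, length(x$concentration),
              min(x$concentration), max(x$concentration)))
  invisible(x)
}

#' Fit a Langmuir binding isotherm to an equilibrium titration
#'
#' Unweighted nonlinear least squares of `R_eq(C) = R_max * C / (K_D + C)`
#' (Levenberg-Marquardt, both parameters constrained positive). Standard
#' errors come from the parameter covariance at the optimum. If the
#' optimizer fails, or the fitted `K_D` falls outside
#' `[min(C)/100, max(C) * 100]` (an affinity the titration cannot support),
#' the fit is flagged not converged and the estimates are kept for
#' diagnostics only.
#'
#' Self-start when `init` is omitted: `R_max` starts at 1.1x the largest
#' observed response, `K_D` at the concentration whose response is nearest
#' half of that — robust for both saturating and non-saturating series.
#'
#' @param series a [titration_series()] with at least 4 points.
#' @param init optional named vector `c(K_D = ..., R_max = ...)`.
#' @return An object of class `langmuir_fit`: list with `K_D`, `R_max`
#'   (point estimates), `se_KD`, `se_Rmax`, `rss`, `n_points`, `converged`,
#'   `ligand`, `analyte`, `replicate`, `message`.
#' @examples
#' s <- simulate_titration(K_D = 1, R_max = 100,
#'                         concentrations = 2^(-4:3), cv = 0, seed = 1)
#' fit_langmuir(s)  # recovers (1, 100)
#' @export
fit_langmuir <- function(series, init = NULL) {
  stopifnot(inherits(series, "titration_series"))
  C <- series$concentration
  R <- series$response
  if (length(C) < 4) {
    stop("fit refused: need >= 4 titration points, got ", length(C))
  }
  if (is.null(init)) {
    rmax0 <- 1.1 * max(R)
    kd0 <- C[which.min(abs(R - rmax0 / 2))]
    init <- c(K_D = kd0, R_max = rmax0)
  }
  if (any(init <= 0)) stop("init values must be positive")
  dat <- data.frame(C = C, R = R)
  fit <- tryCatch(
    minpack.lm::nlsLM(R ~ R_max * C / (K_D + C), data = dat,
                      start = list(K_D = init[["K_D"]],
                                   R_max = init[["R_max"]]),
                      lower = c(K_D = .Machine$double.xmin,
                                R_max = .Machine$double.xmin),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(K_D = NA_real_, R_max = NA_real_,
                          se_KD = NA_real_, se_Rmax = NA_real_,
                          rss = NA_real_, n_points = length(C),
                          converged = FALSE, ligand = series$ligand,
                          analyte = series$analyte,
                          replicate = series$replicate,
                          message = conditionMessage(fit)),
                     class = "langmuir_fit"))
  }
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(K_D = NA_real_, R_max = NA_real_))
  kd <- unname(est[["K_D"]])
  in_range <- kd >= min(C) / 100 && kd <= max(C) * 100
  structure(list(K_D = kd, R_max = unname(est[["R_max"]]),
                 se_KD = unname(se[["K_D"]]), se_Rmax = unname(se[["R_max"]]),
                 rss = sum(stats::resid(fit)^2), n_points = length(C),
                 converged = fit$convInfo$isConv && in_range,
                 ligand = series$ligand, analyte = series$analyte,
                 replicate = series$replicate,
                 message = if (in_range) "" else
                   sprintf("K_D %.3g outside supportable range [%.3g, %.3g]",
                           kd, min(C) / 100, max(C) * 100)),
            class = "langmuir_fit")
}

#' @export
print.langmuir_fit <- function(x, ...) {
  cat(sprintf("langmuir_fit: %s::%s  K_D = %.4g +/- %.2g uM, R_max = %.4g +/- %.2g RU (%s, %d points)\n",
              x$ligand, x$analyte, x$K_D, x$se_KD, x$R_max, x$se_Rmax,
              if (x$converged) "converged" else "NOT converged", x$n_points))
  if (nzchar(x$message)) cat("  ", x$message, "\n")
  invisible(x)
}

#' @export
predict.langmuir_fit <- function(object, concentration, ...) {
  object$R_max * concentration / (object$K_D + concentration)
}

#' Pool replicate Langmuir fits of the same pair
#'
#' @param fits list of >= 2 converged [fit_langmuir()] results for the same
#'   ligand::analyte pair.
#' @return Named numeric vector `c(K_D = arithmetic mean, sem = standard
#'   error of the mean, n = number of fits)`.
#' @examples
#' \dontrun{pool_fits(list(f1, f2, f3))}
#' @export
pool_fits <- function(fits) {
  if (inherits(fits, "langmuir_fit")) fits <- list(fits)
  if (length(fits) < 2) {
    stop("pooling needs >= 2 replicate fits; for a single series use its ",
         "per-fit standard error (se_KD)")
  }
  stopifnot(all(vapply(fits, inherits, TRUE, "langmuir_fit")))
  if (!all(vapply(fits, `[[`, TRUE, "converged"))) {
    stop("all pooled fits must have converged")
  }
  pairs <- vapply(fits, function(f) paste(f$ligand, f$analyte, sep = "::"), "")
  if (length(unique(pairs)) != 1) {
    stop("cannot pool fits of different pairs: ",
         paste(unique(pairs), collapse = ", "))
  }
  kds <- vapply(fits, `[[`, 0, "K_D")
  c(K_D = mean(kds), sem = stats::sd(kds) / sqrt(length(kds)),
    n = length(kds))
}

#' Read / write titration series tables
#'
#' TSV with columns `ligand, analyte, replicate, concentration_uM,
#' response_RU`; one file may hold many series (split by ligand, analyte and
#' replicate).
#'
#' @param path file path.
#' @param series list of [titration_series()] (write).
#' @return list of `titration_series` (read) or `path` (write).
#' @export
read_titrations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("ligand", "analyte", "replicate", "concentration_uM",
            "response_RU")
  if (!all(need %in% names(tab))) {
    stop("titration file needs columns: ", paste(need, collapse = ", "))
  }
  parts <- split(tab, paste(tab$ligand, tab$analyte, tab$replicate,
                            sep = "\r"))
  out <- lapply(parts, function(p) {
    titration_series(p$concentration_uM, p$response_RU, ligand = p$ligand[1],
                     analyte = p$analyte[1], replicate = p$replicate[1])
  })
  names(out) <- vapply(out, function(s) {
    sprintf("%s::%s/%d", s$ligand, s$analyte, s$replicate)
  }, "")
  out[order(names(out))]
}

#' @rdname read_titrations
#' @export
write_titrations <- function(series, path) {
  if (inherits(series, "titration_series")) series <- list(series)
  tab <- do.call(rbind, lapply(series, function(s) {
    data.frame(ligand = s$ligand, analyte = s$analyte,
               replicate = s$replicate, concentration_uM = s$concentration,
               response_RU = s$response, stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
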