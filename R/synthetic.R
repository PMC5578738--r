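#' Generate a synthetic ground-truth bipartite interactome
#'
#' Plants a sparse bipartite edge set between two protein families with
#' per-edge affinities, per-protein per-role expression factors, and optional
#' expression failures — the latent structure that the screen's observed
#' matrix is generated from. Affinities are log-uniform over `kd_range`;
#' expression factors are log-normal with median 1; failures are Bernoulli
#' per (protein, role) and force the factor to 0, which downstream makes the
#' affected row/column indistinguishable from background (the
#' failed-bait phenomenon that leaves one orientation's Z at zero).
#'
#' @param n_a,n_b family sizes (e.g. 14 receptors x 8 ligands).
#' @param density fraction of the `n_a * n_b` cross pairs that interact;
#'   each cross pair is an edge independently with this probability.
#' @param n_edges optional exact edge count; when given, exactly `n_edges`
#'   cross pairs are drawn uniformly without replacement and `density` is
#'   ignored.
#' @param kd_range two positive numbers (uM); per-edge K_D is log-uniform in
#'   this interval. Default `c(0.5, 50)`, the weak micromolar regime typical
#'   of cell-surface protein interactions.
#' @param fail_prob probability that a (protein, role) fails to express.
#' @param expr_sdlog log-scale SD of the expression factors (median 1);
#'   default 0.25, a modest batch-to-batch spread.
#' @param noise list with `b0` (background mean signal), `bg_sd` (background
#'   SD) and `cv` (multiplicative noise CV of the specific signal). Defaults
#'   `b0 = 100, bg_sd = 10, cv = 0.10`: background under ~100 a.u. against
#'   strong-binder signals in the tens of thousands, as in a bead assay with
#'   high signal-to-background ratio.
#' @param names_a,names_b optional protein names (defaults `A01..`, `B01..`).
#' @param family_a,family_b family labels for the node annotation.
#' @param seed integer seed; the truth is deterministic given all arguments.
#' @return An object of class `synthetic_truth`: list with `proteins`
#'   (data.frame name/family), `edges` (data.frame protein_a, protein_b,
#'   kd_uM), `expression` (data.frame protein, role, factor),
#'   `failed` (data.frame protein, role), `noise`, `seed`.
#' @export
generate_truth <- function(n_a, n_b, density = 0.1, n_edges = NULL,
                           kd_range = c(0.5, 50),
                           fail_prob = 0, expr_sdlog = 0.25,
                           noise = list(b0 = 100, bg_sd = 10, cv = 0.10),
                           names_a = NULL, names_b = NULL,
                           family_a = "A", family_b = "B", seed = 1L) {
  if (n_a < 1 || n_b < 1) stop("family sizes must be >= 1")
  stopifnot(density >= 0, density <= 1, all(kd_range > 0),
            fail_prob >= 0, fail_prob <= 1)
  set.seed(seed)
  if (is.null(names_a)) names_a <- sprintf("%s%02d", family_a, seq_len(n_a))
  if (is.null(names_b)) names_b <- sprintf("%s%02d", family_b, seq_len(n_b))
  proteins <- data.frame(name = c(names_a, names_b),
                         family = rep(c(family_a, family_b), c(n_a, n_b)),
                         stringsAsFactors = FALSE)
  cross <- expand.grid(protein_a = names_a, protein_b = names_b,
                       stringsAsFactors = FALSE)
  if (is.null(n_edges)) {
    on <- stats::runif(nrow(cross)) < density
  } else {
    stopifnot(n_edges >= 0, n_edges <= nrow(cross))
    on <- seq_len(nrow(cross)) %in% sample.int(nrow(cross), n_edges)
  }
  edges <- cross[on, , drop = FALSE]
  edges$kd_uM <- exp(stats::runif(nrow(edges), log(kd_range[1]),
                                  log(kd_range[2])))
  rownames(edges) <- NULL
  roles <- expand.grid(protein = proteins$name, role = c("bait", "prey"),
                       stringsAsFactors = FALSE)
  roles$factor <- stats::rlnorm(nrow(roles), meanlog = 0, sdlog = expr_sdlog)
  fail <- stats::runif(nrow(roles)) < fail_prob
  roles$factor[fail] <- 0
  structure(list(proteins = proteins, edges = edges,
                 expression = roles[c("protein", "role", "factor")],
                 failed = roles[fail, c("protein", "role")],
                 noise = noise, seed = seed),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d proteins, %d planted edges, %d failed (protein, role)\n",
              nrow(x$proteins), nrow(x$edges), nrow(x$failed)))
  invisible(x)
}

lnorm_mean1 <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate an observed interaction matrix from a planted truth
#'
#' Cell signal model (prey i, bait j):
#' `X(i, j) = b0 * eps_bg + e_bait(j) * e_prey(i) * s_max * c_eff /
#' (c_eff + K_D(i, j)) * eps_mult` when the pair is a planted edge, and
#' background only otherwise. `eps_bg` and `eps_mult` are mean-1 log-normal
#' draws (signals are positive and heteroscedastic); both orientations get
#' independent noise and role-specific expression factors, so the observed
#' matrix is asymmetric even though the truth is unordered. The saturation
#' term makes expected signal strictly decreasing in K_D, reproducing the
#' rank relation between assay signal and measured affinity, with a single
#' effective prey concentration `c_eff` standing in for the avidity of
#' multimerized binding partners.
#'
#' @param truth a [generate_truth()] object.
#' @param seed integer seed for the noise draws (separate from the truth's).
#' @param s_max saturating specific signal (a.u.) at full expression;
#'   default 20000, i.e. `s_max / b0 = 200` under the default background.
#' @param c_eff effective prey concentration (uM), default 1.
#' @return An [interaction_matrix()] over all proteins (family A first).
#' @export
simulate_matrix <- function(truth, seed = 1L, s_max = 20000, c_eff = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(seed)
  prot <- truth$proteins$name
  N <- length(prot)
  nz <- truth$noise
  bg_cv <- nz$bg_sd / nz$b0
  X <- nz$b0 * matrix(lnorm_mean1(N * N, bg_cv), N, N)
  e_bait <- e_prey <- stats::setNames(rep(1, N), prot)
  ex <- truth$expression
  e_bait[ex$protein[ex$role == "bait"]] <- ex$factor[ex$role == "bait"]
  e_prey[ex$protein[ex$role == "prey"]] <- ex$factor[ex$role == "prey"]
  if (nrow(truth$edges)) {
    for (k in seq_len(nrow(truth$edges))) {
      a <- truth$edges$protein_a[k]
      b <- truth$edges$protein_b[k]
      occ <- s_max * c_eff / (c_eff + truth$edges$kd_uM[k])
      i <- match(a, prot); j <- match(b, prot)
      # orientation 1: a is prey, b is bait; orientation 2: reversed
      X[i, j] <- X[i, j] + e_prey[a] * e_bait[b] * occ * lnorm_mean1(1, nz$cv)
      X[j, i] <- X[j, i] + e_prey[b] * e_bait[a] * occ * lnorm_mean1(1, nz$cv)
    }
  }
  X[X < 0] <- 0
  interaction_matrix(X, proteins = prot,
                     meta = list(source = "synthetic", seed = seed,
                                 s_max = s_max, c_eff = c_eff,
                                 truth_seed = truth$seed))
}

#' Expand a simulated matrix into multiplexed plate reads
#'
#' Emulates the plate layout of a multiplexed bead screen: one well per prey
#' carrying every bait on its own bead region, run in duplicate. Replicate
#' MFIs scatter around the matrix cell value with a small log-normal CV, and
#' bead counts are Poisson. With the default parameters
#' [assemble_matrix()] recovers the input matrix up to replicate noise.
#'
#' @param m an [interaction_matrix()] (typically from [simulate_matrix()]).
#' @param seed integer seed.
#' @param replicates number of duplicate wells per prey (default 2).
#' @param mean_beads Poisson mean of counted beads per region (default 200;
#'   counts below the analysis floor of 35 are then rare but possible).
#' @param replicate_cv log-normal CV between replicate MFIs (default 0.05).
#' @return data.frame of plate reads (see [read_plate()]).
#' @export
simulate_plate_reads <- function(m, seed = 1L, replicates = 2,
                                 mean_beads = 200, replicate_cv = 0.05) {
  stopifnot(inherits(m, "interaction_matrix"), replicates >= 1)
  set.seed(seed)
  prot <- m$proteins
  N <- length(prot)
  grid <- expand.grid(prey_i = seq_len(N), bait_j = seq_len(N),
                      replicate = seq_len(replicates))
  mfi_true <- m$X[cbind(grid$prey_i, grid$bait_j)]
  keep <- !is.na(mfi_true)
  grid <- grid[keep, , drop = FALSE]
  mfi_true <- mfi_true[keep]
  n <- nrow(grid)
  data.frame(
    well_id = sprintf("P%02dR%d", grid$prey_i, grid$replicate),
    bead_region = as.integer(grid$bait_j),
    bait = prot[grid$bait_j],
    prey = prot[grid$prey_i],
    mfi = mfi_true * lnorm_mean1(n, replicate_cv),
    bead_count = as.integer(stats::rpois(n, mean_beads)),
    replicate = as.integer(grid$replicate),
    stringsAsFactors = FALSE)
}

#' Simulate an equilibrium SPR titration series
#'
#' `R(C) = R_max * C / (K_D + C) * (1 + cv * xi)` with `xi` standard normal
#' per point, clamped at 0.
#'
#' @param K_D true dissociation constant (uM).
#' @param R_max true saturating response (RU).
#' @param concentrations analyte concentrations (uM), non-empty, positive,
#'   distinct.
#' @param cv multiplicative noise CV (0 for a noiseless series).
#' @param seed integer seed.
#' @param ligand,analyte,replicate passed to [titration_series()].
#' @return A [titration_series()].
#' @export
simulate_titration <- function(K_D, R_max, concentrations, cv = 0,
                               seed = 1L, ligand = "ligand",
                               analyte = "analyte", replicate = 1L) {
  stopifnot(K_D > 0, R_max > 0, cv >= 0)
  if (length(concentrations) == 0) stop("empty concentration list")
  set.seed(seed)
  r <- R_max * concentrations / (K_D + concentrations)
  if (cv > 0) r <- r * (1 + cv * stats::rnorm(length(r)))
  r[r < 0] <- 0
  titration_series(concentrations, r, ligand = ligand, analyte = analyte,
                   replicate = replicate)
}

#' Two-fold dilution series bracketing an affinity
#'
#' Convenience for parameter-recovery protocols: `n` two-fold dilutions whose
#' top concentration is `top_factor * K_D` (default 40x, reaching ~0.02x K_D
#' at the bottom for `n = 12`).
#'
#' @param K_D affinity to bracket (uM).
#' @param n number of concentrations (default 12).
#' @param top_factor top concentration as a multiple of `K_D` (default 40).
#' @return numeric vector of concentrations, ascending.
#' @export
dilution_series <- function(K_D, n = 12, top_factor = 40) {
  stopifnot(K_D > 0, n >= 1, top_factor > 0)
  sort(top_factor * K_D / 2^(seq_len(n) - 1))
}

#' Score a called pair set against a planted truth
#'
#' @param truth a [generate_truth()] object.
#' @param calls a [call_interactions()] result over the simulated screen.
#' @return Named numeric vector: `sensitivity` (fraction of planted edges
#'   called), `false_positives` (called pairs not planted), `n_called`.
#' @export
evaluate_recovery <- function(truth, calls) {
  stopifnot(inherits(truth, "synthetic_truth"), "called" %in% names(calls))
  norm <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  truth_keys <- norm(truth$edges$protein_a, truth$edges$protein_b)
  called <- calls[calls$called, , drop = FALSE]
  call_keys <- unique(norm(called$protein_a, called$protein_b))
  c(sensitivity = if (length(truth_keys)) {
      mean(truth_keys %in% call_keys)
    } else NA_real_,
    false_positives = sum(!(call_keys %in% truth_keys)),
    n_called = length(call_keys))
}

#' One planted-network recovery trial of the full calling pipeline
#'
#' Generates a planted bipartite truth, simulates the observed matrix, runs
#' Z-scoring, orientation combination and threshold calling, and scores the
#' called set against the truth. Defaults reproduce the screen's scale: 23
#' proteins, 10 planted edges with K_D in the 0.5-10 uM range, strong
#' signal-to-background, 10% multiplicative noise, no expression failures.
#'
#' @param seed integer seed driving truth, noise and bootstrap streams.
#' @param n_a,n_b,n_edges family sizes and planted edge count.
#' @param kd_range planted affinity range (uM).
#' @param B,threshold calling parameters.
#' @param ... further arguments passed to [generate_truth()].
#' @return See [evaluate_recovery()].
#' @export
recovery_trial <- function(seed, n_a = 15, n_b = 8, n_edges = 10,
                           kd_range = c(0.5, 10), B = 300, threshold = 5,
                           ...) {
  truth <- generate_truth(n_a, n_b, n_edges = n_edges, kd_range = kd_range,
                          fail_prob = 0, seed = seed, ...)
  m <- simulate_matrix(truth, seed = seed + 1L)
  z <- zscore_matrix(m, B = B, seed = seed + 2L)
  calls <- call_interactions(combine_orientations(z), threshold = threshold)
  evaluate_recovery(truth, calls)
}
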