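---
title: "Methods: scoring, calling and affinity fitting in plexscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, calling and affinity fitting in plexscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the statistical model behind `plexscreen`, the exact
definition of every estimator the package computes, the parameter defaults
with their rationale, and the numerical and design decisions that a user
reproducing or auditing results needs to know. Code chunks are shown but not
evaluated; all quoted numbers were produced by the package's test suite and
the scripts under `analysis/`.

## 1. The assay and its data

A multiplexed bead-array interactome screen expresses every protein of a
candidate set in two forms: a *bait* form captured on a coded bead region,
and a multimerized *prey* form added in solution. One well contains one prey
against every bait simultaneously; a well per prey covers the full matrix,
and each reaction is run in duplicate. The readout per (bead region, well)
is the median fluorescence intensity (MFI) over the beads of that region
counted in that well.

`read_plate()` ingests the long-format reads
(`well_id, bead_region, bait, prey, mfi, bead_count, replicate`) and
validates them (non-negative MFI, bead regions in 1–500, no duplicate
(region, well, replicate) records, optional layout cross-check).
`assemble_matrix()` turns reads into the square matrix
\(X\) with rows = prey and columns = bait:

* replicates with `bead_count < 35` are discarded — below that count the
  median of the bead distribution is too unstable to trust;
* the surviving replicate MFIs of a cell are combined by their **arithmetic
  mean with no background subtraction**. Background handling is deliberately
  deferred to the scoring stage, where each cell is judged against its own
  row and column rather than against a global blank;
* cells with no surviving replicate are masked (`NA` plus a logical mask),
  not imputed, and propagate as `NA` through scoring.

`assay_well_count(n, multiplexed)` records the design arithmetic: screening
23 proteins pairwise needs 23 multiplexed wells instead of the 23 × 23 = 529
wells a one-bait-per-well assay would use.

## 2. The scoring statistic

Specific binding must be detected against cell-to-cell variation in
expression level and background. The package scores each unmasked cell
twice, once against its row and once against its column, with a
bootstrap-of-the-median location/scale estimate.

For a vector \(v\) of \(n\) cell values (one row or one column),
`bootstrap_median_moments()` draws \(B = 300\) resamples of size \(n\) with
replacement, takes the median of each, and returns

\[ \hat\mu = \operatorname{mean}(m_1,\dots,m_B), \qquad
   \hat\sigma = \sqrt{\tfrac1B \sum_b (m_b - \hat\mu)^2 } . \]

\(\hat\sigma\) is the **population** standard deviation of the resample
medians — i.e. the bootstrap standard error of the median — not the sample
standard deviation of the cell values. The cell's row Z-score is
\((x - \hat\mu_{\text{row}})/\hat\sigma_{\text{row}}\), likewise the column
Z-score, and `zscore_matrix()` reports both matrices plus their average
\(X_{zrc} = (X_{zr} + X_{zc})/2\).

Three numerical details:

* **Resampling is index-based**, so the statistic is exactly equivariant
  under affine transformations of the data: scaling all MFIs by \(a>0\) and
  shifting by \(b\) leaves every Z-score bitwise unchanged (asserted in the
  test suite).
* **Degenerate vectors** (constant, e.g. a bait that failed to express and
  left its whole column at flat background in the noiseless limit) have
  \(\hat\sigma = 0\); their Z contribution is defined as 0 and the
  row/column is reported in `degenerate_rows` / `degenerate_cols`. This is
  what silently suppresses both-orientation calls for dead reagents.
* **Reproducibility**: a root seed spawns one independent sub-seed per row
  and per column (by role and position), so results are deterministic per
  seed and identical whether or not other rows are present.

### Orientation combination and calling

Each unordered pair {A, B} appears in two assay orientations (A-bait/B-prey
and B-bait/A-prey). `combine_orientations()` reduces the pair to the
geometric mean of the two averaged Z-scores,

\[ g = \sqrt{Z_{AB} \, Z_{BA}}, \]

**defined only when both are positive**. A pair that is enriched in one
orientation but at/below its null in the other gets `NA`, not a small score
— requiring independent support from both orientations is the main guard
against single-orientation artifacts. `call_interactions()` calls a pair iff
\(g > 5\) (strictly: \(g = 5.0\) is not called), with an explicit
`overrides` table for curator judgments that the automatic rule cannot
express; overrides are flagged and carry a justification string, never
silently merged.

`quantize_scores()` bins called scores into `low`/`mid`/`high` at the
empirical 80th and 90th percentiles of the scored population, using the
default R quantile convention (type 7, linear interpolation); the realized
thresholds are stored as attributes so a report can state them.

### Known limitation: false positives on pure noise

Because \(\hat\sigma\) is the standard error of the median
(\(\approx 1.25\,s/\sqrt{n}\) for sample standard deviation \(s\),
\(n = 23\)), the Z-score of a pure-noise cell is inflated by
\(\approx \sqrt{n}/1.25 \approx 3.8\) relative to a conventional
\((x-\mu)/s\) score. On i.i.d. noise the averaged Z is roughly
\(N(0, 3.8^2)\)-distributed, so \(P(g > 5)\) per noise pair is ≈ 2%, and a
23-protein screen (253 pairs) yields a handful of threshold-crossing noise
pairs per run. The benchmark (`analysis/05_recovery_benchmark.R`; 100
seeds, 10 planted edges at \(K_D\) 0.5–10 µM, signal-to-background 200)
measured mean sensitivity 1.000 (100/100 seeds at 1.0) but a mean of 6.2
false positives per run (range 2–12, no run at 0). The statistic is a
high-sensitivity *screen*: its calls are candidates for orthogonal
confirmation (e.g. SPR), not final. This behaviour is scale-invariant —
no background or gain setting removes it — and is asserted honestly in the
acceptance tests.

## 3. Network assembly

`build_network(calls, prior, families)` merges the called set with a prior
edge list into an undirected bipartite graph. Pairs are normalized
(unordered, deduplicated) and every edge is labelled `new` (called, not in
prior), `confirmed` (called and in prior) or `prior_only` (in prior, not
called here — including pairs suppressed by an undefined geometric mean,
which are excluded from the called set with a warning). Nodes carry family
annotations; `export_network()` writes an edge-list TSV (+ node table) and
GraphML via **igraph**, and `render_heatmap()` emits the low/mid/high
category matrix for a receptor-family × ligand-family block.
`run_bpia(config)` chains all stages, writes every artifact plus a JSON
manifest of parameters, seeds, realized quantization thresholds and
degeneracies, and reruns bitwise-identically for a fixed config; any stage
failure leaves a `FAILED` marker naming the stage and cause.

## 4. Equilibrium affinity fitting

`fit_langmuir()` fits steady-state SPR responses with the 1:1 Langmuir
isotherm

\[ R(C) = \frac{R_{\max} C}{K_D + C}, \]

by Levenberg–Marquardt least squares (**minpack.lm::nlsLM**) with positivity
bounds. Self-starting values are \(R_{\max}^{(0)} = 1.1 \max R\) and
\(K_D^{(0)}\) = the concentration whose response is nearest half-saturation.
Fits with fewer than 4 points are refused; parameter standard errors come
from the usual linearized covariance; a fit whose \(K_D\) lands outside
\([\min C/100,\ \max C \times 100]\) is flagged as unsupported by the
concentration range, as is any optimizer failure (`converged = FALSE`, with
a message — never a silent number). `pool_fits()` combines ≥ 2 converged
replicate fits of the same pair into mean \(K_D\) ± SEM. Kinetic (rate)
fitting is out of scope: the fast-exchange interactions this assay targets
are characterized at equilibrium.

## 5. The synthetic-data generator

The generator is a first-class, tested component: it emulates the
*statistical structure* of the assay so every pipeline stage is testable
without instrument data.

`generate_truth()` plants a sparse bipartite edge set (by `density` or an
exact `n_edges`) with per-edge affinities log-uniform over `kd_range`
(default 0.5–50 µM, the weak micromolar regime of cell-surface receptor
interactions), per-(protein, role) log-normal expression factors
(`expr_sdlog = 0.25`), and Bernoulli expression failures (`fail_prob`) that
force a factor to zero. `simulate_matrix()` then draws

\[ X_{ij} = b_0\,\varepsilon_{\text{bg}}
   + e^{\text{prey}}_i e^{\text{bait}}_j \, S_{\max}
     \frac{c_{\text{eff}}}{c_{\text{eff}} + K_D(i,j)}\,
     \varepsilon_{\text{mult}}, \]

with mean-1 log-normal noises (signals are positive and heteroscedastic,
like MFI data) and independent draws per orientation. Defaults
\(b_0 = 100\), background SD 10, CV 10%, \(S_{\max} = 20000\) (i.e.
signal-to-background 200), \(c_{\text{eff}} = 1\) µM. The saturation term
makes expected signal strictly decreasing in \(K_D\), reproducing the rank
relation between assay signal and affinity; \(c_{\text{eff}}\) is a single
effective concentration standing in for the avidity of multimerized prey.
What the generator does **not** emulate: bead-level optics, kinetics,
spatial plate effects, cross-reactivity of detection reagents, or
carry-over between wells.

`simulate_plate_reads()` expands a matrix into duplicate-well long-format
reads (log-normal replicate scatter, Poisson bead counts), closing the loop
back through `assemble_matrix()`. `simulate_titration()` and
`dilution_series()` produce SPR series for the affinity-recovery protocol
(12 two-fold dilutions from \(40 K_D\) down to \(\approx 0.02 K_D\), 2%
noise), and `recovery_trial()`/`evaluate_recovery()` run and score the
end-to-end planted-network benchmark (the 23-protein condition is built as
a 15 × 8 bipartite truth — 15 receptor-side, 8 ligand-side — matching the
screen's family sizes).

## 6. Reproducibility summary

Every stochastic routine takes an explicit integer seed and is bitwise
reproducible per seed. File formats are plain text (TSV/CSV/JSON/YAML/
GraphML) and round-trip through their readers/writers, asserted in the test
suite. The numbered scripts under `analysis/` re-run the whole workflow
from a fresh checkout, and `scripts/acceptance.R` recomputes the affinity
parameter-recovery results from scratch (see the README).
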