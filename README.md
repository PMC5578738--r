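# plexscreen

Analysis toolkit for extracellular receptor–ligand interactome screens run
on multiplexed bead arrays (Luminex xMAP / Bio-Plex class instruments),
with equilibrium SPR affinity fitting and a fully synthetic test bed.

## The scientific problem

Low-affinity (micromolar) interactions between cell-surface receptor and
ligand families are systematically missed by standard interaction screens.
A bead-array interactome assay addresses this by capturing every candidate
protein as *bait* on a coded bead region and probing it with every
multimerized *prey* in multiplex: one well interrogates one prey against
all baits at once, so a 23-protein all-vs-all screen needs 23 wells
instead of 529. The statistical problem is then to decide, from median
fluorescence intensities (MFI) that vary strongly with per-protein
expression level, which bait–prey pairs specifically interact.

`plexscreen` implements the full path from plate reads to an annotated
interaction network:

1. **Plate I/O and assembly** — validated long-format reads; replicates
   with fewer than 35 counted beads are dropped; surviving replicate MFIs
   are averaged into a square prey × bait matrix with masked (never
   imputed) missing cells. (`read_plate`, `assemble_matrix`)
2. **Scoring** — each cell is scored against its row and its column by a
   bootstrap of the median: with B = 300 resamples, μ and σ are the mean
   and standard deviation of the resample medians, and
   Z = (x − μ)/σ. The two orientation matrices are averaged
   (`X_zrc = (X_zr + X_zc)/2`). (`zscore_matrix`)
3. **Calling** — an unordered pair {A, B} is summarized by the geometric
   mean `g = sqrt(Z_AB * Z_BA)`, defined only when both orientations are
   positive; pairs are called iff `g > 5` (strict), with an explicit,
   justification-carrying curator-override table. Called scores are binned
   low/mid/high at the 80th/90th percentiles. (`combine_orientations`,
   `call_interactions`, `quantize_scores`)
4. **Network report** — calls are merged with a prior screen's edge list
   into a bipartite graph whose edges are labelled `new` / `confirmed` /
   `prior_only`; exports to edge-list TSV and GraphML, plus a category
   heat-map matrix. (`build_network`, `export_network`, `render_heatmap`,
   and the one-shot pipeline `run_bpia`)
5. **Affinity fitting** — steady-state SPR titrations are fit with the 1:1
   Langmuir isotherm `R(C) = Rmax·C/(KD + C)` by bounded
   Levenberg–Marquardt; replicate fits pool into mean KD ± SEM.
   (`fit_langmuir`, `pool_fits`)
6. **Synthetic data** — a tested generator plants bipartite truths with
   log-uniform affinities, expression factors and failures, and emulates
   the assay's noise structure, so every stage above is verifiable without
   instrument data. (`generate_truth`, `simulate_matrix`,
   `simulate_plate_reads`, `simulate_titration`, `recovery_trial`)

See `vignettes/methods.Rmd` for the precise estimator definitions,
parameter rationale, and known limitations (notably: the
standard-error-of-the-median denominator makes the screen maximally
sensitive but not false-positive free on pure noise — calls are candidates
for orthogonal confirmation, not final).

## Worked example

```r
library(plexscreen)

# plant a small receptor-ligand truth and simulate the observed screen
truth <- generate_truth(n_a = 6, n_b = 4, n_edges = 3, kd_range = c(0.5, 10),
                        names_a = sprintf("Rcpt-%d", 1:6),
                        names_b = sprintf("Lig-%d", 1:4),
                        family_a = "receptor", family_b = "ligand", seed = 101)
truth$edges
#>   protein_a protein_b    kd_uM
#> 1    Rcpt-3     Lig-2 2.883361
#> 2    Rcpt-2     Lig-3 1.357753
#> 3    Rcpt-5     Lig-3 3.222747

m     <- simulate_matrix(truth, seed = 102)
z     <- zscore_matrix(m, B = 300, seed = 103)
calls <- call_interactions(combine_orientations(z))
calls[calls$called, c("protein_a", "protein_b", "z_ab", "z_ba", "gmean")]
#>  protein_a protein_b    z_ab   z_ba   gmean
#>     Rcpt-3     Lig-2 1616.17 1164.0 1371.59
#>     Rcpt-2     Lig-3   23.12  758.0  132.38
#>     Rcpt-5     Lig-3   14.42  296.5   65.38

# fit a simulated SPR titration of a 0.76 uM interaction
s <- simulate_titration(K_D = 0.76, R_max = 100,
                        concentrations = dilution_series(0.76),
                        cv = 0.02, seed = 1)
fit_langmuir(s)
#> langmuir_fit: ligand::analyte  K_D = 0.7734 +/- 0.017 uM,
#>   R_max = 101.3 +/- 0.53 RU (converged, 12 points)
```

All three planted edges are recovered with both orientations strongly
positive, and the fitted K_D lands within ~2% of the simulation input.

## The analysis workflow

The repository is organized as an analysis: numbered drivers under
`analysis/` re-run the whole study from a fresh checkout, writing their
tables under `results/` and printing what they found.

```sh
Rscript analysis/01_simulate_screen.R      # 23-protein screen + plate reads
Rscript analysis/02_call_interactions.R    # Z-score, call, quantize (run_bpia)
Rscript analysis/03_network_report.R       # provenance vs the prior screen
Rscript analysis/04_spr_affinities.R       # triplicate Langmuir fits
Rscript analysis/05_recovery_benchmark.R   # 100-seed planted recovery
```

Shipped fixtures under `inst/extdata/`: the protein family annotation
(`beat_side_families.tsv`) and the prior plate-based screen's edge list
(`ecia_prior_edges.tsv`) — the latter is editable curation data, not
asserted truth.

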