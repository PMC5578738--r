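#!/usr/bin/env Rscript
# Step 1 — simulate the bead-array mini-interactome screen.
#
# The screen's raw plate reads are not publicly deposited, so the workflow
# runs on a synthetic stand-in with the same shape: 23 proteins (a
# 14-member receptor family, an 8-member ligand family, and one unrelated
# IgSF protein screened alongside them), every protein used as both bait and
# prey, 10 planted cross-family interactions with micromolar affinities,
# per-protein expression factors, and log-normal background/multiplicative
# noise. Outputs: the ground truth, the assembled 23x23 MFI matrix, and the
# duplicate-well plate reads it derives from.

suppressMessages(library(plexscreen))

out <- "results/screen"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20231L

fams <- read.delim(system.file("extdata", "beat_side_families.tsv",
                               package = "plexscreen"))
beats <- fams$protein[fams$family == "Beat"]
sides <- fams$protein[fams$family == "Side"]

truth <- generate_truth(n_a = length(beats), n_b = length(sides),
                        n_edges = 10, kd_range = c(0.5, 50),
                        fail_prob = 0.05,
                        names_a = beats, names_b = sides,
                        family_a = "Beat", family_b = "Side", seed = seed)
# the extra screened protein is modelled as an orphan: background only
truth$proteins <- rbind(truth$proteins,
                        data.frame(name = "CG17839", family = "other"))
truth$expression <- rbind(truth$expression,
                          data.frame(protein = "CG17839",
                                     role = c("bait", "prey"), factor = 1))

m <- simulate_matrix(truth, seed = seed + 1L)
reads <- simulate_plate_reads(m, seed = seed + 2L)

write_matrix(m, file.path(out, "matrix.tsv"))
write_plate(reads, file.path(out, "plate.csv"))
jsonlite::write_json(
  list(seed = seed, proteins = truth$proteins, edges = truth$edges,
       failed = truth$failed, noise = truth$noise),
  file.path(out, "truth.json"), auto_unbox = TRUE, pretty = TRUE,
  digits = NA)

cat(sprintf("simulated %d x %d screen: %d planted edges, %d failed (protein, role)\n",
            nrow(m$X), ncol(m$X), nrow(truth$edges), nrow(truth$failed)))
cat(sprintf("plate reads: %d rows (%d wells x %d bead regions x 2 replicates)\n",
            nrow(reads), length(unique(reads$well_id)) / 2, ncol(m$X)))
cat("wrote", file.path(out, c("matrix.tsv", "plate.csv", "truth.json")),
    sep = "\n  ")
cat("\n")
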