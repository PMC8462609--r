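#!/usr/bin/env Rscript
# Stage 1 -- draw the synthetic cohort.
#
# Generates the matched tissue/plasma study cohort (29 gastric-cancer
# cases, 20 healthy controls): per-patient annotated somatic calls in
# both compartments, capillary-electrophoresis-style fragment-size
# profiles, and the clinical table, written as the on-disk bundle the
# later stages consume.

library(ctdnatrack)

seed <- as.integer(Sys.getenv("COHORT_SEED", "1"))
out <- "results/cohort"

sim <- simulate_cohort(sim_params(seed = seed), out_dir = out)

cl <- sim$clinical
cat("Simulated cohort (seed ", seed, ") written to ", out, "\n", sep = "")
cat(sprintf("  %d cases, %d controls\n", sum(cl$group == "case"),
            sum(cl$group == "control")))
cat(sprintf("  tissue somatic calls: %d; plasma calls: %d\n",
            nrow(sim$tissue_variants), nrow(sim$plasma_variants)))
cat(sprintf("  cases shedding detectable ctDNA: %d\n", sum(sim$sheds)))
cat(sprintf("  files in manifest: %d\n", nrow(sim$manifest)))
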