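#!/usr/bin/env Rscript
# Stage 2 -- filter tissue calls and design the capture panel.
#
# Reads every case's tissue VCF back from disk, applies the
# five-criterion somatic filter cascade (population AF < 1%, coding
# non-synonymous + HIGH impact, CADD > 30, not cohort-ubiquitous,
# >= 2 reads per strand), reports cohort positivity, and builds the
# 38-gene capture panel ranked by recurrence.

library(ctdnatrack)

cohort_dir <- "results/cohort"
vcfs <- list.files(cohort_dir, pattern = "tissue\\.vcf$",
                   full.names = TRUE)
tissue <- somatic_variants(do.call(rbind, c(
  lapply(vcfs, read_somatic_vcf, compartment = "tissue"),
  make.row.names = FALSE)))
samples <- sub("\\.tissue\\.vcf$", "", basename(vcfs))

fc <- filter_cohort(tissue, samples = samples)
cat(sprintf("Filter cascade over %d tissue samples:\n", length(samples)))
cat(sprintf("  calls in: %d; retained: %d\n",
            nrow(tissue), sum(fc$decisions$passed)))
cat(sprintf("  alteration-positive samples: %d/%d (%.2f%%)\n",
            fc$summary$n_positive, fc$summary$n_samples,
            fc$summary$positive_fraction_pct))
cat(sprintf("  mean retained variants per positive sample: %.2f\n",
            fc$summary$mean_retained_among_positive))

reasons <- table(unlist(fc$decisions$failed_criteria))
cat("  failure reasons:",
    paste(names(reasons), reasons, sep = "=", collapse = ", "), "\n")

panel <- build_panel(fc$retained[vapply(fc$retained, nrow,
                                        integer(1)) > 0])
write_panel_bed(panel, "results/panel.bed")
dec <- fc$decisions
dec$failed_criteria <- vapply(dec$failed_criteria, paste, character(1),
                              collapse = ";")
write.table(dec, "results/filters.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("Panel: %d genes, %d merged intervals -> results/panel.bed\n",
            length(panel$genes), nrow(panel$intervals)))
cat("  top genes:", paste(head(panel$genes, 8), collapse = ", "), "\n")
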