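#!/usr/bin/env Rscript
# Stage 3 -- tissue/plasma concordance and mutational spectra.
#
# Matches each case's plasma calls against the retained tissue set on
# normalized variant keys, summarizes cohort concordance (any plasma
# alteration; tissue-matching alteration), and tabulates the mutational
# spectrum of the retained tissue calls.

library(ctdnatrack)

cohort_dir <- "results/cohort"
tissue_vcfs <- list.files(cohort_dir, pattern = "tissue\\.vcf$",
                          full.names = TRUE)
samples <- sub("\\.tissue\\.vcf$", "", basename(tissue_vcfs))
tissue <- somatic_variants(do.call(rbind, c(
  lapply(tissue_vcfs, read_somatic_vcf, compartment = "tissue"),
  make.row.names = FALSE)))
fc <- filter_cohort(tissue, samples = samples)
positives <- names(which(vapply(fc$retained, nrow, integer(1)) > 0))

results <- lapply(samples, function(id) {
  pv <- read_somatic_vcf(file.path(cohort_dir,
                                   paste0(id, ".plasma.vcf")), "plasma")
  match_variants(fc$retained[[id]], pv, sample_id = id)
})
cc <- cohort_concordance(results, positives)

cat("Tissue/plasma concordance over the alteration-positive cases:\n")
cat(sprintf("  any plasma alteration: %d/%d (%.1f%%)\n",
            cc$plasma_any$num, cc$plasma_any$den, cc$plasma_any$pct))
cat(sprintf("  tissue-matching alteration: %d/%d (%.1f%%)\n",
            cc$shared$num, cc$shared$den, cc$shared$pct))
cat(sprintf("  mean plasma variants per plasma-positive sample: %.1f\n",
            cc$mean_plasma_per_positive))
cat(sprintf("  mean matching variants per matching-positive sample: %.1f\n",
            cc$mean_shared_per_positive))

tab <- do.call(rbind, lapply(results, function(r)
  data.frame(sample_id = r$sample_id, t(r$counts))))
write.table(tab, "results/concordance.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

retained <- somatic_variants(do.call(rbind, c(
  lapply(fc$retained, as.data.frame), make.row.names = FALSE)))
sp <- summarize_spectra(retained)
cat(sprintf("Spectrum of %d retained tissue calls (mean %.2f/sample):\n",
            sum(sp$per_sample_counts), sp$mean_per_sample))
cat("  classes:", paste(names(sp$class_counts), sp$class_counts,
                        sep = "=", collapse = ", "), "\n")
cat("  substitutions:", paste(names(sp$substitution_counts),
                              sp$substitution_counts, sep = "=",
                              collapse = ", "), "\n")
write.table(data.frame(class = names(sp$class_counts),
                       count = as.integer(sp$class_counts)),
            "results/spectra.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(sp$oncomatrix, "results/oncomatrix.tsv", sep = "\t",
            quote = FALSE, col.names = NA)
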