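#!/usr/bin/env Rscript
# Stage 5 -- clinical associations.
#
# Relates the tissue-matching plasma variant load to clinical features:
# detection rate by tumor size (chi-square), correlation of yield with
# serum CEA (Spearman), Kaplan-Meier survival over the matching-count
# strata 0 / 1-2 / 3-6 / >6 with the log-rank test, a Cox model with
# demographics, and M0/M1 discrimination with shadow-feature importance
# plus leave-one-out random-forest AUC.

library(ctdnatrack)

seed <- as.integer(Sys.getenv("COHORT_SEED", "1"))
set.seed(seed)

cohort_dir <- "results/cohort"
clinical <- read_clinical_table(file.path(cohort_dir, "clinical.tsv"))
conc <- read.delim("results/concordance.tsv")
quant <- read.delim("results/quant.tsv")
dir.create("results/stats", showWarnings = FALSE)

cl <- clinical[clinical$group == "case", ]
cl$matching <- conc$shared[match(cl$sample_id, conc$sample_id)]
cl$yield <- quant$total_yield_ng_ml[match(cl$sample_id, quant$sample_id)]
cl$stage_group <- ifelse(cl$t_stage %in% c("T1", "T2"), "T1-T2", "T3-T4")
positives <- conc$sample_id[conc$tissue > 0]
pos <- cl[cl$sample_id %in% positives, ]

## detection by tumor size
stage_tab <- table(factor(pos$stage_group, c("T1-T2", "T3-T4")),
                   factor(pos$matching > 0, c(TRUE, FALSE)))
chi <- tryCatch(pearson_chi2_2x2(stage_tab), error = function(e) NULL)
rate <- prop.table(stage_tab, 1)[, 1] * 100
cat(sprintf("ctDNA detection: T1-T2 %.1f%%, T3-T4 %.1f%%", rate[1], rate[2]))
if (!is.null(chi)) cat(sprintf(" (chi2 = %.2f, p = %.3f)", chi$statistic,
                               chi$p_value))
cat("\n")

## yield vs CEA
sp <- spearman_cor(cl$yield, cl$cea)
cat(sprintf("Spearman yield~CEA in cases: rho = %.2f, p = %.3g (%s)\n",
            sp$rho, sp$p_value, sp$method))

## survival over matching-count strata
bins <- bin_matching_count(cl$matching)
lr <- logrank_test(cl$survival_days, cl$event, droplevels(bins))
cat("Kaplan-Meier medians (days) by matching-variant stratum:\n")
for (b in names(lr$medians)) {
  cat(sprintf("  %-4s: %s\n", b,
              ifelse(is.na(lr$medians[b]), "not reached",
                     sprintf("%.0f", lr$medians[b]))))
}
cat(sprintf("  log-rank chi2 = %.2f (df %d), p = %.4f\n", lr$statistic,
            lr$df, lr$p_value))
write.table(data.frame(bin = names(lr$medians),
                       median_days = as.numeric(lr$medians)),
            "results/stats/km_medians.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

## Cox model: demographics + matching-count bins
cox <- tryCatch({
  bin_mat <- model.matrix(~bins)[, -1, drop = FALSE]
  # sparse strata (< 3 patients) cannot support a coefficient
  bin_mat <- bin_mat[, colSums(bin_mat) >= 3, drop = FALSE]
  cox_ph(cl$survival_days, cl$event,
         cbind(data.frame(age = cl$age,
                          male = as.integer(cl$sex == "male"),
                          t34 = as.integer(cl$stage_group == "T3-T4")),
               as.data.frame(bin_mat)))
}, error = function(e) { message("Cox model skipped: ",
                                 conditionMessage(e)); NULL })
if (!is.null(cox)) {
  cat("Cox proportional hazards (Wald p, Holm-adjusted):\n")
  print(cox, digits = 3)
  write.table(cox, "results/stats/cox.tsv", sep = "\t", quote = FALSE,
              row.names = FALSE)
}

## M0/M1 discrimination
m_known <- cl$m_stage != "unknown"
features <- data.frame(
  n_matching = cl$matching,
  any_plasma = as.integer(conc$plasma[match(cl$sample_id,
                                            conc$sample_id)] > 0),
  cea = cl$cea, ca19_9 = cl$ca19_9, ca72_4 = cl$ca72_4, tmb = cl$tmb,
  msi_high = as.integer(cl$msi_status == "MSI-high"))[m_known, ]
labels <- factor(cl$m_stage[m_known])
imp <- shadow_importance(features, labels, n_iterations = 50)
cat("Shadow-feature importance decisions:\n")
print(imp, row.names = FALSE)
keep <- imp$feature[imp$decision != "rejected"]
if (!length(keep)) keep <- c("n_matching", "any_plasma")
disc <- discriminate(features[, keep, drop = FALSE], labels)
cat(sprintf("M0/M1 discrimination with {%s}: leave-one-out AUC = %.3f\n",
            paste(keep, collapse = ", "), disc$auc))
write.table(imp, "results/stats/importance.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
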