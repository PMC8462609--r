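# End-to-end workflow: simulate -> design-panel -> concord -> quantify
# -> associate, wired by a single configuration and reported as a
# machine-readable results bundle with a checksum manifest.

#' Default run configuration
#'
#' Single nested configuration for every stage; all filter thresholds and
#' cohort parameters appear as named keys with their standard defaults.
#'
#' @param seed Integer master seed for the run.
#' @return Nested list of per-stage parameter lists.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    sim = list(),          # overrides for sim_params()
    filters = list(),      # overrides for filter_config()
    panel = list(max_genes = 38),
    regions = default_nucleosomal_regions(),
    stats = list(exome_mb = 40, shadow_iterations = 40,
                 shadow_ntree = 100, rf_ntree = 300))
}

#' Read / write a run configuration (YAML)
#'
#' @param path YAML file path.
#' @return Configuration list merged over [default_config()].
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (k in names(user)) {
    cfg[[k]] <- if (is.list(cfg[[k]]) && is.list(user[[k]])) {
      utils::modifyList(cfg[[k]], user[[k]])
    } else user[[k]]
  }
  cfg
}

#' @rdname read_run_config
#' @param config Configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Executes every stage on a synthetic cohort drawn from the
#' configuration's seed and writes a results bundle: the on-disk cohort,
#' the designed panel with per-variant filter decisions, per-patient
#' concordance and mutational spectra, cfDNA yield and nucleosomal
#' quantification, and the clinical-association statistics. Identical
#' configuration and seed reproduce identical checksums.
#'
#' @param config Configuration list, see [default_config()].
#' @param out_dir Output directory for the results bundle.
#' @return list with `report` (the headline numbers), `manifest`
#'   (file checksums incl. the configuration hash), and the per-stage
#'   result objects.
#' @export
run_all <- function(config = default_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config.yaml")
  write_run_config(config, cfg_path)

  sim <- stage("simulate", {
    params <- do.call(sim_params, c(config$sim,
                                    list(seed = config$seed)))
    simulate_cohort(params, out_dir = file.path(out_dir, "cohort"))
  })
  case_ids <- sim$clinical$sample_id[sim$clinical$group == "case"]

  design <- stage("design-panel", {
    fcfg <- do.call(filter_config, config$filters)
    fc <- filter_cohort(sim$tissue_variants, samples = case_ids,
                        config = fcfg)
    panel <- build_panel(fc$retained[vapply(fc$retained, nrow,
                                            integer(1)) > 0],
                         max_genes = config$panel$max_genes)
    write_panel_bed(panel, file.path(out_dir, "panel.bed"))
    dec <- fc$decisions
    dec$failed_criteria <- vapply(dec$failed_criteria, paste,
                                  character(1), collapse = ";")
    utils::write.table(dec, file.path(out_dir, "filters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(filtered = fc, panel = panel)
  })

  concord <- stage("concord", {
    fc <- design$filtered
    results <- lapply(case_ids, function(id) {
      match_variants(
        fc$retained[[id]],
        sim$plasma_variants[sim$plasma_variants$sample_id == id, ,
                            drop = FALSE],
        sample_id = id)
    })
    positives <- names(which(vapply(fc$retained, nrow, integer(1)) > 0))
    summary <- cohort_concordance(results, positives)
    tab <- do.call(rbind, lapply(results, function(r)
      data.frame(sample_id = r$sample_id, t(r$counts))))
    utils::write.table(tab, file.path(out_dir, "concordance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    retained_pool <- do.call(rbind, c(lapply(fc$retained, as.data.frame),
                                      make.row.names = FALSE))
    spectra <- summarize_spectra(retained_pool)
    utils::write.table(
      data.frame(class = names(spectra$class_counts),
                 count = as.integer(spectra$class_counts)),
      file.path(out_dir, "spectra.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(spectra$oncomatrix,
                       file.path(out_dir, "oncomatrix.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    list(results = results, positives = positives, summary = summary,
         spectra = spectra)
  })

  quant <- stage("quantify", {
    rows <- lapply(names(sim$profiles), function(id) {
      dec <- nucleosomal_decomposition(sim$profiles[[id]],
                                       regions = config$regions)
      data.frame(sample_id = id,
                 group = sim$clinical$group[sim$clinical$sample_id == id],
                 total_yield_ng_ml = dec$total_yield_ng_ml,
                 mono_pg_ml = dec$regions$yield_pg_ml[1],
                 di_pg_ml = dec$regions$yield_pg_ml[2],
                 tri_pg_ml = dec$regions$yield_pg_ml[3],
                 mono_mode_bp = dec$regions$modal_size_bp[1],
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    utils::write.table(tab, file.path(out_dir, "quant.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    case_mean <- mean(tab$total_yield_ng_ml[tab$group == "case"])
    ctrl_mean <- mean(tab$total_yield_ng_ml[tab$group == "control"])
    mw <- mann_whitney_from_samples(
      tab$total_yield_ng_ml[tab$group == "control"],
      tab$total_yield_ng_ml[tab$group == "case"])
    list(table = tab, case_mean = case_mean, control_mean = ctrl_mean,
         fold_change = fold_change(case_mean, ctrl_mean),
         yield_test = mw)
  })

  assoc <- stage("associate", with_sim_seed(config$seed, {
    cl <- sim$clinical[sim$clinical$group == "case", , drop = FALSE]
    match_n <- vapply(concord$results, function(r) r$counts[["shared"]],
                      numeric(1))
    names(match_n) <- vapply(concord$results, function(r) r$sample_id,
                             character(1))
    cl$matching <- match_n[cl$sample_id]
    cl$stage_group <- ifelse(cl$t_stage %in% c("T1", "T2"),
                             "T1-T2", "T3-T4")
    positives <- cl$sample_id %in% concord$positives

    stage_tab <- table(factor(cl$stage_group[positives],
                              levels = c("T1-T2", "T3-T4")),
                       factor(cl$matching[positives] > 0,
                              levels = c(TRUE, FALSE)))
    stage_chi2 <- tryCatch(pearson_chi2_2x2(stage_tab),
                           error = function(e)
                             list(statistic = NA_real_,
                                  p_value = NA_real_, df = 1L))
    m_tab <- table(factor(cl$m_stage[positives & cl$m_stage != "unknown"],
                          levels = c("M0", "M1")),
                   factor(cl$matching[positives &
                                      cl$m_stage != "unknown"] > 0,
                          levels = c(TRUE, FALSE)))
    m_chi2 <- tryCatch(pearson_chi2_2x2(m_tab),
                       error = function(e)
                         list(statistic = NA_real_, p_value = NA_real_,
                              df = 1L))

    yields <- vapply(sim$profiles[cl$sample_id], total_yield, numeric(1))
    sp <- spearman_cor(yields, cl$cea)

    bins <- bin_matching_count(cl$matching)
    lr <- tryCatch(
      logrank_test(cl$survival_days, cl$event, droplevels(bins)),
      error = function(e) list(statistic = NA_real_, p_value = NA_real_,
                               medians = NULL))
    cox <- tryCatch({
      covars <- data.frame(age = cl$age,
                           male = as.integer(cl$sex == "male"),
                           t34 = as.integer(cl$stage_group == "T3-T4"))
      bin_mat <- stats::model.matrix(~ bins)[, -1, drop = FALSE]
      # sparse strata (< 3 patients) cannot support a coefficient
      keep <- colSums(bin_mat) >= 3
      cox_ph(cl$survival_days, cl$event,
             cbind(covars, as.data.frame(bin_mat[, keep, drop = FALSE])))
    }, error = function(e) NULL)

    features <- data.frame(
      n_matching = cl$matching,
      any_plasma = as.integer(cl$sample_id %in%
        unique(sim$plasma_variants$sample_id)),
      cea = cl$cea, ca19_9 = cl$ca19_9, ca72_4 = cl$ca72_4,
      tmb = cl$tmb, msi_high = as.integer(cl$msi_status == "MSI-high"))
    m_known <- cl$m_stage != "unknown"
    disc <- tryCatch({
      imp <- shadow_importance(features[m_known, , drop = FALSE],
                               cl$m_stage[m_known],
                               n_iterations = config$stats$shadow_iterations,
                               ntree = config$stats$shadow_ntree)
      keep <- imp$feature[imp$decision != "rejected"]
      if (!length(keep)) keep <- c("n_matching", "any_plasma")
      discriminate(features[m_known, keep, drop = FALSE],
                   cl$m_stage[m_known],
                   ntree = config$stats$rf_ntree, importance = imp)
    }, error = function(e) NULL)

    stats_dir <- file.path(out_dir, "stats")
    dir.create(stats_dir, showWarnings = FALSE)
    if (!is.null(cox)) {
      utils::write.table(cox, file.path(stats_dir, "cox.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    if (!is.null(disc) && !is.null(disc$importance)) {
      utils::write.table(disc$importance,
                         file.path(stats_dir, "importance.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    km_tab <- data.frame(bin = names(lr$medians),
                         median_days = as.numeric(lr$medians))
    utils::write.table(km_tab, file.path(stats_dir, "km_medians.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(stage_table = stage_tab, stage_chi2 = stage_chi2,
         m_table = m_tab, m_chi2 = m_chi2, spearman_yield_cea = sp,
         logrank = lr, cox = cox, discrimination = disc)
  }))

  report <- list(
    n_cases = sum(sim$clinical$group == "case"),
    n_controls = sum(sim$clinical$group == "control"),
    tissue_positive_pct = design$filtered$summary$positive_fraction_pct,
    plasma_any_pct = concord$summary$plasma_any$pct,
    shared_pct = concord$summary$shared$pct,
    yield_fold_change = round(quant$fold_change, 1),
    yield_p = quant$yield_test$p_two_sided,
    stage_chi2 = assoc$stage_chi2$statistic,
    stage_chi2_p = assoc$stage_chi2$p_value,
    km_medians = assoc$logrank$medians,
    logrank_p = assoc$logrank$p_value,
    auc_m0_m1 = if (!is.null(assoc$discrimination))
      assoc$discrimination$auc else NA_real_)

  report_path <- file.path(out_dir, "report.yaml")
  yaml::write_yaml(lapply(report, function(x)
    if (is.numeric(x)) unname(round(x, 6)) else x), report_path)

  bundle_files <- c(cfg_path, sim$files, file.path(out_dir, "panel.bed"),
                    file.path(out_dir, "filters.tsv"),
                    file.path(out_dir, "concordance.tsv"),
                    file.path(out_dir, "spectra.tsv"),
                    file.path(out_dir, "oncomatrix.tsv"),
                    file.path(out_dir, "quant.tsv"), report_path)
  bundle_files <- bundle_files[file.exists(bundle_files)]
  manifest <- file_manifest(bundle_files, root = out_dir)
  utils::write.table(manifest, file.path(out_dir, "run_manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  list(report = report, manifest = manifest, sim = sim, design = design,
       concordance = concord, quant = quant, assoc = assoc)
}
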