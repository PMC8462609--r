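# The synthetic cohort generator: determinism, programmed structure,
# limit cases, and batch parameter recovery against binomial oracles.

test_that("the same seed reproduces byte-identical cohorts", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_cohort(sim_params(seed = 41), out_dir = d1)
  s2 <- simulate_cohort(sim_params(seed = 41), out_dir = d2)
  expect_equal(s1$manifest$md5, s2$manifest$md5)
  s3 <- simulate_cohort(sim_params(seed = 42))
  expect_false(identical(s1$clinical$cea, s3$clinical$cea))
})

test_that("the cohort has the prescribed shape on disk", {
  d <- withr::local_tempdir()
  sim <- simulate_cohort(sim_params(seed = 4), out_dir = d)
  expect_equal(nrow(sim$clinical), 49)
  expect_equal(sum(sim$clinical$group == "case"), 29)
  # tissue and plasma VCFs for every case, none for controls
  expect_length(list.files(d, pattern = "tissue\\.vcf$"), 29)
  expect_length(list.files(d, pattern = "plasma\\.vcf$"), 29)
  expect_false(any(grepl("HC", list.files(d, pattern = "vcf$"))))
  # fragment profiles for every subject
  expect_length(list.files(d, pattern = "fragments\\.tsv$"), 49)
  expect_true(file.exists(file.path(d, "manifest.tsv")))
})

test_that("plasma detection limit cases behave as programmed", {
  # certain detection, no private variants, guaranteed shedding:
  # plasma keys equal tissue keys
  p1 <- sim_params(seed = 9, per_variant_detection_prob = 1,
                   plasma_private_rate = 0,
                   shed_prob_by_stage = c("T1-T2" = 1, "T3-T4" = 1))
  sim1 <- simulate_cohort(p1)
  fc <- filter_cohort(sim1$tissue_variants)
  for (id in names(which(vapply(fc$retained, nrow, integer(1)) > 0))) {
    pl <- sim1$plasma_variants[sim1$plasma_variants$sample_id == id, ,
                               drop = FALSE]
    expect_setequal(variant_keys(pl), variant_keys(fc$retained[[id]]))
  }
  # zero detection, zero private rate: empty plasma compartment
  p0 <- sim_params(seed = 9, per_variant_detection_prob = 0,
                   plasma_private_rate = 0,
                   shed_prob_by_stage = c("T1-T2" = 0, "T3-T4" = 0))
  sim0 <- simulate_cohort(p0)
  expect_equal(nrow(sim0$plasma_variants), 0)
})

test_that("fixture mode exercises every filter criterion exactly once", {
  sim <- simulate_cohort(sim_params(seed = 2,
                                    fixture_filter_coverage = TRUE))
  fc <- filter_cohort(sim$tissue_variants)
  singles <- fc$decisions$failed_criteria[
    lengths(fc$decisions$failed_criteria) == 1]
  hit <- unique(unlist(singles))
  expect_true(all(c("pop_af", "impact", "cadd", "strand_support",
                    "ubiquity") %in% hit))
})

test_that("batch recovery of the programmed cohort structure", {
  # One 200-seed batch reused for four oracle checks.
  params <- sim_params(seed = 1)
  n_seeds <- 200
  pos_count <- numeric(n_seeds)
  t34_pos <- 0; t34_tot <- 0
  case_yields <- c(); ctrl_yields <- c()
  case_cea <- c(); case_yield_per_subj <- c()
  for (s in seq_len(n_seeds)) {
    sim <- simulate_cohort(sim_params(seed = 10000 + s))
    fc_counts <- table(factor(
      sim$tissue_variants$sample_id[
        variant_passes_alone(sim$tissue_variants)],
      levels = unique(sim$clinical$sample_id)))
    positives <- names(fc_counts[fc_counts > 0])
    pos_count[s] <- length(positives)
    cl <- sim$clinical[sim$clinical$group == "case", ]
    t34 <- cl$sample_id[cl$t_stage %in% c("T3", "T4") &
                        cl$sample_id %in% positives]
    t34_pos <- t34_pos + sum(sim$matching_counts[t34] > 0)
    t34_tot <- t34_tot + length(t34)
    y <- vapply(sim$profiles, total_yield, numeric(1))
    case_yields <- c(case_yields, y[cl$sample_id])
    ctrl_yields <- c(ctrl_yields,
                     y[sim$clinical$sample_id[
                       sim$clinical$group == "control"]])
    case_cea <- c(case_cea, cl$cea)
    case_yield_per_subj <- c(case_yield_per_subj, y[cl$sample_id])
  }
  # (1) tissue-positive count is Binomial(29, 23/29): mean within 3 SE
  p <- 23 / 29
  se <- sqrt(29 * p * (1 - p) / n_seeds)
  expect_lt(abs(mean(pos_count) - 23), 3 * se)
  # (2) plasma-detection fraction among T3-T4 positives near 0.556
  phat <- t34_pos / t34_tot
  se2 <- sqrt(0.556 * (1 - 0.556) / t34_tot)
  expect_lt(abs(phat - 0.556), 3 * se2)
  # (3) yield fold change recovers the programmed 43.6 within 10%
  fc_est <- fold_change(mean(case_yields), mean(ctrl_yields))
  expect_lt(abs(fc_est - 43.6) / 43.6, 0.10)
  # (4) Spearman(yield, CEA) among cases near the programmed copula value
  programmed <- 6 / pi * asin(sim_params()$marker_rho / 2)
  rho <- spearman_cor(case_yield_per_subj, case_cea)$rho
  expect_lt(abs(rho - programmed), 0.1)
})

test_that("programmed survival hazards give monotone ordered KM medians", {
  params <- sim_params(seed = 1)
  set.seed(55)
  n_per_bin <- 500
  counts <- rep(c(0L, 1L, 4L, 8L), each = n_per_bin)
  times <- numeric(length(counts)); events <- logical(length(counts))
  for (i in seq_along(counts)) {
    s <- simulate_survival(counts[i], params)
    times[i] <- s$survival_days; events[i] <- s$event
  }
  bins <- bin_matching_count(counts)
  med <- vapply(levels(bins), function(b)
    km_estimator(times[bins == b], events[bins == b])$median, numeric(1))
  expect_true(med[">6"] < med["3-6"])
  expect_true(med["3-6"] < med["1-2"])
  expect_true(med["1-2"] < med["0"])
})

test_that("plasma VAFs of matched variants do not exceed tissue VAFs", {
  sim <- simulate_cohort(sim_params(seed = 17))
  fc <- filter_cohort(sim$tissue_variants)
  for (id in names(fc$retained)) {
    pl <- sim$plasma_variants[sim$plasma_variants$sample_id == id, ,
                              drop = FALSE]
    r <- match_variants(fc$retained[[id]], pl, sample_id = id)
    if (nrow(r$shared_vafs)) {
      expect_true(all(r$shared_vafs$plasma_vaf <=
                      r$shared_vafs$tissue_vaf + 1e-12))
    }
  }
})

test_that("invalid simulation parameters are rejected", {
  expect_error(sim_params(tissue_positive_prob = 1.5), "probabilities")
  expect_error(sim_params(n_cases = 0), "cohort sizes")
  expect_error(sim_params(fragment_fracs_case = c(0.9, 0.2, 0.2)),
               "mass fractions")
})
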