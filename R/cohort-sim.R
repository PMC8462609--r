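# Synthetic matched tissue/plasma cohort generator.
#
# Emulates the statistical structure a tumor-informed liquid-biopsy study
# assumes: a case/control cfDNA yield contrast, nucleosomal fragment-size
# profiles, overdispersed tissue mutation counts, stage-dependent ctDNA
# shedding with Bernoulli-thinned plasma detection plus plasma-private
# calls, VAF attenuation from tissue to plasma, serum markers linked to
# yield through a Gaussian copula, and survival with hazards increasing in
# the matching-variant bin. All draws are a pure function of the seed.

# Gene pool: gastric-cancer-associated genes with synthetic (approximate,
# hg19-like) loci. Coordinates are 1-based inclusive here; panel output
# converts to BED. Weights make the first genes recurrently mutated so
# panel ranking has structure.
gc_gene_pool <- function() {
  df <- data.frame(
    gene = c("TP53", "CDH1", "ARID1A", "PIK3CA", "RHOA", "KRAS", "ERBB2",
             "APC", "CTNNB1", "SMAD4", "PTEN", "FBXW7", "MUC6", "RNF43",
             "TGFBR2", "MSH6", "MLH1", "BRCA2", "ATM", "NOTCH1", "EGFR",
             "MET", "FGFR2", "CCNE1", "MYC", "GLI3", "PREX2", "ZIC4",
             "SPTA1", "FAT4", "LRP1B", "CSMD3", "PCLO", "DNAH5", "RYR2",
             "OBSCN", "TTN", "SYNE1"),
    chrom = c("chr17", "chr16", "chr1", "chr3", "chr3", "chr12", "chr17",
              "chr5", "chr3", "chr18", "chr10", "chr4", "chr11", "chr17",
              "chr3", "chr2", "chr3", "chr13", "chr11", "chr9", "chr7",
              "chr7", "chr10", "chr19", "chr8", "chr7", "chr8", "chr3",
              "chr1", "chr4", "chr2", "chr8", "chr7", "chr5", "chr1",
              "chr1", "chr2", "chr6"),
    start = c(7565097, 68771128, 27022522, 178866311, 49396579, 25358180,
              37844393, 112043202, 41236328, 48556583, 89623195, 153242410,
              1012824, 56431037, 30647994, 48010221, 37034841, 32889611,
              108093559, 139388896, 55086714, 116312459, 123237848,
              30302805, 128748315, 42000548, 68864353, 147103834,
              158580496, 126237554, 141032565, 113235157, 82383330,
              13690441, 237205505, 228395831, 179390716, 152442819),
    width = c(25772, 98261, 86236, 91886, 52947, 45675, 40521, 108352,
              40991, 49611, 108206, 204054, 24454, 64006, 87371, 23871,
              57357, 84195, 146443, 51622, 188307, 125967, 120334, 12354,
              7734, 276244, 291686, 10106, 76099, 161545, 1900298, 1205925,
              411377, 340556, 791954, 170699, 304814, 515551),
    weight = c(12, 9, 8, 7, 6, 6, 5, 5, 4, 4, 4, 3, 3, 3, 3, 2, 2, 2, 2, 2,
               2, 2, 2, 1.5, 1.5, 1.5, 1.5, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
    stringsAsFactors = FALSE)
  df$end <- df$start + df$width - 1
  df
}

#' Gene intervals of the synthetic gene pool
#'
#' @return data.frame with `gene`, `chrom`, `start`, `end` in 0-based
#'   half-open coordinates, suitable for [build_panel()].
#' @export
gc_gene_intervals <- function() {
  pool <- gc_gene_pool()
  data.frame(gene = pool$gene, chrom = pool$chrom,
             start = pool$start - 1, end = pool$end,
             stringsAsFactors = FALSE)
}

#' Simulation parameters for the synthetic cohort
#'
#' Defaults encode the cohort structure the downstream analyses assume:
#' 29 cases and 20 controls; 23/29 of cases carrying at least one
#' filter-passing tissue variant; overdispersed (negative-binomial) tissue
#' variant counts with mean about 8.4 among positives; stage-dependent
#' probability that a tumor sheds detectable ctDNA (0.10 for T1-T2, 0.556
#' for T3-T4); Bernoulli thinning of the tissue set into plasma plus a
#' Poisson number of plasma-private calls; log-normal cfDNA yields with
#' group means 87.59 (case) and 2.01 (control) ng/mL; tri-modal
#' (mono/di/tri-nucleosomal) Gaussian fragment peaks with case modes
#' shifted down; Weibull survival with log-hazard increments over the
#' matching-count bins 0 / 1-2 / 3-6 / >6; and serum markers tied to
#' yield by a Gaussian copula.
#'
#' @param n_cases,n_controls Cohort arm sizes.
#' @param seed Integer seed; same seed gives byte-identical outputs.
#' @param tissue_positive_prob Probability a case has >=1 filter-passing
#'   tissue variant.
#' @param tissue_count_mu,tissue_count_size Negative-binomial mean-1 and
#'   dispersion of the passing tissue variant count among positives
#'   (count = 1 + NB, so support starts at 1).
#' @param tissue_fail_rate Poisson rate of additional filter-failing calls.
#' @param shed_prob_by_stage Named vector, probability of detectable
#'   shedding for `T1-T2` and `T3-T4` tumors (given tissue positivity).
#' @param per_variant_detection_prob Detection probability of each tissue
#'   variant in plasma, given shedding (one variant is always detected so
#'   shedding implies a non-empty matching set).
#' @param plasma_private_rate Poisson mean of plasma-only variants per case.
#' @param vaf_shape1,vaf_shape2 Beta law of tissue VAF.
#' @param plasma_vaf_atten Multiplicative attenuation of plasma VAF
#'   relative to the matched tissue VAF (expectation scale).
#' @param yield_mean_case,yield_mean_control Group mean cfDNA yields, ng/mL.
#' @param yield_sdlog_case,yield_sdlog_control Log-scale SDs of the yields.
#' @param fragment_modes_control,fragment_modes_case Modal sizes (bp) of
#'   the mono/di/tri-nucleosomal peaks.
#' @param fragment_widths Peak SDs (bp).
#' @param fragment_fracs_control,fragment_fracs_case Mass fractions of the
#'   three peaks (remainder goes to a flat baseline).
#' @param fragment_mode_jitter_sd Per-subject jitter SD of peak modes (bp).
#' @param surv_shape,surv_scale0 Weibull shape and baseline scale (days).
#' @param surv_log_hr Log-hazard increments for bins 0, 1-2, 3-6, >6.
#' @param censor_range Uniform administrative censoring window (days).
#' @param marker_rho Latent-normal correlation between yield and CEA
#'   (Spearman approximately (6/pi)*asin(rho/2)).
#' @param stage_probs Probabilities of T1..T4 among cases.
#' @param m1_prob Probability of M1 (distant metastasis) among cases.
#' @param fixture_filter_coverage If TRUE, append to the first case one
#'   engineered variant failing each single filter criterion plus one key
#'   present in all tissue samples, so every cascade branch is exercised.
#' @return A list of parameters, classed `sim_params`.
#' @export
sim_params <- function(n_cases = 29, n_controls = 20, seed = 1,
                       tissue_positive_prob = 23 / 29,
                       tissue_count_mu = 7.4, tissue_count_size = 3,
                       tissue_fail_rate = 1.5,
                       shed_prob_by_stage = c("T1-T2" = 0.10,
                                              "T3-T4" = 0.556),
                       per_variant_detection_prob = 0.45,
                       plasma_private_rate = 2,
                       vaf_shape1 = 1.6, vaf_shape2 = 6,
                       plasma_vaf_atten = 0.3,
                       yield_mean_case = 87.59, yield_mean_control = 2.01,
                       yield_sdlog_case = 1.0, yield_sdlog_control = 0.6,
                       fragment_modes_control = c(170, 350, 520),
                       fragment_modes_case = c(166, 344, 512),
                       fragment_widths = c(15, 25, 35),
                       fragment_fracs_control = c(0.68, 0.2, 0.1),
                       fragment_fracs_case = c(0.73, 0.15, 0.1),
                       fragment_mode_jitter_sd = 2,
                       surv_shape = 1.2, surv_scale0 = 1090,
                       surv_log_hr = c(0, 0.645, 1.123, 3.485),
                       censor_range = c(900, 2500),
                       marker_rho = 0.618,
                       stage_probs = c(T1 = 0.17, T2 = 0.19,
                                       T3 = 0.39, T4 = 0.25),
                       m1_prob = 0.4,
                       fixture_filter_coverage = FALSE) {
  p <- as.list(environment())
  probs <- c(p$tissue_positive_prob, p$shed_prob_by_stage,
             p$per_variant_detection_prob, p$stage_probs, p$m1_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (p$n_cases < 1 || p$n_controls < 0) {
    stop("invalid cohort sizes", call. = FALSE)
  }
  fr <- c(p$fragment_fracs_control, p$fragment_fracs_case)
  if (any(fr < 0) || sum(p$fragment_fracs_control) > 1 ||
      sum(p$fragment_fracs_case) > 1) {
    stop("fragment peak mass fractions must be non-negative with sum <= 1",
         call. = FALSE)
  }
  class(p) <- "sim_params"
  p
}

with_sim_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

# Random somatic calls, vectorized. mode "pass" satisfies every filter
# criterion; "fail_pop_af" etc. violate exactly the named criterion;
# "fail_random" picks one criterion to violate per call.
random_variants <- function(n, sample_id, compartment, modes = "pass",
                            vaf = NULL, params) {
  if (n == 0) return(NULL)
  modes <- rep_len(modes, n)
  rnd <- modes == "fail_random"
  modes[rnd] <- paste0("fail_", sample(c("pop_af", "impact", "cadd",
                                         "strand_support"),
                                       sum(rnd), replace = TRUE))
  pool <- gc_gene_pool()
  gi <- sample(nrow(pool), n, replace = TRUE, prob = pool$weight)
  pos <- floor(stats::runif(n, pool$start[gi], pool$end[gi] + 1))
  vt <- sample(c("SNP", "INS", "DEL"), n, replace = TRUE,
               prob = c(0.8, 0.1, 0.1))
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  # SNPs: C>T-enriched pyrimidine spectrum, random strand representation
  sub6 <- sample(c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"), n,
                 replace = TRUE, prob = c(0.14, 0.10, 0.40, 0.10, 0.16, 0.10))
  ref <- substr(sub6, 1, 1); alt <- substr(sub6, 3, 3)
  flip <- stats::runif(n) < 0.5
  ref[flip] <- comp[ref[flip]]; alt[flip] <- comp[alt[flip]]
  csq <- sample(c("missense", "nonsense", "splice-site"), n,
                replace = TRUE, prob = c(0.75, 0.15, 0.10))
  csq_fail <- sample(c("synonymous", "other"), n, replace = TRUE)
  ext <- vapply(sample(1:3, n, replace = TRUE), function(k)
    paste(sample(bases, k, replace = TRUE), collapse = ""), character(1))
  anchor <- sample(bases, n, replace = TRUE)
  ins <- vt == "INS"; del <- vt == "DEL"
  ref[ins] <- anchor[ins]
  alt[ins] <- paste0(anchor[ins], ext[ins])
  ref[del] <- paste0(anchor[del], ext[del])
  alt[del] <- anchor[del]
  indel_csq <- ifelse(stats::runif(n) < 0.8,
                      ifelse(ins, "frameshift-ins", "frameshift-del"),
                      "in-frame-indel")
  csq[ins | del] <- indel_csq[ins | del]
  csq_fail[ins | del] <- "other"

  v <- data.frame(
    chrom = pool$chrom[gi], pos = pos, ref = ref, alt = alt,
    gene = pool$gene[gi], consequence_class = csq, variant_type = vt,
    population_af = stats::runif(n, 0, 0.009), impact = "HIGH",
    cadd_phred = stats::runif(n, 30.5, 50),
    fwd_support = 2L + stats::rpois(n, 8),
    rev_support = 2L + stats::rpois(n, 8),
    vaf = if (is.null(vaf)) stats::rbeta(n, params$vaf_shape1,
                                         params$vaf_shape2)
          else rep_len(vaf, n),
    sample_id = sample_id, compartment = compartment,
    stringsAsFactors = FALSE)

  i <- modes == "fail_pop_af"
  v$population_af[i] <- stats::runif(sum(i), 0.02, 0.3)
  i <- modes == "fail_impact"
  if (any(i)) {
    lowimp <- stats::runif(sum(i)) < 0.5
    v$impact[i][lowimp] <- "MODERATE"
    v$consequence_class[i][!lowimp] <- csq_fail[i][!lowimp]
  }
  i <- modes == "fail_cadd"
  v$cadd_phred[i] <- stats::runif(sum(i), 5, 29)
  i <- modes %in% c("fail_strand", "fail_strand_support")
  if (any(i)) {
    side_fwd <- stats::runif(sum(i)) < 0.5
    low <- sample(0:1, sum(i), replace = TRUE)
    v$fwd_support[i][side_fwd] <- low[side_fwd]
    v$rev_support[i][!side_fwd] <- low[!side_fwd]
  }
  bad <- setdiff(modes, c("pass", "fail_pop_af", "fail_impact",
                          "fail_cadd", "fail_strand",
                          "fail_strand_support"))
  if (length(bad)) stop("unknown variant mode: ", bad[1], call. = FALSE)
  v
}

#' Simulate the tissue somatic calls of one patient
#'
#' Positives receive `1 + NB(size, mu)` filter-passing variants plus a
#' Poisson number of filter-failing ones; negatives only failing calls.
#' Annotations span both sides of every filter threshold so the cascade
#' is exercised by construction.
#'
#' @param sample_id Patient identifier.
#' @param tissue_positive Does the patient carry passing variants?
#' @param params [sim_params()].
#' @return A [somatic_variants()] data.frame (possibly empty).
#' @export
simulate_tissue_variants <- function(sample_id, tissue_positive, params) {
  n_pass <- if (tissue_positive) {
    1 + stats::rnbinom(1, size = params$tissue_count_size,
                       mu = params$tissue_count_mu)
  } else 0
  n_fail <- stats::rpois(1, params$tissue_fail_rate) +
    as.integer(!tissue_positive)
  rows <- rbind(
    random_variants(n_pass, sample_id, "tissue", "pass", params = params),
    random_variants(n_fail, sample_id, "tissue", "fail_random",
                    params = params))
  if (is.null(rows)) return(empty_variants())
  somatic_variants(rows)
}

#' Simulate the plasma calls of one patient
#'
#' If the tumor sheds, each retained tissue variant is carried into plasma
#' with `per_variant_detection_prob` (at least one always), with VAF
#' attenuated multiplicatively; an independent Poisson number of
#' plasma-private variants is added for every case.
#'
#' @param sample_id Patient identifier.
#' @param tissue_retained Filter-passing tissue variants of the patient.
#' @param sheds Logical, does the tumor shed detectable ctDNA?
#' @param params [sim_params()].
#' @return list with `variants` (plasma [somatic_variants()]) and
#'   `matching_count`.
#' @export
simulate_plasma_variants <- function(sample_id, tissue_retained, sheds,
                                     params) {
  matched <- empty_variants()
  if (isTRUE(sheds) && nrow(tissue_retained) > 0) {
    n <- nrow(tissue_retained)
    keep <- stats::runif(n) < params$per_variant_detection_prob
    keep[sample(n, 1)] <- TRUE  # shedding implies >=1 detectable variant
    matched <- tissue_retained[keep, , drop = FALSE]
    att <- params$plasma_vaf_atten * exp(stats::rnorm(nrow(matched), 0, 0.35) -
                                         0.35^2 / 2)
    matched$vaf <- pmin(matched$vaf * att, matched$vaf)
    matched$compartment <- "plasma"
    matched$fwd_support <- 2L + stats::rpois(nrow(matched), 4)
    matched$rev_support <- 2L + stats::rpois(nrow(matched), 4)
  }
  n_priv <- stats::rpois(1, params$plasma_private_rate)
  private <- random_variants(n_priv, sample_id, "plasma", "pass",
                             params = params)
  if (!is.null(private)) private$vaf <- private$vaf * params$plasma_vaf_atten
  all_rows <- rbind(if (nrow(matched)) matched, private)
  variants <- if (is.null(all_rows)) empty_variants() else {
    all_rows$sample_id <- sample_id
    somatic_variants(all_rows)
  }
  list(variants = variants, matching_count = nrow(matched))
}

#' Simulate one fragment-size profile
#'
#' Sum of three Gaussian peaks (mono/di/tri-nucleosomal) plus a flat
#' baseline over 100-1000 bp, normalized so that the trapezoidal integral
#' over the analysis range equals the subject's drawn yield exactly.
#'
#' @param group `"case"` or `"control"`.
#' @param yield_ng_ml Total cfDNA yield to conserve, ng/mL.
#' @param params [sim_params()].
#' @param sample_id Subject identifier.
#' @param jitter Apply per-subject jitter to peak modes/widths?
#' @return A [fragment_profile()].
#' @export
simulate_fragment_profile <- function(group, yield_ng_ml, params,
                                      sample_id = "S", jitter = TRUE) {
  sizes <- seq(100, 1000, by = 1)
  modes <- if (group == "case") params$fragment_modes_case
           else params$fragment_modes_control
  fracs <- if (group == "case") params$fragment_fracs_case
           else params$fragment_fracs_control
  widths <- params$fragment_widths
  if (jitter) {
    modes <- modes + stats::rnorm(3, 0, params$fragment_mode_jitter_sd)
    widths <- widths * stats::runif(3, 0.9, 1.1)
  }
  if (any(modes < 100) || any(modes > 1000)) {
    stop("fragment peak modes must lie inside the analysis range",
         call. = FALSE)
  }
  shape <- rep(0, length(sizes))
  for (k in 1:3) {
    shape <- shape + fracs[k] * stats::dnorm(sizes, modes[k], widths[k])
  }
  baseline_mass <- max(0, 1 - sum(fracs))
  shape <- shape + baseline_mass / diff(range(sizes))
  total_pg <- yield_ng_ml * 1000
  conc <- shape * total_pg / pracma::trapz(sizes, shape)
  fragment_profile(sample_id, sizes, conc)
}

#' Simulate one survival outcome
#'
#' Weibull proportional hazards on the matching-count bin (0, 1-2, 3-6,
#' >6) with uniform administrative censoring; hazard is non-decreasing in
#' the bin, so median survival decreases with the plasma mutation load.
#'
#' @param matching_count Number of tissue-matching plasma variants.
#' @param params [sim_params()].
#' @return list with `survival_days` and `event`.
#' @export
simulate_survival <- function(matching_count, params) {
  stopifnot(matching_count >= 0)
  bin <- bin_matching_count(matching_count)
  beta <- params$surv_log_hr[match(bin, matching_bins())]
  u <- stats::runif(1)
  t_event <- params$surv_scale0 *
    (-log(u) / exp(beta))^(1 / params$surv_shape)
  t_cens <- stats::runif(1, params$censor_range[1], params$censor_range[2])
  list(survival_days = min(t_event, t_cens), event = t_event <= t_cens)
}

draw_markers <- function(group, yield, params) {
  if (group == "case") {
    meanlog <- log(params$yield_mean_case) - params$yield_sdlog_case^2 / 2
    sdlog <- params$yield_sdlog_case
    cea_ml <- log(8); cea_sl <- 1.0
    ca199_ml <- log(25); ca724_ml <- log(5)
  } else {
    meanlog <- log(params$yield_mean_control) -
      params$yield_sdlog_control^2 / 2
    sdlog <- params$yield_sdlog_control
    cea_ml <- log(2); cea_sl <- 0.6
    ca199_ml <- log(10); ca724_ml <- log(2)
  }
  z1 <- (log(yield) - meanlog) / sdlog
  rho <- params$marker_rho
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(1)
  list(cea = exp(cea_ml + cea_sl * z2),
       ca19_9 = stats::rlnorm(1, ca199_ml, 0.9),
       ca72_4 = stats::rlnorm(1, ca724_ml, 0.9))
}

draw_yield <- function(group, params) {
  if (group == "case") {
    stats::rlnorm(1, log(params$yield_mean_case) -
                    params$yield_sdlog_case^2 / 2, params$yield_sdlog_case)
  } else {
    stats::rlnorm(1, log(params$yield_mean_control) -
                    params$yield_sdlog_control^2 / 2,
                  params$yield_sdlog_control)
  }
}

# Engineered calls for fixture mode: one variant failing each single
# criterion, one passing everything, and one key shared by every tissue
# sample (fails only the ubiquity criterion).
filter_coverage_variants <- function(sample_id, params) {
  modes <- c("pass", "fail_pop_af", "fail_impact", "fail_cadd",
             "fail_strand_support")
  random_variants(length(modes), sample_id, "tissue", modes,
                  params = params)
}

ubiquitous_variant <- function(sample_id) {
  data.frame(
    chrom = "chr17", pos = 7577120, ref = "C", alt = "T", gene = "TP53",
    consequence_class = "missense", variant_type = "SNP",
    population_af = 0.0001, impact = "HIGH", cadd_phred = 42,
    fwd_support = 10L, rev_support = 12L, vaf = 0.3,
    sample_id = sample_id, compartment = "tissue", stringsAsFactors = FALSE)
}

#' Simulate a full synthetic cohort
#'
#' Draws the clinical table, per-patient tissue and plasma variant sets,
#' and per-subject fragment profiles, optionally writing the on-disk
#' cohort (VCFs, fragment TSVs, clinical TSV, checksum manifest).
#'
#' @param params [sim_params()].
#' @param out_dir Optional output directory; created if missing.
#' @return list with `params`, `clinical` ([patient_records()]),
#'   `tissue_variants`, `plasma_variants` (pooled [somatic_variants()]),
#'   `profiles` (named list of [fragment_profile()]),
#'   `matching_counts` (named, cases), `sheds` (named logical, cases),
#'   and, when written to disk, `files` and `manifest`.
#' @export
simulate_cohort <- function(params = sim_params(), out_dir = NULL) {
  stopifnot(inherits(params, "sim_params"))
  with_sim_seed(params$seed, {
    case_ids <- sprintf("GC%02d", seq_len(params$n_cases))
    ctrl_ids <- sprintf("HC%02d", seq_len(params$n_controls))

    clinical <- list(); tissue <- list(); plasma <- list()
    profiles <- list(); matching_counts <- integer(0); sheds <- logical(0)

    for (id in case_ids) {
      t_stage <- sample(names(params$stage_probs), 1,
                        prob = params$stage_probs)
      stage_group <- if (t_stage %in% c("T1", "T2")) "T1-T2" else "T3-T4"
      n_stage <- sample(n_stage_levels()[1:4], 1,
                        prob = c(0.3, 0.3, 0.25, 0.15))
      m_stage <- if (stats::runif(1) < params$m1_prob) "M1" else "M0"
      age <- round(min(max(stats::rnorm(1, 66, 10), 32), 90))
      sex <- sample(c("male", "female"), 1, prob = c(0.6, 0.4))

      positive <- stats::runif(1) < params$tissue_positive_prob
      tv <- simulate_tissue_variants(id, positive, params)
      if (params$fixture_filter_coverage) {
        extra <- if (id == case_ids[1]) {
          rbind(filter_coverage_variants(id, params), ubiquitous_variant(id))
        } else ubiquitous_variant(id)
        tv <- somatic_variants(rbind(as.data.frame(tv), extra))
      }
      retained <- tv[variant_passes_alone(tv), , drop = FALSE]

      sheds_i <- positive && nrow(retained) > 0 &&
        stats::runif(1) < params$shed_prob_by_stage[[stage_group]]
      pl <- simulate_plasma_variants(id, retained, sheds_i, params)

      surv <- simulate_survival(pl$matching_count, params)
      yield <- draw_yield("case", params)
      prof <- simulate_fragment_profile("case", yield, params,
                                        sample_id = id)
      mk <- draw_markers("case", yield, params)

      clinical[[id]] <- data.frame(
        sample_id = id, group = "case", age = age, sex = sex,
        t_stage = t_stage, n_stage = n_stage, m_stage = m_stage,
        survival_days = round(surv$survival_days, 1), event = surv$event,
        cea = signif(mk$cea, 6), ca19_9 = signif(mk$ca19_9, 6),
        ca72_4 = signif(mk$ca72_4, 6),
        msi_status = sample(c("MSS", "MSI-high"), 1, prob = c(0.85, 0.15)),
        tmb = round(nrow(tv) / 40, 4), stringsAsFactors = FALSE)
      tissue[[id]] <- tv
      plasma[[id]] <- pl$variants
      profiles[[id]] <- prof
      matching_counts[[id]] <- pl$matching_count
      sheds[[id]] <- sheds_i
    }

    for (id in ctrl_ids) {
      age <- round(min(max(stats::rnorm(1, 58, 11), 25), 85))
      sex <- sample(c("male", "female"), 1, prob = c(0.5, 0.5))
      yield <- draw_yield("control", params)
      prof <- simulate_fragment_profile("control", yield, params,
                                        sample_id = id)
      mk <- draw_markers("control", yield, params)
      clinical[[id]] <- data.frame(
        sample_id = id, group = "control", age = age, sex = sex,
        t_stage = "unknown", n_stage = "unknown", m_stage = "unknown",
        survival_days = params$censor_range[2], event = FALSE,
        cea = signif(mk$cea, 6), ca19_9 = signif(mk$ca19_9, 6),
        ca72_4 = signif(mk$ca72_4, 6), msi_status = "unknown", tmb = 0,
        stringsAsFactors = FALSE)
      profiles[[id]] <- prof
    }

    clinical <- patient_records(do.call(rbind, c(clinical,
                                                 make.row.names = FALSE)))
    tissue_all <- do.call(rbind, c(lapply(tissue, as.data.frame),
                                   make.row.names = FALSE))
    plasma_all <- do.call(rbind, c(lapply(plasma, as.data.frame),
                                   make.row.names = FALSE))
    tissue_all <- if (is.null(tissue_all)) empty_variants()
                  else somatic_variants(tissue_all)
    plasma_all <- if (is.null(plasma_all)) empty_variants()
                  else somatic_variants(plasma_all)

    out <- list(params = params, clinical = clinical,
                tissue_variants = tissue_all, plasma_variants = plasma_all,
                profiles = profiles, matching_counts = matching_counts,
                sheds = sheds)

    if (!is.null(out_dir)) {
      out <- c(out, write_cohort(out, out_dir, case_ids,
                                 c(case_ids, ctrl_ids)))
    }
    out
  })
}

# Single-variant view of the filter cascade used inside the simulator to
# decide which generated tissue calls count as "retained" (cohort
# ubiquity cannot fail for private random positions, so presence is 0).
variant_passes_alone <- function(variants) {
  if (nrow(variants) == 0) return(logical(0))
  d <- passes_filters(variants, rep(0, nrow(variants)))
  d$passed
}

write_cohort <- function(sim, out_dir, case_ids, all_ids) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop("cannot create output directory ", out_dir, call. = FALSE)
  }
  files <- character(0)
  for (id in case_ids) {
    tp <- file.path(out_dir, paste0(id, ".tissue.vcf"))
    pp <- file.path(out_dir, paste0(id, ".plasma.vcf"))
    tv <- sim$tissue_variants[sim$tissue_variants$sample_id == id, ,
                              drop = FALSE]
    pv <- sim$plasma_variants[sim$plasma_variants$sample_id == id, ,
                              drop = FALSE]
    write_somatic_vcf(tv, tp, sample_id = id)
    write_somatic_vcf(pv, pp, sample_id = id)
    files <- c(files, tp, pp)
  }
  for (id in all_ids) {
    fp <- file.path(out_dir, paste0(id, ".fragments.tsv"))
    write_fragment_profile(sim$profiles[[id]], fp)
    files <- c(files, fp)
  }
  cp <- file.path(out_dir, "clinical.tsv")
  write_clinical_table(sim$clinical, cp)
  files <- c(files, cp)
  manifest <- file_manifest(files, root = out_dir)
  mp <- file.path(out_dir, "manifest.tsv")
  utils::write.table(manifest, mp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(files = files, manifest = manifest)
}
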