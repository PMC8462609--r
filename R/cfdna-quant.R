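# cfDNA quantification: total yield from a size profile, nucleosomal
# size-region decomposition, case/control fold change, tumor fraction
# from plasma VAFs, and tumor mutational burden.

# Trapezoidal integral of the concentration curve between lo and hi (bp),
# interpolating the endpoints onto the size grid so that contiguous
# regions add exactly.
integrate_profile <- function(profile, lo, hi) {
  s <- profile$sizes; c0 <- profile$concentrations
  if (lo < s[1] || hi > s[length(s)]) {
    stop("integration range [", lo, ", ", hi,
         "] outside profile support", call. = FALSE)
  }
  inside <- s > lo & s < hi
  xs <- c(lo, s[inside], hi)
  ys <- c(stats::approx(s, c0, xout = lo)$y, c0[inside],
          stats::approx(s, c0, xout = hi)$y)
  pracma::trapz(xs, ys)
}

#' Total cfDNA yield of a fragment profile
#'
#' Trapezoidal integral of the concentration curve (pg/mL per bp) over
#' the analysis range, converted to ng/mL.
#'
#' @param profile A [fragment_profile()].
#' @return Yield in ng per mL of plasma.
#' @export
total_yield <- function(profile) {
  if (!inherits(profile, "fragment_profile")) {
    stop("total_yield expects a fragment_profile", call. = FALSE)
  }
  r <- profile$analysis_range
  integrate_profile(profile, r[1], r[2]) / 1000
}

#' Case/control yield fold change
#'
#' @param case_mean,control_mean Group mean yields (ng/mL);
#'   `control_mean` must be positive.
#' @return The unrounded ratio `case_mean / control_mean` (report to one
#'   decimal).
#' @export
fold_change <- function(case_mean, control_mean) {
  if (!is.finite(control_mean) || control_mean <= 0) {
    stop("control mean yield must be positive", call. = FALSE)
  }
  case_mean / control_mean
}

#' Default nucleosomal size regions
#'
#' Mono [100, 250), di [250, 450), tri [450, 700) bp, motivated by the
#' ~170 bp mono-nucleosomal peak and its multiples; explicit
#' configuration, not an instrument constant.
#'
#' @return Named list of two-vectors (bp).
#' @export
default_nucleosomal_regions <- function() {
  list(mono = c(100, 250), di = c(250, 450), tri = c(450, 700))
}

#' Decompose a fragment profile into nucleosomal size regions
#'
#' Per region: yield (integral of the concentration curve, pg/mL) and
#' modal size (argmax of the curve inside the region; ties resolved to
#' the smallest size). Optionally also the concentration-weighted mean
#' size, since instrument "average size" statistics differ.
#'
#' @param profile A [fragment_profile()].
#' @param regions Named list of ordered, non-overlapping `[lo, hi)`
#'   two-vectors inside the analysis range.
#' @return list classed `nucleosomal_decomposition` with a `regions`
#'   data.frame (region, lo, hi, yield_pg_ml, modal_size_bp,
#'   mean_size_bp) and `total_yield_ng_ml`.
#' @export
nucleosomal_decomposition <- function(profile,
                                      regions =
                                        default_nucleosomal_regions()) {
  bounds <- do.call(rbind, regions)
  if (any(bounds[, 2] <= bounds[, 1])) {
    stop("each region needs lo < hi", call. = FALSE)
  }
  ord <- order(bounds[, 1])
  if (any(diff(ord) < 0) ||
      any(utils::head(bounds[ord, 2], -1) > bounds[ord, 1][-1])) {
    stop("regions must be ordered and non-overlapping", call. = FALSE)
  }
  rng <- profile$analysis_range
  if (bounds[1, 1] < rng[1] || max(bounds[, 2]) > rng[2]) {
    stop("regions must lie within the analysis range", call. = FALSE)
  }
  rows <- lapply(names(regions), function(nm) {
    lo <- regions[[nm]][1]; hi <- regions[[nm]][2]
    y <- integrate_profile(profile, lo, hi)
    inside <- profile$sizes >= lo & profile$sizes < hi
    s <- profile$sizes[inside]; conc <- profile$concentrations[inside]
    mode <- s[which.max(conc)]  # which.max takes the first (smallest) tie
    wmean <- if (sum(conc) > 0) sum(s * conc) / sum(conc) else NA_real_
    data.frame(region = nm, lo = lo, hi = hi, yield_pg_ml = y,
               modal_size_bp = mode, mean_size_bp = wmean,
               stringsAsFactors = FALSE)
  })
  structure(list(regions = do.call(rbind, rows),
                 total_yield_ng_ml = total_yield(profile)),
            class = "nucleosomal_decomposition")
}

#' Tumor cfDNA fraction from plasma variants
#'
#' Arithmetic mean of the plasma mutant allele fractions; the standard
#' tumor-informed proxy for the circulating tumor fraction.
#'
#' @param plasma_variants Plasma [somatic_variants()] of one patient.
#' @return Mean VAF, or `NA` when no plasma variant with a known VAF
#'   exists.
#' @export
tumor_fraction <- function(plasma_variants) {
  vafs <- plasma_variants$vaf
  vafs <- vafs[!is.na(vafs)]
  if (!length(vafs)) return(NA_real_)
  mean(vafs)
}

#' Tumor mutational burden
#'
#' Somatic coding mutations per megabase of assayed region.
#'
#' @param n_coding_somatic Number of coding somatic mutations.
#' @param region_size_mb Assayed region size in Mb (> 0).
#' @return Mutations per Mb.
#' @export
tmb <- function(n_coding_somatic, region_size_mb) {
  if (!is.finite(region_size_mb) || region_size_mb <= 0) {
    stop("region_size_mb must be positive", call. = FALSE)
  }
  n_coding_somatic / region_size_mb
}
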