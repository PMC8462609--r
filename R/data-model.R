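# Shared domain containers and variant-key normalization.
#
# Variant tables are plain data.frames with a fixed column contract
# (one row per somatic call); fragment profiles are small lists carrying
# a size grid and a concentration curve. Validators enforce the closed
# vocabularies so bad inputs fail loudly at the boundary.

#' @name ctdnatrack-vocab
#' @title Closed vocabularies for the domain types
#' @description Column names and categorical levels used throughout the
#'   package. Consequence classes follow the usual somatic-annotation
#'   coarse classes; impact levels follow the VeP/SnpEff convention.
#' @keywords internal
NULL

variant_columns <- function() {
  c("chrom", "pos", "ref", "alt", "gene", "consequence_class",
    "variant_type", "population_af", "impact", "cadd_phred",
    "fwd_support", "rev_support", "vaf", "sample_id", "compartment")
}

consequence_classes <- function() {
  c("missense", "nonsense", "frameshift-ins", "frameshift-del",
    "splice-site", "in-frame-indel", "synonymous", "other")
}

#' Consequence classes counted as protein-coding non-synonymous
#'
#' The default set used by the filter cascade's impact criterion. The
#' annotation vocabulary upstream tools emit varies, so the set is a
#' configuration value rather than a constant (see [filter_config()]).
#'
#' @return Character vector of consequence classes.
#' @export
coding_nonsyn_classes <- function() {
  c("missense", "nonsense", "frameshift-ins", "frameshift-del",
    "splice-site", "in-frame-indel")
}

impact_levels <- function() c("HIGH", "MODERATE", "LOW", "MODIFIER")
variant_types <- function() c("SNP", "INS", "DEL")

t_stage_levels <- function() c("T1", "T2", "T3", "T4", "unknown")
n_stage_levels <- function() c("N0", "N1", "N2", "N3", "unknown")
m_stage_levels <- function() c("M0", "M1", "unknown")
msi_levels <- function() c("MSS", "MSI-high", "unknown")

clinical_columns <- function() {
  c("sample_id", "group", "age", "sex", "t_stage", "n_stage", "m_stage",
    "survival_days", "event", "cea", "ca19_9", "ca72_4", "msi_status", "tmb")
}

#' Infer the variant type from the allele pair
#'
#' SNP when both alleles are single bases, INS when the alternate is
#' longer, DEL when the reference is longer. Equal-length multi-base
#' pairs (MNVs) are outside the closed type vocabulary and raise an error.
#'
#' @param ref,alt Character vectors of alleles.
#' @return Character vector over `c("SNP", "INS", "DEL")`.
#' @export
infer_variant_type <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  out <- ifelse(lr == 1L & la == 1L, "SNP",
         ifelse(la > lr, "INS",
         ifelse(lr > la, "DEL", NA_character_)))
  if (anyNA(out)) {
    bad <- which(is.na(out))[1]
    stop("unsupported equal-length multi-base allele pair (MNV): ",
         ref[bad], ">", alt[bad], call. = FALSE)
  }
  out
}

#' Construct / validate a somatic-variant table
#'
#' One row per somatic call. Missing annotations are `NA` sentinels; they
#' are never coerced to 0 and downstream filters reject them with an
#' explicit `missing_annotation` reason.
#'
#' @param df A data.frame with the columns of `variant_columns()`.
#' @return The validated data.frame (invisibly classed `somatic_variants`).
#' @export
somatic_variants <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(variant_columns(), names(df))
  if (length(missing_cols)) {
    stop("somatic variant table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[, variant_columns(), drop = FALSE]
  if (nrow(df) == 0) {
    class(df) <- c("somatic_variants", class(df))
    return(df)
  }
  if (any(df$pos < 1)) stop("pos must be >= 1", call. = FALSE)
  if (any(df$ref == df$alt)) stop("ref and alt alleles must differ", call. = FALSE)
  chk01 <- function(x, nm) {
    bad <- !is.na(x) & (x < 0 | x > 1)
    if (any(bad)) stop(nm, " outside [0, 1]", call. = FALSE)
  }
  chk01(df$population_af, "population_af")
  chk01(df$vaf, "vaf")
  bad_cadd <- !is.na(df$cadd_phred) & df$cadd_phred < 0
  if (any(bad_cadd)) stop("cadd_phred must be non-negative", call. = FALSE)
  for (col in c("fwd_support", "rev_support")) {
    x <- df[[col]]
    if (any(!is.na(x) & (x < 0 | x != floor(x)))) {
      stop(col, " must be a non-negative integer", call. = FALSE)
    }
  }
  chk_vocab(df$consequence_class, consequence_classes(), "consequence_class",
            allow_na = TRUE)
  chk_vocab(df$impact, impact_levels(), "impact", allow_na = TRUE)
  chk_vocab(df$compartment, c("tissue", "plasma"), "compartment")
  expected_type <- infer_variant_type(df$ref, df$alt)
  if (any(df$variant_type != expected_type)) {
    stop("variant_type inconsistent with allele lengths", call. = FALSE)
  }
  if (!inherits(df, "somatic_variants")) {
    class(df) <- c("somatic_variants", class(df))
  }
  df
}

chk_vocab <- function(x, levels, name, allow_na = FALSE) {
  bad <- if (allow_na) !is.na(x) & !(x %in% levels) else !(x %in% levels)
  if (any(bad)) {
    stop("invalid ", name, " value(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct / validate a clinical (patient record) table
#'
#' Enforces the closed staging and status vocabularies; unknown labels
#' raise a validation error listing every offending value.
#'
#' @param df A data.frame with the columns of `clinical_columns()`.
#' @return The validated data.frame, classed `patient_records`.
#' @export
patient_records <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(clinical_columns(), names(df))
  if (length(missing_cols)) {
    stop("clinical table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[, clinical_columns(), drop = FALSE]
  if (anyDuplicated(df$sample_id)) {
    stop("duplicated sample_id in clinical table", call. = FALSE)
  }
  chk_vocab(df$group, c("case", "control"), "group")
  chk_vocab(df$sex, c("male", "female"), "sex")
  chk_vocab(df$t_stage, t_stage_levels(), "t_stage")
  chk_vocab(df$n_stage, n_stage_levels(), "n_stage")
  chk_vocab(df$m_stage, m_stage_levels(), "m_stage")
  chk_vocab(df$msi_status, msi_levels(), "msi_status")
  if (any(df$survival_days < 0)) stop("survival_days must be >= 0", call. = FALSE)
  if (!all(df$event %in% c(0L, 1L, TRUE, FALSE))) {
    stop("event must be logical (death observed yes/no)", call. = FALSE)
  }
  df$event <- as.logical(df$event)
  if (!inherits(df, "patient_records")) {
    class(df) <- c("patient_records", class(df))
  }
  df
}

#' Construct a cfDNA fragment-size profile
#'
#' Emulates the size-to-concentration output of a capillary-electrophoresis
#' instrument: an ordered size grid in bp and a matching non-negative
#' concentration vector in pg/mL per size bin.
#'
#' @param sample_id Subject identifier.
#' @param sizes Strictly increasing fragment sizes (bp).
#' @param concentrations Non-negative concentrations (pg/mL), same length.
#' @param analysis_range Two-vector, analysis window in bp; default
#'   `c(100, 1000)`.
#' @return A list classed `fragment_profile`.
#' @export
fragment_profile <- function(sample_id, sizes, concentrations,
                             analysis_range = c(100, 1000)) {
  if (length(sizes) != length(concentrations)) {
    stop("sizes and concentrations must have the same length", call. = FALSE)
  }
  if (length(sizes) == 0) stop("empty fragment profile", call. = FALSE)
  if (any(diff(sizes) <= 0)) {
    stop("sizes must be strictly increasing", call. = FALSE)
  }
  if (any(concentrations < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  if (length(analysis_range) != 2 || analysis_range[1] >= analysis_range[2]) {
    stop("analysis_range must be an increasing pair of sizes", call. = FALSE)
  }
  structure(
    list(sample_id = sample_id,
         sizes = as.numeric(sizes),
         concentrations = as.numeric(concentrations),
         analysis_range = as.numeric(analysis_range)),
    class = "fragment_profile")
}

#' Construct a capture-panel specification
#'
#' @param genes Unique gene symbols on the panel.
#' @param intervals data.frame with columns `chrom`, `start`, `end`, `gene`;
#'   0-based half-open coordinates. Overlapping intervals are merged per
#'   chromosome and gene.
#' @param provenance Named list mapping gene -> character vector of
#'   supporting filtered variant keys.
#' @return A list classed `panel_spec`.
#' @export
panel_spec <- function(genes, intervals, provenance = list()) {
  if (anyDuplicated(genes)) stop("panel genes must be unique", call. = FALSE)
  stopifnot(is.data.frame(intervals))
  need <- c("chrom", "start", "end", "gene")
  if (!all(need %in% names(intervals))) {
    stop("intervals need columns chrom, start, end, gene", call. = FALSE)
  }
  if (nrow(intervals) && any(intervals$end <= intervals$start)) {
    stop("intervals must satisfy start < end (0-based half-open)", call. = FALSE)
  }
  intervals <- merge_intervals(intervals)
  structure(list(genes = genes, intervals = intervals,
                 provenance = provenance),
            class = "panel_spec")
}

# Merge overlapping/adjacent intervals per (chrom, gene); keeps the
# non-overlap invariant of the panel container.
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0) return(intervals)
  pieces <- split(intervals, paste(intervals$chrom, intervals$gene, sep = "\r"))
  merged <- lapply(pieces, function(d) {
    d <- d[order(d$start), , drop = FALSE]
    keep_start <- d$start[1]; keep_end <- d$end[1]
    out <- list()
    if (nrow(d) > 1) {
      for (i in 2:nrow(d)) {
        if (d$start[i] <= keep_end) {
          keep_end <- max(keep_end, d$end[i])
        } else {
          out[[length(out) + 1L]] <- c(keep_start, keep_end)
          keep_start <- d$start[i]; keep_end <- d$end[i]
        }
      }
    }
    out[[length(out) + 1L]] <- c(keep_start, keep_end)
    data.frame(chrom = d$chrom[1],
               start = vapply(out, `[`, numeric(1), 1),
               end = vapply(out, `[`, numeric(1), 2),
               gene = d$gene[1], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, merged)
  rownames(res) <- NULL
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Canonical variant key
#'
#' Normalizes a (chrom, pos, ref, alt) quadruple to the canonical matching
#' key used module-wide: alleles uppercased, shared trailing then leading
#' bases of indels trimmed (keeping at least one base of each allele), and
#' the position left-shifted by the leading trim. Key equality IS the
#' tissue/plasma matching relation.
#'
#' @param chrom,pos,ref,alt Vectors describing one variant per element.
#' @return data.frame with normalized `chrom`, `pos`, `ref`, `alt` and a
#'   `key` string `"chrom:pos:REF>ALT"`.
#' @export
normalize_variant_key <- function(chrom, pos, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  pos <- as.numeric(pos)
  n <- length(ref)
  for (i in seq_len(n)) {
    r <- ref[i]; a <- alt[i]; p <- pos[i]
    # trim shared trailing bases
    while (nchar(r) > 1 && nchar(a) > 1 &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1, nchar(r) - 1)
      a <- substr(a, 1, nchar(a) - 1)
    }
    # trim shared leading bases, shifting the position right
    while (nchar(r) > 1 && nchar(a) > 1 &&
           substr(r, 1, 1) == substr(a, 1, 1)) {
      r <- substr(r, 2, nchar(r))
      a <- substr(a, 2, nchar(a))
      p <- p + 1
    }
    ref[i] <- r; alt[i] <- a; pos[i] <- p
  }
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             key = paste0(chrom, ":", pos, ":", ref, ">", alt),
             stringsAsFactors = FALSE)
}

#' Variant keys for a somatic-variant table
#'
#' @param variants A somatic-variant data.frame.
#' @return Character vector of normalized keys, one per row.
#' @export
variant_keys <- function(variants) {
  if (nrow(variants) == 0) return(character(0))
  normalize_variant_key(variants$chrom, variants$pos,
                        variants$ref, variants$alt)$key
}
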