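# Readers/writers for the formats the pipeline touches: the flat-INFO
# somatic VCF dialect, the clinical TSV, fragment-size TSVs, and the
# BED4 panel. Coordinate conventions: VCF is 1-based, BED is 0-based
# half-open; the conversion lives only in the writers/readers here.

vcf_info_keys <- function() {
  c("POP_AF", "IMPACT", "CADD", "SAF", "SAR", "VAF", "GENE", "CSQ_CLASS")
}

#' Read a somatic-variant VCF (flat INFO dialect)
#'
#' Consumes annotated somatic calls at the VCF level. The expected dialect
#' carries flat INFO keys `POP_AF`, `IMPACT`, `CADD`, `SAF`, `SAR`, `VAF`,
#' `GENE`, `CSQ_CLASS` (a thin adapter from VeP/SnpEff CSQ strings can
#' populate them upstream). Multi-allelic records are split into one
#' variant per ALT allele; per-allele (comma-separated) INFO values are
#' distributed, scalar values recycled. A missing annotation becomes an
#' `NA` sentinel -- never silently 0 -- and later fails the filter cascade
#' with reason `missing_annotation`.
#'
#' @param path Path to a VCF 4.x file.
#' @param compartment `"tissue"` or `"plasma"`.
#' @param sample_id Subject identifier; defaults to a `##sample_id=` header
#'   line if present, else the file name stem.
#' @return A validated [somatic_variants()] data.frame.
#' @export
read_somatic_vcf <- function(path, compartment = c("tissue", "plasma"),
                             sample_id = NULL) {
  compartment <- match.arg(compartment)
  if (!file.exists(path)) stop("no such VCF: ", path, call. = FALSE)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  meta <- vcf@meta
  defined <- sub("^##INFO=<ID=([^,]+),.*$", "\\1",
                 grep("^##INFO=<ID=", meta, value = TRUE))
  missing_keys <- setdiff(vcf_info_keys(), defined)
  if (length(missing_keys)) {
    stop("VCF '", path, "' missing mandatory INFO key(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  if (is.null(sample_id)) {
    sid_line <- grep("^##sample_id=", meta, value = TRUE)
    sample_id <- if (length(sid_line)) {
      sub("^##sample_id=", "", sid_line[1])
    } else {
      sub("\\.vcf(\\.gz)?$", "", basename(path))
    }
  }
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0) {
    return(empty_variants())
  }
  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    info <- parse_info(fix[i, "INFO"])
    per_allele <- function(key, j) {
      val <- info[[key]]
      if (is.null(val) || identical(val, ".")) return(NA_character_)
      parts <- strsplit(val, ",", fixed = TRUE)[[1]]
      v <- if (length(parts) >= j) parts[j] else parts[1]
      if (identical(v, ".")) NA_character_ else v
    }
    do.call(rbind, lapply(seq_along(alts), function(j) {
      data.frame(
        chrom = fix[i, "CHROM"],
        pos = as.numeric(fix[i, "POS"]),
        ref = fix[i, "REF"],
        alt = alts[j],
        gene = per_allele("GENE", j),
        consequence_class = per_allele("CSQ_CLASS", j),
        population_af = as.numeric(per_allele("POP_AF", j)),
        impact = per_allele("IMPACT", j),
        cadd_phred = as.numeric(per_allele("CADD", j)),
        fwd_support = as.integer(per_allele("SAF", j)),
        rev_support = as.integer(per_allele("SAR", j)),
        vaf = as.numeric(per_allele("VAF", j)),
        stringsAsFactors = FALSE)
    }))
  })
  df <- do.call(rbind, rows)
  df$variant_type <- infer_variant_type(df$ref, df$alt)
  df$sample_id <- sample_id
  df$compartment <- compartment
  somatic_variants(df)
}

parse_info <- function(info_string) {
  if (is.na(info_string) || info_string == "." || info_string == "") {
    return(list())
  }
  fields <- strsplit(info_string, ";", fixed = TRUE)[[1]]
  kv <- strsplit(fields, "=", fixed = TRUE)
  out <- lapply(kv, function(x) if (length(x) > 1) x[2] else "")
  names(out) <- vapply(kv, `[`, character(1), 1)
  out
}

empty_variants <- function() {
  somatic_variants(data.frame(
    chrom = character(0), pos = numeric(0), ref = character(0),
    alt = character(0), gene = character(0),
    consequence_class = character(0), variant_type = character(0),
    population_af = numeric(0), impact = character(0),
    cadd_phred = numeric(0), fwd_support = integer(0),
    rev_support = integer(0), vaf = numeric(0),
    sample_id = character(0), compartment = character(0),
    stringsAsFactors = FALSE))
}

#' Write a somatic-variant table as a single-sample VCF
#'
#' Emits the flat INFO dialect read by [read_somatic_vcf()]; the two are
#' inverse on the fields of the variant table.
#'
#' @param variants Somatic-variant data.frame for one sample/compartment.
#' @param path Output path.
#' @param sample_id Identifier recorded in the `##sample_id=` header line;
#'   defaults to the (single) id found in `variants`.
#' @return `path`, invisibly.
#' @export
write_somatic_vcf <- function(variants, path, sample_id = NULL) {
  sid <- if (is.null(sample_id)) unique(variants$sample_id) else sample_id
  if (length(sid) > 1) stop("one VCF per sample", call. = FALSE)
  fmt <- function(x, digits = 6) {
    ifelse(is.na(x), ".", formatC(x, format = "g", digits = digits))
  }
  fmt_chr <- function(x) ifelse(is.na(x), ".", as.character(x))
  header <- c(
    "##fileformat=VCFv4.2",
    if (length(sid)) paste0("##sample_id=", sid),
    "##INFO=<ID=POP_AF,Number=A,Type=Float,Description=\"General-population allele frequency\">",
    "##INFO=<ID=IMPACT,Number=A,Type=String,Description=\"Annotated impact class\">",
    "##INFO=<ID=CADD,Number=A,Type=Float,Description=\"CADD PHRED-scaled score\">",
    "##INFO=<ID=SAF,Number=A,Type=Integer,Description=\"Alt-supporting reads, forward strand\">",
    "##INFO=<ID=SAR,Number=A,Type=Integer,Description=\"Alt-supporting reads, reverse strand\">",
    "##INFO=<ID=VAF,Number=A,Type=Float,Description=\"Variant allele fraction\">",
    "##INFO=<ID=GENE,Number=A,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ_CLASS,Number=A,Type=String,Description=\"Coarse consequence class\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(0)
  if (nrow(variants)) {
    ord <- order(variants$chrom, variants$pos, variants$ref, variants$alt)
    v <- variants[ord, , drop = FALSE]
    info <- paste0(
      "POP_AF=", fmt(v$population_af, 10),
      ";IMPACT=", fmt_chr(v$impact),
      ";CADD=", fmt(v$cadd_phred),
      ";SAF=", fmt_chr(v$fwd_support),
      ";SAR=", fmt_chr(v$rev_support),
      ";VAF=", fmt(v$vaf, 10),
      ";GENE=", fmt_chr(v$gene),
      ";CSQ_CLASS=", fmt_chr(v$consequence_class))
    body <- paste(v$chrom, format(v$pos, scientific = FALSE, trim = TRUE),
                  ".", v$ref, v$alt, ".", "PASS", info, sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read / write the clinical table
#'
#' Tab-separated with header columns `sample_id, group, age, sex, t_stage,
#' n_stage, m_stage, survival_days, event, cea, ca19_9, ca72_4,
#' msi_status, tmb`. Stage labels outside the closed vocabularies raise a
#' validation error listing the offending values.
#'
#' @param path File path.
#' @return [patient_records()] data.frame.
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  patient_records(df)
}

#' @rdname read_clinical_table
#' @param records A [patient_records()] data.frame.
#' @export
write_clinical_table <- function(records, path) {
  records <- patient_records(records)
  records$event <- as.integer(records$event)
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a cfDNA fragment-size profile
#'
#' Two-column tab-separated table with header `size_bp` and
#' `conc_pg_ml`, emulating exported electropherogram traces.
#'
#' @param path File path.
#' @param sample_id Subject identifier; defaults to the file name stem.
#' @param analysis_range Analysis window in bp.
#' @return A [fragment_profile()].
#' @export
read_fragment_profile <- function(path, sample_id = NULL,
                                  analysis_range = c(100, 1000)) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("size_bp", "conc_pg_ml") %in% names(df))) {
    stop("fragment profile needs columns size_bp, conc_pg_ml", call. = FALSE)
  }
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(tsv|txt)$", "", basename(path))
  }
  fragment_profile(sample_id, df$size_bp, df$conc_pg_ml, analysis_range)
}

#' @rdname read_fragment_profile
#' @param profile A [fragment_profile()].
#' @export
write_fragment_profile <- function(profile, path) {
  utils::write.table(
    data.frame(size_bp = profile$sizes,
               conc_pg_ml = format(profile$concentrations, digits = 12,
                                   scientific = FALSE, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a capture panel as BED4
#'
#' 0-based half-open intervals with the gene symbol in column 4. An empty
#' panel yields a header comment only.
#'
#' @param panel A [panel_spec()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_bed <- function(panel, path) {
  lines <- "#chrom\tstart\tend\tgene"
  if (nrow(panel$intervals)) {
    iv <- panel$intervals
    lines <- c(lines, paste(iv$chrom,
                            format(iv$start, scientific = FALSE, trim = TRUE),
                            format(iv$end, scientific = FALSE, trim = TRUE),
                            iv$gene, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_panel_bed
#' @export
read_panel_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) {
    return(panel_spec(character(0),
                      data.frame(chrom = character(0), start = numeric(0),
                                 end = numeric(0), gene = character(0),
                                 stringsAsFactors = FALSE)))
  }
  parts <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  iv <- data.frame(chrom = parts[, 1], start = as.numeric(parts[, 2]),
                   end = as.numeric(parts[, 3]), gene = parts[, 4],
                   stringsAsFactors = FALSE)
  panel_spec(unique(iv$gene), iv)
}

#' Checksum manifest for a set of files
#'
#' @param paths Files to fingerprint.
#' @param root Paths are stored relative to this directory.
#' @return data.frame with `file` and `md5` columns.
#' @export
file_manifest <- function(paths, root = NULL) {
  md5 <- unname(tools::md5sum(paths))
  file <- if (is.null(root)) paths else {
    np <- normalizePath(paths)
    nr <- paste0(normalizePath(root), "/")
    ifelse(startsWith(np, nr), substring(np, nchar(nr) + 1), np)
  }
  data.frame(file = file, md5 = md5, stringsAsFactors = FALSE)
}
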