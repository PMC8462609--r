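# Five-criterion somatic-variant filter cascade and panel construction.
#
# A variant is retained only when ALL of the following hold:
#   (i)   general-population allele frequency < 1%
#   (ii)  protein-coding non-synonymous consequence AND HIGH impact
#   (iii) CADD PHRED score > 30 (strict)
#   (iv)  not present in 100% of the cohort's tissue samples
#   (v)   >= 2 alt-supporting reads on each strand
# Any missing annotation fails with an explicit `missing_annotation`
# reason; decisions are data, never exceptions.

#' Filter-cascade configuration
#'
#' Boundary semantics of the criteria: `<1%` strict,
#' `>30` strict, `>=2` inclusive. The consequence vocabulary counted as
#' protein-coding non-synonymous is configurable; cohort ubiquity can be
#' evaluated per variant key (default) or per gene.
#'
#' @param pop_af_max Exclusive upper bound on population allele frequency.
#' @param cadd_min Exclusive lower bound on the CADD PHRED score.
#' @param min_strand Inclusive minimum alt-supporting reads per strand.
#' @param presence_max Exclusive upper bound on the cohort presence
#'   fraction (1.0 excludes only fully ubiquitous variants).
#' @param coding_classes Consequence classes counted as protein-coding
#'   non-synonymous.
#' @param high_impact Impact label required by criterion (ii).
#' @param ubiquity_unit `"key"` or `"gene"`: level at which criterion (iv)
#'   presence is computed by [filter_cohort()].
#' @return list classed `filter_config`.
#' @export
filter_config <- function(pop_af_max = 0.01, cadd_min = 30, min_strand = 2,
                          presence_max = 1.0,
                          coding_classes = coding_nonsyn_classes(),
                          high_impact = "HIGH",
                          ubiquity_unit = c("key", "gene")) {
  ubiquity_unit <- match.arg(ubiquity_unit)
  structure(as.list(environment()), class = "filter_config")
}

#' Apply the filter cascade to variants
#'
#' Evaluates the five criteria independently and conjoins them. Returns a
#' decision per variant, not an exception: `passed` is TRUE iff
#' `failed_criteria` is empty. `NA` annotations contribute the reason
#' `missing_annotation` and can never pass.
#'
#' @param variants Somatic-variant data.frame.
#' @param cohort_presence_fraction Numeric vector in `[0, 1]`, the fraction
#'   of cohort tissue samples carrying each variant's key (recycled if
#'   length 1).
#' @param config A [filter_config()].
#' @return data.frame with `key`, `passed`, and a list-column
#'   `failed_criteria` with values among `pop_af`, `impact`, `cadd`,
#'   `ubiquity`, `strand_support`, `missing_annotation`.
#' @export
passes_filters <- function(variants, cohort_presence_fraction,
                           config = filter_config()) {
  n <- nrow(variants)
  pres <- rep_len(cohort_presence_fraction, n)
  if (n && any(pres < 0 | pres > 1)) {
    stop("cohort_presence_fraction must lie in [0, 1]", call. = FALSE)
  }
  keys <- variant_keys(variants)
  failed <- vector("list", n)
  for (i in seq_len(n)) {
    v <- variants[i, ]
    f <- character(0)
    missing_ann <- FALSE
    if (is.na(v$population_af)) missing_ann <- TRUE
    else if (!(v$population_af < config$pop_af_max)) f <- c(f, "pop_af")
    if (is.na(v$consequence_class) || is.na(v$impact)) missing_ann <- TRUE
    else if (!(v$consequence_class %in% config$coding_classes &&
               v$impact == config$high_impact)) f <- c(f, "impact")
    if (is.na(v$cadd_phred)) missing_ann <- TRUE
    else if (!(v$cadd_phred > config$cadd_min)) f <- c(f, "cadd")
    if (!(pres[i] < config$presence_max)) f <- c(f, "ubiquity")
    if (is.na(v$fwd_support) || is.na(v$rev_support)) missing_ann <- TRUE
    else if (!(v$fwd_support >= config$min_strand &&
               v$rev_support >= config$min_strand)) {
      f <- c(f, "strand_support")
    }
    if (missing_ann) f <- c(f, "missing_annotation")
    failed[[i]] <- f
  }
  out <- data.frame(key = keys,
                    passed = lengths(failed) == 0,
                    stringsAsFactors = FALSE)
  out$failed_criteria <- failed
  out
}

#' Filter a tissue cohort and summarize positivity
#'
#' Computes the cohort presence fraction of every normalized key over the
#' tissue samples, applies [passes_filters()], and reports per-sample
#' retained sets plus the cohort summary (alteration-positive samples and
#' mean retained count among positives).
#'
#' @param tissue_variants Pooled tissue [somatic_variants()] for the cohort.
#' @param samples Character vector of all tissue sample ids analyzed (the
#'   ubiquity denominator); defaults to the ids present in the input.
#' @param config A [filter_config()].
#' @return list with `retained` (per-sample named list of variant
#'   data.frames), `decisions`, and `summary` (n_samples, n_positive,
#'   positive_fraction_pct, mean_retained_among_positive,
#'   per_sample_counts).
#' @export
filter_cohort <- function(tissue_variants, samples = NULL,
                          config = filter_config()) {
  if (nrow(tissue_variants) &&
      !all(tissue_variants$compartment == "tissue")) {
    stop("filter_cohort expects tissue-compartment variants", call. = FALSE)
  }
  if (is.null(samples)) samples <- unique(tissue_variants$sample_id)
  n_samples <- length(samples)
  if (nrow(tissue_variants) == 0 || n_samples == 0) {
    return(list(retained = stats::setNames(vector("list", n_samples),
                                           samples),
                decisions = passes_filters(empty_variants(), numeric(0),
                                           config),
                summary = list(n_samples = n_samples, n_positive = 0L,
                               positive_fraction_pct = if (n_samples) 0
                                                       else NA_real_,
                               mean_retained_among_positive = NA_real_,
                               per_sample_counts = stats::setNames(
                                 integer(n_samples), samples))))
  }
  keys <- variant_keys(tissue_variants)
  unit <- if (config$ubiquity_unit == "gene") tissue_variants$gene else keys
  presence <- tapply(tissue_variants$sample_id, unit,
                     function(s) length(unique(s))) / n_samples
  pres_frac <- as.numeric(presence[unit])
  decisions <- passes_filters(tissue_variants, pres_frac, config)
  retained_df <- tissue_variants[decisions$passed, , drop = FALSE]
  retained <- lapply(stats::setNames(samples, samples), function(s)
    retained_df[retained_df$sample_id == s, , drop = FALSE])
  counts <- vapply(retained, nrow, integer(1))
  n_pos <- sum(counts > 0)
  list(retained = retained,
       decisions = decisions,
       summary = list(
         n_samples = n_samples,
         n_positive = n_pos,
         positive_fraction_pct = 100 * n_pos / n_samples,
         mean_retained_among_positive =
           if (n_pos) mean(counts[counts > 0]) else NA_real_,
         per_sample_counts = counts))
}

#' Build the capture panel from retained variants
#'
#' Genes are ranked by (number of samples mutated, total retained variant
#' count, lexicographic symbol) and truncated to `max_genes`; intervals
#' are merged per gene and the supporting variant keys recorded as
#' provenance.
#'
#' @param retained Named per-sample list of retained variant data.frames
#'   (as produced by [filter_cohort()]), or a single pooled data.frame.
#' @param max_genes Panel size cap (default 38).
#' @param gene_intervals data.frame `gene`, `chrom`, `start`, `end`
#'   (0-based half-open), e.g. [gc_gene_intervals()].
#' @return A [panel_spec()].
#' @export
build_panel <- function(retained, max_genes = 38,
                        gene_intervals = gc_gene_intervals()) {
  pooled <- if (is.data.frame(retained)) retained else {
    do.call(rbind, c(lapply(retained, as.data.frame),
                     make.row.names = FALSE))
  }
  if (is.null(pooled) || nrow(pooled) == 0) {
    stop("no retained variants to build a panel from", call. = FALSE)
  }
  tab <- stats::aggregate(
    cbind(n_samples = sample_id) ~ gene, data = pooled,
    FUN = function(s) length(unique(s)))
  tot <- table(pooled$gene)
  tab$n_variants <- as.integer(tot[tab$gene])
  tab <- tab[order(-tab$n_samples, -tab$n_variants, tab$gene), ,
             drop = FALSE]
  genes <- utils::head(tab$gene, max_genes)
  missing <- setdiff(genes, gene_intervals$gene)
  if (length(missing)) {
    stop("gene(s) missing from gene_intervals: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  iv <- gene_intervals[gene_intervals$gene %in% genes,
                       c("chrom", "start", "end", "gene"), drop = FALSE]
  keys <- variant_keys(pooled)
  provenance <- lapply(stats::setNames(genes, genes), function(g)
    sort(unique(keys[pooled$gene == g])))
  panel_spec(genes, iv, provenance)
}
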