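# Tissue/plasma variant matching, cohort concordance, and mutational
# spectrum summaries. Matching is exact on the normalized
# (chrom, pos, ref, alt) key -- deep targeted panel calls make exact keys
# auditable, so no fuzzy window is used.

#' Match the tissue and plasma variant sets of one patient
#'
#' Set-algebra partition on normalized keys into tissue-only, plasma-only
#' and shared variants. VAF pairs of shared keys are retained for tumor
#' fraction and allele-frequency analyses.
#'
#' @param tissue,plasma [somatic_variants()] data.frames of one patient.
#' @param sample_id Patient id; required only when both sets are empty.
#' @return list classed `concordance_result` with `sample_id`,
#'   `tissue_only_keys`, `plasma_only_keys`, `shared_keys`, `counts`
#'   (named: tissue_only, plasma_only, shared, tissue, plasma) and
#'   `shared_vafs` (key, tissue_vaf, plasma_vaf).
#' @export
match_variants <- function(tissue, plasma, sample_id = NULL) {
  ids <- unique(c(tissue$sample_id, plasma$sample_id, sample_id))
  if (length(ids) > 1) {
    stop("tissue and plasma sets mix sample ids: ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  tk <- unique(variant_keys(tissue))
  pk <- unique(variant_keys(plasma))
  shared <- intersect(tk, pk)
  t_only <- setdiff(tk, pk)
  p_only <- setdiff(pk, tk)
  shared_vafs <- if (length(shared)) {
    tkeys <- variant_keys(tissue); pkeys <- variant_keys(plasma)
    data.frame(
      key = shared,
      tissue_vaf = tissue$vaf[match(shared, tkeys)],
      plasma_vaf = plasma$vaf[match(shared, pkeys)],
      stringsAsFactors = FALSE)
  } else {
    data.frame(key = character(0), tissue_vaf = numeric(0),
               plasma_vaf = numeric(0), stringsAsFactors = FALSE)
  }
  structure(list(
    sample_id = if (length(ids)) ids else NA_character_,
    tissue_only_keys = sort(t_only),
    plasma_only_keys = sort(p_only),
    shared_keys = sort(shared),
    counts = c(tissue_only = length(t_only), plasma_only = length(p_only),
               shared = length(shared), tissue = length(tk),
               plasma = length(pk)),
    shared_vafs = shared_vafs), class = "concordance_result")
}

#' Cohort-level concordance summary
#'
#' Over the tissue-alteration-positive patients, reports (a) the fraction
#' with at least one plasma alteration of any kind, (b) the fraction with
#' at least one tissue-matching (shared) plasma alteration, (c) the mean
#' plasma alteration count among plasma-positive samples, and (d) the
#' mean shared count among shared-positive samples. Every percentage
#' carries its numerator and denominator.
#'
#' @param results List of [match_variants()] results.
#' @param tissue_positive_ids Sample ids with >= 1 retained tissue variant.
#' @return list with `plasma_any` and `shared` (`num`, `den`, `pct`) and
#'   the two means; `NA` sentinels when `tissue_positive_ids` is empty.
#' @export
cohort_concordance <- function(results, tissue_positive_ids) {
  ids <- vapply(results, function(r) r$sample_id, character(1))
  res <- results[ids %in% tissue_positive_ids]
  den <- length(tissue_positive_ids)
  if (den == 0) {
    return(list(plasma_any = list(num = NA_integer_, den = 0L,
                                  pct = NA_real_),
                shared = list(num = NA_integer_, den = 0L, pct = NA_real_),
                mean_plasma_per_positive = NA_real_,
                mean_shared_per_positive = NA_real_))
  }
  n_plasma <- vapply(res, function(r) r$counts[["plasma"]], numeric(1))
  n_shared <- vapply(res, function(r) r$counts[["shared"]], numeric(1))
  num_any <- sum(n_plasma > 0)
  num_shared <- sum(n_shared > 0)
  list(
    plasma_any = list(num = num_any, den = den, pct = 100 * num_any / den),
    shared = list(num = num_shared, den = den,
                  pct = 100 * num_shared / den),
    mean_plasma_per_positive =
      if (num_any) mean(n_plasma[n_plasma > 0]) else NA_real_,
    mean_shared_per_positive =
      if (num_shared) mean(n_shared[n_shared > 0]) else NA_real_)
}

substitution_classes <- function() {
  c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
}

# Pyrimidine-normalized 6-class label of a SNP; purine-reference
# substitutions are complemented (G>A counts as C>T, etc.).
pyrimidine_class <- function(ref, alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  purine <- ref %in% c("A", "G")
  ref2 <- ifelse(purine, comp[ref], ref)
  alt2 <- ifelse(purine, comp[alt], alt)
  paste0(ref2, ">", alt2)
}

#' Summarize the mutational spectrum of a variant set
#'
#' Counts consequence classes, variant types and SNP substitutions (in
#' the 6-class pyrimidine-normalized convention), per-sample variant
#' counts with the cohort mean, top recurrently mutated genes, and a
#' gene-by-sample oncomatrix of consequence classes (`multi_hit` where a
#' gene is mutated more than once in a sample).
#'
#' @param variants [somatic_variants()] data.frame.
#' @param top_n Number of top genes to report.
#' @return list classed `spectrum_summary`.
#' @export
summarize_spectra <- function(variants, top_n = 10) {
  class_counts <- stats::setNames(integer(length(consequence_classes())),
                                  consequence_classes())
  type_counts <- stats::setNames(integer(3), variant_types())
  sub_counts <- stats::setNames(integer(6), substitution_classes())
  if (nrow(variants) == 0) {
    return(structure(list(
      class_counts = class_counts, type_counts = type_counts,
      substitution_counts = sub_counts,
      per_sample_counts = integer(0), mean_per_sample = NA_real_,
      top_genes = data.frame(gene = character(0), n_samples = integer(0),
                             n_variants = integer(0), fraction = numeric(0),
                             stringsAsFactors = FALSE),
      oncomatrix = matrix(character(0), 0, 0)),
      class = "spectrum_summary"))
  }
  cc <- table(factor(variants$consequence_class,
                     levels = consequence_classes()))
  class_counts[names(cc)] <- as.integer(cc)
  tc <- table(factor(variants$variant_type, levels = variant_types()))
  type_counts[names(tc)] <- as.integer(tc)
  snps <- variants[variants$variant_type == "SNP", , drop = FALSE]
  if (nrow(snps)) {
    sc <- table(factor(pyrimidine_class(toupper(snps$ref),
                                        toupper(snps$alt)),
                       levels = substitution_classes()))
    sub_counts[names(sc)] <- as.integer(sc)
  }
  per_sample <- table(variants$sample_id)
  per_sample_counts <- stats::setNames(as.integer(per_sample),
                                       names(per_sample))
  gene_samples <- tapply(variants$sample_id, variants$gene,
                         function(s) length(unique(s)))
  gene_total <- table(variants$gene)
  genes <- names(gene_samples)
  top <- data.frame(gene = genes,
                    n_samples = as.integer(gene_samples),
                    n_variants = as.integer(gene_total[genes]),
                    stringsAsFactors = FALSE)
  top$fraction <- top$n_variants / nrow(variants)
  top <- top[order(-top$n_samples, -top$n_variants, top$gene), ,
             drop = FALSE]
  rownames(top) <- NULL
  top <- utils::head(top, top_n)
  samples <- sort(unique(variants$sample_id))
  all_genes <- sort(unique(variants$gene))
  onco <- matrix("", nrow = length(all_genes), ncol = length(samples),
                 dimnames = list(all_genes, samples))
  for (i in seq_len(nrow(variants))) {
    g <- variants$gene[i]; s <- variants$sample_id[i]
    onco[g, s] <- if (nzchar(onco[g, s])) "multi_hit"
                  else variants$consequence_class[i]
  }
  structure(list(
    class_counts = class_counts, type_counts = type_counts,
    substitution_counts = sub_counts,
    per_sample_counts = per_sample_counts,
    mean_per_sample = mean(per_sample_counts),
    top_genes = top, oncomatrix = onco), class = "spectrum_summary")
}
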