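# In-code fixture builders shared across the suite.

make_variant <- function(chrom = "chr1", pos = 100, ref = "C", alt = "T",
                         gene = "TP53", consequence_class = "missense",
                         variant_type = NULL, population_af = 0.001,
                         impact = "HIGH", cadd_phred = 35,
                         fwd_support = 5L, rev_support = 4L, vaf = 0.2,
                         sample_id = "S1", compartment = "tissue") {
  if (is.null(variant_type)) variant_type <- infer_variant_type(ref, alt)
  somatic_variants(data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
    consequence_class = consequence_class, variant_type = variant_type,
    population_af = population_af, impact = impact,
    cadd_phred = cadd_phred, fwd_support = fwd_support,
    rev_support = rev_support, vaf = vaf, sample_id = sample_id,
    compartment = compartment, stringsAsFactors = FALSE))
}

bind_variants <- function(...) {
  somatic_variants(do.call(rbind, lapply(list(...), as.data.frame)))
}

# Exhaustive Mann-Whitney oracle: enumerate every labeling of the ranks
# 1..(n1+n2) and tabulate the U statistic of the first group.
enumerate_u_counts <- function(n1, n2) {
  N <- n1 + n2
  combos <- utils::combn(N, n1)
  u <- apply(combos, 2, function(idx) sum(idx) - n1 * (n1 + 1) / 2)
  counts <- numeric(n1 * n2 + 1)
  for (val in u) counts[val + 1] <- counts[val + 1] + 1
  counts
}

# All permutations of 1..n, independent of the package's generator:
# filter the n^n grid down to the n! permutations (n <= 5 in tests).
grid_permutations <- function(n) {
  g <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  g[apply(g, 1, function(r) length(unique(r)) == n), , drop = FALSE]
}
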