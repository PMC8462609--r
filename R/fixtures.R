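# Deterministic synthetic fixture cohort with prescribed concordance
# structure. Used by tests and the acceptance script to exercise the
# filter cascade and the cohort concordance reporting end-to-end with
# known counts; entirely constructed, no randomness.

#' Synthetic cohort with prescribed filter/concordance counts
#'
#' Constructs a 29-sample tissue cohort in which exactly 23 samples
#' retain at least one variant after the five-criterion cascade (the
#' other 6 carry only a common-population-AF variant), with per-positive
#' retained counts summing to 193 (cohort mean 8.39). Plasma sets are
#' built so that, among the 23 tissue-positive samples, 21 carry at least
#' one plasma alteration of any kind and exactly 11 share at least one
#' variant with their tissue. All values are fixed by construction; the
#' cohort is synthetic and carries no patient data.
#'
#' @return list with `tissue` and `plasma` (pooled [somatic_variants()])
#'   and `samples` (the 29 tissue sample ids).
#' @export
synthetic_concordance_cohort <- function() {
  samples <- sprintf("P%02d", 1:29)
  genes <- gc_gene_pool()$gene

  passing <- function(sample_id, i, compartment = "tissue") {
    # unique locus per (sample, index): no key is shared across samples
    data.frame(
      chrom = "chr1",
      pos = 1e6 + match(sample_id, samples) * 1e4 + i,
      ref = "C", alt = "T",
      gene = genes[(i - 1) %% length(genes) + 1],
      consequence_class = "missense", variant_type = "SNP",
      population_af = 0.001, impact = "HIGH", cadd_phred = 35,
      fwd_support = 5L, rev_support = 4L, vaf = 0.2,
      sample_id = sample_id, compartment = compartment,
      stringsAsFactors = FALSE)
  }
  failing <- function(sample_id) {
    v <- passing(sample_id, 1)
    v$population_af <- 0.05  # fails the population-frequency criterion
    v
  }
  private_plasma <- function(sample_id, i) {
    v <- passing(sample_id, 100 + i, compartment = "plasma")
    v$pos <- 5e6 + match(sample_id, samples) * 1e4 + i
    v$vaf <- 0.05
    v
  }

  # 23 positives with retained counts summing to 193 (mean 8.39)
  counts <- rep(8L, 23); counts[1:9] <- 9L
  tissue <- list(); plasma <- list()
  for (s in seq_len(23)) {
    id <- samples[s]
    tissue[[id]] <- do.call(rbind, lapply(seq_len(counts[s]),
                                          function(i) passing(id, i)))
    shared <- if (s <= 11) {
      v <- tissue[[id]][1:2, , drop = FALSE]
      v$compartment <- "plasma"
      v$vaf <- v$vaf * 0.3
      v
    }
    priv <- if (s <= 21) {
      do.call(rbind, lapply(1:2, function(i) private_plasma(id, i)))
    }
    pl <- rbind(shared, priv)
    if (!is.null(pl)) plasma[[id]] <- pl
  }
  # 6 tissue-negative samples: only a filter-failing variant
  for (s in 24:29) {
    id <- samples[s]
    tissue[[id]] <- failing(id)
  }

  list(tissue = somatic_variants(do.call(rbind, c(tissue,
                                                  make.row.names = FALSE))),
       plasma = somatic_variants(do.call(rbind, c(plasma,
                                                  make.row.names = FALSE))),
       samples = samples)
}
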