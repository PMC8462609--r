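# ctdnatrack

Tumor-informed circulating-tumor-DNA (ctDNA) analysis for gastric cancer,
packaged as a tested R workflow. The package covers the computational
pipeline of a matched tissue/plasma liquid-biopsy study:

* **Panel design** — a five-criterion somatic filter cascade over tissue
  whole-exome calls (population allele frequency < 1%, protein-coding
  non-synonymous + HIGH impact, CADD > 30, not present in 100% of cohort
  samples, ≥ 2 supporting reads per strand), followed by recurrence-ranked
  selection of up to 38 genes into a capture panel (BED output).
* **Tissue–plasma concordance** — exact matching on normalized
  (chrom, pos, ref, alt) keys, per-patient Venn partitions, cohort
  concordance fractions with explicit numerators/denominators, and
  maftools-style mutational-spectrum summaries (consequence classes,
  pyrimidine-normalized substitutions, oncomatrix).
* **cfDNA quantification** — total yield as the trapezoidal integral of a
  capillary-electrophoresis size profile over 100–1000 bp; decomposition
  into mono-/di-/tri-nucleosomal size regions; tumor fraction as the mean
  plasma variant allele fraction; TMB as coding mutations per megabase.
* **Statistics** — the exact Mann–Whitney null distribution of U via the
  counting recurrence, with two-sided tail probabilities
  `p = 2·min(P(U ≤ u), P(U ≥ u))`; uncorrected Pearson χ² and Fisher exact
  tests on 2×2 tables; Spearman correlation (permutation-exact for n ≤ 9);
  Kaplan–Meier strata over the matching-variant bins 0 / 1–2 / 3–6 / >6
  with log-rank and Efron-ties Cox models; Boruta-style shadow-feature
  importance over random forests; and leave-one-out ROC discrimination
  (AUC by the rank identity `AUC = U/(n1·n2)`).
* **Synthetic cohort** — `simulate_cohort()` generates a full study (29
  cases, 20 controls) with the programmed structure the analyses assume:
  a 43.6-fold case/control cfDNA yield contrast, nucleosomal fragment
  peaks shifted down in cases, negative-binomial tissue mutation counts,
  stage-dependent ctDNA shedding (0.10 for T1–T2, 0.556 for T3–T4),
  plasma-private variants, VAF attenuation, yield-linked serum CEA, and
  survival hazards increasing with the plasma mutation load.

## Worked example

The `analysis/` directory holds the numbered pipeline drivers
(`01_simulate.R` … `05_associate.R`), each a thin narrative script over
the package. Running them in order on the default seed prints, among
other output:

```
$ Rscript analysis/02_design_panel.R
Filter cascade over 29 tissue samples:
  calls in: 239; retained: 191
  alteration-positive samples: 23/29 (79.31%)
  mean retained variants per positive sample: 8.30
  failure reasons: cadd=13, impact=12, pop_af=14, strand_support=9
Panel: 34 genes, 34 merged intervals -> results/panel.bed

$ Rscript analysis/04_quantify.R
Total cfDNA yield: cases 74.30 vs controls 1.78 ng/mL
  fold change 41.7 (U = 4, p = 8.49e-13, exact)
  mono-nucleosomal yield: 54490 vs 1216 pg/mL (U = 2, p = 2.83e-13)
  mono-nucleosomal modal size: 166 (cases) vs 170 bp (controls)

$ Rscript analysis/05_associate.R
ctDNA detection: T1-T2 9.1%, T3-T4 58.3% (chi2 = 6.13, p = 0.013)
Kaplan-Meier medians (days) by matching-variant stratum:
  0   : 510
  3-6 : 415
  >6  : 21
  log-rank chi2 = 29.58 (df 2), p = 0.0000
```

Reading the output: 23 of the 29 simulated cases carry at least one
filter-passing tissue variant (79.31% positivity); total cfDNA is massively
elevated in cases, with an exact rank-sum tail probability computed from
the full null distribution of U at group sizes 20 vs 29; ctDNA detection
rises steeply with tumor size; and median survival falls monotonically with
the number of tissue-matching plasma variants. Each run's tables land under
`results/`.

The same pipeline is available as a single call:

```r
library(ctdnatrack)
res <- run_all(default_config(seed = 1), out_dir = "results/run")
res$report
```

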