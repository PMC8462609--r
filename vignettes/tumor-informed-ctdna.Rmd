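---
title: "Tumor-informed ctDNA analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor-informed ctDNA analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

In a tumor-informed liquid biopsy, a patient's tumor tissue is sequenced
first; the somatic variants found there define a personal (or cohort-level)
target set, and plasma cell-free DNA (cfDNA) is then deep-sequenced over a
compact capture panel to look for those same alterations. ctdnatrack
implements the computational side of such a study for gastric cancer: the
somatic filter cascade that turns whole-exome tissue calls into a capture
panel, exact tissue/plasma variant matching and concordance reporting, cfDNA
yield and nucleosomal fragment-size quantification, and the statistical
layer that relates the plasma mutation load to clinical outcome. Because
patient-level data from such studies are not publishable, the package ships
a synthetic-cohort generator that reproduces the statistical structure every
downstream stage assumes, so the whole pipeline is testable end to end.

# The filter cascade

A tissue call is retained for panel design only when all five criteria hold:

1. **Population frequency** — general-population allele frequency `< 0.01`
   (strict). Common polymorphisms are not somatic markers.
2. **Coding impact** — consequence class in the protein-coding
   non-synonymous set (missense, nonsense, frameshift insertion/deletion,
   splice site, in-frame indel) *and* annotated impact `HIGH`. The exact
   annotation vocabulary differs between annotators, so the set is a
   `filter_config()` value rather than a constant.
3. **Deleteriousness** — CADD PHRED score `> 30` (strict; a score of
   exactly 30 fails).
4. **Cohort ubiquity** — the normalized variant key must not be present in
   100% of the cohort's tissue samples; fully ubiquitous calls are treated
   as artifacts or germline leakage. Presence is computed per variant key by
   default; a per-gene alternative is available via
   `filter_config(ubiquity_unit = "gene")` because the level at which
   ubiquity should be judged is genuinely open — per key is the stricter,
   more auditable reading and is the default.
5. **Strand support** — at least 2 alternate-supporting reads on each
   strand (inclusive).

A missing annotation is carried as an `NA` sentinel and fails the cascade
with the explicit reason `missing_annotation`; it is never coerced to a
passing (or zero) value. Decisions are returned as data (`passed` +
`failed_criteria`), so a filter report can always be audited per variant.

Panel construction ranks genes by (number of samples mutated, total
retained variant count, lexicographic symbol) and truncates to
`max_genes = 38`. The ranking tuple is this package's rule: recurrence is
the natural recall-maximizing criterion for a fixed-size panel, and the
lexicographic tail makes truncation deterministic.

# Variant matching

Tissue/plasma matching is exact on the normalized key
`(chrom, pos, ref, alt)`: alleles are uppercased, shared trailing then
leading bases of indels are trimmed (keeping at least one base each), and
the position is shifted by the leading trim. Exact keys are auditable and
appropriate for deep targeted sequencing over the same panel regions; no
fuzzy positional window is used. Concordance is reported as fractions with
explicit numerators and denominators — never bare percentages.

# cfDNA quantification

Fragment profiles emulate capillary-electrophoresis output: a size grid
(bp) against concentration (pg/mL per bp). Total yield is the trapezoidal
integral over the analysis range (default 100–1000 bp), converted to ng/mL.
Nucleosomal decomposition integrates the same curve over three explicit
size regions — mono `[100, 250)`, di `[250, 450)`, tri `[450, 700)` bp —
chosen around the ~170 bp mono-nucleosomal peak and its multiples;
instrument vendors do not publish their region bounds, so these are
configuration with motivated defaults. The per-region "size" statistic is
the modal size (argmax of the curve, ties to the smallest size);
instrument "average size" readouts are ambiguous between mode,
concentration-weighted mean and molarity-weighted mean, so the
concentration-weighted mean is also reported. Tumor fraction is the
arithmetic mean of the plasma variant allele fractions; TMB is coding
mutations per megabase of assayed region.

# The statistical layer

* **Exact Mann–Whitney.** The null distribution of U is computed by the
  Gaussian-binomial polynomial recurrence (multiply by `1 - q^(n2+k)`,
  divide by `1 - q^k`, `k = 1..n1`), which is the generating-function form
  of the standard counting recurrence
  `N(u; n1, n2) = N(u; n1-1, n2) + N(u-n2; n1, n2-1)`. Counts are bounded
  by `choose(n1+n2, n1)`, which for the cohort sizes used here
  (`choose(49, 20) ≈ 2.8e13`) is far below 2^53, so double-precision
  arithmetic is exact. The two-sided p-value is `2·min(lower, upper)`
  capped at 1 — the convention that reproduces classical printed tail
  probabilities. The sample-based front end uses mid-ranks, falls back to
  the tie-corrected normal approximation with continuity correction when
  ties are present or `n1·n2` exceeds the exact cap, and is tested against
  both `wilcox.test()` and exhaustive labeling enumeration.
* **2×2 tests.** The chi-square statistic is the plain (uncorrected)
  Pearson form; Yates' correction is deliberately not applied, matching the
  convention under which the cohort's detection-rate contrasts were
  computed. Fisher's exact test sums hypergeometric probabilities of tables
  as or more extreme.
* **Spearman correlation** is the Pearson correlation of mid-ranks;
  two-sided p by exhaustive permutation for n ≤ 9, t-approximation above.
* **Survival.** Kaplan–Meier curves via `survival::survfit`; the reported
  median is defined explicitly as the smallest time with S(t) ≤ 0.5 (an
  `NA` sentinel when never reached), rather than an interpolated median.
  The k-sample log-rank test and an Efron-ties Cox model mirror the
  standard clinical analysis; Wald p-values are primary and Holm-adjusted
  values are reported alongside, since multiplicity conventions vary.
  Matching-count strata use the explicit bins 0 / 1–2 / 3–6 / >6 with 6
  inside "3–6" and 7 the first member of ">6".
* **Shadow-feature importance** is the Boruta algorithm implemented over
  `randomForest`: each iteration appends a permuted shadow copy of every
  feature, and a feature scores a hit when its permutation importance
  exceeds the maximum shadow importance; decisions come from binomial
  tests on hit counts with Holm correction. At cohort-sized n the data are
  fixed across iterations, so a feature that separates the labels by
  chance can be confirmed consistently — a known small-sample caveat of
  the algorithm, visible in the demo cohort.
* **Discrimination.** AUC is computed by the rank (Mann–Whitney) identity
  with half-credit for ties; the M0/M1 classifier is a random forest under
  leave-one-out cross-validation (logistic regression by configuration).
  Leave-one-out is the defensible scheme at n ≈ 29; the original analysis
  scheme behind such AUCs is typically unstated, and resubstitution would
  be optimistic.

# The synthetic cohort

`simulate_cohort()` draws, per seed, a complete study: 29 cases and 20
controls with the following programmed structure (all values are
`sim_params()` defaults and are the package's standing study conditions):

* **Tissue positivity**: each case carries ≥ 1 filter-passing tissue
  variant with probability 23/29; positive cases draw
  `1 + NB(size = 3, mu = 7.4)` passing variants (mean 8.4, overdispersed —
  a Poisson law cannot reach the observed 1–23 per-sample range), plus a
  Poisson number of deliberately filter-failing calls whose single violated
  criterion is chosen at random, so the cascade is exercised continuously.
* **Stage-dependent shedding**: the probability that a tumor sheds
  detectable ctDNA is 0.10 for T1–T2 and 0.556 for T3–T4 tumors. Given
  shedding, each tissue variant appears in plasma with probability 0.45
  (at least one always does); every case additionally gains
  Poisson(2) plasma-private variants, because real plasma profiles contain
  alterations never seen in the sampled tissue block.
* **VAFs**: tissue VAFs are Beta(1.6, 6) (range comfortably covering
  0.03–0.87); plasma VAFs are the matched tissue VAF attenuated by a
  factor 0.3 with multiplicative log-normal noise, truncated so the plasma
  VAF never exceeds the tissue VAF.
* **Yields**: log-normal per group with means 87.59 (case) and 2.01
  (control) ng/mL — a programmed 43.6-fold contrast — and log-scale SDs
  1.0 / 0.6.
* **Fragment profiles**: three Gaussian peaks at 170/350/520 bp (controls)
  and 166/344/512 bp (cases, shifted down, emulating the shorter tumor
  fragments) with mass fractions 0.68/0.2/0.1 vs 0.73/0.15/0.1, a flat
  baseline carrying the residual mass, and per-subject jitter; the curve
  is normalized so its integral equals the drawn yield exactly (mass
  conservation is exact, not approximate).
* **Survival**: Weibull (shape 1.2, baseline scale 1090 days) with
  log-hazard increments 0 / 0.645 / 1.123 / 3.485 over the matching-count
  bins, chosen so the programmed medians fall near 803 / 469 / 315 / 44
  days; censoring is uniform on [900, 2500] days.
* **Serum markers**: CEA is tied to yield through a Gaussian copula with
  latent correlation 0.618 (Spearman ≈ 0.6); CA 19-9 and CA 72-4 are
  independent log-normals.

The generator reproduces what the downstream analyses *assume* — group
contrasts, shedding structure, hazard ordering, marker correlation. It does
**not** emulate sequencing reads, UMI consensus errors, annotation noise,
inter-laboratory electrophoresis artifacts, or the correlation between
M stage and shedding; passing tests therefore demonstrate correctness of
the computations under the programmed structure, not clinical performance
on real cohorts.

A separate deterministic fixture, `synthetic_concordance_cohort()`,
constructs a 29-sample cohort with exact counts (23 tissue-positive,
per-positive retained counts summing to 193, 21 plasma-positive, 11
matching-positive) for auditing the filter and concordance bookkeeping
end to end; it is fully synthetic and labeled as such.

# Numerical choices and degenerate inputs

* Integrals are trapezoidal on the profile's own grid with endpoint
  interpolation, so regions that tile the analysis range sum to the total
  exactly.
* Modal-size ties resolve to the smallest size (first argmax).
* Filter decisions on empty cohorts are empty summaries, not errors; empty
  plasma sets give zero-count partitions; concordance over an empty
  positive set returns `NA` sentinels with zero denominators.
* `fold_change` keeps the unrounded ratio (so the reciprocal identity
  holds) and is rounded to one decimal only at reporting time.
* Constant covariates, rank-deficient Cox designs, and single-class
  discrimination inputs raise immediate errors; near-empty survival strata
  (< 3 patients) are dropped from the Cox design because they cannot
  support a coefficient.
* All randomness flows through a single integer seed; cohorts, manifests,
  and whole pipeline runs are byte-identical under a repeated seed.

# Problem sizes used by the test suite

The statistical property checks run at sizes chosen to give stable
verdicts at interactive cost: 200-seed cohort batches for the binomial
recovery of tissue positivity, stage-wise shedding, the yield fold change
and the marker correlation; 2,000 synthetic patients (500 per stratum) for
the Kaplan–Meier median ordering; n = 2,000 for Cox coefficient recovery
within 3 standard errors; 200 seeds for the Cox null-calibration check;
and exhaustive enumeration oracles up to `n1 + n2 = 12` for the exact
rank-sum distribution and n = 5 for permutation-exact Spearman p-values.

# Known limitations

* Annotation inputs (population AF resource, CADD version, consequence
  vocabulary) are consumed as opaque fields; the package takes no position
  on annotator choice.
* The instrument-reported per-region "size" statistic of electrophoresis
  platforms is not reproducible from first principles; the package reports
  modal and concentration-weighted-mean sizes and leaves vendor statistics
  alone.
* Plasma inputs are assumed panel-restricted (a capture panel cannot
  report variants outside its regions).
* Shadow-feature importance at n ≈ 30 is sensitive to chance separations;
  treat confirmations on small cohorts as hypotheses, not findings.
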