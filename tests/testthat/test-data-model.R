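# Domain containers, variant-key normalization, and format round trips.

test_that("variant key normalization trims indels and left-shifts", {
  # SNP untouched
  k <- normalize_variant_key("chr1", 100, "C", "T")
  expect_equal(k$key, "chr1:100:C>T")
  # two representations of the same deletion collapse to one key
  k1 <- normalize_variant_key("chr1", 100, "AC", "A")
  k2 <- normalize_variant_key("chr1", 100, "ACC", "AC")
  expect_equal(k1$key, k2$key)
  # lower case normalized up
  expect_equal(normalize_variant_key("chr1", 100, "c", "t")$key,
               "chr1:100:C>T")
  # shared leading base trimming shifts the position
  k3 <- normalize_variant_key("chr2", 50, "TAG", "TA")
  k4 <- normalize_variant_key("chr2", 51, "AG", "A")
  expect_equal(k3$key, k4$key)
})

test_that("key normalization is idempotent", {
  set.seed(11)
  bases <- c("A", "C", "G", "T")
  for (i in 1:50) {
    ref <- paste(sample(bases, sample(1:4, 1), replace = TRUE),
                 collapse = "")
    alt <- paste(sample(bases, sample(1:4, 1), replace = TRUE),
                 collapse = "")
    if (ref == alt) next
    k1 <- normalize_variant_key("chrX", 1000, ref, alt)
    k2 <- normalize_variant_key(k1$chrom, k1$pos, k1$ref, k1$alt)
    expect_equal(k2$key, k1$key)
  }
})

test_that("variant validator enforces the invariants", {
  expect_error(make_variant(pos = 0), "pos")
  expect_error(make_variant(ref = "C", alt = "C", variant_type = "SNP"),
               "differ")
  expect_error(make_variant(population_af = 1.2), "population_af")
  expect_error(make_variant(vaf = -0.1), "vaf")
  expect_error(make_variant(ref = "C", alt = "T", variant_type = "INS"),
               "inconsistent")
  expect_error(make_variant(compartment = "serum"), "compartment")
  # NA annotations are allowed (explicit unknown sentinels)
  v <- make_variant(cadd_phred = NA_real_)
  expect_true(is.na(v$cadd_phred))
})

test_that("somatic VCF write/read is the identity on variant fields", {
  v <- bind_variants(
    make_variant(pos = 100),
    make_variant(pos = 200, ref = "A", alt = "AGT", gene = "CDH1",
                 consequence_class = "frameshift-ins", vaf = 0.41),
    make_variant(chrom = "chr7", pos = 5533, ref = "GTT", alt = "G",
                 consequence_class = "frameshift-del",
                 population_af = 0.0001234, cadd_phred = 47.25))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_somatic_vcf(v, f)
  back <- read_somatic_vcf(f, "tissue")
  expect_equal(nrow(back), 3)
  ord <- order(v$pos)
  for (col in variant_columns()) {
    expect_equal(back[[col]], v[[col]][ord], info = col,
                 tolerance = 1e-9)
  }
})

test_that("multi-allelic records split into one variant per ALT", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##sample_id=S9",
    "##INFO=<ID=POP_AF,Number=A,Type=Float,Description=\"x\">",
    "##INFO=<ID=IMPACT,Number=A,Type=String,Description=\"x\">",
    "##INFO=<ID=CADD,Number=A,Type=Float,Description=\"x\">",
    "##INFO=<ID=SAF,Number=A,Type=Integer,Description=\"x\">",
    "##INFO=<ID=SAR,Number=A,Type=Integer,Description=\"x\">",
    "##INFO=<ID=VAF,Number=A,Type=Float,Description=\"x\">",
    "##INFO=<ID=GENE,Number=A,Type=String,Description=\"x\">",
    "##INFO=<ID=CSQ_CLASS,Number=A,Type=String,Description=\"x\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    paste0("chr1\t500\t.\tG\tA,T\t.\tPASS\t",
           "POP_AF=0.001,0.002;IMPACT=HIGH;CADD=33,35;SAF=3;SAR=4;",
           "VAF=0.1,0.2;GENE=TP53;CSQ_CLASS=missense")), f)
  v <- read_somatic_vcf(f, "plasma")
  expect_equal(nrow(v), 2)
  expect_equal(v$alt, c("A", "T"))
  expect_equal(unique(v$chrom), "chr1")
  expect_equal(unique(v$pos), 500)
  expect_equal(v$population_af, c(0.001, 0.002))
  expect_equal(v$fwd_support, c(3L, 3L))  # scalar INFO recycled
  expect_equal(unique(v$sample_id), "S9")
})

test_that("a record lacking CADD yields a sentinel that fails filtering", {
  f <- withr::local_tempfile(fileext = ".vcf")
  v <- make_variant()
  v$cadd_phred <- NA_real_
  write_somatic_vcf(v, f)
  back <- read_somatic_vcf(f, "tissue")
  expect_true(is.na(back$cadd_phred))
  dec <- passes_filters(back, 0.5)
  expect_false(dec$passed)
  expect_true("missing_annotation" %in% dec$failed_criteria[[1]])
})

test_that("missing mandatory INFO keys raise a schema error naming them", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=POP_AF,Number=A,Type=Float,Description=\"x\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t1\t.\tC\tT\t.\tPASS\tPOP_AF=0.1"), f)
  expect_error(read_somatic_vcf(f, "tissue"), "CADD")
})

test_that("clinical table round-trips and rejects bad vocabularies", {
  sim <- simulate_cohort(sim_params(seed = 5))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_clinical_table(sim$clinical, f)
  back <- read_clinical_table(f)
  expect_equal(nrow(back), 49)
  expect_equal(as.vector(table(back$group)[c("case", "control")]),
               c(29L, 20L))
  expect_equal(back$sample_id, sim$clinical$sample_id)
  expect_equal(back$survival_days, sim$clinical$survival_days)
  expect_equal(back$cea, sim$clinical$cea, tolerance = 1e-9)
  bad <- sim$clinical
  bad$t_stage[1] <- "T9"
  expect_error(patient_records(bad), "T9")
})

test_that("fragment profile round-trips and enforces ordering", {
  prof <- fragment_profile("S1", seq(100, 1000, 10),
                           abs(sin(seq(100, 1000, 10) / 40)) + 0.1)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_fragment_profile(prof, f)
  back <- read_fragment_profile(f, "S1")
  expect_equal(back$sizes, prof$sizes)
  expect_equal(back$concentrations, prof$concentrations,
               tolerance = 1e-9)
  expect_error(fragment_profile("S1", c(100, 90, 120), c(1, 1, 1)),
               "increasing")
  expect_error(fragment_profile("S1", c(100, 110), c(1, -1)),
               "non-negative")
})

test_that("panel BED uses 0-based half-open intervals; empty panel is a header", {
  panel <- panel_spec(
    c("TP53", "CDH1"),
    data.frame(chrom = c("chr17", "chr16"), start = c(100, 5000),
               end = c(200, 5100), gene = c("TP53", "CDH1"),
               stringsAsFactors = FALSE))
  f <- withr::local_tempfile(fileext = ".bed")
  write_panel_bed(panel, f)
  back <- read_panel_bed(f)
  expect_equal(back$intervals$start, c(5000, 100))
  expect_setequal(back$genes, c("TP53", "CDH1"))
  empty <- panel_spec(character(0),
                      data.frame(chrom = character(0), start = numeric(0),
                                 end = numeric(0), gene = character(0)))
  write_panel_bed(empty, f)
  expect_equal(readLines(f), "#chrom\tstart\tend\tgene")
})

test_that("overlapping panel intervals are merged per gene", {
  p <- panel_spec("TP53",
                  data.frame(chrom = "chr17", start = c(100, 150, 400),
                             end = c(200, 300, 500), gene = "TP53",
                             stringsAsFactors = FALSE))
  expect_equal(nrow(p$intervals), 2)
  expect_equal(p$intervals$start, c(100, 400))
  expect_equal(p$intervals$end, c(300, 500))
})
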