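write_test_vcf <- function(rows, path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=c1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    rows), path)
  path
}

test_that("DP/GQ gates are strict and applied per carrier", {
  regions <- data.frame(chrom = "c1", start = 99L, end = 200L)
  vcf <- write_test_vcf(c(
    "c1\t150\t.\tA\tT\t.\tPASS\t.\tGT:DP:GQ\t0/1:11:16\t0/0:99:99",  # keep
    "c1\t151\t.\tA\tT\t.\tPASS\t.\tGT:DP:GQ\t0/1:10:99\t0/0:99:99",  # DP at gate
    "c1\t152\t.\tA\tT\t.\tPASS\t.\tGT:DP:GQ\t0/1:99:15\t0/0:99:99",  # GQ at gate
    "c1\t153\t.\tA\tT\t.\tPASS\t.\tGT:DP:GQ\t0/1:10:10\t0/1:11:16",  # 2nd carrier passes
    "c1\t500\t.\tA\tT\t.\tPASS\t.\tGT:DP:GQ\t0/1:99:99\t0/0:99:99")) # outside region
  got <- read_region_variants(vcf, regions)
  expect_equal(got$pos, c(150L, 153L))
  expect_equal(got$carriers[1], "S1")
  expect_equal(got$carriers[2], "S2")
})

variant_key_for_test <- function(df) paste(df$chrom, df$pos, df$ref, df$alt,
                                           sep = ":")

test_that("multi-allelic records are split into per-alt variants", {
  regions <- data.frame(chrom = "c1", start = 99L, end = 200L)
  vcf <- write_test_vcf(
    "c1\t150\t.\tA\tT,G\t.\tPASS\t.\tGT:DP:GQ\t1/2:40:80\t0/0:99:99")
  got <- read_region_variants(vcf, regions)
  expect_equal(nrow(got), 2)
  expect_setequal(got$alt, c("T", "G"))
  expect_equal(got$key, variant_key_for_test(got))
})

test_that("calls with missing DP/GQ in all carriers are dropped with a note", {
  regions <- data.frame(chrom = "c1", start = 99L, end = 200L)
  vcf <- write_test_vcf(
    "c1\t150\t.\tA\tT\t.\tPASS\t.\tGT:DP:GQ\t0/1:.:.\t0/0:99:99")
  expect_message(got <- read_region_variants(vcf, regions), "missing DP/GQ")
  expect_equal(nrow(got), 0)
})

test_that("evidence attachment uses the max-AF rule and honest absence", {
  v <- data.frame(chrom = "c1", pos = c(10L, 20L, 30L), ref = "A",
                  alt = "T", key = c("c1:10:A:T", "c1:20:A:T", "c1:30:A:T"),
                  carriers = "S1", stringsAsFactors = FALSE)
  af <- data.frame(chrom = "c1", pos = 10L, ref = "A", alt = "T",
                   AF_a = 0.001, AF_b = 0.019)
  tss <- data.frame(chrom = "c1", start = 18L, end = 25L)
  got <- attach_evidence(v, af_table = af, tss_bed = tss)
  expect_equal(got$max_population_af, c(0.019, NA, NA))
  expect_equal(got$overlaps_tss, c(FALSE, TRUE, FALSE))
  expect_false(any(got$overlaps_ires))
  ## absence passes rarity downstream
  expect_true(rarity_filter(got$max_population_af[2]))
  ## keys preserved; attachment idempotent on the key columns
  expect_identical(got$key, v$key)
  again <- attach_evidence(got[, names(v)], af_table = af, tss_bed = tss)
  expect_identical(again, got)
})

test_that("nested pairing proxy matches exhaustive enumeration", {
  expect_equal(internal_mfe_proxy("AAAA"), 0L)
  expect_equal(internal_mfe_proxy("GGGAAACCC"), 3L)
  expect_equal(internal_mfe_proxy("GCGCAAAAGCGC"),
               oracle_max_pairs("GCGCAAAAGCGC"))
  set.seed(5)
  for (i in 1:20) {
    s <- random_dna(sample(4:11, 1))
    expect_equal(internal_mfe_proxy(s), oracle_max_pairs(s), info = s)
  }
  ## GU wobble counts as a pair
  expect_equal(internal_mfe_proxy("GAAAT"), 1L)
  expect_error(internal_mfe_proxy(strrep("A", 501)), "500")
})

test_that("ClinVar filtering keeps 5'UTR records and tallies buckets", {
  regions <- data.frame(chrom = "1", start = 1000L, end = 1100L)
  cds <- data.frame(chrom = "1", start = 1100L, end = 1400L)
  rec <- data.frame(
    chrom = "1",
    start = c(1050L, 1050L, 1060L, 1070L, 1080L, 5000L),
    stop = c(1050L, 1250L, 1060L, 1070L, 1080L, 5000L),
    clinical_significance = c("Uncertain significance", "Pathogenic",
                              "Likely benign", "Pathogenic",
                              "Conflicting interpretations of pathogenicity",
                              "Benign"),
    variant_type = c("single nucleotide variant", "copy number loss",
                     "single nucleotide variant", "single nucleotide variant",
                     "single nucleotide variant", "single nucleotide variant"),
    molecular_consequence = c("5_prime_UTR_variant", NA,
                              "missense_variant", "5_prime_UTR_variant",
                              "5_prime_UTR_variant", "5_prime_UTR_variant"),
    stringsAsFactors = FALSE)
  got <- filter_clinvar_utr(rec, regions, cds_regions = cds)
  ## kept: VUS, P (in-region), conflicting; removed: CNV into CDS, missense,
  ## out-of-region benign
  expect_equal(nrow(got$retained), 3)
  expect_equal(unname(got$tally["VUS"]), 1L)
  expect_equal(unname(got$tally["P/LP"]), 1L)
  expect_equal(unname(got$tally["conflicting"]), 1L)
  ## buckets partition the retained set
  expect_equal(sum(got$tally), nrow(got$retained))
})

test_that("every retained variant overlaps a region (interval oracle)", {
  s <- synth_fixture()
  res <- pipeline_fixture()
  reg <- res$regions
  for (i in seq_len(nrow(res$variants))) {
    v <- res$variants[i, ]
    hit <- any(reg$chrom == v$chrom & v$pos - 1L >= reg$start &
                 v$pos - 1L < reg$end)
    expect_true(hit, info = v$key)
  }
  ## and the retained set is a subset of the planted VCF
  expect_true(all(res$variants$key %in% s$truth_variants$key))
})
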