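test_that("analysis regions include exons and trimmed intronic flanks", {
  ## 5'UTR exons [1000,1100) and [1500,1520), CDS at 1520 (+): one internal
  ## junction, so 2 UTR exons + donor [1100,1125) + acceptor [1475,1500)
  tx <- transcript_model("TX", "G", "G", "c", "+",
                         data.frame(start = c(1000L, 1500L),
                                    end = c(1100L, 1700L)),
                         cds_start_genomic = 1520L,
                         cds_end_genomic = 1650L)
  ann <- fake_annotation(tx)
  reg <- build_analysis_regions(ann, "TX")
  expect_equal(reg$start, c(1000L, 1100L, 1475L, 1500L))
  expect_equal(reg$end, c(1100L, 1125L, 1500L, 1520L))
  expect_equal(reg$kind, c("utr_exon", "near_splice_donor",
                           "near_splice_acceptor", "utr_exon"))
  ## single-exon-contained 5'UTR: one region, no flanks
  tx1 <- transcript_model("TX1", "G", "G", "c", "+",
                          data.frame(start = 0L, end = 500L),
                          cds_start_genomic = 100L, cds_end_genomic = 400L)
  reg1 <- build_analysis_regions(fake_annotation(tx1), "TX1")
  expect_equal(nrow(reg1), 1)
  expect_equal(reg1$kind, "utr_exon")
  expect_error(build_analysis_regions(ann, "TX", flank_bp = 0),
               "configuration error")
})

test_that("no emitted region base overlaps its transcript's CDS", {
  res <- pipeline_fixture()
  ann <- res$annotation
  for (i in seq_len(nrow(res$regions))) {
    r <- res$regions[i, ]
    cds <- utr5screen:::cds_intervals(ann$transcripts[[r$transcript_id]])
    expect_equal(utr5screen:::intersect_bp(r$start, r$end,
                                           cds$start, cds$end), 0L,
                 info = paste(r$transcript_id, r$kind))
  }
  ## near-splice flanks never exceed the configured width
  fl <- res$regions[res$regions$kind != "utr_exon", ]
  expect_true(all(fl$end - fl$start <= 25))
})

test_that("region file round trip through BED6 is the identity", {
  res <- pipeline_fixture()
  path <- tempfile(fileext = ".bed")
  write_analysis_regions(res$regions, path)
  back <- read_analysis_regions(path)
  expect_equal(back[, c("chrom", "start", "end", "kind", "transcript_id",
                        "gene_symbol")],
               res$regions[, c("chrom", "start", "end", "kind",
                               "transcript_id", "gene_symbol")])
})

test_that("capture coverage arithmetic matches hand-worked intervals", {
  tx <- transcript_model("TX", "G", "G", "c", "+",
                         data.frame(start = 100L, end = 400L),
                         cds_start_genomic = 200L, cds_end_genomic = 350L)
  ann <- fake_annotation(tx)
  sel <- data.frame(gene_id = "G", gene_symbol = "G", canonical_id = "TX",
                    enriched_id = "TX", canonical_mean_tpm = 1,
                    enriched_mean_tpm = 1, has_noncanonical_enriched = FALSE)
  ## UTR [100,200), bait [150,250), pad 0 -> 50%
  cov <- capture_coverage(ann, sel, capture_design(
    "kit", data.frame(chrom = "c", start = 150L, end = 250L)))
  expect_equal(cov$per_gene$percent_captured, 50)
  expect_false(cov$per_gene$fully_captured)
  ## UTR [100,200), bait [210,260), pad 50 -> padded [160,310) -> 40 bp
  cov <- capture_coverage(ann, sel, capture_design(
    "kit", data.frame(chrom = "c", start = 210L, end = 260L),
    padding_bp = 50))
  expect_equal(cov$per_gene$captured_bp, 40L)
  expect_equal(cov$per_gene$percent_captured, 40)
  ## full bait -> 100%, counted as fully captured
  cov <- capture_coverage(ann, sel, capture_design(
    "kit", data.frame(chrom = "c", start = 0L, end = 500L)))
  expect_equal(cov$per_gene$percent_captured, 100)
  expect_true(cov$per_gene$fully_captured)
  expect_equal(cov$summary$n_fully_captured, 1L)
  expect_warning(capture_coverage(ann, sel, capture_design(
    "empty", data.frame(chrom = character(0), start = integer(0),
                        end = integer(0)))), "empty")
})

test_that("padding and added baits never decrease coverage", {
  s <- synth_fixture()
  res <- pipeline_fixture()
  baits <- read_bed(s$capture)
  strict <- capture_coverage(res$annotation, res$selection,
                             capture_design("kit", baits))
  padded <- capture_coverage(res$annotation, res$selection,
                             capture_design("kit", baits, padding_bp = 50))
  expect_true(all(padded$per_gene$percent_captured >=
                    strict$per_gene$percent_captured))
  more <- rbind(baits[, c("chrom", "start", "end")],
                data.frame(chrom = baits$chrom[1], start = 0L, end = 5000L))
  bigger <- capture_coverage(res$annotation, res$selection,
                             capture_design("kit", more))
  expect_true(all(bigger$per_gene$percent_captured >=
                    strict$per_gene$percent_captured))
})
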