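test_that("mean abundance is a plain arithmetic mean with sd carried", {
  m <- rbind(NC = c(48.38, 48.38), C = c(2.54, 2.54))
  colnames(m) <- c("s1", "s2")
  mu <- mean_abundance(m)
  expect_equal(mu$mean_tpm[mu$transcript_id == "NC"], 48.38)
  expect_equal(mu$mean_tpm[mu$transcript_id == "C"], 2.54)
  ## the non-canonical isoform outranks the canonical at these abundances,
  ## as in the published CRB1- and RIMS2-style cases (48.38 vs 2.54 TPM and
  ## 41.58 vs 12.19 TPM)
  expect_gt(48.38, 2.54)
  r <- mean_abundance(rbind(NC = c(41.58, 41.58), C = c(12.19, 12.19)))
  expect_equal(r$transcript_id[which.max(r$mean_tpm)], "NC")
  expect_error(mean_abundance(matrix(numeric(0), 0, 0)), "input error")
})

test_that("selection keeps canonical always plus planted non-canonical tops", {
  s <- synth_fixture()
  res <- pipeline_fixture()
  sel <- res$selection
  truth <- s$truth_genes
  expect_equal(nrow(sel), nrow(truth))
  ## retained-transcript count identity
  expect_equal(length(selected_transcripts(sel)),
               nrow(truth) + sum(truth$planted_enriched))
  expect_equal(sel$has_noncanonical_enriched[match(truth$gene_symbol,
                                                   sel$gene_symbol)],
               truth$planted_enriched)
  expect_true(all(sel$enriched_mean_tpm >= sel$canonical_mean_tpm))
})

test_that("ties at equal means resolve to the canonical transcript", {
  can <- transcript_model("TC", "G1", "G1", "c", "+",
                          data.frame(start = 0L, end = 300L),
                          cds_start_genomic = 100L, is_canonical = TRUE)
  non <- transcript_model("TN", "G1", "G1", "c", "+",
                          data.frame(start = 0L, end = 300L),
                          cds_start_genomic = 100L)
  ann <- fake_annotation(can, non)
  mu <- data.frame(transcript_id = c("TC", "TN"), mean_tpm = c(5, 5),
                   sd_tpm = 0)
  sel <- select_isoforms(ann, mu, "G1")
  expect_equal(sel$enriched_id, "TC")
  expect_false(sel$has_noncanonical_enriched)
})

test_that("sample-column permutation never changes the selection", {
  s <- synth_fixture()
  m <- read_expression_matrix(s$expression)
  ann <- s$annotation
  genes <- s$truth_genes$gene_symbol
  a <- select_isoforms(ann, mean_abundance(m), genes)
  b <- select_isoforms(ann, mean_abundance(m[, rev(seq_len(ncol(m)))]), genes)
  expect_identical(a, b)
})

test_that("5'UTR overlap classes follow the containment rule", {
  mk <- function(id, starts, ends, cds, canonical = FALSE)
    transcript_model(id, "G1", "G1", "c", "+",
                     data.frame(start = starts, end = ends),
                     cds_start_genomic = cds, is_canonical = canonical)
  sel_row <- function(can, enr)
    data.frame(gene_id = "G1", gene_symbol = "G1", canonical_id = can,
               enriched_id = enr, canonical_mean_tpm = 1,
               enriched_mean_tpm = 2, has_noncanonical_enriched = TRUE)
  ## distinct: UTRs [100,200) vs [500,600)
  ann <- fake_annotation(mk("A", 100L, 300L, 200L, TRUE),
                         mk("B", 500L, 700L, 600L))
  expect_equal(classify_utr_overlap(sel_row("A", "B"), ann)$class,
               "fully_distinct")
  ## containment: [100,200) vs [150,200)
  ann <- fake_annotation(mk("A", 100L, 300L, 200L, TRUE),
                         mk("B", 150L, 300L, 200L))
  got <- classify_utr_overlap(sel_row("A", "B"), ann)
  expect_equal(got$class, "fully_overlapping")
  expect_equal(got$shared_bases, 50L)
  ## partial: [100,200) vs [150,250)
  ann <- fake_annotation(mk("A", 100L, 300L, 200L, TRUE),
                         mk("B", 150L, 350L, 250L))
  got <- classify_utr_overlap(sel_row("A", "B"), ann)
  expect_equal(got$class, "partly_overlapping")
  expect_equal(got$shared_bases, 50L)
  ## symmetric in its two arguments
  swapped <- classify_utr_overlap(sel_row("B", "A"), ann)
  expect_equal(swapped$class, got$class)
  expect_equal(swapped$shared_bases, got$shared_bases)
  ## contract: canonical-only gene
  bad <- sel_row("A", "A")
  bad$has_noncanonical_enriched <- FALSE
  expect_error(classify_utr_overlap(bad, ann), "contract violation")
})

test_that("planted overlap classes are recovered from the synthetic genome", {
  s <- synth_fixture()
  res <- pipeline_fixture()
  sel <- res$selection
  truth <- s$truth_genes[s$truth_genes$planted_enriched, ]
  for (i in seq_len(nrow(truth))) {
    row <- sel[sel$gene_symbol == truth$gene_symbol[i], ]
    got <- classify_utr_overlap(row, s$annotation)
    expect_equal(got$class, truth$planted_overlap_class[i],
                 info = truth$gene_symbol[i])
  }
})
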