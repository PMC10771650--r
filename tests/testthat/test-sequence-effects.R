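test_that("uORF typing follows stop location and frame", {
  ## uATG at offset 1, no UTR stop, same frame as CDS -> in-frame extension
  ctx <- utr_context("CATGGTGACC", paste0("ATG", strrep("GCA", 5), "TAA"))
  got <- scan_uorfs(ctx)
  expect_equal(nrow(got), 1)
  expect_equal(got$start_c, -9L)
  expect_equal(got$orf_type, "inframe_cds_extension")
  ## out-of-frame, no UTR stop -> oORF overlapping the CDS
  ctx <- utr_context("CATGGTGACCC", paste0("ATG", strrep("GCA", 5), "TAA"))
  expect_equal(scan_uorfs(ctx)$orf_type, "oorf_out_of_frame_overlapping_cds")
  ## in-UTR stop -> uORF; peptide counts codons before the stop (Met incl.)
  ctx <- utr_context(paste0("CC", "ATG", strrep("GCC", 24), "TAA", "CCACC"),
                     "ATGGCATAA")
  got <- scan_uorfs(ctx)
  expect_equal(got$orf_type, "uorf_stop_in_utr")
  expect_equal(got$peptide_length_aa, 25L)
  ## N inside a scanned codon flags the record ambiguous
  ctx <- utr_context("CCATGNNNCC", "ATGTAA")
  expect_true(scan_uorfs(ctx)$ambiguous)
})

test_that("Kozak strength implements the -3 purine / +4 G rule", {
  expect_equal(kozak_strength("GCCACCATGG", 6)$strength, "strong")
  expect_equal(kozak_strength("GCCCCCATGG", 6)$strength, "moderate")
  expect_equal(kozak_strength("GCCCCCATGT", 6)$strength, "weak")
  expect_equal(kozak_strength("GCCGCCATGA", 6)$strength, "moderate")
  ## truncated context: unknown bases count as non-matching
  expect_equal(kozak_strength("ATG", 0)$strength, "weak")
  expect_true(is.na(kozak_strength("ATG", 0)$minus3_base))
})

test_that("primary Kozak window and prioritized positions are positional", {
  expect_true(kozak_alteration(-6)$in_classical_window)
  expect_true(kozak_alteration(-6)$prioritized_position)
  expect_true(kozak_alteration(-7)$in_classical_window)
  expect_false(kozak_alteration(-7)$prioritized_position)
  expect_false(kozak_alteration(-11)$in_classical_window)
})

test_that("variant diffing reports gains, losses and stop losses", {
  ## engineered gain: strong Kozak, stop 75 nt downstream -> 25-aa peptide
  g <- uaug_gain_context()
  ev <- diff_uaug_events(g$ref_ctx, g$alt_ctx, g$utr_offset)
  expect_equal(ev$events, "uaug_gain")
  expect_equal(nrow(ev$gained), 1)
  expect_equal(ev$gained$orf_type, "uorf_stop_in_utr")
  expect_equal(ev$gained$peptide_length_aa, 25L)
  expect_equal(ev$gained$kozak, "strong")
  ## no-op diff is empty; reverse application restores the reference
  expect_length(diff_uaug_events(g$ref_ctx, g$ref_ctx)$events, 0)
  back <- apply_utr_variant(g$alt_ctx, g$utr_offset, "T", "C")
  expect_identical(back$utr_seq, g$ref_ctx$utr_seq)
  ## destroying an existing uATG is a loss
  ref <- utr_context("CCATGGCCTAACC", "ATGGCATAA")
  alt <- apply_utr_variant(ref, 3L, "T", "C")
  ev <- diff_uaug_events(ref, alt, 3L)
  expect_equal(ev$events, "uaug_loss")
  expect_equal(nrow(ev$lost), 1)
  ## destroying only the stop is a stop loss, not a gain/loss
  alt2 <- apply_utr_variant(ref, 9L, "A", "C")
  ev2 <- diff_uaug_events(ref, alt2, 9L)
  expect_equal(ev2$events, "ustop_loss")
  ## a variant changing no start/stop content produces no events
  alt3 <- apply_utr_variant(ref, 0L, "C", "G")
  expect_length(diff_uaug_events(ref, alt3, 0L)$events, 0)
})

test_that("a frame-disrupting indel inside a uORF is flagged", {
  ref <- utr_context("CCATGGCCGCCTAACC", "ATGGCATAA")
  alt <- apply_utr_variant(ref, 6L, "C", "CA")  # +1 nt inside the uORF
  ev <- diff_uaug_events(ref, alt, 6L)
  expect_true("uframe_shift" %in% ev$events)
  ## same indel upstream of any uORF: no frame-shift event
  ref2 <- utr_context("CCCCCATGGCCTAACC", "ATGGCATAA")
  alt2 <- apply_utr_variant(ref2, 0L, "C", "CA")
  expect_false("uframe_shift" %in% diff_uaug_events(ref2, alt2, 0L)$events)
})

test_that("scanner agrees with the brute-force enumerator on random input", {
  set.seed(31)
  cds <- paste0("ATG", strrep("GCA", 10), "TAA")
  for (i in 1:300) {
    utr <- random_dna(sample(0:300, 1), gc = stats::runif(1, 0.3, 0.7))
    got <- scan_uorfs(utr_context(utr, cds))
    want <- oracle_scan_uorfs(utr, cds)
    expect_equal(got$start_c, want$start_c, info = utr)
    expect_equal(got$orf_type, want$orf_type, info = utr)
    expect_equal(got$stop_c, want$stop_c, info = utr)
    expect_equal(got$peptide_length_aa, want$peptide_length_aa, info = utr)
    ## peptide length identity for every in-UTR-stop uORF
    has_stop <- !is.na(got$stop_c)
    expect_equal(got$peptide_length_aa[has_stop],
                 ((got$stop_c - got$start_c)[has_stop] - 2L) %/% 3L)
  }
})

test_that("Kozak frequency matrix equals direct counting", {
  ctx <- function(utr) utr_context(utr, "ATGGCATAA")
  two <- list(ctx("CCACCACCACCA"), ctx("CCACCACCACCA"))
  m <- kozak_frequency_matrix(two)
  expect_true(all(abs(colSums(m) - 1) < 1e-9))
  expect_true(all(apply(m, 2, max) == 1))
  ## split column: A vs C at position -1
  pair <- list(ctx("CCACCACCACCA"), ctx("CCACCACCACCC"))
  m2 <- kozak_frequency_matrix(pair)
  expect_equal(unname(m2["A", "-1"]), 0.5)
  expect_equal(unname(m2["C", "-1"]), 0.5)
  ## 50 random transcripts vs an independent tally
  set.seed(99)
  utrs <- replicate(50, random_dna(sample(10:40, 1)))
  m3 <- kozak_frequency_matrix(lapply(utrs, ctx))
  for (p in -10:-1) {
    bases <- substr(utrs, nchar(utrs) + p + 1, nchar(utrs) + p + 1)
    bases <- bases[bases != ""]
    tab <- table(factor(bases, levels = c("A", "C", "G", "T")))
    expect_equal(unname(m3[, as.character(p)]),
                 unname(as.vector(tab) / sum(tab)))
  }
  expect_error(kozak_frequency_matrix(list()), "input error")
})
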