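# Independent oracles and in-code fixtures shared across the suite.

# Brute-force uORF enumerator: explicit character-vector walk over all
# start positions, naive in-frame stop search. Deliberately avoids the
# package's regex/substr machinery.
oracle_scan_uorfs <- function(utr, cds) {
  b <- strsplit(paste0(utr, cds), "")[[1]]
  ulen <- nchar(utr)
  out <- list()
  if (ulen >= 3) for (i in 1:(ulen - 2)) {
    if (!(b[i] == "A" && b[i + 1] == "T" && b[i + 2] == "G")) next
    stop_first <- NA_integer_
    j <- i
    while (j + 2 <= length(b)) {
      cod <- paste0(b[j], b[j + 1], b[j + 2])
      if (cod == "TAA" || cod == "TAG" || cod == "TGA") {
        stop_first <- j
        break
      }
      j <- j + 3
    }
    in_frame <- ((ulen - (i - 1)) %% 3) == 0
    stop_in_utr <- !is.na(stop_first) && (stop_first + 2) <= ulen
    out[[length(out) + 1]] <- data.frame(
      start_c = (i - 1) - ulen,
      orf_type = if (stop_in_utr) "uorf_stop_in_utr"
        else if (!in_frame) "oorf_out_of_frame_overlapping_cds"
        else "inframe_cds_extension",
      stop_c = if (stop_in_utr) (stop_first + 1) - ulen else NA_integer_,
      peptide_length_aa = if (stop_in_utr) (stop_first - i) %/% 3
        else NA_integer_,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(start_c = integer(0), orf_type = character(0),
                      stop_c = integer(0), peptide_length_aa = integer(0)))
  do.call(rbind, out)
}

# Exhaustive nested-pairing search (no memoization): every branch of
# "position j unpaired, or paired with some k" is explored.
oracle_max_pairs <- function(seq, min_loop = 3) {
  b <- strsplit(toupper(chartr("U", "T", seq)), "")[[1]]
  n <- length(b)
  ok <- function(x, y)
    paste0(b[x], b[y]) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  rec <- function(i, j) {
    if (j <= i) return(0L)
    best <- rec(i, j - 1)
    for (k in i:(j - 1)) {
      if (j - k > min_loop && ok(k, j)) {
        left <- if (k > i) rec(i, k - 1) else 0L
        best <- max(best, left + rec(k + 1, j - 1) + 1L)
      }
    }
    best
  }
  if (n == 0) 0L else rec(1L, n)
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Hand-written toy GTF/FASTA (independent of the generator): one plus-strand
# and one minus-strand transcript with spliced 5'UTRs on a 600 bp contig.
#  T1 (+): exons [100,200) + [300,400), CDS start 350  -> 5'UTR 150 nt
#  T2 (-): exons [300,400) + [100,200) (5'->3'), CDS start 150
#  T3 (+): exons [100,160) + [200,260), CDS start 208  -> exon1's last base
#          is c.-9, so the first intronic base maps to c.-9+1
write_toy_annotation <- function(dir = tempfile("toy")) {
  dir.create(dir, showWarnings = FALSE)
  attr1 <- 'gene_id "G%d"; transcript_id "T%d"; gene_name "G%d"; transcript_biotype "protein_coding"; tag "Ensembl_canonical";'
  line <- function(type, s, e, strand, g)
    paste("chrT", "toy", type, s, e, ".", strand, ".",
          sprintf(attr1, g, g, g), sep = "\t")
  gtf <- file.path(dir, "toy.gtf")
  writeLines(c(
    line("exon", 101, 200, "+", 1), line("exon", 301, 400, "+", 1),
    line("CDS", 351, 400, "+", 1),
    line("exon", 101, 200, "-", 2), line("exon", 301, 400, "-", 2),
    line("CDS", 101, 151, "-", 2),
    line("exon", 101, 160, "+", 3), line("exon", 201, 260, "+", 3),
    line("CDS", 209, 260, "+", 3)), gtf)
  fasta <- file.path(dir, "toy.fa")
  set.seed(424242)
  writeLines(c(">chrT", random_dna(600)), fasta)
  list(gtf = gtf, fasta = fasta)
}

load_toy_annotation <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressMessages(do.call(
        load_annotation, write_toy_annotation()))
    cache
  }
})

# An annotation object assembled directly from transcript models (no files),
# for interval-level tests that need exact control.
fake_annotation <- function(...) {
  txs <- list(...)
  names(txs) <- vapply(txs, `[[`, "", "transcript_id")
  genes <- split(names(txs), vapply(txs, `[[`, "", "gene_id"))
  structure(list(transcripts = txs, genes = genes,
                 genome = Biostrings::DNAStringSet()),
            class = "GenomeAnnotation")
}

# Session-cached synthetic cohort and pipeline run (seeded, deterministic).
synth_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressMessages(
        simulate_cohort(sim_config(seed = 7), dir = tempfile("synthfix")))
    cache
  }
})

pipeline_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      s <- synth_fixture()
      cache <<- suppressMessages(run_pipeline(
        list(gtf = s$gtf, fasta = s$fasta, expression = s$expression,
             panel = s$panel, vcf = s$vcf, af = s$af, spliceai = s$spliceai,
             te = s$te, mfe = s$mfe, tss = s$tss, ires = s$ires,
             capture = s$capture, cases = s$cases_path),
        out_dir = tempfile("pipefix")))
    }
    cache
  }
})
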