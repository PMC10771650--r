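## Sequence-level 5'UTR consequence annotation: uORF scanning, uAUG
## gain/loss on variant application, Kozak context strength, and the primary
## Kozak positional predicate. All sequences are mRNA-sense in the DNA
## alphabet (A/C/G/T/N); positions within the UTR use HGVS-style c.
## coordinates where c.-1 is the base immediately 5' of the main AUG.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Build a 5'UTR sequence context
#'
#' @param utr_seq Spliced 5'UTR sequence, 5'->3' (character).
#' @param cds_seq Downstream coding sequence starting with ATG; truncated to
#'   `max_cds` bases (999 by default, enough to type CDS-overlapping ORFs).
#' @param transcript_id Optional id carried for reporting.
#' @return Object of class `UtrContext`.
#' @export
utr_context <- function(utr_seq, cds_seq, transcript_id = NA_character_,
                        max_cds = 999L) {
  utr_seq <- toupper(utr_seq); cds_seq <- toupper(cds_seq)
  if (!startsWith(cds_seq, "ATG")) stop("cds_seq must start with ATG")
  if (grepl("[^ACGTN]", paste0(utr_seq, cds_seq)))
    stop("sequence alphabet must be A/C/G/T/N")
  cds_seq <- substr(cds_seq, 1L, max_cds)
  structure(list(utr_seq = utr_seq, cds_seq = cds_seq,
                 transcript_id = transcript_id),
            class = "UtrContext")
}

#' Build the context of a transcript from an annotation
#'
#' Splices the 5'UTR and leading CDS genomic sequence (strand-aware).
#'
#' @param ann A `GenomeAnnotation`.
#' @param transcript_id Transcript id.
#' @param max_cds CDS bases captured (default 999).
#' @return A [utr_context()].
#' @export
transcript_context <- function(ann, transcript_id, max_cds = 999L) {
  tx <- ann$transcripts[[transcript_id]]
  if (is.null(tx)) stop("unknown transcript ", transcript_id)
  utr <- five_prime_utr(tx)
  utr_seq <- paste(vapply(seq_len(nrow(utr)), function(i)
    get_sequence(ann, tx$chrom, utr$start[i], utr$end[i], tx$strand),
    character(1)), collapse = "")
  cds <- cds_intervals(tx)
  if (tx$strand == "-") cds <- cds[rev(seq_len(nrow(cds))), , drop = FALSE]
  cds_seq <- paste(vapply(seq_len(nrow(cds)), function(i)
    get_sequence(ann, tx$chrom, cds$start[i], cds$end[i], tx$strand),
    character(1)), collapse = "")
  utr_context(utr_seq, cds_seq, transcript_id, max_cds = max_cds)
}

## Offsets (0-based) of every occurrence of `pat` in `seq`.
find_all <- function(seq, pat) {
  m <- gregexpr(pat, seq, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

#' Scan a 5'UTR for upstream open reading frames
#'
#' Every ATG in the UTR yields one record. Reading continues into the CDS for
#' the stop search. Types: `uorf_stop_in_utr` when the first in-frame stop
#' codon ends within the UTR; otherwise `oorf_out_of_frame_overlapping_cds`
#' or `inframe_cds_extension` depending on the frame relative to the CDS.
#' Candidate starts whose scanned codons contain `N` are flagged `ambiguous`
#' and excluded from typing.
#'
#' @param ctx A [utr_context()].
#' @return Data frame with one row per uATG: `start_c`, `frame_vs_cds`,
#'   `stop_c` (NA unless stop in UTR), `orf_type`, `kozak`,
#'   `peptide_length_aa` (NA unless stop in UTR), `ambiguous`.
#' @export
scan_uorfs <- function(ctx) {
  utr <- ctx$utr_seq
  full <- paste0(utr, ctx$cds_seq)
  ulen <- nchar(utr)
  starts <- find_all(utr, "ATG")
  rec <- lapply(starts, function(a) {
    in_frame <- ((ulen - a) %% 3L) == 0L
    stop_first <- NA_integer_
    ambiguous <- FALSE
    i <- a
    while (i + 3L <= nchar(full)) {
      codon <- substr(full, i + 1L, i + 3L)
      if (grepl("N", codon, fixed = TRUE)) { ambiguous <- TRUE; break }
      if (codon %in% STOP_CODONS) { stop_first <- i; break }
      i <- i + 3L
    }
    stop_in_utr <- !is.na(stop_first) && (stop_first + 3L) <= ulen
    orf_type <- if (ambiguous) NA_character_
      else if (stop_in_utr) "uorf_stop_in_utr"
      else if (!in_frame) "oorf_out_of_frame_overlapping_cds"
      else "inframe_cds_extension"
    data.frame(
      start_c = a - ulen,
      frame_vs_cds = ifelse(in_frame, "in_frame", "out_of_frame"),
      stop_c = if (stop_in_utr) stop_first + 2L - ulen else NA_integer_,
      orf_type = orf_type,
      kozak = kozak_strength(full, a)$strength,
      peptide_length_aa = if (stop_in_utr) (stop_first - a) %/% 3L
                          else NA_integer_,
      ambiguous = ambiguous, stringsAsFactors = FALSE)
  })
  if (!length(rec))
    return(data.frame(start_c = integer(0), frame_vs_cds = character(0),
                      stop_c = integer(0), orf_type = character(0),
                      kozak = character(0), peptide_length_aa = integer(0),
                      ambiguous = logical(0)))
  do.call(rbind, rec)
}

#' Kozak context strength of an AUG
#'
#' Two-feature rule: strong when the base at position -3 is a purine (A/G)
#' and the base at +4 is G; moderate when exactly one of the two holds; weak
#' otherwise. Positions count the A of AUG as +1. Bases outside the available
#' sequence are recorded as unknown and count as non-matching.
#'
#' @param seq Sequence containing the AUG (character).
#' @param aug_offset 0-based offset of the A of ATG within `seq`.
#' @return List with `strength`, `minus3_base`, `plus4_base`, `aug_offset`.
#' @export
kozak_strength <- function(seq, aug_offset) {
  stopifnot(substr(seq, aug_offset + 1L, aug_offset + 3L) == "ATG")
  m3 <- if (aug_offset >= 3L) substr(seq, aug_offset - 2L, aug_offset - 2L)
        else NA_character_
  p4 <- if (aug_offset + 4L <= nchar(seq))
          substr(seq, aug_offset + 4L, aug_offset + 4L) else NA_character_
  ok3 <- !is.na(m3) && m3 %in% c("A", "G")
  ok4 <- !is.na(p4) && identical(p4, "G")
  strength <- if (ok3 && ok4) "strong" else if (ok3 || ok4) "moderate" else "weak"
  list(strength = strength, minus3_base = m3, plus4_base = p4,
       aug_offset = aug_offset)
}

#' Positional assessment of a variant against the primary Kozak window
#'
#' The classical/retinal primary Kozak context is considered touched when the
#' variant's exonic c. position lies in `[-10, -1]` relative to the main AUG;
#' positions -3, -4, -5, -6 and -9 are the prioritized subset.
#'
#' @param c_offset Exonic 5'UTR c. position (negative integer).
#' @param window Positional window (default `c(-10, -1)`).
#' @param prioritized Prioritized positions (default `c(-3,-4,-5,-6,-9)`).
#' @return List with `in_classical_window` and `prioritized_position`.
#' @export
kozak_alteration <- function(c_offset, window = c(-10L, -1L),
                             prioritized = c(-3L, -4L, -5L, -6L, -9L)) {
  inw <- !is.na(c_offset) && c_offset >= window[1] && c_offset <= window[2]
  list(in_classical_window = inw,
       prioritized_position = inw && c_offset %in% prioritized)
}

#' Apply a simple variant to a UTR context
#'
#' SNV or left-normalized indel expressed in UTR coordinates.
#'
#' @param ctx A [utr_context()].
#' @param utr_offset 0-based offset of the first `ref` base within the UTR.
#' @param ref,alt Reference / alternate alleles (UTR-sense strings).
#' @return A new [utr_context()].
#' @export
apply_utr_variant <- function(ctx, utr_offset, ref, alt) {
  utr <- ctx$utr_seq
  if (utr_offset < 0 || utr_offset + nchar(ref) > nchar(utr))
    stop("contract violation: variant outside the 5'UTR span")
  if (substr(utr, utr_offset + 1L, utr_offset + nchar(ref)) != toupper(ref))
    stop("reference allele mismatch at UTR offset ", utr_offset)
  new_utr <- paste0(substr(utr, 1L, utr_offset), toupper(alt),
                    substr(utr, utr_offset + nchar(ref) + 1L, nchar(utr)))
  utr_context(new_utr, ctx$cds_seq, ctx$transcript_id, max_cds = nchar(ctx$cds_seq))
}

#' Diff uAUG content between reference and alternate contexts
#'
#' Rescans both contexts and reports perturbation events: `uaug_gain` (uAUG
#' present only in the alternate), `uaug_loss` (only in the reference),
#' `ustop_loss` (a surviving uORF lost its in-UTR stop without replacement),
#' and `uframe_shift` (an indel inside an existing uORF changing its length
#' modulo 3). Records are matched on their c. position relative to the main
#' AUG, which is invariant to upstream indels.
#'
#' @param ref_ctx,alt_ctx Reference and variant-applied contexts.
#' @param utr_offset Optional 0-based UTR offset of the variant, used to
#'   restrict `uframe_shift` to indels falling inside an existing uORF.
#' @return List with `events` (character vector), `gained` and `lost` uORF
#'   record data frames, and `ref_uorfs`/`alt_uorfs` scans.
#' @export
diff_uaug_events <- function(ref_ctx, alt_ctx, utr_offset = NULL) {
  ref <- scan_uorfs(ref_ctx)
  alt <- scan_uorfs(alt_ctx)
  gained <- alt[!(alt$start_c %in% ref$start_c), , drop = FALSE]
  lost <- ref[!(ref$start_c %in% alt$start_c), , drop = FALSE]
  events <- character(0)
  if (nrow(gained)) events <- c(events, "uaug_gain")
  if (nrow(lost)) events <- c(events, "uaug_loss")
  shared <- intersect(ref$start_c, alt$start_c)
  for (s in shared) {
    r <- ref[ref$start_c == s, ][1, ]
    a <- alt[alt$start_c == s, ][1, ]
    if (identical(r$orf_type, "uorf_stop_in_utr") &&
        !identical(a$orf_type, "uorf_stop_in_utr") && !isTRUE(a$ambiguous))
      events <- c(events, "ustop_loss")
  }
  indel_shift <- (nchar(ref_ctx$utr_seq) - nchar(alt_ctx$utr_seq)) %% 3L != 0L
  if (indel_shift && nrow(ref) > 0L) {
    ulen <- nchar(ref_ctx$utr_seq)
    in_uorf <- if (is.null(utr_offset)) TRUE else any(vapply(
      seq_len(nrow(ref)), function(i) {
        a0 <- ref$start_c[i] + ulen
        e0 <- if (!is.na(ref$stop_c[i])) ref$stop_c[i] + ulen else ulen - 1L
        utr_offset >= a0 && utr_offset <= e0
      }, logical(1)))
    if (in_uorf) events <- c(events, "uframe_shift")
  }
  list(events = unique(events), gained = gained, lost = lost,
       ref_uorfs = ref, alt_uorfs = alt)
}

#' Nucleotide frequency matrix over the primary Kozak window
#'
#' Column-wise A/C/G/T frequencies over positions -10..+4 around the main AUG
#' for a set of transcript contexts. Transcripts with short 5'UTRs contribute
#' only to the columns they cover; each available column sums to 1.
#'
#' @param contexts List of [utr_context()] objects.
#' @return 4 x 15 numeric matrix, rows A/C/G/T, columns named -10..-1,
#'   +1..+4, with `NaN` columns where no transcript contributed.
#' @export
kozak_frequency_matrix <- function(contexts) {
  if (!length(contexts)) stop("input error: empty transcript set")
  positions <- c(-10:-1, 1:4)
  counts <- matrix(0L, nrow = 4, ncol = length(positions),
                   dimnames = list(c("A", "C", "G", "T"),
                                   ifelse(positions > 0,
                                          paste0("+", positions), positions)))
  for (ctx in contexts) {
    utr <- ctx$utr_seq
    full <- paste0(utr, ctx$cds_seq)
    ulen <- nchar(utr)
    for (j in seq_along(positions)) {
      p <- positions[j]
      off <- if (p < 0) ulen + p else ulen + p - 1L  # 0-based in `full`
      if (off < 0 || off >= nchar(full)) next
      b <- substr(full, off + 1L, off + 1L)
      if (b %in% rownames(counts)) counts[b, j] <- counts[b, j] + 1L
    }
  }
  sweep(counts, 2, colSums(counts), "/")
}
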