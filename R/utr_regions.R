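## The "5'UTR analysis file": every 5'UTR exon of the selected transcripts
## plus 25 bp intronic near-splice flanks at internal 5'UTR splice junctions,
## sorted, BED-serializable; and the exome-capture audit over those 5'UTRs.

#' Build sorted 5'UTR analysis regions
#'
#' For each selected transcript, emits its 5'UTR exons (`utr_exon`) and, for
#' every splice junction internal to the 5'UTR, a donor-side and an
#' acceptor-side intronic flank of `flank_bp` bases (`near_splice_donor`,
#' `near_splice_acceptor`). No flank is emitted upstream of the transcription
#' start (the promoter side is excluded), and any flank base falling inside
#' the transcript's own CDS is trimmed away.
#'
#' @param ann A `GenomeAnnotation`.
#' @param transcript_ids Transcripts to process (e.g. from
#'   [selected_transcripts()]).
#' @param flank_bp Intronic flank width in bases (default 25).
#' @return Data frame sorted by `chrom` then `start` with columns `chrom`,
#'   `start`, `end` (0-based half-open), `kind`, `transcript_id`,
#'   `gene_symbol`, `strand`.
#' @export
build_analysis_regions <- function(ann, transcript_ids, flank_bp = 25L) {
  if (!is.numeric(flank_bp) || flank_bp <= 0)
    stop("configuration error: flank_bp must be positive")
  flank_bp <- as.integer(flank_bp)
  rows <- list()
  add <- function(chrom, start, end, kind, tx) {
    if (end <= start) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chrom, start = start, end = end, kind = kind,
      transcript_id = tx$transcript_id, gene_symbol = tx$gene_symbol,
      strand = tx$strand, stringsAsFactors = FALSE)
  }
  for (id in transcript_ids) {
    tx <- ann$transcripts[[id]]
    if (is.null(tx)) stop("unknown transcript ", id)
    utr <- five_prime_utr(tx)
    n <- nrow(utr)
    if (n == 0L) next
    cds_iv <- cds_intervals(tx)
    trim <- function(s, e) {
      ir <- IRanges::setdiff(iv_to_iranges(s, e),
                             iv_to_iranges(cds_iv$start, cds_iv$end))
      iranges_to_iv(ir)
    }
    for (i in seq_len(n)) {
      add(tx$chrom, utr$start[i], utr$end[i], "utr_exon", tx)
      ## a junction follows UTR piece i when the piece ends at its exon's
      ## 3' boundary and another exon follows in transcript order
      ex <- tx$exons
      if (tx$strand == "+") {
        host <- which(ex$start <= utr$start[i] & ex$end >= utr$end[i])[1]
        at_boundary <- utr$end[i] == ex$end[host] && host < nrow(ex)
        if (at_boundary) {
          don <- trim(ex$end[host], ex$end[host] + flank_bp)
          acc <- trim(ex$start[host + 1L] - flank_bp, ex$start[host + 1L])
          for (j in seq_len(nrow(don)))
            add(tx$chrom, don$start[j], don$end[j], "near_splice_donor", tx)
          for (j in seq_len(nrow(acc)))
            add(tx$chrom, acc$start[j], acc$end[j], "near_splice_acceptor", tx)
        }
      } else {
        host <- which(ex$start <= utr$start[i] & ex$end >= utr$end[i])[1]
        at_boundary <- utr$start[i] == ex$start[host] && host < nrow(ex)
        if (at_boundary) {
          don <- trim(ex$start[host] - flank_bp, ex$start[host])
          acc <- trim(ex$end[host + 1L], ex$end[host + 1L] + flank_bp)
          for (j in seq_len(nrow(don)))
            add(tx$chrom, don$start[j], don$end[j], "near_splice_donor", tx)
          for (j in seq_len(nrow(acc)))
            add(tx$chrom, acc$start[j], acc$end[j], "near_splice_acceptor", tx)
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), kind = character(0),
                      transcript_id = character(0), gene_symbol = character(0),
                      strand = character(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start, out$end), ]
  rownames(out) <- NULL
  out
}

## CDS genomic intervals of a transcript (0-based half-open).
cds_intervals <- function(tx) {
  if (!is_coding(tx)) return(data.frame(start = integer(0), end = integer(0)))
  lo <- min(tx$cds_start_genomic, tx$cds_end_genomic, na.rm = TRUE)
  hi <- max(tx$cds_start_genomic, tx$cds_end_genomic, na.rm = TRUE)
  if (is.na(tx$cds_end_genomic)) { lo <- tx$cds_start_genomic; hi <- lo }
  ir <- IRanges::intersect(iv_to_iranges(tx$exons$start, tx$exons$end),
                           IRanges::IRanges(lo + 1L, hi + 1L))
  iranges_to_iv(ir)
}

#' Write / read the analysis-region BED6 file
#'
#' BED name field is `gene|transcript|kind`; round trip through
#' [read_analysis_regions()] restores the in-memory representation.
#'
#' @param regions From [build_analysis_regions()].
#' @param path BED path.
#' @return `path` (write) or the regions data frame (read).
#' @export
write_analysis_regions <- function(regions, path) {
  df <- regions
  df$name <- paste(df$gene_symbol, df$transcript_id, df$kind, sep = "|")
  write_bed6(df[, c("chrom", "start", "end", "name", "strand")], path)
}

#' @rdname write_analysis_regions
#' @export
read_analysis_regions <- function(path) {
  bed <- read_bed(path)
  parts <- strsplit(bed$name, "|", fixed = TRUE)
  out <- data.frame(chrom = bed$chrom, start = bed$start, end = bed$end,
                    kind = vapply(parts, `[[`, "", 3L),
                    transcript_id = vapply(parts, `[[`, "", 2L),
                    gene_symbol = vapply(parts, `[[`, "", 1L),
                    strand = if ("strand" %in% names(bed)) bed$strand else "*",
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$end), ]
  rownames(out) <- NULL
  out
}

#' Define a capture design
#'
#' @param name Design label.
#' @param intervals `data.frame(chrom, start, end)` (0-based half-open), e.g.
#'   from [read_bed()].
#' @param padding_bp Symmetric padding applied to every interval (0 = strict).
#' @return Object of class `CaptureDesign`.
#' @export
capture_design <- function(name, intervals, padding_bp = 0L) {
  stopifnot(padding_bp >= 0)
  structure(list(name = name, intervals = intervals,
                 padding_bp = as.integer(padding_bp)),
            class = "CaptureDesign")
}

#' Audit exome-capture coverage of gene-level 5'UTRs
#'
#' The gene-level 5'UTR is the genomic union of the selected transcripts'
#' 5'UTR exons (near-splice flanks are excluded from the denominator). The
#' captured fraction is the intersection with the design's (padded) baits.
#'
#' @param ann A `GenomeAnnotation`.
#' @param selection Output of [select_isoforms()].
#' @param design A [capture_design()].
#' @return List of class `CoverageReport`: `per_gene` data frame
#'   (`gene_symbol`, `utr_length_bp`, `captured_bp`, `percent_captured`,
#'   `fully_captured`) and `summary` (`design`, `padding_bp`, `mean_percent`,
#'   `n_fully_captured`, `n_genes`).
#' @export
capture_coverage <- function(ann, selection, design) {
  if (nrow(design$intervals) == 0L)
    warning("empty capture design: reporting zero coverage")
  pad <- design$padding_bp
  baits <- design$intervals
  per_gene <- lapply(seq_len(nrow(selection)), function(i) {
    txids <- unique(c(selection$canonical_id[i], selection$enriched_id[i]))
    ivs <- do.call(rbind, lapply(txids, function(id) {
      tx <- ann$transcripts[[id]]
      u <- five_prime_utr(tx)
      if (nrow(u)) cbind(chrom = tx$chrom, u) else NULL
    }))
    utr_len <- 0L; cap <- 0L
    if (!is.null(ivs)) {
      for (ch in unique(ivs$chrom)) {
        a <- ivs[ivs$chrom == ch, ]
        red <- IRanges::reduce(iv_to_iranges(a$start, a$end))
        utr_len <- utr_len + sum(BiocGenerics::width(red))
        b <- baits[baits$chrom == ch, , drop = FALSE]
        if (nrow(b)) {
          bir <- IRanges::reduce(iv_to_iranges(pmax(b$start - pad, 0L),
                                               b$end + pad))
          cap <- cap + sum(BiocGenerics::width(IRanges::intersect(red, bir)))
        }
      }
    }
    pct <- if (utr_len > 0) 100 * cap / utr_len else NA_real_
    data.frame(gene_symbol = selection$gene_symbol[i],
               utr_length_bp = utr_len, captured_bp = cap,
               percent_captured = pct,
               fully_captured = isTRUE(pct == 100),
               stringsAsFactors = FALSE)
  })
  per_gene <- do.call(rbind, per_gene)
  structure(list(
    per_gene = per_gene,
    summary = data.frame(
      design = design$name, padding_bp = pad,
      mean_percent = mean(per_gene$percent_captured, na.rm = TRUE),
      n_fully_captured = sum(per_gene$fully_captured),
      n_genes = nrow(per_gene), stringsAsFactors = FALSE)
  ), class = "CoverageReport")
}

#' @export
print.CoverageReport <- function(x, ...) {
  s <- x$summary
  cat(sprintf("CoverageReport %s (pad %d bp): mean %.1f%% captured, %d/%d genes fully captured\n",
              s$design, s$padding_bp, s$mean_percent, s$n_fully_captured,
              s$n_genes))
  invisible(x)
}
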