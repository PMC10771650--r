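## Transcript/genome data model. All internal coordinates are 0-based
## half-open; GTF/VCF values (1-based inclusive) are converted at the I/O
## boundary. Exons are stored 5'->3' along the transcript strand.

#' Construct a transcript model
#'
#' Strand-aware exon/CDS structure of one protein-coding transcript, the
#' source of 5'UTR intervals and genomic-to-c. coordinate mapping.
#'
#' @param transcript_id,gene_id,gene_symbol Identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons `data.frame(start, end)` in 0-based half-open coordinates,
#'   ordered 5'->3' along the strand (ascending start on `+`, descending
#'   on `-`). Reordered if given otherwise.
#' @param cds_start_genomic 0-based genomic position of the first base of the
#'   canonical AUG (the A; on `-` this is the genomically rightmost base of
#'   the codon). `NA` for non-coding transcripts.
#' @param cds_end_genomic 0-based position of the last CDS base (optional).
#' @param biotype Transcript biotype string.
#' @param is_canonical,is_mane Canonicity flags.
#' @return Object of class `TranscriptModel`.
#' @export
transcript_model <- function(transcript_id, gene_id, gene_symbol, chrom, strand,
                             exons, cds_start_genomic = NA_integer_,
                             cds_end_genomic = NA_integer_,
                             biotype = "protein_coding",
                             is_canonical = FALSE, is_mane = FALSE) {
  stopifnot(strand %in% c("+", "-"), nrow(exons) >= 1L,
            all(exons$start < exons$end), all(exons$start >= 0L))
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  if (any(utils::head(exons$end, -1) > utils::tail(exons$start, -1)))
    stop("overlapping exons in transcript ", transcript_id)
  if (strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  rownames(exons) <- NULL
  if (!is.na(cds_start_genomic)) {
    inside <- any(cds_start_genomic >= exons$start & cds_start_genomic < exons$end)
    if (!inside)
      stop("structural annotation error: CDS start of ", transcript_id,
           " falls outside its exons")
  }
  structure(list(
    transcript_id = transcript_id, gene_id = gene_id,
    gene_symbol = gene_symbol, chrom = chrom, strand = strand,
    exons = exons,
    cds_start_genomic = as.integer(cds_start_genomic),
    cds_end_genomic = as.integer(cds_end_genomic),
    biotype = biotype, is_canonical = isTRUE(is_canonical),
    is_mane = isTRUE(is_mane)
  ), class = "TranscriptModel")
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cat(sprintf("TranscriptModel %s (%s/%s) %s%s, %d exon(s), CDS start %s\n",
              x$transcript_id, x$gene_id, x$gene_symbol, x$chrom, x$strand,
              nrow(x$exons),
              ifelse(is.na(x$cds_start_genomic), "none", x$cds_start_genomic)))
  invisible(x)
}

is_coding <- function(tx) !is.na(tx$cds_start_genomic)

#' Load a genome annotation from GTF and FASTA
#'
#' Parses an Ensembl-dialect GTF (via rtracklayer) together with the genome
#' FASTA into a `GenomeAnnotation`: protein-coding transcripts with exon/CDS
#' structure in the internal 0-based half-open convention, plus a sequence
#' accessor. Non-coding transcripts are dropped with a message reporting the
#' count. A transcript is flagged canonical when its GTF `tag` attribute
#' carries either `Ensembl_canonical` or `MANE_Select` (which tag fired is
#' recorded on the model via `is_mane`).
#'
#' @param gtf_path Path to a GTF file (1-based inclusive coordinates).
#' @param fasta_path Path to the genome FASTA.
#' @return Object of class `GenomeAnnotation` with elements `transcripts`
#'   (named list of [transcript_model()] objects), `genes` (gene_id ->
#'   transcript ids), and `genome` (a `DNAStringSet`).
#' @export
load_annotation <- function(gtf_path, fasta_path) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  md <- S4Vectors::mcols(gr)
  is_tx_row <- md$type %in% c("exon", "CDS")
  gr <- gr[is_tx_row]
  md <- S4Vectors::mcols(gr)
  ids <- unique(md$transcript_id)
  ids <- ids[!is.na(ids)]
  txs <- list()
  n_noncoding <- 0L
  for (id in ids) {
    sel <- which(md$transcript_id == id)
    sub <- gr[sel]
    smd <- S4Vectors::mcols(sub)
    ex <- sub[smd$type == "exon"]
    cds <- sub[smd$type == "CDS"]
    if (length(ex) == 0L)
      stop("structural annotation error: transcript ", id, " has no exon")
    strand <- as.character(BiocGenerics::strand(ex))[1]
    chrom <- as.character(GenomeInfoDb::seqnames(ex))[1]
    if (!chrom %in% names(genome))
      stop("lookup error: chromosome ", chrom, " absent from FASTA")
    biotype <- smd$transcript_biotype[1]
    if (is.null(biotype) || is.na(biotype)) biotype <- "protein_coding"
    if (length(cds) == 0L || !identical(biotype, "protein_coding")) {
      n_noncoding <- n_noncoding + 1L
      next
    }
    cds_start <- if (strand == "+") min(BiocGenerics::start(cds)) - 1L
                 else max(BiocGenerics::end(cds)) - 1L
    cds_end <- if (strand == "+") max(BiocGenerics::end(cds)) - 1L
               else min(BiocGenerics::start(cds)) - 1L
    tags <- unlist(strsplit(as.character(stats::na.omit(unique(smd$tag))), ","))
    is_mane <- any(grepl("MANE_Select", tags))
    is_canon <- any(grepl("Ensembl_canonical", tags)) || is_mane
    txs[[id]] <- transcript_model(
      transcript_id = id,
      gene_id = smd$gene_id[1],
      gene_symbol = if (!is.null(smd$gene_name)) smd$gene_name[1] else smd$gene_id[1],
      chrom = chrom, strand = strand,
      exons = data.frame(start = BiocGenerics::start(ex) - 1L,
                         end = BiocGenerics::end(ex)),
      cds_start_genomic = cds_start, cds_end_genomic = cds_end,
      biotype = biotype, is_canonical = is_canon, is_mane = is_mane)
  }
  if (n_noncoding > 0L)
    message("dropped ", n_noncoding, " non-coding transcript(s) at load")
  genes <- split(names(txs), vapply(txs, `[[`, "", "gene_id"))
  structure(list(transcripts = txs, genes = genes, genome = genome),
            class = "GenomeAnnotation")
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat(sprintf("GenomeAnnotation: %d transcript(s) in %d gene(s), %d contig(s)\n",
              length(x$transcripts), length(x$genes), length(x$genome)))
  invisible(x)
}

#' Fetch genomic sequence for an interval
#'
#' Returns the sequence of a 0-based half-open interval, reverse-complemented
#' when `strand == "-"`.
#'
#' @param ann A `GenomeAnnotation`.
#' @param chrom,start,end Interval (0-based half-open).
#' @param strand `"+"` or `"-"`.
#' @return Character scalar (DNA alphabet).
#' @export
get_sequence <- function(ann, chrom, start, end, strand = "+") {
  if (!chrom %in% names(ann$genome))
    stop("lookup error: unknown chromosome ", chrom)
  len <- Biostrings::width(ann$genome[chrom])
  if (start < 0 || end > len) stop("lookup error: interval outside ", chrom)
  s <- Biostrings::subseq(ann$genome[[chrom]], start + 1L, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' 5'UTR exonic intervals of a transcript
#'
#' The exonic intervals strictly 5' of the canonical AUG, in 5'->3' order
#' along the transcript. Empty when the annotated transcript start coincides
#' with the CDS start.
#'
#' @param tx A `TranscriptModel` (protein-coding).
#' @return `data.frame(start, end)`, 0-based half-open, 5'->3' order.
#' @export
five_prime_utr <- function(tx) {
  if (!is_coding(tx))
    stop("unsupported biotype: ", tx$transcript_id, " has no CDS")
  out <- list()
  for (i in seq_len(nrow(tx$exons))) {
    s <- tx$exons$start[i]; e <- tx$exons$end[i]
    if (tx$strand == "+") {
      if (e <= tx$cds_start_genomic) {
        out[[length(out) + 1L]] <- c(s, e)
      } else if (s < tx$cds_start_genomic) {
        out[[length(out) + 1L]] <- c(s, tx$cds_start_genomic)
        break
      } else break
    } else {
      if (s > tx$cds_start_genomic) {
        out[[length(out) + 1L]] <- c(s, e)
      } else if (e > tx$cds_start_genomic + 1L) {
        out[[length(out) + 1L]] <- c(tx$cds_start_genomic + 1L, e)
        break
      } else break
    }
  }
  if (!length(out)) return(data.frame(start = integer(0), end = integer(0)))
  do.call(rbind.data.frame,
          lapply(out, function(v) data.frame(start = v[1], end = v[2])))
}

#' @describeIn five_prime_utr Total 5'UTR length in bases.
#' @export
five_prime_utr_length <- function(tx) {
  u <- five_prime_utr(tx)
  sum(u$end - u$start)
}

## Genomic coordinates of all exonic bases, 5'->3' (transcript order).
exonic_positions <- function(tx) {
  unlist(lapply(seq_len(nrow(tx$exons)), function(i) {
    p <- seq.int(tx$exons$start[i], tx$exons$end[i] - 1L)
    if (tx$strand == "-") rev(p) else p
  }), use.names = FALSE)
}

#' Map a genomic position to transcript (HGVS c.) coordinates
#'
#' 5'UTR exonic bases map to `c.-N` with `c.-1` immediately 5' of the AUG;
#' CDS bases map to `c.N` starting at 1; intronic bases inside a 5'UTR intron
#' map to nearest-exon-edge notation (`c.-N+k` from the donor side, `c.-N-k`
#' from the acceptor side; exact midpoints break toward the donor).
#'
#' @param tx A `TranscriptModel`.
#' @param genomic_pos 0-based genomic position.
#' @return List with `kind` (`"utr5"`, `"cds"` or `"utr5_intronic"`),
#'   `c_offset` (the signed c. position of the base, or of the anchoring exon
#'   edge for intronic positions) and `intron_offset` (signed `+k`/`-k`, 0 for
#'   exonic).
#' @export
map_genomic_to_c <- function(tx, genomic_pos) {
  if (!is_coding(tx)) stop("unsupported biotype: non-coding transcript")
  pos5to3 <- exonic_positions(tx)
  cds_index <- match(tx$cds_start_genomic, pos5to3)
  idx <- match(genomic_pos, pos5to3)
  if (!is.na(idx)) {
    if (idx < cds_index)
      return(list(kind = "utr5", c_offset = idx - cds_index, intron_offset = 0L))
    return(list(kind = "cds", c_offset = idx - cds_index + 1L, intron_offset = 0L))
  }
  ## intronic: find the flanking exon pair (transcript order)
  n <- nrow(tx$exons)
  for (i in seq_len(n - 1L)) {
    up <- tx$exons[i, ]; dn <- tx$exons[i + 1L, ]
    if (tx$strand == "+") {
      inside <- genomic_pos >= up$end && genomic_pos < dn$start
      d_donor <- genomic_pos - up$end + 1L
      d_accept <- dn$start - genomic_pos
      donor_base <- up$end - 1L; accept_base <- dn$start
    } else {
      inside <- genomic_pos < up$start && genomic_pos >= dn$end
      d_donor <- up$start - genomic_pos
      d_accept <- genomic_pos - dn$end + 1L
      donor_base <- up$start; accept_base <- dn$end - 1L
    }
    if (!inside) next
    ## only introns fully 5' of the CDS start are 5'UTR introns
    donor_c <- map_genomic_to_c(tx, donor_base)
    accept_c <- map_genomic_to_c(tx, accept_base)
    if (donor_c$kind != "utr5")
      stop("out-of-range: position not in a 5'UTR intron of ", tx$transcript_id)
    if (d_donor <= d_accept) {
      return(list(kind = "utr5_intronic", c_offset = donor_c$c_offset,
                  intron_offset = d_donor))
    }
    return(list(kind = "utr5_intronic", c_offset = accept_c$c_offset,
                intron_offset = -d_accept))
  }
  stop("out-of-range: position ", genomic_pos, " not mappable on ",
       tx$transcript_id)
}

#' Invert a c.-position record to the genomic coordinate
#'
#' Exact inverse of [map_genomic_to_c()].
#'
#' @param tx A `TranscriptModel`.
#' @param kind,c_offset,intron_offset As returned by [map_genomic_to_c()].
#' @return 0-based genomic position.
#' @export
map_c_to_genomic <- function(tx, kind, c_offset, intron_offset = 0L) {
  pos5to3 <- exonic_positions(tx)
  cds_index <- match(tx$cds_start_genomic, pos5to3)
  anchor <- if (c_offset < 0) pos5to3[cds_index + c_offset]
            else pos5to3[cds_index + c_offset - 1L]
  if (kind %in% c("utr5", "cds")) return(anchor)
  stopifnot(kind == "utr5_intronic", intron_offset != 0L)
  step <- if (tx$strand == "+") 1L else -1L
  anchor + step * intron_offset
}

#' Format a c.-position record as an HGVS-style string
#'
#' @param cpos A record from [map_genomic_to_c()].
#' @return Character like `"c.-123"`, `"c.-9+1"` or `"c.15"`.
#' @export
format_c_position <- function(cpos) {
  base <- paste0("c.", cpos$c_offset)
  if (cpos$kind == "utr5_intronic")
    base <- paste0(base, ifelse(cpos$intron_offset > 0, "+", ""),
                   cpos$intron_offset)
  base
}

#' Write intervals as a BED6 file
#'
#' @param df Data frame with `chrom`, `start`, `end` (0-based half-open) and
#'   optionally `name`, `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(df, path) {
  gr <- GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start + 1L, df$end),
    strand = if ("strand" %in% names(df)) df$strand else "*")
  if ("name" %in% names(df)) S4Vectors::mcols(gr)$name <- df$name
  S4Vectors::mcols(gr)$score <- if ("score" %in% names(df)) df$score else 0
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a BED file into 0-based half-open intervals
#'
#' @param path BED3/BED6 path.
#' @return Data frame with `chrom`, `start`, `end`, and `name`/`strand` when
#'   present.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                    start = BiocGenerics::start(gr) - 1L,
                    end = BiocGenerics::end(gr),
                    stringsAsFactors = FALSE)
  md <- S4Vectors::mcols(gr)
  if (!is.null(md$name)) out$name <- md$name
  st <- as.character(BiocGenerics::strand(gr))
  if (any(st != "*")) out$strand <- st
  out
}
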