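## Per-gene isoform selection from a transcript-level TPM matrix: always keep
## the canonical isoform; additionally keep the top-mean protein-coding
## isoform when it is non-canonical ("tissue-enriched" non-canonical isoform).

#' Read a transcript-level TPM matrix from TSV
#'
#' First column = transcript id, remaining columns = samples.
#'
#' @param path TSV path with a header row.
#' @return Numeric matrix, rownames = transcript ids.
#' @export
read_expression_matrix <- function(path) {
  df <- read_tsv_table(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("input error: negative TPM values")
  m
}

#' Per-transcript mean (and sd) abundance
#'
#' Plain arithmetic mean of TPM across all samples, with the standard
#' deviation carried for reporting. No filtering or transformation is
#' applied.
#'
#' @param m Numeric matrix (transcripts x samples) or the path of a TSV
#'   readable by [read_expression_matrix()].
#' @return `data.frame(transcript_id, mean_tpm, sd_tpm)`.
#' @export
mean_abundance <- function(m) {
  if (is.character(m)) m <- read_expression_matrix(m)
  if (!is.matrix(m) || ncol(m) < 1L || nrow(m) < 1L)
    stop("input error: empty expression matrix")
  data.frame(transcript_id = rownames(m),
             mean_tpm = rowMeans(m),
             sd_tpm = apply(m, 1, stats::sd),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select canonical plus enriched non-canonical isoform per gene
#'
#' For every gene in `gene_list` the canonical protein-coding transcript is
#' always retained; when the transcript with the highest mean TPM among the
#' gene's protein-coding isoforms is non-canonical, it is retained as the
#' tissue-enriched isoform, so at most 2 transcripts survive per gene. Ties at
#' equal means resolve to the canonical transcript (and among non-canonical
#' ties to the lexicographically smallest id) for determinism.
#'
#' @param ann A `GenomeAnnotation`.
#' @param means Data frame from [mean_abundance()]. Transcript ids absent
#'   from the annotation are skipped with a message; annotated transcripts
#'   missing from `means` count as expression 0.
#' @param gene_list Character vector of gene symbols (or ids).
#' @return `data.frame(gene_id, gene_symbol, canonical_id, enriched_id,
#'   canonical_mean_tpm, enriched_mean_tpm, has_noncanonical_enriched)`.
#' @export
select_isoforms <- function(ann, means, gene_list) {
  unknown <- setdiff(means$transcript_id, names(ann$transcripts))
  if (length(unknown))
    message("skipped ", length(unknown),
            " expression row(s) not resolvable against the annotation")
  mu <- stats::setNames(means$mean_tpm, means$transcript_id)
  sym_of <- vapply(ann$transcripts, `[[`, "", "gene_symbol")
  gid_of <- vapply(ann$transcripts, `[[`, "", "gene_id")
  out <- list()
  for (g in gene_list) {
    txids <- names(ann$transcripts)[sym_of == g | gid_of == g]
    if (!length(txids)) stop("configuration error: gene ", g, " not annotated")
    txs <- ann$transcripts[txids]
    coding <- txs[vapply(txs, function(t)
      identical(t$biotype, "protein_coding"), logical(1))]
    canon <- coding[vapply(coding, `[[`, TRUE, "is_canonical")]
    if (!length(canon))
      stop("configuration error: no canonical protein-coding transcript for ", g)
    canon_id <- names(canon)[order(names(canon))][1]
    tpm <- vapply(names(coding), function(id)
      if (!is.na(mu[id])) unname(mu[id]) else 0, numeric(1))
    top <- max(tpm)
    top_ids <- names(tpm)[tpm == top]
    enriched_id <- if (canon_id %in% top_ids) canon_id else sort(top_ids)[1]
    gene_id <- txs[[1]]$gene_id
    out[[g]] <- data.frame(
      gene_id = gene_id, gene_symbol = g,
      canonical_id = canon_id, enriched_id = enriched_id,
      canonical_mean_tpm = unname(tpm[canon_id]),
      enriched_mean_tpm = unname(tpm[enriched_id]),
      has_noncanonical_enriched = enriched_id != canon_id,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Transcripts retained by a selection
#'
#' @param selection Output of [select_isoforms()].
#' @return Character vector of transcript ids (canonical first per gene).
#' @export
selected_transcripts <- function(selection) {
  unique(unlist(Map(function(c, e) unique(c(c, e)),
                    selection$canonical_id, selection$enriched_id),
                use.names = FALSE))
}

#' Classify the 5'UTR overlap between canonical and enriched isoforms
#'
#' Genomic intersection of the two 5'UTR interval sets: `fully_distinct` when
#' no base is shared, `fully_overlapping` when the shorter 5'UTR is contained
#' in the longer one (shared bases equal the shorter length), otherwise
#' `partly_overlapping`.
#'
#' @param sel One row of [select_isoforms()] output with
#'   `has_noncanonical_enriched == TRUE`.
#' @param ann A `GenomeAnnotation`.
#' @return `data.frame(gene_id, class, shared_bases, len_canonical,
#'   len_noncanonical)`.
#' @export
classify_utr_overlap <- function(sel, ann) {
  if (!isTRUE(sel$has_noncanonical_enriched))
    stop("contract violation: gene has no non-canonical enriched isoform")
  uc <- five_prime_utr(ann$transcripts[[sel$canonical_id]])
  un <- five_prime_utr(ann$transcripts[[sel$enriched_id]])
  len_c <- sum(uc$end - uc$start)
  len_n <- sum(un$end - un$start)
  shared <- intersect_bp(uc$start, uc$end, un$start, un$end)
  cls <- if (shared == 0L) "fully_distinct"
         else if (shared == min(len_c, len_n)) "fully_overlapping"
         else "partly_overlapping"
  data.frame(gene_id = sel$gene_id, class = cls, shared_bases = shared,
             len_canonical = len_c, len_noncanonical = len_n,
             stringsAsFactors = FALSE)
}
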