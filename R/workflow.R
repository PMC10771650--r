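## Pipeline orchestration: variant-to-transcript annotation glue and the
## end-to-end runner (select -> regions -> coverage -> annotate -> classify
## -> prioritize), with TSV/BED outputs carrying provenance headers.

#' Annotate one variant against a transcript
#'
#' Maps the variant to c. coordinates, computes the distance to the nearest
#' 5'UTR splice junction, and (for exonic SNVs) rescans the reference and
#' alternate 5'UTR contexts for uAUG/uORF perturbation events.
#'
#' @param ann A `GenomeAnnotation`.
#' @param transcript_id Transcript to annotate against.
#' @param chrom,pos,ref,alt Variant in VCF convention (1-based `pos`).
#' @return List: `c_offset` (exonic c. position or `NA`), `kind`,
#'   `c_label`, `within_near_splice`, `distance_to_junction`, `events`
#'   (from [diff_uaug_events()], or `NULL`).
#' @export
annotate_variant_context <- function(ann, transcript_id, chrom, pos, ref, alt) {
  tx <- ann$transcripts[[transcript_id]]
  cpos <- map_genomic_to_c(tx, pos - 1L)
  utr <- five_prime_utr(tx)
  ulen <- sum(utr$end - utr$start)
  ## junction positions in UTR transcript coordinates
  cums <- cumsum(utr$end - utr$start)
  junctions <- utils::head(cums, -1)
  dist_junction <- NA_integer_
  events <- NULL
  c_offset <- NA_integer_
  if (cpos$kind == "utr5") {
    c_offset <- cpos$c_offset
    off <- ulen + c_offset  # 0-based UTR offset
    if (length(junctions))
      dist_junction <- min(vapply(junctions, function(j)
        if (off < j) j - off else off - j + 1L, integer(1)))
    if (nchar(ref) == 1L && nchar(alt) == 1L) {
      ctx <- transcript_context(ann, transcript_id)
      comp <- function(b) chartr("ACGT", "TGCA", toupper(b))
      ref_u <- if (tx$strand == "-") comp(ref) else toupper(ref)
      alt_u <- if (tx$strand == "-") comp(alt) else toupper(alt)
      alt_ctx <- apply_utr_variant(ctx, off, ref_u, alt_u)
      events <- diff_uaug_events(ctx, alt_ctx, off)
    }
  } else if (cpos$kind == "utr5_intronic") {
    dist_junction <- abs(cpos$intron_offset)
  }
  list(c_offset = c_offset, kind = cpos$kind,
       c_label = format_c_position(cpos),
       within_near_splice = cpos$kind == "utr5_intronic",
       distance_to_junction = dist_junction, events = events)
}

## Deterministic transcript choice for a variant: among overlapping analysis
## regions prefer the canonical transcript, then lexicographic id.
match_variant_region <- function(ann, regions, chrom, pos, ref) {
  span_end <- pos + nchar(ref) - 1L
  hit <- regions[regions$chrom == chrom & pos <= regions$end &
                   span_end >= regions$start + 1L, , drop = FALSE]
  if (!nrow(hit)) return(NULL)
  canon <- vapply(hit$transcript_id, function(id)
    isTRUE(ann$transcripts[[id]]$is_canonical), logical(1))
  hit <- hit[order(!canon, hit$transcript_id), , drop = FALSE]
  hit[1, ]
}

#' Run the full 5'UTR variant interpretation pipeline
#'
#' Stages: isoform selection, analysis-region construction, optional capture
#' audit, variant reading with DP/GQ gates, evidence attachment, sequence
#' effect annotation, 7-category classification, cohort summary, and
#' MOI/phenotype prioritization. Every written output carries a header with
#' the package version, the configuration hash and the active thresholds.
#'
#' @param paths Named list of input paths: `gtf`, `fasta`, `expression`,
#'   `panel`, `vcf`, and optionally `af`, `spliceai`, `te`, `mfe`, `tss`,
#'   `ires`, `capture`, `cases`.
#' @param out_dir Output directory.
#' @param config A [classifier_config()].
#' @param flank_bp Near-splice flank width (default 25).
#' @param capture_pad Padding applied to the capture design (default 0).
#' @return List with all in-memory stage results and output paths.
#' @export
run_pipeline <- function(paths, out_dir = tempfile("utr5run"),
                         config = classifier_config(), flank_bp = 25L,
                         capture_pad = 0L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(list(paths = paths[sort(names(paths))], config = config,
                           flank_bp = flank_bp, capture_pad = capture_pad))
  hdr <- c(paste0("utr5screen ", as.character(utils::packageVersion("utr5screen"))),
           paste0("config_hash ", hash),
           paste0("thresholds maf<", config$maf_max, " spliceai>",
                  config$spliceai_min, " |te|>=", config$te_abs_log2fc_min,
                  " |mfe|>=", config$mfe_abs_fc_min, " flank=", flank_bp))
  ann <- load_annotation(paths$gtf, paths$fasta)
  panel <- read_tsv_table(paths$panel)
  means <- mean_abundance(read_expression_matrix(paths$expression))
  selection <- select_isoforms(ann, means, panel$gene_symbol)
  write_tsv_report(selection, file.path(out_dir, "selection.tsv"), hdr)
  regions <- build_analysis_regions(ann, selected_transcripts(selection),
                                    flank_bp = flank_bp)
  write_analysis_regions(regions, file.path(out_dir, "regions.bed"))
  coverage <- NULL
  if (!is.null(paths$capture)) {
    design <- capture_design(basename(paths$capture), read_bed(paths$capture),
                             padding_bp = capture_pad)
    coverage <- capture_coverage(ann, selection, design)
    write_tsv_report(coverage$per_gene, file.path(out_dir, "coverage.tsv"),
                     c(hdr, paste0("design ", design$name, " pad ",
                                   capture_pad,
                                   " ; gene 5'UTR = union over selected isoforms")))
  }
  variants <- read_region_variants(paths$vcf, regions)
  annotated <- attach_evidence(variants,
                               af_table = paths$af,
                               spliceai_table = paths$spliceai,
                               te_table = paths$te, mfe_table = paths$mfe,
                               tss_bed = paths$tss, ires_bed = paths$ires)
  annotated$gene_symbol <- NA_character_
  annotated$transcript_id <- NA_character_
  annotated$c_label <- NA_character_
  annotated$c_offset <- NA_integer_
  annotated$within_near_splice <- FALSE
  annotated$distance_to_junction <- NA_integer_
  assignments <- list()
  events_by_key <- list()
  for (i in seq_len(nrow(annotated))) {
    reg <- match_variant_region(ann, regions, annotated$chrom[i],
                                annotated$pos[i], annotated$ref[i])
    if (is.null(reg)) next
    ctx <- annotate_variant_context(ann, reg$transcript_id,
                                    annotated$chrom[i], annotated$pos[i],
                                    annotated$ref[i], annotated$alt[i])
    annotated$gene_symbol[i] <- reg$gene_symbol
    annotated$transcript_id[i] <- reg$transcript_id
    annotated$c_label[i] <- ctx$c_label
    annotated$c_offset[i] <- ctx$c_offset
    annotated$within_near_splice[i] <- ctx$within_near_splice
    annotated$distance_to_junction[i] <- ctx$distance_to_junction
    av <- as.list(annotated[i, ])
    av$events <- ctx$events
    events_by_key[[annotated$key[i]]] <- ctx$events
    assignments[[annotated$key[i]]] <- categorize(av, config)
  }
  write_tsv_report(annotated, file.path(out_dir, "annotated.tsv"), hdr)
  ## cohort summary over variants passing rarity + >=1 category filter
  keep <- vapply(annotated$key, function(k) {
    a <- assignments[[k]]
    !is.null(a) && length(a$passing) > 0 &&
      rarity_filter(annotated$max_population_af[annotated$key == k][1], config)
  }, logical(1))
  cohort_of <- rep("cohort", nrow(annotated))
  cases <- NULL
  if (!is.null(paths$cases)) {
    cases <- read_tsv_table(paths$cases)
    m <- match(annotated$key, cases$key)
    cohort_of[!is.na(m)] <- cases$cohort[m[!is.na(m)]]
  }
  summary_tbl <- summarize_categories(assignments[annotated$key[keep]],
                                      cohort_of[keep])
  write_tsv_report(summary_tbl, file.path(out_dir, "summary.tsv"), hdr)
  candidates <- NULL
  if (!is.null(cases)) {
    candidates <- prioritize(cases, assignments, annotated, panel, config)
    write_tsv_report(candidates, file.path(out_dir, "candidates.tsv"), hdr)
  }
  list(annotation = ann, selection = selection, regions = regions,
       coverage = coverage, variants = variants, annotated = annotated,
       assignments = assignments, summary = summary_tbl,
       candidates = candidates, out_dir = out_dir, config_hash = hash)
}
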