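## Synthetic-data generator: emits every input the pipeline reads (FASTA,
## GTF, TPM TSV, VCF, evidence TSVs, TSS/IRES/capture BEDs, panel and case
## tables) with planted, machine-readable ground truth. Synthetic 5'UTRs are
## built over the {A,C,G} alphabet (no T), so the reference UTRs carry no
## uAUG and no stop codon: every start/stop-codon event observed downstream
## is a planted one. One RNG stream per output file, all derived from the
## master seed, so adding an output never perturbs the others.

#' Simulation configuration
#'
#' @param seed Master seed; identical configs produce byte-identical files.
#' @param n_genes Number of genes (>= 6 so that every plant finds a host).
#' @param fraction_noncanonical_enriched Fraction of genes whose
#'   non-canonical isoform is planted as expression-top.
#' @param fraction_spliced_utrs Fraction of genes with multi-exon 5'UTRs.
#' @param n_samples Expression samples.
#' @param cohorts Cohort labels cycled over planted variants.
#' @return List of class `SimulationConfig`.
#' @export
sim_config <- function(seed = 1L, n_genes = 10L,
                       fraction_noncanonical_enriched = 0.4,
                       fraction_spliced_utrs = 0.5, n_samples = 20L,
                       cohorts = c("GE", "CMGG")) {
  stopifnot(n_genes >= 6L, n_samples >= 1L,
            fraction_noncanonical_enriched >= 0,
            fraction_noncanonical_enriched <= 1,
            fraction_spliced_utrs >= 0, fraction_spliced_utrs <= 1)
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 fraction_noncanonical_enriched = fraction_noncanonical_enriched,
                 fraction_spliced_utrs = fraction_spliced_utrs,
                 n_samples = as.integer(n_samples), cohorts = cohorts),
            class = "SimulationConfig")
}

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

## T-free random sequence: cannot contain ATG or any stop codon.
rand_utr <- function(n) rand_seq(n, alphabet = c("A", "C", "G"))

UAUG_PASS_PAD <- "ACCACGG"    # C>T at pad offset 4 creates ATG in strong Kozak
UAUG_FAIL_PAD <- "CCCACGC"    # C>T at pad offset 4 creates ATG in weak Kozak
NATURAL_UORF_PAD <- "ATGGCCGCCTAA"  # 3-aa uORF with in-UTR stop

#' Generate the synthetic reference: FASTA, GTF and gene panel
#'
#' Each gene sits on its own contig (the last one named `chrX` to host the
#' X-linked plants), strands alternating. Canonical transcripts carry a
#' 70 nt 5'UTR, either contiguous or split 40+30 over an intron; CDS is 93 nt
#' (ATG + 29 codons + TAA) with the main-AUG Kozak context cycled over
#' strong/moderate/weak. Genes designated enriched get a second,
#' non-canonical protein-coding isoform whose 5'UTR is fully distinct,
#' partly overlapping or fully contained relative to the canonical one
#' (cycled). Gene 1 carries uAUG-gain planting pads; gene 2 a natural 3-aa
#' uORF.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created).
#' @return List with `fasta`, `gtf`, `panel` paths and `truth_genes` data
#'   frame (`gene_symbol`, `canonical_id`, `noncanonical_id`,
#'   `planted_enriched`, `planted_overlap_class`, `spliced`, `kozak_class`,
#'   `modes`).
#' @export
generate_reference <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(stream_seed(config$seed, "reference"))
  n <- config$n_genes
  n_spliced <- round(config$fraction_spliced_utrs * n)
  n_enriched <- round(config$fraction_noncanonical_enriched * n)
  overlap_cycle <- c("fully_distinct", "partly_overlapping", "fully_overlapping")
  kozak_cycle <- c("strong", "moderate", "weak")
  seqs <- character(0)
  gtf <- list()
  truth <- list()
  for (i in seq_len(n)) {
    sym <- sprintf("GENE%02d", i)
    chrom <- if (i == n) "chrX" else sprintf("g%02d", i)
    strand <- if (i %% 2 == 1) "+" else "-"
    spliced <- i <= n_spliced
    enriched <- i <= n_enriched
    ovl <- if (enriched) overlap_cycle[(i - 1) %% 3 + 1] else NA_character_
    kz <- kozak_cycle[(i - 1) %% 3 + 1]
    g <- build_gene_contig(sym, chrom, strand, spliced, ovl, kz,
                           pads = (i == 1), uorf = (i == 2))
    seqs[chrom] <- g$seq
    gtf[[length(gtf) + 1L]] <- g$gtf
    modes <- if (i == n) "XL" else if (i %% 2 == 1) "AD" else "AR"
    truth[[length(truth) + 1L]] <- data.frame(
      gene_symbol = sym, canonical_id = g$canonical_id,
      noncanonical_id = g$noncanonical_id, planted_enriched = enriched,
      planted_overlap_class = ovl, spliced = spliced, kozak_class = kz,
      modes = modes, stringsAsFactors = FALSE)
  }
  fasta <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta)
  gtf_path <- file.path(dir, "annotation.gtf")
  write_gtf(do.call(rbind, gtf), gtf_path)
  truth_genes <- do.call(rbind, truth)
  panel <- do.call(rbind, lapply(seq_len(n), function(i) panel_entry(
    truth_genes$gene_symbol[i], split_csv(truth_genes$modes[i]),
    c("retinal-dystrophy", paste0("pheno-", truth_genes$gene_symbol[i])))))
  panel_path <- file.path(dir, "panel.tsv")
  write_tsv_report(panel, panel_path)
  list(fasta = fasta, gtf = gtf_path, panel = panel_path,
       truth_genes = truth_genes)
}

## Lay one gene out on its own contig (sense layout, flipped for minus).
build_gene_contig <- function(sym, chrom, strand, spliced, overlap_class,
                              kozak_class, pads = FALSE, uorf = FALSE) {
  flankL <- rand_seq(500)
  flankR <- rand_seq(500)
  u1 <- if (spliced) 40L else 70L
  u2 <- if (spliced) 30L else 0L
  utr <- rand_utr(u1 + u2)
  if (pads) {
    substr(utr, 6L, 12L) <- UAUG_PASS_PAD
    substr(utr, 15L, 21L) <- UAUG_FAIL_PAD
  }
  if (uorf) substr(utr, 26L, 37L) <- NATURAL_UORF_PAD
  ## main-AUG Kozak: -3 base and +4 base (first base of codon 2)
  m3 <- if (kozak_class == "strong") "A" else "C"
  substr(utr, nchar(utr) - 2L, nchar(utr) - 2L) <- m3
  codon2 <- if (kozak_class == "weak") "CCA" else "GCA"
  cds <- paste0("ATG", codon2, strrep("GCA", 28), "TAA")
  utr3 <- rand_seq(50)
  intron <- if (spliced) rand_seq(120) else ""
  ## sense-layout coordinates (0-based half-open)
  utr1_s <- 500L
  if (spliced) {
    utr1_e <- utr1_s + u1
    ex2_s <- utr1_e + 120L
    cds_s <- ex2_s + u2
  } else {
    utr1_e <- utr1_s + u1
    cds_s <- utr1_e
    ex2_s <- NA_integer_
  }
  cds_e <- cds_s + nchar(cds)           # half-open
  gene_e <- cds_e + 50L
  sense <- paste0(flankL, substr(utr, 1L, u1), intron,
                  if (spliced) substr(utr, u1 + 1L, u1 + u2) else "",
                  cds, utr3, flankR)
  stopifnot(nchar(sense) == gene_e + 500L)
  exons_can <- if (spliced)
    data.frame(start = c(utr1_s, ex2_s), end = c(utr1_e, gene_e))
  else data.frame(start = utr1_s, end = gene_e)
  canonical_id <- paste0("TX_", sym, "_C")
  noncanonical_id <- NA_character_
  exons_non <- NULL
  if (!is.na(overlap_class)) {
    noncanonical_id <- paste0("TX_", sym, "_N")
    sense <- paste0(substr(sense, 1L, 100L), rand_utr(70L),
                    substr(sense, 171L, nchar(sense)))  # T-free alt first exon
    exons_non <- switch(overlap_class,
      fully_distinct = data.frame(start = c(100L, cds_s),
                                  end = c(170L, gene_e)),
      partly_overlapping = data.frame(start = c(100L, cds_s - 15L),
                                      end = c(170L, gene_e)),
      fully_overlapping = data.frame(start = cds_s - 20L, end = gene_e))
  }
  total <- nchar(sense)
  flip_iv <- function(df) {
    out <- data.frame(start = total - df$end, end = total - df$start)
    out[order(out$start), ]
  }
  flip_pos <- function(p) total - 1L - p
  if (strand == "-") {
    sense <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(sense)))
    exons_can <- flip_iv(exons_can)
    if (!is.null(exons_non)) exons_non <- flip_iv(exons_non)
    cds_row <- c(flip_pos(cds_e - 1L), flip_pos(cds_s) + 1L)  # [lo0, hi_open)
  } else {
    cds_row <- c(cds_s, cds_e)
  }
  gtf_rows <- function(txid, ex) {
    rbind(
      data.frame(chrom = chrom, source = "synth", type = "exon",
                 start = ex$start + 1L, end = ex$end, strand = strand,
                 gene_id = sym, transcript_id = txid, gene_name = sym,
                 transcript_biotype = "protein_coding",
                 tag = if (endsWith(txid, "_C")) "Ensembl_canonical" else NA,
                 stringsAsFactors = FALSE),
      data.frame(chrom = chrom, source = "synth", type = "CDS",
                 start = cds_row[1] + 1L, end = cds_row[2], strand = strand,
                 gene_id = sym, transcript_id = txid, gene_name = sym,
                 transcript_biotype = "protein_coding",
                 tag = if (endsWith(txid, "_C")) "Ensembl_canonical" else NA,
                 stringsAsFactors = FALSE))
  }
  gtf <- gtf_rows(canonical_id, exons_can)
  if (!is.null(exons_non)) gtf <- rbind(gtf, gtf_rows(noncanonical_id, exons_non))
  list(seq = sense, gtf = gtf, canonical_id = canonical_id,
       noncanonical_id = noncanonical_id)
}

## GTF writing goes through rtracklayer so that the written dialect matches
## what the loader parses.
write_gtf <- function(rows, path) {
  gr <- GenomicRanges::GRanges(
    rows$chrom, IRanges::IRanges(rows$start, rows$end), strand = rows$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = rows$source, type = rows$type, gene_id = rows$gene_id,
    transcript_id = rows$transcript_id, gene_name = rows$gene_name,
    transcript_biotype = rows$transcript_biotype, tag = rows$tag)
  suppressWarnings(rtracklayer::export(gr, path, format = "gtf"))
  path
}

#' Generate the transcript-level expression matrix
#'
#' Log-normal TPM draws per transcript and sample; transcripts planted as
#' enriched receive a 4x mean multiplier over their gene's canonical
#' isoform, so the planted isoform tops the per-gene mean for any reasonable
#' sample size.
#'
#' @param truth_genes From [generate_reference()].
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @return Path of the written TSV.
#' @export
generate_expression <- function(truth_genes, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(stream_seed(config$seed, "expression"))
  ids <- c(truth_genes$canonical_id,
           stats::na.omit(truth_genes$noncanonical_id))
  enriched_ids <- truth_genes$noncanonical_id[truth_genes$planted_enriched &
                                                !is.na(truth_genes$noncanonical_id)]
  m <- matrix(0, nrow = length(ids), ncol = config$n_samples,
              dimnames = list(ids, sprintf("S%02d", seq_len(config$n_samples))))
  for (i in seq_along(ids)) {
    mult <- if (ids[i] %in% enriched_ids) 4 else 1
    m[i, ] <- round(mult * stats::rlnorm(config$n_samples,
                                         meanlog = log(5), sdlog = 0.3), 3)
  }
  path <- file.path(dir, "expression.tsv")
  df <- data.frame(transcript_id = rownames(m), m, check.names = FALSE)
  write_tsv_report(df, path)
  path
}

## Genomic SNV record from a UTR-sense edit on a transcript.
snv_at_utr_offset <- function(ann, txid, utr_offset, alt_utr = NULL) {
  tx <- ann$transcripts[[txid]]
  pos0 <- exonic_positions(tx)[utr_offset + 1L]
  ref_utr <- get_sequence(ann, tx$chrom, pos0, pos0 + 1L, tx$strand)
  if (is.null(alt_utr))
    alt_utr <- setdiff(c("C", "G", "A"), ref_utr)[1]
  comp <- function(b) chartr("ACGT", "TGCA", b)
  if (tx$strand == "-") {
    ref <- comp(ref_utr); alt <- comp(alt_utr)
  } else {
    ref <- ref_utr; alt <- alt_utr
  }
  list(chrom = tx$chrom, pos = pos0 + 1L, ref = ref, alt = alt,
       key = variant_key(tx$chrom, pos0 + 1L, ref, alt))
}

## Genomic SNV in a 5'UTR intron, `k` bases past the donor (k > 0).
snv_in_utr_intron <- function(ann, txid, k, alt_plus = NULL) {
  tx <- ann$transcripts[[txid]]
  utr <- five_prime_utr(tx)
  donor_base <- if (tx$strand == "+") utr$end[1] - 1L else utr$start[1]
  donor_c <- map_genomic_to_c(tx, donor_base)
  pos0 <- map_c_to_genomic(tx, "utr5_intronic", donor_c$c_offset, k)
  ref <- get_sequence(ann, tx$chrom, pos0, pos0 + 1L, "+")
  alt <- if (is.null(alt_plus)) setdiff(c("A", "C", "G", "T"), ref)[1] else alt_plus
  list(chrom = tx$chrom, pos = pos0 + 1L, ref = ref, alt = alt,
       key = variant_key(tx$chrom, pos0 + 1L, ref, alt))
}

## UTR offset of the exonic c. position `c_off` (negative), on transcript tx.
utr_offset_of_c <- function(ann, txid, c_off) {
  tx <- ann$transcripts[[txid]]
  five_prime_utr_length(tx) + c_off
}

#' Plant variants and evidence tables with ground truth
#'
#' For every functional category at least one passing and one failing plant
#' is emitted, with scores on either side of each threshold: uAUG gains in
#' strong and weak Kozak context; a natural-uORF uAUG loss and a uORF stop
#' loss; primary-Kozak positions -3 / -7 / -11; near-splice variants at
#' donor +1 / +2 (SpliceAI 0.25 / 0.15) and a +30 decoy outside the flank;
#' TE log2FC +0.6 / -0.4; MFE FC +2.0 / +1.2; TSS and IRES overlaps plus a
#' near miss; allele frequencies 0.019 / 0.02 / absent; and DP/GQ calls at
#' 11/16 (retained), 10/80 and 40/15 (dropped).
#'
#' @param ann Loaded `GenomeAnnotation` of the synthetic reference.
#' @param truth_genes From [generate_reference()].
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @return List of file paths (`vcf`, `af`, `spliceai`, `te`, `mfe`, `tss`,
#'   `ires`, `capture`) plus `truth_variants` data frame.
#' @export
plant_variants <- function(ann, truth_genes, config, dir) {
  set.seed(stream_seed(config$seed, "variants"))
  tg <- truth_genes
  n <- nrow(tg)
  if (n < 6L) stop("plan error: need at least 6 genes to host all plants")
  can <- tg$canonical_id
  gene_at <- function(i) can[(i - 1L) %% n + 1L]
  spliced_tx <- can[tg$spliced]
  if (!length(spliced_tx))
    stop("plan error: splice plants need at least one spliced 5'UTR gene")
  splice_gene <- spliced_tx[min(4L, length(spliced_tx))]
  xl_gene <- can[n]
  plants <- list()
  add <- function(name, v, categories, pass, dp = 40L, gq = 80L,
                  af = NA_real_, ds = NA_real_, te = NA_real_,
                  mfe = NA_real_, tss = FALSE, ires = FALSE,
                  in_regions = TRUE, retained = TRUE, txid) {
    plants[[name]] <<- list(name = name, v = v, categories = categories,
                            pass = pass, dp = dp, gq = gq, af = af, ds = ds,
                            te = te, mfe = mfe, tss = tss, ires = ires,
                            in_regions = in_regions, retained = retained,
                            txid = txid)
  }
  ## uAUG gains (gene 1 pads): pad at UTR offsets 5..11 / 14..20, edit base
  ## at pad offset 4 (0-based UTR offsets 9 and 18)
  add("uaug_gain_strong", snv_at_utr_offset(ann, can[1], 9L, "T"),
      "uaug_gained", TRUE, txid = can[1])
  add("uaug_gain_weak", snv_at_utr_offset(ann, can[1], 18L, "T"),
      "uaug_gained", FALSE, txid = can[1])
  ## natural uORF (gene 2, pad at UTR offsets 25..36)
  add("uaug_loss", snv_at_utr_offset(ann, can[2], 26L, "C"),
      "uorf_change", TRUE, txid = can[2])
  add("ustop_loss", snv_at_utr_offset(ann, can[2], 35L, "C"),
      "uorf_change", FALSE, txid = can[2])
  ## primary Kozak positions (gene 3)
  add("kozak_minus3", snv_at_utr_offset(ann, can[3],
                                        utr_offset_of_c(ann, can[3], -3L)),
      "kozak_alteration", TRUE, txid = can[3])
  add("kozak_minus7", snv_at_utr_offset(ann, can[3],
                                        utr_offset_of_c(ann, can[3], -7L)),
      "kozak_alteration", FALSE, txid = can[3])
  add("kozak_minus11", snv_at_utr_offset(ann, can[3],
                                         utr_offset_of_c(ann, can[3], -11L)),
      character(0), FALSE, txid = can[3])
  ## splicing (first spliced gene with a free slot)
  add("splice_pass", snv_in_utr_intron(ann, splice_gene, 1L),
      "splicing", TRUE, ds = 0.25, txid = splice_gene)
  add("splice_fail", snv_in_utr_intron(ann, splice_gene, 2L),
      "splicing", FALSE, ds = 0.15, txid = splice_gene)
  add("splice_outside", snv_in_utr_intron(ann, splice_gene, 30L),
      character(0), FALSE, ds = 0.9, in_regions = FALSE, txid = splice_gene)
  ## TE (gene 5), MFE (gene 6)
  add("te_pass", snv_at_utr_offset(ann, can[5], 45L), "te_change", TRUE,
      te = 0.6, txid = can[5])
  add("te_fail", snv_at_utr_offset(ann, can[5], 50L), "te_change", FALSE,
      te = -0.4, txid = can[5])
  add("mfe_pass", snv_at_utr_offset(ann, can[6], 45L), "mfe_change", TRUE,
      mfe = 2.0, txid = can[6])
  add("mfe_fail", snv_at_utr_offset(ann, can[6], 50L), "mfe_change", FALSE,
      mfe = 1.2, txid = can[6])
  ## TSS / IRES (gene 7 by cycle)
  add("tss_overlap", snv_at_utr_offset(ann, gene_at(7L), 45L),
      "tss_or_ires", TRUE, tss = TRUE, txid = gene_at(7L))
  add("ires_overlap", snv_at_utr_offset(ann, gene_at(7L), 50L),
      "tss_or_ires", TRUE, ires = TRUE, txid = gene_at(7L))
  add("tss_near_miss", snv_at_utr_offset(ann, gene_at(7L), 55L),
      character(0), FALSE, txid = gene_at(7L))
  ## rarity boundary (gene 8)
  add("af_pass", snv_at_utr_offset(ann, gene_at(8L), 45L),
      "tss_or_ires", TRUE, af = 0.019, tss = TRUE, txid = gene_at(8L))
  add("af_fail", snv_at_utr_offset(ann, gene_at(8L), 50L),
      "tss_or_ires", TRUE, af = 0.02, tss = TRUE, txid = gene_at(8L))
  ## DP/GQ gates (gene 9)
  add("dp_gq_boundary", snv_at_utr_offset(ann, gene_at(9L), 45L),
      "tss_or_ires", TRUE, dp = 11L, gq = 16L, tss = TRUE,
      txid = gene_at(9L))
  add("dp_too_low", snv_at_utr_offset(ann, gene_at(9L), 50L),
      "tss_or_ires", TRUE, dp = 10L, gq = 80L, tss = TRUE,
      retained = FALSE, txid = gene_at(9L))
  add("gq_too_low", snv_at_utr_offset(ann, gene_at(9L), 55L),
      "tss_or_ires", TRUE, dp = 40L, gq = 15L, tss = TRUE,
      retained = FALSE, txid = gene_at(9L))
  ## X-linked candidate host (last gene, contig chrX)
  add("xl_candidate", snv_at_utr_offset(ann, xl_gene, 60L),
      "tss_or_ires", TRUE, tss = TRUE, txid = xl_gene)
  ## serialize outputs -------------------------------------------------
  keys <- vapply(plants, function(p) p$v$key, character(1))
  if (anyDuplicated(keys)) stop("plan error: duplicate planted variant keys")
  ord <- order(vapply(plants, function(p) p$v$chrom, character(1)),
               vapply(plants, function(p) p$v$pos, integer(1)))
  plants <- plants[ord]
  vcf_path <- file.path(dir, "variants.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", names(ann$genome), ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    vapply(plants, function(p) sprintf(
      "%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:DP:GQ\t0/1:%d:%d",
      p$v$chrom, p$v$pos, p$v$ref, p$v$alt, p$dp, p$gq), character(1))),
    vcf_path)
  tab <- function(field, cols, fname) {
    sel <- plants[vapply(plants, function(p) !is.na(p[[field]][1]) &&
                           !isFALSE(p[[field]][1]), logical(1))]
    df <- do.call(rbind, lapply(sel, function(p) {
      row <- data.frame(chrom = p$v$chrom, pos = p$v$pos, ref = p$v$ref,
                        alt = p$v$alt, stringsAsFactors = FALSE)
      for (j in seq_along(cols)) row[[cols[j]]] <- p[[field]]
      row
    }))
    path <- file.path(dir, fname)
    write_tsv_report(df, path)
    path
  }
  ## AF: two population columns; the planted value is the max, the second
  ## column is lower so the max rule is actually exercised
  af_sel <- plants[vapply(plants, function(p) !is.na(p$af), logical(1))]
  af_path <- file.path(dir, "af.tsv")
  write_tsv_report(do.call(rbind, lapply(af_sel, function(p) data.frame(
    chrom = p$v$chrom, pos = p$v$pos, ref = p$v$ref, alt = p$v$alt,
    AF_popA = p$af / 10, AF_popB = p$af, stringsAsFactors = FALSE))),
    af_path)
  sp_sel <- plants[vapply(plants, function(p) !is.na(p$ds), logical(1))]
  sp_path <- file.path(dir, "spliceai.tsv")
  write_tsv_report(do.call(rbind, lapply(sp_sel, function(p) data.frame(
    chrom = p$v$chrom, pos = p$v$pos, ref = p$v$ref, alt = p$v$alt,
    DS_AG = 0, DS_DG = 0, DS_AL = 0, DS_DL = p$ds,
    stringsAsFactors = FALSE))), sp_path)
  te_path <- tab("te", "te_log2fc", "te.tsv")
  mfe_path <- tab("mfe", "mfe_fc", "mfe.tsv")
  bed_for <- function(field, fname, near_miss_key = NULL) {
    sel <- plants[vapply(plants, function(p) isTRUE(p[[field]]), logical(1))]
    iv <- do.call(rbind, lapply(sel, function(p) data.frame(
      chrom = p$v$chrom, start = p$v$pos - 4L, end = p$v$pos + 3L,
      stringsAsFactors = FALSE)))
    if (!is.null(near_miss_key)) {
      nm <- plants[[near_miss_key]]
      iv <- rbind(iv, data.frame(chrom = nm$v$chrom, start = nm$v$pos,
                                 end = nm$v$pos + 4L))  # starts 1 bp past
    }
    iv <- iv[order(iv$chrom, iv$start), , drop = FALSE]
    path <- file.path(dir, fname)
    write_bed6(iv, path)
    path
  }
  tss_path <- bed_for("tss", "tss.bed", near_miss_key = "tss_near_miss")
  ires_path <- bed_for("ires", "ires.bed")
  ## capture design: baits over the first UTR exon of every canonical
  ## transcript (partial coverage; padding closes part of the gap)
  baits <- do.call(rbind, lapply(can, function(id) {
    tx <- ann$transcripts[[id]]
    u <- five_prime_utr(tx)
    data.frame(chrom = tx$chrom, start = u$start[1] + 10L,
               end = u$end[1], stringsAsFactors = FALSE)
  }))
  capture_path <- file.path(dir, "capture.bed")
  write_bed6(baits[order(baits$chrom, baits$start), ], capture_path)
  truth_variants <- do.call(rbind, lapply(plants, function(p) data.frame(
    name = p$name, key = p$v$key, chrom = p$v$chrom, pos = p$v$pos,
    ref = p$v$ref, alt = p$v$alt, transcript_id = p$txid,
    gene_symbol = ann$transcripts[[p$txid]]$gene_symbol,
    categories = paste(p$categories, collapse = ","),
    intended_pass = p$pass, in_regions = p$in_regions,
    retained = p$retained,
    rarity_pass = is.na(p$af) || p$af < 0.02,
    stringsAsFactors = FALSE)))
  rownames(truth_variants) <- NULL
  list(vcf = vcf_path, af = af_path, spliceai = sp_path, te = te_path,
       mfe = mfe_path, tss = tss_path, ires = ires_path,
       capture = capture_path, truth_variants = truth_variants)
}

#' Generate case metadata with expected candidates
#'
#' Builds cases so that a configured subset satisfies every prioritization
#' gate, including one sporadic autosomal-recessive homozygote, one
#' autosomal-dominant heterozygote, one X-linked hemizygote, one
#' phenotype-mismatch decoy and one inheritance-mismatch decoy.
#'
#' @param truth_genes,truth_variants Generator truth tables.
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @return List with `cases` path, `cases` data frame and
#'   `expected_candidates` (case_id + key).
#' @export
generate_cases <- function(truth_genes, truth_variants, config, dir) {
  tv <- truth_variants
  tg <- truth_genes
  pick <- function(name) tv[tv$name == name, ][1, ]
  tag_of <- function(gene) paste0("pheno-", gene)
  mk <- function(case_id, plant, pattern, sex, zyg, other = 0L,
                 tags = NULL, altdx = FALSE) {
    p <- pick(plant)
    data.frame(case_id = case_id, cohort = "GE",
               phenotype_tags = if (is.null(tags)) tag_of(p$gene_symbol) else tags,
               family_pattern = pattern, sex = sex, key = p$key,
               zygosity = zyg, other_alleles = other,
               alternative_diagnosis = altdx, solved_status = "unsolved",
               stringsAsFactors = FALSE)
  }
  cases <- rbind(
    mk("CASE_AR_HOM", "uaug_loss", "sporadic", "female", "hom"),       # gene 2 (AR)
    mk("CASE_AD_HET", "uaug_gain_strong", "AD", "male", "het"),        # gene 1 (AD)
    mk("CASE_XL_HEMI", "xl_candidate", "sporadic", "male", "hemi"),    # chrX gene
    mk("CASE_PHENO_DECOY", "kozak_minus3", "AD", "female", "het",
       tags = "unrelated-phenotype"),                                  # gene 3 (AD)
    mk("CASE_MOI_DECOY", "mfe_pass", "AD", "male", "het")              # gene 6 (AR-only)
  )
  path <- file.path(dir, "cases.tsv")
  write_tsv_report(cases, path)
  expected <- cases[cases$case_id %in%
                      c("CASE_AR_HOM", "CASE_AD_HET", "CASE_XL_HEMI"),
                    c("case_id", "key")]
  rownames(expected) <- NULL
  list(cases_path = path, cases = cases, expected_candidates = expected)
}

#' Simulate a complete synthetic cohort
#'
#' Writes every pipeline input into `dir` and returns the paths plus the
#' planted truth.
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @return List: all file paths, `truth_genes`, `truth_variants`,
#'   `expected_candidates`, `cases`, and the loaded `annotation`.
#' @export
simulate_cohort <- function(config = sim_config(), dir = tempfile("synth")) {
  ref <- generate_reference(config, dir)
  expr <- generate_expression(ref$truth_genes, config, dir)
  ann <- suppressMessages(load_annotation(ref$gtf, ref$fasta))
  pl <- plant_variants(ann, ref$truth_genes, config, dir)
  cs <- generate_cases(ref$truth_genes, pl$truth_variants, config, dir)
  c(ref, list(expression = expr), pl[setdiff(names(pl), "truth_variants")],
    list(truth_variants = pl$truth_variants, cases_path = cs$cases_path,
         cases = cs$cases, expected_candidates = cs$expected_candidates,
         annotation = ann, dir = dir))
}
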