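## Variant parsing against the 5'UTR analysis regions, sequencing-quality
## gating, evidence attachment from external tables, and ClinVar-style
## filtering to the search space.

#' Read variants overlapping the analysis regions from a VCF
#'
#' Multi-allelic records are split into per-alt rows. A variant is retained
#' when it overlaps at least one analysis region and, in at least one carrier
#' sample (any genotype carrying a non-reference allele), sequencing depth
#' and genotype quality strictly exceed the gates (`DP > dp_min`,
#' `GQ > gq_min`). Calls with missing DP or GQ in all carriers are dropped
#' with a logged reason.
#'
#' @param vcf_path Path to a VCF (4.2+) with FORMAT fields DP and GQ.
#' @param regions Analysis regions from [build_analysis_regions()] (or any
#'   data frame with `chrom`, `start`, `end` in 0-based half-open
#'   coordinates).
#' @param dp_min,gq_min Strict lower gates (defaults 10 and 15).
#' @return Data frame: `chrom`, `pos` (1-based, as in VCF), `ref`, `alt`,
#'   `key`, `carriers` (comma-separated sample names passing the gates).
#' @export
read_region_variants <- function(vcf_path, regions, dp_min = 10, gq_min = 15) {
  vcf <- VariantAnnotation::readVcf(vcf_path)
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  n <- length(rr)
  if (n == 0L) return(empty_variants())
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref <- as.character(rr$REF)
  alt <- as.character(rr$ALT)
  gt <- VariantAnnotation::geno(vcf)$GT
  dp <- VariantAnnotation::geno(vcf)$DP
  gq <- VariantAnnotation::geno(vcf)$GQ
  if (is.null(dp) || is.null(gq))
    stop("VCF lacks FORMAT DP and/or GQ")
  keep <- logical(n)
  carriers <- character(n)
  for (i in seq_len(n)) {
    is_carrier <- grepl("[1-9]", gt[i, ]) & !grepl("\\.", gt[i, ])
    pass <- is_carrier & !is.na(dp[i, ]) & !is.na(gq[i, ]) &
      dp[i, ] > dp_min & gq[i, ] > gq_min
    if (any(is_carrier) && !any(is_carrier & !is.na(dp[i, ]) & !is.na(gq[i, ]))) {
      message("dropped ", chrom[i], ":", pos[i], " (missing DP/GQ in carriers)")
    }
    keep[i] <- any(pass)
    carriers[i] <- paste(colnames(gt)[pass], collapse = ",")
  }
  ## region overlap on the REF footprint
  span_end <- pos + nchar(ref) - 1L
  in_region <- vapply(seq_len(n), function(i) {
    r <- regions[regions$chrom == chrom[i], , drop = FALSE]
    if (!nrow(r)) return(FALSE)
    any(pos[i] <= r$end & span_end[i] >= r$start + 1L)
  }, logical(1))
  out <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                    key = variant_key(chrom, pos, ref, alt),
                    carriers = carriers, stringsAsFactors = FALSE)
  out <- out[keep & in_region, , drop = FALSE]
  out <- unique(out)
  rownames(out) <- NULL
  out
}

empty_variants <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), key = character(0), carriers = character(0))
}

read_keyed_table <- function(path_or_df) {
  if (is.null(path_or_df)) return(NULL)
  df <- if (is.character(path_or_df)) read_tsv_table(path_or_df) else path_or_df
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(df))) {
    warning("malformed evidence table: missing key columns; skipped")
    return(NULL)
  }
  df$key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
  df
}

#' Attach external evidence to variants
#'
#' Joins population allele frequency, SpliceAI delta scores, translational
#' efficiency log2 fold change, and secondary-structure minimum-free-energy
#' fold change tables (all keyed by chrom/pos/ref/alt), plus CAGE TSS and
#' IRES interval overlap. Missing keys yield `NA` fields, never fabricated
#' zeros; downstream, an absent allele frequency passes the rarity filter
#' (absence from reference populations is itself evidence of rarity).
#'
#' @param variants From [read_region_variants()] (needs `chrom`, `pos`,
#'   `ref`, `alt`, `key`).
#' @param af_table TSV path or data frame with key columns plus one or more
#'   population AF columns; `max_population_af` is the row-wise maximum.
#' @param spliceai_table Key columns plus `DS_AG`, `DS_DG`, `DS_AL`, `DS_DL`.
#' @param te_table Key columns plus `te_log2fc`.
#' @param mfe_table Key columns plus `mfe_fc`.
#' @param tss_bed,ires_bed BED paths or interval data frames
#'   (`chrom`,`start`,`end`, 0-based half-open).
#' @return `variants` with columns `max_population_af`, `DS_AG`, `DS_DG`,
#'   `DS_AL`, `DS_DL`, `spliceai_max`, `te_log2fc`, `mfe_fc`, `overlaps_tss`,
#'   `overlaps_ires` appended. Idempotent and key-preserving.
#' @export
attach_evidence <- function(variants, af_table = NULL, spliceai_table = NULL,
                            te_table = NULL, mfe_table = NULL,
                            tss_bed = NULL, ires_bed = NULL) {
  v <- variants
  af <- read_keyed_table(af_table)
  v$max_population_af <- NA_real_
  if (!is.null(af)) {
    afcols <- setdiff(names(af), c("chrom", "pos", "ref", "alt", "key"))
    idx <- match(v$key, af$key)
    hit <- !is.na(idx)
    if (length(afcols) && any(hit))
      v$max_population_af[hit] <- apply(
        af[idx[hit], afcols, drop = FALSE], 1,
        function(r) if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
  }
  sp <- read_keyed_table(spliceai_table)
  for (col in c("DS_AG", "DS_DG", "DS_AL", "DS_DL")) v[[col]] <- NA_real_
  if (!is.null(sp)) {
    idx <- match(v$key, sp$key)
    hit <- !is.na(idx)
    for (col in c("DS_AG", "DS_DG", "DS_AL", "DS_DL"))
      if (col %in% names(sp)) v[[col]][hit] <- sp[[col]][idx[hit]]
  }
  ds <- as.matrix(v[, c("DS_AG", "DS_DG", "DS_AL", "DS_DL")])
  v$spliceai_max <- apply(ds, 1, function(r)
    if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
  te <- read_keyed_table(te_table)
  v$te_log2fc <- if (!is.null(te)) te$te_log2fc[match(v$key, te$key)] else NA_real_
  mf <- read_keyed_table(mfe_table)
  v$mfe_fc <- if (!is.null(mf)) mf$mfe_fc[match(v$key, mf$key)] else NA_real_
  v$overlaps_tss <- overlaps_intervals(v, tss_bed)
  v$overlaps_ires <- overlaps_intervals(v, ires_bed)
  v
}

overlaps_intervals <- function(variants, bed) {
  if (is.null(bed)) return(rep(FALSE, nrow(variants)))
  iv <- if (is.character(bed)) read_bed(bed) else bed
  vapply(seq_len(nrow(variants)), function(i) {
    r <- iv[iv$chrom == variants$chrom[i], , drop = FALSE]
    if (!nrow(r)) return(FALSE)
    p0 <- variants$pos[i] - 1L  # 0-based position of the first ref base
    any(p0 >= r$start & p0 < r$end)
  }, logical(1))
}

#' Maximum nested base-pairing score (internal fold proxy)
#'
#' Nussinov-style dynamic program returning the maximum number of nested
#' Watson-Crick + GU wobble pairs with a minimum hairpin loop of 3 unpaired
#' bases. This is a test proxy used only by the synthetic-data generator to
#' manufacture self-consistent secondary-structure fixtures; production
#' minimum-free-energy fold changes are always supplied as external tables.
#'
#' @param seq DNA/RNA sequence, length <= 500.
#' @param min_loop Minimum unpaired bases enclosed by a pair (default 3).
#' @return Integer pair count.
#' @export
internal_mfe_proxy <- function(seq, min_loop = 3L) {
  seq <- toupper(chartr("U", "T", seq))
  n <- nchar(seq)
  if (n > 500L) stop("refusing sequences longer than 500 nt")
  if (n == 0L) return(0L)
  b <- strsplit(seq, "")[[1]]
  can_pair <- function(x, y) {
    paste0(x, y) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  }
  M <- matrix(0L, n, n)
  for (span in seq_len(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- M[i, j - 1L]
      for (k in i:(j - 1L)) {
        if (j - k > min_loop && can_pair(b[k], b[j])) {
          left <- if (k > i) M[i, k - 1L] else 0L
          inner <- if (k + 1L <= j - 1L) M[k + 1L, j - 1L] else 0L
          best <- max(best, left + inner + 1L)
        }
      }
      M[i, j] <- best
    }
  }
  M[1L, n]
}

#' Read a ClinVar-style tab-delimited variant table
#'
#' Keeps GRCh38 rows when an `Assembly` column is present and normalizes the
#' column names used downstream.
#'
#' @param path Tab-delimited file with named columns including
#'   `Chromosome`/`chrom`, `Start`/`pos`, `Stop` (optional),
#'   `ClinicalSignificance`, `Type`, `MolecularConsequence`.
#' @return Data frame with `chrom`, `start`, `stop` (1-based inclusive),
#'   `clinical_significance`, `variant_type`, `molecular_consequence`.
#' @export
read_clinvar_table <- function(path) {
  df <- read_tsv_table(path)
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(df)) return(df[[nm]])
    rep(NA, nrow(df))
  }
  if ("Assembly" %in% names(df)) df <- df[df$Assembly == "GRCh38", , drop = FALSE]
  out <- data.frame(
    chrom = as.character(pick("Chromosome", "chrom")),
    start = as.integer(pick("Start", "pos", "start")),
    stop = as.integer(pick("Stop", "stop")),
    clinical_significance = as.character(pick("ClinicalSignificance",
                                              "clinical_significance")),
    variant_type = as.character(pick("Type", "variant_type")),
    molecular_consequence = as.character(pick("MolecularConsequence",
                                              "molecular_consequence")),
    stringsAsFactors = FALSE)
  out$stop[is.na(out$stop)] <- out$start[is.na(out$stop)]
  out
}

PROTEIN_ALTERING <- c("missense_variant", "stop_gained", "stop_lost",
                      "start_lost", "frameshift_variant",
                      "inframe_insertion", "inframe_deletion",
                      "synonymous_variant")

#' Filter a ClinVar-style table to the 5'UTR search space
#'
#' Retains records that overlap an analysis region, are not copy-number
#' gains/losses extending into coding sequence, and whose consequence on the
#' canonical transcript is neither protein-altering nor synonymous. Tallies
#' clinical significance into P/LP, B/LB, conflicting, VUS and other buckets
#' (unknown strings bucket as other, with a message).
#'
#' @param records From [read_clinvar_table()].
#' @param regions Analysis regions (0-based half-open).
#' @param cds_regions Optional CDS intervals (`chrom`,`start`,`end`, 0-based
#'   half-open) used to detect copy-number events extending into coding
#'   sequence.
#' @return List with `retained` (data frame) and `tally` (named integer
#'   vector over `P/LP`, `B/LB`, `conflicting`, `VUS`, `other`).
#' @export
filter_clinvar_utr <- function(records, regions, cds_regions = NULL) {
  ovl <- function(iv, chrom, s1, e1) {
    ## s1/e1 are 1-based inclusive; iv is 0-based half-open
    r <- iv[iv$chrom == chrom, , drop = FALSE]
    nrow(r) > 0 && any(s1 <= r$end & e1 >= r$start + 1L)
  }
  keep <- vapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    if (!ovl(regions, rec$chrom, rec$start, rec$stop)) return(FALSE)
    is_cnv <- grepl("copy number", rec$variant_type, ignore.case = TRUE) ||
      rec$variant_type %in% c("Duplication", "Deletion") &&
        (rec$stop - rec$start) > 50
    if (is_cnv && !is.null(cds_regions) &&
        ovl(cds_regions, rec$chrom, rec$start, rec$stop)) return(FALSE)
    cons <- rec$molecular_consequence
    if (!is.na(cons) && any(vapply(PROTEIN_ALTERING, grepl, logical(1),
                                   x = cons, fixed = TRUE))) return(FALSE)
    TRUE
  }, logical(1))
  retained <- records[keep, , drop = FALSE]
  rownames(retained) <- NULL
  tally <- c("P/LP" = 0L, "B/LB" = 0L, conflicting = 0L, VUS = 0L, other = 0L)
  for (s in retained$clinical_significance) {
    b <- significance_bucket(s)
    tally[b] <- tally[b] + 1L
  }
  list(retained = retained, tally = tally)
}

significance_bucket <- function(s) {
  sl <- tolower(trimws(s))
  if (grepl("conflicting", sl)) return("conflicting")
  if (sl %in% c("pathogenic", "likely pathogenic", "pathogenic/likely pathogenic"))
    return("P/LP")
  if (sl %in% c("benign", "likely benign", "benign/likely benign"))
    return("B/LB")
  if (sl %in% c("uncertain significance", "vus")) return("VUS")
  if (!sl %in% c("not provided", "other", "risk factor", "drug response", "association"))
    message("unknown clinical significance '", s, "' bucketed as other")
  "other"
}
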