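## A fully worked candidate-prioritization fixture: eleven published
## candidate 5'UTR variants in ten inherited-retinal-disease genes, each
## encoded with its reported genomic key, zygosity, population frequency,
## functional category evidence, family inheritance pattern and a matching
## gene panel. Running the classifier and prioritizer over this fixture
## reproduces the published candidate set (11 variants, 10 genes, 4 of them
## splicing) end to end; it doubles as a regression fixture for the
## MOI/phenotype gates.

## uAUG-gain contexts are built as real sequences and run through the
## annotator rather than asserted: a single-base substitution creates an ATG
## in strong Kozak context, with (for the uORF case) an in-frame stop codon
## whose first base lies 75 nt downstream, still inside the 5'UTR.

#' Sequence context for a variant-created uORF with an in-UTR stop
#'
#' Builds a 5'UTR in which a C>T substitution creates an ATG in strong Kozak
#' context (A at -3, G at +4) whose in-frame stop codon starts `stop_offset`
#' nucleotides downstream, inside the UTR.
#'
#' @param utr_len Total UTR length (>= aug_offset + stop_offset + 3).
#' @param aug_offset 0-based UTR offset of the created A of ATG.
#' @param stop_offset Distance in nt from the A of ATG to the first stop base
#'   (default 75, i.e. a 25-aa peptide including the initiator Met).
#' @return List with `ref_ctx`, `alt_ctx`, `utr_offset` (of the edited base),
#'   `ref`, `alt`.
#' @export
uaug_gain_context <- function(utr_len = 130L, aug_offset = 7L,
                              stop_offset = 75L) {
  stopifnot(aug_offset >= 4L, aug_offset + stop_offset + 3L <= utr_len)
  fill <- function(n) substr(strrep("CCA", ceiling(n / 3) + 1L), 1L, n)
  prefix <- fill(aug_offset)
  substr(prefix, aug_offset - 2L, aug_offset - 2L) <- "A"   # Kozak -3
  n_codons <- stop_offset / 3L - 1L
  body <- paste0("ACG", strrep("GCC", n_codons), "TAA")
  utr <- paste0(prefix, body, fill(utr_len - aug_offset - stop_offset - 3L))
  ref_ctx <- utr_context(utr, paste0("ATG", strrep("GCA", 20), "TAG"))
  alt_ctx <- apply_utr_variant(ref_ctx, aug_offset + 1L, "C", "T")
  list(ref_ctx = ref_ctx, alt_ctx = alt_ctx, utr_offset = aug_offset + 1L,
       ref = "C", alt = "T")
}

#' Sequence context for a variant-created out-of-frame CDS-overlapping ORF
#'
#' Same construction as [uaug_gain_context()] but with no in-frame stop in
#' the UTR and a reading frame differing from the CDS.
#'
#' @param utr_len Total UTR length.
#' @param aug_offset 0-based UTR offset of the created A of ATG; chosen so
#'   that `(utr_len - aug_offset) %% 3 != 0`.
#' @return Same shape as [uaug_gain_context()].
#' @export
oorf_gain_context <- function(utr_len = 30L, aug_offset = 10L) {
  stopifnot((utr_len - aug_offset) %% 3L != 0L, aug_offset >= 4L)
  fill <- function(n) substr(strrep("CCC", ceiling(n / 3) + 1L), 1L, n)
  prefix <- fill(aug_offset)
  substr(prefix, aug_offset - 2L, aug_offset - 2L) <- "A"
  tail_len <- utr_len - aug_offset - 3L
  utr <- paste0(prefix, "ACG", substr(strrep("GCC", ceiling(tail_len / 3) + 1L),
                                      1L, tail_len))
  ref_ctx <- utr_context(utr, paste0("ATG", strrep("GCA", 20), "TAG"))
  alt_ctx <- apply_utr_variant(ref_ctx, aug_offset + 1L, "C", "T")
  list(ref_ctx = ref_ctx, alt_ctx = alt_ctx, utr_offset = aug_offset + 1L,
       ref = "C", alt = "T")
}

replica_row <- function(case_id, cohort, gene, key, zygosity, maf,
                        family_pattern, sex, phenotype, other_alleles = 0L,
                        c_offset = NA_integer_, dist_junction = NA_integer_,
                        within_near_splice = FALSE, spliceai = NA_real_,
                        mfe_fc = NA_real_, te_log2fc = NA_real_,
                        tss = FALSE, ires = FALSE, events = NULL) {
  list(case_id = case_id, cohort = cohort, gene_symbol = gene, key = key,
       zygosity = zygosity, max_population_af = maf,
       family_pattern = family_pattern, sex = sex, phenotype_tags = phenotype,
       other_alleles = other_alleles, c_offset = c_offset,
       distance_to_junction = dist_junction,
       within_near_splice = within_near_splice, spliceai_max = spliceai,
       mfe_fc = mfe_fc, te_log2fc = te_log2fc, overlaps_tss = tss,
       overlaps_ires = ires, events = events)
}

#' The published eleven-candidate prioritization fixture
#'
#' Eleven case-variant observations in ten genes with the reported
#' zygosities, population frequencies, family inheritance patterns and
#' per-category evidence, plus a gene panel granting each gene its reported
#' inheritance modes and phenotype association. The two uORF-creating
#' variants carry real sequence contexts that are re-annotated at run time.
#'
#' @return List with `cases` (data frame), `annotated` (data frame),
#'   `assignments` (named list of [categorize()] results), `panel`, and
#'   `config`.
#' @export
table2_replica <- function() {
  cfg <- classifier_config()
  rdh12 <- uaug_gain_context()
  nphp4 <- oorf_gain_context()
  ev_rdh12 <- diff_uaug_events(rdh12$ref_ctx, rdh12$alt_ctx, rdh12$utr_offset)
  ev_nphp4 <- diff_uaug_events(nphp4$ref_ctx, nphp4$alt_ctx, nphp4$utr_offset)
  rows <- list(
    replica_row("F1", "GE", "RDH12", "chr14:67722520:C:T", "het", 0.00008544,
                "sporadic", "female", "macular-dystrophy", other_alleles = 2L,
                c_offset = -122L, events = ev_rdh12),
    replica_row("F2", "GE", "NPHP4", "chr1:5986310:G:A", "het", 0.00001972,
                "sporadic", "male", "rod-cone-dystrophy", other_alleles = 1L,
                c_offset = -21L, events = ev_nphp4),
    replica_row("F3", "GE", "NMNAT1", "chr1:9943515:G:A", "het", NA,
                "sporadic", "female", "macular-dystrophy", other_alleles = 1L,
                c_offset = -57L, dist_junction = 3L, spliceai = 0.84),
    replica_row("F4", "GE", "PRPF31", "chr19:54115798:G:A", "het", NA,
                "AD", "female", "early-onset-severe-retinal-dystrophy",
                dist_junction = 1L, within_near_splice = TRUE,
                spliceai = 0.91),
    replica_row("F5", "GE", "PRPF31", "chr19:54115798:G:T", "het", NA,
                "sporadic", "male", "rod-cone-dystrophy",
                dist_junction = 1L, within_near_splice = TRUE,
                spliceai = 0.93),
    replica_row("F6", "GE", "NDP", "chrX:43958715:C:T", "hemi", NA,
                "sporadic", "male", "exudative-vitreoretinopathy",
                c_offset = -70L, dist_junction = 9L, spliceai = 0.62),
    replica_row("F7", "GE", "RD3", "chr1:211492150:C:T", "hom", NA,
                "sporadic", "male", "rod-cone-dystrophy",
                c_offset = -394L, mfe_fc = 2.1, tss = TRUE),
    replica_row("F8", "GE", "MERTK", "chr2:111898611:G:A", "hom", 0.00002632,
                "sporadic", "male", "early-onset-severe-retinal-dystrophy",
                c_offset = -125L, mfe_fc = 1.9, tss = TRUE),
    replica_row("F9", "GE", "PAX6", "chr11:31806455:A:G", "het", NA,
                "AD", "female", "cone-dysfunction",
                c_offset = -44L, mfe_fc = -1.7),
    replica_row("F10", "CMGG", "ARL3", "chr10:102714363:C:T", "het", NA,
                "AR", "female", "retinal-dystrophy",
                c_offset = -88L, mfe_fc = 1.8),
    replica_row("F11", "CMGG", "PRPF4", "chr9:113275738:C:T", "het", NA,
                "sporadic", "male", "rod-cone-dystrophy",
                c_offset = -6L))
  panel <- do.call(rbind, list(
    panel_entry("RDH12", "AR", c("macular-dystrophy", "early-onset-severe-retinal-dystrophy")),
    panel_entry("NPHP4", "AR", c("rod-cone-dystrophy")),
    panel_entry("NMNAT1", "AR", c("macular-dystrophy", "early-onset-severe-retinal-dystrophy")),
    panel_entry("PRPF31", "AD", c("rod-cone-dystrophy", "early-onset-severe-retinal-dystrophy")),
    panel_entry("NDP", "XL", c("exudative-vitreoretinopathy")),
    panel_entry("RD3", "AR", c("rod-cone-dystrophy", "early-onset-severe-retinal-dystrophy")),
    panel_entry("MERTK", "AR", c("early-onset-severe-retinal-dystrophy", "rod-cone-dystrophy")),
    panel_entry("PAX6", "AD", c("cone-dysfunction", "aniridia")),
    panel_entry("ARL3", c("AD", "AR"), c("retinal-dystrophy", "rod-cone-dystrophy")),
    panel_entry("PRPF4", "AD", c("rod-cone-dystrophy"))))
  annotated <- do.call(rbind, lapply(rows, function(r) data.frame(
    key = r$key, gene_symbol = r$gene_symbol,
    max_population_af = r$max_population_af, stringsAsFactors = FALSE)))
  annotated <- unique(annotated)
  assignments <- list()
  for (r in rows) assignments[[r$key]] <- categorize(r, cfg)
  cases <- do.call(rbind, lapply(rows, function(r) data.frame(
    case_id = r$case_id, cohort = r$cohort, phenotype_tags = r$phenotype_tags,
    family_pattern = r$family_pattern, sex = r$sex, key = r$key,
    zygosity = r$zygosity, other_alleles = r$other_alleles,
    alternative_diagnosis = FALSE, stringsAsFactors = FALSE)))
  list(cases = cases, annotated = annotated, assignments = assignments,
       panel = panel, config = cfg, rows = rows)
}
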