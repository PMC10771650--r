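## The 7-category functional classifier, rarity filter, cohort summary table,
## and the inheritance/phenotype-aware candidate prioritizer.
##
## Threshold boundaries follow the published criteria exactly: MAF and
## SpliceAI are strict ("lower than 2%", "higher than 0.2"); TE and MFE are
## inclusive (|log2FC| >= 0.5, |FC| >= 1.5).

CATEGORY_NAMES <- c("uaug_gained", "uorf_change", "kozak_alteration",
                    "splicing", "te_change", "mfe_change", "tss_or_ires")

CATEGORY_LABELS <- c(
  uaug_gained = "uAUG gained",
  uorf_change = "Change in existing uORF",
  kozak_alteration = "Alteration of classical or retinal primary Kozak context",
  splicing = "Splicing",
  te_change = "Change in translational efficiency",
  mfe_change = "Change in secondary structure minimum free energy",
  tss_or_ires = "Overlapping a retinal transcription start site or an IRES")

#' Classifier configuration
#'
#' All thresholds of the 7-category classifier, defaulting to the published
#' working values: rarity MAF < 0.02 in all populations; any SpliceAI delta
#' score > 0.2 within +/-25 bp of an intron-exon boundary; |TE log2FC| >=
#' 0.5 (~1.5-fold translation change); |MFE FC| >= 1.5; gained uAUGs kept in
#' strong or moderate Kozak context; primary-Kozak window -10..-1 with
#' prioritized positions -3, -4, -5, -6, -9.
#'
#' @param maf_max,spliceai_min,near_splice_bp,te_abs_log2fc_min,mfe_abs_fc_min
#'   Numeric thresholds.
#' @param kozak_prioritized_positions,kozak_window Integer vectors.
#' @param uaug_kozak_allowed Kozak strengths retained for gained uAUGs.
#' @return List of class `ClassifierConfig`.
#' @export
classifier_config <- function(maf_max = 0.02, spliceai_min = 0.2,
                              near_splice_bp = 25L,
                              te_abs_log2fc_min = 0.5, mfe_abs_fc_min = 1.5,
                              kozak_prioritized_positions = c(-3L, -4L, -5L, -6L, -9L),
                              kozak_window = c(-10L, -1L),
                              uaug_kozak_allowed = c("strong", "moderate")) {
  stopifnot(maf_max > 0, spliceai_min > 0, near_splice_bp > 0,
            te_abs_log2fc_min > 0, mfe_abs_fc_min > 0,
            all(kozak_prioritized_positions >= kozak_window[1] &
                  kozak_prioritized_positions <= kozak_window[2]))
  structure(list(maf_max = maf_max, spliceai_min = spliceai_min,
                 near_splice_bp = as.integer(near_splice_bp),
                 te_abs_log2fc_min = te_abs_log2fc_min,
                 mfe_abs_fc_min = mfe_abs_fc_min,
                 kozak_prioritized_positions = kozak_prioritized_positions,
                 kozak_window = kozak_window,
                 uaug_kozak_allowed = uaug_kozak_allowed),
            class = "ClassifierConfig")
}

#' Rarity filter
#'
#' Passes when the maximum population allele frequency is strictly below the
#' MAF threshold, or when the variant is absent from all reference
#' populations (`NA`).
#'
#' @param max_population_af Numeric (may be `NA`).
#' @param config A [classifier_config()].
#' @return Logical.
#' @export
rarity_filter <- function(max_population_af, config = classifier_config()) {
  is.na(max_population_af) | max_population_af < config$maf_max
}

#' Assign a variant to the 7 functional categories
#'
#' Categories are evidence-driven, independent and non-mutually exclusive;
#' absent evidence simply withholds a category. Per-category filters: (i)
#' gained uAUG in strong/moderate Kozak; (ii) natural uAUG loss; (iii)
#' variant at a prioritized primary-Kozak position; (iv) within the
#' near-splice window and any SpliceAI delta above the threshold (strict);
#' (v) |TE log2FC| above threshold (inclusive); (vi) |MFE FC| above threshold
#' (inclusive); (vii) TSS or IRES overlap. Intronic near-splice variants are
#' eligible only for the splicing category.
#'
#' @param av One-row data frame (or list) of annotated evidence: fields
#'   `key`, `spliceai_max`, `te_log2fc`, `mfe_fc`, `overlaps_tss`,
#'   `overlaps_ires`, `c_offset` (exonic c. position, `NA` when intronic),
#'   `distance_to_junction` (bp, `NA` when not near a junction),
#'   `within_near_splice` (logical), and `events` (list with `events`,
#'   `gained` from [diff_uaug_events()], or `NULL`).
#' @param config A [classifier_config()].
#' @return List of class `CategoryAssignment`: `key`, `categories`,
#'   `filter_pass` (named logical over held categories), `passing`
#'   (categories whose filter passed), `multi_category`.
#' @export
categorize <- function(av, config = classifier_config()) {
  held <- character(0)
  pass <- logical(0)
  hold <- function(cat, ok) {
    held <<- c(held, cat)
    pass <<- c(pass, stats::setNames(isTRUE(ok), cat))
  }
  intronic <- isTRUE(av$within_near_splice)
  ev <- av$events
  if (!intronic && !is.null(ev) && length(ev$events)) {
    if ("uaug_gain" %in% ev$events)
      hold("uaug_gained",
           any(ev$gained$kozak %in% config$uaug_kozak_allowed))
    if (any(c("uaug_loss", "ustop_loss", "uframe_shift") %in% ev$events))
      hold("uorf_change", "uaug_loss" %in% ev$events)
  }
  if (!intronic && !is.null(av$c_offset) && !is.na(av$c_offset)) {
    ka <- kozak_alteration(av$c_offset, config$kozak_window,
                           config$kozak_prioritized_positions)
    if (ka$in_classical_window)
      hold("kozak_alteration", ka$prioritized_position)
  }
  near <- !is.null(av$distance_to_junction) && !is.na(av$distance_to_junction) &&
    av$distance_to_junction <= config$near_splice_bp
  if (near && !is.na(nullna(av$spliceai_max)))
    hold("splicing", av$spliceai_max > config$spliceai_min)
  if (!intronic) {
    if (!is.na(nullna(av$te_log2fc)))
      hold("te_change", abs(av$te_log2fc) >= config$te_abs_log2fc_min)
    if (!is.na(nullna(av$mfe_fc)))
      hold("mfe_change", abs(av$mfe_fc) >= config$mfe_abs_fc_min)
    if (isTRUE(av$overlaps_tss) || isTRUE(av$overlaps_ires))
      hold("tss_or_ires", TRUE)
  }
  passing <- held[pass]
  structure(list(key = av$key, categories = held, filter_pass = pass,
                 passing = passing,
                 multi_category = length(passing) > 1L),
            class = "CategoryAssignment")
}

nullna <- function(x) if (is.null(x) || length(x) == 0L) NA_real_ else x

#' Summarize filtered assignments into the per-cohort category table
#'
#' Takes one assignment per variant (only variants surviving rarity and at
#' least one category filter) and tabulates per-cohort counts per single
#' category, a "> 1 category" row for multi-category variants, and a total
#' row with a percent column (2 decimals). Row counts partition the total.
#'
#' @param assignments List of [categorize()] results (filter-passing).
#' @param cohorts Character vector, same length, naming each variant's
#'   cohort.
#' @param cohort_levels Optional fixed cohort column order.
#' @return Data frame: `category`, one count column per cohort, `total`,
#'   `percent`.
#' @export
summarize_categories <- function(assignments, cohorts,
                                 cohort_levels = unique(cohorts)) {
  stopifnot(length(assignments) == length(cohorts))
  row_of <- vapply(assignments, function(a) {
    if (a$multi_category) "> 1 category" else a$passing[1]
  }, character(1))
  counts <- matrix(0L, nrow = length(CATEGORY_NAMES) + 1L,
                   ncol = length(cohort_levels),
                   dimnames = list(c(CATEGORY_NAMES, "> 1 category"),
                                   cohort_levels))
  for (i in seq_along(row_of)) {
    counts[row_of[i], cohorts[i]] <- counts[row_of[i], cohorts[i]] + 1L
  }
  summary_from_counts(counts)
}

#' Build the category summary table from a count matrix
#'
#' Formatter for per-cohort category counts: appends row totals, the percent
#' column (100 * row_total / grand_total, rounded to 2 decimals) and the
#' total row.
#'
#' @param counts Integer matrix; rows = the 7 categories plus
#'   `"> 1 category"` (any subset, in order), columns = cohorts.
#' @return Data frame: `category`, cohort columns, `total`, `percent`.
#' @export
summary_from_counts <- function(counts) {
  row_total <- rowSums(counts)
  grand <- sum(row_total)
  pct <- if (grand > 0) round(100 * row_total / grand, 2) else rep(0, length(row_total))
  out <- data.frame(category = rownames(counts), counts, total = row_total,
                    percent = pct, row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  total_row <- data.frame(category = "Total", t(colSums(counts)),
                          total = grand, percent = 100,
                          check.names = FALSE, stringsAsFactors = FALSE)
  names(total_row) <- names(out)
  rbind(out, total_row)
}

#' Gene panel entry constructor
#'
#' @param gene_symbol Gene symbol.
#' @param inheritance_modes Subset of `c("AD","AR","XL")`.
#' @param phenotype_tags Character vector of controlled phenotype tags.
#' @param rating `"green"`, `"amber"` or `"red"` (diagnostic-grade,
#'   borderline, research).
#' @return One-row data frame (modes and tags comma-joined).
#' @export
panel_entry <- function(gene_symbol, inheritance_modes, phenotype_tags,
                        rating = "green") {
  stopifnot(length(inheritance_modes) >= 1L,
            all(inheritance_modes %in% c("AD", "AR", "XL")),
            rating %in% c("green", "amber", "red"))
  data.frame(gene_symbol = gene_symbol,
             inheritance_modes = paste(inheritance_modes, collapse = ","),
             phenotype_tags = paste(phenotype_tags, collapse = ","),
             rating = rating, stringsAsFactors = FALSE)
}

split_csv <- function(x) strsplit(x, ",", fixed = TRUE)[[1]]

#' Mode-of-inheritance compatibility
#'
#' A non-sporadic family pattern excludes genes lacking that mode (an AD
#' pedigree excludes AR-only genes and vice versa); sporadic cases are
#' compatible with all modes. Zygosity is then checked against every mode
#' the gene carries: AD passes for het (or hom); AR passes for hom, or het
#' with at least one additional rare allele reported in the same gene; XL
#' passes for hemizygous males, het females, or hom.
#'
#' @param family_pattern `"AD"`, `"AR"`, `"XL"` or `"sporadic"`.
#' @param sex `"male"`/`"female"` (used for XL).
#' @param zygosity `"het"`, `"hom"` or `"hemi"`.
#' @param gene_modes Character vector of the gene's modes.
#' @param other_alleles Count of additional rare alleles in the gene.
#' @return List with `pass` (logical) and `rationale` (character).
#' @export
moi_compatible <- function(family_pattern, sex, zygosity, gene_modes,
                           other_alleles = 0L) {
  if (!length(gene_modes))
    return(list(pass = FALSE, rationale = "not on panel"))
  if (family_pattern != "sporadic" && !(family_pattern %in% gene_modes))
    return(list(pass = FALSE,
                rationale = paste0("family pattern ", family_pattern,
                                   " incompatible with gene modes ",
                                   paste(gene_modes, collapse = "/"))))
  reasons <- character(0)
  for (m in gene_modes) {
    ok <- switch(m,
      AD = zygosity %in% c("het", "hom"),
      AR = zygosity == "hom" ||
        (zygosity == "het" && other_alleles >= 1L),
      XL = zygosity == "hemi" && identical(sex, "male") ||
        zygosity == "het" && identical(sex, "female") || zygosity == "hom",
      FALSE)
    if (ok) reasons <- c(reasons, paste0("compatible with ", m, " (", zygosity, ")"))
  }
  if (length(reasons)) return(list(pass = TRUE, rationale = reasons[1]))
  list(pass = FALSE, rationale = paste0("zygosity ", zygosity,
                                        " inconsistent with gene modes ",
                                        paste(gene_modes, collapse = "/")))
}

#' Prioritize candidate variants across cases
#'
#' A case variant becomes a candidate when it passes the rarity filter,
#' carries at least one filter-passing functional category, is compatible
#' with the gene's mode of inheritance given the family pattern and
#' zygosity, and the case's phenotype tags intersect the gene's panel tags.
#' Candidates in cases flagged `alternative_diagnosis` are emitted with a
#' screen warning, mirroring the alternative-diagnosis screen.
#'
#' @param cases Data frame with one row per case-variant observation:
#'   `case_id`, `cohort`, `phenotype_tags` (comma-joined), `family_pattern`,
#'   `sex`, `key`, `zygosity`, `other_alleles`, `alternative_diagnosis`
#'   (logical), `solved_status` (optional).
#' @param assignments Named list of [categorize()] results keyed by variant
#'   key.
#' @param annotated Data frame of annotated variants (needs `key`,
#'   `gene_symbol`, `max_population_af`).
#' @param panel Data frame of [panel_entry()] rows.
#' @param config A [classifier_config()].
#' @return Data frame of `CandidateVariant` rows: `case_id`, `key`, `gene`,
#'   `categories` (comma-joined passing set), `rating`, `rationale`,
#'   `screen_warning`.
#' @export
prioritize <- function(cases, assignments, annotated, panel,
                       config = classifier_config()) {
  out <- list()
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    av <- annotated[annotated$key == cs$key, , drop = FALSE]
    if (nrow(av) == 0L)
      stop("consistency error: case ", cs$case_id,
           " references unknown variant ", cs$key)
    av <- av[1, ]
    asg <- assignments[[cs$key]]
    if (is.null(asg)) next
    if (!rarity_filter(av$max_population_af, config)) next
    if (!length(asg$passing)) next
    pe <- panel[panel$gene_symbol == av$gene_symbol, , drop = FALSE]
    modes <- if (nrow(pe)) split_csv(pe$inheritance_modes[1]) else character(0)
    moi <- moi_compatible(cs$family_pattern, cs$sex, cs$zygosity, modes,
                          cs$other_alleles)
    if (!moi$pass) next
    gene_tags <- if (nrow(pe)) split_csv(pe$phenotype_tags[1]) else character(0)
    case_tags <- split_csv(cs$phenotype_tags)
    if (!length(intersect(gene_tags, case_tags))) next
    warn <- if (isTRUE(cs$alternative_diagnosis))
      "screen: case carries a possible alternative molecular diagnosis" else ""
    out[[length(out) + 1L]] <- data.frame(
      case_id = cs$case_id, key = cs$key, gene = av$gene_symbol,
      categories = paste(asg$passing, collapse = ","),
      rating = if (nrow(pe)) pe$rating[1] else NA_character_,
      rationale = paste0(moi$rationale, "; phenotype tags match: ",
                         paste(intersect(gene_tags, case_tags), collapse = ",")),
      screen_warning = warn, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(case_id = character(0), key = character(0),
                      gene = character(0), categories = character(0),
                      rating = character(0), rationale = character(0),
                      screen_warning = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
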