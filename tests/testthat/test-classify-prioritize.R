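av_base <- function(...) {
  av <- list(key = "k", spliceai_max = NA_real_, te_log2fc = NA_real_,
             mfe_fc = NA_real_, overlaps_tss = FALSE, overlaps_ires = FALSE,
             c_offset = NA_integer_, distance_to_junction = NA_integer_,
             within_near_splice = FALSE, events = NULL)
  utils::modifyList(av, list(...))
}

test_that("category filters sit exactly on the published boundaries", {
  cfg <- classifier_config()
  ## splicing: strict > 0.2 within the 25 bp window
  a <- categorize(av_base(within_near_splice = TRUE,
                          distance_to_junction = 1L, spliceai_max = 0.25), cfg)
  expect_equal(a$passing, "splicing")
  a <- categorize(av_base(within_near_splice = TRUE,
                          distance_to_junction = 1L, spliceai_max = 0.20), cfg)
  expect_equal(a$categories, "splicing")
  expect_length(a$passing, 0)
  a <- categorize(av_base(within_near_splice = TRUE,
                          distance_to_junction = 30L, spliceai_max = 0.9), cfg)
  expect_length(a$categories, 0)
  ## TE and MFE: inclusive thresholds
  expect_equal(categorize(av_base(te_log2fc = 0.5), cfg)$passing, "te_change")
  expect_length(categorize(av_base(te_log2fc = 0.49), cfg)$passing, 0)
  expect_equal(categorize(av_base(mfe_fc = -1.5), cfg)$passing, "mfe_change")
  expect_length(categorize(av_base(mfe_fc = 1.49), cfg)$passing, 0)
  ## Kozak positional filter
  expect_equal(categorize(av_base(c_offset = -6L), cfg)$passing,
               "kozak_alteration")
  k <- categorize(av_base(c_offset = -7L), cfg)
  expect_equal(k$categories, "kozak_alteration")
  expect_length(k$passing, 0)
  expect_length(categorize(av_base(c_offset = -11L), cfg)$categories, 0)
})

test_that("uAUG gain passes only in strong or moderate Kozak context", {
  cfg <- classifier_config()
  g <- uaug_gain_context()
  ev <- diff_uaug_events(g$ref_ctx, g$alt_ctx, g$utr_offset)
  a <- categorize(av_base(c_offset = -120L, events = ev), cfg)
  expect_equal(a$passing, "uaug_gained")
  weak <- ev
  weak$gained$kozak <- "weak"
  a <- categorize(av_base(c_offset = -120L, events = weak), cfg)
  expect_equal(a$categories, "uaug_gained")
  expect_length(a$passing, 0)
  ## uORF perturbation passes only for a natural uAUG loss
  loss <- list(events = "uaug_loss", gained = ev$gained[0, ],
               lost = ev$gained)
  expect_equal(categorize(av_base(events = loss), cfg)$passing, "uorf_change")
  stoploss <- list(events = "ustop_loss", gained = ev$gained[0, ],
                   lost = ev$gained[0, ])
  a <- categorize(av_base(events = stoploss), cfg)
  expect_equal(a$categories, "uorf_change")
  expect_length(a$passing, 0)
})

test_that("intronic near-splice variants are eligible only for splicing", {
  cfg <- classifier_config()
  a <- categorize(av_base(within_near_splice = TRUE,
                          distance_to_junction = 2L, spliceai_max = 0.5,
                          te_log2fc = 0.9, mfe_fc = 3, overlaps_tss = TRUE),
                  cfg)
  expect_equal(a$categories, "splicing")
})

test_that("multi-category variants are flagged", {
  cfg <- classifier_config()
  a <- categorize(av_base(mfe_fc = 2, overlaps_tss = TRUE), cfg)
  expect_setequal(a$passing, c("mfe_change", "tss_or_ires"))
  expect_true(a$multi_category)
})

test_that("rarity gate is strict below 2% and passes absence", {
  expect_true(rarity_filter(0.019))
  expect_false(rarity_filter(0.02))
  expect_true(rarity_filter(NA))
})

test_that("summary partitions the total and percents sum to 100", {
  cfg <- classifier_config()
  asg <- list(categorize(av_base(key = "a", mfe_fc = 2), cfg),
              categorize(av_base(key = "b", mfe_fc = 2, overlaps_tss = TRUE), cfg),
              categorize(av_base(key = "c", te_log2fc = 1), cfg),
              categorize(av_base(key = "d", overlaps_ires = TRUE), cfg))
  tbl <- summarize_categories(asg, c("GE", "GE", "CMGG", "GE"))
  tot <- tbl[tbl$category == "Total", ]
  expect_equal(tot$total, 4)
  expect_equal(tbl$total[tbl$category == "> 1 category"], 1)
  body <- tbl[tbl$category != "Total", ]
  expect_equal(sum(body$total), tot$total)
  expect_lt(abs(sum(body$percent) - 100), 0.05)
  expect_equal(sum(body$GE), 3)
  ## single variant, single category
  one <- summarize_categories(asg[3], "GE")
  expect_equal(one$percent[one$category == "te_change"], 100)
  expect_true(all(one$percent[!one$category %in% c("te_change", "Total")] == 0))
})

test_that("inheritance compatibility follows mode, pattern and zygosity", {
  expect_true(moi_compatible("sporadic", "male", "hom", "AR")$pass)
  expect_true(moi_compatible("AD", "female", "het", "AD")$pass)
  expect_true(moi_compatible("sporadic", "male", "hemi", "XL")$pass)
  ## AR het needs a second allele in the gene
  expect_false(moi_compatible("AR", "female", "het", "AR")$pass)
  expect_true(moi_compatible("AR", "female", "het", "AR",
                             other_alleles = 1)$pass)
  ## pattern excludes genes lacking the mode
  expect_false(moi_compatible("AD", "female", "het", "AR")$pass)
  expect_false(moi_compatible("AR", "female", "hom", "AD")$pass)
  ## dual-mode gene: AR-pattern het passes through the dominant mode
  expect_true(moi_compatible("AR", "female", "het", c("AD", "AR"))$pass)
  ## XL female heterozygote in an XL family
  expect_true(moi_compatible("XL", "female", "het", "XL")$pass)
  expect_false(moi_compatible("XL", "male", "het", "XL")$pass)
  expect_equal(moi_compatible("AD", "male", "het", character(0))$rationale,
               "not on panel")
})

test_that("prioritization is a monotone conjunction of its gates", {
  r <- table2_replica()
  cand <- prioritize(r$cases, r$assignments, r$annotated, r$panel, r$config)
  expect_true(all(cand$key %in% names(r$assignments)))
  ## relaxing the phenotype gate (tags superset) never shrinks the list
  panel_all <- r$panel
  panel_all$phenotype_tags <- paste(panel_all$phenotype_tags,
                                    "retinal-dystrophy", sep = ",")
  cases_all <- r$cases
  cases_all$phenotype_tags <- paste(cases_all$phenotype_tags,
                                    "retinal-dystrophy", sep = ",")
  more <- prioritize(cases_all, r$assignments, r$annotated, panel_all,
                     r$config)
  expect_true(all(cand$key %in% more$key))
  ## permuting case order leaves the candidate set unchanged
  perm <- prioritize(r$cases[rev(seq_len(nrow(r$cases))), ], r$assignments,
                     r$annotated, r$panel, r$config)
  expect_setequal(paste(perm$case_id, perm$key),
                  paste(cand$case_id, cand$key))
  ## unknown variant key is a consistency error
  bad <- r$cases[1, ]
  bad$key <- "chr1:1:A:T"
  expect_error(prioritize(bad, r$assignments, r$annotated, r$panel,
                          r$config), "consistency error")
  ## a case failing only phenotype overlap is excluded
  mism <- r$cases[1, ]
  mism$phenotype_tags <- "unrelated"
  expect_equal(nrow(prioritize(mism, r$assignments, r$annotated, r$panel,
                               r$config)), 0)
})

test_that("alternative-diagnosis cases carry a screen warning", {
  r <- table2_replica()
  cs <- r$cases
  cs$alternative_diagnosis[cs$case_id == "F5"] <- TRUE
  cand <- prioritize(cs, r$assignments, r$annotated, r$panel, r$config)
  expect_equal(nrow(cand), 11)
  expect_match(cand$screen_warning[cand$case_id == "F5"], "screen")
  expect_equal(cand$screen_warning[cand$case_id == "F4"], "")
})
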