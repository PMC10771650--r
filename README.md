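# utr5screen

Isoform-aware interpretation of 5′ untranslated region (5′UTR) variants in
Mendelian disease genes, implemented as a tested R pipeline.

5′UTRs modulate protein translation through upstream open reading frames
(uORFs), the Kozak context of the main start codon, mRNA secondary structure,
and cap-independent entry elements (IRES). Variants in these regions are
routinely skipped by diagnostic tiering pipelines because their consequences
are not protein-coding. `utr5screen` closes that gap for gene-panel
diagnostics (the design target is inherited retinal disease, but nothing in
the package is retina-specific): it selects the clinically relevant
isoforms per gene from tissue expression data, restricts the search space to
their 5′UTRs plus near-splice intronic flanks, annotates candidate variants
with sequence-level and table-supplied evidence, classifies them into seven
functional categories, and prioritizes candidates by family inheritance
pattern and phenotype.

## The method in brief

1. **Isoform selection.** From a transcript × sample TPM matrix, the mean
   abundance of every protein-coding isoform is computed. Per gene the
   canonical transcript is always retained; if the top-mean isoform is
   non-canonical it is retained as the tissue-enriched isoform (≤ 2
   transcripts per gene). The 5′UTRs of the two isoforms are compared and
   classed as fully distinct, partly overlapping, or fully overlapping
   (containment of the shorter in the longer).
2. **Search space.** For each selected transcript the 5′UTR exons are
   emitted together with ±25 bp intronic near-splice flanks at 5′UTR splice
   junctions (no flank on the promoter side, CDS bases trimmed), sorted into
   a BED-serializable analysis file. Exome capture designs can be audited
   against the per-gene 5′UTR union (strict or padded baits).
3. **Variant annotation.** VCF records overlapping the analysis regions are
   kept when at least one carrier call has DP > 10 and GQ > 15. Each variant
   is mapped to HGVS-style c. coordinates (`c.-123`, `c.-9+1`, …), rescanned
   for uAUG/uORF gains and losses against the reference 5′UTR, and joined
   with external evidence: population allele frequency, SpliceAI delta
   scores, translational-efficiency (TE) log2 fold change,
   secondary-structure minimum-free-energy (MFE) fold change, and CAGE
   TSS / IRES interval overlap.
4. **Classification.** Seven non-mutually-exclusive categories with
   per-category filters: (i) uAUG gained — kept if the created AUG lies in a
   strong or moderate Kozak context (−3 purine / +4 G rule); (ii) change in
   an existing uORF — kept for natural uAUG loss; (iii) primary Kozak
   alteration — kept at positions −3, −4, −5, −6, −9; (iv) splicing — kept
   within ±25 bp of a junction with any SpliceAI delta > 0.2; (v) TE —
   |log2FC| ≥ 0.5; (vi) MFE — |FC| ≥ 1.5; (vii) retinal TSS and/or IRES
   overlap. A rarity gate (MAF < 2 % in all populations, absence counts as
   rare) precedes all category filters.
5. **Prioritization.** A variant becomes a candidate when it passes rarity
   and at least one category filter, its zygosity is compatible with a mode
   of inheritance of the gene given the family pattern (AD/AR/XL, sporadic
   compatible with all), and the case phenotype tags intersect the gene's
   panel tags.

A synthetic-data generator (`simulate_cohort()`) writes every input format
with planted ground truth — including plants on both sides of every
threshold — so the whole pipeline is testable offline.

## Worked example

A single-nucleotide substitution creating an upstream AUG in a strong Kozak
context, with an in-frame stop codon starting 75 nt downstream inside the
5′UTR:

```r
library(utr5screen)
g  <- uaug_gain_context(utr_len = 130, aug_offset = 7, stop_offset = 75)
ev <- diff_uaug_events(g$ref_ctx, g$alt_ctx, g$utr_offset)
ev$gained
#>   start_c frame_vs_cds stop_c         orf_type  kozak peptide_length_aa
#> 1    -123     in_frame    -46 uorf_stop_in_utr strong                25
```

The gained uORF starts at c.−123, ends at an in-UTR stop, and encodes a
25-amino-acid peptide (initiator Met included) — the classic uORF mechanism
by which a 5′UTR variant suppresses translation of the primary ORF.

Running the prioritizer over the package's eleven-candidate replica fixture
(each case encoded with its reported zygosity, MAF, functional category,
family pattern and a matching gene panel):

```r
r <- table2_replica()
prioritize(r$cases, r$assignments, r$annotated, r$panel, r$config)
#>    case_id   gene             categories rating
#> 1       F1  RDH12            uaug_gained  green
#> 2       F2  NPHP4            uaug_gained  green
#> 3       F3 NMNAT1               splicing  green
#> ...
#> 11     F11  PRPF4       kozak_alteration  green
```

Eleven candidates in ten genes; four of them splicing-category.

An end-to-end run on synthetic data:

```r
s   <- simulate_cohort(sim_config(seed = 1), dir = "synthetic")
res <- run_pipeline(list(gtf = s$gtf, fasta = s$fasta,
                         expression = s$expression, panel = s$panel,
                         vcf = s$vcf, af = s$af, spliceai = s$spliceai,
                         te = s$te, mfe = s$mfe, tss = s$tss, ires = s$ires,
                         capture = s$capture, cases = s$cases_path),
                    out_dir = "out")
res$candidates    # matches s$expected_candidates
```

The same two stages are exposed as a thin command-line wrapper:

```sh
Rscript inst/scripts/utr5screen.R simulate --seed 1 --out synthetic
Rscript inst/scripts/utr5screen.R run --dir synthetic --out out
```

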