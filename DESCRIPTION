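Package: utr5screen
Title: Annotation, Classification and Prioritization of 5'UTR Variants in
    Mendelian Disease Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An isoform-aware pipeline for interpreting 5' untranslated region
    (5'UTR) variants in Mendelian disease genes. Selects the canonical and the
    most highly expressed non-canonical protein-coding isoform per gene from a
    transcript-level TPM matrix, builds a sorted 5'UTR analysis region file
    (UTR exons plus 25 bp near-splice intronic flanks), audits exome-capture
    coverage of the selected 5'UTRs, annotates variants with sequence-level
    5'UTR consequences (uORF creation and perturbation, Kozak context),
    integrates external evidence (population allele frequency, SpliceAI delta
    scores, translational efficiency and secondary-structure fold changes,
    CAGE TSS and IRES overlap), classifies variants into seven functional
    categories with per-category filters, and prioritizes candidates by mode
    of inheritance and phenotype compatibility. Ships a synthetic-data
    generator that plants machine-readable ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    SummarizedExperiment,
    IRanges,
    S4Vectors,
    VariantAnnotation,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
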