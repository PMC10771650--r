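---
title: "Interpreting 5'UTR variants in disease gene panels with utr5screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting 5'UTR variants in disease gene panels with utr5screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(utr5screen)
```

## The problem

5' untranslated regions sit between the transcription start site and the
main AUG and control how efficiently the downstream open reading frame is
translated. Four mechanisms dominate clinical interpretation of variants in
these regions:

* creation of an upstream AUG (uAUG), which captures scanning ribosomes and
  can suppress translation of the primary ORF — most strongly when the new
  AUG sits in a favourable Kozak context and opens a uORF with its own stop
  codon inside the UTR;
* perturbation of an existing uORF (loss of its uAUG or stop codon, or a
  frame-disrupting indel);
* disruption of splicing when the 5'UTR is itself spliced; and
* effects on translation-regulatory structure: the primary Kozak context,
  RNA secondary structure, transcription start sites and internal ribosome
  entry sites (IRES).

Diagnostic pipelines built around protein-coding consequences miss all of
these. `utr5screen` packages the interpretation workflow — isoform-aware
region selection, annotation, seven-category classification and
inheritance/phenotype-aware prioritization — as composable R functions with
a synthetic-data generator that makes every stage testable offline.

## Data model and coordinate conventions

All internal coordinates are 0-based half-open; conversion to and from the
1-based inclusive conventions of GTF and VCF happens only at the I/O
boundary. This makes interval arithmetic (lengths, intersections, flanks)
free of off-by-one cases, at the cost of one conversion per parser.

c. positions follow the HGVS convention: there is no position 0, `c.-1` is
the base immediately 5' of the A of the main AUG, and intronic bases inside
a 5'UTR intron are written relative to the nearer exon edge (`c.-9+1` one
base past a donor, `c.-8-2` two bases before an acceptor). When a position
is exactly equidistant from both edges the donor side is used. The mapping
is exactly invertible, and the test suite asserts the round trip on every
exonic and 5'UTR-intronic base of every synthetic transcript.

Only protein-coding transcripts are modelled; others are dropped at load
time with a logged count. A transcript is treated as canonical when its GTF
`tag` attribute carries either the annotation's canonical tag or a MANE tag
(which one fired is kept on the model), since gene-panel releases differ in
which of the two they set.

## Isoform selection

Per-transcript abundance is the plain arithmetic mean of TPM across all
supplied samples — no filtering, transformation or outlier handling, so the
selection is exactly reproducible from the matrix. Per gene, the canonical
transcript is always retained; the top-mean protein-coding isoform is
additionally retained when it is non-canonical. Ties resolve to the
canonical transcript, and among non-canonical ties to the smallest
transcript id, making the selection deterministic and invariant to sample
order (both properties are tested).

The two retained 5'UTRs are compared by genomic intersection. "Fully
overlapping" is implemented as containment of the shorter UTR in the longer
one (shared bases equal the shorter length). The boundary case where two
UTRs share their entire common span without containment is classed as
partly overlapping; this is a design choice — the three-way vocabulary does
not fix it — and it is stated here rather than hidden in code.

## The analysis region file

For every selected transcript the 5'UTR exons are emitted, plus a donor and
an acceptor flank of 25 intronic bases at each splice junction internal to
the 5'UTR. Three deliberate exclusions:

* no flank is emitted upstream of the transcription start — that is
  promoter territory, and promoter variation is out of scope;
* flank bases that would fall inside the transcript's own CDS are trimmed;
* near-splice flanks are excluded from the capture-audit denominator, which
  measures "fraction of the 5'UTR captured", not of the search space.

For the capture audit the gene-level 5'UTR is the genomic union over the
gene's (≤ 2) selected isoforms; the report header records this rule.
Padding a design by ±N bp extends every bait symmetrically, and coverage is
monotone in both padding and bait set (tested as a property).

## Sequence-effect annotation

`scan_uorfs()` records one entry per ATG in the UTR; reading continues into
the CDS (truncated at 999 nt, enough to type CDS-overlapping ORFs) until
the first in-frame stop (`TAA`, `TAG`, `TGA`). Three ORF types result:
a uORF whose stop codon ends inside the UTR; an out-of-frame ORF
overlapping the CDS; and an in-frame CDS extension. Peptide length counts
codons from the initiator Met up to (not including) the stop, so a stop
codon whose first base is 75 nt downstream of the uAUG yields a 25-residue
peptide. Codons containing `N` flag the record ambiguous and exclude it
from typing. The scanner is verified against an independent brute-force
enumerator on 1,000 random sequences (lengths 0–300, GC 0.3–0.7).

Kozak strength uses the standard two-feature rule: strong when position −3
holds a purine and +4 holds G, moderate when exactly one condition holds,
weak otherwise. Bases beyond the available sequence count as non-matching.
A tissue-specific Kozak consensus can be supplied for reporting, but the
classifier's Kozak-category filter is purely positional (window −10..−1,
prioritized positions −3, −4, −5, −6, −9), so no consensus string
influences any gate.

Variant diffing rescans reference and alternate contexts and matches uORFs
on their c. position (invariant to indels between the uAUG and the main
AUG). Gains and losses are set differences; a stop loss is an existing
in-UTR-stop uORF whose alternate context no longer stops before the CDS;
an indel changing UTR length mod 3 inside an existing uORF adds a
frame-shift event. Indels are expected left-normalized; applying a variant
and its exact reverse restores the reference event set (tested).

## Classification and prioritization

Filter boundaries are implemented exactly as stated by their sources:
rarity and SpliceAI are strict (`MAF < 0.02`, `delta > 0.2`), TE and MFE
are inclusive (`|log2FC| >= 0.5`, `|FC| >= 1.5`). A variant absent from all
population tables passes rarity — absence from reference populations is
evidence of rarity, not missing data — while absent functional evidence
simply withholds the corresponding category rather than fabricating a zero.
Intronic near-splice variants are eligible only for the splicing category;
the other six require an exonic 5'UTR position. Categories are
evidence-driven and independent; the cohort summary counts only
filter-passing categories, with multi-category variants pooled into one
"> 1 category" row so the rows partition the total.

The DP/GQ sequencing gate is applied per carrier: a site is kept when at
least one carrier call exceeds both thresholds. Whether the original
filtering was per-call or per-site is not derivable from the workflow's
description; the per-carrier rule is the more faithful reading of
call-level filtering and is recorded in the report header.

Inheritance compatibility works in two steps. A non-sporadic family
pattern first excludes genes that lack the pattern's mode (an AD pedigree
excludes AR-only genes and vice versa); sporadic cases are compatible with
every mode. Zygosity is then checked against each mode the gene carries:
AD accepts heterozygotes (and homozygotes), AR accepts homozygotes or
heterozygotes with at least one additional rare allele reported in the same
gene, XL accepts hemizygous males, heterozygous females and homozygotes.
One consequence is deliberate: a heterozygous variant in a gene linked to
both dominant and recessive disease passes in a recessive-pattern family
through the dominant mode. Real candidate sets contain exactly this
configuration (a dominant gain-of-function hypothesis in a family with two
affected siblings), and a rule keyed only on the family pattern would
silently drop it. Phenotype compatibility is a non-empty intersection of
controlled tags — no ontology reasoning. The panel rating (green/amber/red)
is carried into the candidate rationale but is not a gate.

## The synthetic-data generator

`simulate_cohort()` emulates the full input bundle: a multi-contig genome
(one gene per contig, both strands, the last contig named `chrX` to host
X-linked cases), GTF annotation with canonical and non-canonical isoforms,
a TPM matrix, a VCF, evidence tables, TSS/IRES/capture BEDs, a gene panel
and case metadata. Design choices that matter for interpreting test
results:

* Synthetic 5'UTRs are drawn from the {A, C, G} alphabet. With no T, a
  reference UTR can contain neither an ATG nor a stop codon, so every
  start/stop event observed downstream is a planted one and truth recovery
  is exact rather than probabilistic.
* Defaults are 10 genes, half with spliced (40+30 nt) and half with
  contiguous 70 nt UTRs, 93 nt CDS, main-AUG Kozak classes cycling
  strong/moderate/weak, 40% of genes with a planted non-canonical
  expression-top isoform (4× mean multiplier, log-normal noise with
  sdlog 0.3 over 20 samples), and overlap classes cycling through the
  three-way vocabulary. Contigs are a few kilobases, so a full simulate +
  pipeline run takes seconds; these sizes are the package's chosen test
  scale and are stated here because recovery statistics quoted in the
  tests refer to them.
* Every category receives at least one plant on each side of its
  threshold: Kozak-strength pass/fail uAUG gains, a natural-uORF uAUG loss
  and a stop loss, Kozak positions −3/−7/−11, donor +1/+2 SpliceAI
  0.25/0.15 plus a +30 decoy outside the flank, TE ±0.6/−0.4, MFE
  2.0/1.2, TSS/IRES hits and a 1 bp near miss, allele frequencies
  0.019/0.02/absent, and DP/GQ calls at 11/16, 10 and 15.
* One RNG stream per output file, each derived from the master seed, so
  identical configs are byte-identical (tested by hashing) and adding an
  output file never perturbs the others.

What the generator does **not** emulate: read-level sequencing error,
population-genetic AF structure, realistic splice-site motifs (SpliceAI
scores are table-planted, not predicted), overlapping genes, or UTRs with
biological base composition. Passing the planted-truth suite therefore
demonstrates that the pipeline's logic — gates, thresholds, coordinate
arithmetic, event detection — is correct, not that the external predictors
it consumes are accurate on real data.

The internal base-pairing score (`internal_mfe_proxy()`, a Nussinov-style
dynamic program over Watson–Crick + GU pairs with minimum loop 3) exists so
the generator and tests can manufacture self-consistent secondary-structure
fixtures; production MFE fold changes always come from external tables, and
no scientific claim rests on the proxy.

## Numerical and degenerate-input choices

* Thresholds sit exactly on their stated boundaries; equality fails the
  strict gates (MAF 0.02, SpliceAI 0.20) and passes the inclusive ones
  (TE 0.5, MFE 1.5). Tests pin each boundary from both sides.
* An empty 5'UTR (transcript starting at the CDS) yields an empty region
  set, zero-length coverage denominators report `NA` percent, and an empty
  capture design reports zero coverage with a warning.
* Multi-allelic VCF records are split before any gate; carrier detection
  accepts any genotype containing a non-reference allele.
* Summary percentages are rounded to 2 decimals; the partition identity is
  asserted before rounding, and the rounded column is required to sum to
  100 within 0.05.

## Known limitations

* Near-cognate start codons (CUG/GUG) are not scanned; only AUG-initiated
  uORFs are modelled.
* Event detection for indels relies on left-normalized input and c.-position
  matching; complex substitutions are not decomposed.
* The capture audit measures bait overlap, not empirical read depth.
* MOI logic does not model compound heterozygosity phase, penetrance, or
  de novo status beyond the sporadic pattern.
* ClinVar filtering trusts the table's molecular-consequence annotation for
  the canonical transcript rather than recomputing consequences.
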