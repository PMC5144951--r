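---
title: "Comparing sequencing technologies with SMU analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing sequencing technologies with SMU analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smucompare)
```

# The problem

De novo transcriptome assemblies from different sequencing technologies —
deep, accurate short reads versus long, noisy full-length cDNA reads — differ
in transcript length, completeness, and isoform diversity. When a draft
genome exists, even a fragmented one, it can arbitrate: each technology's
transcripts are spliced-aligned to the genome and compared locus by locus.
This package implements that arbitration as a reusable pipeline: single
mapping unit (SMU) analysis, splice-variant classification, full-length
completeness scoring, mapping rates, rarefaction, and miRNA precursor triage,
together with a synthetic generator that makes every stage testable.

# The SMU model

An alignment record carries a query span, a target span, match and block
counts, and a CIGAR over `{M, =, X, I, D, N}`. Two derived quantities drive
all filtering:

* **query coverage** = (q_end − q_start) / query_len — the fraction of the
  transcript that aligned, and
* **percent identity** = n_match / block_len — matches over all alignment
  columns, so indels count against identity.

The identity denominator is a design choice: spliced aligners report both
conventions, and "indels in the denominator" (PAF columns 10/11) is the
dominant one; it is the one implemented. Thresholds are inclusive (`>=`),
reading "at 98%" as attainment. Exon chains are obtained by splitting the
CIGAR on `N` operations; `M`, `=`, `X` and `D` consume target within exons.
An `N` at either CIGAR terminus is rejected — an intron cannot flank an
alignment.

A transcript of the reference set is classified after filtering at the SMU
thresholds (default 100% coverage / 90% identity): zero retained locations is
`unmapped`, exactly one is an `smu`, two or more is `multi`. The upstream
description of multi-mappers ("more than two locations") is ambiguous about
exactly two; because "one location in the genome" is the operative SMU
definition, `multi` here means *at least two*, so the three statuses
partition every input. Each SMU is anchored by its own reference transcript;
overlapping reference transcripts deliberately yield distinct, overlapping
SMUs rather than merged loci, since merging rules are not part of the SMU
definition and would entangle antisense and nested genes.

Membership is exon-aware: a technology transcript joins an SMU only on the
same scaffold and strand with at least 1 bp of exon-level overlap with the
reference exon chain. Span-level overlap would wrongly join transcripts lying
entirely inside a reference intron.

## Per-SMU statistics

The length of a splice variant is its **summed exon length**. Per SMU and
technology, the longest variant defines the technology's contribution; the
best set is the argmax over technologies present. Ties are recorded rather
than broken — the pipeline reports both "best (possibly shared)" counts and
"uniquely best" counts, which are different statistics. Coverage improvement
is defined only under a unique best: the difference between the best
technology's longest variant and each other technology's longest variant
(1000/600/250 nt → 400 and 750 nt). Tied SMUs are skipped with a warning.

Nonredundant variant counts collapse members by their **intron chain** (the
ordered intron intervals), ignoring terminal coordinates: length variants of
one splice structure count once, and all intron-less members form one class.
Terminal variation is counted separately by the variant classifier, so
counting it here too would double-report.

The per-SMU mean uses Tukey fences (Q1 − 1.5·IQR, Q3 + 1.5·IQR) with
linearly interpolated quartiles (R's type-7 quantile); the outlier rule is
not dictated by any upstream definition, so the standard parameter-free
choice was taken and is switchable (`outlier_rule = "none"`).

# Splice-variant taxonomy

Candidate exon chains are classified against the SMU reference chain into
`identical`, `alt_start`, `premature_stop`, `intron_retention`,
`exon_skipping` and `complex`:

* `identical`: same intron set and same terminal coordinates (exclusive).
* `intron_retention`: a reference intron lies entirely inside a candidate
  exon; each such intron is counted.
* `exon_skipping`: a candidate intron entirely contains a reference exon;
  each skipped exon is counted.
* `alt_start` / `premature_stop`: the 5′ or 3′ terminus differs, resolved by
  strand (on `-`, the genomic high end is 5′). Both labels are emitted when
  both termini differ; summaries additionally report a pooled
  `length_variant` column.
* `complex`: any intron boundary difference not explained by the rules above
  (including introns partially outside the shared span, shifted splice
  sites, and novel introns inside reference exons).

Event labels may co-occur (e.g. a retention with a shortened 5′ end).
Boundary comparison is exact (0 bp tolerance): the synthetic truth is exact,
and real aligner wobble should be absorbed upstream, not here.

One property worth stating explicitly: the taxonomy is **not symmetric**.
Swapping candidate and reference of an intron-retention pair does not yield
exon skipping — seen from the other side, the event is a novel intron inside
a reference exon, which falls to `complex`. The test suite pins this down
with constructed single-event pairs, and verifies the classifier
exhaustively against an independent brute-force implementation (explicit
base-position sets and interval relations) on every pair of exon chains with
up to three exons over an 11-point coordinate grid.

# Completeness and rarefaction

H-category scoring takes a protein hit table (12-column tabular alignment
format with a length sidecar, or a 14-column dialect with qlen/slen). Per
query the best hit is the lowest e-value, ties broken by the product of
query and target coverage — best-hit semantics are not specified upstream,
and this is standard practice. H1 counts queries with any hit; H2 requires
query coverage ≥ 0.70 of the transcript (nt); H3 additionally target
coverage ≥ 0.70 of the protein (aa) — each sequence in its own units. The
ordering H3 ≤ H2 ≤ H1 ≤ T is asserted on every call.

Mapping rate is the fraction of transcripts with at least one alignment
passing a coverage/identity pair; the defaults report 98/98 and 90/98. N50
uses the "largest L with cumulative length ≥ half the total" convention.

Rarefaction supports the exact hypergeometric expectation
E[S(n)] = Σᵢ (1 − C(N−cᵢ, n)/C(N, n)), computed with log-binomials for
stability, and a Monte Carlo mode (subsampling reads without replacement).
When more than `subsample_transcripts` (default 1000) transcripts are
present, a seeded uniform transcript subset is drawn first, following the
usual practice of rarefying a manageable random subset. Tests cross-check
the analytic curve against `vegan::rarefy` and the Monte Carlo mode to
within three standard errors.

# miRNA precursor triage

Candidates arrive with a sequence, a mature interval, and a pre-computed
minimum free energy (MFE); folding itself is out of scope and the MFE is
consumed, not computed. Mature matching is plain Hamming distance against
known matures of equal length (U/T equivalent, no gaps — "two mismatches"
means substitutions), ties going to the lexicographically smallest family.
MFEI = ((MFE/length)·100)/(GC·100); candidates are rejected if unmatched or
if MFEI exceeds −0.85. Accepted candidates are flagged low quality when they
look like fold-back repeats: longer than `long_precursor_nt` (default 250)
with MFEI below `mfei_floor` (default −2.0). Both thresholds are exposed;
the defaults bracket the 60–307 nt precursor range typical of such surveys.
Finally, predictions on one source transcript whose matures reverse-
complement match within the allowance (the two arms of one duplex) collapse
to the lowest-MFEI representative.

# The synthetic generator

The generator is first-class, tested code; it defines the study conditions
under which the pipeline's properties are verified.

* **Genome**: i.i.d. bases at a target GC (default 0.42, the range typical
  of conifer transcript sets); scaffolds of 200 kb by default.
* **Gene models**: 3–5 exons of 120–400 nt, introns of 60–300 nt, placed
  without overlap with 500 nt gaps. The reference isoform is a stop-free CDS
  (ATG…TAA) spliced over the exons, so the protein database is exactly its
  translation. Alternative isoforms are drawn from a menu of planted events
  — identical, alternative start, premature stop, intron retention, exon
  skipping — constructed so the classifier must recover the planted label
  exactly at zero noise. `floor(dup_fraction × n_genes)` genes are copied to
  a second locus with identical sequence, making their transcripts
  multi-mappers by construction.
* **Transcript sets**: isoforms are sampled per gene with Poisson draws
  (with replacement, deduplicated), exhaustively, or reference-only (used
  for the combined reference set). Substitutions and single-base indels are
  i.i.d. per base — no homopolymer model, which is sufficient to stress the
  identity thresholds. The truth PAF carries the exact exon chain of every
  transcript.
* **Truncation** is modelled as *clipped alignment flanks*: the emitted
  transcript keeps its full sequence and the truth alignment covers an
  interior span (q_start > 0 after a 5′ event). This is the coherent reading
  of truncation in a truth-alignment world — a physically trimmed sequence
  would simply re-align end to end and never stress a coverage threshold —
  and it doubles as a model of incompletely aligned transcript ends against
  a fragmented draft genome. Each technology also draws a characteristic
  length cap N(mean_len, len_sd) emulating assembly fragmentation; the
  excess is clipped from a random end.
* **Read counts**: negative binomial, mean = profile depth, dispersion 0.3
  (typical RNA-seq overdispersion; configurable).

The default profiles contrast the three platforms qualitatively: `hiseq`
(deep, accurate, fragmented: 0.4% substitutions, 25% truncation chance per
end, 1.6 isoform draws per gene, depth 300), `miseq` (similar, shallower),
and `pacbio` (long and isoform-rich but noisy: 2% substitutions, 3% indels,
3.7 isoform draws, depth 12). The isoform sampling depths mirror the per-SMU
splice-variant means observed in short- versus long-read comparisons of this
kind. What the generator does *not* emulate: repeat landscapes and
pseudogenes, rRNA contamination, chimeric reads, homopolymer error
structure, and expression-dependent isoform sampling. Passing tests
therefore demonstrate the correctness of the computations under controlled
conditions, not the field behaviour of any particular instrument.

# Pipeline and reproducibility

`run_comparison()` drives simulate → SMU → classify → completeness →
rarefaction from a single configuration (an R list or a YAML file); all
randomness flows from one seed, and stage seeds are fixed offsets of it, so
a repeated run is byte-identical. Every number in `summary.json` is
recomputable from the stage TSVs. The default run uses 120 genes on a 1 Mb
genome; the acceptance test exercises 200 genes at zero noise and recovers
100% of planted variant labels and SMU/multi statuses. Best-technology
statistics are computed over the SMUs covered by all technologies, matching
how such comparisons are reported.

```{r example}
stats <- local({
  ref <- parse_paf(paste("ref", 1000, 0, 1000, "+", "s1", 1e6, 1000, 2200,
                         1000, 1000, 60, "cg:Z:600M200N400M", sep = "\t"))
  smus <- build_smus(classify_mapping_status(ref), ref)
  tech <- list(
    hiseq = parse_paf(paste("h1", 1000, 0, 1000, "+", "s1", 1e6, 1000, 2200,
                            1000, 1000, 60, "cg:Z:600M200N400M", sep = "\t")),
    miseq = parse_paf(paste("m1", 600, 0, 600, "+", "s1", 1e6, 1000, 1600,
                            600, 600, 60, "cg:Z:600M", sep = "\t")),
    pacbio = parse_paf(paste("p1", 250, 0, 250, "+", "s1", 1e6, 1000, 1250,
                             250, 250, 60, "cg:Z:250M", sep = "\t")))
  smus <- assign_members(smus, tech)
  coverage_improvement(smus[[1]])
})
stats
```

# Known limitations

* SAM/BAM input is not parsed; convert to PAF upstream.
* SMUs are not merged into gene loci; expression quantification and
  differential expression are out of scope.
* The classifier's 0 bp boundary tolerance is right for synthetic truth but
  strict for real aligner output; a tolerance parameter is the natural
  extension point.
* Whether H-categories should use any-hit rather than best-hit semantics is
  a sensitivity question the implementation leaves to the caller (filter the
  hit table before scoring to emulate any-hit).
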