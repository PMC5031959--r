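---
title: "Methods: small-RNA and degradome analysis in heatmiR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-RNA and degradome analysis in heatmiR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatmiR)
```

## Overview

heatmiR reimplements, as a tested pipeline, the classical plant
small-RNA-seq + degradome (PARE) workflow for identifying conserved and
novel miRNAs, calling condition-responsive differential expression,
validating miRNA targets from degradome cleavage signatures, and running
hypergeometric term enrichment. The emulated study design is three
single-sample libraries from one plant — a control and two treatment
conditions — with matched degradome libraries. Every stage is exercised
end to end on synthetic libraries with planted ground truth, so the
pipeline is testable without any external download.

## Preprocessing

Raw reads are adapter-trimmed (leftmost full match of the 3' adapter, or
a read-terminal partial match of at least 8 adapter bases; reads without
a qualifying match are removed), filtered to 19–24 nt inserts, cleaned of
junk reads, collapsed to unique tags with per-library counts, and
annotated against contaminant references (rRNA, tRNA, snoRNA, snRNA,
other Rfam-style ncRNA, mRNA, repeats) by exact substring membership.

Two operational decisions deserve mention:

* **Junk definition.** The source workflows never define "junk reads";
  here a read is junk when it contains an ambiguous base (N) or is at
  least 80% one nucleotide. The threshold is configurable
  (`homopolymer_frac`). Because N-containing reads are always junk,
  ambiguous bases never survive preprocessing.
* **Single-label precedence.** Published accounting tables of this kind
  have overlapping rows (their categories do not sum to raw − valid). We
  impose the fixed precedence rRNA > tRNA > snoRNA > snRNA > other Rfam >
  mRNA > repeat > valid so that the cascade is a partition and the
  conservation invariant — raw = adapter/length + junk + Σ classes +
  valid — is exactly testable. Exact substring matching (no mismatches)
  keeps annotation deterministic and oracle-checkable.

`library_summary()` recomputes every percentage from counts: total
percentages against the raw read count and unique percentages against
the unique raw count, to two decimals.

## Hairpin model

Precursor screening needs a secondary structure, a minimum free energy
(MFE) and the minimal folding free energy index,

MFEI = (|MFE| / length × 100) / GC%.

`fold_internal()` is a deliberately simplified, fully deterministic
folding engine: a Nussinov-style dynamic program over weighted pairs
(GC −3.0, AU −2.0, GU −1.0 kcal/mol), minimum hairpin loop 3 nt, no
pseudoknots, with a deterministic traceback that prefers the pairing
whose 5' partner is earliest. It is *not* a thermodynamic model — no
stacking, no entropy — but it is exact (verified against exhaustive
structure enumeration), fast, and sufficient to build and screen
stem-loops. Externally computed structures (e.g. from a full
thermodynamic folder) can be supplied to `hairpin_record()` via its
`structure`/`mfe` arguments and flow through the same validation.

One property worth recording: folding is invariant under sequence
*reversal* (the pair-score table is symmetric) but **not** under reverse
complementation, because a G:U wobble pair complements to A:C, which
cannot pair. The test suite checks the reversal invariance.

"Stable hairpin" is operationalized as (a) a single terminal loop,
(b) the mature span entirely within one arm, (c) at least 16 mature
bases paired (`mature_pair_min`, configurable), and — for novel
candidates only — (d) MFEI ≥ 0.80. Criteria (a)–(c) are this package's
own definition; the upstream tools' internal criteria are unpublished.

## miRNA discovery

A valid tag is **conserved** when it matches a catalog mature sequence
(full tag against equal-length catalog windows, Hamming distance ≤ 1 —
no indels, since the mapping tolerance is stated as "one mismatch" and
gapped mapping would silently change calls) and the matched mature lies
within an arm of a valid stem-loop precursor. A tag mapping entirely
within the arm *opposite* the annotated mature arm of a known precursor
is a **novel candidate**, accepted when the precursor MFEI is ≥ 0.80 and
the tag reaches ≥ 10 TPM in at least one library (both boundaries
inclusive). Conserved classification takes precedence, so no tag is both.
Counts attach to the mature *sequence*: catalog names sharing a sequence
report the same abundance.

Families are the `miR<number>` token of the matched catalog name
(case-insensitive, species prefixes and letter/arm suffixes stripped);
names without the token stay unassigned. Token extraction is a decision —
how name-less sequences were assigned to families upstream is unstated.

## Differential expression

Counts are normalized as tags per million of the library's valid-read
total (the plain definition; what "modified" global normalization meant
upstream is unstated, and which total normalized it is also unstated —
the valid-read total is the natural choice since only valid tags are
quantified). For each miRNA and library pair a 2×2 table
[count, total − count] is tested with the Pearson chi-square (no
continuity correction) and the two-sided Fisher exact test
(minimum-likelihood rule). A miRNA is up (down) when **both** p ≤ 0.05
and the log2 TPM ratio is ≥ 1 (≤ −1). A miRNA detected in exactly one
library is flagged `library_specific`; its ratio is computed against the
TPM of one raw pseudo-read. No multiple-testing correction is applied by
default — faithful to the stated criterion, and statistically
non-conservative; a Benjamini–Hochberg option sits behind `adjust`.

This single-sample dual-test design has no dispersion model; it is kept
deliberately, as the procedure under study, not as a recommendation.

## Degradome validation

Degradome tags map to transcripts by exact match; each tag contributes
its count at the transcript position of its 5' end, at every locus for
multi-mapping tags (full count at each locus; fractional weighting is an
unstated alternative). Duplexes are scored ungapped against every
transcript window: Watson-Crick 0, G:U 0.5, mismatch 1, penalties
doubled at miRNA positions 2–13, default score cap 4.0 (configurable;
the cap is conventional practice, not a stated value). The predicted
cleavage site is the transcript base paired to miRNA position 10 — the
canonical slicing register — matched exactly (no window).

Sites with degradome support are classified against the transcript's
target plot in the order: category 4 (single raw read), 0 (unique
maximum), 1 (shared maximum), 2 (between median and maximum), 3 (at or
below the median). Category 4 is evaluated first because its wording is
unconditional; the median is computed over covered positions only, since
including zero positions on long transcripts would make category 3
nearly unreachable.

## Enrichment

For term enrichment of target genes the upper tail P(X ≥ S) of the
hypergeometric distribution is used (population TB = annotated genes,
successes B = genes with the term, draws TS = selected genes); the
upper tail is the standard enrichment direction where the exact upstream
convention cannot be confirmed. Background defaults to all genes in the
annotation table; significance is p ≤ 0.05, uncorrected by default.

## The synthetic-data generator

`generate_reference_set()` builds stem-loop precursors by construction —
a 20–24 nt arm, a 4–8 nt loop, and the reverse-complement arm with 1–3
symmetric mismatches, at least one of which falls inside the
mature:star duplex window so the star strand is never the exact reverse
complement of its mature (real duplexes bulge; operationally this keeps
star tags from matching the planted target sites in the transcriptome).
Candidates are re-drawn until the *folded* structure passes the full
novel-mode hairpin validation, so every planted precursor is valid by
construction.

Abundances follow a log-normal (σ = 1) per mature, with star strands at
20% of their mature and a floor of 50 TPM expected abundance so that
every planted novel candidate is recoverable under the ≥ 10 TPM copy
threshold (5× the threshold; sampling noise at the default depth leaves
a negligible failure probability). A fifth of the matures receive a
planted log2 fold change of ±2 per treatment library.

Libraries are drawn from a single multinomial over *absolute*
concentrations: planted sequences scale with their fold changes while a
2,000-sequence background pool of valid non-miRNA sRNAs (24-nt-dominated,
like the siRNA background of real plant libraries), contaminant classes
(30% of reads in total), junk (0.5%), and length outliers (1.5%) keep
fixed weights. The background pool matters statistically: without it,
planted fold changes shift the library total and induce spurious
apparent fold changes in non-regulated miRNAs — the classic
compositionality artifact, which real libraries damp because miRNAs are
a minority of valid reads. Default depth is 5 × 10⁵ reads per library.
Every legitimate read carries the 3' adapter (TruSeq-style small-RNA
adapter) except a 2% no-adapter fraction.

Degradome libraries emit, for each planted cleavage, 20–21 nt tags whose
5' end is exactly the planted site at `degradome_signal_to_noise` (10)
times the unit background count, plus background tags starting uniformly
along transcripts (0.02/nt expected). Annotation tables carry a term
planted at high frequency among target genes, giving the enrichment
stage a known top hit.

What the generator does **not** emulate: sequencing errors and quality
scores, isomiR end-variation, genome-scale reference complexity,
replicate structure, and bulges/gaps in miRNA:target duplexes. Passing
tests therefore demonstrate correctness of the computational procedure
under the stated statistical structure, not performance on real
sequencing data.

## Problem sizes and numerical choices

The shipped study conditions are 60 expressed precursors (plus 10
silent catalog entries), 100 transcripts of 300–600 nt (40% carrying a
planted target site), three libraries at 5 × 10⁵ reads, and three
seeds for stochastic recovery checks (median reported). Ties in the
folding traceback break toward the earliest 5' pairing; the Fisher
two-sided sum uses the customary 1 + 1e-7 relative tolerance when
comparing table probabilities; percentages in accounting tables are
rounded to two decimals and shared-set percentages to one, matching how
such tables are conventionally printed. Degenerate inputs are defined
throughout: zero-margin 2×2 tables report p = 1 with a warning,
zero-GC sequences have undefined MFEI and fail the threshold with a
warning, and a miRNA absent from both libraries is excluded upstream of
the differential test.

## Known limitations

* The internal folding model's energies are not thermodynamic; MFEI
  values are comparable within this model but not to RNAfold output.
  Use the external-structure hook for real data.
* The dual chi-square/Fisher criterion without correction inflates
  discoveries on real data with many tested miRNAs; the BH flag exists
  for that reason.
* Exact-substring contaminant annotation will under-filter diverged
  contaminant copies; real workflows often allow mismatches here.
* Single-sample libraries cannot separate biological from technical
  variance; fold-change-gated dual testing is a historical design, and
  its error control is purely the sampling model's.
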