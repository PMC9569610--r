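---
title: "Curating fusion transcript calls from FFPE tumor RNA: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating fusion transcript calls from FFPE tumor RNA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusiontriage)
```

## The problem

RNA-based fusion callers are sensitive but noisy: on archival FFPE sarcoma
material a single tumor routinely yields tens of candidate chimeric
transcripts, of which at most a handful are real. In a diagnostic setting
the decisive questions are (i) how strongly the data support each candidate
once library depth is accounted for, (ii) which candidates are worth
confirming by an orthogonal method, and (iii) whether a confirmation assay
actually worked. `fusiontriage` addresses these three questions as a
reusable, fully tested pipeline that consumes caller output tables — it
never touches reads or runs an aligner itself.

## Read evidence and cohort summaries

Each call is scored as fusion-supporting reads per million uniquely mapped
reads: spanning pairs plus spanning unique (split) reads, scaled by the
sample's total uniquely mapped reads. Two conventions matter for
reproducing published tables:

* rounding is **half-up** at two decimals (1.5356 becomes 1.54; R's
  default banker's rounding would sometimes disagree), applied only at
  reporting boundaries — internal arithmetic keeps full precision;
* cohort medians are computed over the **rounded per-call values**, with
  the even-length median taken as the mean of the two middle values and
  rounded the same way. This is what a reader recomputes from a printed
  table, and the bundled example tables reproduce cell-for-cell under it.

The per-million normalization is the load-bearing choice: a targeted panel
at ~2.5 M uniquely mapped reads and an exome capture at ~20 M differ
nearly tenfold in raw junction counts for comparable biology.

## Breakpoint annotation

Gene models come from GTF (1-based, inclusive; imported via `rtracklayer`).
A call's fusion point is interpreted as the last transcribed base of the 5'
partner and the first transcribed base of the 3' partner. The 5' breakpoint
is an exon border when it equals the **transcriptional** 3' edge of any
exon of any transcript of the gene — for minus-strand transcripts that is
the lower genomic coordinate, a detail that silently breaks naive
implementations. Because no canonical-transcript choice is given for this
kind of data, a border in *any* transcript counts (union rule); this is
deliberately permissive and documented rather than configurable per
transcript set. Chromosome names are compared after stripping a `chr`
prefix.

Distance-based artifact calls use the absolute difference of the two fusion
point coordinates; the readthrough threshold comparison is strict
(`distance < 100000` excludes, 100 kbp exactly does not).

Frame status of an exon-exon call compares the cumulative CDS length 5' of
the junction, modulo 3, with the CDS phase the 3' partner's junction exon
has in its native transcript. Junctions into exons without CDS overlap —
lncRNA or pseudogene partners, UTR-only exons — are `non_coding`. The
arithmetic is invariant under splitting an exon into two adjacent exons of
the same total length, which the tests assert.

Junction-sequence extension splices flanking exon sequence (reverse
complementing minus-strand exons) onto the caller-reported junction
segment, assuming that segment is a spliced suffix/prefix around the
junction; a mismatch against the genome warns but still extends by
coordinate arithmetic, since the caller's sequence may include variants the
reference lacks.

## The filter cascade and its defaults

Exclusion rules are evaluated per call, and every decision records the
ordered list of rules fired, because a curation pipeline whose decisions
cannot be audited is useless in a diagnostic context. Defaults:

| parameter | default | rationale |
|---|---|---|
| `min_partner_distance` | 100 000 bp | readthrough signature; strict `<` |
| `max_common_mapping_reads` | 0 | "high" is unquantified upstream; the strictest reading is the default and the audit trail lets users relax it |
| `exclude_banned` | TRUE | trust the caller's own blacklist |
| pathognomonic matching | ordered (5', 3') pairs | fusion orientation is biologically meaningful |
| cross-patient exclusion | ordered gene-pair level | breakpoint-level matching would miss splice variants of the same event |
| `literature_genes` | user-supplied | "described in the literature" is curation, not computation; no bundled database pretends otherwise |

Representative-transcript selection (several transcripts, one gene pair)
takes the maximum spanning-unique-read count; ties break on spanning pairs,
then on the lexicographically smallest point pair — the tie-breaks are not
scientifically meaningful, only deterministic.

The recurrence screen groups by ordered pair **within a disease group** by
default (recurrence across unrelated entities is a different claim), drops
pathognomonic pairs and pairs with only artifact-flagged calls, requires
two patients, and restricts representative selection to exon-exon
transcripts since those are the ones a junction-spanning assay can target.
Patients whose calls for a pair are all ineligible drop out, and a pair
retaining fewer than two patients is not reported.

## RT-qPCR evaluation

Amplification efficiency comes from ordinary least squares of Cq on log10
input over a dilution series (six 10-fold points in the standard design),
`E = (10^(-1/slope) - 1) * 100%`. Validity bounds default to [90, 110]%,
comfortably containing the 98–103% range a well-behaved assay shows.

"Amplified" is operationalized as Cq present and ≤ 40 cycles with melt
temperature within ±1.0 °C of the assay's expectation when both are
available; the source workflow gates on "Cq and Tm evaluation" without
numbers, so both gates are config-exposed (`qpcr_config()`). A missing Tm
measurement, or an assay without a Tm expectation, leaves the Cq gate
decisive. Confirmation requires at least one of two tumor replicates
amplifying and **no** amplification in any of the three control roles
(matched normal, no-template, carrier RNA); a missing control role is an
error, not a silent pass. The published Cq ranges of confirmed assays
(27.01–36.28) sit well inside the default gate, which the acceptance tests
verify.

## The synthetic cohort generator

The generator is first-class, tested code, not a fixture: it emits exactly
the file dialects the readers consume, plus a truth table. Its defaults are
the study conditions the pipeline was built for: 17 patients (9 ARMS, 8
URCS), six planted pathognomonic fusions at ~1.4 supporting reads per
million, totals uniform in [17.5, 25.9] million uniquely mapped reads, and
secondary/novel candidates at ~0.45 per million. Counts are negative
binomial (dispersion 5) because read counts are over-dispersed; the count
family is a modeling choice, not something the curation rules depend on.

Construction guarantees, asserted by tests:

* planted pathognomonic calls sit at exon-exon borders of the toy model and
  never violate an artifact rule;
* each planted artifact call violates exactly its designated rule — e.g. a
  `banned` call is interchromosomal, has zero common-mapping reads and a
  literature partner, so `BANNED` is its only exclusion reason;
* recurrent pairs share both breakpoints across their patients;
* everything, including written files, is byte-identical given the seed.

The toy genome holds ten genes (the six real pathognomonic partner symbols
plus four synthetic ones) on three chromosomes, with exactly one gene pair
under the readthrough distance threshold — requesting more close-partner
artifacts than that pair can supply is an impossible-config error rather
than a silently broken truth table. Ten genes keep brute-force oracles
(full edge enumeration) cheap.

What the simulation does **not** emulate: FFPE degradation beyond a DV200
metadata column, read-level errors, caller-specific miscalls, expression
heterogeneity. Passing the planted-truth tests therefore shows the decision
logic is implemented correctly, not that the upstream caller's output on
real FFPE data is this clean.

## Problem sizes and numerical choices

The test suite runs the cascade-recovery property on 100 randomly
configured cohorts (4–10 patients each) and the breakpoint oracle on ~20
randomized toy models probed at every exon edge ±1 plus random positions —
sizes chosen so brute-force enumeration stays exact while covering all rule
combinations. Monte-Carlo efficiency recovery uses 100 replicates at Cq
noise sd 0.2, where the estimator's per-replicate spread is ~2 percentage
points and its bias is well under 1.

Degenerate inputs are handled explicitly: empty call tables flow through
every stage as empty results; a dilution series with one distinct input
level, an empty evidence vector, a zero total, or a plate missing a control
role are errors naming the offending piece.

## Known limitations

* Criterion (2)'s literature set is user-supplied; results are only as good
  as that curation.
* The union-over-transcripts border rule can call a junction "exon border"
  via a minor transcript; a canonical-transcript mode would be stricter.
* Identical-sequence artifact flagging catches paralog-driven duplicate
  calls (same 5' partner, identical predicted sequence) but not artifacts
  that differ in sequence.
* Published totals for the same patient can differ between source tables
  (panel vs exome runs); tables are treated as independent inputs and not
  reconciled.
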