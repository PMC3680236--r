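---
title: "Detecting alternative-splicing events and their variation across individuals"
author: "splicescape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting alternative-splicing events and their variation across individuals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicescape)
```

## Scope and model

splicescape analyzes alternative splicing (AS) after read alignment.
Its inputs are the products of a spliced aligner run on bulk RNA-seq of
several individuals: per-individual splice-junction evidence (the
intron interval removed by splicing, with read support), per-base
coverage tracks, per-gene fragment counts, and a GFF3 gene annotation.
Spliced alignment itself is out of scope; the package consumes its
outputs.

The analysis proceeds in five stages.

1. **Junction filtering.** A junction is trusted when it is supported
   by at least `min_reads = 2` reads, at `min_distinct_positions = 2`
   distinct alignment start positions (a guard against PCR and mapping
   duplicates — a stack of identical reads counts once), with a
   `min_overhang = 4` bp anchor on both sides. We apply the overhang
   rule to the per-junction *maximal* anchors reported in the evidence
   file, not to each individual read; the evidence formats in common
   use (e.g. TopHat-style BED12) only carry per-junction maxima, and
   the thresholds are configurable for stricter readings.
2. **Event detection.** Four event classes are built from filtered
   junctions plus coverage. A donor spliced to two acceptors is an
   alternative 3' splice site event (A3SS); two donors sharing an
   acceptor are an A5SS; donor/acceptor roles follow the strand. An
   intron is called retained (IR) when every base has depth >= 1 *and*
   its spliced junction passed filtering in the same individual — both
   conditions in the same individual, since retention is an
   individual-level state. Exon skipping (ES) requires a filtered
   exclusion junction strictly containing a complete, annotated,
   internal exon together with both inclusion junctions; this
   conservative triple rule follows the classical EST-era definition
   and avoids calling skipping from a lone long junction.
3. **Isoform quantification.** Every event has exactly two isoforms;
   the long (L) isoform is the inclusion form (retained intron,
   included exon, or the junction removing the shorter intron). The
   Isoform(L) frequency is `inclusion / (inclusion + exclusion)` — an
   event supported by 12 inclusion and 4 exclusion junction reads has
   frequency 75%. When both counts are zero the frequency is undefined
   and propagates as `NA`; it is never imputed as 0.
4. **Expression context.** Gene expression is summarized as FPKM
   (fragments per kilobase of collapsed exon per million mapped
   fragments). Only events in genes with FPKM >= 5 in *every*
   individual enter the variation analysis, so isoform-ratio noise from
   barely covered genes is excluded. Expression categories are `zero`
   (FPKM = 0), `low` (0 < FPKM < 5), `medium` (5 <= FPKM <= 40) and
   `high` (FPKM > 40); the boundary values 5 and 40 belong to the
   medium class.
5. **Variation statistics.** L-frequency profiles are compared across
   individuals with Spearman rank correlation (pairwise-complete,
   mid-ranks for ties) and clustered with average linkage (UPGMA) on
   the distance 1 − ρ. For each event and each within-group pair of
   individuals, a two-sided Fisher exact test evaluates the 2×2 table
   of reads split by individual and isoform. All (event, pair) tests of
   a group form one Benjamini–Hochberg family, and an event is
   *variable* when at least one of its pairs is flagged at FDR 5%.

## Design decisions where the design was open

**Pairwise events.** When one donor splices to k > 2 acceptors we emit
all k(k−1)/2 unordered pairs as separate events rather than one
k-ary event. This keeps every event strictly two-isoform, so the
L-frequency and the Fisher 2×2 table are well defined for each event.
The cost is that a three-acceptor site counts as three events; the
event keys make the grouping recoverable. A side effect is that the
junction trio of an ES event also satisfies the pairwise A3SS/A5SS
definitions, so an ES locus contributes companion alt-site events;
these are genuine consequences of the definitions, not duplicates, and
they carry distinct keys.

**IR inclusion counts.** Which reads "support retention" is a genuine
choice. We use the floored mean coverage depth at the two exon–intron
boundary bases (first and last intron base). The alternative —
intron-body read totals — grows with intron length and would make the
Fisher table margins incomparable between short and long introns.
Boundary depth behaves like a junction count and is commensurate with
the spliced-junction reads on the other side of the table. Averaged
counts are floored, not rounded: Fisher tables need integers and
flooring is deterministic and conservative.

**Degenerate Fisher tables.** Tables with a zero row or column margin
(e.g. an event with no reads in one individual) are uninformative;
they receive p = 1 rather than being dropped, so the number of tests —
and hence the BH family and the variable-fraction denominator — does
not depend on which tables happened to degenerate.

**BH family.** The tests pooled per group are all (event, pair)
combinations within that group. Pooling across pairs is the more
conservative reading (the family is larger), and it makes "variable in
at least one pair" a statement about a single controlled family.

**Two denominators.** The fraction of variable events is reported both
over events that entered at least one test and over all events
quantified in the group; the two differ when events lack defined
frequencies in some pairs. Reports carry both columns.

**Known vs novel junctions.** A junction is known only on an exact
(chrom, strand, start, end) match with an annotated intron; a 1-bp
shift or a strand flip makes it novel. Sharing histograms split by
this label.

## The synthetic-data generator

`simulation_config()` defaults describe the study design the package
targets: 20 individuals (12 southern, PT02–PT13; 8 northern,
PT14–PT21), an AS-type mixture of 40% IR, 32% A3SS, 20% A5SS and 8% ES,
mean informative junction depth of 42 reads (junction depth is
Poisson), and base L-frequencies drawn from Beta(2, 2). Between-
individual structure is injected by shifting the true frequency of a
configurable fraction of events (default 15%) by Δp = 0.3, by default
in one randomly chosen individual per shifted event (individual-
specific splicing); a group-wide shift mode is available. Inclusion
counts are Binomial(n, p) with no overdispersion — deliberately
matching the sampling assumption of the Fisher exact test so that null
simulations are calibrated; a real dataset with extra-binomial noise
would show more false positives than these simulations do. Five
percent of events are emitted with read count 1 at a repetitive
position to exercise the support filter, and a fraction of non-event
introns receive coverage with a one-base internal gap as IR decoys.

What the generator does *not* emulate: overdispersed read counts,
sequencing error, mapping bias, intron-body coverage from unspliced
pre-mRNA, and genes with more than one event. Passing the end-to-end
tests therefore demonstrates correctness of the detection,
quantification and testing machinery under the stated sampling model,
not robustness to alignment artifacts.

Expression counts are Poisson at rate `fpkm × kb`; true FPKM values
are log-normal, rescaled so that the library-size identity
`sum(FPKM × kb) = 1e6` holds, which makes recomputed FPKM an unbiased
estimate of the truth. Because the synthetic gene universe is small,
absolute FPKM values are high; a configurable slice of genes (default
5%) is forced to near-zero expression so the FPKM >= 5 filter has
something to remove.

## Numerical and reporting choices

* Internal coordinates are 0-based half-open; GFF3 (1-based closed)
  and bedGraph are converted at the I/O boundary only.
* Event identity across individuals is a key string, a pure function
  of type, chromosome, strand and anchor coordinates; alternative
  sites within a key are sorted numerically so keys are orientation-
  and input-order-invariant.
* The two-sided Fisher p-value sums all hypergeometric outcomes with
  probability at most (1 + 1e-7) times the observed one — the same
  relative-tolerance convention as `stats::fisher.test`, with which
  the implementation agrees to 1e-10 on random tables.
* Ties in ranking (`top_expressed`) break lexicographically by gene
  ID; clustering ties merge deterministically in label order.
* Gene assignment of an event: the gene whose span contains the event
  anchors on the same strand, smallest gene ID on ties; unassigned
  events keep `NA` and are excluded from AS-gene counts and from the
  expression filter.
* Report tables are plain TSV with fixed rounding (correlations to 6
  decimals, percentages to 4), so identical configurations give
  byte-identical bundles; the run manifest hashes the analysis
  parameters (not the output path).

## Problem sizes used by the test suite

The packaged checks run at desk scale, chosen to keep the suite fast
while leaving Monte-Carlo margins: null calibration uses 2000 events ×
6 individuals at the default depth; the estimator-envelope check uses
5000 events at depth 50; the power check uses 2000 events with
Δp = 0.3 at depth 50 between two individuals, a design whose expected
BH-adjusted power (~0.83 by exact computation over the base-frequency
range U(0.1, 0.6)) exceeds the 0.8 requirement by 3.5 Monte-Carlo
standard errors; determinism is checked on a 20-individual, 60-gene
simulated study.

## Known limitations

* IR calling requires the spliced junction to pass filtering, so a
  fully retained intron (no spliced reads at all) is invisible — with
  both isoforms quantifiable this is the intended two-isoform
  behaviour, but it under-counts extreme retention.
* Event classes are limited to IR, A3SS, A5SS and ES; mutually
  exclusive exons and alternative first/last exons are not modelled.
* FPKM uses the collapsed exon union per gene; transcript-level
  abundance estimation is out of scope.
* The coverage-based feature-density summary is depth-weighted, not
  fragment-resolved; it is a mapping diagnostic, not an expression
  estimate.
```{r session}
sessionInfo()
```
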