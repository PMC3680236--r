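# splicescape

Alternative splicing (AS) lets one gene produce several mRNA isoforms
by differential splice-site usage. In plants the dominant form is
intron retention, and how much isoform usage varies *between
individuals* of a population — as opposed to between tissues — is a
population-genomics question that bulk RNA-seq can answer directly.
splicescape is an R package for exactly that analysis: it takes the
post-alignment outputs of a spliced aligner for N individuals
(splice-junction evidence, per-base coverage, per-gene fragment
counts) plus a GFF3 annotation, and produces per-individual AS event
catalogs, isoform-frequency estimates, and inter-individual variation
statistics. It is aimed at researchers analyzing multi-individual
RNA-seq panels, e.g. from forest-tree or crop populations.

## Method core

* **Junction filter** — a junction is trusted iff supported by ≥ 2
  reads at ≥ 2 distinct alignment positions with ≥ 4 bp anchors on
  both sides (all configurable).
* **Event classes** — intron retention (IR: every intron base covered
  at depth ≥ 1 and the spliced junction observed in the same
  individual), alternative 3'/5' splice sites (A3SS/A5SS: two
  junctions sharing a donor / an acceptor, one event per unordered
  pair of alternative sites), exon skipping (ES: an exclusion junction
  strictly containing a complete internal annotated exon, with both
  inclusion junctions present).
* **Isoform(L) frequency** — each event has a long (inclusion) and a
  short (exclusion) isoform;
  `freq(L) = inclusion / (inclusion + exclusion)`.
  An A3SS event with 12 reads on the long-isoform junction and 4 on
  the short one has `12 / (12 + 4) = 75%`.
* **Expression context** — per-gene FPKM
  (`count / (exonic_kb) / (mapped_fragments / 1e6)` over the collapsed
  exon union); variation analysis keeps only events whose gene has
  FPKM ≥ 5 in every individual.
* **Variation statistics** — Spearman correlation of L-frequency
  profiles between individuals; UPGMA clustering on `1 − ρ`; per event
  and per within-group pair of individuals a two-sided Fisher exact
  test on `[[incl_A, excl_A], [incl_B, excl_B]]`, Benjamini–Hochberg
  adjusted at FDR 5% over all (event, pair) tests of the group. An
  event is *variable* if at least one of its pairs is flagged.

A fully seeded synthetic-data generator (`simulation_config()`,
`simulate_study()`) emits the exact input formats with known ground
truth, so the whole pipeline is testable without external data.

## Worked example

Simulate an 8-individual study (two groups of four) and run the full
pipeline:

```r
library(splicescape)

cfg <- simulation_config(seed = 11, n_genes = 50,
                         individuals = sprintf("PT%02d", 2:9),
                         groups = setNames(rep(c("southern", "northern"),
                                               each = 4),
                                           sprintf("PT%02d", 2:9)))
sim <- simulate_study(cfg, "sim")
allc <- do.call(rbind, lapply(sim$counts, read.delim))
write.table(allc, "sim/counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

rc <- run_config(annotation = sim$annotation, junctions = sim$junctions,
                 coverage = sim$coverage, counts = "sim/counts.tsv",
                 groups = cfg$groups, k_high = 6L, out_dir = "sim/out")
res <- run_all(rc)

read.delim("sim/out/conservation_summary.tsv")
#>   event_type n_events n_in_1 n_in_ge_k n_in_all pct_of_events pct_in_1 ...
#> 1       A3SS       11      0        11       11       32.3529        0
#> 2       A5SS        9      0         9        7       26.4706        0
#> 3         IR       10      0        10       10       29.4118        0
#> 4         ES        4      0         4        4       11.7647        0
#> 5      Total       34      0        34       32      100.0000        0

read.delim("sim/out/variation_summary.tsv")
#>      group n_events_tested n_events_detected n_variable fraction_tested
#> 1 southern              32                32          3         0.09375
#> 2 northern              32                32          1         0.03125
```

Reading the output: 34 distinct AS events were detected across the 8
individuals (the per-type shares follow the configured mixture; at
this depth nearly all events replicate in every individual, so the
"in all" column dominates). In the variation stage, 3 of the 32
expressed, testable events differ significantly between at least one
pair of southern individuals at FDR 5% — these are the events the
generator planted with a frequency shift of 0.3 in single individuals.
The pairwise Spearman correlations of isoform ratios
(`sim/out/correlation_matrix.tsv`) fall around 0.85–0.95, and
`sim/out/dendrogram.nwk` holds the average-linkage tree.

A thin command-line wrapper with `simulate`, `run` and `summarize`
subcommands is installed at `inst/scripts/splicescape.R`.

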