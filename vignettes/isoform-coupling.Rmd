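---
title: "Detecting TSS-TES and exon couplings in long-read data"
author: "isocouple"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting TSS-TES and exon couplings in long-read data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isocouple)
```

## The question

A gene with several promoters (TSSs) and several cleavage/polyadenylation
sites (TESs) could in principle combine them freely. Long-read cDNA
sequencing makes the combination observable: one full-length read carries
its TSS, its TES and its exon chain on a single molecule. `isocouple`
asks, gene by gene, whether the observed TSS x TES combinations depart
from what independent choice of the two ends would produce — and, in a
second arm, whether inclusion of individual exons depends on which TSS
(or TES) the molecule used. A gene whose TSSs contribute unequally to its
alternative 3' ends shows *promoter dominance*.

## The model

For one gene, let $O_{ij}$ be the number of full-length reads assigned
to TSS cluster $i$ and TES cluster $j$, with $n = \sum_{ij} O_{ij}$.
Under independence the expected count is

$$E_{ij} = \frac{O_{i\cdot}\,O_{\cdot j}}{n},$$

and the Pearson statistic is $X^2 = \sum_{ij} (O_{ij}-E_{ij})^2/E_{ij}$.
Because many tables are small and sparse, the reference distribution is
not taken from the asymptotic $\chi^2$: null tables are drawn uniformly
from the set of tables with the observed margins (Patefield's algorithm,
via `stats::r2dtable`), giving the conditional Monte-Carlo p value

$$p = \frac{1 + \#\{X^2_{\mathrm{sim}} \ge X^2_{\mathrm{obs}}\}}{B + 1},$$

whose floor is $1/(B+1)$. p values are adjusted across all tested genes
with Benjamini-Hochberg. Cell-level effects are reported as Pearson
residuals $r_{ij} = (O_{ij}-E_{ij})/\sqrt{E_{ij}}$ (so
$\sum r_{ij}^2 = X^2$), and a (TSS, TES) pair is called *coupled* when
its gene passes the q-value cut-off and $|r_{ij}|$ passes the residual
cut-off. Promoter dominance is summarized per 3' end as the
column-normalized fractions $O_{ij}/O_{\cdot j}$; a TES has a dominant
TSS when the gene is significant and the largest fraction reaches the
dominance threshold.

The exon arm tests, for every reference junction of a gene, the 2 x K
table of junction inclusion/exclusion against the K TSS (or TES)
clusters with the same Monte-Carlo test; the inclusion-row residual per
cluster says which promoter over- or under-uses the junction.

An alternative null that resamples the table from the independence
multinomial (rather than conditioning on both margins) is available via
`null = "multinomial"` for sensitivity analysis; the conditional test is
the default because both margins are fixed by design of the question
(which ends exist is not at issue, only their association).

## From reads to tables

* **Database.** Transcript 5' and 3' ends from the GTF (by default only
  `protein_coding` genes) are clustered per gene by single linkage on
  sorted positions: consecutive ends at most one window apart merge.
  Defaults are 50 nt for TSSs and 150 nt for TESs — 3' cleavage is
  intrinsically more heterogeneous than initiation, hence the wider
  window. Single linkage is order-independent and matches the intent of
  merging ends into one transcription unit, at the cost of chaining:
  a run of ends each within the window can form a cluster wider than
  the window. This is documented, tested, and in practice limited by
  the sparsity of annotated ends. The cluster representative is the
  modal member position (ties resolved to the 5'-most in
  transcriptional direction); candidate 5'-3' isoforms are *all*
  TSS x TES cluster combinations with the TSS upstream of the TES —
  enumerating all combinations, not just annotated transcripts, is what
  makes novel couplings countable. External promoter or 3'-end
  databases can be merged in: an external end within the window of an
  existing same-kind cluster is absorbed (the representative does not
  move); anything else founds a new cluster and the pair cross-product
  is re-enumerated. Absorption without re-clustering keeps the
  annotation-derived representatives stable.
* **Assignment.** A primary alignment is *full length* when its
  strand-aware 5' end lies within the assignment window (representative
  +/- window) of a TSS cluster and its 3' end within the window of a
  TES cluster of the same, strand-matching gene. The same window pair
  governs clustering and assignment — one resolution parameter per end
  kind. Among several matching clusters the nearest representative
  wins, ties to the 5'-most. Reads satisfying both ends in more than
  one gene are dropped as `ambiguous_gene` so contingency tables stay
  disjoint. Soft-clipped bases are excluded: the aligned span defines
  the ends, because adapter and poly(A) clipping otherwise shifts them.
  Secondary and supplementary alignments are skipped to avoid double
  counting chimeric cDNA; the MAPQ default is 10. Every scanned read
  receives exactly one status (`filtered`, `unassigned`, `no_tss`,
  `no_tes`, `ambiguous_gene`, `full_length`), so the tallies partition
  the input — an invariant the tests assert.
* **Junction correction.** Long reads wobble at splice boundaries, so
  observed introns are snapped to a reference junction set built from
  the annotation (consecutive exons per transcript) plus, optionally,
  STAR short-read junctions supported by at least `min_jcounts = 2`
  unique mappers. An intron snaps when exactly one reference junction
  has both boundaries within `tol` (default 10 nt, above typical
  nanopore splice wobble); zero candidates reject the read as
  `novel_junction`, several reject it as `ambiguous_junction` unless
  `snap_closest = TRUE`. Rejection on ambiguity is the conservative
  default: a mis-snapped junction would contaminate the coupling table,
  a rejected read only costs depth. A junction's *exclusion* count
  requires the read's aligned span to cover the whole intron interval,
  so reads that simply end before a junction are not mistaken for
  skipping it.

## Testing thresholds and defaults

| Parameter | Default | Meaning |
|---|---|---|
| `tss_window` | 50 nt | TSS clustering and assignment window |
| `tes_window` | 150 nt | TES clustering and assignment window |
| `B` | 2000 | Monte-Carlo null tables per test (p floor 1/2001) |
| `alpha` | 0.01 | significance level on BH q values |
| `residual_cutoff` | 0.5 | minimum absolute Pearson residual for a coupled pair |
| `min_reads` | 20 | minimum full-length reads per tested gene/junction |
| `dominance_threshold` | 0.5 | minimum fraction for a dominant-TSS call |
| `min_jcounts` | 2 | minimum short-read support for a reference junction |
| `tol` | 10 nt | per-boundary junction snap tolerance |
| `min_mapq` | 10 | minimum mapping quality |

Only genes with at least two TSS *and* two TES clusters enter the
gene-level family (the question is undefined otherwise), and only genes
reaching `min_reads` full-length reads are tested — below that the
Monte-Carlo test is dominated by discreteness. `min_reads`,
`dominance_threshold` and `tol` have no field-standard values; the
numbers above are this package's declared defaults, all exposed as
arguments.

## What the simulator emulates — and what it does not

`sim_config()` lays out non-overlapping genes on one contig, each with
configurable alternative TSSs/TESs (spaced 500 nt by default, well
beyond both windows, so truth recovery is unambiguous) and internal
exons whose inclusion probability may depend on the TSS. Reads sample a
TSS from the marginal weights, a TES from the gene's row-stochastic
coupling matrix, and exon inclusions conditional on the TSS; they then
receive

* truncated-normal end jitter (sd 10 nt by default), capped at half the
  assignment window so that an un-truncated read is full length by
  construction — this makes exact truth-recovery fixtures possible;
* 5' truncation (20% of reads by default, a typical incomplete-cDNA
  share in long-read libraries): the 5' end moves along the spliced
  transcript to beyond the assignment window of *every* TSS of the
  gene, plus an exponential tail (mean 150 nt), so truncated reads are
  never full length;
* bounded uniform junction-boundary noise (off by default).

Alignments are emitted directly as a coordinate-sorted BAM (the
package's contract starts at aligned data); sequences are not modelled.
The simulator therefore does *not* emulate base-level nanopore error,
soft-clipped adapters, poly(A) tails, overlapping genes, antisense
transcription, or expression heterogeneity between genes. Passing tests
show that the statistics and the bookkeeping are correct under the
stated geometric noise model — not that any particular biological
library will yield as clean assignments.

Study-condition choices used by the test-suite cohorts: statistical
calibration runs on 500 genes with 3 TSS and 3 TES clusters at 150
reads per gene. The richer 3 x 3 tables are the deliberate choice here:
the conditional null of a sparse 2 x 2 table is strongly discrete, so
its p values are valid but visibly sub-uniform at any sample size,
whereas multi-ended genes — exactly the genes the method exists for —
give a near-continuous null. Coupling recovery uses 50 genes with an
odds ratio of 9 at 200 reads; dominance convergence one gene at 5000
reads; the depth property 30 genes (half coupled, half independent)
under nested subsampling at 8%, 30% and 100%.

## Numerical choices and degenerate inputs

* The Monte-Carlo comparison uses `stat_sim >= stat_obs - 1e-9` so
  floating-point ties (notably the all-equal table with statistic 0)
  count as exceedances; a perfectly independent table yields p = 1.
* All-zero rows or columns of a count table are dropped (with a
  warning) before testing; if fewer than two positive rows or columns
  remain, the gene or junction is reported `tested = FALSE` rather than
  erroring, and a fully zero table is a degenerate-input error at the
  `expected_table` level.
* Cluster representatives break multiplicity ties towards the
  transcriptional 5' side, making database construction deterministic
  under permutations of the input — asserted by a property test against
  a brute-force single-linkage oracle.
* Seeded runs are bit-identical; the Monte-Carlo seed never perturbs
  the caller's RNG state (`withr::with_seed`).
* Internally all coordinates are 1-based closed intervals on
  `GRanges`/`GAlignments`, the native convention of the R genomics
  stack; GTF enters unchanged, BED and STAR `SJ.out.tab` are converted
  at parse time. Junction boundaries are stored as the first and last
  intronic base.

## Known limitations

* The full-length definition checks end-window membership only; it does
  not require coverage of the gene body between the ends. A read with a
  large internal deletion that still hits both windows counts as full
  length in the TSS-TES arm (the junction arm would reject it at
  correction).
* Reads are pooled; replicate structure is not modelled. The test
  answers "is there association in this pool", not "does association
  replicate across samples".
* Pair-level `coupled` calls condition on the gene-level q value rather
  than re-testing each pair, avoiding a second multiplicity layer but
  inheriting the gene-level resolution.
* Junction tests treat each junction separately (2 x K tables); a joint
  model over whole chains is out of scope.
* The transcriptome-wide bias plot shows log10 expected versus log10
  observed counts with coupled pairs highlighted; axis limits are upper
  bounds on that scale.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_genes = 4, n_reads = 200,
                  coupling = coupling_from_odds_ratio(9), seed = 11)
ann <- generate_annotation(cfg, "sim.gtf")
simulate_reads(cfg, ann, "sim.bam")
res <- run_coupling_pipeline("sim.bam", "sim.gtf", "results/", seed = 7)
gene_results(res)
dominance(res)
plot_bias(res)
```

The same stages are scriptable from a shell through
`inst/cli/isocouple.R` (`build-db`, `count`, `test`, `junctions`,
`exon-test`, `simulate`), each subcommand reading and writing plain
files so that batch systems can drive many BAMs without an embedded
workflow engine.
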