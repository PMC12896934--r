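---
title: "Classifying heterosis expression patterns with hvigor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying heterosis expression patterns with hvigor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hvigor)
```

## The question

When two purebred lines are crossed, the hybrid often outperforms both
parents — heterosis, or hybrid vigor. At the transcriptome level the
signature of interest is *transgressive* expression: genes whose abundance
in the hybrid falls outside the range spanned by the two parents.
Over-dominantly expressed genes (hybrid above both parents) are the usual
starting point for explaining trait-level heterosis, for example in meat
quality traits of crossbred pigs such as shear force, color, and
intramuscular fat.

`hvigor` takes a three-group expression experiment — `parentA`, `parentB`,
and `hybrid`, with biological replicates per group — and answers:

1. Which genes show which inheritance pattern in the hybrid?
2. Which transgressive genes are credible hybrid-vigor candidates?
3. How do those genes relate to measured traits and to an interaction
   network?

## Heterosis statistics

For each gene, let $\bar{A}$, $\bar{B}$, $\bar{H}$ be the group mean
abundances. The package computes

* mid-parent value, $\mathrm{MPV} = (\bar{A} + \bar{B})/2$;
* mid-parent heterosis, $\mathrm{MPH} = 100\,(\bar{H} -
  \mathrm{MPV})/\mathrm{MPV}$;
* best-parent heterosis, $\mathrm{BPH} = 100\,(\bar{H} -
  \max(\bar{A},\bar{B}))/\max(\bar{A},\bar{B})$.

Since $\max(\bar{A},\bar{B}) \ge \mathrm{MPV} > 0$, MPH is never smaller
than BPH, and $\mathrm{BPH} > 0$ exactly when the hybrid exceeds both
parents. Genes with $\mathrm{MPV}$ below `min_mpv` (default 1 abundance
unit) keep their significance-based pattern call but get `NA` percentages:
ratios against a near-zero denominator are noise, not biology.

```{r heterosis-example, eval = FALSE}
het <- compute_heterosis_stats(expr)   # expr: an expression_matrix()
head(het[, c("gene_id", "mpv", "mph_pct", "bph_pct")])
```

## Pattern classification

Patterns are defined by *significance against each parent*, from two
differential contrasts of the hybrid versus each parent:

| pattern            | vs parent A     | vs parent B     | extra condition          |
|--------------------|-----------------|-----------------|--------------------------|
| transgressive_up   | up              | up              | —                        |
| transgressive_down | down            | down            | —                        |
| dominant_like      | significant     | not significant | (or the mirror image)    |
| additive_like      | not significant | not significant | $|\mathrm{MPH}| \le$ band |
| unclassified       | everything else (including opposite directions)       |

Candidate hybrid-vigor genes are the `transgressive_up` genes with
$\mathrm{BPH} > 0$, ranked by BPH descending.

Two defaults deserve explanation:

* **Classification uses significance only** (`lfc_cutoff = 0` in
  `pattern_call_config()`). The categories above are *relative* statements
  about the hybrid versus each parent; imposing an additional 2-fold
  magnitude gate would silently reclassify genuinely transgressive genes of
  moderate amplitude as additive. A fold-change gate (default
  `|log2FC| > 1`) remains the default for the separate *DEG reporting*
  contrasts (`deg_thresholds()`), where it serves its usual role of
  filtering small-amplitude hits.
* **Moderated t is the default test** (`method = "moderated"` in
  `run_contrast()`, via limma on log2 abundances). With typical replication
  (around five biological replicates per group) the per-gene Welch t-test
  is noticeably underpowered; empirical-Bayes variance moderation borrows
  information across genes and restores power while keeping raw p-values
  calibrated under the null. `method = "welch"` is retained for a
  model-free cross-check.

## Normalization and composition bias

Counts are converted to abundances before testing. `normalize_fpkm()`
implements the classical count $\times 10^9 / (\text{length} \times
\text{library total})$ formula. The pipeline default, however, is
`normalize_abundance()` with *mode-based size factors*: each sample's
factor is the kernel-density mode of its log-ratios to a geometric-mean
reference gene-wise profile.

The reason is composition bias. In a heterosis experiment a large,
*asymmetric* fraction of the transcriptome can be transgressive (in the
motivating use case roughly 30% of informative genes, mostly upward in the
hybrid). Scaling by raw library totals then deflates every hybrid gene and
produces spurious "down" calls in null genes. The mode of the log-ratio
distribution tracks the majority null population even when the median is
dragged by the regulated tail, so mode-based factors recover unbiased fold
changes; `method = "median"` (median-of-ratios) is available when
regulation is known to be sparse.

## Trait statistics

`tukey_hsd()` performs one-way ANOVA followed by Tukey–Kramer pairwise
comparisons, with p-values from the studentized range distribution. Group
letters come from an insert-and-absorb compact letter display: starting
from a single letter column containing all groups, every significantly
different pair splits the columns containing both, and subset columns are
absorbed. The result is *sound* (significantly different groups never
share a letter) and *complete* (non-different groups always share one),
which is verified property-style in the test suite.

`correlate_genes_traits()` links candidate or hub genes to traits via
Pearson correlation of log2 abundance against each trait across shared
samples, with conventional significance stars. `enrich()` performs
hypergeometric over-representation of a gene list in GMT gene sets with
Benjamini–Hochberg adjustment, and `hub_genes()` ranks degree centrality
on the subgraph of an interaction network induced by a query list.

## The synthetic generator

Because deposited sequencing data are rarely available offline, the
package ships a generator (`simulate_expression()`) producing counts with
a *known* inheritance mode per gene:

* baseline parent means are log-uniform on `base_range` (default 20–2000);
* the two parents differ by `parent_fold` (default 2) in a random
  direction;
* the hybrid mean follows the gene's mode: mid-parent (additive), high or
  low parent (dominant), `effect_size` times the high parent
  (overdominant), the low parent divided by `effect_size` (underdominant),
  or all-equal (null);
* counts are negative binomial with common `dispersion` (Poisson at 0),
  after per-sample library factors drawn from `libsize_range`.

Mode counts follow the requested fractions by largest-remainder
apportionment, so realized counts are within one gene of the target. The
default configuration — 20,000 genes, 5 replicates per group, 20%
overdominant, 10% underdominant, effect size 2, dispersion 0.1 — is sized
like a bulk RNA-seq heterosis study and is the regime in which the
package's recovery guarantees (recall of transgressive modes, false-call
rate among null genes, type-I error calibration) are tested.

`simulate_traits()` couples traits to driver genes as weighted sums of
z-scored log2 abundance plus Gaussian noise, so that with zero noise a
driver correlates perfectly (±1) with its trait — a useful end-to-end
oracle.

What the generator does *not* model: gene-gene correlation, gene-specific
dispersion trends, GC/length biases, batch effects, or allele-specific
expression. It is a calibration instrument for the statistics above, not a
full RNA-seq emulator.

## Running the whole pipeline

```{r pipeline, eval = FALSE}
cfg <- run_config(list(
  simulation = list(n_genes = 20000, n_reps_per_group = 5),
  seed = 1))
summary <- run_pipeline(cfg, "run1")
```

`run_pipeline()` writes every stage output as TSV (counts, abundances,
contrasts, heterosis table, candidates, optional hubs/enrichment/trait
tables) plus `summary.json` and the resolved configuration; identical
configuration and seed reproduce byte-identical files. Real data enter
through the `input:` block (count matrix + sample sheet, optionally gene
lengths, traits, an edge list, and GMT sets); `inst/scripts/run_pipeline.R`
wraps this as a command-line tool.

## Limitations

* Patterns are called from two marginal contrasts, not a joint model;
  borderline genes near the significance threshold can flip category.
* Percent-based MPH/BPH are undefined at near-zero MPV by design.
* Mode-based size factors assume the null (unregulated) population is the
  largest single coherent component of the log-ratio distribution.
* Degree is the only hub statistic implemented; the ranking function is
  isolated so alternatives can be added.
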