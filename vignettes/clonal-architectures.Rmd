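---
title: "Quantifying intra-tumor heterogeneity from clonal architectures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intra-tumor heterogeneity from clonal architectures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonearch)
```

## The problem

Bulk sequencing of a single tumor sample mixes reads from all of its
clones — groups of cells sharing the same somatic mutations. Subclonal
reconstruction tools cluster variant allele frequencies (VAFs) into clones
and arrange them into a rooted phylogeny: the root carries the clonal
(truncal) mutations present in every cancer cell, non-root clones carry the
subclonal mutations that arose later. `clonearch` takes such phylogenies —
many candidates per sample, each scored by a likelihood — and turns them
into per-sample descriptions of intra-tumor heterogeneity that can be
related to genomic instability: how many clones, how branching the
phylogeny, how many clonal versus subclonal mutations, and which molecular
features travel with each.

## The Tree score

For a rooted phylogeny with $N$ clones and $L$ leaves, with $d(l)$ the edge
count from leaf $l$ to the root,

$$\mathrm{Tree\ score} \;=\; 1 \;-\; \frac{1}{L}\sum_{l}\frac{d(l)}{N-1}.$$

A strictly linear phylogeny has one leaf at depth $N-1$, so it scores
exactly 0 for every $N$; the star (root plus $N-1$ leaves at depth 1)
attains the maximum $1 - 1/(N-1)$. Exhaustive enumeration of rooted
topologies (part of the test suite) confirms that a positive score first
becomes attainable at $N = 3$: with one or two clones no branching is
expressible. For $N = 1$ the formula divides by zero; we define the score
as 0, which is continuous with the linear case.

## Likelihood-weighted consensus

Probabilistic reconstruction returns hundreds of candidate trees per
sample, each with a complete-data log-likelihood (CDLL). `clonearch`
summarizes a sample in two steps:

1. `select_top_fraction()` keeps the best `fraction` of candidates by CDLL
   (default 0.1, i.e. the top 10%); the retained count is
   `ceiling(fraction * n)` with a minimum of 1, and CDLL ties are broken by
   input order (candidate order is the only information available — the
   tools do not define a canonical tie order).
2. `s50_weights()` assigns each retained tree the min–max normalized weight
   $(\mathrm{CDLL}_i - \min)/(\max - \min)$; `consensus_summary()` then
   reports the weighted means of clone count, Tree score, and clonal and
   subclonal mutation counts. When all retained CDLLs are equal the weight
   formula is 0/0; we fall back to uniform weights, which preserves the
   plain mean.

Note that the worst retained tree always receives weight 0: it still
appears in `n_candidates_used` but does not influence the means.

## The branching-process tumor simulator

`simulate_tumor()` implements a discrete-time Galton–Watson model. Each
generation, a cell with $k$ accumulated drivers dies with probability
$d(k,s) = \tfrac12(1-s)^k$ and otherwise replicates; on replication one of
the two daughters acquires a new alteration with probability $\mu$, and a
mutated daughter founds a new clone whether the alteration is a driver or a
passenger. A driver-free population is exactly critical (expected offspring
1 per cell), which the tests verify against the martingale property.

Simulation is clone-level, not cell-level: deaths, replications and mutated
daughters within a clone are binomial draws, which is distributionally
exact because cells of a clone are exchangeable. This makes desk-scale
sweeps cheap without changing the model.

Design choices the model description leaves open:

* **Driver probability.** The constant $K = 0.025$ is motivated as the
  approximate fraction of genes that are cancer drivers, which reads as a
  driver *fraction*; the literal product form $P(\mathrm{driver}) = K\mu$
  makes drivers $\sim\mu^2$-rare, under which simulated tumors essentially
  never expand at realistic $\mu$. Both are implemented
  (`driver_mode = "conditional_K"`, the default, and
  `"conditional_K_mu"`); neither is asserted to be the original intent.
* **Stopping rule.** Growth stops at `n_max` cells (default $10^5$) or
  `g_max` generations (default 2000), whichever comes first. These keep
  multi-clone expansions observable at desk-scale runtimes.
* **Extinction.** Starting from one cell, a near-critical process almost
  surely dies. With `condition_on_survival = TRUE` (default) extinct runs
  restart with a fresh seed stream up to `max_attempts = 100` times, and
  the attempt count is reported so the survivorship conditioning is
  auditable. `parameter_sweep()` records a cell whose budget is exhausted
  as an extinct row rather than failing, because the near-critical corner
  of the $(\mu, s)$ plane is expected to behave exactly that way.
* **Detection floor.** `extract_phylogeny()` keeps clones holding at least
  1% of the final population — the VAF floor below which exome studies do
  not call variants. Private mutations of dropped intermediate ancestors
  collapse into their nearest retained descendant (what bulk sequencing
  would attribute there); mutations of dropped terminal lineages are lost.
  If the founding clone itself falls under the floor while several retained
  lineages survive, the retained set's most recent common ancestor is kept
  so the output is a single rooted tree.

## Per-sample instability metrics

From MAF-like mutation tables and SEG segmentations, `sample_metrics()`
reports: the mutation count (every variant row counts; no consequence
filtering, no deduplication of multi-allelic sites), the number of
copy-number-altered segments (mean log-ratio strictly above 0.3 or below
−0.3), and the mean number of reads per mutated site (mean RMS), a
sequencing-depth covariate that bounds the detectability of rare clones.
Samples are stratified into instability classes by strict thresholds of
300 mutations and 80 altered segments: `M` (many mutations only), `C`
(many CNAs only), `MC` (both), `Low` otherwise. Boundary equality falls in
the lower category, so the measure-zero boundary is absorbed by `Low` (or
the single-sided class). `clone_heatmap()` bins samples on
`log1p`-transformed, cohort-maximum-normalized burden axes (20 bins per
axis by default; `log1p` admits zero counts, and natural versus base-10
log only rescales the normalized axes, so the choice is immaterial).

When several purity/ploidy solutions exist for a sample,
`select_absolute_solution()` keeps the one minimizing the unweighted
squared Euclidean distance to a curated reference pair, ties to the first
listed — deliberately unweighted, as the selection criterion is stated in
raw (purity, ploidy) units.

## Neutral-evolution classification

Under neutral growth the cumulative count of subclonal mutations with VAF
at least $f$ is linear in $1/f$. `neutral_fit()` computes the empirical
$M(f)$ curve over the window $f \in [0.12, 0.24]$ (the window in which
exome sequencing sees subclonal mutations reliably while excluding clonal
ones near 0.5; configurable and recorded in the output), fits ordinary
least squares of $M(f)$ on $1/f$ through an intercept, and classifies a
sample as exhibiting neutral features when $R^2 > 0.98$ (strict). Samples
with fewer than 10 in-window mutations — or fewer than 3 distinct support
points, where a line fits vacuously — are *unevaluable* (`NA`), not
non-neutral. VAFs are used as read ratios with no purity or copy-number
correction.

## Clonal/subclonal enrichment

Feature score matrices (e.g. mutational-signature exposures) are binarized
— any positive score means the patient exhibits the feature. For each
feature and tumor type, `enrichment_scan()` asks whether carriers have
more clonal and, separately, more subclonal mutations than non-carriers.
"Wilcoxon one-tailed" is implemented as the two-sample rank-sum
(Mann–Whitney) test, the only coherent two-group reading; the exact null
distribution is used when the smaller group has at most 8 observations and
there are no ties, otherwise the tie-corrected normal approximation with
continuity correction. P-values become scores ($-\log_{10} p$);
Benjamini–Hochberg FDR is controlled independently within each tumor type,
and FDR columns are always emitted. Default score cuts are 2.5 for
signatures and 3.0 ($p < 10^{-3}$) for alterations; classes are `C`
(clonal only above the cut), `S` (subclonal only), `CS` (both), `none`.
Feature–type pairs with fewer than 3 carriers or non-carriers are skipped
with a recorded reason rather than tested degenerately.

## What the synthetic cohorts emulate

`generate_cohort()` produces everything the pipeline consumes, under one
master seed:

* **True trees** grow by sequential attachment: each new clone attaches to
  the root with probability `branching_tendency`, otherwise it extends the
  most recent lineage — 0 yields the chain (score 0), 1 the star. (A rule
  that attached "anywhere uniformly" could not reach the linear limit, so
  the interpolation is between chain and star.) Cell fractions follow a
  stick-breaking scheme down the tree, so subtree fractions are consistent
  and sum to at most 1.
* **Mutation tables** observe each clone's mutations at expected VAF
  `purity × CCF / 2` — a diploid convention with no copy-number-aware
  multiplicity — with Poisson depth (mean 100, exome-like) and binomial
  alternate reads; records below 1% observed VAF are dropped, emulating
  the detection floor.
* **Candidate sets** are the true tree plus Poisson-many perturbation
  moves per candidate. Moves include clone merges and splits, not only
  prune–regraft: regrafting alone preserves the clone count, which would
  make consensus clone-count recovery vacuous. Pseudo-CDLLs are
  `-(moves) × cdll_gap` plus standard Gumbel noise — heavy-tailed enough
  to scramble rankings occasionally, so the S50 weighting is exercised
  nontrivially while the true topology wins in expectation. Cohorts use
  50 candidates per sample, a scaled-down stand-in for a 500-tree harvest.
* **Burdens and segments** realize a configurable Low/M/C/MC class mix,
  drawn log-uniformly inside each class region and away from the 300/80
  boundaries so classification is unambiguous; altered segment values land
  strictly outside the (−0.3, 0.3) band. Clone counts are drawn per class
  so doubly-unstable (MC) samples carry the most clones — the gradient the
  heatmap analysis is meant to recover.
* **Feature matrices** draw carriers at a configured prevalence; planted
  features resample carriers' clonal or subclonal counts with a
  multiplicative Poisson shift, null features are untouched. Planting is
  sequential on the shared per-sample counts, so stacking several planted
  features on one target compounds.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: copy-number-aware VAF multiplicities,
trinucleotide mutation contexts (signature calls are abstract binary
features), sampling of multiple regions per tumor, caller-specific error
modes, and any coupling between purity and burden. Conclusions about real
cohorts rest on the method, not on these simulations.

## Numerical choices and degenerate inputs

* Single-clone trees: Tree score 0; depth counted in edges; the root of a
  one-node tree is its own leaf at depth 0.
* Degenerate S50 range (all CDLLs equal): uniform weights.
* Zero-mutation roots are legal but flagged (some reconstructions emit a
  non-cancerous root).
* Classification boundaries (exactly 300 / 80) are `Low`-ward; the
  neutrality cut and the CNA value cuts are strict.
* All simulation randomness flows from one top-level seed through a
  deterministic child-seed derivation, so any grid cell, sample or
  replicate can be reproduced in isolation; identical seeds give
  bit-identical results.

## Problem sizes

The shipped tests and reference computations run at desk scale, stated
here as package choices: Tree-score enumeration is exhaustive to $N = 7$
(874 topologies); simulator calibration uses 2,000 replicates of a
100-cell critical process over 50 generations; the $(\mu, s)$ sweep is a
4×4 log-grid spanning $\mu \in [10^{-7}, 10^{-3}]$ and
$s \in [10^{-4}, 0.5]$ with 10 replicates per cell; synthetic cohorts use
100–200 samples with 50 candidate trees each. Larger runs only tighten the
Monte-Carlo error around the same expectations.

## Worked example

```{r example, eval = FALSE}
cfg <- cohort_config(n_samples = 50, seed = 7)
bundle <- generate_cohort(cfg)
dir <- tempfile()
write_cohort(bundle, dir)

report <- run_pipeline(pipeline_config(
  tree_json = file.path(dir, "trees.json"),
  maf = file.path(dir, "mutations.maf.tsv"),
  seg = file.path(dir, "segments.seg.tsv"),
  features = file.path(dir, "features.tsv"),
  tumor_types = file.path(dir, "tumor_types.tsv"),
  purity = file.path(dir, "purity.tsv"),
  out_dir = file.path(dir, "out")
))
report$consensus
report$metrics

plot_tree_score(dplyr::rename(report$consensus,
                              n_clones = mean_n_clones,
                              tree_score = mean_tree_score))
```

## Known limitations

* Consensus summaries average clone counts and scores but do not build a
  consensus *topology*; the weighted means are the cohort-level statistics
  of interest here.
* The neutrality fit inherits the two-point caveat: with exactly two
  distinct in-window VAF values a line fits perfectly, so at least three
  support points are required before a fit is attempted.
* The simulator has no spatial structure, no copy-number events and no
  sequencing-read emulation; it models clone birth and selection only.
* Subclonal reconstruction itself (VAF clustering, MCMC tree inference)
  and purity/ploidy estimation are out of scope: the package consumes
  their outputs.
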