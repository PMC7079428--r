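---
title: "Linking transcript abundance to phenotypic traits with DUO, Pearson and Spearman"
author: "duonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking transcript abundance to phenotypic traits with DUO, Pearson and Spearman}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duonet)
```

## The problem

In a segregating population — here modelled on a biparental cross of
tetraploid potato, with two parents and 34 progeny lines — transcripts whose
abundance co-varies with a measured phenotype are candidate expression
markers for that trait.  `duonet` scores every transcript–trait pair with
three complementary similarity measures:

* **Pearson** correlation, for linear abundance–trait relationships;
* **Spearman** correlation, for monotone but possibly nonlinear ones;
* **DUO**, a co-occurrence metric over discretized HIGH/LOW expression and
  trait states, for associations carried by the *extremes* of the
  distributions rather than by their overall shape.

DUO is an adaptation of the Custom Correlation Coefficient (CCC), a
co-occurrence correlation originally designed for two-category genotype
vectors; here the two categories are high and low abundance/trait states.

## The pipeline and its model

The pipeline order is fixed and mirrors how the three metrics are defined:

1. **Abundance filter.**  Transcripts are retained when their abundance
   (FPKM/TPM; unitless, assumed already depth- and length-normalized) is
   *strictly greater than* `minAbundance = 5` in at least `minSamples = 8`
   of the samples.  "More than five" is read as a strict inequality; a
   transcript at exactly 5 everywhere is dropped.  Both the threshold, the
   count, the comparator, and the sample subset over which qualifying
   samples are counted are exposed, because informal phrasings of this rule
   differ in whether parents count toward the eight.  The default counts
   all samples.
2. **Row scaling.**  Transcript and trait rows are stacked over one ordered
   sample list and each row is divided by its own non-missing maximum:
   \(x_i^\ast = x_i / \max(X)\).  Every surviving row then lies in
   \([0,1]\) and attains exactly 1.  Rows with maximum 0 carry no signal
   and are dropped with a report.  Negative values would silently break the
   \([0,1]\) guarantee, so they are an error: shift or re-encode traits to
   a nonnegative scale first.  An optional `zscore` mode (row mean/SD) is
   provided for comparison; Pearson and Spearman are invariant to the
   choice, and the DUO discretization is always defined on the max-scaled
   matrix.
3. **Matrix-wide discretization.**  Two thresholds are computed from the
   *pooled* non-missing values of the combined matrix — transcripts and
   traits jointly, since both row kinds live in the same matrix — such that
   25% of values lie above the upper threshold (HIGH) and 25% below the
   lower one (LOW).  Thresholds are nearest-rank order statistics of the
   pooled values: with \(N\) sorted values, the lower threshold is
   \(v_{(\lfloor lN \rfloor + 1)}\) and the upper
   \(v_{(\lceil (1-h)N \rceil)}\).  Cells strictly above/below become
   H/L; cells *equal to a threshold are NEUTRAL*; missing cells are
   MISSING.  With distinct values the realized fractions are within one
   cell of the targets; under heavy ties (expression matrices contain many
   zeros) the strict comparisons keep them at or below the targets, which
   makes "lay above"/"lay below" literal.  A matrix of identical values
   cannot be discretized and aborts.
4. **Scoring.**  For each pair, Pearson and Spearman are computed over
   pairwise-complete samples (Spearman as Pearson on midranks, average
   ranks on ties; at least 3 complete pairs required, zero-variance pairs
   flagged undefined).  DUO computes four directional components, one per
   ordered state pair \(i \in \{H_A, L_A\}\), \(j \in \{H_B, L_B\}\):
   \[ D_{ij} = 4\,R_{ij}\,(1 - f_i/1.5)(1 - f_j/1.5) \]
   where \(R_{ij}\) is the fraction of jointly observed samples in which
   the two states co-occur and \(f_i, f_j\) are the relative state
   frequencies.  Positions missing in either vector are excluded from
   \(n\), \(R\) and \(f\), keeping all quantities coherent per pair — the
   same pairwise-complete convention the correlations use.  With quartile
   discretization (\(f = 0.25\)) a component is bounded by
   \(4 \cdot 0.25 \cdot (1 - 1/6)^2 = 25/36 \approx 0.694\); more generally
   by \(4\min(f_i,f_j)(1-f_i/1.5)(1-f_j/1.5)\).
5. **Thresholding and networks.**  Correlation edges require
   \(|r| \ge 0.5\) (signed weight kept); DUO emits one edge per component
   \(\ge 0.65\), the endpoints carrying the component's state tags
   (`tx:H — trait:L`).  One pair can thus contribute several DUO edges.
   Networks are undirected simple graphs, exportable as SIF, weighted
   edge-list TSV, or GraphML, with lexicographic ordering so exports diff
   cleanly.
6. **Comparison.**  Networks are compared by counting shared
   transcript–trait associations, whole-network and per trait.  Under the
   default *pair-level* matching a DUO state edge collapses to its
   unordered feature pair, because correlation edges carry no states;
   *state-level* matching (DUO edges only match identical state tags) is
   available for diagnostics.  Per-trait counts are distinct transcripts
   with at least one qualifying edge to the trait, not edge counts.
   A trait–trait Spearman table with two significance tiers (p < 0.05,
   p < 0.001; two-sided t approximation with \(n-2\) degrees of freedom,
   adequate at \(n = 36\)) summarizes phenotype structure.

Categorical traits (e.g. flowering time early/late) are numerically encoded
through a user-declared mapping — never inferred, because level orderings
are domain knowledge — and then flow through scaling and discretization like
any other row.  A binary trait lands its two levels in HIGH/LOW naturally.
No special-case logic is applied; note that an unbalanced binary trait has
a minor-level frequency near 0.25, where the DUO penalty term is weakest,
so chance co-occurrence with such traits is the main contributor to the DUO
null rate (measured below).

No p-values are attached to transcript–trait scores: selection is by the
score thresholds themselves, and no multiple-testing correction is applied.
The trait–trait table is the only place significance flags appear.

## The synthetic-data generator

`simulateDataset()` emulates the post-quantification study design: 36
samples (2 parents + 34 progeny), a log-normal FPKM-like abundance
background (meanlog 2.5, sdlog 1.2 — heavy-tailed, strictly positive;
negative-binomial counts are unnecessary because the pipeline consumes
normalized abundance, not counts), 17 traits of which 3 are two-level
categorical, sporadic missing trait values (rate 0.02), and planted
associations with machine-readable ground truth.  Planted shapes:

* `linear` — transcript \(= a\cdot\)trait\(+\) noise at a configured
  population correlation (effect = \(\rho\));
* `monotone` — a strictly increasing cubic response with noise scaled by
  \(1-\)effect;
* `duo-block-HH`/`-LL`/`-HL` — the pattern DUO targets and the correlation
  metrics miss: the extreme quartiles of trait and transcript are forced to
  co-occur, and the *remaining* values are arranged in reversed (HH, LL) or
  matching (HL) rank order between the two rows.  This counterbalancing is
  deliberate: aligning a full extreme quartile by itself induces a rank
  correlation of about 0.55, so a generator that merely shuffled the
  mid-range would produce "DUO-only" plants that Spearman flags too.  The
  reversed-rank remainder cancels that correlation — in the recovery
  sweeps the correlation metrics' flag rates on these plants are zero at
  the |r| ≥ 0.5 cut — while leaving the aligned extremes, and hence the
  DUO component, untouched.  For the HH shape
  each row's scaled maximum (structurally a HIGH cell, since max-scaled
  rows always contain a 1) is parked on the partner's low slots, giving
  state frequencies of 10/36 and a deterministic
  \(D_{HH} = 4\cdot\tfrac14\,(1 - \tfrac{10/36}{1.5})^2 = 484/729 \approx 0.664\);
  LL and HL blocks keep \(f = 9/36\) and reach \(25/36 \approx 0.694\).
* `consensus-block` — a jittered copy of the trait pattern (identical
  states, shared maximum), detected by all three metrics; and
* `midrange-linear` — a near-perfect linear pair confined to the neutral
  band, detected by both correlations but structurally invisible to DUO
  (each row has exactly one HIGH cell, its maximum, so every component is
  bounded by \(4/36 \cdot (1-1/54)^2 \approx 0.107\)).  These two shapes
  exist so that three-way network-overlap bookkeeping can be verified
  *exactly*, which stochastic detection cannot guarantee.

Pattern rows are constructed in scaled \([0,1]\) space against nearest-rank
threshold estimates computed from the scaled background, trait and
statistical-plant rows (the same pool the pipeline will threshold, minus
the pattern rows themselves, which contribute exactly 25% high and 25% low
cells and therefore leave the pooled quantiles essentially unchanged).
Band placement keeps a 15–20% safety margin around the estimates, so the
realized thresholds reproduce the designed states exactly.  Two
consequences are documented rather than hidden: pattern-plant trait rows
are kept free of missing values (an NA on the row maximum would change the
scaling anchor and destroy the planted states), and "expressed" background
rows are guaranteed to pass the default abundance filter (the generator
emulates the *retained* transcript matrix; rows below the filter are
planted explicitly via `nSilent`, clamped below 5, for exact filter
bookkeeping).

What the generator does *not* emulate: between-sample normalization
artifacts, assembly/quantification noise, transcript–transcript
co-expression structure, linkage between traits, and dosage effects of a
tetraploid cross.  Passing tests therefore demonstrate the correctness of
the pipeline's operations and the designed separation between metrics on
planted patterns — not biological sensitivity/specificity on real data.

## Numerical choices

* Quantile definition: nearest-rank order statistics (no interpolation),
  ties NEUTRAL, as above.  If the configured fractions make the two ranks
  cross (only possible when they sum to 1), the lower rank is clamped.
* All exports sort lexicographically by byte order (`radix`), independent
  of locale, and numbers are printed with `%.17g`, so writing and
  re-reading reproduces doubles bit-exactly and repeated runs are
  byte-identical.
* Seeds are explicit everywhere; the generator restores the caller's RNG
  state.  Identical config + inputs give identical outputs, including the
  run manifest (which hashes the config and inputs with MD5 and carries
  stage counts instead of timestamps).
* Spearman significance uses the t approximation rather than an exact
  permutation distribution; at \(n = 36\) and with only two reported
  significance tiers the approximation error is immaterial (the Monte-Carlo
  test pins the realized p < 0.05 rate at 0.05 ± 0.02).

## Calibration

With no planted effects, the measured false-positive rates at the default
thresholds, averaged over 50 generator seeds (250 transcripts × 17 traits
each), are about 0.18% for Pearson, 0.24% for Spearman and 0.03% for DUO;
the test suite pins them below 0.5%, 0.6% and 0.2% respectively.  The DUO
null hits come almost entirely from unbalanced categorical traits, as
discussed above.

## Problem sizes

The test suite and the acceptance script run the full pipeline at 2000
transcripts (the generator scales to the study's 18,542; per-pair scoring
is scale-invariant, so recovery rates do not change beyond Monte-Carlo
error), recovery sweeps at 120 transcripts × 20 seeds, and null
calibration at 250 transcripts × 50 seeds.  These sizes were chosen so a
complete desk-scale replication of every property takes well under a
minute per sweep.

## Known limitations

* Observed association counts on real data (how many transcripts pass
  |r| ≥ 0.5 or DUO ≥ 0.65) are dataset-bound; the package reproduces the
  procedure, not any particular published count.
* DUO's frequency penalty assumes roughly quartile state frequencies;
  heavily unbalanced binary traits weaken it (see Calibration).
* Max-scaling is sensitive to a single outlying sample (it sets the row's
  anchor).  This is inherent to the published procedure; the `zscore` mode
  is provided for sensitivity checks but is not used for DUO.

## A worked run

```{r example, eval = FALSE}
sim <- simulateDataset(simConfig(nTranscripts = 400, seed = 7))
al <- alignSamples(sim$expression, sim$traits)
flt <- filterTranscripts(al$expression)
M <- combineAndScale(flt$expression, al$traits)
st <- discretize(M)
nets <- list(
  pearson = buildNetwork(thresholdScores(correlateAll(M, "pearson"))),
  spearman = buildNetwork(thresholdScores(correlateAll(M, "spearman"))),
  duo = buildNetwork(thresholdScores(duoAll(st))))
compareNetworks(nets, traitIds = featureIds(sim$traits))
```
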