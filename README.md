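# duonet

Trait–transcript association networks for segregating populations, scored
with Pearson, Spearman and the DUO co-occurrence metric.

## What it does

Given a transcript abundance matrix (FPKM/TPM, transcripts × samples) and a
phenotype table (traits × samples, quantitative or encoded categorical,
`NA` allowed), `duonet`:

1. filters transcripts by abundance ("more than 5 in at least 8 samples",
   thresholds configurable);
2. stacks transcripts and traits into one matrix and scales each row by its
   maximum, `x* = x / max(X)`, so all features live in [0, 1];
3. discretizes the pooled matrix into HIGH / LOW / NEUTRAL states using
   matrix-wide quartile thresholds (25% of cells above, 25% below);
4. scores every transcript–trait pair with Pearson, Spearman (pairwise
   complete, midranks on ties) and DUO

       D_ij = 4 R_ij (1 - f_i/1.5)(1 - f_j/1.5)

   where `i`/`j` range over the HIGH and LOW states of the two features,
   `R_ij` is the fraction of jointly observed samples in which the two
   states co-occur and `f_i`, `f_j` are the state frequencies — four
   directional components (HH, LL, HL, LH) per pair;
5. builds association networks at the default cuts |r| ≥ 0.5 and
   DUO ≥ 0.65 (DUO edges carry state tags, e.g. `tx:H — trait:L`),
   exports them as SIF / edge-list TSV / GraphML, and counts the
   associations shared between the three metric networks, whole-network
   and per trait;
6. computes a trait–trait Spearman table with p < 0.05 / p < 0.001 flags.

A synthetic-data module (`simConfig()` / `simulateDataset()`) generates
matrices shaped like the motivating study — 36 samples (2 parents + 34
progeny), log-normal abundance background, 17 traits of which 3 are
two-level categorical — with planted linear, monotone and extreme-quartile
block associations plus ground truth, so the whole pipeline is testable at
desk scale.  DUO exists because extreme-state co-occurrence can carry an
association that neither Pearson nor Spearman sees; the generator's
`duo-block-*` shapes realize exactly that pattern, and the test suite
verifies the separation.

See `vignettes/trait-transcript-association.Rmd` for the model, numerical
choices and calibration.

## Worked example

The bundled 8-transcript × 6-sample micro-dataset (one quantitative trait
with a missing value, one categorical trait), small enough to check by
hand:

```r
library(duonet)
fx  <- fixtureSmall()
al  <- alignSamples(fx$expression, fx$traits)
flt <- filterTranscripts(al$expression, minAbundance = 5, minSamples = 1)
M   <- combineAndScale(flt$expression, al$traits)
st  <- discretize(M)
st
#> StateMatrix: 9 features x 6 samples
#>   thresholds: lower 0.25, upper 0.9
#>   realized fractions: high 0.226 (target 0.250), low 0.245 (target 0.250)
```

One transcript co-occurs with the categorical trait in its LOW state:

```r
d <- duoAll(st)
subset(d, featureA == "t8" & featureB == "traitB")
#>  featureA stateA featureB stateB     score n
#>        t8      H   traitB      H 0.3950617 6
#>        t8      H   traitB      L 0.0000000 6
#>        t8      L   traitB      H 0.0000000 6
#>        t8      L   traitB      L 0.8888889 6

buildNetwork(thresholdScores(d))
#> AssociationNetwork (duo): 2 nodes, 1 edges
```

The LL component is 4 · (3/6) · (1 − (3/6)/1.5)² = 8/9 ≈ 0.889: three of
the six samples are LOW in both features, each feature is LOW in half the
samples.  At the default DUO cut (0.65) this is the fixture's one DUO edge,
`t8:L — traitB:L`.  The expected states and all DUO components for this
fixture are shipped in `inst/extdata/fixture_small_expected.json`,
precomputed by a brute-force reference implementation
(`scripts/make-fixture-expected.R`).

For a full run (simulation → filter → scale → discretize → score →
networks → comparison → manifest):

```r
manifest <- runPipeline(list(simulate = list(nTranscripts = 2000, seed = 1)),
                        "out/")
```

or from the shell:

```sh
Rscript inst/scripts/assoc.R simulate --seed 1 --out data/
Rscript inst/scripts/assoc.R run --config pipeline.yaml --out out/
```

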