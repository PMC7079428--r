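# Bundled deterministic micro-dataset for worked examples and end-to-end
# checks.  Small enough that scaling, thresholds, states and every DUO
# component can be verified by hand (or by the brute-force oracle that
# generated inst/extdata/fixture_small_expected.json).

#' Deterministic 8-transcript x 6-sample micro-dataset
#'
#' Returns a fixed worked example: eight transcripts, six samples, one
#' quantitative trait (with one missing observation) and one two-level
#' categorical trait.  The expected scaled values, thresholds, state labels
#' and all pairwise DUO components are shipped in
#' `system.file("extdata", "fixture_small_expected.json", package = "duonet")`,
#' precomputed by an independent position-by-position reference
#' implementation.
#'
#' @return list with `expression` ([ExpressionMatrix-class]) and `traits`
#'   ([TraitTable-class]).
#' @examples
#' fx <- fixtureSmall()
#' dim(fx$expression)
#' @export
fixtureSmall <- function() {
  samples <- paste0("s", 1:6)
  ev <- matrix(c(
    9,   1,   4,   5,   10,  0.5,
    2,   8,   6,   1,   3,   12,
    0.2, 0.3, 0.1, 0.4, 0.2, 0.5,
    30,  25,  28,  35,  27,  32,
    1,   2,   3,   4,   5,   6,
    6,   5,   4,   3,   2,   1,
    7,   7,   7,   7,   7,   14,
    1,   9,   0.5, 10,  8,   2),
    nrow = 8, byrow = TRUE,
    dimnames = list(paste0("t", 1:8), samples))
  tv <- matrix(c(
    3.5, 1.2, 2.8, NA, 4.0, 0.8,
    0,   1,   0,   1,  1,   0),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("traitA", "traitB"), samples))
  list(expression = ExpressionMatrix(ev),
       traits = TraitTable(tv,
                           c(traitA = "quantitative",
                             traitB = "categorical"),
                           list(traitB = c(early = 0, late = 1))))
}
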