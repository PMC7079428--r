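#' @import methods
NULL

STATE_CODES <- c("H", "L", "N", "M")
METRICS <- c("pearson", "spearman", "duo")

#' Transcript abundance matrix
#'
#' Container for a transcripts x samples matrix of nonnegative normalized
#' abundances (FPKM/TPM).  Quantified abundance is complete: missing cells are
#' a validity error, as are negative or non-finite values and duplicated
#' identifiers.
#'
#' @slot values numeric matrix, transcripts in rows, samples in columns;
#'   dimnames carry the transcript and sample identifiers.
#'
#' @seealso [readExpression()], [filterTranscripts()]
#' @export
setClass("ExpressionMatrix", representation(values = "matrix"))

setValidity("ExpressionMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("abundance values must be numeric")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("transcript and sample identifiers (dimnames) are required")
  err <- tryCatch({
    checkUniqueIds(rownames(v), "transcript")
    checkUniqueIds(colnames(v), "sample")
    NULL
  }, error = function(e) conditionMessage(e))
  if (!is.null(err)) return(err)
  if (anyNA(v)) return("expression values must be complete (no NA)")
  if (any(!is.finite(v))) return("expression values must be finite")
  if (any(v < 0)) return("expression values must be nonnegative")
  TRUE
})

#' @param values numeric matrix with transcript rownames and sample colnames.
#' @rdname ExpressionMatrix-class
#' @export
ExpressionMatrix <- function(values) {
  new("ExpressionMatrix", values = as.matrix(values))
}

#' Phenotype trait table
#'
#' Traits x samples matrix of numeric trait values.  Categorical traits are
#' stored as their declared numeric codes; missing observations are NA.
#'
#' @slot values numeric matrix (traits x samples), NA allowed.
#' @slot traitKind named character, one of "quantitative"/"categorical" per
#'   trait.
#' @slot encodings named list; for each categorical trait a named numeric
#'   vector mapping level label to code.
#'
#' @seealso [readTraits()], [alignSamples()]
#' @export
setClass("TraitTable",
         representation(values = "matrix", traitKind = "character",
                        encodings = "list"))

setValidity("TraitTable", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("trait values must be numeric")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("trait and sample identifiers (dimnames) are required")
  err <- tryCatch({
    checkUniqueIds(rownames(v), "trait")
    checkUniqueIds(colnames(v), "sample")
    NULL
  }, error = function(e) conditionMessage(e))
  if (!is.null(err)) return(err)
  if (any(!is.finite(v) & !is.na(v)))
    return("non-missing trait values must be finite")
  kind <- object@traitKind
  if (!identical(lexSort(names(kind)), lexSort(rownames(v))))
    return("traitKind must be named by the trait identifiers")
  if (!all(kind %in% c("quantitative", "categorical")))
    return("traitKind entries must be 'quantitative' or 'categorical'")
  catTraits <- names(kind)[kind == "categorical"]
  if (!all(catTraits %in% names(object@encodings)))
    return("every categorical trait needs an encoding")
  for (tr in catTraits) {
    enc <- object@encodings[[tr]]
    if (is.null(names(enc)) || !is.numeric(enc))
      return(sprintf("encoding for '%s' must be a named numeric vector", tr))
    x <- v[tr, ]
    if (!all(x[!is.na(x)] %in% enc))
      return(sprintf("categorical trait '%s' contains values outside its encoding", tr))
  }
  TRUE
})

#' @param values numeric matrix with trait rownames and sample colnames.
#' @param traitKind named character vector ("quantitative"/"categorical");
#'   defaults to all-quantitative.
#' @param encodings named list of label->code vectors for categorical traits.
#' @rdname TraitTable-class
#' @export
TraitTable <- function(values, traitKind = NULL, encodings = list()) {
  values <- as.matrix(values)
  if (is.null(traitKind))
    traitKind <- setNames(rep("quantitative", nrow(values)), rownames(values))
  new("TraitTable", values = values, traitKind = traitKind,
      encodings = encodings)
}

#' Row-scaled combined feature matrix
#'
#' The union of transcript and trait rows over one shared ordered sample list,
#' after row-wise scaling.  Under the default "max" scaling every row is
#' divided by its own non-NA maximum, so values lie in [0, 1] and each
#' surviving row attains exactly 1.  NA is allowed only in trait rows.
#'
#' @slot values numeric matrix (features x samples).
#' @slot featureType named character, "transcript" or "trait" per row.
#' @slot scalingMode "max" or "zscore".
#' @slot dropped character, identifiers of rows removed because scaling was
#'   undefined (zero maximum / zero variance).
#'
#' @seealso [combineAndScale()], [discretize()]
#' @export
setClass("CombinedMatrix",
         representation(values = "matrix", featureType = "character",
                        scalingMode = "character", dropped = "character"))

setValidity("CombinedMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("feature and sample identifiers (dimnames) are required")
  ft <- object@featureType
  if (!identical(names(ft), rownames(v)))
    return("featureType must be named by (and ordered as) the feature ids")
  if (!all(ft %in% c("transcript", "trait")))
    return("featureType entries must be 'transcript' or 'trait'")
  if (!object@scalingMode %in% c("max", "zscore"))
    return("scalingMode must be 'max' or 'zscore'")
  tx <- v[ft == "transcript", , drop = FALSE]
  if (anyNA(tx)) return("transcript rows must not contain NA")
  if (object@scalingMode == "max") {
    if (any(v < 0, na.rm = TRUE) || any(v > 1, na.rm = TRUE))
      return("max-scaled values must lie in [0, 1]")
    rowMax <- apply(v, 1, max, na.rm = TRUE)
    if (any(rowMax != 1))
      return("every max-scaled row must attain exactly 1")
  }
  TRUE
})

#' Discretized state matrix
#'
#' Per-cell HIGH/LOW/NEUTRAL/MISSING labels (coded "H"/"L"/"N"/"M") together
#' with the two matrix-wide thresholds that produced them.  A cell is "H" iff
#' its value is strictly above the upper threshold, "L" iff strictly below the
#' lower one; values equal to a threshold are "N", NA cells are "M".
#'
#' @slot states character matrix of state codes.
#' @slot featureType named character as in [CombinedMatrix-class].
#' @slot lowerThreshold,upperThreshold numeric scalars.
#' @slot highFraction,lowFraction configured target fractions.
#' @slot realizedHigh,realizedLow realized matrix-wide state fractions.
#'
#' @seealso [discretize()], [duoAll()]
#' @export
setClass("StateMatrix",
         representation(states = "matrix", featureType = "character",
                        lowerThreshold = "numeric", upperThreshold = "numeric",
                        highFraction = "numeric", lowFraction = "numeric",
                        realizedHigh = "numeric", realizedLow = "numeric"))

setValidity("StateMatrix", function(object) {
  s <- object@states
  if (!is.character(s)) return("states must be a character matrix")
  if (is.null(rownames(s)) || is.null(colnames(s)))
    return("feature and sample identifiers (dimnames) are required")
  if (!all(s %in% STATE_CODES))
    return("states must be one of H, L, N, M")
  if (!identical(names(object@featureType), rownames(s)))
    return("featureType must be named by (and ordered as) the feature ids")
  if (object@lowerThreshold > object@upperThreshold)
    return("lowerThreshold must not exceed upperThreshold")
  TRUE
})

#' DUO score for one feature pair
#'
#' The four directional co-occurrence components of the DUO metric for a
#' feature pair, D_ij = 4 R_ij (1 - f_i/1.5)(1 - f_j/1.5), where i is the
#' high or low state of the first feature, j of the second, R_ij the fraction
#' of jointly observed samples in which i and j co-occur, and f the relative
#' state frequencies.
#'
#' @slot pair character(2), the two feature identifiers.
#' @slot components named numeric, keys "HH","LL","HL","LH".
#' @slot R named numeric, per-component co-occurrence fractions.
#' @slot fA,fB named numeric, per-state relative frequencies ("H","L").
#' @slot n integer, jointly non-missing sample count.
#'
#' @seealso [duoPair()]
#' @export
setClass("DuoScore",
         representation(pair = "character", components = "numeric",
                        R = "numeric", fA = "numeric", fB = "numeric",
                        n = "integer"))

#' Correlation score for one feature pair
#'
#' @slot pair character(2).
#' @slot metric "pearson" or "spearman".
#' @slot r correlation coefficient in [-1, 1] (NA when undefined).
#' @slot n pairwise-complete sample count.
#'
#' @seealso [correlatePair()]
#' @export
setClass("CorrelationScore",
         representation(pair = "character", metric = "character",
                        r = "numeric", n = "integer"))

#' Association network
#'
#' Undirected simple graph of feature(-state) nodes connected by
#' above-threshold association edges of a single metric.  DUO edge endpoints
#' carry state tags ("feature:H"/"feature:L"); correlation edges do not.
#'
#' @slot edges data.frame with columns featureA, stateA, featureB, stateB,
#'   weight, n.
#' @slot metric provenance tag, one of "pearson", "spearman", "duo".
#'
#' @seealso [buildNetwork()], [exportNetwork()], [compareNetworks()]
#' @export
setClass("AssociationNetwork",
         representation(edges = "data.frame", metric = "character"))

setValidity("AssociationNetwork", function(object) {
  if (!object@metric %in% METRICS)
    return("metric must be one of pearson, spearman, duo")
  e <- object@edges
  need <- c("featureA", "stateA", "featureB", "stateB", "weight", "n")
  if (!all(need %in% names(e)))
    return(paste("edges must have columns:", paste(need, collapse = ", ")))
  if (nrow(e) == 0) return(TRUE)
  if (any(e$featureA == e$featureB & (is.na(e$stateA) | e$stateA == e$stateB)))
    return("self-loops are not allowed")
  if (object@metric == "duo") {
    if (any(is.na(e$stateA) | is.na(e$stateB)) ||
        !all(c(e$stateA, e$stateB) %in% c("H", "L")))
      return("DUO edges must carry H/L state tags on both endpoints")
  } else if (!all(is.na(e$stateA) & is.na(e$stateB))) {
    return("correlation edges must not carry state tags")
  }
  key <- edgeKeys(e, stateLevel = TRUE)
  if (anyDuplicated(key)) return("duplicate edges are not allowed")
  TRUE
})

#' Network overlap summary
#'
#' Edge-sharing counts between the Pearson, Spearman and DUO association
#' networks: whole-network pair counts, per-trait distinct-transcript counts,
#' and Venn-ready region sizes, all under a declared matching rule.
#'
#' @slot overall named numeric: P, S, D singletons, pairwise and triple
#'   intersections of association pairs.
#' @slot perTrait data.frame of per-trait distinct-transcript counts.
#' @slot transcriptVenn named numeric: whole-network distinct-transcript
#'   counts and intersections.
#' @slot matching "pair" or "state".
#'
#' @seealso [compareNetworks()]
#' @export
setClass("OverlapSummary",
         representation(overall = "numeric", perTrait = "data.frame",
                        transcriptVenn = "numeric", matching = "character"))
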