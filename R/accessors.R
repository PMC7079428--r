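# Accessors, dim() and show() methods for the data containers.

#' @describeIn ExpressionMatrix-class the abundance matrix.
#' @export
setMethod("featureValues", "ExpressionMatrix", function(x) x@values)

#' @describeIn TraitTable-class the trait code matrix.
#' @export
setMethod("featureValues", "TraitTable", function(x) x@values)

#' @describeIn CombinedMatrix-class the scaled feature matrix.
#' @export
setMethod("featureValues", "CombinedMatrix", function(x) x@values)

#' @describeIn ExpressionMatrix-class transcript identifiers.
#' @export
setMethod("featureIds", "ExpressionMatrix", function(x) rownames(x@values))

#' @describeIn TraitTable-class trait identifiers.
#' @export
setMethod("featureIds", "TraitTable", function(x) rownames(x@values))

#' @describeIn CombinedMatrix-class feature identifiers.
#' @export
setMethod("featureIds", "CombinedMatrix", function(x) rownames(x@values))

#' @describeIn StateMatrix-class feature identifiers.
#' @export
setMethod("featureIds", "StateMatrix", function(x) rownames(x@states))

#' @describeIn ExpressionMatrix-class sample identifiers.
#' @export
setMethod("sampleIds", "ExpressionMatrix", function(x) colnames(x@values))

#' @describeIn TraitTable-class sample identifiers.
#' @export
setMethod("sampleIds", "TraitTable", function(x) colnames(x@values))

#' @describeIn CombinedMatrix-class sample identifiers.
#' @export
setMethod("sampleIds", "CombinedMatrix", function(x) colnames(x@values))

#' @describeIn StateMatrix-class sample identifiers.
#' @export
setMethod("sampleIds", "StateMatrix", function(x) colnames(x@states))

#' @describeIn CombinedMatrix-class per-feature type tag.
#' @export
setMethod("featureType", "CombinedMatrix", function(x) x@featureType)

#' @describeIn StateMatrix-class per-feature type tag.
#' @export
setMethod("featureType", "StateMatrix", function(x) x@featureType)

#' @describeIn TraitTable-class per-trait kind flag.
#' @export
setMethod("traitKind", "TraitTable", function(x) x@traitKind)

#' @describeIn TraitTable-class label-to-code encodings.
#' @export
setMethod("traitEncodings", "TraitTable", function(x) x@encodings)

#' @describeIn StateMatrix-class the H/L/N/M state code matrix.
#' @export
setMethod("stateCodes", "StateMatrix", function(x) x@states)

#' @describeIn StateMatrix-class the lower/upper thresholds.
#' @export
setMethod("stateThresholdsOf", "StateMatrix", function(x)
  c(lower = x@lowerThreshold, upper = x@upperThreshold))

#' @describeIn StateMatrix-class realized matrix-wide high/low fractions.
#' @export
setMethod("realizedFractions", "StateMatrix", function(x)
  c(high = x@realizedHigh, low = x@realizedLow))

#' @describeIn DuoScore-class the four named components.
#' @export
setMethod("duoComponents", "DuoScore", function(x) x@components)

#' @describeIn AssociationNetwork-class the edge table.
#' @export
setMethod("networkEdges", "AssociationNetwork", function(x) x@edges)

#' @describeIn AssociationNetwork-class the metric provenance tag.
#' @export
setMethod("networkMetric", "AssociationNetwork", function(x) x@metric)

#' @describeIn AssociationNetwork-class node names (state-tagged for DUO).
#' @export
setMethod("networkNodes", "AssociationNetwork", function(x) {
  e <- x@edges
  if (nrow(e) == 0) return(character())
  lexSort(unique(c(nodeNames(e$featureA, e$stateA),
                   nodeNames(e$featureB, e$stateB))))
})

setMethod("dim", "ExpressionMatrix", function(x) dim(x@values))
setMethod("dim", "TraitTable", function(x) dim(x@values))
setMethod("dim", "CombinedMatrix", function(x) dim(x@values))
setMethod("dim", "StateMatrix", function(x) dim(x@states))

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d transcripts x %d samples\n",
              nrow(object@values), ncol(object@values)))
  cat("  abundance range:",
      sprintf("[%.4g, %.4g]", min(object@values), max(object@values)), "\n")
})

setMethod("show", "TraitTable", function(object) {
  k <- table(factor(object@traitKind, c("quantitative", "categorical")))
  cat(sprintf("TraitTable: %d traits (%d quantitative, %d categorical) x %d samples\n",
              nrow(object@values), k[["quantitative"]], k[["categorical"]],
              ncol(object@values)))
  cat(sprintf("  missing cells: %d\n", sum(is.na(object@values))))
})

setMethod("show", "CombinedMatrix", function(object) {
  cat(sprintf("CombinedMatrix (%s-scaled): %d features (%d transcripts, %d traits) x %d samples\n",
              object@scalingMode, nrow(object@values),
              sum(object@featureType == "transcript"),
              sum(object@featureType == "trait"), ncol(object@values)))
  if (length(object@dropped))
    cat("  dropped rows (undefined scaling):",
        paste(object@dropped, collapse = ", "), "\n")
})

setMethod("show", "StateMatrix", function(object) {
  cat(sprintf("StateMatrix: %d features x %d samples\n",
              nrow(object@states), ncol(object@states)))
  cat(sprintf("  thresholds: lower %.6g, upper %.6g\n",
              object@lowerThreshold, object@upperThreshold))
  cat(sprintf("  realized fractions: high %.3f (target %.3f), low %.3f (target %.3f)\n",
              object@realizedHigh, object@highFraction,
              object@realizedLow, object@lowFraction))
})

setMethod("show", "DuoScore", function(object) {
  cat(sprintf("DuoScore %s -- %s (n = %d)\n",
              object@pair[1], object@pair[2], object@n))
  print(round(object@components, 6))
})

setMethod("show", "CorrelationScore", function(object) {
  cat(sprintf("CorrelationScore (%s) %s -- %s: r = %.6g, n = %d\n",
              object@metric, object@pair[1], object@pair[2],
              object@r, object@n))
})

setMethod("show", "AssociationNetwork", function(object) {
  cat(sprintf("AssociationNetwork (%s): %d nodes, %d edges\n",
              object@metric, length(networkNodes(object)),
              nrow(object@edges)))
})

setMethod("show", "OverlapSummary", function(object) {
  cat(sprintf("OverlapSummary (%s-level matching)\n", object@matching))
  cat("  association pairs:\n")
  print(object@overall)
  cat("  distinct transcripts (whole network):\n")
  print(object@transcriptVenn)
  cat(sprintf("  per-trait counts: %d traits (see perTrait slot)\n",
              nrow(object@perTrait)))
})
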