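# Abundance filtering, row scaling and matrix-wide discretization.

#' Filter transcripts by minimum abundance
#'
#' Retains the transcripts whose abundance exceeds `minAbundance` in at least
#' `minSamples` samples — the "more than five in at least eight" rule, with
#' both the threshold and the comparator exposed.  Row order is preserved; an
#' empty result is legal and reported.
#'
#' @param expr an [ExpressionMatrix-class].
#' @param minAbundance abundance threshold (default 5, FPKM/TPM units).
#' @param minSamples minimum number of qualifying samples (default 8).
#' @param comparator `"gt"` (strict, the default reading of "more than") or
#'   `"ge"`.
#' @param samples optional character vector restricting which samples are
#'   counted (e.g. progeny only); all samples by default.
#' @return list with `expression` (the filtered matrix) and `report`
#'   (`kept`, `dropped` counts and the kept ids).
#' @examples
#' m <- ExpressionMatrix(matrix(c(6, 6, 0, 0), 2, 2,
#'   dimnames = list(c("tA", "tB"), c("s1", "s2"))))
#' filterTranscripts(m, minAbundance = 5, minSamples = 1)$report$kept
#' @export
filterTranscripts <- function(expr, minAbundance = 5, minSamples = 8,
                              comparator = c("gt", "ge"), samples = NULL) {
  stopifnot(is(expr, "ExpressionMatrix"))
  comparator <- match.arg(comparator)
  v <- expr@values
  if (!is.null(samples)) {
    if (!all(samples %in% colnames(v)))
      stop("unknown sample(s): ",
           paste(setdiff(samples, colnames(v)), collapse = ", "))
    v <- v[, samples, drop = FALSE]
  }
  if (minAbundance < 0) stop("minAbundance must be >= 0")
  if (minSamples < 1 || minSamples > ncol(v))
    stop("minSamples must be between 1 and the number of samples counted")
  hits <- if (comparator == "gt") v > minAbundance else v >= minAbundance
  keep <- rowSums(hits) >= minSamples
  list(expression = ExpressionMatrix(expr@values[keep, , drop = FALSE]),
       report = list(kept = sum(keep), dropped = sum(!keep),
                     keptIds = rownames(v)[keep]))
}

#' Combine expression and trait rows into one row-scaled matrix
#'
#' Stacks transcript and trait rows over a shared ordered sample list and
#' scales each row.  Under `mode = "max"` (the default) every entry is
#' divided by its row's non-NA maximum, so all features take values in
#' [0, 1]; rows whose maximum is 0 carry no signal and are dropped with a
#' report.  `mode = "zscore"` centers and scales by the row mean and
#' standard deviation instead (constant rows dropped); Pearson and Spearman
#' are invariant to the choice, the DUO discretization is defined on the
#' max-scaled matrix.
#'
#' Negative values break the [0, 1] guarantee and are rejected under max
#' scaling: shift or re-encode traits to a nonnegative scale first.
#'
#' @param expr an [ExpressionMatrix-class].
#' @param traits a [TraitTable-class] over the same samples in the same
#'   order (see [alignSamples()]).
#' @return a [CombinedMatrix-class].
#' @examples
#' # a row c(2, 4, 8, 0) scales to c(0.25, 0.5, 1, 0)
#' @export
combineAndScale <- function(expr, traits, mode = c("max", "zscore")) {
  stopifnot(is(expr, "ExpressionMatrix"), is(traits, "TraitTable"))
  mode <- match.arg(mode)
  if (!identical(sampleIds(expr), sampleIds(traits)))
    stop("expression and trait samples differ or are ordered differently; ",
         "run alignSamples() first")
  overlap <- intersect(featureIds(expr), featureIds(traits))
  if (length(overlap))
    stop("transcript and trait identifiers overlap: ",
         paste(overlap, collapse = ", "))
  v <- rbind(expr@values, traits@values)
  type <- setNames(rep(c("transcript", "trait"),
                       c(nrow(expr@values), nrow(traits@values))),
                   rownames(v))
  if (mode == "max") {
    negRows <- rownames(v)[apply(v, 1, function(r) any(r < 0, na.rm = TRUE))]
    if (length(negRows))
      stop("negative values would break the [0, 1] scaling guarantee; ",
           "offending row(s): ", paste(negRows, collapse = ", "),
           ". Shift or re-encode these features to a nonnegative scale.")
    rowMax <- apply(v, 1, function(r) suppressWarnings(max(r, na.rm = TRUE)))
    rowMax[!is.finite(rowMax)] <- 0  # all-NA rows
    dropped <- rownames(v)[rowMax == 0]
    keep <- rowMax > 0
    scaled <- v[keep, , drop = FALSE] / rowMax[keep]
  } else {
    mu <- rowMeans(v, na.rm = TRUE)
    sd_ <- apply(v, 1, stats::sd, na.rm = TRUE)
    dropped <- rownames(v)[is.na(sd_) | sd_ == 0]
    keep <- !(is.na(sd_) | sd_ == 0)
    scaled <- (v[keep, , drop = FALSE] - mu[keep]) / sd_[keep]
  }
  if (length(dropped))
    message(length(dropped), " row(s) dropped (undefined scaling): ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  new("CombinedMatrix", values = scaled, featureType = type[keep],
      scalingMode = mode, dropped = as.character(dropped))
}

#' Discretize a combined matrix into HIGH/LOW/NEUTRAL states
#'
#' Computes two matrix-wide thresholds from the pooled non-NA values, chosen
#' as nearest-rank order statistics so that (up to) `highFraction` of the
#' cells lie strictly above the upper threshold and (up to) `lowFraction`
#' strictly below the lower one.  Cells strictly above the upper threshold
#' are labelled "H", strictly below the lower "L", NA cells "M", everything
#' else — including cells exactly equal to a threshold — "N".  With distinct
#' values the realized fractions are within one cell of the targets; under
#' heavy ties the strict comparisons keep them at or below the targets.
#'
#' @param M a [CombinedMatrix-class] (max-scaled).
#' @param highFraction,lowFraction target matrix-wide fractions (default
#'   0.25 each; must be positive and sum to at most 1).
#' @return a [StateMatrix-class].
#' @export
discretize <- function(M, highFraction = 0.25, lowFraction = 0.25) {
  stopifnot(is(M, "CombinedMatrix"))
  if (highFraction <= 0 || lowFraction <= 0 ||
      highFraction + lowFraction > 1)
    stop("fractions must be positive and sum to at most 1")
  v <- M@values
  thr <- stateThresholds(v, highFraction, lowFraction)
  s <- matrix("N", nrow(v), ncol(v), dimnames = dimnames(v))
  s[v > thr[["upper"]]] <- "H"
  s[v < thr[["lower"]]] <- "L"
  s[is.na(v)] <- "M"
  nObs <- sum(!is.na(v))
  new("StateMatrix", states = s, featureType = M@featureType,
      lowerThreshold = thr[["lower"]], upperThreshold = thr[["upper"]],
      highFraction = highFraction, lowFraction = lowFraction,
      realizedHigh = sum(s == "H") / nObs, realizedLow = sum(s == "L") / nObs)
}

#' Write a state matrix as TSV
#'
#' One-character code per cell (H/L/N/M) plus a sidecar `<path>.thresholds`
#' file recording the thresholds and fractions.
#'
#' @param x a [StateMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeStates <- function(x, path) {
  stopifnot(is(x, "StateMatrix"))
  lines <- c(paste(c("feature_id", colnames(x@states)), collapse = "\t"),
             vapply(seq_len(nrow(x@states)), function(i)
               paste(c(rownames(x@states)[i], x@states[i, ]), collapse = "\t"),
               character(1)))
  con <- file(path, open = "wb")
  writeLines(lines, con, useBytes = TRUE)
  close(con)
  side <- c(paste0("lower_threshold\t", fmtNum(x@lowerThreshold)),
            paste0("upper_threshold\t", fmtNum(x@upperThreshold)),
            paste0("high_fraction\t", fmtNum(x@highFraction)),
            paste0("low_fraction\t", fmtNum(x@lowFraction)),
            paste0("realized_high\t", fmtNum(x@realizedHigh)),
            paste0("realized_low\t", fmtNum(x@realizedLow)))
  con <- file(paste0(path, ".thresholds"), open = "wb")
  writeLines(side, con, useBytes = TRUE)
  close(con)
  invisible(path)
}
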