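# Pair scoring: the DUO co-occurrence metric and Pearson/Spearman
# correlations, plus threshold-based edge emission.

asStateVector <- function(x, what) {
  x <- as.character(x)
  if (!all(x %in% STATE_CODES))
    stop(what, " must contain only state codes H, L, N, M")
  x
}

#' DUO score for one pair of state vectors
#'
#' Computes the four directional co-occurrence components between two
#' discretized features.  For each ordered state pair (i in {H, L} of the
#' first feature, j in {H, L} of the second),
#' \deqn{D_{ij} = 4 R_{ij} (1 - f_i/1.5)(1 - f_j/1.5)}
#' where, over the n positions where neither vector is MISSING, R_ij is the
#' fraction in which i and j co-occur and f_i, f_j are the relative state
#' frequencies.  Positions with "M" in either vector are excluded from n, R
#' and f (pairwise-complete analysis).
#'
#' @param statesA,statesB equal-length character vectors of state codes
#'   ("H", "L", "N", "M").
#' @param pair optional character(2) of feature identifiers.
#' @return a [DuoScore-class] with components named "HH", "LL", "HL", "LH".
#' @examples
#' s <- c("H", "L", "N", "N")
#' duoComponents(duoPair(s, s))  # HH = LL = 25/36
#' @export
duoPair <- function(statesA, statesB, pair = c("A", "B")) {
  a <- asStateVector(statesA, "statesA")
  b <- asStateVector(statesB, "statesB")
  if (length(a) != length(b))
    stop("state vectors must have equal length")
  ok <- a != "M" & b != "M"
  n <- sum(ok)
  if (n == 0)
    stop("no jointly observed positions; DUO score undefined")
  a <- a[ok]; b <- b[ok]
  fA <- c(H = sum(a == "H"), L = sum(a == "L")) / n
  fB <- c(H = sum(b == "H"), L = sum(b == "L")) / n
  comps <- c(HH = NA_real_, LL = NA_real_, HL = NA_real_, LH = NA_real_)
  R <- comps
  for (key in names(comps)) {
    i <- substr(key, 1, 1); j <- substr(key, 2, 2)
    R[key] <- sum(a == i & b == j) / n
    comps[key] <- 4 * R[key] * (1 - fA[[i]] / 1.5) * (1 - fB[[j]] / 1.5)
  }
  new("DuoScore", pair = pair, components = comps, R = R,
      fA = fA, fB = fB, n = as.integer(n))
}

# Vectorized DUO of every transcript row against one trait state vector.
# Returns a long data.frame with 4 rows (components) per pair.
duoAgainst <- function(H, L, M, ids, statesB, idB) {
  okB <- statesB != "M"
  n <- sum(okB)
  if (n == 0) {
    return(data.frame(featureA = rep(ids, each = 4), stateA = NA_character_,
                      featureB = idB, stateB = NA_character_,
                      component = rep(c("HH", "LL", "HL", "LH"),
                                      length(ids)),
                      score = NA_real_, R = NA_real_, fA = NA_real_,
                      fB = NA_real_, n = 0L, defined = FALSE,
                      stringsAsFactors = FALSE))
  }
  Hm <- H[, okB, drop = FALSE]; Lm <- L[, okB, drop = FALSE]
  Mm <- M[, okB, drop = FALSE]
  bH <- statesB[okB] == "H"; bL <- statesB[okB] == "L"
  # transcripts have no missing cells, but keep the general pairwise rule
  obsA <- !Mm
  # per-pair n and per-pair state frequencies over jointly observed positions
  nPair <- rowSums(obsA)
  cHH <- as.vector(Hm %*% bH); cLL <- as.vector(Lm %*% bL)
  cHL <- as.vector(Hm %*% bL); cLH <- as.vector(Lm %*% bH)
  fAH <- rowSums(Hm) / nPair; fAL <- rowSums(Lm) / nPair
  fBH <- as.vector(obsA %*% bH) / nPair
  fBL <- as.vector(obsA %*% bL) / nPair
  comp <- function(cnt, fa, fb, sA, sB) {
    R <- cnt / nPair
    score <- 4 * R * (1 - fa / 1.5) * (1 - fb / 1.5)
    defined <- nPair > 0
    score[!defined] <- NA_real_
    R[!defined] <- NA_real_
    data.frame(featureA = ids, stateA = sA, featureB = idB, stateB = sB,
               component = paste0(sA, sB),
               score = score, R = R, fA = fa, fB = fb,
               n = as.integer(nPair), defined = defined,
               stringsAsFactors = FALSE)
  }
  out <- rbind(comp(cHH, fAH, fBH, "H", "H"),
               comp(cLL, fAL, fBL, "L", "L"),
               comp(cHL, fAH, fBL, "H", "L"),
               comp(cLH, fAL, fBH, "L", "H"))
  out[lexOrder(out$featureA, out$component), , drop = FALSE]
}

#' DUO scores for all selected feature pairs
#'
#' Scores every transcript-trait pair (default) or every unordered feature
#' pair of a [StateMatrix-class] with the DUO metric.  Pairs are emitted in
#' lexicographic order of the feature identifiers, four component rows per
#' pair.  Pairs with no jointly observed samples are flagged
#' (`defined = FALSE`) rather than aborting the stream.
#'
#' @param states a [StateMatrix-class].
#' @param pairs `"transcript-trait"` or `"all"`.
#' @return a data.frame with columns featureA, stateA, featureB, stateB,
#'   component, score, R, fA, fB, n, defined, metric.
#' @export
duoAll <- function(states, pairs = c("transcript-trait", "all")) {
  stopifnot(is(states, "StateMatrix"))
  pairs <- match.arg(pairs)
  s <- states@states
  type <- states@featureType
  H <- s == "H"; L <- s == "L"; M <- s == "M"
  empty <- data.frame(featureA = character(), stateA = character(),
                      featureB = character(), stateB = character(),
                      component = character(), score = numeric(),
                      R = numeric(), fA = numeric(), fB = numeric(),
                      n = integer(), defined = logical(),
                      stringsAsFactors = FALSE)
  if (pairs == "transcript-trait") {
    tx <- lexSort(rownames(s)[type == "transcript"])
    tr <- lexSort(rownames(s)[type == "trait"])
    if (length(tx) == 0 || length(tr) == 0) {
      out <- empty
    } else {
      Ht <- H[tx, , drop = FALSE]; Lt <- L[tx, , drop = FALSE]
      Mt <- M[tx, , drop = FALSE]
      out <- do.call(rbind, lapply(tr, function(j)
        duoAgainst(Ht, Lt, Mt, tx, s[j, ], j)))
      out <- out[lexOrder(out$featureA, out$featureB, out$component), ,
                 drop = FALSE]
    }
  } else {
    ids <- lexSort(rownames(s))
    if (length(ids) < 2) {
      out <- empty
    } else {
      res <- vector("list", length(ids) - 1)
      for (k in seq_len(length(ids) - 1)) {
        a <- ids[k]; rest <- ids[(k + 1):length(ids)]
        res[[k]] <- duoAgainst(H[rest, , drop = FALSE],
                               L[rest, , drop = FALSE],
                               M[rest, , drop = FALSE],
                               rest, s[a, ], a)
        # orient as (a, rest): swap endpoints and transpose the state tags
        r <- res[[k]]
        res[[k]] <- data.frame(featureA = r$featureB, stateA = r$stateB,
                               featureB = r$featureA, stateB = r$stateA,
                               component = paste0(r$stateB, r$stateA),
                               score = r$score, R = r$R, fA = r$fB,
                               fB = r$fA, n = r$n, defined = r$defined,
                               stringsAsFactors = FALSE)
      }
      out <- do.call(rbind, res)
      out <- out[lexOrder(out$featureA, out$featureB, out$component), ,
                 drop = FALSE]
    }
  }
  rownames(out) <- NULL
  out$metric <- rep("duo", nrow(out))
  out
}

#' Correlation of one feature pair
#'
#' Pearson correlation, or Spearman as the Pearson correlation of midrank
#' transformed values (average ranks on ties), over the pairwise-complete
#' positions.
#'
#' @param x,y equal-length numeric vectors (NA allowed).
#' @param method `"pearson"` or `"spearman"`.
#' @param pair optional character(2) of feature identifiers.
#' @return a [CorrelationScore-class]; `r` is NA (undefined) when either
#'   vector has zero variance over the complete positions.
#' @export
correlatePair <- function(x, y, method = c("pearson", "spearman"),
                          pair = c("x", "y")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("vectors must have equal length")
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3)
    stop("fewer than 3 pairwise-complete observations")
  r <- suppressWarnings(stats::cor(x[ok], y[ok], method = method))
  new("CorrelationScore", pair = pair, metric = method,
      r = as.numeric(r), n = as.integer(n))
}

#' Correlations for all transcript-trait pairs
#'
#' @param M a [CombinedMatrix-class] (correlations are invariant to the row
#'   scaling).
#' @param method `"pearson"` or `"spearman"`.
#' @param minN minimum pairwise-complete count for a reported score
#'   (default 3).
#' @return a data.frame with columns featureA (transcript), featureB
#'   (trait), score, n, defined, metric, in lexicographic pair order.
#' @export
correlateAll <- function(M, method = c("pearson", "spearman"), minN = 3) {
  stopifnot(is(M, "CombinedMatrix"))
  method <- match.arg(method)
  v <- M@values
  tx <- lexSort(rownames(v)[M@featureType == "transcript"])
  tr <- lexSort(rownames(v)[M@featureType == "trait"])
  if (length(tx) == 0 || length(tr) == 0)
    return(data.frame(featureA = character(), featureB = character(),
                      score = numeric(), n = integer(), defined = logical(),
                      metric = character(), stringsAsFactors = FALSE))
  A <- t(v[tx, , drop = FALSE])
  B <- t(v[tr, , drop = FALSE])
  r <- suppressWarnings(stats::cor(A, B, use = "pairwise.complete.obs",
                                   method = method))
  nMat <- crossprod(!is.na(A), !is.na(B))
  out <- data.frame(featureA = rep(tx, times = length(tr)),
                    featureB = rep(tr, each = length(tx)),
                    score = as.vector(r), n = as.integer(nMat),
                    stringsAsFactors = FALSE)
  out$defined <- !is.na(out$score) & out$n >= minN
  out$score[!out$defined] <- NA_real_
  out$metric <- method
  out <- out[lexOrder(out$featureA, out$featureB), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Emit association edges from a score stream
#'
#' Applies the per-metric thresholds: a Pearson/Spearman score becomes an
#' edge when |r| >= `corrThreshold`; each DUO component >= `duoThreshold`
#' becomes its own edge with the component's state tags on the endpoints
#' (one pair can contribute several DUO edges).  Undefined scores are
#' skipped.
#'
#' @param scores a data.frame from [correlateAll()] or [duoAll()].
#' @param corrThreshold absolute-correlation cut in (0, 1] (default 0.5).
#' @param duoThreshold DUO component cut, > 0 (default 0.65).
#' @return the qualifying rows as an edge data.frame with columns featureA,
#'   stateA, featureB, stateB, weight, n, metric.
#' @export
thresholdScores <- function(scores, corrThreshold = 0.5, duoThreshold = 0.65) {
  if (corrThreshold <= 0 || corrThreshold > 1)
    stop("corrThreshold must be in (0, 1]")
  if (duoThreshold <= 0) stop("duoThreshold must be > 0")
  stopifnot(all(c("featureA", "featureB", "score", "metric") %in%
                  names(scores)))
  ok <- if ("defined" %in% names(scores)) scores$defined else !is.na(scores$score)
  isDuo <- scores$metric == "duo"
  keep <- ok & ((isDuo & scores$score >= duoThreshold) |
                  (!isDuo & abs(scores$score) >= corrThreshold))
  keep[is.na(keep)] <- FALSE
  e <- scores[keep, , drop = FALSE]
  out <- data.frame(featureA = e$featureA,
                    stateA = if ("stateA" %in% names(e)) e$stateA else NA_character_,
                    featureB = e$featureB,
                    stateB = if ("stateB" %in% names(e)) e$stateB else NA_character_,
                    weight = e$score, n = e$n, metric = e$metric,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a score table as TSV
#'
#' @param scores a data.frame from [correlateAll()] or [duoAll()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeScores <- function(scores, path) {
  cols <- intersect(c("featureA", "stateA", "featureB", "stateB",
                      "component", "metric", "score", "R", "fA", "fB",
                      "n", "defined", "weight"), names(scores))
  s <- scores[, cols, drop = FALSE]
  num <- vapply(s, is.numeric, logical(1)) &
    !vapply(s, is.integer, logical(1))
  for (cl in names(s)[num]) s[[cl]] <- fmtNum(s[[cl]])
  lines <- c(paste(cols, collapse = "\t"),
             do.call(paste, c(lapply(s, as.character), sep = "\t")))
  con <- file(path, open = "wb")
  writeLines(lines, con, useBytes = TRUE)
  close(con)
  invisible(path)
}
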