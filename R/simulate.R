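# Synthetic expression/trait generator with planted association structure
# and machine-readable ground truth.

PLANT_SHAPES <- c("linear", "monotone", "duo-block-HH", "duo-block-LL",
                  "duo-block-HL", "consensus-block", "midrange-linear")
PATTERN_SHAPES <- c("duo-block-HH", "duo-block-LL", "duo-block-HL",
                    "consensus-block", "midrange-linear")

expectedMetricsFor <- function(shape) {
  switch(shape,
         "linear" = "pearson",
         "monotone" = "spearman",
         "duo-block-HH" = , "duo-block-LL" = , "duo-block-HL" = "duo",
         "consensus-block" = "pearson,spearman,duo",
         "midrange-linear" = "pearson,spearman")
}

#' Declare one planted association
#'
#' @param trait trait identifier the transcripts are planted on.
#' @param n number of planted transcripts.
#' @param shape one of `"linear"` (transcript = a*trait + noise),
#'   `"monotone"` (strictly increasing nonlinear response),
#'   `"duo-block-HH"`/`"-LL"`/`"-HL"` (co-occurring extreme quartiles with a
#'   rank-counterbalanced remainder — the pattern DUO targets and the
#'   correlation metrics miss), `"consensus-block"` (extreme co-occurrence
#'   plus rank-aligned remainder, detected by all three metrics), or
#'   `"midrange-linear"` (a linear pair confined to the neutral band,
#'   detected by the correlation metrics but structurally invisible to DUO).
#' @param effect effect size: the population correlation for `"linear"`,
#'   rank fidelity in (0, 1] for `"monotone"`/`"consensus-block"`/
#'   `"midrange-linear"`, and the fraction of the extreme quartile forced to
#'   co-occur for the duo-block shapes.
#' @return a plant declaration (named list) for [simConfig()].
#' @export
plant <- function(trait, n, shape, effect) {
  shape <- match.arg(shape, PLANT_SHAPES)
  if (effect <= 0 || effect > 1)
    stop("effect must be in (0, 1]")
  list(trait = trait, n = as.integer(n), shape = shape, effect = effect)
}

defaultPlants <- function() {
  list(plant("trait01", 5, "linear", 0.9),
       plant("trait02", 5, "monotone", 0.9),
       plant("trait03", 5, "duo-block-HH", 1),
       plant("trait04", 3, "duo-block-LL", 1),
       plant("trait05", 3, "duo-block-HL", 1),
       plant("trait06", 3, "consensus-block", 0.95),
       plant("trait07", 3, "midrange-linear", 0.95))
}

#' Generator configuration
#'
#' Defaults emulate the post-quantification study design: 36 samples (34
#' progeny + 2 parents), an FPKM-like log-normal abundance background,
#' 17 traits of which 3 are two-level categorical, planted linear, monotone
#' and extreme-quartile block associations, and sporadic missing trait
#' values.
#'
#' @param nSamples number of samples (2 parents + progeny).
#' @param nTranscripts total transcript rows, planted rows included.
#' @param nTraits number of traits.
#' @param nCategorical how many of the last traits are two-level categorical.
#' @param plants list of [plant()] declarations.
#' @param meanlog,sdlog log-normal background abundance parameters.
#' @param nSilent number of background rows clamped below the default
#'   abundance filter (never more than 5 FPKM), for exact filter bookkeeping.
#' @param naRate per-cell missingness rate for trait rows (pattern-plant
#'   trait rows are kept complete so their planted states are exact).
#' @param seed integer seed; fully determines the output.
#' @return a validated config of class `simConfig`.
#' @export
simConfig <- function(nSamples = 36, nTranscripts = 2000, nTraits = 17,
                      nCategorical = 3, plants = defaultPlants(),
                      meanlog = 2.5, sdlog = 1.2, nSilent = 0,
                      naRate = 0.02, seed = 1) {
  if (nSamples < 12) stop("nSamples must be at least 12")
  if (nCategorical < 0 || nCategorical > nTraits)
    stop("nCategorical must be between 0 and nTraits")
  traitIds <- sprintf("trait%02d", seq_len(nTraits))
  kind <- setNames(rep("quantitative", nTraits), traitIds)
  if (nCategorical > 0)
    kind[traitIds[(nTraits - nCategorical + 1):nTraits]] <- "categorical"
  patternTraits <- character()
  nPlanted <- 0L
  for (p in plants) {
    if (!p$trait %in% traitIds) stop("unknown plant trait: ", p$trait)
    if (kind[[p$trait]] == "categorical")
      stop("plants must target quantitative traits: ", p$trait)
    if (p$shape %in% PATTERN_SHAPES) {
      if (p$trait %in% patternTraits)
        stop("trait ", p$trait, " hosts more than one pattern-shape plant")
      patternTraits <- c(patternTraits, p$trait)
    }
    nPlanted <- nPlanted + p$n
  }
  for (p in plants)
    if (p$shape %in% c("linear", "monotone") && p$trait %in% patternTraits)
      stop("trait ", p$trait,
           " hosts a pattern plant and cannot also host ", p$shape)
  if (nPlanted + nSilent > nTranscripts)
    stop("planted (", nPlanted, ") + silent (", nSilent,
         ") rows exceed nTranscripts (", nTranscripts, ")")
  structure(list(nSamples = nSamples, nTranscripts = nTranscripts,
                 nTraits = nTraits, nCategorical = nCategorical,
                 plants = plants, meanlog = meanlog, sdlog = sdlog,
                 nSilent = nSilent, naRate = naRate, seed = seed,
                 traitIds = traitIds, traitKind = kind,
                 patternTraits = patternTraits),
            class = "simConfig")
}

# ---- pattern-pair machinery ------------------------------------------------

# value bands in scaled [0, 1] space, placed with a safety margin around the
# estimated pooled thresholds so that realized thresholds (computed on the
# full matrix) assign the intended states
patternBands <- function(q) {
  lowTop <- 0.6 * q[["lower"]]
  midLo <- 1.4 * q[["lower"]]
  midHi <- 0.8 * q[["upper"]]
  highLo <- min(1.2 * q[["upper"]], 0.9)
  highHi <- min(1.35 * q[["upper"]], 0.95)
  if (midLo >= midHi)
    stop("threshold estimates leave no neutral band; background too discrete")
  list(high = function(k) c(1, stats::runif(k - 1, highLo, highHi)),
       mid = function(k) stats::runif(k, midLo, midHi),
       low = function(k) stats::runif(k, 0, lowTop),
       bounds = list(high = c(highLo, highHi), mid = c(midLo, midHi),
                     low = c(0, lowTop)))
}

# Trait-side pattern: nE high slots, nE low slots, mids elsewhere.  For the
# HH block the trait carries nE aligned highs plus a separate maximum slot,
# so the co-occurring transcripts can park their own maxima away from the
# aligned block (keeps the residual Pearson correlation low).
makePatternTrait <- function(n, bands, shape) {
  nE <- round(0.25 * n)
  if (shape == "midrange-linear") {
    maxSlot <- sample(n, 1)
    vals <- numeric(n)
    vals[-maxSlot] <- bands$mid(n - 1)
    return(list(values = replace(vals, maxSlot, 1), highSlots = maxSlot,
                lowSlots = integer(), maxSlot = maxSlot, nE = nE))
  }
  slots <- sample(n)
  if (shape == "duo-block-HH") {
    alignHigh <- slots[seq_len(nE)]
    maxSlot <- slots[nE + 1]
    lowSlots <- slots[nE + 1 + seq_len(nE)]
    vals <- numeric(n)
    vals[alignHigh] <- bands$high(nE + 1)[-1]
    vals[maxSlot] <- 1
    vals[lowSlots] <- bands$low(nE)
    midSlots <- slots[-seq_len(2 * nE + 1)]
    vals[midSlots] <- bands$mid(length(midSlots))
    return(list(values = vals, highSlots = c(alignHigh, maxSlot),
                alignHigh = alignHigh, lowSlots = lowSlots,
                maxSlot = maxSlot, nE = nE))
  }
  highSlots <- slots[seq_len(nE)]
  lowSlots <- slots[nE + seq_len(nE)]
  vals <- numeric(n)
  hv <- bands$high(nE)
  vals[highSlots] <- hv
  vals[lowSlots] <- bands$low(nE)
  vals[slots[-seq_len(2 * nE)]] <- bands$mid(n - 2 * nE)
  list(values = vals, highSlots = highSlots, lowSlots = lowSlots,
       maxSlot = highSlots[which(hv == 1)], nE = nE)
}

# Transcript-side pattern against a fixed trait pattern.  `aligned` extremes
# of the transcript are co-assigned with the trait's extreme slots; the
# remaining slots receive the transcript's other values in reversed
# (duo-block) or matching (HL / consensus) rank order of the trait's values
# there, cancelling or preserving the residual correlation.
makePatternTranscript <- function(traitPat, shape, effect, bands, n) {
  nE <- traitPat$nE
  m <- max(1L, round(effect * nE))
  vals <- numeric(n)
  if (shape == "midrange-linear") {
    # same neutral-band ladder with jitter; shared max slot
    base <- traitPat$values
    jitterSd <- (1 - effect) * stats::sd(base[-traitPat$maxSlot])
    v <- base + stats::rnorm(n, 0, jitterSd)
    rng <- range(base[-traitPat$maxSlot])
    v <- pmin(pmax(v, rng[1]), rng[2])
    v[traitPat$maxSlot] <- 1
    return(v)
  }
  if (shape == "consensus-block") {
    # jittered copy of the trait pattern: identical states, shared maximum,
    # near-unit correlation -> detected by all three metrics
    base <- traitPat$values
    v <- base + stats::rnorm(n, 0, (1 - effect) * stats::sd(base))
    clamp <- function(idx, b) pmin(pmax(v[idx], b[1]), b[2])
    v[traitPat$highSlots] <- clamp(traitPat$highSlots, bands$bounds$high)
    v[traitPat$lowSlots] <- clamp(traitPat$lowSlots, bands$bounds$low)
    rest <- setdiff(seq_len(n), c(traitPat$highSlots, traitPat$lowSlots))
    v[rest] <- clamp(rest, bands$bounds$mid)
    v[traitPat$maxSlot] <- 1
    return(v)
  }
  # duo-block shapes
  if (shape == "duo-block-HH") {
    # m aligned highs (band values); the transcript's maximum goes to one of
    # the trait's low slots and one transcript low sits on the trait's
    # maximum slot, so both 1.0 cells pull the covariance down, not up
    alignSlots <- traitPat$alignHigh[seq_len(m)]
    vals[alignSlots] <- bands$high(m + 1)[-1]
    txMaxSlot <- traitPat$lowSlots[1]
    vals[txMaxSlot] <- 1
    vals[traitPat$maxSlot] <- bands$low(1)
    rest <- setdiff(seq_len(n), c(alignSlots, txMaxSlot, traitPat$maxSlot))
    restVals <- c(bands$high(nE - m + 1)[-1], bands$low(nE - 1),
                  bands$mid(length(rest) - (nE - m) - (nE - 1)))
    traitRest <- traitPat$values[rest]
    vals[rest[order(traitRest)]] <- sort(restVals, decreasing = TRUE)
    return(vals)
  }
  alignSlots <- traitPat$lowSlots[seq_len(m)]
  rest <- setdiff(seq_len(n), alignSlots)
  if (shape == "duo-block-HL") {
    vals[alignSlots] <- bands$high(m)
    restVals <- c(bands$high(nE - m + 1)[-1],  # drop the extra row max
                  bands$low(nE), bands$mid(length(rest) - (nE - m) - nE))
  } else { # duo-block-LL
    vals[alignSlots] <- bands$low(m)
    restVals <- c(bands$high(nE), bands$low(nE - m),
                  bands$mid(length(rest) - nE - (nE - m)))
  }
  # reversed rank order for the co-occurring LL shape (cancels the rank
  # correlation the aligned extremes induce), matching order for HL
  # (cancels the induced anti-correlation)
  decreasing <- shape == "duo-block-LL"
  traitRest <- traitPat$values[rest]
  vals[rest[order(traitRest)]] <- sort(restVals, decreasing = decreasing)
  vals
}

# ---- generator -------------------------------------------------------------

#' Generate a synthetic expression/trait dataset with ground truth
#'
#' Background transcripts are drawn from a log-normal FPKM-like distribution
#' independent of every trait; planted transcripts follow their declared
#' [plant()] shape.  Pattern shapes are constructed in scaled [0, 1] space
#' against threshold estimates from the scaled background, with safety
#' margins, then rescaled to abundance units; this makes their discretized
#' states (and hence their DUO components) exact by construction.
#'
#' @param cfg a [simConfig()].
#' @return list with `expression` ([ExpressionMatrix-class]), `traits`
#'   ([TraitTable-class]) and `truth` (plants table with expected detecting
#'   metrics, per-transcript filter flags computed by direct counting, and
#'   the threshold estimates used).
#' @export
simulateDataset <- function(cfg) {
  stopifnot(inherits(cfg, "simConfig"))
  withSeed(cfg$seed, {
    n <- cfg$nSamples
    samples <- c("P1", "P2", sprintf("L%02d", seq_len(n - 2)))
    traitIds <- cfg$traitIds
    kind <- cfg$traitKind

    # trait base values (latent z kept for linear plants)
    zTrait <- matrix(stats::rnorm(cfg$nTraits * n), cfg$nTraits, n,
                     dimnames = list(traitIds, samples))
    traitVals <- matrix(NA_real_, cfg$nTraits, n,
                        dimnames = list(traitIds, samples))
    encodings <- list()
    catLevels <- list(c(susceptible = 0, resistant = 1),
                      c(soft = 0, stiff = 1), c(early = 0, late = 1))
    ci <- 0
    for (tr in traitIds) {
      if (kind[[tr]] == "categorical") {
        ci <- ci + 1
        k <- min(max(stats::rbinom(1, n, 0.5), max(3L, n %/% 6)),
                 n - max(3L, n %/% 6))
        traitVals[tr, ] <- sample(rep(c(1, 0), c(k, n - k)))
        encodings[[tr]] <- if (ci <= length(catLevels)) catLevels[[ci]]
                           else c(level0 = 0, level1 = 1)
      } else {
        traitVals[tr, ] <- pmax(50 + 15 * zTrait[tr, ], 0.1)
      }
    }

    # background transcripts; "expressed" rows are guaranteed to pass the
    # default abundance filter, "silent" rows are clamped below it
    nPlanted <- sum(vapply(cfg$plants, `[[`, integer(1), "n"))
    nBackground <- cfg$nTranscripts - nPlanted - cfg$nSilent
    if (nBackground < 0) stop("infeasible config")
    bg <- matrix(stats::rlnorm(nBackground * n, cfg$meanlog, cfg$sdlog),
                 nBackground, n)
    for (i in seq_len(nrow(bg))) {
      short <- 8L - sum(bg[i, ] > 5)
      if (short > 0) {
        idx <- order(bg[i, ], decreasing = TRUE)[seq_len(8L)]
        idx <- idx[bg[i, idx] <= 5]
        bg[i, idx] <- stats::runif(length(idx), 6, 12)
      }
    }
    silent <- matrix(stats::runif(cfg$nSilent * n, 0, 4.5), cfg$nSilent, n)

    # planted rows: statistical shapes first (they are part of the pooled
    # value distribution the threshold estimate must reflect)
    plantRows <- list()
    plantInfo <- list()
    abundScale <- 60
    traitScale <- 25
    plantIdsOf <- function(p)
      sprintf("plant_%s_%s_%02d", gsub("[^a-zA-Z]", "", p$shape),
              p$trait, seq_len(p$n))
    for (p in cfg$plants) {
      if (p$shape %in% PATTERN_SHAPES) next
      ids <- plantIdsOf(p)
      if (p$shape == "linear") {
        z <- zTrait[p$trait, ]
        for (i in seq_len(p$n)) {
          eps <- stats::rnorm(n)
          plantRows[[ids[i]]] <-
            pmax(55 + 12 * (p$effect * z + sqrt(1 - p$effect^2) * eps), 0.1)
        }
      } else { # monotone
        t0 <- traitVals[p$trait, ]
        g <- 5 + 80 * ((t0 - min(t0)) / diff(range(t0)))^3
        for (i in seq_len(p$n)) {
          noise <- stats::rnorm(n, 0, (1 - p$effect) * stats::sd(g))
          plantRows[[ids[i]]] <- pmax(g + noise, 0.1)
        }
      }
    }

    # Pooled threshold estimate mimicking the post-filter combined matrix:
    # scaled background, scaled trait rows and scaled statistical plant rows
    # (silent rows are removed by the abundance filter and excluded here).
    # Pattern rows place exactly 25% of their cells above/below these
    # estimates, so adding them leaves the pooled quantiles essentially
    # unchanged.
    bgScaled <- bg / apply(bg, 1, max)
    traitScaled <- traitVals / apply(traitVals, 1, max, na.rm = TRUE)
    plantScaled <- if (length(plantRows)) {
      pm <- do.call(rbind, plantRows)
      as.vector(pm / apply(pm, 1, max))
    } else numeric()
    q <- stateThresholds(c(as.vector(bgScaled), plantScaled,
                           traitScaled[!is.na(traitScaled)]), 0.25, 0.25)
    bands <- patternBands(q)

    # pattern-shape plants, constructed in scaled space against the estimate
    for (p in cfg$plants) {
      if (!p$shape %in% PATTERN_SHAPES) next
      ids <- plantIdsOf(p)
      pat <- makePatternTrait(n, bands, p$shape)
      traitVals[p$trait, ] <- pat$values * traitScale
      for (i in seq_len(p$n))
        plantRows[[ids[i]]] <-
          makePatternTranscript(pat, p$shape, p$effect, bands, n) * abundScale
    }
    for (p in cfg$plants) {
      plantInfo[[length(plantInfo) + 1L]] <-
        data.frame(trait = p$trait, transcript = plantIdsOf(p),
                   shape = p$shape, effect = p$effect,
                   expectedMetrics = expectedMetricsFor(p$shape),
                   stringsAsFactors = FALSE)
    }

    exprVals <- rbind(
      if (length(plantRows)) do.call(rbind, plantRows) else NULL,
      bg, silent)
    rownames(exprVals) <- c(names(plantRows),
                            sprintf("tx%05d", seq_len(nBackground)),
                            if (cfg$nSilent)
                              sprintf("sil%05d", seq_len(cfg$nSilent)))
    colnames(exprVals) <- samples

    # sporadic missing trait observations; pattern-plant trait rows stay
    # complete so their planted states are exact
    if (cfg$naRate > 0) {
      for (tr in setdiff(traitIds, cfg$patternTraits)) {
        hit <- stats::runif(n) < cfg$naRate
        if (sum(!hit) >= 3) traitVals[tr, hit] <- NA
      }
    }

    # filter flags by direct per-row counting
    passes <- logical(nrow(exprVals))
    names(passes) <- rownames(exprVals)
    for (i in seq_len(nrow(exprVals))) {
      cnt <- 0L
      for (j in seq_len(n)) if (exprVals[i, j] > 5) cnt <- cnt + 1L
      passes[i] <- cnt >= 8L
    }

    plants <- if (length(plantInfo)) do.call(rbind, plantInfo)
              else data.frame(trait = character(), transcript = character(),
                              shape = character(), effect = numeric(),
                              expectedMetrics = character(),
                              stringsAsFactors = FALSE)
    list(expression = ExpressionMatrix(exprVals),
         traits = TraitTable(traitVals, kind, encodings),
         truth = list(plants = plants, passesFilter = passes,
                      thresholdEstimates = q, seed = cfg$seed))
  })
}

#' Write a simulated dataset to a directory
#'
#' Writes expression TSV, trait TSV, schema YAML and ground-truth JSON.
#'
#' @param sim result of [simulateDataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeExpression(sim$expression, file.path(dir, "expression.tsv"))
  writeTraits(sim$traits, file.path(dir, "traits.tsv"))
  writeTraitSchema(sim$traits, file.path(dir, "trait_schema.yaml"))
  truth <- sim$truth
  truth$passesFilter <- as.list(truth$passesFilter)
  truth$thresholdEstimates <- as.list(truth$thresholdEstimates)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
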