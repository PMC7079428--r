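#!/usr/bin/env Rscript
# Regenerates inst/extdata/fixture_small_expected.json: the expected scaled
# values, thresholds, states, DUO components and pipeline counts for the
# bundled micro-dataset, computed with deliberately naive position-by-position
# reference code (independent of the package's vectorized implementations).
# Run from the repository root after changing fixtureSmall().

library(duonet)

fx <- fixtureSmall()
ev <- featureValues(fx$expression)
tv <- featureValues(fx$traits)
cfg <- list(filter = list(minAbundance = 5, minSamples = 1),
            discretize = list(highFraction = 0.25, lowFraction = 0.25),
            metrics = list(corrThreshold = 0.5, duoThreshold = 0.65))

# --- filter: explicit per-row counting
kept <- character()
for (i in seq_len(nrow(ev))) {
  cnt <- 0L
  for (j in seq_len(ncol(ev)))
    if (ev[i, j] > cfg$filter$minAbundance) cnt <- cnt + 1L
  if (cnt >= cfg$filter$minSamples) kept <- c(kept, rownames(ev)[i])
}

# --- scale each row by its non-NA maximum
comb <- rbind(ev[kept, , drop = FALSE], tv)
scaled <- comb
for (i in seq_len(nrow(comb))) {
  mx <- -Inf
  for (j in seq_len(ncol(comb)))
    if (!is.na(comb[i, j]) && comb[i, j] > mx) mx <- comb[i, j]
  for (j in seq_len(ncol(comb)))
    scaled[i, j] <- comb[i, j] / mx
}

# --- pooled nearest-rank thresholds
pool <- sort(scaled[!is.na(scaled)])
N <- length(pool)
lower <- pool[min(floor(cfg$discretize$lowFraction * N) + 1, N)]
upper <- pool[max(ceiling((1 - cfg$discretize$highFraction) * N), 1)]

# --- states
states <- matrix("N", nrow(scaled), ncol(scaled), dimnames = dimnames(scaled))
for (i in seq_len(nrow(scaled))) for (j in seq_len(ncol(scaled))) {
  x <- scaled[i, j]
  states[i, j] <- if (is.na(x)) "M" else if (x > upper) "H"
                  else if (x < lower) "L" else "N"
}

# --- DUO, position by position, for every transcript-trait pair
duoRef <- function(sa, sb) {
  n <- 0L
  cnt <- c(HH = 0L, LL = 0L, HL = 0L, LH = 0L)
  fa <- c(H = 0L, L = 0L); fb <- c(H = 0L, L = 0L)
  for (k in seq_along(sa)) {
    if (sa[k] == "M" || sb[k] == "M") next
    n <- n + 1L
    if (sa[k] %in% c("H", "L")) fa[sa[k]] <- fa[sa[k]] + 1L
    if (sb[k] %in% c("H", "L")) fb[sb[k]] <- fb[sb[k]] + 1L
    key <- paste0(sa[k], sb[k])
    if (key %in% names(cnt)) cnt[key] <- cnt[key] + 1L
  }
  comps <- sapply(names(cnt), function(key) {
    i <- substr(key, 1, 1); j <- substr(key, 2, 2)
    4 * (cnt[[key]] / n) * (1 - fa[[i]] / n / 1.5) * (1 - fb[[j]] / n / 1.5)
  })
  list(components = as.list(comps), n = n)
}
duo <- list()
for (a in kept) for (b in rownames(tv)) {
  d <- duoRef(states[a, ], states[b, ])
  duo[[length(duo) + 1]] <- c(list(featureA = a, featureB = b), d)
}

# --- per-metric edge counts at the default cuts
corEdges <- function(method) {
  cnt <- 0L
  for (a in kept) for (b in rownames(tv)) {
    ok <- !is.na(scaled[a, ]) & !is.na(scaled[b, ])
    r <- cor(scaled[a, ok], scaled[b, ok], method = method)
    if (!is.na(r) && abs(r) >= cfg$metrics$corrThreshold) cnt <- cnt + 1L
  }
  cnt
}
duoEdges <- 0L
for (d in duo)
  duoEdges <- duoEdges + sum(unlist(d$components) >= cfg$metrics$duoThreshold)

out <- list(
  config = cfg,
  keptTranscripts = kept,
  thresholds = list(lower = lower, upper = upper),
  states = setNames(apply(states, 1, paste, collapse = ""), rownames(states)),
  duo = duo,
  counts = list(transcriptsIn = nrow(ev),
                transcriptsAfterFilter = length(kept),
                traits = nrow(tv),
                edges = list(pearson = corEdges("pearson"),
                             spearman = corEdges("spearman"),
                             duo = duoEdges)))
jsonlite::write_json(out, "inst/extdata/fixture_small_expected.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("states:\n"); print(out$states)
cat("thresholds:", lower, upper, "\n")
cat("edges:", unlist(out$counts$edges), "\n")
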