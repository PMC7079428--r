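# Independent reference implementations used as oracles.  All deliberately
# naive (explicit position-by-position loops, textbook formulas); they must
# never call the package's vectorized code paths.

duoPairRef <- function(sa, sb) {
  stopifnot(length(sa) == length(sb))
  n <- 0L
  cnt <- c(HH = 0L, LL = 0L, HL = 0L, LH = 0L)
  fa <- c(H = 0L, L = 0L)
  fb <- c(H = 0L, L = 0L)
  for (k in seq_along(sa)) {
    if (sa[k] == "M" || sb[k] == "M") next
    n <- n + 1L
    if (sa[k] %in% c("H", "L")) fa[sa[k]] <- fa[sa[k]] + 1L
    if (sb[k] %in% c("H", "L")) fb[sb[k]] <- fb[sb[k]] + 1L
    key <- paste0(sa[k], sb[k])
    if (key %in% names(cnt)) cnt[key] <- cnt[key] + 1L
  }
  if (n == 0L) return(NULL)
  comps <- numeric(4)
  names(comps) <- names(cnt)
  for (key in names(cnt)) {
    i <- substr(key, 1, 1)
    j <- substr(key, 2, 2)
    comps[key] <- 4 * (cnt[[key]] / n) *
      (1 - (fa[[i]] / n) / 1.5) * (1 - (fb[[j]] / n) / 1.5)
  }
  list(components = comps, R = cnt / n, fA = fa / n, fB = fb / n, n = n)
}

pearsonRef <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- 0; sxx <- 0; syy <- 0
  for (k in seq_len(n)) {
    sxy <- sxy + (x[k] - mx) * (y[k] - my)
    sxx <- sxx + (x[k] - mx)^2
    syy <- syy + (y[k] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

midrankRef <- function(x) {
  r <- numeric(length(x))
  for (k in seq_along(x)) {
    below <- sum(x < x[k])
    ties <- sum(x == x[k])
    r[k] <- below + (ties + 1) / 2
  }
  r
}

spearmanRef <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  pearsonRef(midrankRef(x[ok]), midrankRef(y[ok]))
}

randomStates <- function(n, pH = 0.25, pL = 0.25, pM = 0) {
  sample(c("H", "L", "N", "M"), n, replace = TRUE,
         prob = c(pH, pL, 1 - pH - pL - pM, pM))
}

# small StateMatrix built directly from a character matrix
makeStateMatrix <- function(states, type, lower = 0.25, upper = 0.75) {
  new("StateMatrix", states = states,
      featureType = setNames(type, rownames(states)),
      lowerThreshold = lower, upperThreshold = upper,
      highFraction = 0.25, lowFraction = 0.25,
      realizedHigh = mean(states == "H"), realizedLow = mean(states == "L"))
}

lexSortTest <- function(x) sort(x, method = "radix")

fixtureExpected <- function() {
  jsonlite::read_json(system.file("extdata", "fixture_small_expected.json",
                                  package = "duonet"),
                      simplifyVector = FALSE)
}
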