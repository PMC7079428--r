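test_that("DUO analytic cases: identical quartile-balanced vectors and disjoint states", {
  s <- c("H", "L", "N", "N")
  d <- duoPair(s, s)
  comps <- duoComponents(d)
  expect_equal(comps[["HH"]], 25 / 36)
  expect_equal(comps[["LL"]], 25 / 36)
  expect_equal(comps[["HL"]], 0)
  expect_equal(comps[["LH"]], 0)

  d2 <- duoPair(c("H", "H", "N", "N"), c("N", "N", "L", "L"))
  expect_equal(unname(duoComponents(d2)), rep(0, 4))
})

test_that("DUO is symmetric with HL and LH transposed", {
  for (seed in 1:25) {
    withr::with_seed(seed, {
      a <- randomStates(20, pM = 0.05)
      b <- randomStates(20, pM = 0.05)
    })
    if (sum(a != "M" & b != "M") == 0) next
    ab <- duoComponents(duoPair(a, b))
    ba <- duoComponents(duoPair(b, a))
    expect_equal(ab[["HH"]], ba[["HH"]])
    expect_equal(ab[["LL"]], ba[["LL"]])
    expect_equal(ab[["HL"]], ba[["LH"]])
    expect_equal(ab[["LH"]], ba[["HL"]])
  }
})

test_that("duoPair matches the position-by-position reference", {
  for (seed in 1:200) {
    withr::with_seed(seed, {
      n <- sample(4:50, 1)
      a <- randomStates(n, pM = 0.08)
      b <- randomStates(n, pM = 0.08)
    })
    ref <- duoPairRef(a, b)
    if (is.null(ref)) {
      expect_error(duoPair(a, b), "undefined")
      next
    }
    d <- duoPair(a, b)
    expect_equal(duoComponents(d), ref$components, tolerance = 1e-12)
    expect_equal(d@R, ref$R, tolerance = 1e-12,
                 ignore_attr = FALSE)
    expect_identical(d@n, ref$n)
  }
})

test_that("every DUO component respects its per-pair upper bound", {
  for (seed in 1:100) {
    withr::with_seed(seed, {
      a <- randomStates(36, pH = runif(1, 0.1, 0.4), pL = runif(1, 0.1, 0.4))
      b <- randomStates(36, pH = runif(1, 0.1, 0.4), pL = runif(1, 0.1, 0.4))
    })
    d <- duoPair(a, b)
    for (key in c("HH", "LL", "HL", "LH")) {
      fi <- d@fA[[substr(key, 1, 1)]]
      fj <- d@fB[[substr(key, 2, 2)]]
      bound <- 4 * min(fi, fj) * (1 - fi / 1.5) * (1 - fj / 1.5)
      expect_lte(duoComponents(d)[[key]], bound + 1e-12)
    }
  }
})

test_that("duoPair requires jointly observed positions", {
  expect_error(duoPair(c("M", "M"), c("H", "L")), "undefined")
  expect_error(duoPair(c("H", "x"), c("H", "L")), "state codes")
})

test_that("duoAll enumerates pairs deterministically and matches the reference", {
  withr::with_seed(99, {
    s <- matrix(randomStates(13 * 10), 13, 10,
                dimnames = list(c(sprintf("t%02d", 10:1), paste0("ph", 3:1)),
                                paste0("s", 1:10)))
  })
  s["ph1", c(2, 5)] <- "M"
  st <- makeStateMatrix(s, rep(c("transcript", "trait"), c(10, 3)))
  d <- duoAll(st)
  expect_identical(nrow(d), 10L * 3L * 4L)
  # lexicographic ordering of pairs
  pairKeys <- unique(paste(d$featureA, d$featureB))
  expect_identical(pairKeys, sort(pairKeys, method = "radix"))
  for (i in seq(1, nrow(d), by = 17)) {
    ref <- duoPairRef(s[d$featureA[i], ], s[d$featureB[i], ])
    expect_equal(d$score[i], ref$components[[d$component[i]]],
                 tolerance = 1e-12)
    expect_identical(d$n[i], ref$n)
  }
  # 'all' selector covers every unordered pair once
  dAll <- duoAll(st, pairs = "all")
  expect_identical(nrow(dAll), as.integer(choose(13, 2) * 4))
  ref <- duoPairRef(s["ph1", ], s["ph2", ])
  got <- dAll[dAll$featureA == "ph1" & dAll$featureB == "ph2", ]
  expect_equal(setNames(got$score, got$component)[names(ref$components)],
               ref$components, tolerance = 1e-12)
})

test_that("a planted perfectly co-occurring pair tops the DUO stream", {
  withr::with_seed(7, {
    s <- matrix(randomStates(8 * 36), 8, 36,
                dimnames = list(c(paste0("t", 1:7), "phX"), paste0("s", 1:36)))
  })
  planted <- rep(c("H", "L", "N", "N"), 9)
  s["t3", ] <- planted
  s["phX", ] <- planted
  st <- makeStateMatrix(s, rep(c("transcript", "trait"), c(7, 1)))
  d <- duoAll(st)
  hh <- d[d$component == "HH", ]
  expect_identical(hh$featureA[which.max(hh$score)], "t3")
  expect_equal(max(hh$score), 25 / 36)
})

test_that("correlations behave on canonical shapes and match references", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlatePair(2 * x + 1, x)@r, 1)
  expect_equal(correlatePair(rev(x), x)@r, -1)
  expect_equal(correlatePair(rev(x), x, method = "spearman")@r, -1)
  x3 <- -3:3
  expect_equal(correlatePair(x3, x3^3, method = "spearman")@r, 1)
  expect_lt(correlatePair(x3, x3^3, method = "pearson")@r, 1)

  for (seed in 1:50) {
    withr::with_seed(seed, {
      n <- sample(5:40, 1)
      a <- round(rnorm(n), 1)  # rounding induces ties for the midrank path
      b <- round(a * 0.5 + rnorm(n), 1)
      a[sample(n, 2)] <- NA
    })
    if (sum(!is.na(a)) < 3) next
    expect_equal(correlatePair(a, b)@r, pearsonRef(a, b), tolerance = 1e-10)
    expect_equal(correlatePair(a, b, method = "spearman")@r,
                 spearmanRef(a, b), tolerance = 1e-10)
  }
})

test_that("spearman is invariant under strictly increasing transforms", {
  withr::with_seed(21, x <- runif(30))
  for (g in list(exp, function(z) z^3, function(z) log(z + 1))) {
    expect_equal(correlatePair(x, g(x), method = "spearman")@r, 1)
  }
})

test_that("degenerate correlations are flagged, not scored", {
  expect_error(correlatePair(c(1, 2), c(3, 4)), "fewer than 3")
  v <- rbind(t1 = c(0.2, 0.4, 1, 0.6), flat = c(1, 1, 1, 1),
             ph = c(0.1, 0.6, 1, 0.3), phFlat = c(1, 1, 1, 1))
  colnames(v) <- paste0("s", 1:4)
  M <- new("CombinedMatrix", values = v,
           featureType = setNames(rep(c("transcript", "trait"), each = 2),
                                  rownames(v)),
           scalingMode = "max", dropped = character())
  sc <- correlateAll(M)
  expect_false(sc$defined[sc$featureA == "flat" & sc$featureB == "ph"])
  expect_true(sc$defined[sc$featureA == "t1" & sc$featureB == "ph"])
})

test_that("thresholding emits edges per metric rule and per DUO component", {
  duoScores <- data.frame(
    featureA = c("t1", "t1", "t2", "t2"), stateA = c("H", "L", "H", "L"),
    featureB = "ph", stateB = c("H", "L", "H", "L"),
    component = c("HH", "LL", "HH", "LL"),
    score = c(25 / 36, 0.60, 0.70, 0.66),
    n = 36L, defined = TRUE, metric = "duo", stringsAsFactors = FALSE)
  e <- thresholdScores(duoScores)
  expect_identical(nrow(e), 3L)                       # 0.6944, 0.70, 0.66
  expect_identical(sum(e$featureA == "t2"), 2L)       # two edges, one pair
  corScores <- data.frame(featureA = c("t1", "t2", "t3"), featureB = "ph",
                          score = c(0.49, -0.5, 0.51), n = 36L,
                          defined = TRUE, metric = "pearson",
                          stringsAsFactors = FALSE)
  e2 <- thresholdScores(corScores)
  expect_identical(e2$featureA, c("t2", "t3"))        # |r| >= 0.5, signed kept
  expect_error(thresholdScores(corScores, corrThreshold = 1.2), "corrThreshold")
})
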