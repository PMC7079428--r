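test_that("abundance filter applies the strict 'more than' rule", {
  n <- 36
  rows <- rbind(
    justEight = c(rep(6, 8), rep(0, n - 8)),
    allFive = rep(5, n),            # exactly 5 everywhere: dropped
    sevenOnly = c(rep(6, 7), rep(0, n - 7)),
    strong = rep(50, n))
  colnames(rows) <- paste0("s", seq_len(n))
  x <- ExpressionMatrix(rows)
  flt <- filterTranscripts(x, minAbundance = 5, minSamples = 8)
  expect_identical(flt$report$keptIds, c("justEight", "strong"))
  expect_identical(flt$report$dropped, 2L)
  # non-strict comparator keeps the all-exactly-5 row
  fltGe <- filterTranscripts(x, comparator = "ge")
  expect_true("allFive" %in% fltGe$report$keptIds)
  # idempotence
  again <- filterTranscripts(flt$expression)
  expect_identical(featureValues(again$expression),
                   featureValues(flt$expression))
})

test_that("filter can be restricted to a sample subset", {
  n <- 10
  v <- matrix(0, 2, n, dimnames = list(c("a", "b"), paste0("s", 1:n)))
  v["a", 1:3] <- 10        # qualifies only via s1..s3
  v["b", 8:10] <- 10
  x <- ExpressionMatrix(v)
  flt <- filterTranscripts(x, minSamples = 3, samples = paste0("s", 1:5))
  expect_identical(flt$report$keptIds, "a")
})

test_that("row scaling divides by the per-row non-NA maximum", {
  ev <- matrix(c(2, 4, 8, 0,
                 0, 0, 0, 0,
                 5, 5, 10, 5), 3, 4, byrow = TRUE,
               dimnames = list(c("t1", "tzero", "t2"), paste0("s", 1:4)))
  tv <- matrix(c(1, NA, 3, 2), 1, 4,
               dimnames = list("traitA", paste0("s", 1:4)))
  M <- suppressMessages(combineAndScale(ExpressionMatrix(ev),
                                        TraitTable(tv)))
  expect_equal(unname(featureValues(M)["t1", ]), c(0.25, 0.5, 1, 0))
  expect_equal(unname(featureValues(M)["traitA", ]), c(1 / 3, NA, 1, 2 / 3))
  expect_identical(M@dropped, "tzero")
  expect_false("tzero" %in% featureIds(M))
  # every surviving row attains exactly 1; minimum >= 0
  expect_true(all(apply(featureValues(M), 1, max, na.rm = TRUE) == 1))
  expect_true(min(featureValues(M), na.rm = TRUE) >= 0)
})

test_that("negative trait values are rejected at scaling", {
  ev <- matrix(1:4, 1, 4, dimnames = list("t1", paste0("s", 1:4)))
  tv <- matrix(c(-1, 0, 2, 1), 1, 4,
               dimnames = list("shifted", paste0("s", 1:4)))
  expect_error(combineAndScale(ExpressionMatrix(ev), TraitTable(tv)),
               "shifted.*nonnegative scale")
})

test_that("zscore mode centers rows and is flagged on the container", {
  withr::with_seed(5, {
    ev <- matrix(rlnorm(40), 4, 10,
                 dimnames = list(paste0("t", 1:4), paste0("s", 1:10)))
  })
  tv <- matrix(seq(1, 10), 1, 10,
               dimnames = list("traitA", paste0("s", 1:10)))
  M <- combineAndScale(ExpressionMatrix(ev), TraitTable(tv), mode = "zscore")
  expect_identical(M@scalingMode, "zscore")
  expect_equal(unname(rowMeans(featureValues(M))), rep(0, 5))
  expect_equal(unname(apply(featureValues(M), 1, sd)), rep(1, 5))
})

test_that("discretization yields exact quartiles on distinct values", {
  # 90 distinct sub-unit values plus one 1.0 per row (the row maxima);
  # 100 pooled cells -> exactly 25 HIGH and 25 LOW
  withr::with_seed(42, base <- sample(seq(0.005, 0.895, length.out = 90)))
  v <- cbind(matrix(base, 10, 9), 1)
  dimnames(v) <- list(paste0("f", 1:10), paste0("s", 1:10))
  M <- new("CombinedMatrix", values = v,
           featureType = setNames(rep("transcript", 10), rownames(v)),
           scalingMode = "max", dropped = character())
  st <- discretize(M)
  expect_identical(sum(stateCodes(st) == "H"), 25L)
  expect_identical(sum(stateCodes(st) == "L"), 25L)
  expect_equal(unname(realizedFractions(st)), c(0.25, 0.25))
})

test_that("cells equal to a threshold are NEUTRAL and NA becomes MISSING", {
  # 7 pooled non-NA values; nearest-rank thresholds are v(2) and v(6)
  v <- matrix(c(0.25, 0.5, 0.75, 1,
                0.3, 0.6, 1, NA), 2, 4, byrow = TRUE,
              dimnames = list(c("a", "b"), paste0("s", 1:4)))
  M <- new("CombinedMatrix", values = v,
           featureType = setNames(c("transcript", "trait"), c("a", "b")),
           scalingMode = "max", dropped = character())
  st <- discretize(M)
  thr <- stateThresholdsOf(st)
  # pooled sorted: .25 .3 .5 .6 .75 1 1 -> lower = v[2]=.3, upper = v[6]=1
  expect_equal(unname(thr), c(0.3, 1))
  s <- stateCodes(st)
  expect_identical(unname(s["a", ]), c("L", "N", "N", "N"))  # 0.3-tie is N on row b
  expect_identical(unname(s["b", ]), c("N", "N", "N", "M"))
  expect_identical(sum(s == "H"), 0L)  # 1 equals the upper threshold: NEUTRAL
})

test_that("an all-tied matrix cannot be discretized", {
  v <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  M <- new("CombinedMatrix", values = v,
           featureType = setNames(rep("transcript", 2), c("a", "b")),
           scalingMode = "max", dropped = character())
  expect_error(discretize(M), "degenerate")
})

test_that("realized fractions stay within one cell of targets (property)", {
  # rows carry one structural 1.0 (the max) and otherwise distinct values;
  # as long as the ones sit strictly above the upper threshold the
  # distinct-value guarantee applies
  for (seed in 1:20) {
    withr::with_seed(seed, {
      nr <- sample(3:8, 1); nc <- sample(5:12, 1)
      v <- cbind(matrix(runif(nr * (nc - 1), 0.01, 0.9), nr, nc - 1), 1)
    })
    if (nr > floor(nr * nc / 4)) next  # ones would straddle the threshold
    dimnames(v) <- list(paste0("f", seq_len(nr)), paste0("s", seq_len(nc)))
    M <- new("CombinedMatrix", values = v,
             featureType = setNames(rep("transcript", nr), rownames(v)),
             scalingMode = "max", dropped = character())
    hf <- 0.25; lf <- 0.25
    st <- discretize(M, hf, lf)
    ncell <- nr * nc
    expect_lte(abs(realizedFractions(st)[["high"]] - hf), 1 / ncell)
    expect_lte(abs(realizedFractions(st)[["low"]] - lf), 1 / ncell)
  }
})
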