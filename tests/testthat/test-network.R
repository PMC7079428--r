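duoEdgeFrame <- function(weights, a = paste0("t", seq_along(weights)),
                         b = "ph", sA = "H", sB = "H") {
  k <- length(weights)
  data.frame(featureA = a, stateA = rep_len(sA, k),
             featureB = rep_len(b, k), stateB = rep_len(sB, k),
             weight = weights, n = rep_len(36L, k),
             metric = rep_len("duo", k), stringsAsFactors = FALSE)
}

test_that("network construction filters by weight and simplifies the graph", {
  net <- buildNetwork(duoEdgeFrame(c(0.70, 0.66, 0.60)), minWeight = 0.65)
  expect_identical(nrow(networkEdges(net)), 2L)
  expect_identical(networkNodes(net), c("ph:H", "t1:H", "t2:H"))

  empty <- buildNetwork(duoEdgeFrame(numeric(0), a = character()))
  expect_identical(nrow(networkEdges(empty)), 0L)
  expect_length(networkNodes(empty), 0)

  # duplicate undirected edge and self-loop are removed
  e <- duoEdgeFrame(c(0.7, 0.7, 0.9), a = c("t1", "ph", "t2"),
                    b = c("ph", "t1", "t2"), sA = c("H", "H", "H"),
                    sB = c("H", "H", "H"))
  net2 <- buildNetwork(e)
  expect_identical(nrow(networkEdges(net2)), 1L)

  mixed <- duoEdgeFrame(c(0.7, 0.8))
  mixed$metric <- c("duo", "pearson")
  expect_error(buildNetwork(mixed), "mixed-metric")
})

test_that("correlation edges apply the cut to |r| and keep signed weights", {
  e <- data.frame(featureA = c("t1", "t2"), stateA = NA_character_,
                  featureB = "ph", stateB = NA_character_,
                  weight = c(-0.82, 0.3), n = 36L, metric = "pearson",
                  stringsAsFactors = FALSE)
  net <- buildNetwork(e, minWeight = 0.5)
  expect_identical(networkEdges(net)$weight, -0.82)
  expect_identical(networkNodes(net), c("ph", "t1"))
})

test_that("SIF and edge-list exports are stable and state-tagged", {
  net <- buildNetwork(duoEdgeFrame(c(0.7, 0.66), a = c("t2", "t1"),
                                   sA = c("H", "L"), sB = c("L", "H")))
  d <- withr::local_tempdir()
  exportNetwork(net, file.path(d, "n.sif"), format = "sif")
  expect_identical(readLines(file.path(d, "n.sif")),
                   c("t1:L\tduo\tph:H", "t2:H\tduo\tph:L"))
  exportNetwork(net, file.path(d, "n.tsv"), format = "edgelist")
  lines <- readLines(file.path(d, "n.tsv"))
  expect_identical(lines[1], "nodeA\tnodeB\tmetric\tweight\tn")
  expect_length(lines, 3)

  emptyNet <- buildNetwork(duoEdgeFrame(numeric(0), a = character()))
  exportNetwork(emptyNet, file.path(d, "e.tsv"), format = "edgelist")
  expect_identical(readLines(file.path(d, "e.tsv")),
                   "nodeA\tnodeB\tmetric\tweight\tn")
  expect_error(exportNetwork(net, file.path(d, "x"), format = "dot"),
               "should be one of")
})

test_that("GraphML round-trips an isomorphic graph with equal weights", {
  net <- buildNetwork(duoEdgeFrame(c(0.7, 0.66, 0.8), a = c("t1", "t2", "t3"),
                                   sA = c("H", "L", "H"), sB = c("H", "L", "L")))
  f <- withr::local_tempfile(fileext = ".graphml")
  exportNetwork(net, f, format = "graphml")
  back <- readNetworkGraphML(f, metric = "duo")
  eo <- networkEdges(net)
  eb <- networkEdges(back)
  keyO <- paste(nodeA = paste0(eo$featureA, ":", eo$stateA),
                paste0(eo$featureB, ":", eo$stateB))
  keyB <- paste(paste0(eb$featureA, ":", eb$stateA),
                paste0(eb$featureB, ":", eb$stateB))
  expect_setequal(keyB, keyO)
  expect_equal(eb$weight[order(keyB)], eo$weight[order(keyO)])
})

test_that("trait correlation table has unit diagonal and calibrated flags", {
  withr::with_seed(31, {
    v <- matrix(abs(rnorm(5 * 20, 10, 3)), 5, 20,
                dimnames = list(paste0("ph", 1:5), paste0("s", 1:20)))
  })
  v["ph2", ] <- 30 - v["ph1", ]          # perfect anti-monotone pair
  v["ph5", ] <- 7                         # constant trait
  tc <- traitCorrelationTable(TraitTable(v))
  expect_equal(unname(diag(tc$r)), rep(1, 5))
  expect_equal(tc$r["ph1", "ph2"], -1)
  expect_identical(tc$flags["ph1", "ph2"], "**")
  expect_equal(tc$p["ph1", "ph2"], 0)
  expect_true(all(is.na(tc$r["ph5", setdiff(rownames(v), "ph5")])))
  expect_identical(tc$flags["ph5", "ph1"], "!")
  expect_identical(tc$r, t(tc$r))
})

test_that("trait correlation is invariant under monotone transforms", {
  withr::with_seed(8, {
    v <- matrix(abs(rnorm(3 * 15, 5)), 3, 15,
                dimnames = list(paste0("ph", 1:3), paste0("s", 1:15)))
  })
  t1 <- traitCorrelationTable(TraitTable(v))
  v2 <- v
  v2["ph2", ] <- exp(v2["ph2", ] / 2)
  t2 <- traitCorrelationTable(TraitTable(v2))
  expect_equal(t1$r, t2$r)
})

test_that("significance flags hit their nominal rate on independent traits", {
  # Monte-Carlo calibration of the t-approximation p-value at n = 36
  nRep <- 1000
  withr::with_seed(123, {
    hits <- vapply(seq_len(nRep), function(i) {
      v <- matrix(abs(rnorm(2 * 36, 50, 10)), 2, 36,
                  dimnames = list(c("a", "b"), paste0("s", 1:36)))
      tc <- traitCorrelationTable(TraitTable(v))
      tc$p["a", "b"] < 0.05
    }, logical(1))
  })
  expect_gte(mean(hits), 0.03)
  expect_lte(mean(hits), 0.07)
})

test_that("network comparison matches pairs across metrics as declared", {
  pe <- buildNetwork(data.frame(featureA = "a", stateA = NA_character_,
                                featureB = "T", stateB = NA_character_,
                                weight = 0.8, n = 36L, metric = "pearson",
                                stringsAsFactors = FALSE))
  sp <- buildNetwork(data.frame(featureA = "a", stateA = NA_character_,
                                featureB = "T", stateB = NA_character_,
                                weight = 0.7, n = 36L, metric = "spearman",
                                stringsAsFactors = FALSE))
  du <- buildNetwork(duoEdgeFrame(0.7, a = "a", b = "T", sA = "H", sB = "L"))
  ovPair <- compareNetworks(list(pearson = pe, spearman = sp, duo = du),
                            matching = "pair", traitIds = "T")
  expect_identical(unname(ovPair@overall),
                   c(1, 1, 1, 1, 1, 1, 1))
  ovState <- compareNetworks(list(pearson = pe, spearman = sp, duo = du),
                             matching = "state", traitIds = "T")
  expect_identical(unname(ovState@overall[c("PD", "SD", "PSD")]), c(0, 0, 0))
  # state-level counts never exceed pair-level counts
  expect_true(all(ovState@overall <= ovPair@overall))

  duFar <- buildNetwork(duoEdgeFrame(0.7, a = "z", b = "T"))
  ovDisj <- compareNetworks(list(pearson = pe, duo = duFar),
                            matching = "pair", traitIds = "T")
  expect_identical(unname(ovDisj@overall[c("PS", "PD", "SD", "PSD")]),
                   c(0, 0, 0, 0))
})

test_that("overlap counts obey inclusion-exclusion bounds (property)", {
  for (seed in 1:30) {
    withr::with_seed(seed, {
      universeT <- sprintf("t%02d", 1:12)
      traits <- c("T1", "T2")
      mkNet <- function(metric) {
        k <- sample(0:10, 1)
        if (k == 0)
          return(buildNetwork(data.frame(
            featureA = character(), stateA = character(),
            featureB = character(), stateB = character(),
            weight = numeric(), n = integer(), metric = character(),
            stringsAsFactors = FALSE)))
        df <- unique(data.frame(featureA = sample(universeT, k, TRUE),
                                featureB = sample(traits, k, TRUE),
                                stringsAsFactors = FALSE))
        df$stateA <- if (metric == "duo")
          sample(c("H", "L"), nrow(df), TRUE) else NA_character_
        df$stateB <- if (metric == "duo")
          sample(c("H", "L"), nrow(df), TRUE) else NA_character_
        df$weight <- if (metric == "duo") runif(nrow(df), 0.65, 1)
                     else runif(nrow(df), 0.5, 1)
        df$n <- 36L
        df$metric <- metric
        buildNetwork(df)
      }
      nets <- list(pearson = mkNet("pearson"), spearman = mkNet("spearman"),
                   duo = mkNet("duo"))
    })
    for (matching in c("pair", "state")) {
      x <- compareNetworks(nets, matching = matching, traitIds = traits)@overall
      expect_lte(x[["PSD"]], min(x[["PS"]], x[["PD"]], x[["SD"]]))
      expect_lte(x[["PS"]], min(x[["P"]], x[["S"]]))
      expect_lte(x[["PD"]], min(x[["P"]], x[["D"]]))
      expect_lte(x[["SD"]], min(x[["S"]], x[["D"]]))
      expect_true(all(vennRegions(
        compareNetworks(nets, matching = matching, traitIds = traits)) >= 0))
    }
  }
})
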