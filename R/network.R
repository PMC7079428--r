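# Association networks: construction, export, trait-trait correlation table
# and cross-metric comparison.

nodeNames <- function(feature, state) {
  ifelse(is.na(state), feature, paste0(feature, ":", state))
}

# canonical undirected edge keys; stateLevel = FALSE collapses an edge to its
# unordered feature pair (DUO state tags stripped)
edgeKeys <- function(e, stateLevel = TRUE) {
  a <- if (stateLevel) nodeNames(e$featureA, e$stateA) else e$featureA
  b <- if (stateLevel) nodeNames(e$featureB, e$stateB) else e$featureB
  paste(pmin(a, b), pmax(a, b), sep = "\034")
}

#' Build an association network from an edge stream
#'
#' Keeps exactly the edges whose weight passes the metric's cut (score >=
#' `minWeight` for DUO, |score| >= `minWeight` for correlations), removes
#' self-loops and duplicate undirected edges, and returns an
#' [AssociationNetwork-class].  Isolated nodes are omitted by construction.
#'
#' @param edges an edge data.frame (from [thresholdScores()], or raw scores
#'   with a `weight`/`score` column) carrying a single metric.
#' @param minWeight edge weight cut; defaults to 0.65 for DUO and 0.5 for
#'   correlation metrics.
#' @return an [AssociationNetwork-class].
#' @export
buildNetwork <- function(edges, minWeight = NULL) {
  if (!"weight" %in% names(edges) && "score" %in% names(edges))
    edges$weight <- edges$score
  stopifnot(all(c("featureA", "featureB", "weight", "metric") %in%
                  names(edges)))
  metric <- unique(edges$metric)
  if (length(metric) > 1)
    stop("mixed-metric edge stream (", paste(metric, collapse = ", "),
         "); build one network per metric")
  if (length(metric) == 0) metric <- "duo"  # empty stream: arbitrary tag
  if (!metric %in% METRICS) stop("unknown metric: ", metric)
  if (is.null(minWeight)) minWeight <- if (metric == "duo") 0.65 else 0.5
  if (!"stateA" %in% names(edges)) edges$stateA <- NA_character_
  if (!"stateB" %in% names(edges)) edges$stateB <- NA_character_
  if (!"n" %in% names(edges)) edges$n <- NA_integer_
  keep <- if (metric == "duo") edges$weight >= minWeight
          else abs(edges$weight) >= minWeight
  keep[is.na(keep)] <- FALSE
  e <- edges[keep, c("featureA", "stateA", "featureB", "stateB",
                     "weight", "n"), drop = FALSE]
  # drop self-loops, deduplicate on the undirected state-tagged key
  loop <- e$featureA == e$featureB &
    (is.na(e$stateA) | is.na(e$stateB) | e$stateA == e$stateB)
  e <- e[!loop, , drop = FALSE]
  e <- e[!duplicated(edgeKeys(e, stateLevel = TRUE)), , drop = FALSE]
  e <- e[lexOrder(e$featureA, e$featureB, e$stateA, e$stateB), ,
         drop = FALSE]
  rownames(e) <- NULL
  new("AssociationNetwork", edges = e, metric = metric)
}

#' Export an association network
#'
#' Writes the network as SIF (`nodeA <metric> nodeB`), a weighted edge-list
#' TSV, or GraphML (via igraph), with bit-exact lexicographic edge ordering
#' for reproducible diffs.  DUO node names carry their state tags
#' (`feature:H` / `feature:L`).
#'
#' @param net an [AssociationNetwork-class].
#' @param path output path.
#' @param format `"sif"`, `"edgelist"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
exportNetwork <- function(net, path, format = c("sif", "edgelist", "graphml")) {
  stopifnot(is(net, "AssociationNetwork"))
  format <- match.arg(format)
  e <- net@edges
  a <- nodeNames(e$featureA, e$stateA)
  b <- nodeNames(e$featureB, e$stateB)
  ord <- lexOrder(a, b)
  a <- a[ord]; b <- b[ord]; e <- e[ord, , drop = FALSE]
  if (format == "sif") {
    lines <- if (nrow(e)) paste(a, net@metric, b, sep = "\t") else character()
  } else if (format == "edgelist") {
    lines <- c("nodeA\tnodeB\tmetric\tweight\tn",
               if (nrow(e)) paste(a, b, net@metric, fmtNum(e$weight),
                                  e$n, sep = "\t"))
  } else {
    g <- igraph::graph_from_data_frame(
      data.frame(from = a, to = b,
                 weight = if (nrow(e)) e$weight else numeric(),
                 stringsAsFactors = FALSE),
      directed = FALSE)
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  con <- file(path, open = "wb")
  writeLines(lines, con, useBytes = TRUE)
  close(con)
  invisible(path)
}

#' Read a GraphML network export back
#'
#' @param path a GraphML file written by [exportNetwork()].
#' @param metric metric tag to attach.
#' @return an [AssociationNetwork-class].
#' @export
readNetworkGraphML <- function(path, metric = "duo") {
  g <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_data_frame(g, what = "edges")
  splitNode <- function(x) {
    hasState <- grepl(":[HL]$", x)
    list(feature = ifelse(hasState, sub(":[HL]$", "", x), x),
         state = ifelse(hasState, sub("^.*:", "", x), NA_character_))
  }
  fa <- splitNode(el$from); fb <- splitNode(el$to)
  buildNetwork(data.frame(featureA = fa$feature, stateA = fa$state,
                          featureB = fb$feature, stateB = fb$state,
                          weight = if (nrow(el)) el$weight else numeric(),
                          n = NA_integer_, metric = metric,
                          stringsAsFactors = FALSE),
               minWeight = -Inf)
}

#' Trait-trait Spearman correlation table
#'
#' Symmetric matrix of pairwise-complete Spearman correlations between all
#' traits with a unit diagonal, plus two-sided p-values from the
#' large-sample t approximation (t = r sqrt((n-2)/(1-r^2)), df = n-2) and
#' two significance tiers: "*" for p < 0.05, "**" for p < 0.001.  Constant
#' traits give undefined cells (NA, flagged "!").
#'
#' @param traits a [TraitTable-class].
#' @param minN minimum pairwise-complete count (default 3).
#' @return a list of class `traitCorrelation`: `r`, `p`, `n` matrices and a
#'   `flags` character matrix.
#' @export
traitCorrelationTable <- function(traits, minN = 3) {
  stopifnot(is(traits, "TraitTable"))
  v <- t(traits@values)
  r <- suppressWarnings(stats::cor(v, use = "pairwise.complete.obs",
                                   method = "spearman"))
  n <- crossprod(!is.na(v))
  small <- n < minN
  r[small] <- NA
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(tstat), df = pmax(n - 2, 1))
  p[!is.na(r) & abs(r) == 1] <- 0  # exact monotone pairs: t is infinite
  diag(r) <- 1; diag(p) <- NA
  flags <- matrix("", nrow(r), ncol(r), dimnames = dimnames(r))
  flags[!is.na(p) & p < 0.05] <- "*"
  flags[!is.na(p) & p < 0.001] <- "**"
  flags[is.na(r)] <- "!"
  diag(flags) <- ""
  structure(list(r = r, p = p, n = n, flags = flags),
            class = "traitCorrelation")
}

#' @export
print.traitCorrelation <- function(x, digits = 2, ...) {
  m <- matrix(paste0(format(round(x$r, digits)), x$flags),
              nrow(x$r), dimnames = dimnames(x$r))
  m[x$flags == "!"] <- "NA!"
  print(m, quote = FALSE)
  cat("** p < 0.001, * p < 0.05 (Spearman, t approximation); ! undefined\n")
  invisible(x)
}

#' Write a trait correlation table as TSV
#'
#' @param tc a `traitCorrelation` list from [traitCorrelationTable()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTraitCorrelation <- function(tc, path) {
  v <- tc$r
  lines <- c(paste(c("trait_id", colnames(v)), collapse = "\t"),
             vapply(seq_len(nrow(v)), function(i)
               paste(c(rownames(v)[i],
                       paste0(fmtNum(v[i, ]), tc$flags[i, ])),
                     collapse = "\t"), character(1)))
  con <- file(path, open = "wb")
  writeLines(lines, con, useBytes = TRUE)
  close(con)
  invisible(path)
}

setIntersections <- function(P, S, D) {
  x <- c(P = length(P), S = length(S), D = length(D),
         PS = length(intersect(P, S)), PD = length(intersect(P, D)),
         SD = length(intersect(S, D)),
         PSD = length(intersect(intersect(P, S), D)))
  storage.mode(x) <- "double"
  x
}

#' Compare Pearson, Spearman and DUO association networks
#'
#' Counts the transcript-trait associations shared between the three metric
#' networks, whole-network and per-trait.  Under `matching = "pair"` (the
#' default) a DUO edge `t:H -- trait:L` collapses to the unordered feature
#' pair (t, trait) and can match a correlation edge; under
#' `matching = "state"` DUO edges only match edges with identical state
#' tags, so DUO-correlation intersections are empty.  Per-trait counts are
#' distinct transcripts with at least one qualifying edge to that trait.
#'
#' @param networks named list with elements `pearson`, `spearman`, `duo`
#'   ([AssociationNetwork-class]; any subset).
#' @param matching `"pair"` or `"state"`.
#' @param traitIds trait identifiers; inferred from the networks' featureB
#'   endpoints when NULL.
#' @return an [OverlapSummary-class].
#' @export
compareNetworks <- function(networks, matching = c("pair", "state"),
                            traitIds = NULL) {
  matching <- match.arg(matching)
  stopifnot(is.list(networks), length(networks) > 0)
  for (nm in names(networks))
    stopifnot(is(networks[[nm]], "AssociationNetwork"))
  edgeTab <- lapply(networks, function(net) net@edges)
  if (is.null(traitIds))
    traitIds <- lexSort(unique(unlist(lapply(edgeTab, `[[`, "featureB"))))
  keysOf <- function(e, metric) {
    if (nrow(e) == 0) return(character())
    unique(edgeKeys(e, stateLevel = (matching == "state" & metric == "duo")))
  }
  kP <- if ("pearson" %in% names(networks))
    keysOf(edgeTab$pearson, "pearson") else character()
  kS <- if ("spearman" %in% names(networks))
    keysOf(edgeTab$spearman, "spearman") else character()
  kD <- if ("duo" %in% names(networks))
    keysOf(edgeTab$duo, "duo") else character()
  overall <- setIntersections(kP, kS, kD)

  transcriptsPerTrait <- function(e, trait) {
    if (nrow(e) == 0) return(character())
    hit <- (e$featureB == trait & !(e$featureA %in% traitIds)) |
      (e$featureA == trait & !(e$featureB %in% traitIds))
    unique(ifelse(e$featureB[hit] == trait, e$featureA[hit],
                  e$featureB[hit]))
  }
  perTrait <- do.call(rbind, lapply(traitIds, function(tr) {
    P <- if (!is.null(edgeTab$pearson)) transcriptsPerTrait(edgeTab$pearson, tr) else character()
    S <- if (!is.null(edgeTab$spearman)) transcriptsPerTrait(edgeTab$spearman, tr) else character()
    D <- if (!is.null(edgeTab$duo)) transcriptsPerTrait(edgeTab$duo, tr) else character()
    as.data.frame(c(list(trait = tr), as.list(setIntersections(P, S, D))),
                  stringsAsFactors = FALSE)
  }))
  if (is.null(perTrait))
    perTrait <- data.frame(trait = character(), P = integer(),
                           S = integer(), D = integer(), PS = integer(),
                           PD = integer(), SD = integer(), PSD = integer(),
                           stringsAsFactors = FALSE)

  allTranscripts <- function(e) {
    if (is.null(e) || nrow(e) == 0) return(character())
    unique(c(e$featureA[!(e$featureA %in% traitIds)],
             e$featureB[!(e$featureB %in% traitIds)]))
  }
  venn <- setIntersections(allTranscripts(edgeTab$pearson),
                           allTranscripts(edgeTab$spearman),
                           allTranscripts(edgeTab$duo))
  new("OverlapSummary", overall = overall, perTrait = perTrait,
      transcriptVenn = venn, matching = matching)
}

#' Exclusive Venn region sizes from an overlap summary
#'
#' Converts the inclusion counts (P, S, D, PS, PD, SD, PSD) into the seven
#' exclusive Venn diagram regions.
#'
#' @param summary an [OverlapSummary-class].
#' @param level `"pairs"` (association pairs) or `"transcripts"`.
#' @return named numeric vector of the exclusive region sizes.
#' @export
vennRegions <- function(summary, level = c("pairs", "transcripts")) {
  level <- match.arg(level)
  x <- if (level == "pairs") summary@overall else summary@transcriptVenn
  c(P_only = x[["P"]] - x[["PS"]] - x[["PD"]] + x[["PSD"]],
    S_only = x[["S"]] - x[["PS"]] - x[["SD"]] + x[["PSD"]],
    D_only = x[["D"]] - x[["PD"]] - x[["SD"]] + x[["PSD"]],
    PS_only = x[["PS"]] - x[["PSD"]],
    PD_only = x[["PD"]] - x[["PSD"]],
    SD_only = x[["SD"]] - x[["PSD"]],
    PSD = x[["PSD"]])
}

#' Write an overlap summary as JSON
#'
#' Count columns involving a metric that was not run are omitted.
#'
#' @param summary an [OverlapSummary-class].
#' @param path output path.
#' @param metrics the metrics that were actually computed.
#' @return `path`, invisibly.
#' @export
writeOverlap <- function(summary, path,
                         metrics = c("pearson", "spearman", "duo")) {
  letters_ <- c(pearson = "P", spearman = "S", duo = "D")
  absent <- letters_[setdiff(names(letters_), metrics)]
  keepKey <- function(keys)
    keys[!vapply(keys, function(k)
      any(vapply(absent, grepl, logical(1), x = k, fixed = TRUE)),
      logical(1))]
  ovr <- as.list(summary@overall)[keepKey(names(summary@overall))]
  venn <- as.list(summary@transcriptVenn)[keepKey(names(summary@transcriptVenn))]
  pt <- summary@perTrait[, c("trait", keepKey(setdiff(names(summary@perTrait),
                                                      "trait"))),
                         drop = FALSE]
  out <- list(matching = summary@matching, metrics = metrics,
              overall = ovr, transcript_venn = venn, per_trait = pt)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
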