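# End-to-end orchestration: simulate/read -> filter -> scale -> discretize ->
# score -> networks -> comparison, with a reproducible run manifest.

defaultPipelineConfig <- function() {
  list(filter = list(minAbundance = 5, minSamples = 8, comparator = "gt"),
       scaling = list(mode = "max"),
       discretize = list(highFraction = 0.25, lowFraction = 0.25),
       metrics = list(use = c("pearson", "spearman", "duo"),
                      corrThreshold = 0.5, duoThreshold = 0.65),
       compare = list(matching = "pair"))
}

mergeConfig <- function(base, user) {
  for (k in names(user)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(user[[k]]))
      mergeConfig(base[[k]], user[[k]]) else user[[k]]
  }
  base
}

configDigest <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full trait-transcript association pipeline
#'
#' Chains the pipeline in its fixed order — abundance filter, row scaling,
#' matrix-wide discretization, per-metric scoring, thresholding, network
#' construction and network comparison — and writes every stage output plus
#' a run manifest to `outDir`.  Two runs on identical inputs and config
#' produce byte-identical outputs.
#'
#' @param config a config list, or the path to a YAML config file.
#'   Recognized keys (all optional except one input source):
#'   `input` (`expression`, `traits`, `schema` file paths) or `simulate`
#'   (arguments for [simConfig()]); `filter` (`minAbundance` 5,
#'   `minSamples` 8, `comparator` "gt"); `scaling` (`mode` "max");
#'   `discretize` (`highFraction`/`lowFraction` 0.25); `metrics` (`use`,
#'   `corrThreshold` 0.5, `duoThreshold` 0.65); `compare` (`matching`
#'   "pair").
#' @param outDir output directory (created if needed).
#' @return the run manifest, invisibly (also written as `manifest.json`).
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- mergeConfig(defaultPipelineConfig(), config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  inputDigests <- list()
  if (!is.null(cfg$input)) {
    for (k in c("expression", "traits")) {
      p <- cfg$input[[k]]
      if (is.null(p)) stop("config$input$", k, " is required")
      if (!file.exists(p)) stop("input file not found: ", p)
      inputDigests[[k]] <- unname(tools::md5sum(p))
    }
    schema <- if (!is.null(cfg$input$schema)) {
      inputDigests$schema <- unname(tools::md5sum(cfg$input$schema))
      readTraitSchema(cfg$input$schema)
    } else list()
    expr <- readExpression(cfg$input$expression)
    traits <- readTraits(cfg$input$traits, schema)
  } else if (!is.null(cfg$simulate)) {
    sim <- simulateDataset(do.call(simConfig, cfg$simulate))
    expr <- sim$expression
    traits <- sim$traits
  } else stop("config needs either an 'input' or a 'simulate' section")

  aligned <- alignSamples(expr, traits)
  flt <- filterTranscripts(aligned$expression,
                           minAbundance = cfg$filter$minAbundance,
                           minSamples = cfg$filter$minSamples,
                           comparator = cfg$filter$comparator)
  M <- combineAndScale(flt$expression, aligned$traits,
                       mode = cfg$scaling$mode)
  states <- discretize(M, highFraction = cfg$discretize$highFraction,
                       lowFraction = cfg$discretize$lowFraction)
  writeStates(states, file.path(outDir, "states.tsv"))

  use <- cfg$metrics$use
  bad <- setdiff(use, METRICS)
  if (length(bad)) stop("unknown metric(s): ", paste(bad, collapse = ", "))
  networks <- list()
  pairsScored <- 0L
  for (metric in intersect(c("pearson", "spearman"), use)) {
    sc <- correlateAll(M, method = metric)
    pairsScored <- pairsScored + nrow(sc)
    writeScores(sc, file.path(outDir, paste0("scores_", metric, ".tsv")))
    networks[[metric]] <- buildNetwork(
      thresholdScores(sc, corrThreshold = cfg$metrics$corrThreshold,
                      duoThreshold = cfg$metrics$duoThreshold),
      minWeight = cfg$metrics$corrThreshold)
  }
  if ("duo" %in% use) {
    sc <- duoAll(states, pairs = "transcript-trait")
    pairsScored <- pairsScored + nrow(sc) / 4L
    writeScores(sc, file.path(outDir, "scores_duo.tsv"))
    networks$duo <- buildNetwork(
      thresholdScores(sc, corrThreshold = cfg$metrics$corrThreshold,
                      duoThreshold = cfg$metrics$duoThreshold),
      minWeight = cfg$metrics$duoThreshold)
  }
  for (metric in names(networks)) {
    exportNetwork(networks[[metric]],
                  file.path(outDir, paste0("network_", metric, ".sif")),
                  format = "sif")
    exportNetwork(networks[[metric]],
                  file.path(outDir, paste0("network_", metric, ".edges.tsv")),
                  format = "edgelist")
  }

  overlap <- compareNetworks(networks, matching = cfg$compare$matching,
                             traitIds = featureIds(aligned$traits))
  writeOverlap(overlap, file.path(outDir, "overlap.json"), metrics = use)
  writeTraitCorrelation(traitCorrelationTable(aligned$traits),
                        file.path(outDir, "trait_correlation.tsv"))

  manifest <- list(
    tool = "duonet",
    version = as.character(utils::packageVersion("duonet")),
    configHash = configDigest(cfg),
    inputs = inputDigests,
    thresholds = list(
      filterMinAbundance = cfg$filter$minAbundance,
      filterMinSamples = cfg$filter$minSamples,
      corrThreshold = cfg$metrics$corrThreshold,
      duoThreshold = cfg$metrics$duoThreshold,
      stateLower = unname(stateThresholdsOf(states)["lower"]),
      stateUpper = unname(stateThresholdsOf(states)["upper"])),
    counts = list(
      samples = length(sampleIds(aligned$expression)),
      samplesDropped = length(aligned$dropped$expression) +
        length(aligned$dropped$traits),
      transcriptsIn = dim(expr)[1],
      transcriptsAfterFilter = flt$report$kept,
      traits = dim(traits)[1],
      rowsDroppedAtScaling = length(M@dropped),
      pairsScored = pairsScored,
      edges = lapply(networks, function(x) nrow(networkEdges(x))),
      nodes = lapply(networks, function(x) length(networkNodes(x)))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
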