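#' Default pipeline configuration
#'
#' Cutoffs mirror the analysis design: prevalence > 9 samples, FDR 0.001,
#' RMT scan from 0.30 in steps of 0.01, 100 random networks, 500 omission
#' permutations, 999 Mantel permutations. Every stochastic stage takes its
#' seed from \code{seeds} (derived from \code{seeds$master} when a stage
#' seed is absent).
#'
#' @return a config list accepted by \code{\link{runPipeline}}
#' @export
defaultConfig <- function() {
  list(
    synth = list(nTaxa = 150L, nModules = 4L,
                 moduleSize = c(20L, 6L, 13L, 15L),
                 withinModuleRho = 0.9, noiseSD = 0.3, sparsity = 0.1,
                 beta = 1, metaNoiseSD = 0.4),
    input = NULL,
    rarefyDepth = NULL,
    minPrevalence = 9,
    fdrCutoff = 0.001,
    rmt = list(start = 0.30, end = 0.95, step = 0.01, alpha = 0.05),
    nullReps = 100L,
    omissionPermutations = 500L,
    mantelPermutations = 999L,
    seeds = list(master = 1L),
    outDir = NULL
  )
}

stageSeed <- function(config, stage, offset) {
  config$seeds[[stage]] %||% deriveSeed(config$seeds$master %||% 1L, offset)
}

#' Run the full association-network pipeline
#'
#' Orchestrates all stages from one config (a list, or the path to a YAML
#' file with the same shape): data generation or ingestion, optional
#' rarefaction, prevalence filtering, all-pairs Spearman correlation with BH
#' FDR, the RMT threshold scan, network construction, topology summary with
#' random-ensemble comparison, omission-score edge classification with the
#' four phase-group subnetworks, and the connectivity-vs-GS Mantel table.
#' When \code{outDir} is set, artifacts (TSV/GraphML/JSON) are written there
#' and a machine-readable run report (config hash, seeds, cutoffs, stage
#' outputs) goes to \code{report.json}; re-running the same config
#' reproduces identical outputs.
#'
#' @param config a config list (see \code{\link{defaultConfig}}) or the path
#'   to a YAML file
#' @return invisibly, a list with every stage result and the report
#' @export
runPipeline <- function(config = defaultConfig()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  base <- defaultConfig()
  config <- utils::modifyList(base, config, keep.null = TRUE)
  stopIfNot(!is.null(config$synth) || !is.null(config$input),
            "config needs a 'synth' block or an 'input' block")

  # --- ingest or synthesise -------------------------------------------
  if (!is.null(config$input)) {
    stopIfNot(!is.null(config$input$abundance) &&
                !is.null(config$input$metadata),
              "input block needs 'abundance' and 'metadata' paths")
    table <- readAbundanceTable(config$input$abundance,
                                kind = config$input$kind %||% "count")
    meta <- readSampleMetadata(config$input$metadata)
    truth <- NULL
  } else {
    sp <- config$synth
    com <- generateCommunity(
      nTaxa = sp$nTaxa %||% 150L, nModules = sp$nModules %||% 4L,
      moduleSize = sp$moduleSize %||% c(20L, 6L, 13L, 15L),
      withinModuleRho = sp$withinModuleRho %||% 0.9,
      noiseSD = sp$noiseSD %||% 0.3, sparsity = sp$sparsity %||% 0.1,
      seed = stageSeed(config, "synth", 11L)
    )
    table <- com$table
    truth <- com$truth
    meta <- generateMetadata(table, truth, beta = sp$beta %||% 1,
                             noiseSD = sp$metaNoiseSD %||% 0.4,
                             seed = stageSeed(config, "metadata", 12L))
  }
  message(sprintf("input: %d taxa x %d samples", nrow(table), ncol(table)))

  if (!is.null(config$rarefyDepth) && identical(abundanceKind(table), "count"))
    table <- rarefyCounts(table, config$rarefyDepth,
                          seed = stageSeed(config, "rarefy", 13L))

  # --- network construction -------------------------------------------
  filtered <- prevalenceFilter(table, config$minPrevalence)
  message(sprintf("prevalence filter: %d taxa retained", nrow(filtered)))
  cs <- spearmanAllPairs(filtered)
  scan <- rmtThreshold(cs, scanStart = config$rmt$start,
                       scanEnd = config$rmt$end, step = config$rmt$step,
                       alpha = config$rmt$alpha)
  message(sprintf("RMT threshold: %.2f", chosenCutoff(scan)))
  net <- buildNetwork(cs, qCutoff = config$fdrCutoff,
                      rhoCutoff = chosenCutoff(scan),
                      taxonomy = taxonomyTable(filtered))
  stopIfNot(nEdges(net) >= 1, "the built network has no edges")
  message(sprintf("network: %d nodes, %d edges", nNodes(net), nEdges(net)))

  # --- topology, modules, roles, null comparison ----------------------
  topo <- summarizeTopology(net)
  mods <- detectModules(net)
  roles <- nodeRoles(net, mods$membership)
  ens <- randomEnsemble(nNodes(net), nEdges(net),
                        reps = config$nullReps,
                        seed = stageSeed(config, "null", 14L),
                        keepGraphs = TRUE)
  nullCmp <- compareToRandom(topo, ens)
  effPhylum <- groupEffectSizes(
    net, structure(taxonomyTable(filtered)$phylum,
                   names = rownames(filtered)), ens = ens)

  # --- group-specific edges -------------------------------------------
  grp <- structure(meta[colnames(filtered), "phase_group"],
                   names = colnames(filtered))
  cls <- classifyEdges(filtered, net, grp,
                       nRandom = config$omissionPermutations,
                       seed = stageSeed(config, "omission", 15L))
  subnets <- lapply(sort(unique(grp)), function(gv)
    suppressWarnings(groupSubnetwork(net, cls, gv)))
  names(subnets) <- sort(unique(grp))

  # --- GS / Mantel -----------------------------------------------------
  mantel <- connectivityMantelTable(
    net, filtered, meta,
    nPermutations = config$mantelPermutations,
    seed = stageSeed(config, "mantel", 16L))

  nGlobal <- sum(tapply(cls$globalEdge,
                        paste(cls$taxon1, cls$taxon2), all))
  report <- list(
    configHash = configHash(config),
    cutoffs = list(minPrevalence = config$minPrevalence,
                   fdr = config$fdrCutoff,
                   rmtCutoff = chosenCutoff(scan)),
    seeds = config$seeds,
    network = list(nodes = nNodes(net), edges = nEdges(net),
                   pctPositive = topo$pctPositive),
    edges = list(global = nGlobal,
                 groupSpecific = nEdges(net) - nGlobal),
    subnetworkEdges = lapply(subnets, nEdges)
  )

  res <- list(table = table, truth = truth, meta = meta,
              filtered = filtered, correlations = cs, scan = scan,
              net = net, topology = topo, modules = mods, roles = roles,
              ensemble = ens, nullComparison = nullCmp,
              effectSizes = effPhylum, classification = cls,
              subnetworks = subnets, mantel = mantel, report = report)

  if (!is.null(config$outDir)) writeArtifacts(res, config, config$outDir)
  invisible(res)
}

configHash <- function(config) {
  config$outDir <- NULL  # hash the analysis, not where it is written
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config[order(names(config))],
                              auto_unbox = TRUE, digits = NA,
                              null = "null"), tf)
  unname(tools::md5sum(tf))
}

writeArtifacts <- function(res, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  writeAbundanceTable(res$table, file.path(dir, "abundance.tsv"))
  wt(res$meta, "metadata.tsv")
  wt(scanTable(res$scan), "threshold_scan.tsv")
  writeNetwork(res$net, file.path(dir, "network.graphml"), "graphml")
  writeNetwork(res$net, file.path(dir, "edges.tsv"), "edgelist")
  wt(res$topology, "topology.tsv")
  wt(res$nullComparison, "null_comparison.tsv")
  wt(res$effectSizes, "effect_sizes.tsv")
  wt(as.data.frame(res$classification), "edge_classification.tsv")
  wt(res$roles, "node_roles.tsv")
  wt(res$mantel, "mantel.tsv")
  jsonlite::write_json(res$report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
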