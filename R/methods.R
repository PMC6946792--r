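#' @rdname AbundanceExperiment-class
#' @export
setMethod("abundances", "AbundanceExperiment",
          function(x) assay(x, "abundance"))

#' @rdname AbundanceExperiment-class
#' @export
setMethod("abundanceKind", "AbundanceExperiment",
          function(x) metadata(x)$kind)

#' @rdname AbundanceExperiment-class
#' @export
setMethod("taxonomyTable", "AbundanceExperiment", function(x) {
  td <- as.data.frame(rowData(x))
  td[, intersect(TAXONOMY_RANKS, colnames(td)), drop = FALSE]
})

setMethod("show", "AbundanceExperiment", function(object) {
  m <- abundances(object)
  cat(sprintf("AbundanceExperiment (%s): %d taxa x %d samples\n",
              abundanceKind(object), nrow(m), ncol(m)))
  dom <- table(rowData(object)$domain)
  cat("  domains:", paste(names(dom), dom, sep = "=", collapse = ", "), "\n")
})

#' @rdname CorrelationSet-class
#' @export
setMethod("corRho", "CorrelationSet", function(x) x@rho)

#' @rdname CorrelationSet-class
#' @export
setMethod("corP", "CorrelationSet", function(x) x@p)

#' @rdname CorrelationSet-class
#' @export
setMethod("corQ", "CorrelationSet", function(x) x@q)

#' @rdname CorrelationSet-class
#' @export
setMethod("corTaxa", "CorrelationSet", function(x) rownames(x@rho))

setMethod("show", "CorrelationSet", function(object) {
  n <- nrow(object@rho)
  np <- n * (n - 1) / 2
  ok <- sum(!is.na(object@rho[upper.tri(object@rho)]))
  cat(sprintf("CorrelationSet: %d taxa, %d pairs (%d defined), n = %d samples\n",
              n, np, ok, object@nSamples))
})

#' @rdname ThresholdScan-class
#' @export
setMethod("chosenCutoff", "ThresholdScan", function(x) x@chosenCutoff)

#' @rdname ThresholdScan-class
#' @export
setMethod("scanTable", "ThresholdScan", function(x) x@scan)

setMethod("show", "ThresholdScan", function(object) {
  cat(sprintf("ThresholdScan: %d cutoffs scanned, chosen cutoff = %.2f (alpha = %g)\n",
              nrow(object@scan), object@chosenCutoff, object@alpha))
})

#' @rdname AssociationNetwork-class
#' @export
setMethod("networkGraph", "AssociationNetwork", function(x) x@graph)

#' @rdname AssociationNetwork-class
#' @export
setMethod("edgeTable", "AssociationNetwork", function(x) {
  g <- x@graph
  if (igraph::ecount(g) == 0L)
    return(data.frame(taxon1 = character(), taxon2 = character(),
                      rho = numeric(), sign = character(), q = numeric(),
                      stringsAsFactors = FALSE))
  el <- igraph::as_edgelist(g, names = TRUE)
  data.frame(taxon1 = el[, 1L], taxon2 = el[, 2L],
             rho = igraph::E(g)$rho %||% rep(NA_real_, nrow(el)),
             sign = igraph::E(g)$sign %||% rep(NA_character_, nrow(el)),
             q = igraph::E(g)$q %||% rep(NA_real_, nrow(el)),
             stringsAsFactors = FALSE)
})

#' @rdname AssociationNetwork-class
#' @export
setMethod("nNodes", "AssociationNetwork",
          function(x) igraph::vcount(x@graph))

#' @rdname AssociationNetwork-class
#' @export
setMethod("nEdges", "AssociationNetwork",
          function(x) igraph::ecount(x@graph))

setMethod("show", "AssociationNetwork", function(object) {
  g <- object@graph
  sgn <- igraph::E(g)$sign
  pp <- if (igraph::ecount(g) > 0 && !is.null(sgn))
    sprintf(", %.1f%% positive", 100 * mean(sgn == "positive")) else ""
  cat(sprintf("AssociationNetwork: %d nodes, %d edges%s\n",
              igraph::vcount(g), igraph::ecount(g), pp))
})

#' @rdname PlantedTruth-class
#' @export
setMethod("moduleAssignments", "PlantedTruth", function(x) x@moduleAssignments)

#' @rdname PlantedTruth-class
#' @export
setMethod("plantedEdges", "PlantedTruth", function(x) x@plantedEdges)

#' @rdname PlantedTruth-class
#' @export
setMethod("driverTaxa", "PlantedTruth", function(x) x@driverTaxa)

setMethod("show", "PlantedTruth", function(object) {
  pe <- object@plantedEdges
  cat(sprintf("PlantedTruth: %d modules, %d planted edges (%d group-specific), %d driver taxa\n",
              length(setdiff(unique(object@moduleAssignments), "background")),
              nrow(pe), sum(!is.na(pe$phaseGroup)), length(object@driverTaxa)))
})
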