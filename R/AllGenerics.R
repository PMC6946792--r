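#' @rdname AbundanceExperiment-class
#' @param x an object
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' @rdname AbundanceExperiment-class
#' @export
setGeneric("abundanceKind", function(x) standardGeneric("abundanceKind"))

#' @rdname AbundanceExperiment-class
#' @export
setGeneric("taxonomyTable", function(x) standardGeneric("taxonomyTable"))

#' @rdname CorrelationSet-class
#' @param x an object
#' @export
setGeneric("corRho", function(x) standardGeneric("corRho"))

#' @rdname CorrelationSet-class
#' @export
setGeneric("corP", function(x) standardGeneric("corP"))

#' @rdname CorrelationSet-class
#' @export
setGeneric("corQ", function(x) standardGeneric("corQ"))

#' @rdname CorrelationSet-class
#' @export
setGeneric("corTaxa", function(x) standardGeneric("corTaxa"))

#' @rdname ThresholdScan-class
#' @param x an object
#' @export
setGeneric("chosenCutoff", function(x) standardGeneric("chosenCutoff"))

#' @rdname ThresholdScan-class
#' @export
setGeneric("scanTable", function(x) standardGeneric("scanTable"))

#' @rdname AssociationNetwork-class
#' @param x an object
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))

#' @rdname AssociationNetwork-class
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname AssociationNetwork-class
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname AssociationNetwork-class
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))

#' @rdname PlantedTruth-class
#' @param x an object
#' @export
setGeneric("moduleAssignments", function(x) standardGeneric("moduleAssignments"))

#' @rdname PlantedTruth-class
#' @export
setGeneric("plantedEdges", function(x) standardGeneric("plantedEdges"))

#' @rdname PlantedTruth-class
#' @export
setGeneric("driverTaxa", function(x) standardGeneric("driverTaxa"))
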