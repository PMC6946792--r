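#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors metadata metadata<- DataFrame SimpleList
NULL

TAXONOMY_RANKS <- c("domain", "phylum", "class", "order", "family",
                    "genus", "species")

#' AbundanceExperiment: taxon-by-sample abundance container
#'
#' Extends \linkS4class{SummarizedExperiment} with a single assay
#' \code{"abundance"} (taxa in rows, samples in columns), a seven-rank
#' taxonomy in \code{rowData}, and a \code{kind} flag distinguishing 16S
#' read counts (\code{"count"}) from functional-gene-array derived signal
#' intensities (\code{"signal"}). Sample metadata, when available, lives in
#' \code{colData}.
#'
#' @slot ... see \linkS4class{SummarizedExperiment}
#' @export
setClass("AbundanceExperiment", contains = "SummarizedExperiment")

setValidity("AbundanceExperiment", function(object) {
  msg <- character()
  if (!"abundance" %in% assayNames(object))
    msg <- c(msg, "assay 'abundance' is required")
  else {
    m <- assay(object, "abundance")
    if (is.null(rownames(m)) || is.null(colnames(m)))
      msg <- c(msg, "taxa and samples must be named")
    else {
      if (anyDuplicated(rownames(m)))
        msg <- c(msg, sprintf("duplicate taxon ID: %s",
                              rownames(m)[duplicated(rownames(m))][1L]))
      if (anyDuplicated(colnames(m)))
        msg <- c(msg, sprintf("duplicate sample ID: %s",
                              colnames(m)[duplicated(colnames(m))][1L]))
    }
    if (anyNA(m) || any(!is.finite(m)))
      msg <- c(msg, "abundance values must be finite and non-missing")
    else if (any(m < 0))
      msg <- c(msg, "abundance values must be non-negative")
    kind <- metadata(object)$kind
    if (is.null(kind) || !kind %in% c("count", "signal"))
      msg <- c(msg, "metadata 'kind' must be \"count\" or \"signal\"")
    else if (identical(kind, "count") && !anyNA(m) &&
             any(abs(m - round(m)) > 1e-8))
      msg <- c(msg, "kind=\"count\" requires integer values")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AbundanceExperiment
#'
#' @param values numeric taxon-by-sample matrix with row and column names;
#'   non-negative, integer when \code{kind = "count"}.
#' @param taxonomy optional: either a character vector of semicolon-separated
#'   rank strings (domain;phylum;class;order;family;genus;species, missing
#'   ranks \code{"unclassified"}) or a data.frame with those columns, one row
#'   per taxon.
#' @param kind \code{"count"} for rarefiable 16S OTU counts, \code{"signal"}
#'   for gene-array derived organism abundances.
#' @param sampleData optional data.frame of per-sample metadata (rownames =
#'   sample IDs).
#' @return an \linkS4class{AbundanceExperiment}
#' @export
AbundanceExperiment <- function(values, taxonomy = NULL,
                                kind = c("count", "signal"),
                                sampleData = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopIfNot(!is.null(rownames(values)) && !is.null(colnames(values)),
            "abundance matrix must have taxon rownames and sample colnames")
  rd <- taxonomyFrame(taxonomy, rownames(values))
  cd <- if (is.null(sampleData)) {
    DataFrame(row.names = colnames(values))
  } else {
    sampleData <- as.data.frame(sampleData)
    stopIfNot(all(colnames(values) %in% rownames(sampleData)),
              "sampleData must cover every sample")
    DataFrame(sampleData[colnames(values), , drop = FALSE])
  }
  se <- SummarizedExperiment(
    assays = SimpleList(abundance = values),
    rowData = rd, colData = cd
  )
  metadata(se)$kind <- kind
  new("AbundanceExperiment", se)
}

# Normalise taxonomy input to a 7-rank DataFrame.
taxonomyFrame <- function(taxonomy, taxa) {
  n <- length(taxa)
  if (is.null(taxonomy)) {
    m <- matrix("unclassified", n, length(TAXONOMY_RANKS),
                dimnames = list(taxa, TAXONOMY_RANKS))
    return(DataFrame(as.data.frame(m)))
  }
  if (is.character(taxonomy)) {
    stopIfNot(length(taxonomy) == n, "one taxonomy string per taxon required")
    parts <- strsplit(taxonomy, ";", fixed = TRUE)
    m <- t(vapply(parts, function(p) {
      p <- trimws(p)
      p <- p[nzchar(p)]
      out <- rep("unclassified", length(TAXONOMY_RANKS))
      out[seq_len(min(length(p), length(TAXONOMY_RANKS)))] <-
        p[seq_len(min(length(p), length(TAXONOMY_RANKS)))]
      out
    }, character(length(TAXONOMY_RANKS))))
    dimnames(m) <- list(taxa, TAXONOMY_RANKS)
    return(DataFrame(as.data.frame(m)))
  }
  taxonomy <- as.data.frame(taxonomy)
  stopIfNot(nrow(taxonomy) == n, "one taxonomy row per taxon required")
  for (rk in TAXONOMY_RANKS)
    if (!rk %in% colnames(taxonomy)) taxonomy[[rk]] <- "unclassified"
  taxonomy <- taxonomy[, TAXONOMY_RANKS]
  taxonomy[is.na(taxonomy)] <- "unclassified"
  rownames(taxonomy) <- taxa
  DataFrame(taxonomy)
}

#' CorrelationSet: all-pairs Spearman correlations
#'
#' Symmetric matrices of Spearman rho, raw two-sided p and BH-adjusted q over
#' every taxon pair. Pairs involving a taxon that is constant across samples
#' carry \code{NA} and are excluded from FDR adjustment and from network
#' construction.
#'
#' @slot rho,p,q symmetric numeric matrices (taxa x taxa)
#' @slot nSamples number of samples the correlations were computed over
#' @export
setClass("CorrelationSet",
  representation(rho = "matrix", p = "matrix", q = "matrix",
                 nSamples = "integer"))

setValidity("CorrelationSet", function(object) {
  msg <- character()
  r <- object@rho
  if (!isSymmetric(unname(r), tol = 1e-8)) msg <- c(msg, "rho not symmetric")
  if (any(abs(r) > 1 + 1e-8, na.rm = TRUE)) msg <- c(msg, "|rho| > 1")
  if (!identical(dim(r), dim(object@p)) || !identical(dim(r), dim(object@q)))
    msg <- c(msg, "rho/p/q dimensions differ")
  ok <- !is.na(object@p) & !is.na(object@q)
  if (any(object@q[ok] < object@p[ok] - 1e-12))
    msg <- c(msg, "q must be >= p elementwise")
  if (length(msg)) msg else TRUE
})

#' ThresholdScan: RMT correlation-threshold scan
#'
#' Per-cutoff nearest-neighbour spacing distribution (NNSD) goodness-of-fit
#' statistics against the Poisson form and the GOE Wigner surmise, with the
#' chosen cutoff (smallest cutoff whose NNSD is Poisson-consistent and
#' GOE-inconsistent).
#'
#' @slot scan data.frame of per-cutoff statistics
#' @slot chosenCutoff the selected correlation threshold
#' @slot alpha significance level used by both goodness-of-fit decisions
#' @export
setClass("ThresholdScan",
  representation(scan = "data.frame", chosenCutoff = "numeric",
                 alpha = "numeric"))

#' AssociationNetwork: signed undirected taxon association network
#'
#' Wraps an \pkg{igraph} graph whose vertices are taxa (with taxonomy and an
#' archaea/bacteria domain flag where known) and whose edges carry the
#' Spearman rho, its sign and the BH-adjusted q they were built from.
#' Module membership and node roles, once computed, are stored as vertex
#' attributes \code{module} and \code{role}.
#'
#' @slot graph an igraph object (undirected, simple)
#' @export
setClass("AssociationNetwork", representation(graph = "ANY"))

setValidity("AssociationNetwork", function(object) {
  g <- object@graph
  msg <- character()
  if (!igraph::is_igraph(g)) return("graph must be an igraph object")
  if (igraph::is_directed(g)) msg <- c(msg, "graph must be undirected")
  if (igraph::vcount(g) > 0 && is.null(igraph::V(g)$name))
    msg <- c(msg, "vertices must be named")
  if (igraph::any_loop(g) || igraph::any_multiple(g))
    msg <- c(msg, "graph must be simple (no loops or multi-edges)")
  if (length(msg)) msg else TRUE
})

#' PlantedTruth: ground truth of a synthetic community
#'
#' Records what the synthetic-community generator planted: the module each
#' taxon belongs to (or \code{"background"}), every within-module taxon pair
#' (the planted edges), which of those pairs are coupled only within one
#' phase group, and the taxa whose abundances drive the performance
#' parameters.
#'
#' @slot moduleAssignments named character vector, taxon -> module ID or
#'   \code{"background"}
#' @slot plantedEdges data.frame with columns taxon1, taxon2, module,
#'   phaseGroup (NA for globally coupled modules)
#' @slot driverTaxa taxa that drive performance parameters
#' @slot params generator parameters actually used
#' @slot seed the seed the community was generated under
#' @export
setClass("PlantedTruth",
  representation(moduleAssignments = "character", plantedEdges = "data.frame",
                 driverTaxa = "character", params = "list", seed = "numeric"))

setValidity("PlantedTruth", function(object) {
  pe <- object@plantedEdges
  need <- c("taxon1", "taxon2", "module", "phaseGroup")
  if (!all(need %in% colnames(pe)))
    return("plantedEdges needs columns taxon1, taxon2, module, phaseGroup")
  taxa <- names(object@moduleAssignments)
  if (!all(c(pe$taxon1, pe$taxon2) %in% taxa))
    return("planted edges must connect declared taxa")
  TRUE
})
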