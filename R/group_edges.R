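#' Omission score of an edge
#'
#' Spearman correlation of the edge's two taxa recomputed over the samples
#' NOT in \code{omit}: the correlation the edge would have if the omitted
#' sample set had never been observed. An empty omission set returns the
#' original correlation.
#'
#' @param x an AbundanceExperiment
#' @param taxon1,taxon2 the edge's endpoints
#' @param omit sample IDs to leave out
#' @return the omission-score Spearman rho (NA with a warning if a taxon is
#'   constant on the remaining samples)
#' @export
omissionScore <- function(x, taxon1, taxon2, omit = character()) {
  m <- abundances(x)
  stopIfNot(all(c(taxon1, taxon2) %in% rownames(m)), "unknown taxon")
  stopIfNot(all(omit %in% colnames(m)), "unknown sample in omission set")
  keep <- setdiff(colnames(m), omit)
  stopIfNot(length(keep) >= 4, "fewer than 4 samples remain after omission")
  a <- m[taxon1, keep]
  b <- m[taxon2, keep]
  if (length(unique(a)) == 1L || length(unique(b)) == 1L) {
    warning("taxon constant on remaining samples; omission score undefined")
    return(NA_real_)
  }
  stats::cor(a, b, method = "spearman")
}

#' Classify network edges as global or group-specific
#'
#' For every edge and every phase group, the omission score (OS) is the
#' Spearman correlation recomputed without that group's samples. Its null
#' distribution comes from \code{nRandom} random same-size sample omissions
#' (drawn without replacement from all samples, independently per draw); the
#' nonparametric p is the fraction of random OS magnitudes smaller than the
#' group's OS magnitude. An edge is group-specific for a group when
#' |OS| < |original rho| and p < 0.05 — the group's samples carry the
#' correlation. Edges specific to no group are global. The magnitude
#' (sign-blind) comparison makes negative edges classifiable.
#'
#' @param x the AbundanceExperiment the network was built from
#' @param net an AssociationNetwork
#' @param groups named character vector (sample -> phase group) partitioning
#'   the samples, e.g. \code{metadata$phase_group} named by sample ID
#' @param nRandom number of random omissions (default 500)
#' @param seed RNG seed
#' @return data.frame of class \code{"EdgeGroupClassification"} with one row
#'   per edge x group: taxon1, taxon2, group, originalRho, OS, ratio
#'   (OS/|originalRho|), p, groupSpecific; plus a \code{global} attribute is
#'   encoded in the \code{globalEdge} column (TRUE on every row of an edge
#'   specific to no group)
#' @export
classifyEdges <- function(x, net, groups, nRandom = 500L, seed = NULL) {
  stopIfNot(nRandom >= 100, "nRandom must be >= 100")
  m <- abundances(x)
  et <- edgeTable(net)
  stopIfNot(nrow(et) >= 1, "network has no edges")
  stopIfNot(all(c(et$taxon1, et$taxon2) %in% rownames(m)),
            "network nodes must be a subset of table taxa")
  samples <- colnames(m)
  stopIfNot(all(samples %in% names(groups)),
            "groups must cover every sample")
  grp <- as.character(groups[samples])
  glev <- sort(unique(grp))
  sizes <- table(grp)
  stopIfNot(all(ncol(m) - sizes >= 4),
            "a group leaves fewer than 4 samples when omitted")
  taxa <- sort(unique(c(et$taxon1, et$taxon2)))
  sub <- m[taxa, , drop = FALSE]
  pairs <- cbind(match(et$taxon1, taxa), match(et$taxon2, taxa))
  orig <- spearmanPairs(sub, pairs)
  # group omission scores
  osMat <- vapply(glev, function(gv) {
    spearmanPairs(sub, pairs, cols = which(grp != gv))
  }, numeric(nrow(pairs)))
  osMat <- matrix(osMat, nrow = nrow(pairs),
                  dimnames = list(NULL, glev))
  # random same-size omissions, shared across edges within a draw
  nS <- length(samples)
  randAbs <- withSeed(seed, {
    out <- list()
    for (sz in sort(unique(as.integer(sizes)))) {
      ra <- vapply(seq_len(nRandom), function(r) {
        keepCols <- setdiff(seq_len(nS), sample(nS, sz))
        abs(spearmanPairs(sub, pairs, cols = keepCols))
      }, numeric(nrow(pairs)))
      out[[as.character(sz)]] <- matrix(ra, nrow = nrow(pairs))
    }
    out
  })
  rows <- lapply(glev, function(gv) {
    ra <- randAbs[[as.character(sizes[[gv]])]]
    osg <- osMat[, gv]
    p <- rowMeans(ra < abs(osg), na.rm = TRUE)
    data.frame(
      taxon1 = et$taxon1, taxon2 = et$taxon2, group = gv,
      originalRho = orig, OS = osg,
      ratio = osg / abs(orig),
      p = p,
      groupSpecific = !is.na(osg) & abs(osg) < abs(orig) & p < 0.05,
      stringsAsFactors = FALSE
    )
  })
  cls <- do.call(rbind, rows)
  key <- paste(cls$taxon1, cls$taxon2)
  specAny <- tapply(cls$groupSpecific, key, any)
  cls$globalEdge <- as.vector(!specAny[key])
  rownames(cls) <- NULL
  class(cls) <- c("EdgeGroupClassification", class(cls))
  cls
}

#' Build a phase-group subnetwork from classified edges
#'
#' Under the strict reading, the subnetwork for a group contains exactly the
#' edges flagged specific to that group (with their incident nodes). Setting
#' \code{includeGlobal = TRUE} adds the global edges as well — the
#' alternative composition under which subnetworks share a conserved core.
#'
#' @param net the overall AssociationNetwork
#' @param classifications output of \code{\link{classifyEdges}}
#' @param group the phase group
#' @param includeGlobal also include edges specific to no group
#' @return an AssociationNetwork (possibly empty, with a warning)
#' @export
groupSubnetwork <- function(net, classifications, group,
                            includeGlobal = FALSE) {
  cl <- classifications[classifications$group == group, , drop = FALSE]
  stopIfNot(nrow(cl) > 0, "no classifications for group %s", group)
  keep <- cl$groupSpecific
  if (includeGlobal) keep <- keep | cl$globalEdge
  g <- networkGraph(net)
  et <- edgeTable(net)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  sel <- key(et$taxon1, et$taxon2) %in% key(cl$taxon1[keep], cl$taxon2[keep])
  if (!any(sel)) {
    warning(sprintf("no edges selected for group %s", group))
    return(new("AssociationNetwork",
               graph = igraph::make_empty_graph(0, directed = FALSE)))
  }
  sg <- igraph::subgraph_from_edges(g, igraph::E(g)[sel],
                                    delete.vertices = TRUE)
  new("AssociationNetwork", graph = sg)
}
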