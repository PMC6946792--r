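ENV_PARAMETERS <- c("ammonia", "acetate", "ph", "vs_load")
PERF_PARAMETERS <- c("biogas", "methane", "vs_removal")

#' Gene significance of taxa against a parameter
#'
#' GS is the squared Pearson correlation (r^2) of each taxon's abundance
#' profile with the parameter across samples; constant taxa (or a constant
#' parameter) give NA.
#'
#' @param x an AbundanceExperiment (>= 4 samples)
#' @param parameter numeric vector, one value per sample (named or in
#'   column order)
#' @return named numeric vector of GS values in [0, 1]
#' @export
geneSignificance <- function(x, parameter) {
  m <- abundances(x)
  stopIfNot(ncol(m) >= 4, "need >= 4 samples")
  if (!is.null(names(parameter))) {
    stopIfNot(all(colnames(m) %in% names(parameter)),
              "parameter must cover every sample")
    parameter <- parameter[colnames(m)]
  }
  stopIfNot(length(parameter) == ncol(m),
            "one parameter value per sample required")
  stopIfNot(all(is.finite(parameter)), "parameter must be finite")
  if (stats::sd(parameter) == 0)
    return(structure(rep(NA_real_, nrow(m)), names = rownames(m)))
  r <- suppressWarnings(as.vector(stats::cor(t(m), parameter)))
  structure(r^2, names = rownames(m))
}

#' Gene-significance matrix over a parameter set
#'
#' @param x an AbundanceExperiment
#' @param meta sample metadata (rownames = sample IDs)
#' @param parameters metadata columns to use (e.g. the environment set
#'   ammonia/acetate/ph/vs_load or the performance set
#'   biogas/methane/vs_removal)
#' @return taxa x parameters matrix of GS values
#' @export
gsMatrix <- function(x, meta, parameters) {
  m <- abundances(x)
  stopIfNot(all(colnames(m) %in% rownames(meta)),
            "metadata must cover every sample")
  stopIfNot(all(parameters %in% colnames(meta)),
            "unknown parameter column(s): %s",
            paste(setdiff(parameters, colnames(meta)), collapse = ", "))
  vapply(parameters, function(pn) {
    geneSignificance(x, structure(meta[colnames(m), pn],
                                  names = colnames(m)))
  }, numeric(nrow(m)))
}

#' Euclidean distance between taxa's GS profiles
#'
#' @param gs taxa x parameters GS matrix
#' @param taxa optional taxon subset (>= 3 after dropping NA rows)
#' @param method distance between GS row-vectors: euclidean (default),
#'   manhattan or bray
#' @return a \code{dist} over taxa
#' @export
gsDistance <- function(gs, taxa = NULL,
                       method = c("euclidean", "manhattan", "bray")) {
  method <- match.arg(method)
  taxa <- taxa %||% rownames(gs)
  stopIfNot(all(taxa %in% rownames(gs)), "unknown taxon in subset")
  sub <- gs[taxa, , drop = FALSE]
  bad <- rowSums(is.na(sub)) > 0
  if (any(bad)) {
    warning(sprintf("%d taxa with undefined GS dropped", sum(bad)))
    sub <- sub[!bad, , drop = FALSE]
  }
  stopIfNot(nrow(sub) >= 3, "need >= 3 taxa with defined GS")
  if (method == "bray") vegan::vegdist(sub, method = "bray")
  else stats::dist(sub, method = method)
}

#' Distance between taxa's network connectivity
#'
#' \eqn{d(i, j) = |k_i - k_j|} with k the node degree in the overall
#' network; a subset (e.g. archaea only, or one class) restricts the taxa
#' compared but degrees always come from the overall network.
#'
#' @param net the overall AssociationNetwork
#' @param taxa taxon subset (must be network nodes)
#' @return a \code{dist} over the subset
#' @export
connectivityDistance <- function(net, taxa = NULL) {
  g <- networkGraph(net)
  nm <- igraph::V(g)$name
  taxa <- taxa %||% nm
  stopIfNot(all(taxa %in% nm), "taxon not in network: %s",
            paste(utils::head(setdiff(taxa, nm), 3), collapse = ", "))
  k <- igraph::degree(g)[taxa]
  stats::dist(matrix(k, dimnames = list(taxa, NULL)), method = "manhattan")
}

triVec <- function(d) {
  m <- as.matrix(d)
  m[lower.tri(m)]
}

alignDist <- function(d1, d2) {
  m1 <- as.matrix(d1)
  m2 <- as.matrix(d2)
  stopIfNot(nrow(m1) == nrow(m2), "distance matrices differ in size")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2))) {
    stopIfNot(setequal(rownames(m1), rownames(m2)),
              "distance matrices cover different taxa")
    m2 <- m2[rownames(m1), rownames(m1)]
  }
  list(m1 = m1, m2 = m2)
}

#' Mantel test
#'
#' The Mantel statistic r_M is the Pearson correlation of the off-diagonal
#' (lower-triangle) entries of two symmetric distance matrices. The
#' one-sided (greater) p-value comes from jointly permuting rows and columns
#' of the second matrix: p = (number of permuted r >= observed + 1) /
#' (permutations + 1).
#'
#' @param d1,d2 conformable symmetric zero-diagonal matrices or \code{dist}
#'   objects (matched by dimnames when present)
#' @param nPermutations permutation count (default 999)
#' @param seed RNG seed
#' @param method correlation flavour for the statistic: pearson (classical)
#'   or spearman
#' @return data.frame with r, p, nPermutations, method
#' @export
mantelTest <- function(d1, d2, nPermutations = 999L, seed = NULL,
                       method = c("pearson", "spearman")) {
  method <- match.arg(method)
  al <- alignDist(d1, d2)
  n <- nrow(al$m1)
  stopIfNot(n >= 3, "need >= 3 taxa")
  v1 <- al$m1[lower.tri(al$m1)]
  r <- stats::cor(v1, al$m2[lower.tri(al$m2)], method = method)
  perm <- withSeed(seed, {
    vapply(seq_len(nPermutations), function(i) {
      idx <- sample.int(n)
      mp <- al$m2[idx, idx]
      stats::cor(v1, mp[lower.tri(mp)], method = method)
    }, numeric(1))
  })
  p <- (sum(perm >= r) + 1) / (nPermutations + 1)
  data.frame(r = r, p = p, nPermutations = nPermutations, method = method)
}

#' Partial Mantel test
#'
#' Correlation between d1 and d2 with the control matrix partialled out:
#' the first-order partial correlation of the lower-triangle vectors,
#' \eqn{r_{12.3} = (r_{12} - r_{13} r_{23}) / \sqrt{(1-r_{13}^2)(1-r_{23}^2)}}.
#' The permutation null jointly permutes rows/columns of d1 and recomputes
#' the partial statistic, preserving the distance structure of all three
#' matrices; p is one-sided (greater). A constant control matrix falls back
#' to the plain Mantel test with a warning.
#'
#' @param d1,d2,dControl conformable symmetric matrices / dist objects
#' @param nPermutations permutation count (default 999)
#' @param seed RNG seed
#' @param method pearson or spearman
#' @return data.frame with r, p, nPermutations, method
#' @export
partialMantelTest <- function(d1, d2, dControl, nPermutations = 999L,
                              seed = NULL, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  al <- alignDist(d1, d2)
  alc <- alignDist(al$m1, dControl)
  n <- nrow(al$m1)
  stopIfNot(n >= 4, "need >= 4 taxa for a partial Mantel test")
  lt <- lower.tri(al$m1)
  v1 <- al$m1[lt]; v2 <- al$m2[lt]; vc <- alc$m2[lt]
  if (stats::sd(vc) == 0) {
    warning("constant control matrix; falling back to plain Mantel test")
    return(mantelTest(d1, d2, nPermutations, seed, method))
  }
  pcor <- function(a, b, cc) {
    r12 <- stats::cor(a, b, method = method)
    r13 <- stats::cor(a, cc, method = method)
    r23 <- stats::cor(b, cc, method = method)
    (r12 - r13 * r23) / sqrt((1 - r13^2) * (1 - r23^2))
  }
  r <- pcor(v1, v2, vc)
  perm <- withSeed(seed, {
    vapply(seq_len(nPermutations), function(i) {
      idx <- sample.int(n)
      mp <- al$m1[idx, idx]
      pcor(mp[lt], v2, vc)
    }, numeric(1))
  })
  p <- (sum(perm >= r) + 1) / (nPermutations + 1)
  data.frame(r = r, p = p, nPermutations = nPermutations, method = method)
}

#' Connectivity-vs-GS Mantel table over taxon subsets
#'
#' For the whole network, each domain (Archaea, Bacteria) and every class
#' with at least \code{minNodes} network nodes, runs three tests between the
#' node-connectivity distance matrix and (i) the environment GS distance,
#' (ii) the performance GS distance, and (iii) the performance GS distance
#' with the environment GS distance controlled (partial Mantel). Degrees are
#' always taken from the overall network; GS distances are Euclidean on GS
#' row-vectors. Subsets smaller than \code{minNodes} are skipped with a
#' reason.
#'
#' @param net the overall AssociationNetwork, annotated with taxonomy
#'   (see \code{\link{annotateNetwork}})
#' @param x the AbundanceExperiment
#' @param meta sample metadata with the environment and performance columns
#' @param envParameters,perfParameters metadata column sets (defaults:
#'   ammonia/acetate/ph/vs_load and biogas/methane/vs_removal)
#' @param nPermutations Mantel permutations (default 999)
#' @param seed RNG seed
#' @param minNodes smallest subset analysed (default 3)
#' @param byClass also analyse per-class subsets (default TRUE; FALSE keeps
#'   only All/Archaea/Bacteria)
#' @return data.frame with one row per subset: subset, level, n, rEnv, pEnv,
#'   rPerf, pPerf, rPartial, pPartial (NA rows carry a skip reason in
#'   \code{note})
#' @export
connectivityMantelTable <- function(net, x, meta,
                                    envParameters = ENV_PARAMETERS,
                                    perfParameters = PERF_PARAMETERS,
                                    nPermutations = 999L, seed = NULL,
                                    minNodes = 3L, byClass = TRUE) {
  g <- networkGraph(net)
  nodes <- igraph::V(g)$name
  stopIfNot(length(nodes) >= minNodes, "network too small")
  m <- abundances(x)
  stopIfNot(all(nodes %in% rownames(m)), "network nodes missing from table")
  xs <- x[rownames(m) %in% nodes, ]
  gsEnv <- gsMatrix(xs, meta, envParameters)
  gsPerf <- gsMatrix(xs, meta, perfParameters)
  dom <- igraph::vertex_attr(g, "domain")
  cls <- igraph::vertex_attr(g, "class")
  subsets <- list(All = nodes)
  if (!is.null(dom)) {
    for (d in intersect(c("Archaea", "Bacteria"), unique(dom)))
      subsets[[d]] <- nodes[dom == d]
    if (!is.null(cls) && byClass) {
      for (cv in setdiff(unique(cls), "unclassified")) {
        if (sum(cls == cv) >= minNodes) subsets[[cv]] <- nodes[cls == cv]
      }
    }
  }
  rows <- lapply(names(subsets), function(sn) {
    taxa <- subsets[[sn]]
    ok <- taxa[rowSums(is.na(gsEnv[taxa, , drop = FALSE])) == 0 &
                 rowSums(is.na(gsPerf[taxa, , drop = FALSE])) == 0]
    base <- data.frame(subset = sn, n = length(ok),
                       rEnv = NA_real_, pEnv = NA_real_,
                       rPerf = NA_real_, pPerf = NA_real_,
                       rPartial = NA_real_, pPartial = NA_real_,
                       note = "", stringsAsFactors = FALSE)
    if (length(ok) < max(minNodes, 4L)) {
      base$note <- sprintf("skipped: %d usable taxa", length(ok))
      return(base)
    }
    dConn <- connectivityDistance(net, ok)
    dEnv <- gsDistance(gsEnv, ok)
    dPerf <- gsDistance(gsPerf, ok)
    s1 <- deriveSeed(seed, 1L); s2 <- deriveSeed(seed, 2L)
    s3 <- deriveSeed(seed, 3L)
    tEnv <- mantelTest(dConn, dEnv, nPermutations, s1)
    tPerf <- mantelTest(dConn, dPerf, nPermutations, s2)
    tPar <- partialMantelTest(dConn, dPerf, dEnv, nPermutations, s3)
    base$rEnv <- tEnv$r; base$pEnv <- tEnv$p
    base$rPerf <- tPerf$r; base$pPerf <- tPerf$p
    base$rPartial <- tPar$r; base$pPartial <- tPar$p
    base
  })
  do.call(rbind, rows)
}
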