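asGraph <- function(net) {
  if (is(net, "AssociationNetwork")) networkGraph(net) else {
    stopIfNot(igraph::is_igraph(net), "expected an AssociationNetwork or igraph")
    net
  }
}

#' Harmonic geodesic distance
#'
#' \eqn{GD = N_{pairs} / \sum_{i<j} 1/d_{ij}} over all unordered node pairs,
#' with \eqn{d_{ij}} the shortest-path length; unreachable pairs contribute
#' zero reciprocal, so disconnected graphs still get a finite GD. This is
#' the harmonic-mean convention under which "average shortest path" remains
#' meaningful off the giant component.
#'
#' @param net an AssociationNetwork or igraph
#' @return the harmonic geodesic distance
#' @export
harmonicGeodesic <- function(net) {
  g <- asGraph(net)
  n <- igraph::vcount(g)
  stopIfNot(n >= 2, "need at least 2 nodes")
  d <- igraph::distances(g)
  inv <- 1 / d[upper.tri(d)]
  inv[!is.finite(inv)] <- 0
  s <- sum(inv)
  stopIfNot(s > 0, "no finite-distance pair: GD undefined")
  (n * (n - 1) / 2) / s
}

#' Average local clustering coefficient
#'
#' Mean over nodes of the local transitivity; nodes with degree < 2
#' contribute 0.
#'
#' @param net an AssociationNetwork or igraph
#' @return average clustering coefficient in [0, 1]
#' @export
avgClustering <- function(net) {
  g <- asGraph(net)
  stopIfNot(igraph::vcount(g) >= 1, "empty graph")
  mean(igraph::transitivity(g, type = "localundirected", isolates = "zero"))
}

#' Detect modules by modularity maximisation
#'
#' Greedy agglomerative (fast-greedy) maximisation of Newman modularity
#' \eqn{Q = \sum_m (e_{mm} - a_m^2)} by default; leading-eigenvector is
#' available as an alternative. Both are deterministic, so no seed is
#' needed. Isolated nodes (none exist in built networks) would each form a
#' singleton module.
#'
#' @param net an AssociationNetwork or igraph with >= 1 edge
#' @param method \code{"fastgreedy"} or \code{"leading_eigen"}
#' @param initial optional candidate partition (named or vertex-ordered);
#'   the returned partition is whichever of the algorithmic and candidate
#'   partitions has the higher Q, so supplying a known-good partition can
#'   never lower the result
#' @return list with \code{membership} (named integer vector), \code{Q} and
#'   \code{nModules}
#' @export
detectModules <- function(net, method = c("fastgreedy", "leading_eigen"),
                          initial = NULL) {
  method <- match.arg(method)
  g <- asGraph(net)
  stopIfNot(igraph::ecount(g) >= 1, "need at least one edge")
  cl <- if (method == "fastgreedy") {
    igraph::cluster_fast_greedy(g)
  } else {
    igraph::cluster_leading_eigen(g)
  }
  mem <- as.integer(igraph::membership(cl))
  Q <- igraph::modularity(g, mem)
  if (Q < 0) {
    # a partition can never beat the trivial one if its Q is negative
    mem <- rep(1L, igraph::vcount(g))
    Q <- igraph::modularity(g, mem)
  }
  if (!is.null(initial)) {
    ini <- if (!is.null(names(initial)))
      as.integer(factor(initial[igraph::V(g)$name])) else as.integer(initial)
    Qi <- igraph::modularity(g, ini)
    if (Qi > Q) { mem <- ini; Q <- Qi }
  }
  list(membership = structure(mem, names = igraph::V(g)$name),
       Q = Q, nModules = length(unique(mem)))
}

#' Power-law fit to the degree distribution
#'
#' Ordinary least squares of log(frequency) on log(degree) over the
#' nonzero-frequency positive degrees, matching the "R-squared of power
#' law" convention of scale-free network summaries. Requires at least 5
#' distinct degree values.
#'
#' @param net an AssociationNetwork or igraph
#' @return list with \code{R2}, \code{p} (slope significance) and
#'   \code{slope}
#' @export
powerlawFit <- function(net) {
  g <- asGraph(net)
  k <- igraph::degree(g)
  tab <- table(k[k > 0])
  stopIfNot(length(tab) >= 5,
            "need >= 5 distinct degree values for a power-law fit")
  kk <- as.numeric(names(tab))
  fit <- stats::lm(log(as.numeric(tab)) ~ log(kk))
  sm <- summary(fit)
  list(R2 = sm$r.squared, p = sm$coefficients[2L, 4L],
       slope = unname(stats::coef(fit)[2L]))
}

#' Topology summary of a network
#'
#' All Table-1-style topological properties of the undirected simple graph:
#' node and edge counts, percent positive edges, power-law R-squared of the
#' degree distribution, average connectivity (2E/N), harmonic geodesic
#' distance, average clustering coefficient, fast-greedy modularity and
#' module count, and Freeman centralization of degree, betweenness and
#' closeness. Edge sign enters only the percent-positive field.
#'
#' @param net an AssociationNetwork or igraph with >= 1 edge
#' @param moduleMethod passed to \code{\link{detectModules}}
#' @return one-row data.frame
#' @export
summarizeTopology <- function(net, moduleMethod = "fastgreedy") {
  g <- asGraph(net)
  stopIfNot(igraph::ecount(g) >= 1, "cannot summarise an empty graph")
  nV <- igraph::vcount(g)
  nE <- igraph::ecount(g)
  sgn <- igraph::E(g)$sign
  pctPos <- if (!is.null(sgn)) 100 * mean(sgn == "positive") else NA_real_
  pl <- tryCatch(powerlawFit(g), error = function(e) list(R2 = NA_real_,
                                                          p = NA_real_))
  mod <- detectModules(g, moduleMethod)
  data.frame(
    nNodes = nV, nEdges = nE, pctPositive = pctPos,
    powerlawR2 = pl$R2, powerlawP = pl$p,
    avgK = 2 * nE / nV,
    GD = harmonicGeodesic(g),
    avgCC = avgClustering(g),
    modularity = mod$Q, nModules = mod$nModules,
    centrDegree = igraph::centr_degree(g)$centralization,
    centrBetweenness = igraph::centr_betw(g)$centralization,
    centrCloseness = suppressWarnings(igraph::centr_clo(g)$centralization)
  )
}

#' Within-module degree z-score and participation coefficient roles
#'
#' Classifies nodes by the Guimera-Amaral Zi-Pi scheme:
#' \eqn{z_i = (k_i^{within} - \bar{k}^{within}_m) / SD_m} (SD 0 gives z 0)
#' and \eqn{P_i = 1 - \sum_m (k_{i,m}/k_i)^2}. Module hubs (candidate
#' keystone taxa) have \eqn{z_i >} \code{zHub} with \eqn{P_i \le}
#' \code{pConnector}; network hubs exceed both thresholds; connectors exceed
#' only the participation threshold; all others are peripheral.
#'
#' @param net an AssociationNetwork or igraph
#' @param membership named module assignment covering all nodes (e.g. from
#'   \code{\link{detectModules}})
#' @param zHub within-module degree z threshold (default 2.5)
#' @param pConnector participation coefficient threshold (default 0.62)
#' @return data.frame with node, module, z, P, role
#' @export
nodeRoles <- function(net, membership, zHub = 2.5, pConnector = 0.62) {
  g <- asGraph(net)
  nm <- igraph::V(g)$name
  stopIfNot(all(nm %in% names(membership)),
            "membership must cover every node")
  mem <- membership[nm]
  k <- igraph::degree(g)
  mods <- sort(unique(mem))
  # k_{i,m}: edges from i into module m
  el <- igraph::as_edgelist(g, names = TRUE)
  kim <- matrix(0, length(nm), length(mods),
                dimnames = list(nm, as.character(mods)))
  for (r in seq_len(nrow(el))) {
    a <- el[r, 1L]; b <- el[r, 2L]
    kim[a, as.character(mem[b])] <- kim[a, as.character(mem[b])] + 1
    kim[b, as.character(mem[a])] <- kim[b, as.character(mem[a])] + 1
  }
  kWithin <- kim[cbind(nm, as.character(mem))]
  z <- numeric(length(nm))
  for (m in mods) {
    idx <- mem == m
    mu <- mean(kWithin[idx])
    sd <- stats::sd(kWithin[idx])
    z[idx] <- if (is.na(sd) || sd == 0) 0 else (kWithin[idx] - mu) / sd
  }
  P <- ifelse(k > 0, 1 - rowSums((kim / pmax(k, 1))^2), 0)
  role <- ifelse(z > zHub & P > pConnector, "network hub",
          ifelse(z > zHub, "module hub",
          ifelse(P > pConnector, "connector", "peripheral")))
  data.frame(node = nm, module = as.integer(mem), z = z, P = P,
             role = role, row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-sample subnetworks of the overall network
#'
#' For each sample, the induced subgraph of the overall network on the taxa
#' with nonzero abundance in that sample (organisms "present" in the
#' sample).
#'
#' @param net the overall AssociationNetwork
#' @param x the AbundanceExperiment the network was built from
#' @param samples sample IDs (default all)
#' @return named list of AssociationNetwork objects
#' @export
perSampleSubnetworks <- function(net, x, samples = NULL) {
  g <- asGraph(net)
  m <- abundances(x)
  samples <- samples %||% colnames(m)
  stopIfNot(all(samples %in% colnames(m)), "sample absent from table: %s",
            paste(setdiff(samples, colnames(m)), collapse = ", "))
  stopIfNot(all(igraph::V(g)$name %in% rownames(m)),
            "network nodes must be a subset of table taxa")
  out <- lapply(samples, function(s) {
    present <- rownames(m)[m[, s] > 0]
    keep <- intersect(igraph::V(g)$name, present)
    if (length(keep) == 0L)
      warning(sprintf("sample %s contains no network taxa", s))
    new("AssociationNetwork",
        graph = igraph::induced_subgraph(g, keep))
  })
  names(out) <- samples
  out
}

#' Correlate per-sample topology with digester parameters
#'
#' Spearman correlation (two-sided t-approximation p) between every
#' topological property column and every environmental/performance
#' parameter, with a significance mask at p < 0.05. Properties constant
#' across samples are undefined and masked.
#'
#' @param summaries data.frame of per-sample topology summaries (rownames =
#'   sample IDs), e.g. stacked \code{\link{summarizeTopology}} rows
#' @param meta sample metadata data.frame (rownames = sample IDs)
#' @param parameters metadata columns to test (default: the numeric ones
#'   besides day)
#' @return data.frame with property, parameter, rho, p, significant
#' @export
topologyVsParameters <- function(summaries, meta, parameters = NULL) {
  stopIfNot(nrow(summaries) >= 5, "need >= 5 samples")
  common <- intersect(rownames(summaries), rownames(meta))
  stopIfNot(length(common) >= 5, "summaries and metadata share < 5 samples")
  summaries <- summaries[common, , drop = FALSE]
  meta <- meta[common, , drop = FALSE]
  if (is.null(parameters)) {
    num <- vapply(meta, is.numeric, logical(1))
    parameters <- setdiff(colnames(meta)[num], "day")
  }
  props <- colnames(summaries)[vapply(summaries, is.numeric, logical(1))]
  res <- expand.grid(property = props, parameter = parameters,
                     stringsAsFactors = FALSE)
  stat <- t(apply(res, 1L, function(rw) {
    pv <- summaries[[rw[["property"]]]]
    mv <- meta[[rw[["parameter"]]]]
    ok <- is.finite(pv) & is.finite(mv)
    if (sum(ok) < 5 || stats::sd(pv[ok]) == 0 || stats::sd(mv[ok]) == 0)
      return(c(NA_real_, NA_real_))
    ct <- suppressWarnings(stats::cor.test(pv[ok], mv[ok],
                                           method = "spearman",
                                           exact = FALSE))
    c(unname(ct$estimate), ct$p.value)
  }))
  res$rho <- stat[, 1L]
  res$p <- stat[, 2L]
  res$significant <- !is.na(res$p) & res$p < 0.05
  res
}
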