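#' Uniform random-graph ensemble matched to a network's size
#'
#' Draws \code{reps} uniform simple random graphs G(n, m) with exactly
#' \code{nNodes} labelled nodes and \code{nEdges} edges (no self-loops or
#' multi-edges) — the "randomly rewired, node and edge counts unchanged"
#' null — and records harmonic geodesic distance, average clustering
#' coefficient and fast-greedy modularity for each replicate. A
#' degree-preserving rewired ensemble of a reference graph is available via
#' \code{method = "degree_preserving"}.
#'
#' @param nNodes,nEdges ensemble size parameters
#' @param reps number of replicates (default 100)
#' @param seed RNG seed
#' @param keepGraphs keep the replicate graphs (needed for
#'   \code{\link{groupEffectSizes}})
#' @param method \code{"gnm"} (uniform G(n,m)) or \code{"degree_preserving"}
#'   (edge-swap rewiring of \code{refGraph})
#' @param refGraph reference igraph, required for degree-preserving rewiring
#' @return list of class \code{"RandomEnsemble"}: \code{stats} (per-metric
#'   mean/sd), \code{metrics} (reps x 3), \code{graphs} (or NULL),
#'   \code{nNodes}, \code{nEdges}, \code{reps}, \code{seed}
#' @export
randomEnsemble <- function(nNodes, nEdges, reps = 100L, seed = NULL,
                           keepGraphs = FALSE,
                           method = c("gnm", "degree_preserving"),
                           refGraph = NULL) {
  method <- match.arg(method)
  stopIfNot(reps >= 2, "reps must be >= 2")
  stopIfNot(nEdges >= 1 && nEdges <= nNodes * (nNodes - 1) / 2,
            "infeasible edge count for %d nodes", nNodes)
  graphs <- withSeed(seed, {
    lapply(seq_len(reps), function(i) {
      if (method == "gnm") {
        igraph::sample_gnm(nNodes, nEdges, directed = FALSE)
      } else {
        stopIfNot(!is.null(refGraph), "degree-preserving rewiring needs refGraph")
        igraph::rewire(refGraph,
                       igraph::keeping_degseq(niter = 10 * nEdges))
      }
    })
  })
  metrics <- t(vapply(graphs, function(g) c(
    GD = harmonicGeodesic(g),
    avgCC = avgClustering(g),
    modularity = detectModules(g)$Q
  ), numeric(3)))
  stats <- data.frame(
    metric = colnames(metrics),
    mean = colMeans(metrics),
    sd = apply(metrics, 2L, stats::sd),
    row.names = colnames(metrics)
  )
  structure(
    list(stats = stats, metrics = as.data.frame(metrics),
         graphs = if (keepGraphs) graphs else NULL,
         nNodes = nNodes, nEdges = nEdges, reps = reps, seed = seed,
         method = method),
    class = "RandomEnsemble"
  )
}

#' @export
print.RandomEnsemble <- function(x, ...) {
  cat(sprintf("RandomEnsemble (%s): %d replicates of G(%d, %d)\n",
              x$method, x$reps, x$nNodes, x$nEdges))
  print(x$stats, row.names = FALSE)
  invisible(x)
}

#' Compare an empirical topology summary to a random ensemble
#'
#' Per-metric z-score \eqn{(x - \bar{x}_{rand}) / SD_{rand}} and a
#' two-sided empirical p from the ensemble rank (with the usual +1
#' correction, so p is never below 1/(reps+1)). An SD of 0 with a
#' non-matching empirical value is reported as infinite z with p below the
#' ensemble resolution.
#'
#' @param empirical one-row data.frame from \code{\link{summarizeTopology}}
#' @param ens a \code{RandomEnsemble} of matching node/edge counts
#' @return data.frame with metric, empirical, randomMean, randomSD, z, p,
#'   direction
#' @export
compareToRandom <- function(empirical, ens) {
  stopIfNot(empirical$nNodes == ens$nNodes &&
              empirical$nEdges == ens$nEdges,
            "ensemble size does not match empirical network")
  mets <- c("GD", "avgCC", "modularity")
  out <- lapply(mets, function(mt) {
    x <- empirical[[mt]]
    v <- ens$metrics[[mt]]
    mu <- mean(v)
    sd <- stats::sd(v)
    z <- if (sd > 0) (x - mu) / sd else if (x == mu) 0 else Inf * sign(x - mu)
    pUp <- (sum(v >= x) + 1) / (ens$reps + 1)
    pDn <- (sum(v <= x) + 1) / (ens$reps + 1)
    data.frame(metric = mt, empirical = x, randomMean = mu, randomSD = sd,
               z = z, p = min(1, 2 * min(pUp, pDn)),
               direction = if (x >= mu) "above" else "below")
  })
  do.call(rbind, out)
}

#' Edge effect sizes between taxon groups
#'
#' For every unordered pair of taxon groups (phyla or classes, including
#' within-group pairs), the observed number of network edges joining them is
#' compared with the distribution of such counts over the random ensemble
#' (same node labels, edge positions randomised): effect size =
#' (observed - random mean) / random SD. Values above 2 flag group pairs
#' that interact more than randomly expected. The sign channel restricts the
#' observed edges to positive or negative associations; the ensemble is then
#' matched to that channel's edge count.
#'
#' @param net an AssociationNetwork
#' @param grouping named character vector, taxon -> group (e.g. a taxonomy
#'   rank); must cover all network nodes
#' @param ens optional \code{RandomEnsemble} with \code{keepGraphs = TRUE}
#'   whose edge count matches the selected channel; generated internally
#'   when NULL
#' @param signChannel \code{"all"}, \code{"positive"} or \code{"negative"}
#' @param reps,seed ensemble parameters when generated internally
#' @return data.frame with group1, group2, observed, randomMean, randomSD,
#'   effectSize, significant
#' @export
groupEffectSizes <- function(net, grouping, ens = NULL,
                             signChannel = c("all", "positive", "negative"),
                             reps = 100L, seed = NULL) {
  signChannel <- match.arg(signChannel)
  g <- networkGraph(net)
  nm <- igraph::V(g)$name
  stopIfNot(all(nm %in% names(grouping)),
            "grouping must cover every network node")
  grp <- as.character(grouping[nm])
  empty <- setdiff(unique(grouping), grp)
  if (length(empty))
    warning(sprintf("group(s) with no network nodes skipped: %s",
                    paste(empty, collapse = ", ")))
  et <- edgeTable(net)
  if (signChannel != "all") et <- et[et$sign == signChannel, , drop = FALSE]
  m <- nrow(et)
  stopIfNot(m >= 1, "no edges in the selected sign channel")
  if (is.null(ens)) {
    ens <- randomEnsemble(length(nm), m, reps = reps, seed = seed,
                          keepGraphs = TRUE)
  }
  stopIfNot(!is.null(ens$graphs), "ensemble must keep its graphs")
  stopIfNot(ens$nNodes == length(nm) && ens$nEdges == m,
            "ensemble size must match the network/channel (%d nodes, %d edges)",
            length(nm), m)
  pairKey <- function(a, b) {
    lo <- pmin(a, b); hi <- pmax(a, b)
    paste(lo, hi, sep = "\t")
  }
  groups <- sort(unique(grp))
  keys <- outer(groups, groups, pairKey)
  allKeys <- unique(keys[upper.tri(keys, diag = TRUE)])
  names(grp) <- nm
  obs <- table(factor(pairKey(grp[et$taxon1], grp[et$taxon2]),
                      levels = allKeys))
  randCounts <- vapply(ens$graphs, function(rg) {
    el <- igraph::as_edgelist(rg, names = FALSE)
    as.vector(table(factor(pairKey(grp[el[, 1L]], grp[el[, 2L]]),
                           levels = allKeys)))
  }, numeric(length(allKeys)))
  randCounts <- matrix(randCounts, nrow = length(allKeys))
  mu <- rowMeans(randCounts)
  sd <- apply(randCounts, 1L, stats::sd)
  es <- ifelse(sd > 0, (as.numeric(obs) - mu) / sd, NA_real_)
  parts <- strsplit(allKeys, "\t", fixed = TRUE)
  data.frame(
    group1 = vapply(parts, `[`, "", 1L),
    group2 = vapply(parts, `[`, "", 2L),
    observed = as.numeric(obs), randomMean = mu, randomSD = sd,
    effectSize = es,
    significant = !is.na(es) & es > 2,
    stringsAsFactors = FALSE
  )
}
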