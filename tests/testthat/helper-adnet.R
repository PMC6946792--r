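# Shared fixtures, built in code.

edgeKey <- function(a, b) paste(pmin(a, b), pmax(a, b))

# Small abundance table with named taxa/samples.
toyTable <- function(values, kind = "count", taxonomy = NULL,
                     sampleData = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("OTU_", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  AbundanceExperiment(values, taxonomy = taxonomy, kind = kind,
                      sampleData = sampleData)
}

# CorrelationSet straight from matrices (for threshold/network unit tests).
toyCorrelationSet <- function(rho, q = NULL, p = NULL, nSamples = 12L) {
  if (is.null(rownames(rho))) {
    nm <- paste0("t", seq_len(nrow(rho)))
    dimnames(rho) <- list(nm, nm)
  }
  if (is.null(p)) { p <- rho * 0; diag(p) <- NA_real_ }
  if (is.null(q)) q <- p
  dimnames(p) <- dimnames(q) <- dimnames(rho)
  new("CorrelationSet", rho = rho, p = p, q = q,
      nSamples = as.integer(nSamples))
}

# AssociationNetwork from an edge data.frame (taxon1, taxon2, rho).
toyNetwork <- function(edges, taxonomy = NULL) {
  edges$sign <- ifelse(edges$rho > 0, "positive", "negative")
  if (is.null(edges$q)) edges$q <- 1e-4
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  net <- new("AssociationNetwork", graph = g)
  if (!is.null(taxonomy)) net <- annotateNetwork(net, taxonomy)
  net
}

# Independent shortest-path oracle (Floyd-Warshall on the adjacency matrix).
bruteDistances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj > 0] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

bruteGD <- function(adj) {
  d <- bruteDistances(adj)
  inv <- 1 / d[upper.tri(d)]
  inv[!is.finite(inv)] <- 0
  (nrow(adj) * (nrow(adj) - 1) / 2) / sum(inv)
}

bruteAvgCC <- function(adj) {
  n <- nrow(adj)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    cc[i] <- if (k < 2) 0 else
      sum(adj[nb, nb]) / (k * (k - 1))
  }
  mean(cc)
}

# Mantel statistic and exact permutation p by full enumeration (tiny n).
bruteMantel <- function(m1, m2) {
  v1 <- m1[lower.tri(m1)]
  r <- stats::cor(v1, m2[lower.tri(m2)])
  n <- nrow(m1)
  perms <- allPermutations(n)
  rs <- apply(perms, 1L, function(idx) {
    mp <- m2[idx, idx]
    stats::cor(v1, mp[lower.tri(mp)])
  })
  list(r = r, pExact = mean(rs >= r))
}

allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- allPermutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# Random symmetric zero-diagonal distance-like matrix.
randomDistanceMatrix <- function(n, seed) {
  withr::with_seed(seed, {
    pts <- matrix(stats::rnorm(n * 3), n)
    rownames(pts) <- paste0("t", seq_len(n))
    as.matrix(stats::dist(pts))
  })
}
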