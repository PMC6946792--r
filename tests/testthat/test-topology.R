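triangle <- function() toyNetwork(data.frame(
  taxon1 = c("a", "b", "c"), taxon2 = c("b", "c", "a"), rho = 0.9))

test_that("closed-form topology on canonical small graphs", {
  s <- summarizeTopology(triangle())
  expect_equal(s$avgK, 2)
  expect_equal(s$avgCC, 1)
  expect_equal(s$GD, 1)
  expect_equal(s$pctPositive, 100)

  star <- toyNetwork(data.frame(taxon1 = "hub",
                                taxon2 = c("l1", "l2", "l3"), rho = 0.9))
  ss <- summarizeTopology(star)
  expect_equal(ss$avgK, 1.5)
  expect_equal(ss$avgCC, 0)

  # two disjoint edges: 6 pairs, unreachable contribute zero reciprocal
  two <- toyNetwork(data.frame(taxon1 = c("a", "c"), taxon2 = c("b", "d"),
                               rho = 0.9))
  expect_equal(harmonicGeodesic(two), 3)

  path <- toyNetwork(data.frame(taxon1 = c("a", "b"), taxon2 = c("b", "c"),
                                rho = 0.9))
  expect_equal(harmonicGeodesic(path), 3 / (1 + 1 + 0.5))

  for (n in c(4, 7)) {
    expect_equal(harmonicGeodesic(igraph::make_full_graph(n)), 1)
  }
  expect_error(summarizeTopology(igraph::make_empty_graph(3,
                                                          directed = FALSE)))
})

test_that("GD and avgCC match a brute-force oracle on small graphs", {
  # exhaustive over all 64 labelled 4-node graphs with >= 1 edge
  pairs4 <- t(combn(4, 2))
  for (mask in 1:63) {
    sel <- which(bitwAnd(mask, 2^(0:5)) > 0)
    adj <- matrix(0, 4, 4)
    for (e in sel) { adj[pairs4[e, 1], pairs4[e, 2]] <- 1
                     adj[pairs4[e, 2], pairs4[e, 1]] <- 1 }
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    if (any(rowSums(adj) > 0) && sum(adj) > 0) {
      expect_equal(harmonicGeodesic(g), bruteGD(adj), tolerance = 1e-12)
      expect_equal(avgClustering(g), bruteAvgCC(adj), tolerance = 1e-12)
    }
  }
  # random 8-node graphs
  withr::with_seed(21, {
    for (i in 1:40) {
      g <- igraph::sample_gnp(8, 0.35)
      if (igraph::ecount(g) == 0) next
      adj <- as.matrix(igraph::as_adjacency_matrix(g))
      expect_equal(harmonicGeodesic(g), bruteGD(adj), tolerance = 1e-12)
      expect_equal(avgClustering(g), bruteAvgCC(adj), tolerance = 1e-12)
      expect_equal(summarizeTopology(g)$avgK,
                   2 * igraph::ecount(g) / igraph::vcount(g))
    }
  })
})

test_that("module detection recovers obvious and planted partitions", {
  two <- toyNetwork(data.frame(
    taxon1 = c("a", "b", "c", "x", "y", "z"),
    taxon2 = c("b", "c", "a", "y", "z", "x"), rho = 0.9))
  mod <- detectModules(two)
  expect_equal(mod$nModules, 2L)
  expect_equal(mod$Q, 0.5)  # 2 * (0.5 - 0.25) on the obvious partition

  k5 <- igraph::make_full_graph(5)
  m5 <- detectModules(k5)
  expect_equal(m5$nModules, 1L)
  expect_lt(abs(m5$Q), 1e-9)

  # planted 3-block graph: adjusted-Rand-style exact recovery
  withr::with_seed(4, {
    g <- igraph::sample_sbm(60, pref.matrix = diag(3) * 0.75 + 0.02,
                            block.sizes = rep(20, 3))
    igraph::V(g)$name <- paste0("v", 1:60)
    mem <- detectModules(g)$membership
    truth <- rep(1:3, each = 20)
    # contingency: every detected module maps to one planted block
    tab <- table(mem, truth)
    expect_gte(sum(apply(tab, 1, max)) / 60, 0.95)
  })
})

test_that("modularity never decreases from the planted partition", {
  withr::with_seed(8, {
    for (i in 1:5) {
      g <- igraph::sample_sbm(45, pref.matrix = diag(3) * 0.6 + 0.03,
                              block.sizes = rep(15, 3))
      planted <- rep(1:3, each = 15)
      qPlanted <- igraph::modularity(g, planted)
      expect_gte(detectModules(g, initial = planted)$Q, qPlanted - 1e-9)
    }
  })
})

test_that("power-law fit is exact on exact log-linear histograms", {
  # degree histogram exactly proportional to k^-2: 36/k^2 over k in
  # {1, 2, 3, 6}, realised as an actual graph... needs >= 5 distinct
  # degrees, so extend with k = 12 (36/144 = 0.25 -> use C = 144)
  counts <- c(144, 36, 16, 9, 4, 1)       # 144 / k^2 at k = 1,2,3,4,6,12
  ks <- c(1, 2, 3, 4, 6, 12)
  degs <- rep(ks, counts)
  if (sum(degs) %% 2 == 1) degs <- c(degs, 1)
  g <- igraph::realize_degseq(degs, method = "smallest")
  pl <- powerlawFit(g)
  expect_equal(pl$R2, 1, tolerance = 1e-9)
  expect_equal(pl$slope, -2, tolerance = 1e-9)
  expect_lt(pl$p, 0.01)
  reg <- igraph::make_ring(10)
  expect_error(powerlawFit(reg), "distinct degree")
  withr::with_seed(3, {
    ba <- igraph::sample_pa(300, m = 3, directed = FALSE)
    pl <- powerlawFit(ba)
    expect_gt(pl$R2, 0.5)
    expect_lt(pl$slope, 0)
    er <- igraph::sample_gnm(500, 1500)
    expect_lt(powerlawFit(er)$R2, 0.95)  # Poisson degrees, not scale-free
  })
})

test_that("Zi-Pi node roles follow the formulas", {
  # module 1: star on a..e (hub 'a'); module 2: pair f-g; bridge a-f
  net <- toyNetwork(data.frame(
    taxon1 = c("a", "a", "a", "a", "f", "a"),
    taxon2 = c("b", "c", "d", "e", "g", "f"), rho = 0.9))
  mem <- c(a = 1, b = 1, c = 1, d = 1, e = 1, f = 2, g = 2)
  roles <- nodeRoles(net, mem, zHub = 1.5)
  rr <- function(n) roles[roles$node == n, ]
  expect_equal(rr("b")$P, 0)                       # all edges inside module
  expect_equal(rr("a")$P, 1 - (4 / 5)^2 - (1 / 5)^2)
  expect_gt(rr("a")$z, 1.5)
  expect_equal(rr("a")$role, "module hub")
  # equal within-degree module: all z = 0
  expect_equal(rr("f")$z, 0)
  expect_equal(rr("g")$z, 0)
  # degree-4 node split evenly across 2 modules has P = 0.5
  net2 <- toyNetwork(data.frame(
    taxon1 = c("x", "x", "x", "x", "p", "r"),
    taxon2 = c("p", "q", "r", "s", "q", "s"), rho = 0.9))
  mem2 <- c(x = 1, p = 1, q = 1, r = 2, s = 2)
  roles2 <- nodeRoles(net2, mem2)
  expect_equal(roles2[roles2$node == "x", "P"], 0.5)
})

test_that("per-sample subnetworks are induced subgraphs on present taxa", {
  net <- toyNetwork(data.frame(
    taxon1 = c("a", "b", "c", "d"), taxon2 = c("b", "c", "a", "e"),
    rho = 0.9))
  m <- matrix(c(1, 1, 1, 1, 1,
                1, 1, 1, 0, 0,
                0, 0, 0, 0, 0), 5, 3,
              dimnames = list(c("a", "b", "c", "d", "e"),
                              c("all", "tri", "none")))
  subs <- suppressWarnings(perSampleSubnetworks(net, toyTable(m)))
  expect_equal(nEdges(subs$all), nEdges(net))
  expect_equal(nEdges(subs$tri), 3L)  # exactly the a-b-c triangle
  expect_equal(nNodes(subs$none), 0L)
  expect_warning(perSampleSubnetworks(net, toyTable(m), "none"),
                 "no network taxa")
  expect_error(perSampleSubnetworks(net, toyTable(m), "missing"), "absent")
})

test_that("topology-parameter correlations recover exact monotone links", {
  withr::local_seed(6)
  n <- 12
  su <- data.frame(nEdges = 1:n, GD = runif(n), flat = rep(1, n))
  rownames(su) <- paste0("s", 1:n)
  meta <- data.frame(vs_load = 2 * (1:n) + 3,
                     ph = rank(-su$GD) + rnorm(n, 0, 1e-9),
                     day = 1:n)
  rownames(meta) <- rownames(su)
  res <- topologyVsParameters(su, meta)
  pick <- function(pr, pa) res[res$property == pr & res$parameter == pa, ]
  expect_equal(pick("nEdges", "vs_load")$rho, 1)
  expect_true(pick("nEdges", "vs_load")$significant)
  expect_equal(pick("GD", "ph")$rho, -1)
  expect_true(is.na(pick("flat", "vs_load")$rho))     # constant masked
  expect_false(pick("flat", "vs_load")$significant)
})
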