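test_that("gene significance is squared Pearson correlation", {
  withr::local_seed(14)
  n <- 12
  par <- rnorm(n)
  orth <- residuals(lm(rnorm(n) ~ par))
  half <- 0.5 * scale(par)[, 1] + sqrt(0.75) * scale(orth)[, 1]
  m <- rbind(same = par, half = half, const = rep(3, n),
             noise = rnorm(n))
  m <- m - min(m) + 1
  m["const", ] <- 3
  colnames(m) <- paste0("s", 1:n)
  gs <- geneSignificance(toyTable(m, kind = "signal"), par)
  expect_equal(unname(gs["same"]), 1, tolerance = 1e-9)
  expect_equal(unname(gs["half"]), 0.25, tolerance = 1e-9)  # r = 0.5
  expect_true(is.na(gs["const"]))
  # invariant under affine rescaling of the parameter
  gs2 <- geneSignificance(toyTable(m, kind = "signal"), 3 - 7 * par)
  expect_equal(gs, gs2, tolerance = 1e-9)
})

test_that("GS distances follow Euclidean geometry on GS rows", {
  gs <- rbind(a = c(1, 0, 0), b = c(0, 1, 0), c = c(1, 0, 0),
              d = c(NA, 1, 1))
  expect_warning(d <- gsDistance(gs), "dropped")
  dm <- as.matrix(d)
  expect_equal(dm["a", "c"], 0)
  expect_equal(dm["a", "b"], sqrt(2))
  expect_error(gsDistance(gs[1:2, ]), ">= 3 taxa")
})

test_that("connectivity distances use overall-network degrees", {
  net <- toyNetwork(data.frame(
    taxon1 = c("h", "h", "h", "a", "a", "b"),
    taxon2 = c("a", "b", "c", "b", "c", "c"), rho = 0.9))
  # degrees: h = 3, a = b = c = 3 in K4; rewire to make them differ
  net2 <- toyNetwork(data.frame(
    taxon1 = c("h", "h", "h", "x"), taxon2 = c("a", "b", "c", "a"),
    rho = 0.9))
  d <- as.matrix(connectivityDistance(net2))
  expect_equal(d["a", "b"], 1)     # degrees 2 and 1
  expect_equal(d["b", "c"], 0)     # equal degrees
  expect_equal(d["h", "x"], 2)     # 3 vs 1
  # a subset keeps degrees from the overall network
  ds <- as.matrix(connectivityDistance(net2, c("h", "a", "b")))
  expect_equal(ds["h", "b"], 2)
  expect_error(connectivityDistance(net2, c("h", "zz")), "not in network")
})

test_that("Mantel statistic matches brute-force enumeration on tiny matrices", {
  for (seed in c(2, 9)) {
    d1 <- randomDistanceMatrix(5, seed)
    d2 <- randomDistanceMatrix(5, seed + 100)
    bf <- bruteMantel(d1, d2)
    res <- mantelTest(d1, d2, nPermutations = 2000, seed = 1)
    expect_equal(res$r, bf$r, tolerance = 1e-12)
    # sampled permutation p agrees with the exact enumeration p
    expect_lt(abs(res$p - bf$pExact), 3 * sqrt(bf$pExact / 2000) + 0.01)
  }
})

test_that("Mantel test agrees with vegan and is reflexive", {
  d1 <- randomDistanceMatrix(12, 5)
  d2 <- randomDistanceMatrix(12, 6)
  res <- mantelTest(d1, d2, nPermutations = 999, seed = 3)
  veg <- vegan::mantel(as.dist(d1), as.dist(d2), permutations = 999)
  expect_equal(res$r, unname(veg$statistic), tolerance = 1e-9)
  expect_lt(abs(res$p - veg$signif), 0.06)
  # d2 = d1: perfect correlation at the permutation floor
  self <- mantelTest(d1, d1, nPermutations = 999, seed = 4)
  expect_equal(self$r, 1)
  expect_equal(self$p, 1 / 1000)
  expect_error(mantelTest(d1, randomDistanceMatrix(5, 1)), "differ in size")
})

test_that("partial Mantel removes control structure", {
  withr::local_seed(10)
  dc <- randomDistanceMatrix(30, 31)
  # d2 (near-)linear in the control: partialling the control out leaves only
  # the small independent residual, so the partial statistic sits at the
  # null (its scale is ~ 1/sqrt(n pairs))
  d2 <- 2 * dc + 5 + 1e-4 * randomDistanceMatrix(30, 33)
  diag(d2) <- 0
  d1 <- randomDistanceMatrix(30, 32)
  resLin <- partialMantelTest(d1, d2, dc, nPermutations = 499, seed = 1)
  expect_lt(abs(resLin$r), 3 / sqrt(choose(30, 2)))
  expect_gt(resLin$p, 0.05)
  # d1 = d2 with an independent control: partial r near 1
  resSelf <- partialMantelTest(d1, d1, dc, nPermutations = 499, seed = 2)
  expect_gt(resSelf$r, 0.95)
  expect_equal(resSelf$p, 1 / 500)
  # independent control: partial ~ plain (within 0.05 across seeds)
  diffs <- vapply(1:10, function(s) {
    a <- randomDistanceMatrix(16, 500 + s)
    b <- randomDistanceMatrix(16, 600 + s)
    cc <- randomDistanceMatrix(16, 700 + s)
    abs(partialMantelTest(a, b, cc, nPermutations = 99, seed = s)$r -
          mantelTest(a, b, nPermutations = 99, seed = s)$r)
  }, numeric(1))
  expect_lt(median(diffs), 0.05)
  # statistic agrees with vegan's partial Mantel
  veg <- vegan::mantel.partial(as.dist(d1), as.dist(d2 + dc),
                               as.dist(dc), permutations = 99)
  ours <- partialMantelTest(d1, d2 + dc, dc, nPermutations = 99, seed = 3)
  expect_equal(ours$r, unname(veg$statistic), tolerance = 1e-9)
  # constant control falls back to the plain test
  dcConst <- matrix(1, 30, 30); diag(dcConst) <- 0
  dimnames(dcConst) <- dimnames(as.matrix(d1))
  expect_warning(fb <- partialMantelTest(d1, d2, dcConst,
                                         nPermutations = 99, seed = 5),
                 "constant control")
  expect_equal(fb$r, mantelTest(d1, d2, nPermutations = 99, seed = 5)$r)
})

test_that("the connectivity Mantel table skips tiny subsets and finds drivers", {
  com <- generateCommunity(seed = 17)
  meta <- generateMetadata(com$table, com$truth, beta = 1, seed = 18)
  filt <- suppressMessages(prevalenceFilter(com$table, 9))
  cs <- spearmanAllPairs(filt)
  net <- buildNetwork(cs, 0.001, chosenCutoff(rmtThreshold(cs)),
                      taxonomy = taxonomyTable(filt))
  tab <- suppressWarnings(connectivityMantelTable(
    net, filt, meta, nPermutations = 499, seed = 19))
  expect_true(all(c("All", "Archaea", "Bacteria") %in% tab$subset))
  arch <- tab[tab$subset == "Archaea", ]
  expect_lt(arch$pPerf, 0.05)
  expect_lt(arch$pPartial, 0.05)
  # every analysed subset had at least 3 usable taxa
  done <- tab[tab$note == "", ]
  expect_true(all(done$n >= 3))
  skipped <- tab[tab$note != "", ]
  if (nrow(skipped)) expect_true(all(grepl("skipped", skipped$note)))
})
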