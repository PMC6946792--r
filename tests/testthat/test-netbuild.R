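test_that("prevalence filter keeps taxa in strictly more than minSamples", {
  withr::local_seed(2)
  n <- 66
  m <- matrix(rpois(5 * n, 5) + 1, 5, n,
              dimnames = list(paste0("t", 1:5), paste0("s", 1:n)))
  m[3, ] <- 0; m[3, 1:9] <- 1    # present in exactly 9 samples
  m[4, ] <- 0; m[4, 1:10] <- 1   # present in 10
  m[5, ] <- 0                    # never detected
  f <- prevalenceFilter(toyTable(m), minSamples = 9)
  kept <- rownames(abundances(f))
  expect_false("t3" %in% kept)   # strict inequality: 9 of 66 removed
  expect_true("t4" %in% kept)
  expect_false("t5" %in% kept)
  # fractional cutoff: 9/66 of the samples
  f2 <- prevalenceFilter(toyTable(m), minSamples = 9 / 66)
  expect_identical(rownames(abundances(f2)), kept)
  expect_error(prevalenceFilter(toyTable(m[3:5, ]), 9), "fewer than 2")
})

test_that("all-pairs Spearman handles monotone, antitone and constant taxa", {
  m <- rbind(x = c(1, 2, 3, 4), y = c(2, 4, 6, 8),
             z = c(8, 6, 4, 2), w = c(5, 5, 5, 5))
  colnames(m) <- paste0("s", 1:4)
  expect_message(cs <- spearmanAllPairs(toyTable(m, kind = "signal")),
                 "constant")
  rho <- corRho(cs)
  expect_equal(rho["x", "y"], 1)
  expect_equal(rho["x", "z"], -1)
  expect_true(all(is.na(rho["w", c("x", "y", "z")])))
  expect_true(all(is.na(corQ(cs)["w", ])))
  expect_true(isSymmetric(unname(rho)))
  expect_error(spearmanAllPairs(toyTable(m[, 1:3], kind = "signal")),
               "4 samples")
})

test_that("Spearman p-values agree with cor.test and q dominates p", {
  withr::local_seed(5)
  m <- matrix(rpois(8 * 20, 10), 8, 20,
              dimnames = list(paste0("t", 1:8), paste0("s", 1:20)))
  cs <- spearmanAllPairs(toyTable(m))
  ct <- suppressWarnings(
    cor.test(m[1, ], m[2, ], method = "spearman", exact = FALSE))
  expect_equal(corRho(cs)[1, 2], unname(ct$estimate), tolerance = 1e-9)
  expect_equal(corP(cs)[1, 2], ct$p.value, tolerance = 1e-9)
  ut <- upper.tri(corP(cs))
  expect_true(all(corQ(cs)[ut] >= corP(cs)[ut] - 1e-12))
})

test_that("BH adjustment reproduces the step-up formula", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.04), 0.04)
  expect_equal(bhAdjust(c(1, 1)), c(1, 1))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # independent oracle: direct evaluation of q_(i) = min_{j>=i} m p_(j) / j
  withr::local_seed(9)
  p <- runif(40)
  o <- order(p)
  qSorted <- rev(cummin(rev(length(p) * p[o] / seq_along(p))))
  qHand <- numeric(length(p)); qHand[o] <- pmin(qSorted, 1)
  expect_equal(bhAdjust(p), qHand)
})

test_that("FDR holds at the null on column-shuffled tables", {
  withr::local_seed(31)
  hits <- 0; pairs <- 0
  for (i in 1:3) {
    m <- matrix(sample(rpois(40 * 30, 8)), 40, 30,
                dimnames = list(paste0("t", 1:40), paste0("s", 1:30)))
    cs <- spearmanAllPairs(toyTable(m))
    q <- corQ(cs)[upper.tri(corQ(cs))]
    hits <- hits + sum(q <= 0.001, na.rm = TRUE)
    pairs <- pairs + sum(!is.na(q))
  }
  expect_lte(hits / pairs, 0.001 + 3 * sqrt(0.001 / pairs))
})

test_that("RMT scan picks the uncorrelated limit for a diagonal matrix", {
  id <- diag(60)
  scan <- rmtThreshold(toyCorrelationSet(id), scanStart = 0.30)
  expect_equal(chosenCutoff(scan), 0.30)
  # deterministic: identical scan on a second run
  scan2 <- rmtThreshold(toyCorrelationSet(id), scanStart = 0.30)
  expect_identical(scanTable(scan), scanTable(scan2))
})

test_that("RMT scan separates planted modules from dense noise", {
  withr::local_seed(13)
  ns <- 12; nt <- 90
  x <- matrix(rnorm(nt * ns), nt, ns)
  for (b in 0:2) {
    f <- rnorm(ns); idx <- b * 15 + 1:15
    x[idx, ] <- sqrt(0.92) * matrix(f, 15, ns, byrow = TRUE) +
      sqrt(0.08) * x[idx, ]
  }
  rho <- cor(t(x), method = "spearman")
  mods <- rep(c(1:3, 0, 0, 0), each = 15)
  bg <- abs(rho[upper.tri(rho) & outer(mods, mods, "!=")])
  scan <- rmtThreshold(toyCorrelationSet(rho))
  cut <- chosenCutoff(scan)
  expect_gt(cut, median(bg))   # above the noise bulk
  expect_lt(cut, 0.9)          # below the planted correlation
  # rerunning the scan reproduces the same cutoff (deterministic)
  expect_equal(chosenCutoff(rmtThreshold(toyCorrelationSet(rho))), cut)
  # a scan capped below the Poisson transition errors out
  expect_error(rmtThreshold(toyCorrelationSet(rho), scanStart = 0.05,
                            scanEnd = 0.10),
               "widen the scan")
})

test_that("network construction applies both cutoffs and drops isolates", {
  rho <- diag(4)
  rho[1, 2] <- rho[2, 1] <- 0.90
  rho[1, 3] <- rho[3, 1] <- -0.87
  rho[2, 4] <- rho[4, 2] <- 0.85   # below the rho cutoff
  q <- matrix(1, 4, 4)
  q[1, 2] <- q[2, 1] <- 5e-4
  q[1, 3] <- q[3, 1] <- 5e-4
  q[2, 4] <- q[4, 2] <- 1e-4
  cs <- toyCorrelationSet(rho, q = q)
  net <- buildNetwork(cs, qCutoff = 0.001, rhoCutoff = 0.86)
  et <- edgeTable(net)
  expect_equal(nEdges(net), 2L)
  expect_setequal(et$sign, c("positive", "negative"))
  expect_equal(et$sign[et$taxon2 == "t3" | et$taxon1 == "t3"], "negative")
  expect_false("t4" %in% igraph::V(networkGraph(net))$name)  # isolated
})

test_that("edge counts match a brute-force double loop", {
  withr::local_seed(77)
  n <- 30
  rho <- cor(matrix(rnorm(15 * n), 15, n), method = "spearman")
  q <- matrix(runif(n * n, 0, 0.01), n, n)
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  cs <- toyCorrelationSet(rho, q = q)
  for (rc in c(0.3, 0.5, 0.7)) {
    net <- buildNetwork(cs, qCutoff = 0.005, rhoCutoff = rc)
    cnt <- 0L
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (!is.na(q[i, j]) && q[i, j] <= 0.005 && abs(rho[i, j]) >= rc)
        cnt <- cnt + 1L
    expect_equal(nEdges(net), cnt)
  }
})
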