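test_that("the sampling design is 2 groups x 3 digesters x 11 days", {
  com <- generateCommunity(seed = 1)
  cd <- as.data.frame(SummarizedExperiment::colData(com$table))
  expect_equal(nrow(cd), 66L)
  expect_equal(length(unique(cd$digester_id)), 6L)
  expect_equal(length(unique(cd$day)), 11L)
  expect_equal(as.vector(table(cd$phase_group)[c("C 45-76", "T 45-76",
                                                 "C 80-97", "T 80-97")]),
               c(18L, 18L, 15L, 15L))
  expect_equal(unname(colSums(abundances(com$table))), rep(11558, 66))
})

test_that("identical seeds reproduce the community exactly", {
  a <- generateCommunity(seed = 42)
  b <- generateCommunity(seed = 42)
  expect_identical(abundances(a$table), abundances(b$table))
  expect_identical(plantedEdges(a$truth), plantedEdges(b$truth))
  c <- generateCommunity(seed = 43)
  expect_false(identical(abundances(a$table), abundances(c$table)))
})

test_that("planted modules carry the requested correlation structure", {
  wiMed <- btMax <- numeric(3)
  for (i in 1:3) {
    com <- generateCommunity(withinModuleRho = 0.9, noiseSD = 0.1,
                             nGroupSpecific = 0L, seed = 30 + i)
    m <- abundances(com$table)
    mod <- moduleAssignments(com$truth)
    rho <- suppressWarnings(cor(t(m), method = "spearman"))
    ut <- upper.tri(rho)
    same <- outer(mod, mod, "==") & outer(mod != "background",
                                          mod != "background", "&")
    diffMod <- outer(mod != "background", mod != "background", "&") & !same
    wiMed[i] <- median(rho[ut & same])
    btMax[i] <- median(abs(rho[ut & diffMod]))
  }
  expect_true(all(wiMed >= 0.7))   # within planted modules
  expect_true(all(btMax <= 0.2))   # between modules
})

test_that("rho = 0 leaves planted and background indistinguishable", {
  com <- generateCommunity(withinModuleRho = 0, seed = 77)
  expect_equal(nrow(plantedEdges(com$truth)), 0L)
  m <- abundances(com$table)
  keep <- rowSums(m > 0) > 9
  rho <- cor(t(m[keep, ]), method = "spearman")
  frac <- mean(abs(rho[upper.tri(rho)]) >= 0.86)
  expect_lt(frac, 1e-3)  # no pair reaches the strong-correlation regime
})

test_that("generated communities live in the diverse n_eff regime", {
  ne <- unlist(lapply(1:3, function(s)
    inverseSimpson(generateCommunity(seed = s)$table)))
  expect_gt(median(ne), 30)
  expect_gt(quantile(ne, 0.05), 20)
})

test_that("metadata construction follows the OLR design and beta limits", {
  com <- generateCommunity(seed = 50)
  # beta large, noise -> 0: driver GS approaches 1
  meta <- generateMetadata(com$table, com$truth, beta = 5, noiseSD = 1e-6,
                           seed = 51)
  drv <- driverTaxa(com$truth)
  la <- log1p(abundances(com$table)[drv, ])
  score <- colMeans(t(scale(t(la))))
  expect_gt(cor(score, meta$biogas)^2, 0.999)
  # control VS load flat, treatment stepped
  ctl <- meta[meta$group == "control", ]
  trt <- meta[meta$group == "treatment", ]
  expect_lt(sd(ctl$vs_load), 0.08)
  expect_gt(mean(trt$vs_load[trt$day >= 80]) -
              mean(trt$vs_load[trt$day <= 76]), 0.1)
  expect_gt(mean(trt$vs_load) - mean(ctl$vs_load), 0.2)
  # beta = 0: GS of all taxa sits at the null, mean ~ 1/(n-1)
  meta0 <- generateMetadata(com$table, com$truth, beta = 0, seed = 52)
  gs <- geneSignificance(com$table, structure(meta0$biogas,
                                              names = meta0$sample_id))
  expect_lt(abs(mean(gs, na.rm = TRUE) - 1 / 65), 3 * 0.02 / sqrt(150) + 0.01)
})

test_that("synthetic data sets round-trip through the on-disk interface", {
  dir <- withr::local_tempdir()
  com <- generateCommunity(nTaxa = 40L, moduleSize = c(6L, 3L, 5L, 5L),
                           seed = 9)
  meta <- generateMetadata(com$table, com$truth, seed = 10)
  paths <- writeSyntheticData(com, meta, dir)
  expect_true(all(file.exists(paths)))
  back <- readAbundanceTable(paths["abundance"], kind = "count")
  expect_equal(abundances(back), abundances(com$table))
  truth <- jsonlite::read_json(paths["truth"])
  expect_equal(length(truth$driverTaxa), length(driverTaxa(com$truth)))
})
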