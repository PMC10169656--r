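# Differential statistics against closed-form oracles, FDR contracts,
# replicate QC, set comparison and clustering.

test_that("identical groups give t = 0, p = 1 and zero fold change", {
  om <- tinyOmics("F1", control = 2, treated = 2)
  mat <- SummarizedExperiment::assay(om)
  mat["F1", ] <- c(1, 2, 3, 1, 2, 3)
  om2 <- omicsFromMatrix(mat)
  dt <- differentialStats(om2)
  expect_identical(dt$log2fc, 0)
  expect_identical(dt$t_stat, 0)
  expect_identical(dt$p_value, 1)
})

test_that("t statistic matches the textbook pooled-variance formula", {
  mat <- rbind(F1 = c(10.0, 10.2, 10.4, 11.0, 11.2, 11.4))
  colnames(mat) <- c(paste0("g_control_r", 1:3), paste0("g_treated_r", 1:3))
  dt <- differentialStats(omicsFromMatrix(mat))
  or <- oracleT(c(11.0, 11.2, 11.4), c(10.0, 10.2, 10.4))
  expect_equal(dt$log2fc, 1.0, tolerance = 1e-12)
  expect_equal(dt$t_stat, or$t, tolerance = 1e-12)      # ~6.1237
  expect_identical(dt$df, 4)
  expect_equal(dt$p_value, or$p, tolerance = 1e-12)
})

test_that("t, df and BH match independent computation on random instances", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(3:6, 1)
    x <- rnorm(n); y <- rnorm(n)
    mat <- rbind(F1 = c(y, x))
    colnames(mat) <- c(paste0("g_control_r", 1:n), paste0("g_treated_r", 1:n))
    dt <- differentialStats(omicsFromMatrix(mat))
    or <- oracleT(x, y)
    expect_equal(dt$t_stat, or$t, tolerance = 1e-10)
    expect_equal(dt$df, or$df, tolerance = 1e-10)
    expect_equal(dt$p_value, or$p, tolerance = 1e-10)
  }
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))
    expect_equal(bhAdjust(p), oracleBH(p), tolerance = 1e-10)
  }
})

test_that("bhAdjust honours its boundary contracts", {
  expect_identical(bhAdjust(0.05), 0.05)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4),
               tolerance = 1e-12)
  expect_identical(bhAdjust(rep(1, 5)), rep(1, 5))
  p <- runif(50)
  expect_true(all(bhAdjust(p) >= p))
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
  expect_error(bhAdjust(c(0.5, -0.1)), "0, 1")
})

test_that("significance flag follows the configured FDR threshold", {
  ex <- simulateStudy(nNodes = 40, nRegulators = 10, nActive = 3,
                      genotypes = "ITD-JMD", seed = 23)
  dt <- differentialStats(ex@phospho, fdrThreshold = 0.1)
  expect_identical(dt$significant, dt$fdr < 0.1)
  dt2 <- differentialStats(ex@phospho, fdrThreshold = 0.02)
  expect_identical(dt2$significant, dt2$fdr < 0.02)
  expect_error(differentialStats(ex@phospho, treated = "nope"), "nope")
})

test_that("class-I filter removes low-localization sites first", {
  mat <- matrix(rnorm(24, 20), 4, 6,
                dimnames = list(c("A_S1", "B_S2", "C_S3", "D_S4"),
                                c(paste0("g_control_r", 1:3),
                                  paste0("g_treated_r", 1:3))))
  om <- omicsFromMatrix(mat, kind = "phospho",
                        locProb = c(0.9, 0.5, NA, 0.74))
  dt <- differentialStats(om)
  expect_setequal(dt$feature, c("A_S1", "C_S3"))  # NA loc kept, <0.75 dropped
  expect_true(all(c("B_S2", "D_S4") %in% attr(dt, "excluded")))
})

test_that("features with fewer than two complete values per group drop out", {
  mat <- matrix(rnorm(12, 20), 2, 6,
                dimnames = list(c("KEEP", "DROP"),
                                c(paste0("g_control_r", 1:3),
                                  paste0("g_treated_r", 1:3))))
  mat["DROP", c(1, 2)] <- NA
  dt <- differentialStats(omicsFromMatrix(mat))
  expect_identical(dt$feature, "KEEP")
  expect_identical(attr(dt, "excluded"), "DROP")
})

test_that("statistics are invariant to sample order", {
  ex <- simulateStudy(nNodes = 25, nRegulators = 6, nActive = 2,
                      genotypes = "ITD-JMD", seed = 29)
  dt1 <- differentialStats(ex@proteome)
  set.seed(1); perm <- sample(ncol(ex@proteome))
  dt2 <- differentialStats(ex@proteome[, perm])
  expect_equal(dt1, dt2, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("type-I error is controlled under the global null", {
  pn <- generatePriorNetwork(5, seed = 31)
  empty <- RegulonSet(data.frame(regulator = character(), class = character(),
                                 target = character(), sign = numeric()))
  truth <- GroundTruth(data.frame(genotype = character(),
                                  regulator = character(),
                                  activity = numeric()))
  ex <- simulateExperiment(pn, empty,
                           data.frame(protein = character(),
                                      site = character(), effect = numeric()),
                           truth, nBackgroundSites = 10000,
                           locProbLowFraction = 0, genotypes = "ITD-JMD",
                           seed = 37)
  dt <- differentialStats(ex@phospho)
  frac <- mean(dt$p_value < 0.05)
  expect_gt(frac, 0.03); expect_lt(frac, 0.07)
})

test_that("replicate correlation matches the covariance formula", {
  om <- tinyOmics(c("a", "b", "c"), control = c(1, 2, 3), treated = c(2, 4, 6),
                  nrep = 2)
  rc <- replicateCorrelation(om)
  expect_equal(diag(rc$correlation), rep(1, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  # perfectly linear columns correlate at 1
  expect_equal(rc$correlation["ITD-JMD_control_r1", "ITD-JMD_treated_r1"], 1,
               tolerance = 1e-12)
  set.seed(41)
  mat <- matrix(rnorm(12), 3, 4,
                dimnames = list(c("x", "y", "z"),
                                c(paste0("g_control_r", 1:2),
                                  paste0("g_treated_r", 1:2))))
  rc2 <- suppressWarnings(replicateCorrelation(omicsFromMatrix(mat)))
  for (i in 1:3) for (j in 1:4) {
    a <- mat[, i]; b <- mat[, j]
    direct <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(rc2$correlation[i, j], direct, tolerance = 1e-12)
  }
  # pairs with < 2 overlapping values are undefined
  mat2 <- mat
  mat2[c(1, 2), 1] <- NA; mat2[3, 2] <- NA
  rc3 <- suppressWarnings(replicateCorrelation(omicsFromMatrix(mat2)))
  expect_true(is.na(rc3$correlation[1, 2]))
  # QC flags sub-floor replicate pairs
  expect_true(all(c("sample_a", "sample_b", "r", "below_floor") %in%
                    colnames(rc3$qc)))
})

test_that("significant-set comparison equals naive set arithmetic", {
  t1 <- diffStub(c("a", "b", "c"), significant = c(TRUE, TRUE, FALSE))
  t2 <- diffStub(c("a", "b", "c"), significant = c(TRUE, FALSE, TRUE))
  ov <- compareSignificantSets(list(JMD = t1, TKD = t2))
  expect_identical(ov$intersection, "a")
  expect_setequal(ov$union, c("a", "b", "c"))
  # identical sets: intersection = union
  ov2 <- compareSignificantSets(list(x = t1, y = t1))
  expect_identical(ov2$intersection, ov2$union)
  # disjoint sets
  t3 <- diffStub(c("a", "b"), significant = TRUE)
  t4 <- diffStub("c", significant = TRUE)
  ov3 <- compareSignificantSets(list(x = t3, y = t4))
  expect_identical(ov3$n_intersection, 0L)
  expect_identical(ov3$n_union, 3L)
  # random instances against brute-force set ops
  set.seed(43)
  for (i in 1:20) {
    f <- paste0("f", 1:30)
    s1 <- sample(c(TRUE, FALSE), 30, replace = TRUE)
    s2 <- sample(c(TRUE, FALSE), 30, replace = TRUE)
    ov <- compareSignificantSets(list(a = diffStub(f, significant = s1),
                                      b = diffStub(f, significant = s2)))
    expect_identical(ov$n_intersection, sum(s1 & s2))
    expect_identical(ov$n_union, sum(s1 | s2))
  }
})

test_that("hierarchical clustering recovers separable profile groups", {
  up <- c(1, 2, 3, 4, 5, 6)
  profiles <- rbind(a1 = up, a2 = 2 * up + 1, b1 = -up, b2 = -3 * up + 2)
  colnames(profiles) <- c(paste0("g_control_r", 1:3), paste0("g_treated_r", 1:3))
  ca <- clusterFeatures(profiles, k = 2)
  expect_identical(ca$cluster[ca$feature == "a1"],
                   ca$cluster[ca$feature == "a2"])
  expect_identical(ca$cluster[ca$feature == "b1"],
                   ca$cluster[ca$feature == "b2"])
  expect_false(ca$cluster[ca$feature == "a1"] == ca$cluster[ca$feature == "b1"])
  # k = 1 puts everything together; bad k errors
  expect_true(all(clusterFeatures(profiles, k = 1)$cluster == 1L))
  expect_error(clusterFeatures(profiles, k = 9), "k must")
  expect_error(clusterFeatures(profiles, k = 0), "k must")
  # deterministic: same input, same assignment; labels follow sorted order
  expect_identical(clusterFeatures(profiles, k = 2),
                   clusterFeatures(profiles[c(3, 1, 4, 2), ], k = 2))
})
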