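# Footprint scoring, the permutation null, phospho-score evidence and the
# combination policy.

kinRegulon <- function(targets, signs = 1, regulator = "K1",
                       class = "kinase") {
  RegulonSet(data.frame(regulator = regulator, class = class,
                        target = targets,
                        sign = rep(signs, length.out = length(targets))))
}

test_that("uniform evidence gives the mean signed t as score", {
  d <- diffStub(paste0("P", 1:6, "_S1"), t_stat = c(3, 3, 3, 0.1, -0.2, 0.3))
  rg <- kinRegulon(paste0("P", 1:3, "_S1"))
  at <- footprintActivity(d, rg, nPerm = 200, seed = 1)
  expect_equal(at$score, 3, tolerance = 1e-12)
  expect_identical(at$sign, 1)
  expect_identical(at$n_evidence, 3L)
})

test_that("flipping regulon signs negates every score", {
  set.seed(5)
  d <- diffStub(paste0("P", 1:20, "_S1"), t_stat = rnorm(20))
  rg1 <- RegulonSet(data.frame(regulator = rep(c("K1", "K2"), each = 4),
                               class = "kinase",
                               target = paste0("P", 1:8, "_S1"),
                               sign = c(1, -1, 1, 1, -1, -1, 1, -1)))
  e <- regulonTable(rg1); e$sign <- -e$sign
  rg2 <- RegulonSet(e)
  a1 <- footprintActivity(d, rg1, nPerm = 200, seed = 2)
  a2 <- footprintActivity(d, rg2, nPerm = 200, seed = 2)
  expect_equal(a2$score, -a1$score, tolerance = 1e-12)
  expect_identical(a2$sign, -a1$sign)
})

test_that("doubling every target statistic doubles every score", {
  set.seed(7)
  d <- diffStub(paste0("P", 1:30, "_S1"), t_stat = rnorm(30))
  rg <- RegulonSet(data.frame(regulator = rep(c("K1", "K2", "K3"), each = 5),
                              class = "kinase",
                              target = paste0("P", 1:15, "_S1"),
                              sign = sample(c(-1, 1), 15, replace = TRUE)))
  d2 <- d; d2$t_stat <- 2 * d$t_stat
  a1 <- footprintActivity(d, rg, nPerm = 200, seed = 3)
  a2 <- footprintActivity(d2, rg, nPerm = 200, seed = 3)
  expect_equal(a2$score, 2 * a1$score, tolerance = 1e-12)
})

test_that("permutation p matches exhaustive subset enumeration", {
  # 6 measured features, regulon of 3 uniform-sign targets: the null has
  # C(6,3) = 20 equally likely values; the sampled p must agree with the
  # enumerated tail up to Monte-Carlo error
  tvals <- c(2.5, -1.2, 0.4, 1.8, -0.6, 0.9)
  d <- diffStub(paste0("P", 1:6, "_S1"), t_stat = tvals)
  rg <- kinRegulon(paste0("P", c(1, 4, 6), "_S1"))
  obs <- mean(tvals[c(1, 4, 6)])
  nullAll <- apply(combn(6, 3), 2, function(ix) mean(tvals[ix]))
  pExact <- mean(abs(nullAll) >= abs(obs))
  at <- footprintActivity(d, rg, nPerm = 4000, seed = 9)
  expect_equal(at$score, obs, tolerance = 1e-12)
  expect_lt(abs(at$p_value - pExact), 0.05)
})

test_that("small regulons are skipped and recorded", {
  d <- diffStub(paste0("P", 1:6, "_S1"), t_stat = rnorm(6))
  rg <- RegulonSet(data.frame(
    regulator = c("K1", "K1", "K1", "K2", "K2"), class = "kinase",
    target = paste0("P", c(1, 2, 3, 4, 5), "_S1"), sign = 1))
  at <- footprintActivity(d, rg, minTargets = 3, nPerm = 200, seed = 4)
  expect_identical(at$protein, "K1")
  expect_identical(attr(at, "skipped"), "K2")
  at2 <- footprintActivity(d, rg, minTargets = 2, nPerm = 200, seed = 4)
  expect_setequal(at2$protein, c("K1", "K2"))
  expect_error(footprintActivity(d, rg, nPerm = 50), "nPerm")
})

test_that("phospho-score aggregates regulatory sites with their effects", {
  d <- diffStub(c("CDK7_T170", "AKT1_S473", "GSK3B_S9"),
                log2fc = c(2, 2, -1), significant = TRUE)
  rs <- data.frame(protein = c("CDK7", "AKT1", "AKT1"),
                   site = c("CDK7_T170", "AKT1_S473", "GSK3B_S9"),
                   effect = c(1, 1, -1))
  ps <- phosphoScore(d, rs)
  # an up-shifted activating site implies activation
  expect_identical(ps$sign[ps$protein == "CDK7"], 1)
  expect_equal(ps$score[ps$protein == "CDK7"], 2, tolerance = 1e-12)
  # activating +2 and inhibiting -(-1) = +1 average to +1.5 here; exact
  # cancellation must give sign 0
  d2 <- diffStub(c("X_S1", "X_S2"), log2fc = c(2, 2))
  rs2 <- data.frame(protein = "X", site = c("X_S1", "X_S2"),
                    effect = c(1, -1))
  ps2 <- phosphoScore(d2, rs2)
  expect_identical(ps2$score, 0)
  expect_identical(ps2$sign, 0)
  # non-significant sites are ignored by default
  d3 <- diffStub("Y_S1", log2fc = 3, significant = FALSE)
  rs3 <- data.frame(protein = "Y", site = "Y_S1", effect = 1)
  expect_identical(nrow(phosphoScore(d3, rs3)), 0L)
  expect_identical(phosphoScore(d3, rs3, onlySignificant = FALSE)$sign, 1)
})

test_that("combination keeps agreements, drops conflicts, passes singletons", {
  fp <- data.frame(protein = c("A", "B", "C"), class = "kinase",
                   method = "footprint", score = c(2, 1, -1), z = 1,
                   sign = c(1, 1, -1), p_value = 0.01, fdr = 0.02,
                   n_evidence = 4L)
  ps <- data.frame(protein = c("B", "C", "D"), class = "other",
                   method = "phosphoscore", score = c(0.5, 2, -3), z = NA,
                   sign = c(1, 1, -1), p_value = NA, fdr = NA,
                   n_evidence = 1L)
  cm <- combineActivities(fp, ps)
  expect_identical(cm$method[cm$protein == "A"], "footprint")  # footprint-only
  expect_identical(cm$method[cm$protein == "B"], "combined")   # agreement
  expect_false("C" %in% cm$protein)                            # conflict
  expect_identical(attr(cm, "conflicts"), "C")
  expect_identical(cm$method[cm$protein == "D"], "phosphoscore")
  # combined rows keep the footprint score and p
  expect_identical(cm$score[cm$protein == "B"], 1)
  expect_identical(cm$p_value[cm$protein == "B"], 0.01)
})

test_that("activity profile comparison matches direct formulas", {
  a <- data.frame(protein = paste0("P", 1:5), score = c(1, 2, -1, 0.5, -2),
                  sign = sign(c(1, 2, -1, 0.5, -2)))
  same <- compareActivityProfiles(a, a)
  expect_equal(same$pearson, 1, tolerance = 1e-12)
  expect_identical(same$sign_agreement, 1)
  neg <- a; neg$score <- -a$score; neg$sign <- -a$sign
  opp <- compareActivityProfiles(a, neg)
  expect_equal(opp$pearson, -1, tolerance = 1e-12)
  expect_identical(opp$sign_agreement, 0)
  set.seed(11)
  b <- a; b$score <- rnorm(5); b$sign <- sign(b$score)
  cmp <- compareActivityProfiles(a, b)
  expect_equal(cmp$pearson, cor(a$score, b$score), tolerance = 1e-12)
  expect_equal(cmp$spearman, cor(a$score, b$score, method = "spearman"),
               tolerance = 1e-12)
  # fewer than 3 shared proteins: undefined
  expect_true(is.na(compareActivityProfiles(a[1:2, ], b[1:2, ])$pearson))
})

test_that("regulator p-values are near-uniform under the global null", {
  set.seed(13)
  nFeat <- 2000
  d <- diffStub(paste0("P", seq_len(nFeat), "_S1"), t_stat = rnorm(nFeat))
  e <- data.frame(regulator = rep(sprintf("K%03d", 1:300), each = 5),
                  class = "kinase",
                  target = paste0("P", sample(nFeat, 1500, replace = FALSE),
                                  "_S1"),
                  sign = sample(c(-1, 1), 1500, replace = TRUE))
  at <- footprintActivity(RegulonSet(e), diff = d, nPerm = 400, seed = 17)
  ks <- suppressWarnings(ks.test(at$p_value, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("two-layer inference recovers simulated regulator signs", {
  ex <- simulateStudy(nNodes = 50, nRegulators = 12, nActive = 4,
                      magnitude = 1.5, genotypes = "ITD-JMD", seed = 47)
  dp <- differentialStats(ex@proteome)
  dph <- differentialStats(ex@phospho)
  act <- inferActivities(dp, dph, ex@regulons, ex@regSites,
                         classes = setNames(networkNodes(ex@network)$class,
                                            networkNodes(ex@network)$node),
                         nPerm = 500, seed = 3)
  tt <- truthTable(ex@truth)
  fp <- attr(act, "footprint")
  hit <- merge(fp, tt, by.x = "protein", by.y = "regulator")
  expect_gte(mean(hit$sign == sign(hit$activity)), 0.75)
  # combined table annotates classes and never contains conflicting rows
  expect_true(all(act$class %in% c("kinase", "phosphatase", "TF", "other")))
  expect_false(any(duplicated(act$protein)))
})
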