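# Generator contracts: graph shape, regulon structure, the linear signed
# shift model, noise calibration and seed determinism.

test_that("prior network generator respects shape constraints", {
  expect_error(generatePriorNetwork(1), "nNodes")
  # minimal graph: one signaling node wired into the phenotype
  pn <- generatePriorNetwork(2, seed = 1)
  ed <- networkEdges(pn)
  expect_identical(nrow(ed), 1L)
  expect_identical(ed$target, "DNA_damage")
  # phenotype is always a sink with in-degree >= 1
  pn2 <- generatePriorNetwork(50, meanOutDegree = 2, seed = 2)
  ed2 <- networkEdges(pn2)
  expect_gte(sum(ed2$target == "DNA_damage"), 1L)
  expect_false(any(ed2$source == "DNA_damage"))
  # all classes assigned
  expect_true(all(networkNodes(pn2)$class %in%
                    c("kinase", "phosphatase", "TF", "other")))
  # no inhibitory edges at the boundary
  pn3 <- generatePriorNetwork(30, fracInhibitory = 0, seed = 3)
  expect_true(all(networkEdges(pn3)$sign == 1))
})

test_that("edge count follows the binomial out-degree model", {
  # oracle: edges ~ Binomial(199 * 199, 3/199), mean 597
  pn <- generatePriorNetwork(200, meanOutDegree = 3, seed = 42)
  nTrial <- 199 * 199; p <- 3 / 199
  expect_lt(abs(nrow(networkEdges(pn)) - nTrial * p),
            3 * sqrt(nTrial * p * (1 - p)) + 1)  # +1: phenotype guarantee
})

test_that("regulons are distinct, class-labelled and deterministic", {
  pn <- generatePriorNetwork(40, seed = 4)
  rg <- generateRegulons(pn, targetsPerRegulator = 5, seed = 9)
  e <- regulonTable(rg$regulons)
  perReg <- table(e$regulator)
  expect_true(all(perReg[names(perReg) %in%
    e$regulator[e$class %in% c("kinase", "phosphatase")]] == 5))
  expect_false(any(duplicated(paste(e$regulator, e$target))))
  # phosphatases appear with their own class label
  nd <- networkNodes(pn)
  pp <- nd$node[nd$class == "phosphatase"]
  if (length(pp)) expect_true(all(e$class[e$regulator %in% pp] == "phosphatase"))
  # kinase/phosphatase targets are phosphosites; TF targets are proteins
  expect_silent(parsePhosphosite(e$target[e$class == "kinase"]))
  expect_true(all(e$target[e$class == "TF"] %in% nd$node))
  # 0-2 regulatory self-sites per protein, on the host itself
  rs <- rg$regSites
  expect_true(all(table(rs$protein) <= 2))
  expect_identical(parsePhosphosite(rs$site)$protein, rs$protein)
  # determinism
  rg2 <- generateRegulons(pn, targetsPerRegulator = 5, seed = 9)
  expect_identical(regulonTable(rg2$regulons), e)
  expect_identical(rg2$regSites, rs)
})

test_that("noise-free shifts equal the additive signed model exactly", {
  pn <- generatePriorNetwork(30, seed = 6)
  rg <- generateRegulons(pn, targetsPerRegulator = 4, seed = 6)
  e <- regulonTable(rg$regulons)
  kin <- unique(e$regulator[e$class == "kinase"])[1:2]
  truth <- GroundTruth(data.frame(genotype = "ITD-JMD", regulator = kin,
                                  activity = c(2, -1.5)))
  ex <- simulateExperiment(pn, rg$regulons, rg$regSites, truth,
                           noiseSd = 0, seed = 11)
  a <- SummarizedExperiment::assay(ex@phospho)
  si <- sampleInfo(ex@phospho)
  shift <- rowMeans(a[, si$treatment == "treated"]) -
    rowMeans(a[, si$treatment == "control"])
  # expected shift per feature: sum over regulators of activity * sign
  amap <- setNames(c(2, -1.5), kin)
  er <- e[e$regulator %in% kin, ]
  expected <- tapply(amap[er$regulator] * er$sign, er$target, sum)
  rs <- ex@regSites[ex@regSites$protein %in% kin, ]
  selfShift <- if (nrow(rs)) setNames(amap[rs$protein] * rs$effect, rs$site)
    else numeric()
  full <- setNames(numeric(nrow(a)), rownames(a))
  full[names(expected)] <- expected
  full[names(selfShift)] <- full[names(selfShift)] + selfShift
  expect_equal(shift, full, tolerance = 1e-12)
  # everything else is exactly zero
  expect_true(all(shift[setdiff(rownames(a),
                                c(names(expected), names(selfShift)))] == 0))
  # proteome layer: only the active regulators' own abundance moves
  ap <- SummarizedExperiment::assay(ex@proteome)
  sip <- sampleInfo(ex@proteome)
  shiftP <- rowMeans(ap[, sip$treatment == "treated"]) -
    rowMeans(ap[, sip$treatment == "control"])
  expect_equal(unname(shiftP[kin]), c(2, -1.5), tolerance = 1e-12)
  expect_true(all(shiftP[setdiff(names(shiftP), kin)] == 0))
})

test_that("null shift dispersion matches the closed-form variance", {
  # oracle: difference of two means of n replicates with sd s has
  # sd s * sqrt(2 / n)
  pn <- generatePriorNetwork(10, seed = 7)
  rg <- generateRegulons(pn, targetsPerRegulator = 3, seed = 7)
  truth <- GroundTruth(data.frame(genotype = character(),
                                  regulator = character(),
                                  activity = numeric()))
  ex <- simulateExperiment(pn, rg$regulons, rg$regSites, truth,
                           nReplicates = 4, noiseSd = 0.3,
                           nBackgroundSites = 1000, genotypes = "ITD-JMD",
                           seed = 13)
  a <- SummarizedExperiment::assay(ex@phospho)
  si <- sampleInfo(ex@phospho)
  shift <- rowMeans(a[, si$treatment == "treated"]) -
    rowMeans(a[, si$treatment == "control"])
  theory <- 0.3 * sqrt(2 / 4)
  expect_lt(abs(sd(shift) - theory) / theory, 0.10)
})

test_that("localization probabilities follow the requested low fraction", {
  # regulon-free configuration: the class-I solvability guarantee is a
  # no-op, so low-probability sites are plain Bernoulli draws
  pn <- generatePriorNetwork(5, seed = 8)
  empty <- RegulonSet(data.frame(regulator = character(),
                                 class = character(), target = character(),
                                 sign = numeric()))
  noSites <- data.frame(protein = character(), site = character(),
                        effect = numeric())
  truth <- GroundTruth(data.frame(genotype = character(),
                                  regulator = character(),
                                  activity = numeric()))
  ex <- simulateExperiment(pn, empty, noSites, truth,
                           locProbLowFraction = 0.2, nBackgroundSites = 500,
                           genotypes = "ITD-JMD", seed = 21)
  lp <- locProb(ex@phospho)
  expect_identical(length(lp), 500L)
  nLow <- sum(lp < 0.75)
  expect_lt(abs(nLow - 100), 3 * sqrt(500 * 0.2 * 0.8))
  expect_true(all(lp >= 0.3 & lp <= 1))
})

test_that("regulon-bearing regulators keep enough class-I targets", {
  ex <- simulateStudy(nNodes = 60, nRegulators = 12, nActive = 4,
                      genotypes = "ITD-JMD", seed = 19)
  lp <- locProb(ex@phospho)
  e <- regulonTable(ex@regulons)
  e <- e[e$class %in% c("kinase", "phosphatase"), ]
  nCI <- tapply(lp[e$target] >= 0.75, e$regulator, sum)
  expect_true(all(nCI >= 3))
})

test_that("simulateExperiment validates its arguments", {
  pn <- generatePriorNetwork(5, seed = 1)
  rg <- generateRegulons(pn, 3, seed = 1)
  truth <- GroundTruth(data.frame(genotype = "g", regulator = "G0001",
                                  activity = 1))
  expect_error(simulateExperiment(pn, rg$regulons, rg$regSites, truth,
                                  nReplicates = 1), "nReplicates")
  expect_error(simulateExperiment(pn, rg$regulons, rg$regSites, truth,
                                  noiseSd = -0.1), "noiseSd")
})

test_that("the whole study is reproducible from one seed", {
  a <- simulateStudy(nNodes = 20, nRegulators = 5, nActive = 2,
                     genotypes = c("ITD-JMD", "ITD-TKD"), seed = 33)
  b <- simulateStudy(nNodes = 20, nRegulators = 5, nActive = 2,
                     genotypes = c("ITD-JMD", "ITD-TKD"), seed = 33)
  expect_identical(SummarizedExperiment::assay(a@phospho),
                   SummarizedExperiment::assay(b@phospho))
  expect_identical(SummarizedExperiment::assay(a@proteome),
                   SummarizedExperiment::assay(b@proteome))
  expect_identical(networkEdges(a@network), networkEdges(b@network))
  expect_identical(truthTable(a@truth), truthTable(b@truth))
})
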