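# Synthetic study generator: a signed prior network with a phenotype sink,
# regulons with known signs, ground-truth regulator activities, and
# two-condition (phospho)proteome matrices in which treated-minus-control
# shifts follow the additive signed footprint model exactly (plus Gaussian
# noise). Every stage is seeded and bit-reproducible.

#' Generate a random signed prior network with a phenotype sink
#'
#' Builds a directed signed graph over \code{nNodes - 1} signaling nodes
#' plus one phenotype node. Every ordered pair (source a signaling node) is
#' an edge independently with probability \code{meanOutDegree / (nNodes -
#' 1)}, so out-degrees are Binomial with the requested mean; each edge is
#' inhibitory with probability \code{fracInhibitory}. Node classes (kinase,
#' phosphatase, TF, other) are drawn with \code{classProps}, whose default
#' mirrors the class imbalance typical of signaling annotation (many
#' kinases and "other" entities, few phosphatases). The phenotype is
#' guaranteed in-degree >= 1 and has out-degree 0 by construction.
#'
#' @param nNodes total node count including the phenotype; >= 2.
#' @param meanOutDegree expected out-degree of a signaling node.
#' @param fracInhibitory probability an edge is inhibitory, in [0, 1].
#' @param classProps named probabilities for classes kinase, phosphatase,
#'   TF, other.
#' @param phenotype phenotype node ID.
#' @param seed integer seed, or \code{NULL} to use the current RNG state.
#' @return A \linkS4class{PriorNetwork}.
#' @examples
#' generatePriorNetwork(20, meanOutDegree = 2, seed = 1)
#' @export
generatePriorNetwork <- function(nNodes, meanOutDegree = 3,
                                 fracInhibitory = 0.3,
                                 classProps = c(kinase = 0.35,
                                                phosphatase = 0.05,
                                                TF = 0.15, other = 0.45),
                                 phenotype = "DNA_damage", seed = NULL) {
  if (nNodes < 2) stopf("nNodes must be >= 2")
  if (fracInhibitory < 0 || fracInhibitory > 1)
    stopf("fracInhibitory must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  nSig <- nNodes - 1L
  sig <- sprintf("G%04d", seq_len(nSig))
  cls <- sample(names(classProps), nSig, replace = TRUE,
                prob = classProps / sum(classProps))
  all <- c(sig, phenotype)
  src <- rep(sig, each = nNodes - 1L)
  tgt <- unlist(lapply(sig, function(u) setdiff(all, u)), use.names = FALSE)
  p <- min(1, meanOutDegree / (nNodes - 1))
  keep <- runif(length(src)) < p
  src <- src[keep]; tgt <- tgt[keep]
  sign <- ifelse(runif(length(src)) < fracInhibitory, -1, 1)
  if (!any(tgt == phenotype)) {
    src <- c(src, sample(sig, 1L)); tgt <- c(tgt, phenotype)
    sign <- c(sign, 1)
  }
  edges <- data.frame(source = src, target = tgt, sign = sign,
                      mechanism = "synthetic", stringsAsFactors = FALSE)
  PriorNetwork(edges,
               nodes = data.frame(node = sig, class = cls,
                                  stringsAsFactors = FALSE),
               phenotype = phenotype)
}

# Draw n distinct phosphosite strings on the given host pool.
.drawSites <- function(hosts, n) {
  out <- character(0)
  while (length(out) < n) {
    h <- sample(hosts, n, replace = TRUE)
    r <- sample(c("S", "T", "Y"), n, replace = TRUE, prob = c(0.6, 0.3, 0.1))
    pos <- sample.int(999L, n, replace = TRUE)
    out <- unique(c(out, phosphositeString(h, r, pos)))
  }
  out[seq_len(n)]
}

#' Generate signed regulons and regulatory-site annotations
#'
#' Every kinase and phosphatase regulator receives
#' \code{targetsPerRegulator} distinct phosphosite targets on signaling
#' proteins; every TF receives protein-level targets. Target signs encode
#' the expected direction of the target's change when the regulator is
#' active (+1 with probability \code{1 - fracNegativeTargets}); phosphatase
#' target signs are drawn the same way — the stored sign already carries any
#' dephosphorylation semantics, there is no hidden extra flip. In addition,
#' every signaling node receives 0-2 regulatory phosphosites on itself,
#' annotated activating (+1, probability 0.7) or inhibiting (-1), the
#' evidence base for the phospho-score.
#'
#' @param network a \linkS4class{PriorNetwork} with >= 1 kinase,
#'   phosphatase or TF node.
#' @param targetsPerRegulator targets per regulator.
#' @param nRegulators optionally restrict to this many regulators (sampled
#'   from the eligible classes); \code{NULL} = all eligible nodes.
#' @param fracNegativeTargets probability a regulon target sign is -1.
#' @param seed integer seed or \code{NULL}.
#' @return list with elements \code{regulons} (a
#'   \linkS4class{RegulonSet}) and \code{regSites} (data.frame
#'   \code{protein}/\code{site}/\code{effect}).
#' @export
generateRegulons <- function(network, targetsPerRegulator = 5,
                             nRegulators = NULL,
                             fracNegativeTargets = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nd <- networkNodes(network)
  sig <- nd$node[!nd$is_phenotype]
  elig <- nd[!nd$is_phenotype & nd$class %in% c("kinase", "phosphatase", "TF"), ]
  if (!nrow(elig)) stopf("network has no kinase/phosphatase/TF node")
  if (!is.null(nRegulators)) {
    if (nRegulators > nrow(elig))
      stopf("asked for %d regulators but only %d eligible nodes",
            nRegulators, nrow(elig))
    elig <- elig[csort(sample(elig$node, nRegulators)) |>
                   match(elig$node), , drop = FALSE]
  }
  entries <- do.call(rbind, lapply(seq_len(nrow(elig)), function(i) {
    reg <- elig$node[i]; cls <- elig$class[i]
    tg <- if (cls == "TF") {
      pool <- setdiff(sig, reg)
      sample(pool, min(targetsPerRegulator, length(pool)))
    } else .drawSites(sig, targetsPerRegulator)
    data.frame(regulator = reg, class = cls, target = tg,
               sign = ifelse(runif(length(tg)) < fracNegativeTargets, -1, 1),
               stringsAsFactors = FALSE)
  }))
  nSelf <- sample(0:2, length(sig), replace = TRUE)
  regSites <- do.call(rbind, lapply(seq_along(sig)[nSelf > 0], function(i) {
    data.frame(protein = sig[i],
               site = .drawSites(sig[i], nSelf[i]),
               effect = ifelse(runif(nSelf[i]) < 0.7, 1, -1),
               stringsAsFactors = FALSE)
  }))
  if (is.null(regSites))
    regSites <- data.frame(protein = character(), site = character(),
                           effect = numeric())
  regSites <- regSites[!duplicated(regSites$site), , drop = FALSE]
  regSites <- regSites[corder(regSites$protein, regSites$site), , drop = FALSE]
  rownames(regSites) <- NULL
  list(regulons = RegulonSet(entries), regSites = regSites)
}

#' Draw ground-truth regulator activities
#'
#' Samples \code{nActive} regulon-bearing active regulators per genotype
#' and assigns each a random sign times \code{magnitude}. A fraction
#' \code{fracShared} of the active set is common to all genotypes with
#' identical activities — the treatment response a drug elicits regardless
#' of genetic context — while the remainder is drawn independently per
#' genotype, giving context-specific rewiring.
#'
#' @param regulons a \linkS4class{RegulonSet}.
#' @param nActive active regulators per genotype.
#' @param magnitude absolute activity (log2 shift contributed to each
#'   target per unit regulon sign).
#' @param genotypes genotype context labels.
#' @param fracShared fraction of active regulators shared across genotypes
#'   (default 0.5; irrelevant for a single genotype).
#' @param phenotype,direction phenotype node and response direction.
#' @param seed integer seed or \code{NULL}.
#' @return A \linkS4class{GroundTruth}.
#' @export
makeGroundTruth <- function(regulons, nActive = 8, magnitude = 1.5,
                            genotypes = c("ITD-JMD", "ITD-TKD"),
                            fracShared = 0.5,
                            phenotype = "DNA_damage", direction = 1,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (fracShared < 0 || fracShared > 1)
    stopf("fracShared must lie in [0, 1]")
  regs <- unique(regulonTable(regulons)$regulator)
  if (nActive > length(regs))
    stopf("nActive exceeds the number of regulon-bearing regulators")
  nShared <- if (length(genotypes) > 1L) round(fracShared * nActive) else 0L
  shared <- sample(regs, nShared)
  sharedAct <- sample(c(-1, 1), nShared, replace = TRUE) * magnitude
  act <- do.call(rbind, lapply(genotypes, function(g) {
    nOwn <- nActive - nShared
    r <- sample(setdiff(regs, shared), nOwn)
    data.frame(genotype = g, regulator = c(shared, r),
               activity = c(sharedAct,
                            sample(c(-1, 1), nOwn, replace = TRUE) * magnitude),
               stringsAsFactors = FALSE)
  }))
  if (is.null(act)) act <- data.frame(genotype = character(),
                                      regulator = character(),
                                      activity = numeric())
  GroundTruth(act, phenotype = phenotype, direction = direction)
}

#' Simulate a two-condition (phospho)proteome experiment
#'
#' For every genotype in the ground truth, control and treated samples are
#' drawn with \code{nReplicates} replicates each. The expected
#' treated-minus-control log2 shift of a feature is the sum, over the
#' active regulators that target it, of activity times regulon sign
#' (effects combine additively); every other feature has expected shift 0.
#' Kinase/phosphatase regulons act on the phospho layer; TF regulons and
#' the active regulators' own protein abundance act on the proteome layer;
#' an active protein's own regulatory sites shift by activity times site
#' effect. Per-replicate values add Gaussian noise with standard deviation
#' \code{noiseSd}; with \code{noiseSd = 0} the shifts equal the linear
#' model exactly. Each phosphosite independently receives a localization
#' probability below 0.75 with probability \code{locProbLowFraction}
#' (uniform on [0.3, 0.75)), otherwise uniform on [0.75, 1].
#'
#' @param network a \linkS4class{PriorNetwork}.
#' @param regulons a \linkS4class{RegulonSet}.
#' @param regSites regulatory-site data.frame
#'   (\code{protein}/\code{site}/\code{effect}).
#' @param truth a \linkS4class{GroundTruth}.
#' @param nReplicates replicates per condition; >= 2.
#' @param noiseSd Gaussian noise standard deviation; >= 0.
#' @param locProbLowFraction fraction of sites below the class-I threshold.
#' @param minClassITargets solvability guarantee: every regulon-bearing
#'   kinase/phosphatase keeps at least this many class-I target sites (the
#'   lowest-probability targets are re-drawn above the threshold where
#'   needed, uniformly for all regulators), so that ground-truth activities
#'   remain identifiable after class-I filtering. Set 0 to disable.
#' @param nBackgroundSites,nBackgroundProteins unregulated features added to
#'   each layer.
#' @param genotypes genotype labels; defaults to those in \code{truth} (or
#'   the standard two-genotype design when the truth is empty).
#' @param seed integer seed or \code{NULL}.
#' @return A \linkS4class{SyntheticExperiment}.
#' @export
simulateExperiment <- function(network, regulons, regSites, truth,
                               nReplicates = 3, noiseSd = 0.25,
                               locProbLowFraction = 0.2,
                               minClassITargets = 3,
                               nBackgroundSites = 300,
                               nBackgroundProteins = 100,
                               genotypes = NULL, seed = NULL) {
  if (nReplicates < 2) stopf("nReplicates must be >= 2")
  if (noiseSd < 0) stopf("noiseSd must be >= 0")
  if (locProbLowFraction < 0 || locProbLowFraction > 1)
    stopf("locProbLowFraction must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  tt <- truthTable(truth)
  if (is.null(genotypes))
    genotypes <- if (nrow(tt)) unique(tt$genotype) else c("ITD-JMD", "ITD-TKD")
  re <- regulonTable(regulons)
  nd <- networkNodes(network)
  sig <- nd$node[!nd$is_phenotype]

  siteRe <- re[re$class %in% c("kinase", "phosphatase"), , drop = FALSE]
  protRe <- re[re$class == "TF", , drop = FALSE]
  bgSites <- if (nBackgroundSites > 0)
    .drawSites(sprintf("BGP%04d", seq_len(max(20L, nBackgroundSites %/% 3L))),
               nBackgroundSites) else character()
  phosphoFeat <- csort(unique(c(siteRe$target, regSites$site, bgSites)))
  bgProt <- if (nBackgroundProteins > 0)
    sprintf("BGQ%04d", seq_len(nBackgroundProteins)) else character()
  protFeat <- csort(unique(c(sig, protRe$target, bgProt)))

  shiftFor <- function(features, g) {
    sh <- setNames(numeric(length(features)), features)
    ag <- tt[tt$genotype == g, , drop = FALSE]
    if (!nrow(ag)) return(sh)
    amap <- setNames(ag$activity, ag$regulator)
    if (identical(features, phosphoFeat)) {
      hit <- siteRe[siteRe$regulator %in% names(amap), , drop = FALSE]
      if (nrow(hit)) {
        contrib <- amap[hit$regulator] * hit$sign
        agg <- tapply(contrib, hit$target, sum)
        sh[names(agg)] <- sh[names(agg)] + agg
      }
      rs <- regSites[regSites$protein %in% names(amap), , drop = FALSE]
      if (nrow(rs)) {
        contrib <- amap[rs$protein] * rs$effect
        agg <- tapply(contrib, rs$site, sum)
        ok <- names(agg) %in% names(sh)
        sh[names(agg)[ok]] <- sh[names(agg)[ok]] + agg[ok]
      }
    } else {
      hit <- protRe[protRe$regulator %in% names(amap), , drop = FALSE]
      if (nrow(hit)) {
        contrib <- amap[hit$regulator] * hit$sign
        agg <- tapply(contrib, hit$target, sum)
        sh[names(agg)] <- sh[names(agg)] + agg
      }
      own <- intersect(names(amap), names(sh))
      sh[own] <- sh[own] + amap[own]
    }
    sh
  }

  buildLayer <- function(features, kind) {
    baseline <- rnorm(length(features), mean = 22, sd = 2)
    cols <- list(); ann <- list()
    for (g in genotypes) {
      sh <- shiftFor(features, g)
      for (tr in c("control", "treated")) {
        for (r in seq_len(nReplicates)) {
          id <- paste(g, tr, paste0("r", r), sep = "_")
          eps <- if (noiseSd > 0) rnorm(length(features), 0, noiseSd) else 0
          cols[[id]] <- baseline + if (tr == "treated") sh else 0
          cols[[id]] <- cols[[id]] + eps
          ann[[id]] <- data.frame(sample_id = id, genotype = g,
                                  treatment = tr, replicate = r,
                                  stringsAsFactors = FALSE)
        }
      }
    }
    mat <- do.call(cbind, cols)
    rownames(mat) <- features
    sampleData <- do.call(rbind, ann)
    rownames(sampleData) <- sampleData$sample_id
    lp <- NULL
    if (kind == "phospho") {
      low <- runif(length(features)) < locProbLowFraction
      lp <- ifelse(low, runif(length(features), 0.30, 0.75),
                   runif(length(features), 0.75, 1.0))
      names(lp) <- features
      if (minClassITargets > 0 && nrow(siteRe)) {
        for (r in csort(unique(siteRe$regulator))) {
          tg <- intersect(siteRe$target[siteRe$regulator == r], features)
          nCI <- sum(lp[tg] >= 0.75)
          need <- min(minClassITargets, length(tg)) - nCI
          if (need > 0) {
            fix <- tg[lp[tg] < 0.75]
            fix <- fix[order(-lp[fix])][seq_len(need)]
            lp[fix] <- runif(need, 0.75, 1.0)
          }
        }
      }
    }
    OmicsMatrix(mat, sampleData, kind = kind, locProb = lp)
  }

  phospho <- buildLayer(phosphoFeat, "phospho")
  proteome <- buildLayer(protFeat, "proteome")
  new("SyntheticExperiment", proteome = proteome, phospho = phospho,
      network = network, regulons = regulons, regSites = regSites,
      truth = truth,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper chaining [generatePriorNetwork()],
#' [generateRegulons()], [makeGroundTruth()] and [simulateExperiment()],
#' with per-stage seeds derived from one root seed so the whole bundle is
#' reproducible.
#'
#' @inheritParams generatePriorNetwork
#' @inheritParams generateRegulons
#' @inheritParams makeGroundTruth
#' @inheritParams simulateExperiment
#' @param fracShared fraction of active regulators shared across genotypes.
#' @param seed root integer seed (required).
#' @return A \linkS4class{SyntheticExperiment}.
#' @examples
#' ex <- simulateStudy(nNodes = 40, nRegulators = 10, nActive = 3,
#'                     genotypes = "ITD-JMD", seed = 7)
#' ex
#' @export
simulateStudy <- function(nNodes = 200, meanOutDegree = 3,
                          fracInhibitory = 0.3, targetsPerRegulator = 5,
                          nRegulators = NULL, nActive = 8, magnitude = 1.5,
                          genotypes = c("ITD-JMD", "ITD-TKD"),
                          fracShared = 0.5,
                          nReplicates = 3, noiseSd = 0.25,
                          locProbLowFraction = 0.2,
                          phenotype = "DNA_damage", direction = 1, seed) {
  seed <- as.integer(seed)
  net <- generatePriorNetwork(nNodes, meanOutDegree, fracInhibitory,
                              phenotype = phenotype,
                              seed = stageSeed(seed, "simulate"))
  rg <- generateRegulons(net, targetsPerRegulator, nRegulators = nRegulators,
                         seed = stageSeed(seed, "simulate") + 1L)
  truth <- makeGroundTruth(rg$regulons, nActive = nActive,
                           magnitude = magnitude, genotypes = genotypes,
                           fracShared = fracShared,
                           phenotype = phenotype, direction = direction,
                           seed = stageSeed(seed, "simulate") + 2L)
  ex <- simulateExperiment(net, rg$regulons, rg$regSites, truth,
                           nReplicates = nReplicates, noiseSd = noiseSd,
                           locProbLowFraction = locProbLowFraction,
                           genotypes = genotypes,
                           seed = stageSeed(seed, "simulate") + 3L)
  ex@seed <- seed
  ex
}
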