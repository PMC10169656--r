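# End-to-end orchestration: config, input cross-validation, per-genotype
# differential -> activity -> model -> enrichment stages, cross-context
# comparison, and a deterministic JSON run report.

#' Analysis configuration
#'
#' Collects every tunable the pipeline uses, with the conventional
#' defaults: differential FDR 0.1, enrichment FDR 0.05, enrichment-score
#' flag at 3 (adjusted p < 1e-3), four feature clusters, footprint
#' regulons need >= 3 measured targets, 1000 permutation draws, causal
#' paths of at most 4 edges to the \code{"DNA_damage"} phenotype with
#' direction +1, class-I localization floor 0.75, replicate-correlation
#' floor 0.75. All randomness flows from the single root \code{seed} via
#' per-stage derived seeds.
#'
#' @param seed root integer seed (required).
#' @param outDir output directory for stage files and the run report.
#' @param inputDir directory holding a [writeExperiment()] bundle (may be
#'   \code{NULL} when an experiment object is passed to [runPipeline()]).
#' @param gmtPath optional GMT file for model characterization.
#' @param fdrDiff,fdrEnrich,esThreshold,nClusters,minTargets,nPerm,maxLen
#'   stage tunables (see above).
#' @param phenotype,direction phenotype node and required response
#'   direction.
#' @param classIThreshold,corFloor phospho localization floor and
#'   replicate-QC floor.
#' @return A validated list of class \code{"AnalysisConfig"}.
#' @export
analysisConfig <- function(seed, outDir = NULL, inputDir = NULL,
                           gmtPath = NULL, fdrDiff = 0.1, fdrEnrich = 0.05,
                           esThreshold = 3, nClusters = 4, minTargets = 3,
                           nPerm = 1000, maxLen = 4,
                           phenotype = "DNA_damage", direction = 1,
                           classIThreshold = 0.75, corFloor = 0.75) {
  if (missing(seed) || is.null(seed) || is.na(suppressWarnings(as.integer(seed))))
    stopf("an integer seed is mandatory")
  for (v in c(fdrDiff = fdrDiff, fdrEnrich = fdrEnrich,
              classIThreshold = classIThreshold))
    if (v <= 0 || v > 1) stopf("thresholds must lie in (0, 1]")
  if (maxLen < 1 || minTargets < 1 || nClusters < 1)
    stopf("maxLen, minTargets and nClusters must be >= 1")
  if (!direction %in% c(-1, 1)) stopf("direction must be +1 or -1")
  structure(list(seed = as.integer(seed), outDir = outDir,
                 inputDir = inputDir, gmtPath = gmtPath,
                 fdrDiff = fdrDiff, fdrEnrich = fdrEnrich,
                 esThreshold = esThreshold, nClusters = as.integer(nClusters),
                 minTargets = as.integer(minTargets),
                 nPerm = as.integer(nPerm), maxLen = as.integer(maxLen),
                 phenotype = phenotype, direction = direction,
                 classIThreshold = classIThreshold, corFloor = corFloor),
            class = "AnalysisConfig")
}

#' Cross-validate pipeline inputs
#'
#' Checks ID consistency across the bundle before anything runs: the
#' phenotype node must exist in the prior network (fatal), and regulon
#' targets, regulatory sites and ground-truth regulators that cannot be
#' matched to measured features or the network are reported as warnings
#' with counts (orphans are tolerated; they simply contribute no
#' evidence).
#'
#' @param experiment a \linkS4class{SyntheticExperiment} (or any list-like
#'   bundle with the same slots).
#' @param config an [analysisConfig()].
#' @return list with \code{fatal} and \code{warnings} character vectors;
#'   fatal problems make [runPipeline()] abort.
#' @export
validateInputs <- function(experiment, config) {
  fatal <- character(); warnings <- character()
  nd <- networkNodes(experiment@network)
  if (!config$phenotype %in% nd$node)
    fatal <- c(fatal, sprintf("phenotype node \"%s\" absent from the network",
                              config$phenotype))
  e <- regulonTable(experiment@regulons)
  phF <- rownames(experiment@phospho); prF <- rownames(experiment@proteome)
  nSite <- sum(!e$target[e$class %in% c("kinase", "phosphatase")] %in% phF)
  if (nSite)
    warnings <- c(warnings, sprintf(
      "%d kinase/phosphatase regulon target(s) not measured in the phospho matrix", nSite))
  nTf <- sum(!e$target[e$class == "TF"] %in% prF)
  if (nTf)
    warnings <- c(warnings, sprintf(
      "%d TF regulon target(s) not measured in the proteome matrix", nTf))
  rs <- experiment@regSites
  if (nrow(rs) && (n <- sum(!rs$site %in% phF)))
    warnings <- c(warnings, sprintf(
      "%d regulatory site(s) not measured in the phospho matrix", n))
  tt <- truthTable(experiment@truth)
  if (nrow(tt) && (n <- sum(!unique(tt$regulator) %in% e$regulator)))
    warnings <- c(warnings, sprintf(
      "%d ground-truth regulator(s) have no regulon", n))
  gnM <- unique(sampleInfo(experiment@proteome)$genotype)
  if (nrow(tt) && (n <- length(setdiff(unique(tt$genotype), gnM))))
    fatal <- c(fatal, sprintf("%d truth genotype(s) absent from the matrices", n))
  list(fatal = fatal, warnings = warnings)
}

.safeName <- function(x) gsub("[^A-Za-z0-9._-]", "-", x)

#' Run the full analysis pipeline
#'
#' Per genotype context: class-I filtering and differential statistics on
#' both layers, replicate QC, hierarchical clustering of significant
#' proteome features, two-layer activity inference, sign-consistent model
#' construction against the phenotype, kinase-substrate set enrichment and
#' (when a GMT is configured) model-node over-representation analysis.
#' Across contexts: significant-set overlap per layer, activity-profile
#' correlation, and model node/edge differences. Every stage output is
#' written under \code{config$outDir} and summarized in
#' \code{report.json}; identical config and inputs give byte-identical
#' outputs.
#'
#' @param config an [analysisConfig()] (with \code{inputDir} set, unless
#'   \code{experiment} is given).
#' @param experiment optional in-memory \linkS4class{SyntheticExperiment};
#'   when \code{NULL} the bundle is read from \code{config$inputDir}.
#' @return The run report, invisibly (also written as JSON).
#' @export
runPipeline <- function(config, experiment = NULL) {
  stopifnot(inherits(config, "AnalysisConfig"))
  if (is.null(experiment)) {
    if (is.null(config$inputDir)) stopf("config$inputDir or experiment required")
    experiment <- readExperiment(config$inputDir)
  }
  if (is.null(config$outDir)) stopf("config$outDir is required")
  chk <- validateInputs(experiment, config)
  if (length(chk$fatal))
    stopf("input validation failed: %s", paste(chk$fatal, collapse = "; "))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(config$outDir, paste0(...))
  gmt <- if (!is.null(config$gmtPath)) readGMT(config$gmtPath) else NULL
  nd <- networkNodes(experiment@network)
  classMap <- setNames(nd$class, nd$node)
  genotypes <- csort(unique(sampleInfo(experiment@proteome)$genotype))
  tt <- truthTable(experiment@truth)

  perG <- list(); diffP <- list(); diffPh <- list(); acts <- list()
  models <- list()
  for (i in seq_along(genotypes)) {
    g <- genotypes[i]; gs <- .safeName(g)
    dp <- differentialStats(experiment@proteome, genotype = g,
                            fdrThreshold = config$fdrDiff)
    dph <- differentialStats(experiment@phospho, genotype = g,
                             fdrThreshold = config$fdrDiff,
                             classIThreshold = config$classIThreshold)
    write.table(dp, fp("diff_proteome_", gs, ".tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(dph, fp("diff_phospho_", gs, ".tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    qc <- replicateCorrelation(experiment@proteome[,
            sampleInfo(experiment@proteome)$genotype == g],
            floor = config$corFloor)
    sigP <- dp$feature[dp$significant]
    clusters <- NULL
    if (length(sigP) >= config$nClusters) {
      clusters <- clusterFeatures(experiment@proteome[,
                    sampleInfo(experiment@proteome)$genotype == g],
                    features = sigP, k = config$nClusters)
      write.table(clusters, fp("clusters_", gs, ".tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    act <- inferActivities(dp, dph, experiment@regulons,
                           experiment@regSites, classes = classMap,
                           minTargets = config$minTargets,
                           nPerm = config$nPerm,
                           seed = stageSeed(config$seed, "activity") + i)
    write.table(act, fp("activity_", gs, ".tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    naive <- buildNaiveNetwork(act, experiment@network)
    model <- connectToPhenotype(naive, experiment@network,
                                phenotype = config$phenotype,
                                direction = config$direction,
                                maxLen = config$maxLen)
    writeModel(model, fp("model_", gs))
    kin <- kinaseSetEnrichment(dph, experiment@regulons, "up",
                               adjustThreshold = config$fdrEnrich,
                               esThreshold = config$esThreshold)
    write.table(kin, fp("kinase_enrichment_up_", gs, ".tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    goRes <- NULL
    if (!is.null(gmt)) {
      goRes <- ora(setdiff(networkNodes(model)$node, config$phenotype),
                   gmt, universe = rownames(experiment@proteome),
                   adjustThreshold = config$fdrEnrich,
                   esThreshold = config$esThreshold)
      write.table(goRes, fp("model_enrichment_", gs, ".tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    fpTab <- attr(act, "footprint")
    # "recovered": non-zero footprint sign passing FDR. Infinite scores only
    # arise in the degenerate zero-noise limit, where the permutation p ties
    # at infinity and the direction is exact by construction; they count as
    # recovered without the FDR gate.
    recovered <- fpTab[fpTab$sign != 0 &
                         ((!is.na(fpTab$fdr) & fpTab$fdr < config$fdrDiff) |
                            is.infinite(fpTab$score)),
                       c("protein", "sign"), drop = FALSE]
    names(recovered)[1L] <- "regulator"
    recovered <- recovered[corder(recovered$regulator), , drop = FALSE]
    diffP[[g]] <- dp; diffPh[[g]] <- dph; acts[[g]] <- act
    models[[g]] <- model
    perG[[g]] <- list(
      genotype = g,
      n_features_proteome = nrow(dp), n_features_phospho = nrow(dph),
      n_sig_proteome = sum(dp$significant),
      n_sig_phospho = sum(dph$significant),
      min_replicate_correlation =
        if (nrow(qc$qc)) min(qc$qc$r, na.rm = TRUE) else NA,
      n_clusters = if (is.null(clusters)) 0L
        else length(unique(clusters$cluster)),
      activities_by_class = as.list(table(act$class)),
      n_activities = nrow(act),
      dropped_conflicts = attr(act, "conflicts"),
      skipped_regulators = attr(act, "skipped"),
      model_nodes = nrow(networkNodes(model)),
      model_edges = nrow(networkEdges(model)),
      model_paths = length(modelPaths(model)),
      n_enriched_kinase_sets = sum(kin$significant),
      n_enriched_model_terms = if (is.null(goRes)) NA_integer_
        else sum(goRes$significant),
      recovered_regulators = recovered)
  }

  cross <- NULL
  if (length(genotypes) >= 2L) {
    g1 <- genotypes[1L]; g2 <- genotypes[2L]
    ovP <- compareSignificantSets(diffP)
    ovPh <- compareSignificantSets(diffPh)
    md <- modelDiff(models[[g1]], models[[g2]])
    cross <- list(
      common_core_proteins = ovP$n_intersection,
      common_core_phosphosites = ovPh$n_intersection,
      union_proteins = ovP$n_union,
      union_phosphosites = ovPh$n_union,
      activity_correlation = compareActivityProfiles(acts[[g1]], acts[[g2]]),
      model_diff = list(
        nodes_only_first = md$nodes_only_a,
        nodes_only_second = md$nodes_only_b,
        n_nodes_shared = length(md$nodes_shared),
        n_edges_shared = length(md$edges_shared)))
  }

  truthList <- NULL
  if (nrow(tt))
    truthList <- lapply(split(tt, tt$genotype), function(d)
      data.frame(regulator = d$regulator, sign = sign(d$activity)))
  report <- list(
    package = "phosphoCircuits",
    version = as.character(packageVersion("phosphoCircuits")),
    seed = config$seed,
    config = unclass(config)[setdiff(names(config),
                                     c("outDir", "inputDir", "gmtPath"))],
    validation_warnings = chk$warnings,
    contexts = perG,
    cross_context = cross,
    truth = truthList)
  jsonlite::write_json(report, fp("report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(report)
}
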