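# Constructors, accessors and show methods for the S4 containers.

#' Construct an OmicsMatrix
#'
#' @param mat numeric matrix of log2 intensities, features x samples;
#'   missing values as \code{NA} (never zero-filled).
#' @param sampleData data.frame with one row per column of \code{mat}
#'   (matched by row name or by a \code{sample_id} column) and columns
#'   \code{genotype}, \code{treatment}, \code{replicate}.
#' @param kind \code{"proteome"} or \code{"phospho"}.
#' @param locProb optional numeric vector in [0, 1], one localization
#'   probability per phospho feature (\code{NA} = unannotated).
#' @return An \linkS4class{OmicsMatrix}.
#' @examples
#' m <- matrix(rnorm(12, 20), 3, 4,
#'             dimnames = list(c("AKT1_S473", "CDK7_T170", "TP53_S15"),
#'                             paste0("s", 1:4)))
#' sd <- data.frame(genotype = "ITD-JMD",
#'                  treatment = rep(c("control", "treated"), each = 2),
#'                  replicate = c(1, 2, 1, 2), row.names = paste0("s", 1:4))
#' OmicsMatrix(m, sd, kind = "phospho")
#' @export
OmicsMatrix <- function(mat, sampleData, kind = c("proteome", "phospho"),
                        locProb = NULL) {
  kind <- match.arg(kind)
  mat <- as.matrix(mat)
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stopf("matrix needs feature row names and sample column names")
  dup <- unique(rownames(mat)[duplicated(rownames(mat))])
  if (length(dup))
    stopf("duplicated feature IDs: %s", paste(dup, collapse = ", "))
  sampleData <- as.data.frame(sampleData)
  if ("sample_id" %in% colnames(sampleData) &&
      !identical(rownames(sampleData), colnames(mat)))
    rownames(sampleData) <- sampleData$sample_id
  miss <- setdiff(colnames(mat), rownames(sampleData))
  if (length(miss))
    stopf("samples missing from annotations: %s", paste(miss, collapse = ", "))
  sampleData <- sampleData[colnames(mat), , drop = FALSE]
  sampleData$replicate <- as.integer(sampleData$replicate)
  if (any(is.na(sampleData$replicate)) || any(sampleData$replicate < 1L))
    stopf("replicate must be an integer >= 1")
  rd <- NULL
  if (kind == "phospho") {
    rd <- parsePhosphosite(rownames(mat))
    rd$loc_prob <- if (is.null(locProb)) NA_real_ else {
      lp <- as.numeric(locProb)
      if (length(lp) != nrow(mat))
        stopf("locProb must have one value per feature")
      if (any(lp < 0 | lp > 1, na.rm = TRUE))
        stopf("localization probabilities must lie in [0, 1]")
      lp
    }
    rd <- DataFrame(rd[c("protein", "residue", "position", "loc_prob")],
                    row.names = rownames(mat))
  }
  se <- SummarizedExperiment(
    assays = list(log2intensity = mat),
    colData = DataFrame(sampleData),
    rowData = rd
  )
  new("OmicsMatrix", se, kind = kind)
}

#' @rdname OmicsMatrix
#' @export
setMethod("omicsKind", "OmicsMatrix", function(x) x@kind)

#' @rdname OmicsMatrix
#' @export
setMethod("sampleInfo", "OmicsMatrix", function(x) {
  df <- as.data.frame(colData(x))
  df$sample_id <- rownames(df)
  df[c("sample_id", "genotype", "treatment", "replicate")]
})

#' @rdname OmicsMatrix
#' @export
setMethod("locProb", "OmicsMatrix", function(x) {
  if (x@kind != "phospho") return(NULL)
  setNames(rowData(x)$loc_prob, rownames(x))
})

setMethod("show", "OmicsMatrix", function(object) {
  cd <- colData(object)
  cat(sprintf("OmicsMatrix (%s): %d features x %d samples\n",
              object@kind, nrow(object), ncol(object)))
  cat(sprintf("  genotypes: %s | treatments: %s\n",
              paste(unique(cd$genotype), collapse = ", "),
              paste(unique(cd$treatment), collapse = ", ")))
  if (object@kind == "phospho") {
    lp <- rowData(object)$loc_prob
    if (!all(is.na(lp)))
      cat(sprintf("  class-I sites (loc_prob >= 0.75): %d/%d\n",
                  sum(lp >= 0.75, na.rm = TRUE), nrow(object)))
  }
  invisible(NULL)
})

#' Construct a PriorNetwork
#'
#' @param edges data.frame with columns \code{source}, \code{target},
#'   \code{sign} (numeric +1/-1 or SIGNOR-style verbs) and optionally
#'   \code{mechanism}.
#' @param nodes optional data.frame with columns \code{node} and
#'   \code{class}; nodes appearing only in \code{edges} are added with class
#'   \code{"other"}.
#' @param phenotype character vector of phenotype node IDs (sinks).
#' @return A \linkS4class{PriorNetwork}. Identical duplicate edges are
#'   collapsed; same-pair edges with opposite signs are both kept.
#' @examples
#' pn <- PriorNetwork(data.frame(source = "CDK2", target = "CDK7",
#'                               sign = "activates"),
#'                    phenotype = character())
#' networkEdges(pn)
#' @export
PriorNetwork <- function(edges, nodes = NULL, phenotype = character()) {
  edges <- as.data.frame(edges)
  if (!nrow(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        sign = numeric(), mechanism = character())
  } else {
    if (!all(c("source", "target", "sign") %in% colnames(edges)))
      stopf("edges needs columns source/target/sign")
    sg <- normalizeSign(edges$sign)
    if (any(is.na(sg)))
      stopf("unrecognized interaction sign(s): %s",
            paste(unique(edges$sign[is.na(sg)]), collapse = ", "))
    edges$sign <- sg
    if (is.null(edges$mechanism)) edges$mechanism <- ""
    edges$mechanism[is.na(edges$mechanism)] <- ""
    edges <- edges[c("source", "target", "sign", "mechanism")]
    edges <- edges[!duplicated(edgeKey(edges$source, edges$target, edges$sign)), ,
                   drop = FALSE]
    edges <- edges[corder(edges$source, edges$target, edges$sign), , drop = FALSE]
    rownames(edges) <- NULL
  }
  ids <- csort(unique(c(edges$source, edges$target, phenotype,
                        if (!is.null(nodes)) nodes$node)))
  nd <- data.frame(node = ids, class = rep("other", length(ids)),
                   is_phenotype = ids %in% phenotype,
                   stringsAsFactors = FALSE)
  if (!is.null(nodes)) {
    nodes <- as.data.frame(nodes)
    if (!all(c("node", "class") %in% colnames(nodes)))
      stopf("nodes needs columns node/class")
    nd$class[match(nodes$node, nd$node)] <- nodes$class
  }
  new("PriorNetwork", nodes = nd, edges = edges)
}

#' @rdname PriorNetwork
#' @export
setMethod("networkNodes", "PriorNetwork", function(x) x@nodes)

#' @rdname PriorNetwork
#' @export
setMethod("networkEdges", "PriorNetwork", function(x) x@edges)

#' @rdname MechanisticModel
#' @export
setMethod("networkNodes", "MechanisticModel", function(x) x@nodes)

#' @rdname MechanisticModel
#' @export
setMethod("networkEdges", "MechanisticModel", function(x) x@edges)

setMethod("show", "PriorNetwork", function(object) {
  cls <- table(object@nodes$class)
  cat(sprintf("PriorNetwork: %d nodes, %d signed edges (%d inhibitory)\n",
              nrow(object@nodes), nrow(object@edges),
              sum(object@edges$sign < 0)))
  cat("  classes:", paste(names(cls), cls, sep = "=", collapse = ", "), "\n")
  phen <- object@nodes$node[object@nodes$is_phenotype]
  if (length(phen)) cat("  phenotype:", paste(phen, collapse = ", "), "\n")
  invisible(NULL)
})

#' Construct a RegulonSet
#'
#' @param entries data.frame with columns \code{regulator}, \code{class}
#'   (kinase/phosphatase/TF/other), \code{target}, \code{sign}.
#' @return A \linkS4class{RegulonSet} with rows sorted by regulator and
#'   target.
#' @export
RegulonSet <- function(entries) {
  entries <- as.data.frame(entries)
  if (!nrow(entries)) {
    entries <- data.frame(regulator = character(), class = character(),
                          target = character(), sign = numeric())
  } else {
    sg <- normalizeSign(entries$sign)
    if (any(is.na(sg)))
      stopf("unrecognized regulon sign(s)")
    entries$sign <- sg
    entries <- entries[c("regulator", "class", "target", "sign")]
    entries <- entries[corder(entries$regulator, entries$target), , drop = FALSE]
    rownames(entries) <- NULL
  }
  new("RegulonSet", entries = entries)
}

#' @rdname RegulonSet
#' @export
setMethod("regulonTable", "RegulonSet", function(x) x@entries)

setMethod("show", "RegulonSet", function(object) {
  e <- object@entries
  cat(sprintf("RegulonSet: %d regulators, %d signed targets\n",
              length(unique(e$regulator)), nrow(e)))
  if (nrow(e)) {
    cls <- table(e$class[!duplicated(e$regulator)])
    cat("  classes:", paste(names(cls), cls, sep = "=", collapse = ", "), "\n")
  }
  invisible(NULL)
})

#' Construct a GroundTruth
#'
#' @param activities data.frame with columns \code{genotype},
#'   \code{regulator}, \code{activity} (signed non-zero magnitude).
#' @param phenotype phenotype node ID (default \code{"DNA_damage"}).
#' @param direction +1 or -1: the direction in which the phenotype responds.
#' @return A \linkS4class{GroundTruth}.
#' @export
GroundTruth <- function(activities, phenotype = "DNA_damage", direction = 1) {
  activities <- as.data.frame(activities)
  if (!nrow(activities))
    activities <- data.frame(genotype = character(), regulator = character(),
                             activity = numeric())
  activities <- activities[corder(activities$genotype, activities$regulator), ,
                           drop = FALSE]
  rownames(activities) <- NULL
  new("GroundTruth", activities = activities, phenotype = phenotype,
      direction = as.numeric(direction))
}

#' @rdname GroundTruth
#' @export
setMethod("truthTable", "GroundTruth", function(x) x@activities)

setMethod("show", "GroundTruth", function(object) {
  a <- object@activities
  cat(sprintf("GroundTruth: %d active regulator states over %d genotype(s)\n",
              nrow(a), length(unique(a$genotype))))
  cat(sprintf("  phenotype: %s (direction %+d)\n", object@phenotype,
              as.integer(object@direction)))
  invisible(NULL)
})

#' @rdname MechanisticModel
#' @export
setMethod("modelPaths", "MechanisticModel", function(x) x@paths)

#' @rdname MechanisticModel
#' @export
setMethod("phenotypeNode", "MechanisticModel", function(x) x@phenotype)

#' @rdname MechanisticModel
#' @export
setMethod("phenotypeDirection", "MechanisticModel", function(x) x@direction)

setMethod("show", "MechanisticModel", function(object) {
  cat(sprintf("MechanisticModel: %d nodes, %d edges, %d causal paths\n",
              nrow(object@nodes), nrow(object@edges), length(object@paths)))
  cat(sprintf("  phenotype: %s (direction %+d), max path length %d\n",
              object@phenotype, as.integer(object@direction), object@maxLen))
  invisible(NULL)
})

setMethod("show", "SyntheticExperiment", function(object) {
  cat("SyntheticExperiment (seed", object@seed, ")\n")
  cat(sprintf("  proteome: %d x %d | phospho: %d x %d\n",
              nrow(object@proteome), ncol(object@proteome),
              nrow(object@phospho), ncol(object@phospho)))
  cat(sprintf("  network: %d nodes / %d edges; truth: %d active states\n",
              nrow(object@network@nodes), nrow(object@network@edges),
              nrow(object@truth@activities)))
  invisible(NULL)
})
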