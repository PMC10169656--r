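#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom stats cor cutree hclust pt phyper p.adjust rbinom rnorm runif sd
#'   as.dist setNames quantile ks.test
#' @importFrom utils read.delim write.table head combn packageVersion
NULL

#' Log2 intensity matrix with sample annotations
#'
#' An \code{OmicsMatrix} is a \linkS4class{SummarizedExperiment} holding one
#' assay (\code{"log2intensity"}) of log2-scale intensities, features in rows
#' and samples in columns, together with the experimental design
#' (\code{genotype}, \code{treatment}, \code{replicate} in \code{colData}).
#' Two flavours exist: \code{"proteome"} (features are protein identifiers)
#' and \code{"phospho"} (features are phosphosite strings of the form
#' \code{"PROTEIN_T170"}, parsed into protein/residue/position columns of
#' \code{rowData}, optionally with a localization probability
#' \code{loc_prob}).
#'
#' Missing intensities are stored as \code{NA}, never as zero: zeros are real
#' (if implausible) log2 values and would corrupt downstream statistics.
#'
#' @slot kind \code{"proteome"} or \code{"phospho"}.
#' @seealso [readOmicsMatrix()], [differentialStats()]
#' @aliases OmicsMatrix-class
#' @exportClass OmicsMatrix
setClass("OmicsMatrix",
  contains = "SummarizedExperiment",
  representation(kind = "character")
)

setValidity("OmicsMatrix", function(object) {
  msg <- character()
  if (length(object@kind) != 1L || !object@kind %in% c("proteome", "phospho"))
    msg <- c(msg, "kind must be \"proteome\" or \"phospho\"")
  cd <- colData(object)
  need <- c("genotype", "treatment", "replicate")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks column(s): ", paste(miss, collapse = ", ")))
  if (!length(miss) && nrow(cd)) {
    key <- paste(cd$genotype, cd$treatment, cd$replicate, sep = "\r")
    if (anyDuplicated(key))
      msg <- c(msg, "duplicated (genotype, treatment, replicate) combinations")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, paste0("duplicated feature IDs: ",
                         paste(unique(rownames(object)[duplicated(rownames(object))]),
                               collapse = ", ")))
  if (length(object@kind) == 1L && identical(object@kind, "phospho")) {
    rd <- rowData(object)
    if (!all(c("protein", "residue", "position") %in% colnames(rd)))
      msg <- c(msg, "phospho rowData needs protein/residue/position columns")
  }
  if (length(msg)) msg else TRUE
})

#' Signed directed prior-knowledge network
#'
#' Nodes carry an optional molecular-function class (kinase, phosphatase, TF,
#' other) and a phenotype flag; edges are signed causal interactions
#' (\code{+1} activation, \code{-1} inhibition) with a free-text mechanism.
#' Phenotype nodes are sinks: they must have out-degree zero. Identical
#' duplicate edges are collapsed; duplicates that disagree in sign are kept
#' as two parallel candidate edges (literature ambiguity is preserved, a
#' causal path later commits to one of them).
#'
#' @slot nodes data.frame with columns \code{node}, \code{class},
#'   \code{is_phenotype} (and, on scored subgraphs, \code{score}/\code{sign}).
#' @slot edges data.frame with columns \code{source}, \code{target},
#'   \code{sign}, \code{mechanism}.
#' @aliases PriorNetwork-class
#' @seealso [readPriorNetwork()], [generatePriorNetwork()]
#' @exportClass PriorNetwork
setClass("PriorNetwork",
  representation(nodes = "data.frame", edges = "data.frame")
)

setValidity("PriorNetwork", function(object) {
  msg <- character()
  if (!all(c("node", "class", "is_phenotype") %in% colnames(object@nodes)))
    msg <- c(msg, "nodes needs columns node/class/is_phenotype")
  if (!all(c("source", "target", "sign", "mechanism") %in% colnames(object@edges)))
    msg <- c(msg, "edges needs columns source/target/sign/mechanism")
  if (!length(msg)) {
    if (nrow(object@edges) && !all(object@edges$sign %in% c(-1, 1)))
      msg <- c(msg, "edge signs must be +1 or -1")
    if (anyDuplicated(object@nodes$node))
      msg <- c(msg, "duplicated node IDs")
    bad <- setdiff(c(object@edges$source, object@edges$target), object@nodes$node)
    if (length(bad))
      msg <- c(msg, paste0("edges reference unknown nodes: ",
                           paste(unique(bad), collapse = ", ")))
    phen <- object@nodes$node[object@nodes$is_phenotype]
    if (length(phen) && any(object@edges$source %in% phen))
      msg <- c(msg, "phenotype nodes must have out-degree 0")
  }
  if (length(msg)) msg else TRUE
})

#' Signed regulator-to-target sets
#'
#' One row per (regulator, target) pair. For kinases and phosphatases the
#' targets are phosphosite strings and the sign encodes the expected
#' direction of the site's change when the regulator is active (no hidden
#' extra flip for phosphatases). For transcription factors the targets are
#' protein identifiers read against the proteome layer.
#'
#' @slot entries data.frame with columns \code{regulator}, \code{class},
#'   \code{target}, \code{sign}.
#' @aliases RegulonSet-class
#' @seealso [generateRegulons()], [footprintActivity()]
#' @exportClass RegulonSet
setClass("RegulonSet", representation(entries = "data.frame"))

setValidity("RegulonSet", function(object) {
  msg <- character()
  e <- object@entries
  if (!all(c("regulator", "class", "target", "sign") %in% colnames(e)))
    msg <- c(msg, "entries needs columns regulator/class/target/sign")
  if (!length(msg) && nrow(e)) {
    if (!all(e$sign %in% c(-1, 1)))
      msg <- c(msg, "regulon signs must be +1 or -1")
    if (!all(e$class %in% c("kinase", "phosphatase", "TF", "other")))
      msg <- c(msg, "regulator class must be kinase/phosphatase/TF/other")
    if (anyDuplicated(paste(e$regulator, e$target, sep = "\r")))
      msg <- c(msg, "duplicate (regulator, target) pairs")
  }
  if (length(msg)) msg else TRUE
})

#' Ground-truth regulator activities for a synthetic experiment
#'
#' Maps regulators to their true signed activity (sign times magnitude) per
#' genotype context, plus the phenotype node and the direction in which the
#' phenotype responds. This is what downstream inference is benchmarked
#' against.
#'
#' @slot activities data.frame with columns \code{genotype},
#'   \code{regulator}, \code{activity} (signed, non-zero).
#' @slot phenotype phenotype node ID.
#' @slot direction +1 or -1.
#' @aliases GroundTruth-class
#' @seealso [makeGroundTruth()], [simulateExperiment()]
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(activities = "data.frame", phenotype = "character",
                 direction = "numeric")
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  a <- object@activities
  if (!all(c("genotype", "regulator", "activity") %in% colnames(a)))
    msg <- c(msg, "activities needs columns genotype/regulator/activity")
  else if (nrow(a) && any(a$activity == 0 | !is.finite(a$activity)))
    msg <- c(msg, "activity magnitudes must be finite and non-zero")
  if (length(object@phenotype) != 1L)
    msg <- c(msg, "phenotype must be a single node ID")
  if (length(object@direction) != 1L || !object@direction %in% c(-1, 1))
    msg <- c(msg, "direction must be +1 or -1")
  if (length(msg)) msg else TRUE
})

#' Context-specific mechanistic model
#'
#' A pruned, sign-consistent subnetwork of the prior connecting
#' activity-modulated proteins to a phenotype node, together with the causal
#' paths that justify every retained node. Each stored path starts at a
#' scored node and ends at the phenotype; the sign implied by the edge
#' product matches the inferred sign at every scored node it traverses, and
#' the product over the whole path equals the requested phenotype direction.
#'
#' @slot nodes data.frame: \code{node}, \code{class}, \code{score},
#'   \code{sign}, \code{is_phenotype}.
#' @slot edges data.frame: \code{source}, \code{target}, \code{sign},
#'   \code{mechanism}.
#' @slot phenotype phenotype node ID.
#' @slot direction +1 or -1.
#' @slot paths list; each element has \code{nodes} (node sequence) and
#'   \code{edgeSigns}.
#' @slot maxLen path length bound used at construction (edges).
#' @aliases MechanisticModel-class
#' @seealso [connectToPhenotype()], [validateModel()]
#' @exportClass MechanisticModel
setClass("MechanisticModel",
  representation(nodes = "data.frame", edges = "data.frame",
                 phenotype = "character", direction = "numeric",
                 paths = "list", maxLen = "integer")
)

setValidity("MechanisticModel", function(object) {
  msg <- character()
  if (nrow(object@edges)) {
    if (!all(object@edges$sign %in% c(-1, 1)))
      msg <- c(msg, "edge signs must be +1 or -1")
    bad <- setdiff(c(object@edges$source, object@edges$target), object@nodes$node)
    if (length(bad))
      msg <- c(msg, "model edges reference nodes outside the model")
  }
  if (length(msg)) msg else TRUE
})

#' Bundle of one synthetic two-condition study
#'
#' Everything one run of the generator produces: proteome and phospho
#' matrices, the prior network, regulons, regulatory-site annotations, the
#' ground truth, and the seed that reproduces it all bit-identically.
#'
#' @slot proteome,phospho \linkS4class{OmicsMatrix} objects.
#' @slot network \linkS4class{PriorNetwork}.
#' @slot regulons \linkS4class{RegulonSet}.
#' @slot regSites data.frame: \code{protein}, \code{site}, \code{effect}.
#' @slot truth \linkS4class{GroundTruth}.
#' @slot seed integer seed used.
#' @aliases SyntheticExperiment-class
#' @seealso [simulateStudy()], [writeExperiment()]
#' @exportClass SyntheticExperiment
setClass("SyntheticExperiment",
  representation(proteome = "OmicsMatrix", phospho = "OmicsMatrix",
                 network = "PriorNetwork", regulons = "RegulonSet",
                 regSites = "data.frame", truth = "GroundTruth",
                 seed = "integer")
)
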