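#' @rdname OmicsMatrix
#' @param x an object.
#' @export
setGeneric("omicsKind", function(x) standardGeneric("omicsKind"))

#' @rdname OmicsMatrix
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname OmicsMatrix
#' @export
setGeneric("locProb", function(x) standardGeneric("locProb"))

#' @rdname PriorNetwork
#' @param x an object.
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname PriorNetwork
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname RegulonSet
#' @param x an object.
#' @export
setGeneric("regulonTable", function(x) standardGeneric("regulonTable"))

#' @rdname GroundTruth
#' @param x an object.
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' @rdname MechanisticModel
#' @param x an object.
#' @export
setGeneric("modelPaths", function(x) standardGeneric("modelPaths"))

#' @rdname MechanisticModel
#' @export
setGeneric("phenotypeNode", function(x) standardGeneric("phenotypeNode"))

#' @rdname MechanisticModel
#' @export
setGeneric("phenotypeDirection", function(x) standardGeneric("phenotypeDirection"))
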