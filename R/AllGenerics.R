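#' @rdname CellProportions-class
#' @param object,x an object.
#' @export
setGeneric("piHat", function(object) standardGeneric("piHat"))

#' @rdname CellProportions-class
#' @export
setGeneric("priorScores", function(object) standardGeneric("priorScores"))

#' @rdname CellProportions-class
#' @export
setGeneric("deltaHat", function(object) standardGeneric("deltaHat"))

#' @rdname GrexModel-accessors
#' @param object an object.
#' @export
setGeneric("geneId", function(object) standardGeneric("geneId"))

#' @rdname GrexModel-accessors
#' @export
setGeneric("snpInfo", function(object) standardGeneric("snpInfo"))

#' @rdname GrexModel-accessors
#' @param cell which cell-type component: 1 is the cell type of interest,
#'   2 the remaining cells.
#' @export
setGeneric("modelWeights", function(object, cell = 1)
    standardGeneric("modelWeights"))

#' @rdname GrexModel-accessors
#' @export
setGeneric("modelType", function(object) standardGeneric("modelType"))

#' @rdname GrexModel-accessors
#' @export
setGeneric("cvPerformance", function(object) standardGeneric("cvPerformance"))

#' @rdname GrexModel-accessors
#' @export
setGeneric("isTrainable", function(object) standardGeneric("isTrainable"))

#' @rdname GrexPrediction-class
#' @param object an object.
#' @export
setGeneric("grexCell1", function(object) standardGeneric("grexCell1"))

#' @rdname GrexPrediction-class
#' @export
setGeneric("grexCell2", function(object) standardGeneric("grexCell2"))

#' @rdname GrexPrediction-class
#' @export
setGeneric("grexTissue", function(object) standardGeneric("grexTissue"))

#' @rdname AssociationResult-class
#' @param object an object.
#' @export
setGeneric("pTissue", function(object) standardGeneric("pTissue"))

#' @rdname AssociationResult-class
#' @export
setGeneric("pCellLevel", function(object) standardGeneric("pCellLevel"))
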