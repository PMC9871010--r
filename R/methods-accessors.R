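#' @rdname CellProportions-class
#' @aliases piHat,CellProportions-method
#' @export
setMethod("piHat", "CellProportions", function(object)
    setNames(object@piHat, object@sampleIds))

#' @rdname CellProportions-class
#' @export
setMethod("priorScores", "CellProportions", function(object)
    setNames(object@prior, object@sampleIds))

#' @rdname CellProportions-class
#' @export
setMethod("deltaHat", "CellProportions", function(object) object@delta)

#' Accessors for GReX prediction models
#'
#' @name GrexModel-accessors
#' @return \code{geneId}: the gene identifier; \code{snpInfo}: a data.frame
#'   of retained SNPs; \code{modelWeights}: named numeric weights for the
#'   requested cell-type component (tissue models return the same weights
#'   for either); \code{modelType}: \code{"tissue"},
#'   \code{"cell_type_specific"} or \code{"nonspecific"};
#'   \code{cvPerformance}: cross-validated correlation; \code{isTrainable}:
#'   whether any SNP was selected.
NULL

#' @rdname GrexModel-accessors
#' @export
setMethod("geneId", "GrexModel", function(object) object@geneId)

#' @rdname GrexModel-accessors
#' @export
setMethod("snpInfo", "GrexModel", function(object) object@snpInfo)

#' @rdname GrexModel-accessors
#' @export
setMethod("cvPerformance", "GrexModel", function(object)
    object@cvPerformance)

#' @rdname GrexModel-accessors
#' @export
setMethod("isTrainable", "GrexModel", function(object) object@trainable)

#' @rdname GrexModel-accessors
#' @export
setMethod("modelWeights", "TissueModel", function(object, cell = 1)
    setNames(object@weights, object@snpInfo$snp))

#' @rdname GrexModel-accessors
#' @export
setMethod("modelWeights", "CellTypeModel", function(object, cell = 1) {
    stopifnot(cell %in% c(1, 2))
    w <- if (cell == 1) object@weightsCell1 else object@weightsCell2
    setNames(w, object@snpInfo$snp)
})

#' @rdname GrexModel-accessors
#' @export
setMethod("modelType", "TissueModel", function(object) "tissue")

#' @rdname GrexModel-accessors
#' @export
setMethod("modelType", "CellTypeModel", function(object) object@modelType)

#' @rdname GrexPrediction-class
#' @export
setMethod("grexCell1", "GrexPrediction", function(object)
    setNames(object@cell1, object@subjectIds))

#' @rdname GrexPrediction-class
#' @export
setMethod("grexCell2", "GrexPrediction", function(object)
    setNames(object@cell2, object@subjectIds))

#' @rdname GrexPrediction-class
#' @export
setMethod("grexTissue", "GrexPrediction", function(object) {
    if (!length(object@tissue)) return(NULL)
    setNames(object@tissue, object@subjectIds)
})

#' @rdname AssociationResult-class
#' @export
setMethod("pTissue", "AssociationResult", function(object) object@pTissue)

#' @rdname AssociationResult-class
#' @export
setMethod("pCellLevel", "AssociationResult", function(object)
    c(cell1 = object@pCell1, cell2 = object@pCell2))

## show methods -------------------------------------------------------------

setMethod("show", "CellProportions", function(object) {
    cat("CellProportions with", length(object@sampleIds), "samples\n")
    cat("  piHat: mean", signif(mean(object@piHat), 3),
        " range [", signif(min(object@piHat), 3), ",",
        signif(max(object@piHat), 3), "]\n")
    cat("  delta:", signif(object@delta, 4),
        " signature genes:", length(object@mixture@geneIds), "\n")
    if (object@nBoot > 0L)
        cat("  bagged over", object@nBoot, "bootstraps, trim",
            object@trimFrac, "per tail\n")
    cat("  converged:", object@converged,
        " objective:", signif(object@objective, 6), "\n")
})

setMethod("show", "TissueModel", function(object) {
    cat("TissueModel for", object@geneId, "\n")
    cat(" ", nrow(object@snpInfo), "SNPs retained; cv r =",
        signif(object@cvPerformance, 3),
        if (!object@trainable) "(untrainable: no predictive SNPs)" else "",
        "\n")
})

setMethod("show", "CellTypeModel", function(object) {
    cat("CellTypeModel for", object@geneId, "(", object@modelType, ")\n")
    cat(" ", nrow(object@snpInfo), "SNPs retained; cv r =",
        signif(object@cvPerformance, 3),
        if (!object@trainable) "(untrainable: no predictive SNPs)" else "",
        "\n")
    if (nrow(object@diffCI))
        cat("  weight-difference CIs from", object@nBoot,
            "bootstraps on", nrow(object@diffCI), "SNPs\n")
})

setMethod("show", "GrexPrediction", function(object) {
    cat("GrexPrediction for", length(object@subjectIds), "subjects",
        if (length(object@tissue)) "(with tissue-level combination)" else "",
        "\n")
})

setMethod("show", "AssociationResult", function(object) {
    cat("AssociationResult for", object@geneId,
        "[mode:", object@mode, "]\n")
    if (object@testable) {
        cat("  p cell1 =", format(object@pCell1, digits = 3),
            " p cell2 =", format(object@pCell2, digits = 3),
            " p tissue =", format(object@pTissue, digits = 3), "\n")
    } else {
        cat("  not testable\n")
    }
})

setMethod("show", "SimulationConfig", function(object) {
    threeCell <- object@threeCell != "none"
    cat("SimulationConfig:", object@snpExp, "SNP-Exp;",
        "eta = (", object@eta1, ",", object@eta2,
        if (threeCell) paste(",", object@eta3) else "", ")\n")
    cat("  nTrain", object@nTrain, " nGwas", object@nGwas,
        " nSnps", object@nSnps, " reps", object@nReps, "\n")
    cat("  b0", object@b0, " |b1|", object@b1Mag, " |b2|", object@b2Mag,
        if (threeCell) paste(" latent third cell:", object@threeCell)
        else "", "\n")
    cat("  pi misspecification:", object@piMisspec, "\n")
})
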