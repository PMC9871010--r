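#' @import methods
#' @importFrom stats dnorm dbeta optim optimize uniroot rbinom rbeta rnorm
#'   runif plogis glm binomial gaussian coef cor sd lm.fit quantile
#'   p.adjust wilcox.test predict setNames var pnorm
#' @importFrom utils read.delim write.table packageVersion
NULL

## ---------------------------------------------------------------------------
## Signature-gene mixture parameters
## ---------------------------------------------------------------------------

#' Two-component Gaussian parameters for signature genes
#'
#' Per-gene means and standard deviations of the expression of a signature
#' gene in the cell type of interest (component 1) and in all other cells
#' (component 2). Bulk expression of sample i is modelled as the
#' proportion-weighted mixture \code{pi_i * s + (1 - pi_i) * t}.
#'
#' @slot geneIds character vector of signature gene identifiers.
#' @slot muCell1 numeric, per-gene mean in the cell type of interest.
#' @slot muCell2 numeric, per-gene mean in the other cells.
#' @slot sigmaCell1 numeric, per-gene standard deviation (> 0) in the cell
#'   type of interest.
#' @slot sigmaCell2 numeric, per-gene standard deviation (> 0) in the other
#'   cells.
#'
#' @export
setClass("SignatureMixture",
    representation(
        geneIds = "character",
        muCell1 = "numeric",
        muCell2 = "numeric",
        sigmaCell1 = "numeric",
        sigmaCell2 = "numeric"
    )
)

setValidity("SignatureMixture", function(object) {
    n <- length(object@geneIds)
    msg <- character()
    if (any(lengths(list(object@muCell1, object@muCell2,
                         object@sigmaCell1, object@sigmaCell2)) != n))
        msg <- c(msg, "all parameter vectors must match length(geneIds)")
    if (any(!is.finite(object@sigmaCell1)) || any(object@sigmaCell1 <= 0) ||
        any(!is.finite(object@sigmaCell2)) || any(object@sigmaCell2 <= 0))
        msg <- c(msg, "all standard deviations must be finite and > 0")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Cell proportions
## ---------------------------------------------------------------------------

#' Estimated proportions of the cell type of interest in bulk samples
#'
#' Holds per-sample proportion estimates together with the prior enrichment
#' scores they were anchored to, the fitted concentration of the prior, the
#' fitted signature-gene mixture, and bagging provenance.
#'
#' @slot sampleIds character vector of sample identifiers.
#' @slot piHat numeric in (0, 1), per-sample proportion of the cell type of
#'   interest.
#' @slot prior numeric in (0, 1), the rescaled prior score per sample.
#' @slot delta numeric(1), fitted concentration of the Beta prior link
#'   (larger means the prior is trusted more).
#' @slot mixture a \linkS4class{SignatureMixture} from the (full-data) fit.
#' @slot nBoot integer(1), number of bootstrap fits aggregated (0 for a
#'   single fit).
#' @slot trimFrac numeric(1), per-tail trim fraction used in the bagged mean.
#' @slot bootSpread numeric, per-sample standard deviation across retained
#'   bootstrap estimates (zero-length for single fits).
#' @slot converged logical(1), whether the coordinate ascent met its
#'   tolerance.
#' @slot objective numeric(1), final value of the joint log-likelihood.
#'
#' @export
setClass("CellProportions",
    representation(
        sampleIds = "character",
        piHat = "numeric",
        prior = "numeric",
        delta = "numeric",
        mixture = "SignatureMixture",
        nBoot = "integer",
        trimFrac = "numeric",
        bootSpread = "numeric",
        converged = "logical",
        objective = "numeric"
    )
)

setValidity("CellProportions", function(object) {
    msg <- character()
    if (length(object@piHat) != length(object@sampleIds))
        msg <- c(msg, "piHat must match length(sampleIds)")
    if (any(object@piHat <= 0) || any(object@piHat >= 1))
        msg <- c(msg, "every piHat must lie strictly in (0, 1)")
    if (length(object@bootSpread) && any(object@bootSpread < 0))
        msg <- c(msg, "bootSpread must be non-negative")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## GReX prediction models
## ---------------------------------------------------------------------------

#' Virtual parent of GReX prediction models
#' @export
setClass("GrexModel", representation("VIRTUAL",
    geneId = "character",
    snpInfo = "data.frame",
    covWeights = "numeric",
    cvPerformance = "numeric",
    trainable = "logical"
))

#' Tissue-level GReX prediction model
#'
#' Sparse elastic-net SNP weights for predicting a gene's tissue-level
#' genetically regulated expression, ignoring cell composition. SNPs whose
#' weight shrinks to zero are dropped from storage.
#'
#' @slot geneId character(1).
#' @slot snpInfo data.frame with columns \code{snp}, \code{chrom},
#'   \code{pos}, \code{refAllele}, \code{effAllele} (rows: retained SNPs).
#' @slot weights numeric, effect-allele dosage weights for retained SNPs.
#' @slot intercept numeric(1).
#' @slot covWeights numeric, covariate weights (named).
#' @slot cvPerformance numeric(1), cross-validated correlation between
#'   prevalidated prediction and observed expression.
#' @slot trainable logical(1), FALSE when no SNP survived selection.
#'
#' @export
setClass("TissueModel", contains = "GrexModel",
    representation(weights = "numeric", intercept = "numeric")
)

#' Cell-type-level GReX prediction model
#'
#' SNP weights for the cell type of interest (cell 1) and for all other
#' cells (cell 2), fitted by symmetric penalization of the mixture
#' decomposition, with bootstrap evidence on the per-SNP weight difference.
#' When the stability bootstrap cannot distinguish the two cell types the
#' model collapses to a nonspecific model with identical weights.
#'
#' @slot geneId character(1).
#' @slot snpInfo data.frame describing retained SNPs (see
#'   \linkS4class{TissueModel}).
#' @slot weightsCell1 numeric, weights in the cell type of interest.
#' @slot weightsCell2 numeric, weights in the other cells.
#' @slot interceptCell1 numeric(1).
#' @slot interceptCell2 numeric(1).
#' @slot covWeights numeric, shared covariate weights.
#' @slot modelType character(1), \code{"cell_type_specific"} or
#'   \code{"nonspecific"}.
#' @slot diffCI data.frame with columns \code{snp}, \code{lo}, \code{hi}:
#'   bootstrap percentile CI of the weight difference (cell1 - cell2) for
#'   each SNP that entered the stability assessment.
#' @slot nBoot integer(1), bootstrap resamples used.
#' @slot cvPerformance numeric(1), cross-validated correlation.
#' @slot trainable logical(1).
#'
#' @export
setClass("CellTypeModel", contains = "GrexModel",
    representation(
        weightsCell1 = "numeric",
        weightsCell2 = "numeric",
        interceptCell1 = "numeric",
        interceptCell2 = "numeric",
        modelType = "character",
        diffCI = "data.frame",
        nBoot = "integer"
    )
)

setValidity("CellTypeModel", function(object) {
    msg <- character()
    if (!object@modelType %in% c("cell_type_specific", "nonspecific"))
        msg <- c(msg, "modelType must be 'cell_type_specific' or 'nonspecific'")
    if (length(object@weightsCell1) != length(object@weightsCell2))
        msg <- c(msg, "weightsCell1 and weightsCell2 must have equal length")
    if (object@modelType == "nonspecific" &&
        length(object@weightsCell1) &&
        !isTRUE(all.equal(object@weightsCell1, object@weightsCell2,
                          tolerance = 1e-12)))
        msg <- c(msg, "nonspecific models must have identical weights")
    if (nrow(object@diffCI) && any(object@diffCI$lo > object@diffCI$hi))
        msg <- c(msg, "diffCI bounds must satisfy lo <= hi")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Predictions and association results
## ---------------------------------------------------------------------------

#' Predicted genetically regulated expression
#'
#' Per-subject GReX in each cell type (identical for nonspecific and
#' tissue-level models) and, when proportions are supplied, the combined
#' tissue-level prediction.
#'
#' @slot subjectIds character.
#' @slot cell1 numeric, GReX in the cell type of interest.
#' @slot cell2 numeric, GReX in the other cells.
#' @slot tissue numeric, proportion-weighted tissue-level GReX
#'   (zero-length when proportions were not supplied).
#'
#' @export
setClass("GrexPrediction",
    representation(
        subjectIds = "character",
        cell1 = "numeric",
        cell2 = "numeric",
        tissue = "numeric"
    )
)

setValidity("GrexPrediction", function(object) {
    msg <- character()
    n <- length(object@subjectIds)
    if (length(object@cell1) != n || length(object@cell2) != n)
        msg <- c(msg, "cell1/cell2 must match length(subjectIds)")
    if (length(object@tissue) && length(object@tissue) != n)
        msg <- c(msg, "tissue must be empty or match length(subjectIds)")
    if (any(!is.finite(object@cell1)) || any(!is.finite(object@cell2)))
        msg <- c(msg, "predictions must be finite")
    if (length(msg)) msg else TRUE
})

#' Per-gene association test result
#'
#' Cell-type-level effects and p-values with their Cauchy combination into a
#' single tissue-level p-value under the composite null of no association in
#' any cell type.
#'
#' @slot geneId character(1).
#' @slot mode character(1): \code{"joint"} (both GReX in one model),
#'   \code{"separate"} (two marginal models, used when the cell-level GReX
#'   are nearly collinear) or \code{"single"} (nonspecific model, one
#'   tissue-level test).
#' @slot effectCell1,seCell1,pCell1 numeric(1), Wald statistics for the cell
#'   type of interest.
#' @slot effectCell2,seCell2,pCell2 numeric(1), Wald statistics for the
#'   other cells.
#' @slot tCauchy numeric(1), combined Cauchy statistic.
#' @slot pTissue numeric(1), combined tissue-level p-value.
#' @slot testable logical(1), FALSE when the model has no predictive SNPs or
#'   both GReX are constant.
#'
#' @export
setClass("AssociationResult",
    representation(
        geneId = "character",
        mode = "character",
        effectCell1 = "numeric", seCell1 = "numeric", pCell1 = "numeric",
        effectCell2 = "numeric", seCell2 = "numeric", pCell2 = "numeric",
        tCauchy = "numeric",
        pTissue = "numeric",
        testable = "logical"
    )
)

setValidity("AssociationResult", function(object) {
    msg <- character()
    if (!object@mode %in% c("joint", "separate", "single", "none"))
        msg <- c(msg, "mode must be joint, separate, single or none")
    pv <- c(object@pCell1, object@pCell2, object@pTissue)
    pv <- pv[!is.na(pv)]
    if (length(pv) && (any(pv <= 0) || any(pv > 1)))
        msg <- c(msg, "p-values must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Simulation configuration
## ---------------------------------------------------------------------------

#' Configuration of a type-I-error / power simulation study
#'
#' Captures one scenario of the simulation design: training and GWAS sample
#' sizes, the genotype block, the distribution of the minor cell-type
#' proportion, the SNP-expression architecture in each cell type, the
#' expression-disease coefficients of the logistic disease model, and the
#' proportion-misspecification scenario injected into training.
#'
#' @slot nTrain,nGwas,nSnps integer(1): sample sizes and SNP block width.
#' @slot mafRange numeric(2) within (0, 0.5]: uniform range of minor allele
#'   frequencies.
#' @slot piShape1,piShape2 numeric(1): Beta parameters of the minor
#'   cell-type proportion (defaults Beta(2, 3), mean 0.4).
#' @slot b0 numeric(1): mean expression offset of cell 1 at zero dosage.
#' @slot b1Mag,b2Mag,b3Mag numeric(1): magnitudes of the causal SNP effect
#'   in cells 1, 2 and (optionally) a latent third cell; signs are drawn
#'   with equal probability each replicate.
#' @slot snpExp character(1): \code{"homogeneous"} (one shared causal SNP)
#'   or \code{"heterogeneous"} (distinct causal SNPs per cell type).
#' @slot eta1,eta2,eta3 numeric(1): expression-disease log-odds coefficients.
#' @slot piMisspec character(1): one of \code{"none"}, \code{"scale_0.8"},
#'   \code{"affine_0.7_0.2"}, \code{"beta_conc_50"}, \code{"beta_conc_5.5"}.
#' @slot threeCell character(1): \code{"none"} (two cell types),
#'   \code{"shared"} (latent third cell with the same SNP effects as cell
#'   2) or \code{"distinct"} (its own causal SNP with magnitude
#'   \code{b3Mag}).
#' @slot nReps integer(1): Monte Carlo replicates.
#' @slot alphaLevel numeric(1): nominal test level.
#' @slot enetAlpha numeric(1): elastic-net mixing parameter.
#' @slot nFolds integer(1): cross-validation folds.
#' @slot nStabilityBoot integer(1): stability-selection bootstraps.
#' @slot seed integer(1): master seed.
#'
#' @export
setClass("SimulationConfig",
    representation(
        nTrain = "integer", nGwas = "integer", nSnps = "integer",
        mafRange = "numeric",
        piShape1 = "numeric", piShape2 = "numeric",
        b0 = "numeric", b1Mag = "numeric", b2Mag = "numeric",
        b3Mag = "numeric",
        snpExp = "character",
        eta1 = "numeric", eta2 = "numeric", eta3 = "numeric",
        piMisspec = "character",
        threeCell = "character",
        nReps = "integer", alphaLevel = "numeric",
        enetAlpha = "numeric", nFolds = "integer",
        nStabilityBoot = "integer",
        seed = "integer"
    )
)

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (object@mafRange[1] <= 0 || object@mafRange[2] > 0.5 ||
        object@mafRange[1] > object@mafRange[2])
        msg <- c(msg, "mafRange must lie within (0, 0.5] and be ordered")
    if (!object@snpExp %in% c("homogeneous", "heterogeneous"))
        msg <- c(msg, "snpExp must be 'homogeneous' or 'heterogeneous'")
    if (!object@piMisspec %in% c("none", "scale_0.8", "affine_0.7_0.2",
                                 "beta_conc_50", "beta_conc_5.5"))
        msg <- c(msg, "unknown piMisspec scenario")
    if (!object@threeCell %in% c("none", "shared", "distinct"))
        msg <- c(msg, "threeCell must be 'none', 'shared' or 'distinct'")
    if (object@alphaLevel <= 0 || object@alphaLevel >= 1)
        msg <- c(msg, "alphaLevel must lie in (0, 1)")
    if (length(msg)) msg else TRUE
})
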