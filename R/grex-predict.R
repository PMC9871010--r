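#' Predict genetically regulated expression
#'
#' Applies stored SNP weights to new dosage data. GReX is the genetic
#' component only: no intercept and no covariate contribution is added, so
#' predictions are comparable across cohorts that lack the training
#' covariates. For cell-type models the prediction is computed per cell
#' type; when per-subject proportions are supplied the tissue-level
#' combination \code{pi * cell1 + (1 - pi) * cell2} is added.
#'
#' Model SNPs absent from \code{Xnew} are tolerated up to
#' \code{maxMissingFrac} (their weight is dropped, with a warning); beyond
#' that the prediction errors and lists the missing SNPs.
#'
#' @param model a \linkS4class{TissueModel} or \linkS4class{CellTypeModel}.
#' @param Xnew subjects x SNPs dosage matrix with SNP ids as column names,
#'   harmonized to the model's effect alleles (see
#'   \code{\link{harmonizeGenotypes}}).
#' @param piNew optional per-subject proportions of the cell type of
#'   interest, used only for the tissue-level combination.
#' @param maxMissingFrac maximum tolerated fraction of model SNPs missing
#'   from \code{Xnew} (default 0.2).
#' @return a \linkS4class{GrexPrediction}.
#' @export
setGeneric("predictGrex", function(model, Xnew, piNew = NULL,
                                   maxMissingFrac = 0.2)
    standardGeneric("predictGrex"))

.applyWeights <- function(w, snps, Xnew, maxMissingFrac) {
    Xnew <- as.matrix(Xnew)
    if (!length(snps)) return(rep(0, nrow(Xnew)))
    if (is.null(colnames(Xnew)))
        stop("Xnew must have SNP ids as column names")
    present <- snps %in% colnames(Xnew)
    if (mean(!present) > maxMissingFrac)
        stop("more than ", round(100 * maxMissingFrac), "% of model SNPs ",
             "missing from the genotype data: ",
             paste(snps[!present], collapse = ", "))
    if (any(!present))
        warning("dropping ", sum(!present), " model SNP(s) absent from the ",
                "genotype data", call. = FALSE)
    drop(Xnew[, snps[present], drop = FALSE] %*% w[present])
}

.subjectIds <- function(Xnew) {
    if (!is.null(rownames(Xnew))) rownames(Xnew) else
        paste0("subject", seq_len(nrow(Xnew)))
}

#' @rdname predictGrex
#' @export
setMethod("predictGrex", "TissueModel",
    function(model, Xnew, piNew = NULL, maxMissingFrac = 0.2) {
        yhat <- .applyWeights(model@weights, model@snpInfo$snp, Xnew,
                              maxMissingFrac)
        new("GrexPrediction", subjectIds = .subjectIds(Xnew),
            cell1 = yhat, cell2 = yhat, tissue = yhat)
    })

#' @rdname predictGrex
#' @export
setMethod("predictGrex", "CellTypeModel",
    function(model, Xnew, piNew = NULL, maxMissingFrac = 0.2) {
        y1 <- .applyWeights(model@weightsCell1, model@snpInfo$snp, Xnew,
                            maxMissingFrac)
        y2 <- .applyWeights(model@weightsCell2, model@snpInfo$snp, Xnew,
                            maxMissingFrac)
        tissue <- if (!is.null(piNew)) {
            stopifnot(length(piNew) == nrow(Xnew))
            piNew * y1 + (1 - piNew) * y2
        } else numeric(0)
        new("GrexPrediction", subjectIds = .subjectIds(Xnew),
            cell1 = y1, cell2 = y2, tissue = tissue)
    })

.tissuePrediction <- function(model, X, pi, maxMissingFrac = 0.2) {
    if (is(model, "CellTypeModel") &&
        modelType(model) == "cell_type_specific" && is.null(pi))
        stop("tissue-level prediction from a cell-type-specific model ",
             "requires per-subject proportions")
    pred <- predictGrex(model, X, piNew = pi,
                        maxMissingFrac = maxMissingFrac)
    tis <- grexTissue(pred)
    if (is.null(tis)) unname(grexCell1(pred)) else unname(tis)
}

#' Evaluate and compare prediction performance on held-out data
#'
#' Computes, per gene, the Pearson correlation between the predicted
#' tissue-level GReX and the observed expression in a held-out set. When
#' two or more methods' model lists are supplied, methods are compared by a
#' paired two-sided Wilcoxon signed-rank test on the per-gene correlation
#' vectors. Genes whose prediction has zero variance get r = 0 and are
#' flagged.
#'
#' @param models either a list of \linkS4class{GrexModel} objects (one per
#'   gene) or a named list of such lists, one per method.
#' @param yTrue held-out samples x genes expression matrix (columns in the
#'   order of each method's model list).
#' @param X held-out dosage matrix with SNP ids as column names.
#' @param pi optional held-out proportions of the cell type of interest,
#'   required for tissue-level predictions from cell-type-specific models.
#' @return for a single method, a data.frame (gene, r, zeroVariance); for
#'   several, a list with \code{perGene} (wide data.frame of correlations)
#'   and \code{comparisons} (pairwise Wilcoxon p-values).
#' @export
evaluatePrediction <- function(models, yTrue, X, pi = NULL) {
    yTrue <- as.matrix(yTrue)
    oneMethod <- function(ml) {
        stopifnot(length(ml) == ncol(yTrue))
        r <- numeric(length(ml))
        flag <- logical(length(ml))
        for (j in seq_along(ml)) {
            pred <- .tissuePrediction(ml[[j]], X, pi)
            if (sd(pred) == 0) {
                r[j] <- 0
                flag[j] <- TRUE
            } else {
                r[j] <- cor(pred, yTrue[, j])
            }
        }
        data.frame(gene = vapply(ml, geneId, character(1)),
                   r = r, zeroVariance = flag, stringsAsFactors = FALSE)
    }
    if (length(models) && is(models[[1L]], "GrexModel"))
        return(oneMethod(models))

    stopifnot(is.list(models), length(models) >= 2,
              !is.null(names(models)))
    per <- lapply(models, oneMethod)
    wide <- per[[1L]]["gene"]
    for (nm in names(per)) wide[[paste0("r.", nm)]] <- per[[nm]]$r
    pairs <- utils::combn(names(per), 2L)
    comparisons <- data.frame(
        methodA = pairs[1L, ], methodB = pairs[2L, ],
        wilcoxonP = apply(pairs, 2L, function(pr) {
            a <- per[[pr[1L]]]$r; b <- per[[pr[2L]]]$r
            if (isTRUE(all.equal(a, b))) 1 else
                wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value
        }),
        stringsAsFactors = FALSE)
    list(perGene = wide, comparisons = comparisons)
}
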