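## Association testing under the composite null: no association between the
## predicted GReX and the phenotype in any cell type of the tissue.

.resolveFamily <- function(family) {
    if (is.character(family))
        family <- switch(family,
                         binomial = binomial(),
                         gaussian = gaussian(),
                         stop("unsupported family: ", family))
    stopifnot(inherits(family, "family"))
    family
}

.waldRow <- function(fit, term) {
    sm <- summary(fit)$coefficients
    if (!term %in% rownames(sm))
        return(c(effect = NA_real_, se = NA_real_, p = NA_real_))
    est <- sm[term, 1L]
    se <- sm[term, 2L]
    p <- sm[term, 4L]
    c(effect = est, se = se, p = max(p, .Machine$double.xmin))
}

.glmGuarded <- function(formula, data, family, geneId) {
    withCallingHandlers(
        glm(formula, data = data, family = family),
        warning = function(w) {
            if (grepl("fitted probabilities numerically 0 or 1",
                      conditionMessage(w)))
                stop("perfect separation in the logistic fit for gene ",
                     geneId, call. = FALSE)
            invokeRestart("muffleWarning")
        })
}

#' Cell-type-level association tests
#'
#' Regresses the phenotype on the per-cell-type GReX predictions through a
#' generalized linear model. When the two cell-level predictions are nearly
#' collinear (|r| >= corCutoff, which always holds for nonspecific models)
#' or one of them is constant, two separate marginal models are fitted;
#' otherwise both predictions enter one joint model. Two-sided Wald
#' p-values are reported per cell type.
#'
#' @param grex a \linkS4class{GrexPrediction}.
#' @param phenotype numeric (or 0/1) outcome vector.
#' @param covariates optional data.frame or matrix of subject covariates.
#' @param family \code{"binomial"}, \code{"gaussian"} or a family object.
#' @param corCutoff collinearity threshold for choosing separate marginal
#'   fits (default 0.99).
#' @param geneId gene label used in error messages.
#' @return list with per-cell effect, se and p-value, and the fitting
#'   \code{mode} (\code{"joint"} or \code{"separate"}); \code{testable} is
#'   FALSE when both predictions are constant.
#' @export
cellLevelTest <- function(grex, phenotype, covariates = NULL,
                          family = "binomial", corCutoff = 0.99,
                          geneId = "gene") {
    stopifnot(is(grex, "GrexPrediction"))
    family <- .resolveFamily(family)
    y1 <- unname(grexCell1(grex))
    y2 <- unname(grexCell2(grex))
    n <- length(phenotype)
    stopifnot(length(y1) == n)
    if (n < 50)
        warning("fewer than 50 subjects; association tests may be unstable",
                call. = FALSE)

    v1 <- sd(y1) > 0
    v2 <- sd(y2) > 0
    if (!v1 && !v2)
        return(list(effectCell1 = NA_real_, seCell1 = NA_real_,
                    pCell1 = NA_real_, effectCell2 = NA_real_,
                    seCell2 = NA_real_, pCell2 = NA_real_,
                    mode = "none", testable = FALSE))

    covDf <- if (is.null(covariates)) NULL else as.data.frame(covariates)
    baseDf <- data.frame(.d = phenotype)
    if (!is.null(covDf)) baseDf <- cbind(baseDf, covDf)
    covTerms <- if (is.null(covDf)) "" else
        paste("+", paste(names(covDf), collapse = " + "))

    separate <- !v1 || !v2 ||
        abs(cor(y1, y2)) >= corCutoff

    if (separate) {
        res1 <- if (v1) {
            df <- cbind(baseDf, .g = y1)
            .waldRow(.glmGuarded(stats::as.formula(paste(".d ~ .g", covTerms)),
                                 df, family, geneId), ".g")
        } else c(effect = NA_real_, se = NA_real_, p = NA_real_)
        res2 <- if (v2) {
            df <- cbind(baseDf, .g = y2)
            .waldRow(.glmGuarded(stats::as.formula(paste(".d ~ .g", covTerms)),
                                 df, family, geneId), ".g")
        } else c(effect = NA_real_, se = NA_real_, p = NA_real_)
        mode <- "separate"
    } else {
        df <- cbind(baseDf, .g1 = y1, .g2 = y2)
        fit <- .glmGuarded(stats::as.formula(paste(".d ~ .g1 + .g2",
                                                   covTerms)),
                           df, family, geneId)
        res1 <- .waldRow(fit, ".g1")
        res2 <- .waldRow(fit, ".g2")
        mode <- "joint"
    }
    list(effectCell1 = unname(res1["effect"]), seCell1 = unname(res1["se"]),
         pCell1 = unname(res1["p"]),
         effectCell2 = unname(res2["effect"]), seCell2 = unname(res2["se"]),
         pCell2 = unname(res2["p"]),
         mode = mode, testable = TRUE)
}

#' Cauchy combination of cell-type-level p-values
#'
#' Aggregates two p-values through the tangent transform to standard Cauchy
#' variates: \code{T = w1 * tan(pi * (0.5 - p1)) + w2 * tan(pi * (0.5 - p2))}
#' and \code{p = 0.5 - atan(T) / pi}. The combination is valid under
#' arbitrary dependence of the component tests, which matters here because
#' the two cell-level GReX are predicted from the same genotypes. With the
#' default equal weights summing to one, the combined p-value always lies
#' between the two inputs and \code{cauchyCombine(p, p) == p}. Setting
#' \code{weights = c(1, 1)} gives the plain unweighted two-term sum for
#' comparison (anti-conservative under dependence).
#'
#' If one p-value is NA (e.g. a constant prediction in one cell type), the
#' other is returned unchanged.
#'
#' @param pU,pV p-values in (0, 1); clipped into [1e-15, 1 - 1e-15] before
#'   the tangent transform so extreme inputs stay finite.
#' @param weights two nonnegative weights (default c(0.5, 0.5)).
#' @return list with \code{tCauchy} and \code{pTissue}.
#' @examples
#' cauchyCombine(0.01, 0.5)   # approximately 0.02
#' cauchyCombine(0.3, 0.3)    # exactly 0.3
#' @export
cauchyCombine <- function(pU, pV, weights = c(0.5, 0.5)) {
    stopifnot(length(weights) == 2, all(weights >= 0), sum(weights) > 0)
    if (is.na(pU) && is.na(pV)) stop("both p-values are NA")
    clip <- function(p) pmin(pmax(p, 1e-15), 1 - 1e-15)
    if (is.na(pU)) return(list(tCauchy = tan(pi * (0.5 - clip(pV))),
                               pTissue = pV))
    if (is.na(pV)) return(list(tCauchy = tan(pi * (0.5 - clip(pU))),
                               pTissue = pU))
    stopifnot(pU > 0, pU <= 1, pV > 0, pV <= 1)
    tC <- weights[1L] * tan(pi * (0.5 - clip(pU))) +
        weights[2L] * tan(pi * (0.5 - clip(pV)))
    if (!is.finite(tC)) stop("non-finite Cauchy statistic")
    list(tCauchy = tC, pTissue = 0.5 - atan(tC) / pi)
}

#' Test one gene for GReX-disease association
#'
#' Predicts GReX from the gene's model, then tests the composite null of no
#' association in any cell type. Cell-type-specific models go through
#' \code{\link{cellLevelTest}} followed by \code{\link{cauchyCombine}};
#' nonspecific and tissue-level models reduce exactly to a single
#' tissue-level test (the two cell-level predictions coincide), reported
#' with \code{mode = "single"}.
#'
#' @param model a trained \linkS4class{CellTypeModel} or
#'   \linkS4class{TissueModel}.
#' @param genotypes subjects x SNPs dosage matrix, harmonized to the model.
#' @param phenotype outcome vector.
#' @param covariates optional covariate data.frame.
#' @param family \code{"binomial"} (default) or \code{"gaussian"}.
#' @param weights Cauchy combination weights (see
#'   \code{\link{cauchyCombine}}).
#' @param corCutoff collinearity threshold passed to
#'   \code{\link{cellLevelTest}}.
#' @return an \linkS4class{AssociationResult}.
#' @export
associateGene <- function(model, genotypes, phenotype, covariates = NULL,
                          family = "binomial", weights = c(0.5, 0.5),
                          corCutoff = 0.99) {
    gid <- geneId(model)
    if (!isTrainable(model))
        return(new("AssociationResult", geneId = gid, mode = "none",
                   effectCell1 = NA_real_, seCell1 = NA_real_,
                   pCell1 = NA_real_, effectCell2 = NA_real_,
                   seCell2 = NA_real_, pCell2 = NA_real_,
                   tCauchy = NA_real_, pTissue = NA_real_,
                   testable = FALSE))

    pred <- predictGrex(model, genotypes)
    specific <- is(model, "CellTypeModel") &&
        modelType(model) == "cell_type_specific"

    if (!specific) {
        ## nonspecific / tissue model: one tissue-level test
        y <- unname(grexCell1(pred))
        if (sd(y) == 0)
            return(new("AssociationResult", geneId = gid, mode = "none",
                       effectCell1 = NA_real_, seCell1 = NA_real_,
                       pCell1 = NA_real_, effectCell2 = NA_real_,
                       seCell2 = NA_real_, pCell2 = NA_real_,
                       tCauchy = NA_real_, pTissue = NA_real_,
                       testable = FALSE))
        fam <- .resolveFamily(family)
        covDf <- if (is.null(covariates)) NULL else as.data.frame(covariates)
        df <- data.frame(.d = phenotype, .g = y)
        covTerms <- ""
        if (!is.null(covDf)) {
            df <- cbind(df, covDf)
            covTerms <- paste("+", paste(names(covDf), collapse = " + "))
        }
        row <- .waldRow(.glmGuarded(
            stats::as.formula(paste(".d ~ .g", covTerms)), df, fam, gid),
            ".g")
        cc <- cauchyCombine(row["p"], row["p"], weights = weights)
        return(new("AssociationResult", geneId = gid, mode = "single",
                   effectCell1 = unname(row["effect"]),
                   seCell1 = unname(row["se"]), pCell1 = unname(row["p"]),
                   effectCell2 = unname(row["effect"]),
                   seCell2 = unname(row["se"]), pCell2 = unname(row["p"]),
                   tCauchy = cc$tCauchy, pTissue = unname(row["p"]),
                   testable = TRUE))
    }

    ct <- cellLevelTest(pred, phenotype, covariates = covariates,
                        family = family, corCutoff = corCutoff,
                        geneId = gid)
    if (!ct$testable)
        return(new("AssociationResult", geneId = gid, mode = "none",
                   effectCell1 = NA_real_, seCell1 = NA_real_,
                   pCell1 = NA_real_, effectCell2 = NA_real_,
                   seCell2 = NA_real_, pCell2 = NA_real_,
                   tCauchy = NA_real_, pTissue = NA_real_,
                   testable = FALSE))
    cc <- cauchyCombine(ct$pCell1, ct$pCell2, weights = weights)
    new("AssociationResult", geneId = gid, mode = ct$mode,
        effectCell1 = ct$effectCell1, seCell1 = ct$seCell1,
        pCell1 = ct$pCell1,
        effectCell2 = ct$effectCell2, seCell2 = ct$seCell2,
        pCell2 = ct$pCell2,
        tCauchy = cc$tCauchy, pTissue = cc$pTissue,
        testable = TRUE)
}

#' Transcriptome-wide multiple-testing summary
#'
#' Collects per-gene association results into one table with Bonferroni and
#' Benjamini-Hochberg annotation. Untestable genes (no predictive SNPs) are
#' excluded from the multiple-testing denominator and flagged.
#'
#' @param results list of \linkS4class{AssociationResult} objects.
#' @param fwer family-wise error rate for the Bonferroni threshold
#'   (default 0.05).
#' @param fdr Benjamini-Hochberg false discovery rate (default 0.10).
#' @return data.frame sorted by tissue-level p-value, with columns
#'   \code{significantBonferroni} and \code{discoveryFDR}; the Bonferroni
#'   threshold (\code{fwer} / number of testable genes) is stored in
#'   attribute \code{"bonferroniThreshold"}.
#' @export
transcriptomeWide <- function(results, fwer = 0.05, fdr = 0.10) {
    stopifnot(length(results) >= 1)
    df <- do.call(rbind, lapply(results, function(r) {
        data.frame(gene = r@geneId, mode = r@mode,
                   effectCell1 = r@effectCell1, seCell1 = r@seCell1,
                   pCell1 = r@pCell1,
                   effectCell2 = r@effectCell2, seCell2 = r@seCell2,
                   pCell2 = r@pCell2,
                   tCauchy = r@tCauchy, pTissue = r@pTissue,
                   testable = r@testable, stringsAsFactors = FALSE)
    }))
    nTestable <- sum(df$testable)
    if (nTestable == 0) stop("no testable genes")
    threshold <- fwer / nTestable

    df$significantBonferroni <- df$testable & !is.na(df$pTissue) &
        df$pTissue < threshold
    df$pAdjustBH <- NA_real_
    df$pAdjustBH[df$testable] <- p.adjust(df$pTissue[df$testable],
                                          method = "BH")
    df$discoveryFDR <- !is.na(df$pAdjustBH) & df$pAdjustBH <= fdr
    df <- df[order(df$pTissue), , drop = FALSE]
    rownames(df) <- NULL
    attr(df, "bonferroniThreshold") <- threshold
    df
}
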