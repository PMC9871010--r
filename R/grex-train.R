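## Training of GReX prediction models.
##
## The tissue-level baseline is a standard elastic-net fit of bulk
## expression on SNP dosages (and covariates). The cell-type-aware model
## decomposes bulk expression y = pi*u + (1-pi)*v into two linear cell-level
## models sharing covariate effects, and fits the implied single regression
## with a symmetric penalty: writing chat = pi - 0.5, the design carries the
## SNP block (coefficient (b1+b2)/2), the chat-by-SNP interactions
## (coefficient b1-b2) and chat itself (intercept difference, unpenalized),
## so both cell types are regularized identically and relabelling the cell
## types only relabels the fitted model.

.defaultSnpInfo <- function(snpIds) {
    data.frame(snp = snpIds, chrom = NA_character_, pos = NA_integer_,
               refAllele = NA_character_, effAllele = NA_character_,
               stringsAsFactors = FALSE)
}

.resolveSnpInfo <- function(snpInfo, X) {
    ids <- colnames(X)
    if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(X)))
    if (is.null(snpInfo)) return(.defaultSnpInfo(ids))
    stopifnot(is.data.frame(snpInfo), "snp" %in% names(snpInfo),
              nrow(snpInfo) == ncol(X))
    snpInfo
}

.makeFoldid <- function(n, nFolds, seed = NULL) {
    draw <- function() sample(rep_len(seq_len(nFolds), n))
    if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

.cvCorrelation <- function(y, cvfit) {
    idx <- which(cvfit$lambda == cvfit$lambda.min)[1L]
    pre <- cvfit$fit.preval[, idx]
    if (sd(pre) == 0) 0 else cor(y, pre)
}

#' Train a tissue-level GReX prediction model
#'
#' Elastic-net regression of bulk expression on SNP dosages and covariates,
#' with the mixing parameter fixed (default 0.5) and the penalty weight
#' chosen at the cross-validation minimum. The intercept is unpenalized.
#' Genes for which no SNP survives selection are returned with
#' \code{isTrainable(model) == FALSE} and are excluded from association
#' testing downstream.
#'
#' @param y numeric vector of normalized bulk expression for one gene.
#' @param X samples x SNPs dosage matrix (values in [0, 2]).
#' @param Z optional samples x covariates matrix.
#' @param alpha elastic-net mixing parameter in (0, 1); default 0.5.
#' @param nFolds cross-validation folds; default 10.
#' @param seed integer seed controlling fold assignment.
#' @param lambda optional fixed penalty weight; skips cross-validation
#'   (used mainly for diagnostics; \code{lambda = 0} with fewer predictors
#'   than samples reproduces ordinary least squares).
#' @param geneId gene identifier stored in the model.
#' @param snpInfo optional data.frame of SNP annotation (column \code{snp}
#'   plus chrom/pos/alleles), one row per column of \code{X}.
#' @return a \linkS4class{TissueModel}.
#' @export
trainTissueModel <- function(y, X, Z = NULL, alpha = 0.5, nFolds = 10L,
                             seed = NULL, lambda = NULL,
                             geneId = "gene", snpInfo = NULL) {
    X <- as.matrix(X)
    n <- length(y)
    stopifnot(nrow(X) == n, alpha > 0, alpha < 1)
    if (sd(y) == 0) stop("expression of ", geneId, " is constant")
    if (is.null(lambda) && n < 2 * nFolds)
        stop("need at least 2 samples per cross-validation fold")
    snpInfo <- .resolveSnpInfo(snpInfo, X)
    colnames(X) <- snpInfo$snp
    if (!is.null(Z)) {
        Z <- as.matrix(Z)
        if (is.null(colnames(Z))) colnames(Z) <- paste0("cov", seq_len(ncol(Z)))
    }
    mat <- cbind(X, Z)
    m <- ncol(X)

    fit <- .penalizedFit(mat, y, alpha, rep(1, ncol(mat)), nFolds, seed,
                         lambda)
    beta <- fit$beta
    b <- beta[seq_len(m)]
    cW <- if (is.null(Z)) numeric(0) else
        setNames(beta[m + seq_len(ncol(Z))], colnames(Z))

    keep <- which(b != 0)
    new("TissueModel",
        geneId = geneId,
        snpInfo = snpInfo[keep, , drop = FALSE],
        weights = unname(b[keep]),
        intercept = fit$a0,
        covWeights = cW,
        cvPerformance = fit$cvPerf,
        trainable = length(keep) > 0L)
}

## shared elastic-net machinery: CV at lambda.min, or a fixed lambda
.penalizedFit <- function(mat, y, alpha, penaltyFactor, nFolds, seed,
                          lambda) {
    if (is.null(lambda)) {
        foldid <- .makeFoldid(length(y), nFolds, seed)
        cvfit <- glmnet::cv.glmnet(mat, y, alpha = alpha, foldid = foldid,
                                   penalty.factor = penaltyFactor,
                                   keep = TRUE, standardize = TRUE)
        co <- coef(cvfit, s = "lambda.min")
        list(a0 = co[1L], beta = as.numeric(co[-1L]),
             cvPerf = .cvCorrelation(y, cvfit), lambda = cvfit$lambda.min)
    } else {
        ## descend a path into the requested lambda for a stable solution
        path <- glmnet::glmnet(mat, y, alpha = alpha,
                               penalty.factor = penaltyFactor,
                               standardize = TRUE, nlambda = 60)
        lams <- sort(unique(c(path$lambda, lambda)), decreasing = TRUE)
        lams <- lams[lams >= lambda]
        fit <- glmnet::glmnet(mat, y, alpha = alpha,
                              penalty.factor = penaltyFactor,
                              standardize = TRUE, lambda = lams,
                              thresh = 1e-16, maxit = 1e8)
        co <- coef(fit, s = lambda)
        list(a0 = co[1L], beta = as.numeric(co[-1L]),
             cvPerf = NA_real_, lambda = lambda)
    }
}

#' Build the symmetric mixture-decomposition design
#'
#' Constructs the augmented regression design for the cell-type-aware
#' model: \code{[chat, X, chat * X, Z]} with \code{chat = piHat - 0.5}. The
#' \code{chat} column (intercept difference between cell types) is
#' unpenalized; the SNP, interaction and covariate blocks are penalized.
#' The overall intercept is handled by the solver and is not a column.
#'
#' @param X samples x SNPs dosage matrix.
#' @param Z optional covariate matrix.
#' @param piHat per-sample proportion of the cell type of interest, in
#'   (0, 1).
#' @return list with \code{design} (matrix), \code{penaltyFactor} and
#'   \code{roles} (one of \code{"prior_centered"}, \code{"snp"},
#'   \code{"interaction"}, \code{"covariate"} per column).
#' @export
buildCellAwareDesign <- function(X, Z = NULL, piHat) {
    X <- as.matrix(X)
    stopifnot(length(piHat) == nrow(X), all(piHat > 0 & piHat < 1))
    if (is.null(colnames(X))) colnames(X) <- paste0("snp", seq_len(ncol(X)))
    chat <- piHat - 0.5
    inter <- X * chat
    colnames(inter) <- paste0(colnames(X), ":chat")
    if (!is.null(Z)) {
        Z <- as.matrix(Z)
        if (is.null(colnames(Z))) colnames(Z) <- paste0("cov", seq_len(ncol(Z)))
    }
    design <- cbind(chat = chat, X, inter, Z)
    roles <- c("prior_centered", rep("snp", ncol(X)),
               rep("interaction", ncol(X)),
               rep("covariate", if (is.null(Z)) 0L else ncol(Z)))
    list(design = design,
         penaltyFactor = ifelse(roles == "prior_centered", 0, 1),
         roles = roles)
}

## Stability assessment of the per-SNP weight difference. Each bootstrap
## resample contributes (a) an OLS refit on the columns pre-selected by the
## full-data penalized fit, giving a percentile CI of the difference, and
## (b) a re-run of the elastic-net selection at the chosen lambda, giving
## the selection frequency of each interaction column.
.stabilityBootstrap <- function(mat, y, cols, interCols, B, ciLevel, seed,
                                alpha, penaltyFactor, lambda) {
    n <- length(y)
    run <- function() {
        diffs <- matrix(NA_real_, nrow = B, ncol = length(interCols))
        freq <- numeric(length(interCols))
        nFail <- 0L
        Xb <- cbind(`(Intercept)` = 1, mat[, cols, drop = FALSE])
        pos <- match(interCols, cols) + 1L
        interIdx <- match(interCols, colnames(mat))
        for (b in seq_len(B)) {
            idx <- sample.int(n, n, replace = TRUE)
            Xi <- Xb[idx, , drop = FALSE]
            fit <- lm.fit(Xi, y[idx])
            cf <- fit$coefficients
            if (fit$rank < ncol(Xi) || anyNA(cf[pos])) {
                ## rank-deficient resample: tiny ridge jitter
                cf <- tryCatch({
                    XtX <- crossprod(Xi) + diag(1e-8, ncol(Xi))
                    drop(solve(XtX, crossprod(Xi, y[idx])))
                }, error = function(e) rep(NA_real_, ncol(Xi)))
                if (anyNA(cf)) { nFail <- nFail + 1L; next }
                warning("rank-deficient bootstrap OLS stabilized with ",
                        "ridge jitter", call. = FALSE)
            }
            diffs[b, ] <- cf[pos]
            refit <- tryCatch(
                glmnet::glmnet(mat[idx, , drop = FALSE], y[idx],
                               alpha = alpha,
                               penalty.factor = penaltyFactor,
                               standardize = TRUE, lambda = lambda),
                error = function(e) NULL)
            if (!is.null(refit))
                freq <- freq + (as.numeric(refit$beta)[interIdx] != 0)
        }
        list(diffs = diffs, freq = freq / B, nFail = nFail)
    }
    out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
    if (out$nFail > 0.2 * B)
        return(NULL)  # caller falls back to a nonspecific model
    alpha2 <- (1 - ciLevel) / 2
    ci <- apply(out$diffs, 2L, quantile, probs = c(alpha2, 1 - alpha2),
                na.rm = TRUE)
    data.frame(snp = sub(":chat$", "", interCols),
               lo = ci[1L, ], hi = ci[2L, ], selFreq = out$freq,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Train a cell-type-aware GReX prediction model
#'
#' Fits the symmetric mixture-decomposition regression by elastic net,
#' penalizing the mean SNP effect \code{(b1 + b2)/2}, the per-SNP
#' difference \code{b1 - b2} and the covariate effects, while leaving the
#' intercept and the proportion main effect unpenalized. Coefficients are
#' back-transformed to per-cell-type weights. When the fit selects any
#' nonzero weight difference, its reliability is assessed by a stability
#' bootstrap: \code{B} resamples are refitted by ordinary least squares on
#' the pre-selected columns (percentile confidence intervals of the
#' per-SNP difference) and the elastic-net selection is re-run on each
#' resample at the chosen penalty (per-SNP selection frequency). The model
#' is kept cell-type-specific only when at least one SNP's interval
#' excludes zero \emph{and} that SNP's selection frequency reaches
#' \code{stabilityFreq}; otherwise it collapses to the tissue-level
#' elastic-net fit with identical weights in both cell types. The joint
#' criterion suppresses the post-selection optimism of refitting OLS on
#' columns chosen by the penalized fit, which would otherwise declare many
#' genes with homogeneous SNP effects cell-type-specific.
#'
#' @inheritParams trainTissueModel
#' @param piHat per-sample proportion of the cell type of interest.
#' @param B bootstrap resamples for stability selection (default 200).
#' @param ciLevel confidence level of the percentile intervals
#'   (default 0.95).
#' @param stabilityFreq minimum bootstrap re-selection frequency for a SNP
#'   difference to count as stable (default 0.8).
#' @return a \linkS4class{CellTypeModel}.
#' @export
trainCellAwareModel <- function(y, X, Z = NULL, piHat, alpha = 0.5,
                                nFolds = 10L, B = 200L, ciLevel = 0.95,
                                stabilityFreq = 0.8,
                                seed = NULL, lambda = NULL,
                                geneId = "gene", snpInfo = NULL) {
    X <- as.matrix(X)
    n <- length(y)
    stopifnot(nrow(X) == n, length(piHat) == n)
    if (sd(y) == 0) stop("expression of ", geneId, " is constant")
    snpInfo <- .resolveSnpInfo(snpInfo, X)
    colnames(X) <- snpInfo$snp

    dz <- buildCellAwareDesign(X, Z, piHat)
    fit <- .penalizedFit(dz$design, y, alpha, dz$penaltyFactor, nFolds,
                         seed, lambda)
    beta <- setNames(fit$beta, colnames(dz$design))
    m <- ncol(X)
    betaC <- beta[dz$roles == "prior_centered"]
    betaX <- beta[dz$roles == "snp"]
    betaCX <- beta[dz$roles == "interaction"]
    betaZ <- beta[dz$roles == "covariate"]

    bU <- betaX + betaCX / 2
    bV <- betaX - betaCX / 2
    aU <- fit$a0 + betaC / 2
    aV <- fit$a0 - betaC / 2

    selected <- which(betaX != 0 | betaCX != 0)
    trainable <- length(selected) > 0L

    diffCI <- data.frame(snp = character(0), lo = numeric(0),
                         hi = numeric(0), selFreq = numeric(0),
                         stringsAsFactors = FALSE)
    specific <- FALSE
    if (any(betaCX != 0)) {
        cols <- c("chat",
                  names(betaX)[betaX != 0],
                  names(betaCX)[betaCX != 0],
                  names(betaZ)[betaZ != 0])
        interCols <- names(betaCX)[betaCX != 0]
        bootSeed <- if (is.null(seed)) NULL else seed + 1L
        diffCIFit <- .stabilityBootstrap(dz$design, y, cols, interCols,
                                         B, ciLevel, bootSeed, alpha,
                                         dz$penaltyFactor, fit$lambda)
        if (is.null(diffCIFit)) {
            warning("more than 20% of stability bootstraps failed for ",
                    geneId, "; falling back to a nonspecific model")
        } else {
            diffCI <- diffCIFit
            specific <- any((diffCI$lo > 0 | diffCI$hi < 0) &
                            diffCI$selFreq >= stabilityFreq)
        }
    }

    if (specific) {
        new("CellTypeModel",
            geneId = geneId,
            snpInfo = snpInfo[selected, , drop = FALSE],
            weightsCell1 = unname(bU[selected]),
            weightsCell2 = unname(bV[selected]),
            interceptCell1 = unname(aU),
            interceptCell2 = unname(aV),
            covWeights = betaZ,
            modelType = "cell_type_specific",
            diffCI = diffCI,
            nBoot = as.integer(B),
            cvPerformance = fit$cvPerf,
            trainable = trainable)
    } else {
        ## stability bootstrap cannot separate the cell types: use the
        ## tissue-level fit with shared weights
        tm <- trainTissueModel(y, X, Z, alpha = alpha, nFolds = nFolds,
                               seed = seed, lambda = lambda,
                               geneId = geneId, snpInfo = snpInfo)
        new("CellTypeModel",
            geneId = geneId,
            snpInfo = tm@snpInfo,
            weightsCell1 = tm@weights,
            weightsCell2 = tm@weights,
            interceptCell1 = tm@intercept,
            interceptCell2 = tm@intercept,
            covWeights = tm@covWeights,
            modelType = "nonspecific",
            diffCI = diffCI,
            nBoot = if (nrow(diffCI)) as.integer(B) else 0L,
            cvPerformance = tm@cvPerformance,
            trainable = tm@trainable)
    }
}

#' Train the asymmetric variant of the cell-type-aware model
#'
#' Benchmarking variant that fits the mixture decomposition in its raw
#' parameterization: design \code{[piHat, X, piHat * X, Z]}, penalizing
#' \code{(b2, b1 - b2, c)} directly. Because the penalty shrinks the
#' cell-2 weights towards zero but the cell-1 weights towards the cell-2
#' weights, swapping the labels of the two cell types changes the fitted
#' model; the symmetric \code{\link{trainCellAwareModel}} was designed to
#' remove exactly this order dependence. No stability selection is
#' performed.
#'
#' @inheritParams trainCellAwareModel
#' @return a \linkS4class{CellTypeModel} (with empty \code{diffCI}).
#' @export
trainAsymmetricModel <- function(y, X, Z = NULL, piHat, alpha = 0.5,
                                 nFolds = 10L, seed = NULL, lambda = NULL,
                                 geneId = "gene", snpInfo = NULL) {
    X <- as.matrix(X)
    n <- length(y)
    stopifnot(nrow(X) == n, length(piHat) == n,
              all(piHat > 0 & piHat < 1))
    if (sd(y) == 0) stop("expression of ", geneId, " is constant")
    snpInfo <- .resolveSnpInfo(snpInfo, X)
    colnames(X) <- snpInfo$snp
    inter <- X * piHat
    colnames(inter) <- paste0(colnames(X), ":pi")
    if (!is.null(Z)) {
        Z <- as.matrix(Z)
        if (is.null(colnames(Z))) colnames(Z) <- paste0("cov", seq_len(ncol(Z)))
    }
    design <- cbind(pi = piHat, X, inter, Z)
    pf <- c(0, rep(1, ncol(design) - 1L))

    fit <- .penalizedFit(design, y, alpha, pf, nFolds, seed, lambda)
    beta <- setNames(fit$beta, colnames(design))
    m <- ncol(X)
    betaPi <- beta[1L]
    betaX <- beta[1L + seq_len(m)]
    betaPX <- beta[1L + m + seq_len(m)]
    betaZ <- if (is.null(Z)) numeric(0) else
        beta[1L + 2L * m + seq_len(ncol(Z))]

    bV <- betaX
    bU <- betaX + betaPX
    aV <- fit$a0
    aU <- fit$a0 + betaPi

    selected <- which(bU != 0 | bV != 0)
    new("CellTypeModel",
        geneId = geneId,
        snpInfo = snpInfo[selected, , drop = FALSE],
        weightsCell1 = unname(bU[selected]),
        weightsCell2 = unname(bV[selected]),
        interceptCell1 = unname(aU),
        interceptCell2 = unname(aV),
        covWeights = betaZ,
        modelType = if (any(betaPX != 0)) "cell_type_specific" else
            "nonspecific",
        diffCI = data.frame(snp = character(0), lo = numeric(0),
                            hi = numeric(0), selFreq = numeric(0),
                            stringsAsFactors = FALSE),
        nBoot = 0L,
        cvPerformance = fit$cvPerf,
        trainable = length(selected) > 0L)
}
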