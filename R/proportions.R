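## Proportion estimation for the cell type of interest in bulk samples.
##
## Bulk expression of a signature gene g in sample i is modelled marginally
## as Gaussian with mean pi_i*mu1_g + (1 - pi_i)*mu2_g and variance
## pi_i^2*sigma1_g^2 + (1 - pi_i)^2*sigma2_g^2 (independent cell-level
## noise), and the prior enrichment score h_i is linked to pi_i through
## h_i ~ Beta(pi_i * delta, (1 - pi_i) * delta), an unbiased but noisy prior.
## The joint log-likelihood is maximized by block coordinate ascent.

.PI_LO <- 0.01
.PI_HI <- 0.99
.DELTA_LO <- 0.1
.DELTA_HI <- 1e4
.SIGMA_LO <- 1e-3
.SIGMA_HI <- 1e3

#' Rescale raw enrichment scores into a proportion prior
#'
#' Linear min-max rescaling of nonnegative enrichment scores (e.g.
#' xCell-style scores for the cell type of interest) to [0, 1], then clipped
#' into [eps, 1 - eps] so that Beta densities evaluated at the prior are
#' finite.
#'
#' @param rawScores numeric vector of finite scores, length >= 2; names are
#'   kept as sample identifiers.
#' @param eps clip margin (default 0.01).
#' @return named numeric vector of prior proportions strictly inside (0, 1).
#' @examples
#' rescalePrior(c(s1 = 0.2, s2 = 0.5, s3 = 0.8))
#' @export
rescalePrior <- function(rawScores, eps = 0.01) {
    if (length(rawScores) < 2)
        stop("need at least 2 samples to rescale a prior")
    if (any(!is.finite(rawScores)))
        stop("prior scores must be finite")
    rng <- range(rawScores)
    if (rng[1] == rng[2])
        stop("all prior scores are identical; the prior carries no ",
             "information about relative cell proportions")
    h <- (rawScores - rng[1]) / (rng[2] - rng[1])
    pmin(pmax(h, eps), 1 - eps)
}

## log-likelihood of the expression block, vectorized over samples x genes
.exprLogLikMatrix <- function(W, pi, mu1, mu2, s1, s2) {
    M <- outer(pi, mu1) + outer(1 - pi, mu2)
    V <- outer(pi^2, s1^2) + outer((1 - pi)^2, s2^2)
    dnorm(W, mean = M, sd = sqrt(V), log = TRUE)
}

#' Joint log-likelihood of signature expression and the proportion prior
#'
#' Evaluates the objective maximized by \code{\link{fitSignatureMixture}}:
#' the sum over samples of the Gaussian log-density of each signature gene
#' under the proportion-weighted mixture, plus the Beta log-density of the
#' prior score given the proportion.
#'
#' @param W samples x genes matrix of normalized signature-gene expression.
#' @param pi numeric vector of proportions in (0, 1), one per sample.
#' @param mixture a \linkS4class{SignatureMixture}.
#' @param prior numeric vector of prior proportions in (0, 1).
#' @param delta positive concentration of the Beta prior link.
#' @return scalar log-likelihood.
#' @export
signatureLogLik <- function(W, pi, mixture, prior, delta) {
    W <- as.matrix(W)
    stopifnot(nrow(W) == length(pi), length(prior) == length(pi),
              ncol(W) == length(mixture@geneIds),
              all(pi > 0 & pi < 1), delta > 0)
    ll <- .exprLogLikMatrix(W, pi, mixture@muCell1, mixture@muCell2,
                            mixture@sigmaCell1, mixture@sigmaCell2)
    if (any(!is.finite(ll))) {
        bad <- which(!is.finite(ll), arr.ind = TRUE)[1L, ]
        stop("non-finite expression log-likelihood at sample ", bad[1L],
             ", gene ", bad[2L])
    }
    lp <- dbeta(prior, pi * delta, (1 - pi) * delta, log = TRUE)
    if (any(!is.finite(lp)))
        stop("non-finite prior log-likelihood at sample ",
             which(!is.finite(lp))[1L])
    sum(ll) + sum(lp)
}

## per-sample objective pieces used by the pi update and bootstrap scoring
.piObjective <- function(p, w, mu1, mu2, s1, s2, h, delta) {
    sum(dnorm(w, p * mu1 + (1 - p) * mu2,
              sqrt(p^2 * s1^2 + (1 - p)^2 * s2^2), log = TRUE)) +
        dbeta(h, p * delta, (1 - p) * delta, log = TRUE)
}

## 1-D bounded maximization of pi for every sample given (Gamma, delta);
## guarded so the accepted value never decreases the objective
.updatePi <- function(W, pi, mu1, mu2, s1, s2, h, delta) {
    for (i in seq_along(pi)) {
        cur <- .piObjective(pi[i], W[i, ], mu1, mu2, s1, s2, h[i], delta)
        opt <- optimize(.piObjective, c(.PI_LO, .PI_HI), maximum = TRUE,
                        w = W[i, ], mu1 = mu1, mu2 = mu2, s1 = s1, s2 = s2,
                        h = h[i], delta = delta, tol = 1e-6)
        if (is.finite(opt$objective) && opt$objective > cur)
            pi[i] <- opt$maximum
    }
    pi
}

## per-gene maximization over (mu1, mu2, log sigma1, log sigma2)
.updateGenes <- function(W, pi, mu1, mu2, s1, s2) {
    for (g in seq_along(mu1)) {
        w <- W[, g]
        fn <- function(p) {
            sg1 <- min(max(exp(p[3L]), .SIGMA_LO), .SIGMA_HI)
            sg2 <- min(max(exp(p[4L]), .SIGMA_LO), .SIGMA_HI)
            val <- sum(dnorm(w, pi * p[1L] + (1 - pi) * p[2L],
                             sqrt(pi^2 * sg1^2 + (1 - pi)^2 * sg2^2),
                             log = TRUE))
            if (!is.finite(val)) -1e12 else val
        }
        start <- c(mu1[g], mu2[g], log(s1[g]), log(s2[g]))
        cur <- fn(start)
        opt <- optim(start, fn, method = "Nelder-Mead",
                     control = list(fnscale = -1, maxit = 200))
        if (is.finite(opt$value) && opt$value > cur) {
            mu1[g] <- opt$par[1L]
            mu2[g] <- opt$par[2L]
            s1[g] <- min(max(exp(opt$par[3L]), .SIGMA_LO), .SIGMA_HI)
            s2[g] <- min(max(exp(opt$par[4L]), .SIGMA_LO), .SIGMA_HI)
        }
    }
    list(mu1 = mu1, mu2 = mu2, s1 = s1, s2 = s2)
}

.updateDelta <- function(pi, h, delta) {
    fn <- function(ld) sum(dbeta(h, pi * exp(ld), (1 - pi) * exp(ld),
                                 log = TRUE))
    cur <- fn(log(delta))
    opt <- optimize(fn, log(c(.DELTA_LO, .DELTA_HI)), maximum = TRUE,
                    tol = 1e-6)
    if (is.finite(opt$objective) && opt$objective > cur)
        delta <- exp(opt$maximum)
    delta
}

## core coordinate-ascent fit; returns a plain list
.fitMixtureCore <- function(W, prior, maxIter = 500L, tol = 1e-6) {
    W <- as.matrix(W)
    N <- nrow(W)
    G <- ncol(W)
    if (G < 2) stop("need at least 2 signature genes")
    if (any(!is.finite(W))) stop("signature expression must be finite")
    stopifnot(length(prior) == N, all(prior > 0 & prior < 1))

    pi <- pmin(pmax(prior, .PI_LO), .PI_HI)
    delta <- 10

    ## regression-informed initialization: w = mu2 + pi * (mu1 - mu2) + noise
    mu1 <- numeric(G); mu2 <- numeric(G); s1 <- numeric(G); s2 <- numeric(G)
    for (g in seq_len(G)) {
        fit <- lm.fit(cbind(1, pi), W[, g])
        mu2[g] <- fit$coefficients[1L]
        mu1[g] <- sum(fit$coefficients)
        sr <- sd(fit$residuals)
        s1[g] <- s2[g] <- min(max(sr, .SIGMA_LO), .SIGMA_HI)
    }

    obj <- sum(.exprLogLikMatrix(W, pi, mu1, mu2, s1, s2)) +
        sum(dbeta(prior, pi * delta, (1 - pi) * delta, log = TRUE))
    converged <- FALSE
    iter <- 0L
    while (iter < maxIter) {
        iter <- iter + 1L
        up <- .updateGenes(W, pi, mu1, mu2, s1, s2)
        mu1 <- up$mu1; mu2 <- up$mu2; s1 <- up$s1; s2 <- up$s2
        pi <- .updatePi(W, pi, mu1, mu2, s1, s2, prior, delta)
        delta <- .updateDelta(pi, prior, delta)

        newObj <- sum(.exprLogLikMatrix(W, pi, mu1, mu2, s1, s2)) +
            sum(dbeta(prior, pi * delta, (1 - pi) * delta, log = TRUE))
        if (newObj < obj - 1e-6 * (1 + abs(obj)))
            stop("internal error: coordinate ascent decreased the objective (",
                 obj, " -> ", newObj, ")")
        done <- abs(newObj - obj) < tol * (1 + abs(obj))
        obj <- newObj
        if (done) { converged <- TRUE; break }
    }
    if (!converged)
        warning("proportion fit did not converge in ", maxIter,
                " iterations; returning best iterate")
    list(pi = pi, mu1 = mu1, mu2 = mu2, s1 = s1, s2 = s2,
         delta = delta, objective = obj, converged = converged,
         nIter = iter)
}

.asSignatureMixture <- function(fit, geneIds) {
    new("SignatureMixture", geneIds = geneIds,
        muCell1 = fit$mu1, muCell2 = fit$mu2,
        sigmaCell1 = fit$s1, sigmaCell2 = fit$s2)
}

#' Fit the signature-gene mixture and estimate cell proportions
#'
#' Maximizes the joint log-likelihood of signature-gene expression and the
#' proportion prior (\code{\link{signatureLogLik}}) by block coordinate
#' ascent: per-gene numeric maximization of the Gaussian parameters,
#' per-sample 1-D bounded maximization of the proportion on [0.01, 0.99],
#' and 1-D maximization of the prior concentration delta. Proportions are
#' initialized at the prior, which anchors component 1 to the cell type the
#' prior describes (no ordering constraint is imposed on the means). The
#' objective is guaranteed non-decreasing across iterations.
#'
#' @param W samples x genes matrix of normalized signature-gene expression
#'   (rownames: sample ids).
#' @param prior numeric vector of prior proportions strictly in (0, 1)
#'   (see \code{\link{rescalePrior}}).
#' @param maxIter maximum coordinate-ascent sweeps (default 500).
#' @param tol relative objective-change tolerance (default 1e-6).
#' @return a \linkS4class{CellProportions} (single fit: \code{nBoot = 0}).
#' @seealso \code{\link{estimateCellProportions}} for the bagged estimator.
#' @export
fitSignatureMixture <- function(W, prior, maxIter = 500L, tol = 1e-6) {
    W <- as.matrix(W)
    fit <- .fitMixtureCore(W, prior, maxIter = maxIter, tol = tol)
    sampleIds <- if (!is.null(rownames(W))) rownames(W) else
        paste0("sample", seq_len(nrow(W)))
    geneIds <- if (!is.null(colnames(W))) colnames(W) else
        paste0("gene", seq_len(ncol(W)))
    new("CellProportions",
        sampleIds = sampleIds, piHat = fit$pi, prior = as.numeric(prior),
        delta = fit$delta, mixture = .asSignatureMixture(fit, geneIds),
        nBoot = 0L, trimFrac = 0, bootSpread = numeric(0),
        converged = fit$converged, objective = fit$objective)
}

## score pi for all N samples under a fitted (Gamma, delta)
.scorePiAll <- function(W, prior, fit) {
    vapply(seq_len(nrow(W)), function(i) {
        opt <- optimize(.piObjective, c(.PI_LO, .PI_HI), maximum = TRUE,
                        w = W[i, ], mu1 = fit$mu1, mu2 = fit$mu2,
                        s1 = fit$s1, s2 = fit$s2, h = prior[i],
                        delta = fit$delta, tol = 1e-6)
        opt$maximum
    }, numeric(1))
}

## drop the most extreme floor(trim * n) values from each tail
.trimTails <- function(x, trim) {
    x <- sort(x)
    k <- floor(length(x) * trim)
    if (k > 0) x <- x[(k + 1L):(length(x) - k)]
    x
}

#' Bagged estimation of cell proportions
#'
#' Robust version of \code{\link{fitSignatureMixture}}: the mixture is
#' refitted on bootstrap subsamples (by default 100 draws of 80% of the
#' samples, with replacement), each fit scores proportions for all samples,
#' and per-sample estimates are aggregated by a tail-truncated mean that
#' drops the most extreme fraction (default 5%) from each tail. The
#' full-data fit supplies the reported mixture parameters, delta and
#' objective.
#'
#' @inheritParams fitSignatureMixture
#' @param nBoot number of bootstrap fits (default 100).
#' @param frac fraction of samples drawn (with replacement) per bootstrap
#'   (default 0.8).
#' @param trim per-tail trim fraction of the bootstrap estimates
#'   (default 0.05; must lie in [0, 0.5)).
#' @param seed integer seed for the bootstrap draws.
#' @return a \linkS4class{CellProportions} with bagging provenance.
#' @export
estimateCellProportions <- function(W, prior, nBoot = 100L, frac = 0.8,
                                    trim = 0.05, seed = NULL,
                                    maxIter = 500L, tol = 1e-6) {
    stopifnot(nBoot >= 2, trim >= 0, trim < 0.5, frac > 0, frac <= 1)
    W <- as.matrix(W)
    N <- nrow(W)
    full <- fitSignatureMixture(W, prior, maxIter = maxIter, tol = tol)

    runBoots <- function() {
        nDraw <- ceiling(frac * N)
        est <- matrix(NA_real_, nrow = N, ncol = nBoot)
        nFail <- 0L
        for (b in seq_len(nBoot)) {
            idx <- sample.int(N, nDraw, replace = TRUE)
            fit <- tryCatch(
                .fitMixtureCore(W[idx, , drop = FALSE], prior[idx],
                                maxIter = maxIter, tol = tol),
                error = function(e) NULL)
            if (is.null(fit)) {
                nFail <- nFail + 1L
                message("bootstrap ", b, " failed; skipped")
                next
            }
            est[, b] <- .scorePiAll(W, prior, fit)
        }
        if (nFail > nBoot / 2)
            stop("more than half of the bootstrap fits failed (",
                 nFail, "/", nBoot, ")")
        est[, colSums(is.na(est)) == 0L, drop = FALSE]
    }
    est <- if (is.null(seed)) runBoots() else
        withr::with_seed(seed, runBoots())

    agg <- t(apply(est, 1L, function(x) {
        kept <- .trimTails(x, trim)
        c(mean(kept), if (length(kept) > 1) sd(kept) else 0)
    }))

    new("CellProportions",
        sampleIds = full@sampleIds, piHat = agg[, 1L],
        prior = as.numeric(prior), delta = full@delta,
        mixture = full@mixture, nBoot = as.integer(ncol(est)),
        trimFrac = trim, bootSpread = agg[, 2L],
        converged = full@converged, objective = full@objective)
}
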