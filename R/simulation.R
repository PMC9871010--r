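## Simulation engine for type-I-error and power studies of the
## cell-type-aware TWAS against the tissue-level elastic-net baseline.
##
## Each replicate simulates a training cohort (bulk expression as a
## proportion-weighted mixture of two cell-level linear SNP models), trains
## both model families, simulates an independent case-control GWAS cohort
## from the same generative model, and tests the gene for association.

#' Construct a simulation scenario configuration
#'
#' @param nTrain training samples (default 300).
#' @param nGwas GWAS subjects (default 3000).
#' @param nSnps SNPs in the genotype block (default 50).
#' @param mafRange uniform range of minor allele frequencies
#'   (default c(0.05, 0.50)).
#' @param piShape1,piShape2 Beta parameters of the minor cell-type
#'   proportion (default Beta(2, 3), mean 0.4).
#' @param b0 mean expression offset of cell 1 at zero dosage (default 1).
#' @param b1Mag,b2Mag magnitudes of the causal SNP effect in cells 1 and 2
#'   (default 1); signs are drawn with equal probability each replicate.
#' @param b3Mag causal effect magnitude of a latent \code{"distinct"} third
#'   cell (default 1; ignored otherwise).
#' @param snpExp \code{"homogeneous"} (one causal SNP shared by both cell
#'   types, same sign) or \code{"heterogeneous"} (distinct causal SNPs).
#' @param eta1,eta2,eta3 expression-disease log-odds coefficients for cells
#'   1, 2 and the latent third cell.
#' @param piMisspec proportion-misspecification scenario injected into
#'   training (see \code{\link{misspecifyPi}}).
#' @param threeCell \code{"none"}, \code{"shared"} or \code{"distinct"}.
#' @param nReps Monte Carlo replicates (default 500).
#' @param alphaLevel nominal test level (default 0.05).
#' @param enetAlpha elastic-net mixing parameter (default 0.5).
#' @param nFolds cross-validation folds (default 10).
#' @param nStabilityBoot stability-selection bootstraps (default 200).
#' @param seed master seed (default 1).
#' @return a \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nTrain = 300L, nGwas = 3000L, nSnps = 50L,
                             mafRange = c(0.05, 0.50),
                             piShape1 = 2, piShape2 = 3,
                             b0 = 1, b1Mag = 1, b2Mag = 1, b3Mag = 1,
                             snpExp = "heterogeneous",
                             eta1 = 0, eta2 = 0, eta3 = 0,
                             piMisspec = "none", threeCell = "none",
                             nReps = 500L, alphaLevel = 0.05,
                             enetAlpha = 0.5, nFolds = 10L,
                             nStabilityBoot = 200L, seed = 1L) {
    new("SimulationConfig",
        nTrain = as.integer(nTrain), nGwas = as.integer(nGwas),
        nSnps = as.integer(nSnps), mafRange = mafRange,
        piShape1 = piShape1, piShape2 = piShape2,
        b0 = b0, b1Mag = b1Mag, b2Mag = b2Mag, b3Mag = b3Mag,
        snpExp = snpExp, eta1 = eta1, eta2 = eta2, eta3 = eta3,
        piMisspec = piMisspec, threeCell = threeCell,
        nReps = as.integer(nReps), alphaLevel = alphaLevel,
        enetAlpha = enetAlpha, nFolds = as.integer(nFolds),
        nStabilityBoot = as.integer(nStabilityBoot),
        seed = as.integer(seed))
}

#' Named scenario presets for the simulation study
#'
#' Shorthand constructors for the standard scenarios: SNP-expression
#' architecture (\code{hom-} homogeneous, \code{het-} heterogeneous with
#' unit effects and \code{b0 = 1}) crossed with the expression-disease
#' pattern (\code{null}, \code{homogeneous-disease} with eta = (0.2, 0.2),
#' \code{major-cell} (0, 0.2), \code{minor-cell} (0.2, 0), and
#' \code{opposite} (-0.2, 0.2)).
#'
#' @param name preset name, e.g. \code{"het-minor-cell"}; see Details.
#' @param ... overrides passed to \code{\link{simulationConfig}} (e.g.
#'   \code{nReps}, \code{seed}, \code{piMisspec}, \code{threeCell}).
#' @return a \linkS4class{SimulationConfig}.
#' @export
scenarioPreset <- function(name, ...) {
    presets <- list(
        `hom-null` = list(snpExp = "homogeneous", eta1 = 0, eta2 = 0),
        `hom-disease` = list(snpExp = "homogeneous", eta1 = 0.2,
                             eta2 = 0.2),
        `het-null` = list(snpExp = "heterogeneous", eta1 = 0, eta2 = 0),
        `het-homogeneous-disease` = list(snpExp = "heterogeneous",
                                         eta1 = 0.2, eta2 = 0.2),
        `het-major-cell` = list(snpExp = "heterogeneous", eta1 = 0,
                                eta2 = 0.2),
        `het-minor-cell` = list(snpExp = "heterogeneous", eta1 = 0.2,
                                eta2 = 0),
        `het-opposite` = list(snpExp = "heterogeneous", eta1 = -0.2,
                              eta2 = 0.2)
    )
    if (!name %in% names(presets))
        stop("unknown preset '", name, "'; available: ",
             paste(names(presets), collapse = ", "))
    args <- utils::modifyList(presets[[name]], list(...))
    do.call(simulationConfig, args)
}

#' Simulate a block of independent SNP genotypes
#'
#' Per-SNP minor allele frequencies are drawn uniformly from
#' \code{mafRange} and genotypes are sampled as Binomial(2, MAF) under
#' Hardy-Weinberg equilibrium, independently across SNPs and samples.
#'
#' @param n samples.
#' @param m SNPs.
#' @param mafRange numeric(2) within (0, 0.5].
#' @param seed optional integer seed.
#' @return list with \code{X} (n x m dosage matrix, columns snp1..snpm)
#'   and \code{maf}.
#' @export
simulateGenotypes <- function(n, m, mafRange = c(0.05, 0.50), seed = NULL) {
    stopifnot(mafRange[1] > 0, mafRange[2] <= 0.5,
              mafRange[1] <= mafRange[2])
    draw <- function() {
        maf <- runif(m, mafRange[1], mafRange[2])
        X <- matrix(rbinom(n * m, 2L, rep(maf, each = n)), nrow = n)
        colnames(X) <- paste0("snp", seq_len(m))
        list(X = X, maf = maf)
    }
    if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

## draw causal-SNP effect vectors for one replicate
.drawEffects <- function(config) {
    m <- config@nSnps
    b1 <- numeric(m); b2 <- numeric(m); b3 <- numeric(m)
    sgn <- function() sample(c(-1, 1), 1L)
    if (config@snpExp == "homogeneous") {
        p <- sample.int(m, 1L)
        s <- sgn()
        b1[p] <- s * config@b1Mag
        b2[p] <- s * config@b2Mag
    } else {
        p <- sample.int(m, 2L)
        b1[p[1L]] <- sgn() * config@b1Mag
        b2[p[2L]] <- sgn() * config@b2Mag
    }
    if (config@threeCell == "shared") {
        b3 <- b2
    } else if (config@threeCell == "distinct") {
        free <- setdiff(seq_len(m), which(b1 != 0 | b2 != 0))
        b3[sample(free, 1L)] <- sgn() * config@b3Mag
    }
    list(b1 = b1, b2 = b2, b3 = b3)
}

#' Simulate bulk-tissue training data from the two-cell mixture model
#'
#' Draws the minor cell-type proportion pi ~ Beta(piShape1, piShape2)
#' (default mean 0.4), cell-level expression \code{u = b0 + X b1 + e} and
#' \code{v = X b2 + e} with unit Gaussian noise, and the bulk mixture
#' \code{y = pi*u + (1-pi)*v}. The prior handed to proportion estimation
#' defaults to the truth; misspecification is injected downstream with
#' \code{\link{misspecifyPi}}. With a latent third cell type the remaining
#' proportion \code{1 - pi} is split 5:1 between cells 2 and 3 (so the
#' three proportions average 40%, 50% and 10%) and
#' \code{y = pi1*u + pi2*v + pi3*w}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param genotypes optional output of \code{\link{simulateGenotypes}};
#'   simulated fresh when NULL.
#' @param effects optional effect vectors (as from an earlier dataset) so
#'   that a GWAS cohort can share the training cohort's causal SNPs.
#' @param n number of samples (defaults to \code{config@nTrain}).
#' @param seed optional integer seed.
#' @return list of class \code{"SimulatedCellData"}: X, maf, pi (cell-1
#'   proportion), u, v (and w for three-cell), y, prior, effects.
#' @export
simulateCellData <- function(config, genotypes = NULL, effects = NULL,
                             n = NULL, seed = NULL) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    if (is.null(n)) n <- config@nTrain
    draw <- function() {
        gen <- if (is.null(genotypes))
            simulateGenotypes(n, config@nSnps, config@mafRange) else
            genotypes
        stopifnot(nrow(gen$X) == n)
        eff <- if (is.null(effects)) .drawEffects(config) else effects
        pi1 <- rbeta(n, config@piShape1, config@piShape2)
        pi1 <- pmin(pmax(pi1, 1e-6), 1 - 1e-6)
        u <- config@b0 + drop(gen$X %*% eff$b1) + rnorm(n)
        v <- drop(gen$X %*% eff$b2) + rnorm(n)
        if (config@threeCell == "none") {
            y <- pi1 * u + (1 - pi1) * v
            out <- list(X = gen$X, maf = gen$maf, pi = pi1, u = u, v = v,
                        y = y, prior = pi1, effects = eff)
        } else {
            pi2 <- (1 - pi1) * 5 / 6
            pi3 <- (1 - pi1) / 6
            w <- drop(gen$X %*% eff$b3) + rnorm(n)
            y <- pi1 * u + pi2 * v + pi3 * w
            out <- list(X = gen$X, maf = gen$maf, pi = pi1, u = u, v = v,
                        w = w, pi2 = pi2, pi3 = pi3, y = y, prior = pi1,
                        effects = eff)
        }
        structure(out, class = "SimulatedCellData")
    }
    if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate case-control status from cell-level expression
#'
#' Disease risk follows a logistic model in the cell-level expression
#' values. The intercept is calibrated by 1-D root finding so that the mean
#' disease probability over the simulated subjects is 0.5, reflecting a 1:1
#' case:control design.
#'
#' @param u,v cell-level expression vectors.
#' @param eta1,eta2 log-odds coefficients.
#' @param w,eta3 optional latent third-cell expression and coefficient.
#' @param seed optional integer seed.
#' @return list with \code{d} (0/1 vector) and the calibrated \code{eta0}.
#' @export
simulateDisease <- function(u, v, eta1, eta2, w = NULL, eta3 = 0,
                            seed = NULL) {
    stopifnot(all(is.finite(u)), all(is.finite(v)))
    lp <- eta1 * u + eta2 * v
    if (!is.null(w)) lp <- lp + eta3 * w
    f <- function(e0) mean(plogis(e0 + lp)) - 0.5
    if (f(-50) > 0 || f(50) < 0)
        stop("intercept root not bracketed; extreme linear predictor")
    eta0 <- uniroot(f, c(-50, 50), tol = 1e-10)$root
    draw <- function() rbinom(length(lp), 1L, plogis(eta0 + lp))
    d <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    list(d = d, eta0 = eta0)
}

#' Inject proportion misspecification
#'
#' Transforms the true proportion into the biased or noisy estimate used
#' for training, under the enumerated scenarios: \code{"none"} (identity),
#' \code{"scale_0.8"} (0.8 pi: mean 0.32, range (0, 0.8)),
#' \code{"affine_0.7_0.2"} (0.7 pi + 0.2: mean 0.48, range (0.2, 1)),
#' \code{"beta_conc_50"} (Beta(50 pi, 50(1-pi)): correlation with the truth
#' about 0.9) and \code{"beta_conc_5.5"} (Beta(5.5 pi, 5.5(1-pi)):
#' correlation about 0.6).
#'
#' @param pi true proportions in (0, 1).
#' @param scenario one of the scenario names above.
#' @param seed optional integer seed (used by the Beta scenarios).
#' @return numeric vector of misspecified proportions in (0, 1).
#' @export
misspecifyPi <- function(pi, scenario = "none", seed = NULL) {
    stopifnot(all(pi > 0 & pi < 1))
    clip <- function(x) pmin(pmax(x, 1e-6), 1 - 1e-6)
    drawBeta <- function(conc) {
        draw <- function() clip(rbeta(length(pi), conc * pi,
                                      conc * (1 - pi)))
        if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    }
    switch(scenario,
        none = pi,
        scale_0.8 = clip(0.8 * pi),
        affine_0.7_0.2 = clip(0.7 * pi + 0.2),
        beta_conc_50 = drawBeta(50),
        beta_conc_5.5 = drawBeta(5.5),
        stop("unknown misspecification scenario: ", scenario))
}

## one replicate: returns p-values (NA when a model was untrainable)
.studyReplicate <- function(config) {
    trainDat <- simulateCellData(config)
    piTrain <- misspecifyPi(trainDat$pi, config@piMisspec)

    ctm <- trainCellAwareModel(trainDat$y, trainDat$X, Z = NULL,
                               piHat = piTrain,
                               alpha = config@enetAlpha,
                               nFolds = config@nFolds,
                               B = config@nStabilityBoot)
    tm <- trainTissueModel(trainDat$y, trainDat$X, Z = NULL,
                           alpha = config@enetAlpha,
                           nFolds = config@nFolds)

    gwasGen <- list(X = matrix(rbinom(config@nGwas * config@nSnps, 2L,
                                      rep(trainDat$maf,
                                          each = config@nGwas)),
                               nrow = config@nGwas),
                    maf = trainDat$maf)
    colnames(gwasGen$X) <- colnames(trainDat$X)
    gwasDat <- simulateCellData(config, genotypes = gwasGen,
                                effects = trainDat$effects,
                                n = config@nGwas)
    dis <- simulateDisease(gwasDat$u, gwasDat$v, config@eta1, config@eta2,
                           w = gwasDat$w, eta3 = config@eta3)

    resCT <- associateGene(ctm, gwasGen$X, dis$d, family = "binomial")
    resT <- associateGene(tm, gwasGen$X, dis$d, family = "binomial")

    c(pCellAware = if (resCT@testable) resCT@pTissue else NA_real_,
      pTissueBase = if (resT@testable) resT@pTissue else NA_real_,
      pCell1 = if (resCT@testable) resCT@pCell1 else NA_real_,
      pCell2 = if (resCT@testable) resCT@pCell2 else NA_real_,
      specific = as.numeric(modelType(ctm) == "cell_type_specific"),
      caseFrac = mean(dis$d))
}

#' Run a Monte Carlo type-I-error / power study
#'
#' For each replicate: simulate a training cohort, inject the configured
#' proportion misspecification, train the cell-type-aware model and the
#' tissue-level baseline, simulate an independent GWAS cohort from the same
#' generative model, test the gene with both methods, and record rejections
#' at the nominal level. Replicates where a model was untrainable (no
#' predictive SNPs) count as non-rejections for that method, mirroring how
#' such genes are untestable in practice. Replicates that fail outright are
#' skipped; more than 10% failures is an error.
#'
#' @param config a \linkS4class{SimulationConfig}; \code{config@seed}
#'   drives all randomness.
#' @return data.frame with one row per method (\code{cellAware},
#'   \code{tissueBaseline}, \code{cell1}, \code{cell2}): rejections, number
#'   of testable replicates, rejection rate over all replicates, and its
#'   binomial Monte Carlo standard error. Per-replicate p-values are
#'   attached as attribute \code{"replicates"}; the fraction of replicates
#'   with a cell-type-specific model as \code{"specificRate"}.
#' @export
runStudy <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    run <- function() {
        reps <- vector("list", config@nReps)
        nFail <- 0L
        for (r in seq_len(config@nReps)) {
            reps[[r]] <- tryCatch(.studyReplicate(config),
                                  error = function(e) {
                                      message("replicate ", r, " failed: ",
                                              conditionMessage(e))
                                      NULL
                                  })
            if (is.null(reps[[r]])) nFail <- nFail + 1L
        }
        if (nFail > 0.1 * config@nReps)
            stop("more than 10% of replicates failed (", nFail, "/",
                 config@nReps, ")")
        do.call(rbind, reps[!vapply(reps, is.null, logical(1))])
    }
    rep <- withr::with_seed(config@seed, run())

    alpha <- config@alphaLevel
    nReps <- nrow(rep)
    summarize <- function(p) {
        rej <- sum(!is.na(p) & p < alpha)
        rate <- rej / nReps
        c(rejections = rej, nTested = sum(!is.na(p)), rate = rate,
          se = sqrt(rate * (1 - rate) / nReps))
    }
    out <- as.data.frame(rbind(
        cellAware = summarize(rep[, "pCellAware"]),
        tissueBaseline = summarize(rep[, "pTissueBase"]),
        cell1 = summarize(rep[, "pCell1"]),
        cell2 = summarize(rep[, "pCell2"])))
    out <- cbind(method = rownames(out), out, nReps = nReps)
    rownames(out) <- NULL
    attr(out, "replicates") <- as.data.frame(rep)
    attr(out, "specificRate") <- mean(rep[, "specific"])
    out
}
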