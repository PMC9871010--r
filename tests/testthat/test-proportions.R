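test_that("rescalePrior maps score range onto a clipped (0,1) prior", {
    expect_equal(unname(rescalePrior(c(0.2, 0.5, 0.8))),
                 c(0.01, 0.5, 0.99))
    expect_equal(unname(rescalePrior(c(0, 1))), c(0.01, 0.99))
    expect_error(rescalePrior(c(3, 3, 3)), "identical")
    expect_error(rescalePrior(1), "at least 2")
    expect_error(rescalePrior(c(0.1, Inf)), "finite")
})

test_that("signatureLogLik matches the closed form on a minimal instance", {
    mix <- new("SignatureMixture", geneIds = "g1", muCell1 = 0,
               muCell2 = 0, sigmaCell1 = 1, sigmaCell2 = 1)
    ## variance at pi = 0.5 is 0.25 + 0.25 = 0.5; Beta(1, 1) log-density 0
    got <- signatureLogLik(matrix(0, 1, 1), pi = 0.5, mix,
                           prior = 0.5, delta = 2)
    expect_equal(got, -0.5 * log(2 * pi * 0.5), tolerance = 1e-12)
})

test_that("signatureLogLik is invariant under full label swap", {
    fx <- makeSignatureFixture(N = 20, G = 4, seed = 7)
    mix <- new("SignatureMixture", geneIds = colnames(fx$W),
               muCell1 = fx$mu1, muCell2 = fx$mu2,
               sigmaCell1 = rep(1, 4), sigmaCell2 = rep(1.3, 4))
    mixSwap <- new("SignatureMixture", geneIds = colnames(fx$W),
                   muCell1 = fx$mu2, muCell2 = fx$mu1,
                   sigmaCell1 = rep(1.3, 4), sigmaCell2 = rep(1, 4))
    piv <- seq(0.2, 0.8, length.out = 20)
    expect_equal(
        signatureLogLik(fx$W, piv, mix, fx$h, delta = 7),
        signatureLogLik(fx$W, 1 - piv, mixSwap, 1 - fx$h, delta = 7),
        tolerance = 1e-12)
})

test_that("signatureLogLik equals an independent density sum", {
    ## brute-force oracle written from the density formulas directly
    oracle <- function(W, piv, mu1, mu2, s1, s2, h, delta) {
        total <- 0
        for (i in seq_len(nrow(W))) {
            for (g in seq_len(ncol(W))) {
                m <- piv[i] * mu1[g] + (1 - piv[i]) * mu2[g]
                v <- piv[i]^2 * s1[g]^2 + (1 - piv[i])^2 * s2[g]^2
                total <- total - (W[i, g] - m)^2 / (2 * v) -
                    0.5 * log(2 * pi * v)
            }
            a <- piv[i] * delta; b <- (1 - piv[i]) * delta
            total <- total + (a - 1) * log(h[i]) + (b - 1) * log(1 - h[i]) -
                lbeta(a, b)
        }
        total
    }
    withr::with_seed(11, {
        W <- matrix(rnorm(6, sd = 2), 3, 2)
        piv <- runif(3, 0.1, 0.9)
        h <- runif(3, 0.1, 0.9)
        mu1 <- rnorm(2); mu2 <- rnorm(2)
        s1 <- runif(2, 0.5, 2); s2 <- runif(2, 0.5, 2)
    })
    mix <- new("SignatureMixture", geneIds = c("a", "b"),
               muCell1 = mu1, muCell2 = mu2,
               sigmaCell1 = s1, sigmaCell2 = s2)
    expect_equal(signatureLogLik(W, piv, mix, h, delta = 3.7),
                 oracle(W, piv, mu1, mu2, s1, s2, h, 3.7),
                 tolerance = 1e-10)
})

test_that("uninformative signature genes leave the prior in charge", {
    withr::with_seed(3, {
        N <- 60; G <- 5
        W <- sapply(seq_len(G), function(g) rnorm(N, g, 1))
        h <- pmin(pmax(runif(N, 0.1, 0.9), 0.01), 0.99)
    })
    cp <- fitSignatureMixture(W, h, maxIter = 100)
    expect_gt(cor(unname(piHat(cp)), h), 0.99)
})

test_that("informative signatures improve on a noisy prior", {
    fx <- makeSignatureFixture(N = 120, G = 15, muDiff = 2,
                               priorConc = 10, seed = 5)
    cp <- fitSignatureMixture(fx$W, fx$h)
    expect_true(cp@converged)
    expect_true(all(piHat(cp) > 0 & piHat(cp) < 1))
    expect_gte(cor(unname(piHat(cp)), fx$pi), cor(fx$h, fx$pi))
})

test_that("a nearly exact prior is reproduced (prior-consistency)", {
    fx <- makeSignatureFixture(N = 80, G = 8, muDiff = 2,
                               priorConc = 5000, seed = 9)
    cp <- fitSignatureMixture(fx$W, fx$h)
    expect_gt(cor(unname(piHat(cp)), fx$h), 0.99)
})

test_that("flipping the prior flips the estimate (label anchoring)", {
    fx <- makeSignatureFixture(N = 80, G = 10, muDiff = 2,
                               priorConc = 30, seed = 13)
    cp <- fitSignatureMixture(fx$W, fx$h)
    cpFlip <- fitSignatureMixture(fx$W, 1 - fx$h)
    expect_gt(cor(unname(piHat(cp)), 1 - unname(piHat(cpFlip))), 0.98)
    expect_lt(mean(abs(unname(piHat(cp)) -
                       (1 - unname(piHat(cpFlip))))), 0.05)
    ## component parameters swap roles
    expect_gt(cor(cp@mixture@muCell1, cpFlip@mixture@muCell2), 0.95)
})

test_that("tail-truncated mean drops the extreme bootstrap estimates", {
    expect_equal(cellTWAS:::.trimTails(rep(0.37, 8), 0.05), rep(0.37, 8))
    expect_equal(mean(cellTWAS:::.trimTails(
        c(0.10, 0.40, 0.40, 0.40, 0.90), 0.20)), 0.40)
    expect_equal(mean(cellTWAS:::.trimTails(rep(0.37, 5), 0.20)), 0.37)
})

test_that("bagged estimation is reproducible and well-formed", {
    fx <- makeSignatureFixture(N = 50, G = 8, muDiff = 2,
                               priorConc = 30, seed = 21)
    cp1 <- estimateCellProportions(fx$W, fx$h, nBoot = 6, seed = 42,
                                   maxIter = 60)
    cp2 <- estimateCellProportions(fx$W, fx$h, nBoot = 6, seed = 42,
                                   maxIter = 60)
    expect_identical(piHat(cp1), piHat(cp2))
    expect_true(all(piHat(cp1) > 0 & piHat(cp1) < 1))
    expect_true(all(cp1@bootSpread >= 0))
    expect_identical(cp1@nBoot, 6L)
})
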