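test_that("simulated genotypes follow HWE binomial sampling", {
    gen <- simulateGenotypes(3000, 20, seed = 5)
    expect_true(all(gen$X %in% 0:2))
    expect_true(all(gen$maf >= 0.05 & gen$maf <= 0.50))
    ## empirical allele frequency within 3 binomial SDs of the drawn MAF
    freq <- colMeans(gen$X) / 2
    sdExp <- sqrt(gen$maf * (1 - gen$maf) / (2 * 3000))
    expect_true(all(abs(freq - gen$maf) <= 3 * sdExp))
    ## fixed-seed reproducibility
    expect_identical(gen$X, simulateGenotypes(3000, 20, seed = 5)$X)
    expect_error(simulateGenotypes(10, 2, mafRange = c(0, 0.6)))
})

test_that("bulk expression is the exact proportion-weighted mixture", {
    cfg <- simulationConfig(nTrain = 200, nReps = 1, seed = 2)
    dat <- simulateCellData(cfg, seed = 2)
    expect_equal(dat$y, dat$pi * dat$u + (1 - dat$pi) * dat$v,
                 tolerance = 1e-14)
    ## three-cell variant: proportions sum to one, mixture exact
    cfg3 <- simulationConfig(threeCell = "distinct", nTrain = 200,
                             seed = 3)
    d3 <- simulateCellData(cfg3, seed = 3)
    expect_equal(d3$pi + d3$pi2 + d3$pi3, rep(1, 200), tolerance = 1e-12)
    expect_equal(d3$y, d3$pi * d3$u + d3$pi2 * d3$v + d3$pi3 * d3$w,
                 tolerance = 1e-14)
    ## latent third cell with shared effects reuses the cell-2 weights
    cfgS <- simulationConfig(threeCell = "shared", nTrain = 50, seed = 4)
    dS <- simulateCellData(cfgS, seed = 4)
    expect_identical(dS$effects$b3, dS$effects$b2)
})

test_that("the minor cell-type proportion averages 40%", {
    withr::with_seed(11, piDraws <- rbeta(1e5, 2, 3))
    expect_lt(abs(mean(piDraws) - 0.40), 0.002)
    cfg <- simulationConfig(nTrain = 5000, seed = 12)
    dat <- simulateCellData(cfg, seed = 12)
    expect_lt(abs(mean(dat$pi) - 0.40), 0.01)
})

test_that("null expression variance matches the mixture moments", {
    ## with b = 0 and unit noise, Var(y) = E[pi^2 + (1 - pi)^2] = 0.6
    cfg <- simulationConfig(nTrain = 20000, b0 = 0, b1Mag = 0,
                            b2Mag = 0, seed = 21)
    dat <- simulateCellData(cfg, seed = 21)
    expect_lt(abs(var(dat$y) - 0.6), 0.03)
})

test_that("single-SNP heritability follows the closed form", {
    cfg <- simulationConfig(nTrain = 30000, snpExp = "homogeneous",
                            b0 = 0, seed = 31)
    dat <- simulateCellData(cfg, seed = 31)
    p <- dat$maf[which(dat$effects$b1 != 0)]
    h2 <- 2 * p * (1 - p) / (2 * p * (1 - p) + 1)
    genVar <- var(drop(dat$X %*% dat$effects$b1))
    expect_lt(abs(genVar / var(dat$u) - h2), 0.02)
})

test_that("disease intercept calibration balances cases and controls", {
    withr::with_seed(41, { u <- rnorm(3000); v <- rnorm(3000) })
    ## no association: the intercept is exactly zero
    d0 <- simulateDisease(u, v, 0, 0, seed = 41)
    expect_equal(d0$eta0, 0, tolerance = 1e-8)
    ## symmetric mean-zero expression keeps the intercept near zero
    dS <- simulateDisease(u, v, 0.2, 0.2, seed = 42)
    expect_lt(abs(dS$eta0), 0.05)
    ## achieved case fraction within 3 binomial SDs of 1/2
    dA <- simulateDisease(u + 1, v, 0.2, -0.1, seed = 43)
    expect_lt(abs(mean(dA$d) - 0.5), 3 * sqrt(0.25 / 3000))
})

test_that("proportion misspecification scenarios match their design", {
    withr::with_seed(51, piTrue <- rbeta(1e4, 2, 3))
    s1 <- misspecifyPi(piTrue, "scale_0.8")
    expect_lt(abs(mean(s1) - 0.32), 0.01)
    expect_lte(max(s1), 0.8)
    s2 <- misspecifyPi(piTrue, "affine_0.7_0.2")
    expect_lt(abs(mean(s2) - 0.48), 0.01)
    expect_gte(min(s2), 0.2)
    ## closed-form correlation of a Beta(conc*pi, conc*(1-pi)) draw with
    ## pi ~ Beta(2,3): sqrt(Var(pi) / (Var(pi) + E[pi(1-pi)]/(conc+1)))
    corOracle <- function(conc) sqrt(0.04 / (0.04 + 0.2 / (conc + 1)))
    s3 <- misspecifyPi(piTrue, "beta_conc_50", seed = 52)
    expect_lt(abs(cor(s3, piTrue) - corOracle(50)), 0.01)
    s4 <- misspecifyPi(piTrue, "beta_conc_5.5", seed = 53)
    expect_lt(abs(cor(s4, piTrue) - corOracle(5.5)), 0.02)
    expect_identical(misspecifyPi(piTrue, "none"), piTrue)
    expect_error(misspecifyPi(piTrue, "bogus"), "unknown")
})

test_that("study runs are reproducible and well-formed", {
    cfg <- scenarioPreset("het-null", nReps = 3, seed = 9,
                          nStabilityBoot = 50)
    r1 <- runStudy(cfg)
    r2 <- runStudy(cfg)
    expect_identical(attr(r1, "replicates"), attr(r2, "replicates"))
    expect_setequal(r1$method,
                    c("cellAware", "tissueBaseline", "cell1", "cell2"))
    expect_true(all(r1$rate >= 0 & r1$rate <= 1))
    expect_error(scenarioPreset("not-a-preset"), "unknown preset")
})
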