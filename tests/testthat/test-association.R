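test_that("Cauchy combination satisfies its algebraic identities", {
    ## exact centre point
    cc <- cauchyCombine(0.5, 0.5)
    expect_identical(cc$tCauchy, 0)
    expect_identical(cc$pTissue, 0.5)
    ## equal inputs are returned unchanged (equal weights sum to one)
    for (p in c(1e-8, 1e-4, 0.01, 0.1, 0.5, 0.9))
        expect_lt(abs(cauchyCombine(p, p)$pTissue - p), 1e-12)
    ## direct numeric evaluation of the transform as the oracle
    direct <- function(p1, p2) {
        tC <- 0.5 * tan(pi * (0.5 - p1)) + 0.5 * tan(pi * (0.5 - p2))
        0.5 - atan(tC) / pi
    }
    expect_equal(cauchyCombine(0.01, 0.5)$pTissue, direct(0.01, 0.5),
                 tolerance = 1e-12)
    expect_equal(round(cauchyCombine(0.01, 0.5)$pTissue, 3), 0.02)
})

test_that("Cauchy combination is symmetric, monotone and bracketed", {
    grid <- c(1e-6, 1e-3, 0.02, 0.1, 0.3, 0.5, 0.7, 0.95)
    for (p1 in grid) for (p2 in grid) {
        a <- cauchyCombine(p1, p2)$pTissue
        expect_equal(a, cauchyCombine(p2, p1)$pTissue, tolerance = 1e-14)
        expect_gte(a, min(p1, p2) - 1e-12)
        expect_lte(a, max(p1, p2) + 1e-12)
    }
    ## increasing either argument never decreases the combination
    for (p2 in grid) {
        vals <- vapply(grid, function(p1)
            cauchyCombine(p1, p2)$pTissue, numeric(1))
        expect_true(all(diff(vals) >= -1e-12))
    }
    ## one NA component: the other p-value passes through
    expect_equal(cauchyCombine(NA, 0.07)$pTissue, 0.07)
    ## the literal unweighted sum is offered but differs
    expect_gt(cauchyCombine(0.2, 0.8, weights = c(1, 1))$pTissue + 1e-12,
              0)
    expect_false(isTRUE(all.equal(
        cauchyCombine(0.01, 0.5, weights = c(1, 1))$pTissue,
        cauchyCombine(0.01, 0.5)$pTissue)))
})

test_that("identical cell-level GReX triggers separate marginal tests", {
    withr::with_seed(7, {
        y <- rnorm(200)
        d <- rbinom(200, 1, 0.5)
    })
    pred <- new("GrexPrediction", subjectIds = paste0("s", 1:200),
                cell1 = y, cell2 = y, tissue = numeric(0))
    ct <- cellLevelTest(pred, d, family = "binomial")
    expect_identical(ct$mode, "separate")
    expect_equal(ct$pCell1, ct$pCell2)
})

test_that("joint testing attributes signal to the right cell type", {
    hits <- 0L
    for (s in 1:6) {
        withr::with_seed(300 + s, {
            n <- 2000
            y1 <- rnorm(n); y2 <- rnorm(n)
            pr <- plogis(0.4 * y1)   # association only in cell 1
            d <- rbinom(n, 1, pr)
        })
        pred <- new("GrexPrediction", subjectIds = paste0("s", 1:n),
                    cell1 = y1, cell2 = y2, tissue = numeric(0))
        ct <- cellLevelTest(pred, d, family = "binomial")
        expect_identical(ct$mode, "joint")
        if (ct$effectCell1 > 0 && ct$pCell1 < ct$pCell2) hits <- hits + 1L
    }
    expect_gte(hits, 5L)
})

test_that("both-constant predictions are reported untestable", {
    pred <- new("GrexPrediction", subjectIds = paste0("s", 1:60),
                cell1 = rep(0, 60), cell2 = rep(0, 60),
                tissue = numeric(0))
    ct <- suppressWarnings(cellLevelTest(pred, rbinom(60, 1, 0.5)))
    expect_false(ct$testable)
})

test_that("nonspecific pipeline reproduces the single tissue-level test", {
    withr::with_seed(23, {
        n <- 500
        X <- simulateGenotypes(n, 3)$X
        d <- rbinom(n, 1, plogis(0.3 * X[, 1] - 0.2))
    })
    mdl <- new("CellTypeModel", geneId = "g",
               snpInfo = data.frame(snp = colnames(X), chrom = "1",
                                    pos = 1:3, refAllele = "A",
                                    effAllele = "G",
                                    stringsAsFactors = FALSE),
               weightsCell1 = c(0.4, -0.2, 0.1),
               weightsCell2 = c(0.4, -0.2, 0.1),
               interceptCell1 = 0, interceptCell2 = 0,
               covWeights = numeric(0), modelType = "nonspecific",
               diffCI = data.frame(snp = character(0), lo = numeric(0),
                                   hi = numeric(0), selFreq = numeric(0)),
               nBoot = 0L, cvPerformance = 0.5, trainable = TRUE)
    res <- associateGene(mdl, X, d, family = "binomial")
    expect_identical(res@mode, "single")
    ## oracle: the direct glm on the combined prediction
    g <- drop(X %*% c(0.4, -0.2, 0.1))
    pOracle <- summary(glm(d ~ g, family = binomial()))$coefficients[2, 4]
    expect_equal(res@pTissue, pOracle, tolerance = 1e-12)
    expect_equal(res@pCell1, res@pTissue)
    ## an untrainable model is untestable
    bad <- mdl
    bad@trainable <- FALSE
    resBad <- associateGene(bad, X, d)
    expect_false(resBad@testable)
    expect_identical(resBad@mode, "none")
})

test_that("transcriptome-wide summary applies Bonferroni and BH", {
    res <- list(makeAssocResult("g1", 0.01), makeAssocResult("g2", 0.02),
                makeAssocResult("g3", 0.5))
    tab <- transcriptomeWide(res, fwer = 0.05, fdr = 0.10)
    expect_equal(attr(tab, "bonferroniThreshold"), 0.05 / 3)
    ## brute-force BH step-up: k = max{i: p_(i) <= i * q / m} = 2
    expect_equal(sum(tab$discoveryFDR), 2L)
    expect_false(tab$discoveryFDR[tab$gene == "g3"])

    one <- transcriptomeWide(list(makeAssocResult("g", 0.2)))
    expect_equal(attr(one, "bonferroniThreshold"), 0.05)

    ## untestable genes leave the denominator
    res2 <- c(res, list(makeAssocResult("g4", NA_real_,
                                        testable = FALSE)))
    tab2 <- transcriptomeWide(res2)
    expect_equal(attr(tab2, "bonferroniThreshold"), 0.05 / 3)
    expect_true(is.na(tab2$pAdjustBH[tab2$gene == "g4"]))
})
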