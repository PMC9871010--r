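test_that("the mixture design carries centered-proportion interactions", {
    X <- matrix(c(2, 0, 1, 1), 2, 2,
                dimnames = list(NULL, c("s1", "s2")))
    dz <- buildCellAwareDesign(X, NULL, piHat = c(0.9, 0.5))
    expect_equal(unname(dz$design[1, "chat"]), 0.4)
    expect_equal(unname(dz$design[1, "s1:chat"]), 0.8)  # (0.9 - 0.5) * 2
    expect_equal(unname(dz$design[2, "chat"]), 0)
    expect_true(all(dz$design[2, c("s1:chat", "s2:chat")] == 0))
    expect_equal(dz$penaltyFactor, c(0, 1, 1, 1, 1))

    ## pi = 0.5 everywhere: interaction block vanishes entirely
    dz5 <- buildCellAwareDesign(X, NULL, piHat = c(0.5, 0.5))
    expect_true(all(dz5$design[, c("chat", "s1:chat", "s2:chat")] == 0))

    ## complementary proportions only flip the sign of chat blocks
    dzC <- buildCellAwareDesign(X, NULL, piHat = 1 - c(0.9, 0.5))
    expect_equal(dzC$design[, "chat"], -dz$design[, "chat"])
    expect_equal(dzC$design[, "s1:chat"], -dz$design[, "s1:chat"])
    expect_equal(dzC$design[, "s2"], dz$design[, "s2"])
})

test_that("tissue model recovers a single causal SNP", {
    withr::with_seed(31, {
        n <- 300
        gen <- simulateGenotypes(n, 50)
        y <- drop(gen$X %*% replace(numeric(50), 7, 1)) + rnorm(n)
    })
    tm <- trainTissueModel(y, gen$X, seed = 1)
    expect_true(isTrainable(tm))
    w <- modelWeights(tm)
    expect_true("snp7" %in% names(w))
    expect_gt(w["snp7"], 0.5)
    expect_lt(w["snp7"], 1.2)
    ## the cross-validated correlation is meaningfully positive
    expect_gt(cvPerformance(tm), 0.2)
})

test_that("pure-noise expression yields an empty or near-empty model", {
    ## CV-minimum elastic net occasionally admits a few noise SNPs; the
    ## model must never carry real signal (cv correlation near zero)
    empty <- 0L
    for (s in 1:10) {
        withr::with_seed(100 + s, {
            gen <- simulateGenotypes(300, 50)
            y <- rnorm(300)
        })
        tm <- trainTissueModel(y, gen$X, seed = s)
        if (!isTrainable(tm)) empty <- empty + 1L
        expect_lt(cvPerformance(tm), 0.25)
    }
    expect_gte(empty, 5L)
})

test_that("an overwhelming penalty empties the model", {
    fx <- makeGrexFixture(n = 120, m = 10, seed = 41)
    tm <- trainTissueModel(fx$y, fx$X, lambda = 1e6)
    expect_false(isTrainable(tm))
    ct <- trainCellAwareModel(fx$y, fx$X, piHat = fx$pi, lambda = 1e6)
    expect_false(isTrainable(ct))
    asym <- trainAsymmetricModel(fx$y, fx$X, piHat = fx$pi, lambda = 1e6)
    expect_false(isTrainable(asym))
    expect_error(trainTissueModel(rep(1, 120), fx$X), "constant")
})

test_that("unpenalized mixture fit equals OLS on the augmented design", {
    fx <- makeGrexFixture(n = 150, m = 8, seed = 51)
    ct <- trainCellAwareModel(fx$y, fx$X, piHat = fx$pi, lambda = 0,
                              B = 50, seed = 3)
    dz <- buildCellAwareDesign(fx$X, NULL, fx$pi)
    ols <- coef(lm(fx$y ~ dz$design))
    bX <- ols[paste0("dz$design", colnames(fx$X))]
    bCX <- ols[paste0("dz$design", colnames(fx$X), ":chat")]
    bU <- unname(bX + bCX / 2)
    bV <- unname(bX - bCX / 2)
    ## compare on the selected support (lambda = 0 keeps everything)
    ord <- match(snpInfo(ct)$snp, colnames(fx$X))
    if (modelType(ct) == "cell_type_specific") {
        expect_equal(unname(modelWeights(ct, 1)), bU[ord],
                     tolerance = 1e-6)
        expect_equal(unname(modelWeights(ct, 2)), bV[ord],
                     tolerance = 1e-6)
    } else {
        ## collapsed model: the tissue-level lambda = 0 fit is plain OLS
        olsT <- coef(lm(fx$y ~ fx$X))[-1]
        expect_equal(unname(modelWeights(ct, 1)), unname(olsT[ord]),
                     tolerance = 1e-6)
    }
})

test_that("relabelling the cell types relabels the fitted model", {
    fx <- makeGrexFixture(n = 200, m = 20, seed = 61)
    ct1 <- trainCellAwareModel(fx$y, fx$X, piHat = fx$pi, B = 50,
                               seed = 17)
    ct2 <- trainCellAwareModel(fx$y, fx$X, piHat = 1 - fx$pi, B = 50,
                               seed = 17)
    expect_identical(snpInfo(ct1)$snp, snpInfo(ct2)$snp)
    expect_equal(unname(modelWeights(ct1, 1)),
                 unname(modelWeights(ct2, 2)), tolerance = 1e-8)
    expect_equal(unname(modelWeights(ct1, 2)),
                 unname(modelWeights(ct2, 1)), tolerance = 1e-8)
    expect_equal(ct1@interceptCell1, ct2@interceptCell2,
                 tolerance = 1e-8)

    ## tissue-level predictions agree once proportions are relabelled too
    withr::with_seed(62, newX <- simulateGenotypes(40, 20)$X)
    piNew <- seq(0.05, 0.95, length.out = 40)
    p1 <- grexTissue(predictGrex(ct1, newX, piNew = piNew))
    p2 <- grexTissue(predictGrex(ct2, newX, piNew = 1 - piNew))
    expect_equal(unname(p1), unname(p2), tolerance = 1e-8)
})

test_that("constant proportions collapse the fit to the tissue model", {
    fx <- makeGrexFixture(n = 200, m = 20, homogeneous = TRUE, seed = 71)
    ct <- trainCellAwareModel(fx$y, fx$X,
                              piHat = rep(0.5, 200), B = 50, seed = 5)
    tm <- trainTissueModel(fx$y, fx$X, seed = 5)
    expect_identical(modelType(ct), "nonspecific")
    expect_equal(modelWeights(ct, 1), modelWeights(ct, 2))
    common <- intersect(names(modelWeights(ct, 1)), names(modelWeights(tm)))
    expect_gt(length(common), 0)
    expect_equal(modelWeights(ct, 1)[common], modelWeights(tm)[common],
                 tolerance = 1e-6)
})

test_that("distinct causal SNPs per cell type yield a specific model", {
    fx <- makeGrexFixture(n = 300, m = 50, bCell1 = 1, bCell2 = 1,
                          seed = 82)
    ct <- trainCellAwareModel(fx$y, fx$X, piHat = fx$pi, seed = 9)
    expect_identical(modelType(ct), "cell_type_specific")
    w1 <- modelWeights(ct, 1); w2 <- modelWeights(ct, 2)
    p1 <- paste0("snp", fx$causal[1L]); p2 <- paste0("snp", fx$causal[2L])
    expect_gt(w1[p1], 0)
    expect_gt(w2[p2], 0)
    expect_true(all(ct@diffCI$lo <= ct@diffCI$hi))
})

test_that("homogeneous SNP effects mostly give nonspecific models", {
    types <- character(10)
    for (s in 1:10) {
        fx <- makeGrexFixture(n = 300, m = 50, homogeneous = TRUE,
                              seed = 200 + s)
        ct <- trainCellAwareModel(fx$y, fx$X, piHat = fx$pi, B = 100,
                                  seed = s)
        types[s] <- modelType(ct)
    }
    expect_gt(sum(types == "nonspecific"), 5)
})

test_that("the asymmetric variant is order-dependent, the symmetric not", {
    fx <- makeGrexFixture(n = 250, m = 20, seed = 91)
    a1 <- trainAsymmetricModel(fx$y, fx$X, piHat = fx$pi, seed = 23)
    a2 <- trainAsymmetricModel(fx$y, fx$X, piHat = 1 - fx$pi, seed = 23)
    ## under relabelling the asymmetric fit does NOT swap its weights
    w1 <- replace(numeric(20), match(snpInfo(a1)$snp,
                                     colnames(fx$X)), a1@weightsCell1)
    w2swap <- replace(numeric(20), match(snpInfo(a2)$snp,
                                         colnames(fx$X)), a2@weightsCell2)
    expect_gt(max(abs(w1 - w2swap)), 1e-3)
})

test_that("asymmetric fit under homogeneous effects has similar weights", {
    fx <- makeGrexFixture(n = 300, m = 20, homogeneous = TRUE, seed = 95)
    a <- trainAsymmetricModel(fx$y, fx$X, piHat = fx$pi, seed = 7)
    expect_lt(max(abs(a@weightsCell1 - a@weightsCell2)), 0.5)
})

test_that("GReX prediction applies weights without intercepts", {
    X <- matrix(2, 1, 1, dimnames = list("s1", "rs1"))
    m <- makeToyCellModel(0.5, -0.5)
    pred <- predictGrex(m, X)
    expect_equal(unname(grexCell1(pred)), 1.0)
    expect_equal(unname(grexCell2(pred)), -1.0)
    predPi <- predictGrex(m, X, piNew = 0.4)
    expect_equal(unname(grexTissue(predPi)), 0.4 * 1 + 0.6 * (-1))

    ## nonspecific: both cell types coincide exactly
    mn <- makeToyCellModel(0.5, 0.5)
    predN <- predictGrex(mn, X)
    expect_identical(grexCell1(predN), grexCell2(predN))
})

test_that("missing model SNPs beyond the tolerated fraction error out", {
    m <- makeToyCellModel(0.5, -0.5)
    Xother <- matrix(1, 2, 1, dimnames = list(NULL, "rsX"))
    expect_error(predictGrex(m, Xother), "rs1")
})

test_that("prediction evaluation flags and compares methods", {
    fx <- makeGrexFixture(n = 200, m = 10, seed = 99)
    tm <- trainTissueModel(fx$y, fx$X, seed = 2)
    ## an identical pair of methods is indistinguishable
    out <- evaluatePrediction(list(a = list(tm), b = list(tm)),
                              matrix(fx$y), fx$X)
    expect_equal(out$comparisons$wilcoxonP, 1)
    ## a perfect prediction scores r = 1
    perfect <- makeToyCellModel(1, 1, snp = "snp1")
    X <- fx$X[, 1, drop = FALSE]
    yT <- matrix(X[, 1] * 1.0)
    res <- evaluatePrediction(list(perfect), yT, X)
    expect_equal(res$r, 1)
    ## a zero-variance prediction is flagged with r = 0
    empty <- makeToyCellModel(0, 0, snp = "snp1")
    res0 <- evaluatePrediction(list(empty), yT, X)
    expect_equal(res0$r, 0)
    expect_true(res0$zeroVariance)
})

test_that("decomposition rescues held-out prediction when cell effects \
cancel at the tissue level", {
    ## a SNP acting in opposite directions in the two cell types leaves
    ## almost no net tissue-level signal; the tissue baseline has nothing
    ## to fit while the cell-aware model recovers both components
    nGenes <- 12
    rCT <- numeric(nGenes); rTM <- numeric(nGenes)
    for (j in seq_len(nGenes)) {
        fx <- makeGrexFixture(n = 450, m = 30, opposite = TRUE,
                              seed = 400 + j)
        tr <- 1:300; ho <- 301:450
        ct <- trainCellAwareModel(fx$y[tr], fx$X[tr, ],
                                  piHat = fx$pi[tr], B = 60, seed = j,
                                  geneId = paste0("g", j))
        tm <- trainTissueModel(fx$y[tr], fx$X[tr, ], seed = j,
                               geneId = paste0("g", j))
        yHo <- matrix(fx$y[ho])
        rCT[j] <- evaluatePrediction(list(ct), yHo, fx$X[ho, ],
                                     pi = fx$pi[ho])$r
        rTM[j] <- evaluatePrediction(list(tm), yHo, fx$X[ho, ],
                                     pi = fx$pi[ho])$r
    }
    expect_gt(median(rCT), median(rTM))
    wp <- wilcox.test(rCT, rTM, paired = TRUE, exact = FALSE)$p.value
    expect_lt(wp, 0.01)
})
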