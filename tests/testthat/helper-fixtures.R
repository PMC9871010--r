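## Shared fixture builders for the test suite. Everything is generated in
## code under fixed seeds; no data files are shipped.

## signature-gene expression mixed from two Gaussian cell components,
## with a Beta-linked noisy prior of the requested concentration
makeSignatureFixture <- function(N = 120, G = 15, muDiff = 2, sigma = 1,
                                 priorConc = 50, seed = 1) {
    withr::with_seed(seed, {
        pi <- rbeta(N, 2, 3)
        mu1 <- rnorm(G, muDiff, 0.3)
        mu2 <- rnorm(G, 0, 0.3)
        S <- sapply(seq_len(G), function(g) rnorm(N, mu1[g], sigma))
        T2 <- sapply(seq_len(G), function(g) rnorm(N, mu2[g], sigma))
        W <- pi * S + (1 - pi) * T2
        h <- pmin(pmax(rbeta(N, priorConc * pi, priorConc * (1 - pi)),
                       0.01), 0.99)
        colnames(W) <- paste0("sig", seq_len(G))
        rownames(W) <- paste0("s", seq_len(N))
        list(W = W, pi = pi, h = h, mu1 = mu1, mu2 = mu2)
    })
}

## bulk expression from the two-cell mixture: one causal SNP per cell
## type ("heterogeneous", default), one shared causal SNP ("homogeneous"),
## or one shared SNP with opposite effects ("opposite" — the cancellation
## regime where the tissue-level average loses the signal)
makeGrexFixture <- function(n = 300, m = 50, b0 = 1, bCell1 = 1,
                            bCell2 = 1, homogeneous = FALSE,
                            opposite = FALSE, seed = 1) {
    withr::with_seed(seed, {
        gen <- simulateGenotypes(n, m)
        pi <- rbeta(n, 2, 3)
        b1 <- numeric(m); b2 <- numeric(m)
        if (opposite) {
            p <- sample.int(m, 1L)
            b1[p] <- bCell1; b2[p] <- -bCell1
            causal <- c(p, p)
        } else if (homogeneous) {
            p <- sample.int(m, 1L)
            b1[p] <- bCell1; b2[p] <- bCell1
            causal <- c(p, p)
        } else {
            p <- sample.int(m, 2L)
            b1[p[1L]] <- bCell1; b2[p[2L]] <- bCell2
            causal <- p
        }
        u <- b0 + drop(gen$X %*% b1) + rnorm(n)
        v <- drop(gen$X %*% b2) + rnorm(n)
        y <- pi * u + (1 - pi) * v
        list(X = gen$X, maf = gen$maf, pi = pi, u = u, v = v, y = y,
             b1 = b1, b2 = b2, causal = causal)
    })
}

## a minimal single-SNP cell-type model built directly
makeToyCellModel <- function(w1, w2, snp = "rs1", ref = "A", eff = "G",
                             type = if (isTRUE(all.equal(w1, w2)))
                                 "nonspecific" else "cell_type_specific") {
    new("CellTypeModel", geneId = "toy",
        snpInfo = data.frame(snp = snp, chrom = "1", pos = 100L,
                             refAllele = ref, effAllele = eff,
                             stringsAsFactors = FALSE),
        weightsCell1 = w1, weightsCell2 = w2,
        interceptCell1 = 0, interceptCell2 = 0,
        covWeights = numeric(0), modelType = type,
        diffCI = data.frame(snp = character(0), lo = numeric(0),
                            hi = numeric(0), selFreq = numeric(0)),
        nBoot = 0L, cvPerformance = NA_real_, trainable = TRUE)
}

makeAssocResult <- function(gene, p, testable = TRUE) {
    new("AssociationResult", geneId = gene, mode = "single",
        effectCell1 = 0.1, seCell1 = 0.1, pCell1 = p,
        effectCell2 = 0.1, seCell2 = 0.1, pCell2 = p,
        tCauchy = 0, pTissue = p, testable = testable)
}

## small VCF written as plain text
writeToyVcf <- function(path, withDS = FALSE, withMissing = FALSE) {
    gtFmt <- if (withDS) "GT:DS" else "GT"
    g <- function(gt, ds) if (withDS) paste0(gt, ":", ds) else gt
    lines <- c(
        "##fileformat=VCFv4.2",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        if (withDS)
            "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
        paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", "ind1", "ind2", "ind3", sep = "\t"),
        paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", gtFmt,
              g("0/1", "1.73"), g("1/1", "2.0"), g("0/0", "0.1"),
              sep = "\t"),
        paste("1", "200", "rs2", "C", "T", ".", "PASS", ".", gtFmt,
              g("0|1", "1.0"),
              if (withMissing) g("./.", ".") else g("0/0", "0.0"),
              g("1/1", "1.9"), sep = "\t"))
    writeLines(lines, path)
    path
}
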