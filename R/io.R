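## Readers and writers for the plain-text formats the tool touches, plus
## genotype-model allele harmonization.
##
## TSV dialect: tab-separated, UTF-8, '.' for missing, mandatory header
## row. Output files carry '#'-prefixed header lines recording the package
## version, seed and a config checksum, which all readers skip.

#' Genotypes harmonized to a model's SNPs and effect alleles
#'
#' @slot subjectIds character.
#' @slot dosages subjects x SNPs matrix aligned to the retained model SNPs,
#'   allele-flipped where needed (values in [0, 2]).
#' @slot provenance data.frame with columns \code{snp} and \code{status}
#'   (\code{matched}, \code{swapped} or \code{dropped}) for every model SNP.
#'
#' @export
setClass("HarmonizedGenotypes",
    representation(subjectIds = "character", dosages = "matrix",
                   provenance = "data.frame"))

setValidity("HarmonizedGenotypes", function(object) {
    msg <- character()
    if (length(object@dosages) &&
        (min(object@dosages) < 0 || max(object@dosages) > 2))
        msg <- c(msg, "dosages must lie in [0, 2]")
    if (!all(object@provenance$status %in%
             c("matched", "swapped", "dropped")))
        msg <- c(msg, "provenance status must be matched/swapped/dropped")
    if (length(msg)) msg else TRUE
})

setMethod("show", "HarmonizedGenotypes", function(object) {
    tab <- table(factor(object@provenance$status,
                        c("matched", "swapped", "dropped")))
    cat("HarmonizedGenotypes:", length(object@subjectIds), "subjects;",
        tab["matched"], "matched,", tab["swapped"], "swapped,",
        tab["dropped"], "dropped SNPs\n")
})

.metaHeader <- function(seed = NULL, extra = character()) {
    cfg <- paste(extra, collapse = ";")
    checksum <- sum(utf8ToInt(cfg)) %% 1e6
    c(paste0("# cellTWAS version=",
             as.character(packageVersion("cellTWAS"))),
      paste0("# seed=", if (is.null(seed)) "NA" else seed),
      paste0("# config=", cfg, " checksum=", checksum))
}

.writeTsv <- function(df, path, seed = NULL, extra = character()) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(.metaHeader(seed, extra), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                na = ".")
    invisible(path)
}

.readTsv <- function(path) {
    read.delim(path, comment.char = "#", na.strings = ".",
               stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a signature/bulk expression matrix
#'
#' TSV with samples as rows and genes as columns; the first column holds
#' the sample identifier and the header row the gene identifiers.
#'
#' @param path file path.
#' @return numeric matrix with sample ids as rownames.
#' @export
readExpressionMatrix <- function(path) {
    df <- .readTsv(path)
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- as.character(df[[1L]])
    m
}

#' Read per-sample prior enrichment scores
#'
#' Two-column TSV (sample id, score).
#'
#' @param path file path.
#' @return named numeric vector of raw scores (not yet rescaled; see
#'   \code{\link{rescalePrior}}).
#' @export
readPriorScores <- function(path) {
    df <- .readTsv(path)
    stopifnot(ncol(df) >= 2)
    setNames(as.numeric(df[[2L]]), as.character(df[[1L]]))
}

#' Write estimated cell proportions
#'
#' Writes a two-column TSV (sample id, proportion) plus a JSON sidecar
#' (\code{<path>.json}) recording delta, the bootstrap count, the trim
#' fraction and the seed.
#'
#' @param cp a \linkS4class{CellProportions}.
#' @param path output TSV path.
#' @param seed seed recorded in the outputs.
#' @return \code{path}, invisibly.
#' @export
writeCellProportions <- function(cp, path, seed = NULL) {
    stopifnot(is(cp, "CellProportions"))
    df <- data.frame(sample_id = cp@sampleIds, pi_hat = cp@piHat)
    .writeTsv(df, path, seed = seed,
              extra = c(paste0("delta=", signif(cp@delta, 6)),
                        paste0("n_boot=", cp@nBoot)))
    jsonlite::write_json(
        list(delta = cp@delta, n_boot = cp@nBoot, trim = cp@trimFrac,
             seed = if (is.null(seed)) NA else seed,
             converged = cp@converged, objective = cp@objective),
        paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Read genotype dosages from VCF or TSV
#'
#' VCF: the DS (dosage) FORMAT field is preferred when present, otherwise
#' GT genotypes are converted to alternate-allele counts. Sporadically
#' missing genotypes are mean-imputed per SNP (with a warning reporting the
#' count). TSV: SNPs as rows (first column SNP id, header subject ids).
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"vcf"} or
#'   \code{"tsv"}.
#' @return list with \code{dosages} (subjects x SNPs matrix) and
#'   \code{snpInfo} (data.frame: snp, chrom, pos, refAllele, effAllele;
#'   the effect allele is the VCF ALT allele).
#' @export
readGenotypes <- function(path, format = c("auto", "vcf", "tsv")) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
    if (format == "vcf") .readGenotypesVcf(path) else
        .readGenotypesTsv(path)
}

.meanImpute <- function(dos) {
    nMiss <- sum(is.na(dos))
    if (nMiss > 0) {
        warning(nMiss, " missing genotype(s) mean-imputed per SNP",
                call. = FALSE)
        for (j in seq_len(ncol(dos))) {
            miss <- is.na(dos[, j])
            if (any(miss))
                dos[miss, j] <- mean(dos[!miss, j])
        }
    }
    dos
}

.readGenotypesVcf <- function(path) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    ids <- fix[, "ID"]
    noId <- is.na(ids) | ids == "."
    ids[noId] <- paste0(fix[noId, "CHROM"], ":", fix[noId, "POS"])
    if (anyDuplicated(ids)) stop("duplicate SNP ids in ", path)

    fmt <- unique(unlist(strsplit(vcf@gt[, 1L], ":")))
    if ("DS" %in% fmt) {
        ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
    } else if ("GT" %in% fmt) {
        gt <- vcfR::extract.gt(vcf, element = "GT")
        ds <- apply(gt, 2L, function(g) {
            g <- gsub("\\|", "/", g)
            vapply(strsplit(g, "/"), function(a) {
                if (length(a) == 0L || anyNA(a) || any(a == "."))
                    return(NA_real_)
                sum(a != "0")
            }, numeric(1))
        })
        if (is.null(dim(ds))) ds <- matrix(ds, nrow = length(ids))
    } else {
        stop("VCF has neither DS nor GT FORMAT fields")
    }
    rownames(ds) <- ids
    dosages <- .meanImpute(t(ds))
    list(dosages = dosages,
         snpInfo = data.frame(snp = ids,
                              chrom = fix[, "CHROM"],
                              pos = as.integer(fix[, "POS"]),
                              refAllele = fix[, "REF"],
                              effAllele = fix[, "ALT"],
                              stringsAsFactors = FALSE))
}

.readGenotypesTsv <- function(path) {
    df <- .readTsv(path)
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids)) stop("duplicate SNP ids in ", path)
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    dosages <- .meanImpute(t(m))
    list(dosages = dosages, snpInfo = .defaultSnpInfo(ids))
}

#' Write genotype dosages as TSV (SNPs x samples)
#'
#' @param dosages subjects x SNPs matrix.
#' @param path output path.
#' @param seed seed recorded in the header.
#' @return \code{path}, invisibly.
#' @export
writeGenotypesTsv <- function(dosages, path, seed = NULL) {
    df <- data.frame(snp = colnames(dosages),
                     t(dosages), check.names = FALSE)
    .writeTsv(df, path, seed = seed)
}

#' Read a phenotype/covariate table
#'
#' TSV with a subject id column, a phenotype column and any covariates.
#'
#' @param path file path.
#' @param phenotypeCol name of the phenotype column (default
#'   \code{"phenotype"}).
#' @return data.frame with rownames = subject ids, the phenotype first.
#' @export
readPhenotypes <- function(path, phenotypeCol = "phenotype") {
    df <- .readTsv(path)
    if (!phenotypeCol %in% names(df))
        stop("phenotype column '", phenotypeCol, "' not found in ", path)
    rownames(df) <- as.character(df[[1L]])
    df[[1L]] <- NULL
    df[c(phenotypeCol, setdiff(names(df), phenotypeCol))]
}

.AMBIGUOUS <- c("A/T", "T/A", "C/G", "G/C")

#' Harmonize genotype dosages to a model's SNPs and alleles
#'
#' Aligns a dosage matrix to the SNPs of a trained model. A SNP whose
#' ref/effect alleles match the model exactly is kept (\code{matched});
#' one with the alleles reversed is kept with dosage transformed to
#' \code{2 - d} (\code{swapped}); strand-ambiguous pairs (A/T, C/G) are
#' dropped by default, as are SNPs absent from the genotypes or with
#' incompatible alleles. Harmonization is an involution: applying it to
#' already-harmonized data changes nothing.
#'
#' @param modelSnpInfo data.frame with columns snp, refAllele, effAllele
#'   (as stored in a \linkS4class{GrexModel}).
#' @param dosages subjects x SNPs matrix (SNP ids as column names).
#' @param genoSnpInfo optional data.frame describing the genotype alleles
#'   (as from \code{\link{readGenotypes}}); when absent, alleles are taken
#'   to already match the model.
#' @param dropAmbiguous drop strand-ambiguous SNPs (default TRUE).
#' @return a \linkS4class{HarmonizedGenotypes}.
#' @export
harmonizeGenotypes <- function(modelSnpInfo, dosages, genoSnpInfo = NULL,
                               dropAmbiguous = TRUE) {
    stopifnot(all(c("snp", "refAllele", "effAllele") %in%
                  names(modelSnpInfo)))
    if (anyDuplicated(modelSnpInfo$snp)) stop("duplicate model SNP ids")
    if (anyDuplicated(colnames(dosages))) stop("duplicate genotype SNP ids")

    status <- character(nrow(modelSnpInfo))
    cols <- vector("list", nrow(modelSnpInfo))
    for (k in seq_len(nrow(modelSnpInfo))) {
        id <- modelSnpInfo$snp[k]
        if (!id %in% colnames(dosages)) { status[k] <- "dropped"; next }
        d <- dosages[, id]
        if (is.null(genoSnpInfo)) {
            status[k] <- "matched"; cols[[k]] <- d; next
        }
        g <- genoSnpInfo[match(id, genoSnpInfo$snp), ]
        if (is.na(g$snp[1L])) { status[k] <- "dropped"; next }
        mRef <- as.character(modelSnpInfo$refAllele[k])
        mEff <- as.character(modelSnpInfo$effAllele[k])
        gRef <- as.character(g$refAllele); gEff <- as.character(g$effAllele)
        if (anyNA(c(mRef, mEff, gRef, gEff))) {
            ## no allele metadata on one side: match on identifier alone
            status[k] <- "matched"; cols[[k]] <- d; next
        }
        pair <- paste0(gRef, "/", gEff)
        if (dropAmbiguous && pair %in% .AMBIGUOUS) {
            status[k] <- "dropped"; next
        }
        if (identical(gRef, mRef) && identical(gEff, mEff)) {
            status[k] <- "matched"; cols[[k]] <- d
        } else if (identical(gRef, mEff) && identical(gEff, mRef)) {
            status[k] <- "swapped"; cols[[k]] <- 2 - d
        } else {
            status[k] <- "dropped"
        }
    }
    keep <- status != "dropped"
    mat <- matrix(numeric(0), nrow = nrow(dosages), ncol = 0L,
                  dimnames = list(rownames(dosages), character(0)))
    if (any(keep)) {
        mat <- do.call(cbind, cols[keep])
        colnames(mat) <- modelSnpInfo$snp[keep]
    }
    subj <- if (!is.null(rownames(dosages))) rownames(dosages) else
        paste0("subject", seq_len(nrow(dosages)))
    rownames(mat) <- subj
    new("HarmonizedGenotypes", subjectIds = subj, dosages = mat,
        provenance = data.frame(snp = modelSnpInfo$snp, status = status,
                                stringsAsFactors = FALSE))
}

#' Write a set of trained models as a TSV model store
#'
#' Writes \code{<prefix>.weights.tsv} with one row per (gene, SNP):
#' gene id, SNP id, chrom, pos, ref/effect alleles, the weight in each cell
#' type and the model type; and \code{<prefix>.extra.tsv} with per-gene
#' metadata (SNP count, cross-validated correlation, weight-difference CI
#' summary).
#'
#' @param models list of \linkS4class{CellTypeModel} /
#'   \linkS4class{TissueModel} objects.
#' @param prefix output path prefix.
#' @param seed seed recorded in the headers.
#' @return the weights path, invisibly.
#' @export
writeModelStore <- function(models, prefix, seed = NULL) {
    rows <- list(); extras <- list()
    for (m in models) {
        si <- snpInfo(m)
        w1 <- modelWeights(m, 1L); w2 <- modelWeights(m, 2L)
        mt <- modelType(m)
        if (nrow(si))
            rows[[length(rows) + 1L]] <- data.frame(
                gene_id = geneId(m), rsid = si$snp, chrom = si$chrom,
                pos = si$pos, ref_allele = si$refAllele,
                eff_allele = si$effAllele,
                weight_cell1 = unname(w1), weight_cell2 = unname(w2),
                model_type = mt, stringsAsFactors = FALSE)
        ciLo <- ciHi <- NA_real_
        if (is(m, "CellTypeModel") && nrow(m@diffCI)) {
            ciLo <- min(m@diffCI$lo); ciHi <- max(m@diffCI$hi)
        }
        extras[[length(extras) + 1L]] <- data.frame(
            gene_id = geneId(m), n_snps = nrow(si),
            cv_performance = cvPerformance(m), model_type = mt,
            trainable = isTrainable(m),
            diff_ci_lo = ciLo, diff_ci_hi = ciHi,
            stringsAsFactors = FALSE)
    }
    wdf <- if (length(rows)) do.call(rbind, rows) else
        data.frame(gene_id = character(0))
    .writeTsv(wdf, paste0(prefix, ".weights.tsv"), seed = seed)
    .writeTsv(do.call(rbind, extras), paste0(prefix, ".extra.tsv"),
              seed = seed)
    invisible(paste0(prefix, ".weights.tsv"))
}

#' Read a TSV model store written by \code{\link{writeModelStore}}
#'
#' @param prefix path prefix used when writing.
#' @return named list of \linkS4class{CellTypeModel} objects (intercepts
#'   and covariate weights are not stored: GReX prediction uses SNP weights
#'   only).
#' @export
readModelStore <- function(prefix) {
    w <- .readTsv(paste0(prefix, ".weights.tsv"))
    ex <- .readTsv(paste0(prefix, ".extra.tsv"))
    models <- list()
    for (i in seq_len(nrow(ex))) {
        g <- ex$gene_id[i]
        wi <- w[w$gene_id == g, , drop = FALSE]
        si <- data.frame(snp = as.character(wi$rsid), chrom = wi$chrom,
                         pos = wi$pos, refAllele = wi$ref_allele,
                         effAllele = wi$eff_allele,
                         stringsAsFactors = FALSE)
        models[[g]] <- new("CellTypeModel", geneId = g, snpInfo = si,
                           weightsCell1 = as.numeric(wi$weight_cell1),
                           weightsCell2 = as.numeric(wi$weight_cell2),
                           interceptCell1 = 0, interceptCell2 = 0,
                           covWeights = numeric(0),
                           modelType = ex$model_type[i],
                           diffCI = data.frame(snp = character(0),
                                               lo = numeric(0),
                                               hi = numeric(0),
                                               selFreq = numeric(0)),
                           nBoot = 0L,
                           cvPerformance = ex$cv_performance[i],
                           trainable = as.logical(ex$trainable[i]))
    }
    models
}

#' Export nonspecific models to a PredictDB-style single-weight table
#'
#' Nonspecific models carry one weight per SNP shared by both cell types
#' and can be consumed by tissue-level TWAS tooling. Cell-type-specific
#' models are skipped with a message.
#'
#' @param models list of models.
#' @param path output TSV path.
#' @param seed seed recorded in the header.
#' @return \code{path}, invisibly.
#' @export
exportPredictDb <- function(models, path, seed = NULL) {
    rows <- list()
    for (m in models) {
        if (modelType(m) == "cell_type_specific") {
            message("skipping cell-type-specific model for ", geneId(m))
            next
        }
        si <- snpInfo(m)
        if (!nrow(si)) next
        w <- modelWeights(m, 1L)
        rows[[length(rows) + 1L]] <- data.frame(
            gene = geneId(m), rsid = si$snp, varID = si$snp,
            ref_allele = si$refAllele, eff_allele = si$effAllele,
            weight = unname(w), stringsAsFactors = FALSE)
    }
    df <- if (length(rows)) do.call(rbind, rows) else
        data.frame(gene = character(0), rsid = character(0),
                   varID = character(0), ref_allele = character(0),
                   eff_allele = character(0), weight = numeric(0))
    .writeTsv(df, path, seed = seed)
}
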