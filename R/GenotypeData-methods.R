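#' @describeIn GenotypeData the SNPs x samples dosage matrix (alternate-
#'   allele copy counts, `NA` = missing).
#' @export
setMethod("dosage", "GenotypeData",
          function(x) assay(x, "dosage"))

#' @describeIn GenotypeData per-SNP metadata as a base data.frame.
#' @export
setMethod("snpInfo", "GenotypeData",
          function(x) as.data.frame(rowData(x)))

#' @describeIn GenotypeData named vector of sample labels.
#' @export
setMethod("sampleLabels", "GenotypeData",
          function(x) setNames(colData(x)$label, colnames(x)))

#' @describeIn GenotypeData set sample labels.
#' @export
setMethod("sampleLabels<-", "GenotypeData", function(x, value) {
    if (!is.null(names(value))) value <- value[colnames(x)]
    colData(x)$label <- as.character(unname(value))
    x
})

#' @describeIn GenotypeData named vector of cohort-split assignments.
#' @export
setMethod("sampleSplits", "GenotypeData",
          function(x) setNames(colData(x)$split, colnames(x)))

#' @describeIn GenotypeData set cohort-split assignments.
#' @export
setMethod("sampleSplits<-", "GenotypeData", function(x, value) {
    if (!is.null(names(value))) value <- value[colnames(x)]
    colData(x)$split <- as.character(unname(value))
    x
})

setMethod("show", "GenotypeData", function(object) {
    d <- dosage(object)
    miss <- if (length(d)) mean(is.na(d)) else 0
    cat("GenotypeData:", nrow(object), "SNPs x", ncol(object), "samples\n")
    cat(sprintf("  missing genotypes: %.2f%%\n", 100 * miss))
    lab <- colData(object)$label
    if (any(!is.na(lab))) {
        tb <- table(lab, useNA = "no")
        cat("  labels:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
    }
    sp <- colData(object)$split
    if (any(!is.na(sp))) {
        tb <- table(sp, useNA = "no")
        cat("  splits:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
    }
})

#' Filter SNPs by missingness
#'
#' Retains exactly the SNPs whose missing-genotype fraction over all
#' samples is at most `maxMissingFraction`; a SNP with *more than* the
#' threshold missing is removed (strict inequality, so at a threshold of
#' 0.10 a SNP missing in exactly 10% of samples is kept).
#'
#' @param g a [GenotypeData-class] object.
#' @param maxMissingFraction proportion in `[0, 1]`; default 0.10.
#' @return the filtered `GenotypeData`.
#' @export
filterSnpsByMissingness <- function(g, maxMissingFraction = 0.10) {
    stopifnot(maxMissingFraction >= 0, maxMissingFraction <= 1)
    frac <- rowMeans(is.na(dosage(g)))
    g[frac <= maxMissingFraction, ]
}

#' Filter samples by missingness within a SNP subset
#'
#' Drops samples whose missing fraction *within the given SNP subset*
#' exceeds `maxMissingFraction` (strict inequality: exactly at the
#' threshold is retained).
#'
#' @param g a [GenotypeData-class] object.
#' @param snpIds SNP ids defining the subset; default all SNPs.
#' @param maxMissingFraction proportion in `[0, 1]`; default 0.30.
#' @return the filtered `GenotypeData` (all SNPs retained).
#' @export
filterSamplesByMissingness <- function(g, snpIds = NULL,
                                       maxMissingFraction = 0.30) {
    stopifnot(maxMissingFraction >= 0, maxMissingFraction <= 1)
    if (is.null(snpIds)) snpIds <- snpInfo(g)$snp_id
    bad <- setdiff(snpIds, snpInfo(g)$snp_id)
    if (length(bad))
        stop("snpIds not present in the genotype matrix: ",
             paste(bad, collapse = ", "))
    frac <- colMeans(is.na(dosage(g)[match(snpIds, snpInfo(g)$snp_id), ,
                                     drop = FALSE]))
    g[, frac <= maxMissingFraction]
}

#' Per-sample and per-SNP missingness report
#'
#' Quality-control summary of genotype missingness. This is a report,
#' not a filter: datasets where no individual exceeds a nominal
#' per-sample threshold (1% by default) need no sample exclusion before
#' network construction.
#'
#' @param g a [GenotypeData-class] object.
#' @param sampleThreshold nominal per-sample threshold to flag; default
#'   0.01.
#' @return a list with per-sample and per-SNP missing fractions plus the
#'   ids of samples above the threshold.
#' @export
missingnessReport <- function(g, sampleThreshold = 0.01) {
    m <- is.na(dosage(g))
    sm <- colMeans(m)
    list(sampleMissing = sm,
         snpMissing = rowMeans(m),
         flaggedSamples = names(sm)[sm > sampleThreshold],
         sampleThreshold = sampleThreshold)
}
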