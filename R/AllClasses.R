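#' @import methods
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   rowData colData `colData<-`
NULL

NUCLEOTIDES <- c("A", "C", "G", "T")

#' GenotypeData: unphased diploid biallelic SNP genotypes
#'
#' A container for an unphased dosage matrix (SNPs in rows, samples in
#' columns) together with per-SNP metadata and per-sample diagnostic /
#' population labels and cohort-split assignments. Extends
#' [SummarizedExperiment::SummarizedExperiment]; the single assay
#' `"dosage"` counts copies of the alternate allele, with `NA` marking a
#' missing genotype (never conflated with dosage 0).
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment]; `rowData`
#'   carries columns `snp_id`, `chrom`, `pos` (1-based, forward strand),
#'   `ref`, `alt`; `colData` carries `label` (e.g. `CASE`, `MCI`,
#'   `CONTROL`, or a population code) and `split` (`DISCOVERY`,
#'   `VALIDATION`, `REPLICATION`, or `NA`).
#'
#' @export
setClass("GenotypeData", contains = "SummarizedExperiment")

setValidity("GenotypeData", function(object) {
    msg <- character(0)
    if (!"dosage" %in% SummarizedExperiment::assayNames(object))
        return("assay 'dosage' is required")
    d <- assay(object, "dosage")
    vals <- d[!is.na(d)]
    if (length(vals) && !all(vals %in% 0:2))
        msg <- c(msg, "non-missing dosage entries must be in {0, 1, 2}")
    rd <- rowData(object)
    need <- c("snp_id", "chrom", "pos", "ref", "alt")
    if (!all(need %in% colnames(rd)))
        return(paste("rowData must contain columns:",
                     paste(need, collapse = ", ")))
    if (nrow(rd) > 0) {
        if (anyNA(rd$snp_id) || any(!nzchar(rd$snp_id)))
            msg <- c(msg, "snp_id entries must be non-empty")
        if (anyDuplicated(rd$snp_id))
            msg <- c(msg, "snp_id entries must be unique")
        if (any(rd$pos < 1))
            msg <- c(msg, "positions must be >= 1 (1-based)")
        if (any(rd$ref == rd$alt))
            msg <- c(msg, "ref and alt alleles must differ")
        if (!all(rd$ref %in% NUCLEOTIDES) || !all(rd$alt %in% NUCLEOTIDES))
            msg <- c(msg, "alleles must be single nucleotides A/C/G/T")
    }
    cd <- colData(object)
    if (!all(c("label", "split") %in% colnames(cd)))
        msg <- c(msg, "colData must contain columns 'label' and 'split'")
    if (length(msg)) msg else TRUE
})

#' Construct a GenotypeData object
#'
#' @param dosage integer matrix, SNPs in rows and samples in columns;
#'   entries 0/1/2 count alternate-allele copies, `NA` is missing.
#' @param snpInfo data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `ref`, `alt` (one row per dosage row).
#' @param sampleLabels optional character vector (named by sample id, or
#'   positional) of diagnostic groups or population codes.
#' @param sampleSplits optional character vector of cohort-split names
#'   (`DISCOVERY` / `VALIDATION` / `REPLICATION`).
#' @return a [GenotypeData-class] object.
#' @export
GenotypeData <- function(dosage, snpInfo, sampleLabels = NULL,
                         sampleSplits = NULL) {
    dosage <- as.matrix(dosage)
    storage.mode(dosage) <- "integer"
    if (nrow(dosage) != nrow(snpInfo))
        stop("dosage has ", nrow(dosage), " rows but snpInfo has ",
             nrow(snpInfo))
    rownames(dosage) <- snpInfo$snp_id
    if (is.null(colnames(dosage)))
        colnames(dosage) <- sprintf("S%04d", seq_len(ncol(dosage)))
    align <- function(v, ids, what) {
        if (is.null(v)) return(rep(NA_character_, length(ids)))
        v <- as.character(unname(v[if (!is.null(names(v))) ids else
                                   seq_along(ids)]))
        if (length(v) != length(ids))
            stop(what, " must cover every sample")
        v
    }
    cd <- DataFrame(
        label = align(sampleLabels, colnames(dosage), "sampleLabels"),
        split = align(sampleSplits, colnames(dosage), "sampleSplits"),
        row.names = colnames(dosage))
    rd <- DataFrame(snpInfo[, c("snp_id", "chrom", "pos", "ref", "alt")],
                    row.names = snpInfo$snp_id)
    rd$chrom <- as.character(rd$chrom)
    rd$pos <- as.integer(rd$pos)
    new("GenotypeData",
        SummarizedExperiment(assays = list(dosage = dosage),
                             rowData = rd, colData = cd))
}

#' AlleleNetwork: allele-specific correlation network
#'
#' Nodes are (SNP, allele) pairs -- two per SNP, including singletons --
#' and edges carry the four-valued allele co-occurrence weights. The
#' node set is implicit (`2 * nrow(snpInfo)` nodes); `edges` lists only
#' weighted pairs, with `snp_a < snp_b` (integer row indices into
#' `snpInfo`) and alleles coded `"REF"` / `"ALT"`.
#'
#' @slot snpInfo data.frame of the SNPs the network was built over.
#' @slot edges data.frame with columns `snp_a`, `allele_a`, `snp_b`,
#'   `allele_b`, `weight`.
#' @slot nNodes integer, `2 *` number of SNPs (singletons included).
#' @slot thresholded logical, whether mean-degree truncation was applied.
#' @slot targetMeanDegree numeric, the truncation target (`NA` before
#'   thresholding).
#' @export
setClass("AlleleNetwork",
    representation(snpInfo = "data.frame", edges = "data.frame",
                   nNodes = "integer", thresholded = "logical",
                   targetMeanDegree = "numeric"))

setValidity("AlleleNetwork", function(object) {
    e <- object@edges
    need <- c("snp_a", "allele_a", "snp_b", "allele_b", "weight")
    if (!all(need %in% colnames(e)))
        return(paste("edges must have columns:", paste(need, collapse = ", ")))
    if (nrow(e)) {
        if (any(e$snp_a >= e$snp_b))
            return("edges must satisfy snp_a < snp_b (no intra-SNP edges)")
        if (!all(c(e$allele_a, e$allele_b) %in% c("REF", "ALT")))
            return("alleles must be coded REF/ALT")
        if (any(e$weight < 0 | e$weight > 1))
            return("weights must lie in [0, 1]")
        key <- paste(e$snp_a, e$allele_a, e$snp_b, e$allele_b)
        if (anyDuplicated(key))
            return("duplicate edges")
    }
    if (object@nNodes != 2L * nrow(object@snpInfo))
        return("nNodes must equal 2 * number of SNPs")
    TRUE
})

#' Bloc: a multi-SNP genetic pattern
#'
#' A bloc is a partial haplotype: one designated allele per SNP for a set
#' of SNPs whose allele nodes formed a single connected component of the
#' thresholded network. Members are ordered genomically (chrom, pos).
#'
#' @slot id bloc identifier.
#' @slot members data.frame with columns `snp_id`, `allele` (nucleotide),
#'   `chrom`, `pos`.
#' @slot sourceComponentSize node count of the originating component
#'   (used by the ">10 nodes" screen; equals `nrow(members)` unless both
#'   alleles of one SNP occurred in the component).
#' @slot multiAllelic `TRUE` when both alleles of at least one SNP
#'   occurred in the source component (the heavier allele was kept).
#' @slot dropped snp_ids removed by [subsetBloc()] (platform overlap).
#' @export
setClass("Bloc",
    representation(id = "character", members = "data.frame",
                   sourceComponentSize = "integer",
                   multiAllelic = "logical", dropped = "character"),
    prototype(multiAllelic = FALSE, dropped = character(0)))

setValidity("Bloc", function(object) {
    m <- object@members
    need <- c("snp_id", "allele", "chrom", "pos")
    if (!all(need %in% colnames(m)))
        return(paste("members must have columns:", paste(need, collapse = ", ")))
    if (nrow(m) < 2) return("a bloc needs at least 2 members")
    if (anyDuplicated(m$snp_id)) return("each SNP at most once per bloc")
    if (length(object@id) != 1 || !nzchar(object@id))
        return("id must be a single non-empty string")
    TRUE
})

#' Construct a Bloc
#'
#' @param id bloc identifier.
#' @param members data.frame with `snp_id`, `allele`, `chrom`, `pos`.
#' @param sourceComponentSize node count of the source component;
#'   defaults to the member count.
#' @param multiAllelic flag, see [Bloc-class].
#' @return a [Bloc-class] object with members in genomic order.
#' @export
Bloc <- function(id, members, sourceComponentSize = nrow(members),
                 multiAllelic = FALSE) {
    members <- members[order(members$chrom, members$pos), , drop = FALSE]
    rownames(members) <- NULL
    new("Bloc", id = as.character(id), members = members,
        sourceComponentSize = as.integer(sourceComponentSize),
        multiAllelic = multiAllelic)
}

#' SyntheticScenario: parameterization of a planted-bloc simulation
#'
#' Describes a simulated case/control genotype dataset with one planted
#' multi-SNP haplotype pattern enriched in cases. Defaults describe the
#' study conditions used throughout the package's validation: 500 SNPs,
#' 2,000 cases and 2,000 controls, a contiguous 23-SNP planted bloc with
#' per-chromosome pattern frequencies 0.6 (case) / 0.3 (control), 1%
#' per-SNP pattern decay and 1% per-genotype missingness.
#'
#' @slot nSnps,nCases,nMci,nControls dataset dimensions.
#' @slot plantedIndices SNP indices carrying the planted pattern.
#' @slot hapFreqCase,hapFreqControl per-chromosome probability that a
#'   chromosome carries the planted pattern (MCI uses the control value).
#' @slot backgroundMafRange uniform range for background minor-allele
#'   frequencies.
#' @slot patternDecay per-SNP probability that a pattern chromosome
#'   mutates away from the bloc allele.
#' @slot missingRate per-genotype missingness probability.
#' @slot splitProps proportions for DISCOVERY/VALIDATION/REPLICATION
#'   (MCI samples all go to DISCOVERY).
#' @slot seed RNG seed; same seed gives identical output.
#' @export
setClass("SyntheticScenario",
    representation(nSnps = "integer", nCases = "integer", nMci = "integer",
                   nControls = "integer", plantedIndices = "integer",
                   hapFreqCase = "numeric", hapFreqControl = "numeric",
                   backgroundMafRange = "numeric", patternDecay = "numeric",
                   missingRate = "numeric", splitProps = "numeric",
                   seed = "integer"))

setValidity("SyntheticScenario", function(object) {
    msg <- character(0)
    probs <- c(object@hapFreqCase, object@hapFreqControl,
               object@patternDecay, object@missingRate,
               object@backgroundMafRange)
    if (any(probs < 0 | probs > 1))
        msg <- c(msg, "all frequencies/rates must lie in [0, 1]")
    if (length(object@plantedIndices) < 2)
        msg <- c(msg, "planted bloc needs at least 2 SNPs")
    if (any(object@plantedIndices < 1) ||
        any(object@plantedIndices > object@nSnps))
        msg <- c(msg, "plantedIndices out of range")
    if (anyDuplicated(object@plantedIndices))
        msg <- c(msg, "plantedIndices must be unique")
    if (object@nCases + object@nControls < 2)
        msg <- c(msg, "need at least one case and one control")
    if (length(object@splitProps) != 3 ||
        abs(sum(object@splitProps) - 1) > 1e-8)
        msg <- c(msg, "splitProps must be 3 proportions summing to 1")
    if (length(msg)) msg else TRUE
})

#' Construct a SyntheticScenario
#'
#' @param nSnps,nCases,nMci,nControls dataset dimensions.
#' @param plantedSize size of the (contiguous, centered) planted bloc;
#'   ignored when `plantedIndices` is given.
#' @param plantedIndices explicit planted SNP indices (scattered
#'   placement).
#' @param hapFreqCase,hapFreqControl per-chromosome pattern frequencies.
#' @param backgroundMafRange background MAF range (uniform).
#' @param patternDecay per-SNP mutation-away probability on pattern
#'   chromosomes.
#' @param missingRate per-genotype missingness.
#' @param splitProps named proportions for the three cohort splits.
#' @param seed RNG seed.
#' @return a [SyntheticScenario-class] object.
#' @export
SyntheticScenario <- function(nSnps = 500L, nCases = 2000L, nMci = 0L,
                              nControls = 2000L, plantedSize = 23L,
                              plantedIndices = NULL,
                              hapFreqCase = 0.6, hapFreqControl = 0.3,
                              backgroundMafRange = c(0.05, 0.5),
                              patternDecay = 0.01, missingRate = 0.01,
                              splitProps = c(DISCOVERY = 0.45,
                                             VALIDATION = 0.18,
                                             REPLICATION = 0.37),
                              seed = 1L) {
    if (is.null(plantedIndices)) {
        if (plantedSize > nSnps)
            stop("plantedSize exceeds nSnps")
        start <- max(1L, as.integer((nSnps - plantedSize) %/% 2) + 1L)
        plantedIndices <- seq.int(start, length.out = plantedSize)
    }
    new("SyntheticScenario", nSnps = as.integer(nSnps),
        nCases = as.integer(nCases), nMci = as.integer(nMci),
        nControls = as.integer(nControls),
        plantedIndices = as.integer(sort(plantedIndices)),
        hapFreqCase = hapFreqCase, hapFreqControl = hapFreqControl,
        backgroundMafRange = backgroundMafRange,
        patternDecay = patternDecay, missingRate = missingRate,
        splitProps = splitProps, seed = as.integer(seed))
}
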