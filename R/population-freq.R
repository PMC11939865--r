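#' Restrict a bloc to the SNPs available on a platform
#'
#' Keeps the bloc members whose SNP ids are present in
#' `availableSnpIds`, preserving genomic order, and records the dropped
#' members in the `dropped` slot. Errors when the intersection is
#' empty.
#'
#' @param bloc a [Bloc-class] object.
#' @param availableSnpIds character vector of SNP ids genotyped on the
#'   target platform.
#' @return the restricted [Bloc-class].
#' @export
subsetBloc <- function(bloc, availableSnpIds) {
    m <- blocMembers(bloc)
    keep <- m$snp_id %in% availableSnpIds
    if (!any(keep))
        stop("no bloc SNP is present in the available set")
    out <- bloc
    out@members <- m[keep, , drop = FALSE]
    rownames(out@members) <- NULL
    out@dropped <- c(bloc@dropped, m$snp_id[!keep])
    out
}

#' Carrier frequency of a bloc in one population
#'
#' Applies the carrier rule ([carrierStatus()]) to every sample:
#' carriers hold at least one copy of the bloc allele at every observed
#' bloc SNP, samples missing more than `maxMissingFraction` of the
#' bloc's SNPs are excluded, and the frequency is carriers over
#' evaluated (non-excluded) samples only.
#'
#' @param g a [GenotypeData-class] for one population (must contain
#'   every bloc SNP; use [subsetBloc()] first for partial overlap).
#' @param bloc a [Bloc-class].
#' @param maxMissingFraction exclusion threshold; default 0.30.
#' @param population optional population code for the report; defaults
#'   to the (unique) sample label when present.
#' @return one-row data.frame: `population`, `n_snps`, `n_evaluated`,
#'   `n_excluded`, `carriers`, `carrier_frequency`.
#' @export
populationCarrierFrequency <- function(g, bloc, maxMissingFraction = 0.30,
                                       population = NA_character_) {
    st <- carrierStatus(g, bloc, maxMissingFraction)
    nEval <- sum(st != "EXCLUDED")
    if (nEval == 0) stop("no evaluable samples (all excluded)")
    if (is.na(population)) {
        lab <- unique(stats::na.omit(sampleLabels(g)))
        population <- if (length(lab) == 1) lab else NA_character_
    }
    data.frame(population = population,
               n_snps = blocSize(bloc),
               n_evaluated = nEval,
               n_excluded = sum(st == "EXCLUDED"),
               carriers = sum(st == "CARRIER"),
               carrier_frequency = sum(st == "CARRIER") / nEval,
               stringsAsFactors = FALSE)
}

#' Profile bloc-carrier frequency across populations
#'
#' For each population panel the bloc is first restricted to the SNPs
#' that panel actually genotyped (platform overlap is data-driven, not
#' hard-coded), then the carrier frequency is computed over evaluated
#' samples. A population with zero SNP overlap yields a flagged `NA`
#' row and the run continues.
#'
#' @param populations named list of [GenotypeData-class] objects, one
#'   per population.
#' @param bloc the full [Bloc-class] to profile.
#' @param maxMissingFraction per-sample exclusion threshold.
#' @return data.frame with one row per population.
#' @export
profilePopulations <- function(populations, bloc,
                               maxMissingFraction = 0.30) {
    stopifnot(length(populations) >= 1)
    if (is.null(names(populations)))
        names(populations) <- sprintf("POP%02d", seq_along(populations))
    rows <- lapply(names(populations), function(pop) {
        g <- populations[[pop]]
        avail <- intersect(blocMembers(bloc)$snp_id, snpInfo(g)$snp_id)
        if (!length(avail)) {
            warning("population ", pop, " has zero bloc-SNP overlap")
            return(data.frame(population = pop, n_snps = 0L,
                              n_evaluated = NA_integer_,
                              n_excluded = NA_integer_,
                              carriers = NA_integer_,
                              carrier_frequency = NA_real_,
                              stringsAsFactors = FALSE))
        }
        sub <- subsetBloc(bloc, avail)
        populationCarrierFrequency(g, sub, maxMissingFraction,
                                   population = pop)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
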