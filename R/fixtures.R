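#' The packaged 23-SNP chromosome 19p13.3 bloc
#'
#' The 23-SNP-allele pattern spanning the *THOP1* / *SLC39A3* / *SGTA*
#' region (upstream of *DIRAS1*) that motivates this package, shipped
#' as a bloc TSV fixture. SNP ids and pattern alleles are the real
#' ones; the base-pair coordinates are evenly spaced placeholders
#' (synthetic), adequate for ordering but not for genome-browser use.
#'
#' @return a [Bloc-class] with 23 members.
#' @export
thop1Bloc <- function() {
    path <- system.file("extdata", "thop1_bloc_synthetic_coords.tsv",
                        package = "blocnet", mustWork = TRUE)
    readBlocTable(path)[[1]]
}

## Deterministic genotypes for a set of carriers/non-carriers of `bloc`.
## Carriers alternate het/hom bloc-allele at every SNP; non-carrier s
## has zero bloc-allele copies at one SNP (rotating with s).
.carrierDosage <- function(k, nCarrier, nNon, offset = 0L) {
    n <- nCarrier + nNon
    d <- matrix(0L, nrow = k, ncol = n)
    for (s in seq_len(n)) {
        d[, s] <- 1L + (seq_len(k) + s) %% 2L
        if (s > nCarrier)
            d[((s + offset - 1L) %% k) + 1L, s] <- 0L
    }
    d
}

.blocSnpInfo <- function(bloc) {
    m <- blocMembers(bloc)
    data.frame(snp_id = m$snp_id, chrom = m$chrom, pos = m$pos,
               ref = vapply(m$allele, function(a)
                   setdiff(c("A", "C", "G", "T"), a)[1], character(1)),
               alt = m$allele, stringsAsFactors = FALSE)
}

#' Deterministic three-stage cohort fixture
#'
#' Builds a complete (no-missing) genotype dataset over the packaged
#' 23-SNP bloc whose carrier counts are fixed by construction:
#' Discovery 35 of 42 cases and 57 of 87 controls (plus 69 MCI samples,
#' which never enter association tables), Validation 17 of 18 vs 23 of
#' 37, Replication 32 of 38 vs 42 of 63. Replaying this fixture through
#' [screenBlocs()] therefore exercises the full cascade against known
#' carrier tables. No randomness is involved.
#'
#' @return list with `genotypes` (a [GenotypeData-class], 23 SNPs x 354
#'   samples with labels and splits) and `bloc` (the packaged
#'   [Bloc-class]).
#' @export
adCohortFixture <- function() {
    bloc <- thop1Bloc()
    k <- blocSize(bloc)
    groups <- list(
        list(split = "DISCOVERY", label = "CASE", n = 42L, carriers = 35L),
        list(split = "DISCOVERY", label = "MCI", n = 69L, carriers = 45L),
        list(split = "DISCOVERY", label = "CONTROL", n = 87L, carriers = 57L),
        list(split = "VALIDATION", label = "CASE", n = 18L, carriers = 17L),
        list(split = "VALIDATION", label = "CONTROL", n = 37L, carriers = 23L),
        list(split = "REPLICATION", label = "CASE", n = 38L, carriers = 32L),
        list(split = "REPLICATION", label = "CONTROL", n = 63L, carriers = 42L))
    mats <- lapply(seq_along(groups), function(i) {
        gr <- groups[[i]]
        .carrierDosage(k, gr$carriers, gr$n - gr$carriers, offset = i)
    })
    dose <- do.call(cbind, mats)
    lab <- unlist(lapply(groups, function(gr) rep(gr$label, gr$n)))
    split <- unlist(lapply(groups, function(gr) rep(gr$split, gr$n)))
    colnames(dose) <- sprintf("%s_%s_%02d", substr(split, 1, 1),
                              lab, stats::ave(seq_along(lab),
                                              paste(split, lab),
                                              FUN = seq_along))
    g <- GenotypeData(dose, .blocSnpInfo(bloc), sampleLabels = lab,
                      sampleSplits = split)
    list(genotypes = g, bloc = bloc)
}

## population, sample size, carriers among evaluated, SNPs available.
## Sample sizes and carrier counts parameterize the synthetic panel.
.POP_PANEL <- data.frame(
    population = c("ASW", "CEU", "CHB", "CHD", "GIH", "JPT", "LWK",
                   "MEX", "MKK", "TSI", "YRI"),
    n = c(87L, 174L, 139L, 109L, 101L, 113L, 110L, 86L, 184L, 102L, 164L),
    carriers = c(31L, 153L, 70L, 51L, 76L, 64L, 15L, 71L, 74L, 79L, 33L),
    n_snps = c(12L, 15L, 14L, 13L, 13L, 14L, 13L, 13L, 13L, 13L, 14L),
    stringsAsFactors = FALSE)

#' Synthetic multi-population genotype panels
#'
#' Builds a synthetic stand-in for an 11-population reference panel
#' (HapMap-style population codes). Each population genotypes only a
#' subset of the packaged 23-SNP bloc (12--15 SNPs, varying by
#' population, so platform overlap is exercised), contains a fixed
#' number of bloc carriers among its evaluated samples, and includes
#' two samples with more than 30% missing bloc genotypes (excluded by
#' the carrier rule) plus a few sub-threshold missing genotypes. These
#' are deterministic synthetic genotypes, *not* real reference-panel
#' data; carrier counts are the panel's construction parameters.
#'
#' @param populations population codes to build (default: all 11).
#' @return named list of [GenotypeData-class] objects.
#' @export
syntheticPopulationPanel <- function(populations = .POP_PANEL$population) {
    bloc <- thop1Bloc()
    m <- blocMembers(bloc)
    out <- list()
    for (pop in populations) {
        row <- .POP_PANEL[.POP_PANEL$population == pop, ]
        if (nrow(row) != 1) stop("unknown population code: ", pop)
        k <- row$n_snps
        pi <- match(pop, .POP_PANEL$population)
        idx <- ((pi - 1L) + seq_len(k) - 1L) %% nrow(m) + 1L
        sub <- subsetBloc(bloc, m$snp_id[idx])
        dose <- .carrierDosage(blocSize(sub), row$carriers,
                               row$n - row$carriers, offset = pi)
        # sub-threshold missingness on the first carriers: still carriers
        for (s in seq_len(min(3L, row$carriers)))
            dose[s, s] <- NA_integer_
        # two excluded samples: missing at > 30% of the bloc SNPs
        nmiss <- floor(0.3 * k) + 1L
        excl <- matrix(1L, nrow = k, ncol = 2L)
        excl[seq_len(nmiss), ] <- NA_integer_
        dose <- cbind(dose, excl)
        colnames(dose) <- sprintf("%s%03d", pop, seq_len(ncol(dose)))
        out[[pop]] <- GenotypeData(dose, .blocSnpInfo(sub),
                                   sampleLabels = rep(pop, ncol(dose)))
    }
    out
}
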