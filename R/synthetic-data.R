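#' Generate a case/control genotype dataset with a planted bloc
#'
#' Simulates unphased diploid biallelic genotypes: each individual
#' receives two chromosomes; each chromosome carries the planted
#' haplotype pattern with probability `hapFreqCase` (cases) or
#' `hapFreqControl` (controls and MCI -- MCI association is never
#' tested, so intermediate samples are generated at control-like
#' frequencies). Pattern chromosomes carry the bloc allele at every
#' planted SNP except with probability `patternDecay` per SNP;
#' non-pattern chromosomes and non-planted SNPs draw alleles
#' independently at MAFs drawn uniformly from `backgroundMafRange`
#' (background SNPs are mutually independent, keeping null calibration
#' clean). Genotypes are masked to missing independently at
#' `missingRate`, and samples are partitioned into the three cohort
#' splits by `splitProps` (MCI all to DISCOVERY). Fully reproducible
#' from the scenario seed via R's Mersenne-Twister generator.
#'
#' @param scenario a [SyntheticScenario-class].
#' @return list with elements `genotypes` (a [GenotypeData-class] with
#'   labels and splits), `bloc` (the planted [Bloc-class], alleles =
#'   the alternate allele at each planted SNP), and `truth` (list:
#'   `patternChromosomes` per sample, `carrier` -- holds at least one
#'   pattern chromosome --, `counts` of truth-carriers per split and
#'   group, `trueOddsRatio` implied by the carrier probabilities
#'   `1 - (1 - f)^2`, and `maf`).
#' @export
generateGenotypes <- function(scenario) {
    stopifnot(is(scenario, "SyntheticScenario"))
    validObject(scenario)
    s <- scenario
    set.seed(s@seed)
    n <- s@nCases + s@nMci + s@nControls
    p <- s@nSnps
    lab <- rep(c("CASE", "MCI", "CONTROL"), c(s@nCases, s@nMci, s@nControls))
    f <- ifelse(lab == "CASE", s@hapFreqCase, s@hapFreqControl)
    maf <- stats::runif(p, s@backgroundMafRange[1], s@backgroundMafRange[2])
    planted <- s@plantedIndices
    drawChrom <- function() {
        h <- matrix(stats::rbinom(p * n, 1L, maf), nrow = p, ncol = n)
        pat <- stats::rbinom(n, 1L, f) == 1L
        if (any(pat))
            h[planted, pat] <- 1L - stats::rbinom(length(planted) * sum(pat),
                                                  1L, s@patternDecay)
        list(h = h, pat = pat)
    }
    c1 <- drawChrom(); c2 <- drawChrom()
    dose <- c1$h + c2$h
    if (s@missingRate > 0) {
        mask <- stats::rbinom(p * n, 1L, s@missingRate) == 1L
        dose[matrix(mask, nrow = p)] <- NA_integer_
    }
    # cohort split: deterministic counts per group, random permutation
    splitNames <- c("DISCOVERY", "VALIDATION", "REPLICATION")
    assign <- function(ng) {
        cnt <- diff(round(cumsum(c(0, s@splitProps)) * ng))
        sample(rep(splitNames, cnt))
    }
    split <- character(n)
    split[lab == "CASE"] <- assign(s@nCases)
    split[lab == "MCI"] <- "DISCOVERY"
    split[lab == "CONTROL"] <- assign(s@nControls)

    refs <- rep(c("A", "C", "G", "T"), length.out = p)
    alts <- rep(c("G", "T", "A", "C"), length.out = p)
    si <- data.frame(snp_id = sprintf("snp%05d", seq_len(p)),
                     chrom = "19", pos = 1000000L + (seq_len(p) - 1L) * 2000L,
                     ref = refs, alt = alts, stringsAsFactors = FALSE)
    colnames(dose) <- sprintf("I%05d", seq_len(n))
    g <- GenotypeData(dose, si, sampleLabels = lab, sampleSplits = split)

    bloc <- Bloc("planted",
                 data.frame(snp_id = si$snp_id[planted],
                            allele = si$alt[planted],
                            chrom = si$chrom[planted],
                            pos = si$pos[planted],
                            stringsAsFactors = FALSE))
    patc <- c1$pat + c2$pat
    qc <- 1 - (1 - s@hapFreqCase)^2
    q0 <- 1 - (1 - s@hapFreqControl)^2
    counts <- table(split = split, label = lab,
                    carrier = patc >= 1)
    list(genotypes = g, bloc = bloc,
         truth = list(patternChromosomes = setNames(patc, colnames(dose)),
                      carrier = setNames(patc >= 1, colnames(dose)),
                      counts = counts,
                      trueOddsRatio = (qc / (1 - qc)) / (q0 / (1 - q0)),
                      maf = maf))
}

#' Jaccard index of two SNP-id sets
#'
#' Used to score recovery of a planted bloc:
#' `|intersection| / |union|` of the member SNP ids.
#'
#' @param a,b [Bloc-class] objects or character vectors of SNP ids.
#' @return numeric in `[0, 1]`.
#' @export
jaccardIndex <- function(a, b) {
    ids <- function(x) if (is(x, "Bloc")) blocMembers(x)$snp_id else
        as.character(x)
    a <- unique(ids(a)); b <- unique(ids(b))
    length(intersect(a, b)) / length(union(a, b))
}

#' Discovery-stage false-survivor rate under a null scenario
#'
#' Repeatedly simulates the scenario (each replicate reseeded
#' deterministically from the scenario seed), evaluates the planted
#' bloc's carrier table on the Discovery split and records whether its
#' confidence interval excludes 1. When case and control pattern
#' frequencies are equal this estimates the false-survivor rate, which
#' should match the nominal CI-exclusion level (5% at `level = 0.95`).
#'
#' @param scenario a [SyntheticScenario-class]; for speed use a
#'   scenario whose SNPs are all planted (carrier calls depend only on
#'   planted SNPs).
#' @param nReplicates number of simulation replicates; default 500.
#' @param level confidence level; default 0.95.
#' @return fraction of replicates with a Discovery-significant result.
#' @export
nullSurvivorRate <- function(scenario, nReplicates = 500L, level = 0.95) {
    hits <- logical(nReplicates)
    for (r in seq_len(nReplicates)) {
        s <- scenario
        s@seed <- as.integer((scenario@seed + 7L * r) %% .Machine$integer.max)
        sim <- generateGenotypes(s)
        g <- sim$genotypes
        lab <- sampleLabels(g); sp <- sampleSplits(g)
        tab <- carrierTable(g, sim$bloc,
                            names(lab)[lab == "CASE" & sp == "DISCOVERY"],
                            names(lab)[lab == "CONTROL" & sp == "DISCOVERY"])
        hits[r] <- associationTest(tab, level)$significant
    }
    mean(hits)
}
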