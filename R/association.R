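#' Carrier status of each sample for a bloc
#'
#' A sample is a CARRIER when it holds at least one copy of the bloc's
#' designated allele at *every* bloc SNP where its genotype is observed;
#' a single observed zero-copy SNP makes it a NONCARRIER. Samples
#' missing at more than `maxMissingFraction` of the bloc's SNPs are
#' EXCLUDED and never enter numerator or denominator downstream.
#' Because missing genotypes are treated as compatible, adding the
#' missing data back can only lower carrier frequencies, never raise
#' them.
#'
#' @param g a [GenotypeData-class] object containing every bloc SNP (use
#'   [subsetBloc()] first for partial platforms).
#' @param bloc a [Bloc-class] object.
#' @param maxMissingFraction per-sample exclusion threshold over the
#'   bloc's SNPs (strict: *more than* this fraction excludes); default
#'   0.30.
#' @return factor (levels `CARRIER`, `NONCARRIER`, `EXCLUDED`) named by
#'   sample id.
#' @export
carrierStatus <- function(g, bloc, maxMissingFraction = 0.30) {
    stopifnot(is(bloc, "Bloc"))
    m <- blocMembers(bloc)
    if (nrow(m) == 0) stop("empty bloc")
    si <- snpInfo(g)
    row <- match(m$snp_id, si$snp_id)
    if (anyNA(row))
        stop("bloc SNP(s) absent from genotypes: ",
             paste(m$snp_id[is.na(row)], collapse = ", "))
    isRef <- m$allele == si$ref[row]
    isAlt <- m$allele == si$alt[row]
    if (any(!isRef & !isAlt))
        stop("bloc allele does not match ref or alt for SNP(s): ",
             paste(m$snp_id[!isRef & !isAlt], collapse = ", "))
    d <- dosage(g)[row, , drop = FALSE]
    # >=1 copy of the bloc allele: dosage >= 1 if the bloc allele is ALT,
    # dosage <= 1 if it is REF (dosage counts ALT copies)
    ok <- d
    ok[isAlt, ] <- d[isAlt, , drop = FALSE] >= 1
    ok[isRef, ] <- d[isRef, , drop = FALSE] <= 1
    missFrac <- colMeans(is.na(d))
    ok[is.na(ok)] <- TRUE                     # missing is compatible
    carrier <- colSums(ok) == nrow(d)
    status <- ifelse(missFrac > maxMissingFraction, "EXCLUDED",
                     ifelse(carrier, "CARRIER", "NONCARRIER"))
    factor(setNames(status, colnames(d)),
           levels = c("CARRIER", "NONCARRIER", "EXCLUDED"))
}

#' 2x2 carrier table for cases vs controls
#'
#' @param g a [GenotypeData-class] object.
#' @param bloc a [Bloc-class] object.
#' @param caseIds,controlIds sample ids of the two groups.
#' @param maxMissingFraction passed to [carrierStatus()].
#' @return named integer vector `c(case_carriers, case_noncarriers,
#'   control_carriers, control_noncarriers)` with attribute `n_excluded`.
#' @export
carrierTable <- function(g, bloc, caseIds, controlIds,
                         maxMissingFraction = 0.30) {
    st <- carrierStatus(g, bloc, maxMissingFraction)
    cc <- function(ids, lev) sum(st[ids] == lev, na.rm = TRUE)
    out <- c(case_carriers = cc(caseIds, "CARRIER"),
             case_noncarriers = cc(caseIds, "NONCARRIER"),
             control_carriers = cc(controlIds, "CARRIER"),
             control_noncarriers = cc(controlIds, "NONCARRIER"))
    attr(out, "n_excluded") <- cc(caseIds, "EXCLUDED") +
        cc(controlIds, "EXCLUDED")
    out
}

.haldane <- function(tab) {
    tab <- as.numeric(tab)
    if (all(tab == 0)) stop("odds ratio undefined: all cells are zero")
    if (any(tab == 0)) list(tab = tab + 0.5, corrected = TRUE)
    else list(tab = tab, corrected = FALSE)
}

#' Carrier odds ratio
#'
#' Cross-product odds ratio `(a d) / (b c)` on the 2x2 carrier table
#' `(a = case carriers, b = case non-carriers, c = control carriers,
#' d = control non-carriers)`. If any cell is zero the Haldane-Anscombe
#' correction (+0.5 to every cell) is applied and flagged via the
#' `"corrected"` attribute.
#'
#' @param tab numeric vector of the 4 cells, in the order above.
#' @return the odds ratio (attribute `corrected`).
#' @export
oddsRatio <- function(tab) {
    h <- .haldane(tab)
    t <- h$tab
    structure((t[1] * t[4]) / (t[2] * t[3]), corrected = h$corrected)
}

#' Woolf confidence interval for a carrier odds ratio
#'
#' Log-scale interval `exp(ln OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`
#' with the conventional two-decimal critical value (1.96 at the 0.95
#' level). Zero cells are Haldane-corrected as in [oddsRatio()].
#'
#' @param tab numeric vector of the 4 cells (see [oddsRatio()]).
#' @param level confidence level; default 0.95.
#' @return numeric `c(low, high)`.
#' @export
woolfCI <- function(tab, level = 0.95) {
    stopifnot(level > 0, level < 1)
    h <- .haldane(tab)
    t <- h$tab
    z <- round(stats::qnorm((1 + level) / 2), 2)
    se <- sqrt(sum(1 / t))
    or <- (t[1] * t[4]) / (t[2] * t[3])
    unname(exp(log(or) + c(-1, 1) * z * se))
}

#' Odds-ratio association test on a 2x2 carrier table
#'
#' Combines [oddsRatio()], [woolfCI()] and a two-sided normal test on
#' `ln OR / SE` (consistent with the Woolf interval). A bloc is
#' significant when the confidence interval excludes 1. No
#' multiple-testing correction is applied: selection is controlled by
#' the independent Validation and Replication stages of
#' [screenBlocs()].
#'
#' @param tab numeric vector of the 4 cells.
#' @param level confidence level; default 0.95.
#' @return one-row data.frame: cells, `or`, `ci_low`, `ci_high`, `p`,
#'   `significant`, `corrected`.
#' @export
associationTest <- function(tab, level = 0.95) {
    h <- .haldane(tab)
    t <- h$tab
    or <- (t[1] * t[4]) / (t[2] * t[3])
    ci <- woolfCI(tab, level)
    se <- sqrt(sum(1 / t))
    p <- 2 * stats::pnorm(-abs(log(or)) / se)
    data.frame(case_carriers = tab[1], case_noncarriers = tab[2],
               control_carriers = tab[3], control_noncarriers = tab[4],
               or = or, ci_low = ci[1], ci_high = ci[2], p = p,
               significant = ci[1] > 1 || ci[2] < 1,
               corrected = h$corrected, row.names = NULL)
}

#' Three-stage bloc screening cascade
#'
#' Stage 1 (Discovery) evaluates every bloc whose source component had
#' at least `minNodes` nodes (default 11, i.e. "more than 10") on
#' Discovery cases vs controls -- intermediate-diagnosis (MCI) samples
#' take part in network construction but never in 2x2 tables -- and
#' keeps those whose confidence interval excludes 1. Stage 2 re-tests
#' the survivors on Validation and selects the single most significant
#' (smallest p, ties broken by larger lower CI bound, then smaller
#' bloc id). Stage 3 evaluates only that bloc on Replication. If the
#' survivor set is empty at any stage the cascade stops with an
#' explicit status.
#'
#' @param blocs list of [Bloc-class] objects.
#' @param g a [GenotypeData-class] whose `colData` carries `label`
#'   (`CASE` / `MCI` / `CONTROL`) and `split` (`DISCOVERY` /
#'   `VALIDATION` / `REPLICATION`).
#' @param minNodes minimum source-component node count; default 11.
#' @param maxMissingFraction carrier-call exclusion threshold.
#' @param level confidence level.
#' @return list (the audit trail): `stages` (named list of per-stage
#'   result data.frames), `survivors` (bloc ids significant at
#'   Discovery), `selected` (bloc id chosen at Validation, or `NA`),
#'   `status` (`"COMPLETE"`, `"NO_ELIGIBLE_BLOCS"`,
#'   `"NO_DISCOVERY_SURVIVORS"` or `"NO_VALIDATION_SURVIVORS"`), and
#'   `parameters`.
#' @export
screenBlocs <- function(blocs, g, minNodes = 11L,
                        maxMissingFraction = 0.30, level = 0.95) {
    if (is(blocs, "Bloc")) blocs <- list(blocs)
    lab <- sampleLabels(g)
    sp <- sampleSplits(g)
    ids <- function(stage, group)
        names(lab)[!is.na(lab) & !is.na(sp) & lab == group & sp == stage]
    evalStage <- function(bl, stage) {
        do.call(rbind, lapply(bl, function(b) {
            tab <- carrierTable(g, b, ids(stage, "CASE"),
                                ids(stage, "CONTROL"), maxMissingFraction)
            cbind(bloc_id = b@id, stage = stage, associationTest(tab, level),
                  n_excluded = attr(tab, "n_excluded"),
                  stringsAsFactors = FALSE)
        }))
    }
    out <- list(stages = list(), survivors = character(0),
                selected = NA_character_, status = "COMPLETE",
                parameters = list(minNodes = minNodes,
                                  maxMissingFraction = maxMissingFraction,
                                  level = level))
    eligible <- Filter(function(b) b@sourceComponentSize >= minNodes, blocs)
    if (!length(eligible)) {
        out$status <- "NO_ELIGIBLE_BLOCS"
        return(out)
    }
    disc <- evalStage(eligible, "DISCOVERY")
    out$stages$DISCOVERY <- disc
    surv <- disc$bloc_id[disc$significant]
    out$survivors <- surv
    if (!length(surv)) {
        out$status <- "NO_DISCOVERY_SURVIVORS"
        return(out)
    }
    keep <- Filter(function(b) b@id %in% surv, eligible)
    val <- evalStage(keep, "VALIDATION")
    out$stages$VALIDATION <- val
    vs <- val[val$significant, , drop = FALSE]
    if (!nrow(vs)) {
        out$status <- "NO_VALIDATION_SURVIVORS"
        return(out)
    }
    vs <- vs[order(vs$p, -vs$ci_low, vs$bloc_id), , drop = FALSE]
    out$selected <- vs$bloc_id[1]
    sel <- Filter(function(b) b@id == out$selected, keep)
    out$stages$REPLICATION <- evalStage(sel, "REPLICATION")
    out
}

#' Write a screening audit trail to disk
#'
#' Per-stage TSV reports (`bloc_id stage a b c d or ci_low ci_high p
#' significant`) plus a JSON audit of the full cascade.
#'
#' @param screen result of [screenBlocs()].
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
writeScreenReport <- function(screen, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- character(0)
    for (stage in names(screen$stages)) {
        p <- file.path(dir, paste0("association_",
                                   tolower(stage), ".tsv"))
        utils::write.table(screen$stages[[stage]], p, sep = "\t",
                           quote = FALSE, row.names = FALSE)
        paths <- c(paths, p)
    }
    ap <- file.path(dir, "screen_audit.json")
    jsonlite::write_json(screen, ap, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    invisible(c(paths, ap))
}
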