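#' Run configuration with published default thresholds
#'
#' Bundles the pipeline thresholds. The defaults encode the analysis
#' parameterization the package is built around: SNPs with more than
#' 10% missing genotypes removed, network truncated to mean node degree
#' 1, blocs screened at more than 10 nodes, samples with more than 30%
#' missing bloc genotypes excluded from carrier calls, and 95%
#' confidence intervals -- so a discovery run with no overrides
#' reproduces that parameterization.
#'
#' @param snpMissing SNP missingness threshold; default 0.10.
#' @param sampleMissing per-sample bloc-missingness exclusion; default
#'   0.30.
#' @param meanDegree network mean-degree target; default 1.0.
#' @param minBlocNodes minimum component node count; default 11.
#' @param ciLevel confidence level; default 0.95.
#' @param maxPairDistance base-pair window for SNP pairs; default `Inf`
#'   (whole chromosome).
#' @param seed RNG seed recorded in provenance (the discovery and
#'   association stages themselves are deterministic).
#' @return a list of class `RunConfig`.
#' @export
runConfig <- function(snpMissing = 0.10, sampleMissing = 0.30,
                      meanDegree = 1.0, minBlocNodes = 11L,
                      ciLevel = 0.95, maxPairDistance = Inf, seed = 1L) {
    stopifnot(snpMissing >= 0, snpMissing <= 1,
              sampleMissing >= 0, sampleMissing <= 1,
              meanDegree >= 0, minBlocNodes >= 2,
              ciLevel > 0, ciLevel < 1)
    structure(list(snpMissing = snpMissing, sampleMissing = sampleMissing,
                   meanDegree = meanDegree,
                   minBlocNodes = as.integer(minBlocNodes),
                   ciLevel = ciLevel, maxPairDistance = maxPairDistance,
                   seed = as.integer(seed)),
              class = "RunConfig")
}

.provenance <- function(outDir, config, inputs = character(0),
                        extra = list()) {
    cfg <- unclass(config)
    cfg$maxPairDistance <- if (is.finite(cfg$maxPairDistance))
        cfg$maxPairDistance else "unlimited"
    rec <- c(list(
        package = "blocnet",
        version = as.character(utils::packageVersion("blocnet")),
        r_version = as.character(getRversion()),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        config = cfg,
        inputs = as.list(if (length(inputs))
            vapply(inputs, function(p) unname(tools::md5sum(p)),
                   character(1)) else character(0))),
        extra)
    path <- file.path(outDir, "provenance.json")
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Discovery stage: filter, build network, extract blocs
#'
#' Applies the SNP missingness filter, builds the candidate allele
#' network over all samples (unlabeled), truncates it to the target
#' mean degree, extracts blocs, and writes `edges.tsv`,
#' `network_summary.tsv`, `blocs.tsv` and a machine-readable
#' `provenance.json` into `outDir`. Filter before/after counts are
#' reported via `message()`. Deterministic given input and config.
#'
#' @param g a [GenotypeData-class] object.
#' @param config a [runConfig()] list.
#' @param outDir output directory (created if needed).
#' @param inputs optional paths of the raw inputs, checksummed into the
#'   provenance record.
#' @return invisibly, a list with the thresholded `network`, `blocs`,
#'   and `summary`.
#' @export
runDiscover <- function(g, config = runConfig(), outDir,
                        inputs = character(0)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    n0 <- nrow(g)
    g <- filterSnpsByMissingness(g, config$snpMissing)
    message("SNP missingness filter (> ", config$snpMissing * 100,
            "%): ", n0, " -> ", nrow(g), " SNPs")
    if (nrow(g) == 0)
        stop("no SNPs remain after the missingness filter")
    net <- buildNetwork(g, config$maxPairDistance)
    net <- thresholdToMeanDegree(net, config$meanDegree)
    blocs <- extractBlocs(net, config$minBlocNodes)
    message("thresholded network: ", nrow(networkEdges(net)),
            " edges, ", length(blocs), " bloc(s) with >= ",
            config$minBlocNodes, " nodes")
    summ <- summarizeNetwork(net)
    writeEdgeList(net, file.path(outDir, "edges.tsv"))
    utils::write.table(summ, file.path(outDir, "network_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (length(blocs))
        writeBlocTable(blocs, file.path(outDir, "blocs.tsv"))
    .provenance(outDir, config, inputs,
                list(stage = "discover", n_snps_input = n0,
                     n_snps_used = nrow(g), n_samples = ncol(g)))
    invisible(list(network = net, blocs = blocs, summary = summ))
}

#' Association stage: three-trial screening cascade
#'
#' Runs [screenBlocs()] and writes per-stage TSV reports, the JSON
#' audit trail and a provenance record into `outDir`.
#'
#' @param g a labeled and split [GenotypeData-class].
#' @param blocs list of [Bloc-class] objects (or a `blocs.tsv` path).
#' @param config a [runConfig()] list.
#' @param outDir output directory.
#' @param inputs optional raw-input paths for provenance.
#' @return invisibly, the [screenBlocs()] audit list.
#' @export
runAssociate <- function(g, blocs, config = runConfig(), outDir,
                         inputs = character(0)) {
    if (is.character(blocs)) blocs <- readBlocTable(blocs)
    lab <- sampleLabels(g)
    sp <- sampleSplits(g)
    if (all(is.na(sp)))
        stop("no cohort-split assignments present; supply a split file")
    if (!any(lab %in% "CASE") || !any(lab %in% "CONTROL"))
        stop("labels must include CASE and CONTROL samples")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    screen <- screenBlocs(blocs, g, minNodes = config$minBlocNodes,
                          maxMissingFraction = config$sampleMissing,
                          level = config$ciLevel)
    writeScreenReport(screen, outDir)
    .provenance(outDir, config, inputs,
                list(stage = "associate", status = screen$status,
                     selected = screen$selected))
    invisible(screen)
}

#' Population-frequency stage
#'
#' Profiles a bloc's carrier frequency across population panels
#' ([profilePopulations()]) and writes a TSV report
#' (`population n_snps n_evaluated carriers_freq`) plus provenance.
#'
#' @param populations named list of [GenotypeData-class] panels.
#' @param bloc the [Bloc-class] to profile (or a bloc TSV path; the
#'   first bloc in the file is used).
#' @param config a [runConfig()] list.
#' @param outDir output directory.
#' @param inputs optional raw-input paths for provenance.
#' @return invisibly, the profile data.frame.
#' @export
runPopFreq <- function(populations, bloc, config = runConfig(), outDir,
                       inputs = character(0)) {
    if (is.character(bloc)) bloc <- readBlocTable(bloc)[[1]]
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    prof <- profilePopulations(populations, bloc, config$sampleMissing)
    utils::write.table(prof, file.path(outDir, "population_freq.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .provenance(outDir, config, inputs, list(stage = "popfreq"))
    invisible(prof)
}
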