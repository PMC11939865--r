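#' Read PLINK ped/map genotypes
#'
#' Parses whitespace-delimited text PLINK files into a
#' [GenotypeData-class] object. Dosage is coded against the *minor*
#' allele observed in the file (the rarer of the two alleles at each
#' SNP); on a frequency tie the lexicographically later nucleotide is
#' taken as the alternate allele, so orientation is deterministic.
#' The genotype code `"0"` (either allele of a pair) maps to missing.
#' For a monomorphic SNP the alternate allele is unobservable and is
#' assigned the alphabetically first nucleotide differing from the
#' observed one.
#'
#' @param pedPath path to the `.ped` file (6 leading columns, then two
#'   allele columns per SNP).
#' @param mapPath path to the `.map` file (chrom, snp_id, genetic
#'   distance, position).
#' @return a [GenotypeData-class] object; sample ids are taken from the
#'   IID column.
#' @export
readPlink <- function(pedPath, mapPath) {
    stopifnot(file.exists(pedPath), file.exists(mapPath))
    map <- utils::read.table(mapPath, header = FALSE,
                             stringsAsFactors = FALSE,
                             colClasses = "character")
    if (ncol(map) != 4)
        stop("malformed map file: expected 4 columns, found ", ncol(map))
    nsnp <- nrow(map)
    lines <- readLines(pedPath)
    lines <- lines[nzchar(trimws(lines))]
    toks <- strsplit(trimws(lines), "[ \t]+")
    nf <- lengths(toks)
    bad <- which(nf != 6 + 2 * nsnp)
    if (length(bad))
        stop("malformed ped line ", bad[1], ": expected ", 6 + 2 * nsnp,
             " fields, found ", nf[bad[1]])
    tok <- do.call(rbind, toks)
    ids <- tok[, 2]
    if (anyDuplicated(ids))
        stop("duplicate sample ids in ped file")
    al <- tok[, -(1:6), drop = FALSE]
    ok <- al %in% c(NUCLEOTIDES, "0")
    if (!all(ok)) {
        first <- which(!ok)[1]
        stop("invalid allele code '", al[first],
             "' (expected A/C/G/T/0) in ped file")
    }
    a1 <- al[, seq(1, 2 * nsnp, by = 2), drop = FALSE]
    a2 <- al[, seq(2, 2 * nsnp, by = 2), drop = FALSE]
    miss <- a1 == "0" | a2 == "0"   # half-missing treated as missing
    n <- nrow(tok)
    dose <- matrix(NA_integer_, nrow = nsnp, ncol = n)
    ref <- alt <- character(nsnp)
    for (j in seq_len(nsnp)) {
        obs <- c(a1[!miss[, j], j], a2[!miss[, j], j])
        alleles <- sort(unique(obs))
        if (length(alleles) > 2)
            stop("SNP ", map[j, 2], ": more than two alleles observed (",
                 paste(alleles, collapse = ", "), ")")
        if (length(alleles) == 0) {
            ref[j] <- "A"; alt[j] <- "C"
        } else if (length(alleles) == 1) {
            ref[j] <- alleles
            alt[j] <- setdiff(NUCLEOTIDES, alleles)[1]
        } else {
            cnt <- c(sum(obs == alleles[1]), sum(obs == alleles[2]))
            # minor allele becomes ALT; tie -> lexicographically later
            alt[j] <- if (cnt[2] <= cnt[1]) alleles[2] else alleles[1]
            ref[j] <- setdiff(alleles, alt[j])
        }
        dj <- (a1[, j] == alt[j]) + (a2[, j] == alt[j])
        dj[miss[, j]] <- NA_integer_
        dose[j, ] <- dj
    }
    colnames(dose) <- ids
    GenotypeData(dose,
                 data.frame(snp_id = map[, 2], chrom = map[, 1],
                            pos = as.integer(map[, 4]),
                            ref = ref, alt = alt,
                            stringsAsFactors = FALSE))
}

#' Write PLINK ped/map genotypes
#'
#' Inverse of [readPlink()] up to allele orientation: the ped format
#' stores nucleotide pairs, so a SNP whose alternate allele is the
#' in-sample *major* allele will be re-oriented on re-read (minor-allele
#' coding is re-derived at load).
#'
#' @param g a [GenotypeData-class] object.
#' @param pedPath,mapPath output paths.
#' @return invisibly, the two paths.
#' @export
writePlink <- function(g, pedPath, mapPath) {
    si <- snpInfo(g)
    d <- dosage(g)
    utils::write.table(
        data.frame(si$chrom, si$snp_id, 0, si$pos),
        mapPath, quote = FALSE, sep = "\t",
        row.names = FALSE, col.names = FALSE)
    n <- ncol(d)
    geno <- matrix("0 0", nrow = nrow(d), ncol = n)
    geno[!is.na(d) & d == 0] <- paste(si$ref, si$ref)[row(d)[!is.na(d) & d == 0]]
    geno[!is.na(d) & d == 1] <- paste(si$ref, si$alt)[row(d)[!is.na(d) & d == 1]]
    geno[!is.na(d) & d == 2] <- paste(si$alt, si$alt)[row(d)[!is.na(d) & d == 2]]
    lines <- vapply(seq_len(n), function(i) {
        paste(c(colnames(d)[i], colnames(d)[i], "0", "0", "0", "-9",
                geno[, i]), collapse = " ")
    }, character(1))
    writeLines(lines, pedPath)
    invisible(c(ped = pedPath, map = mapPath))
}

#' Read biallelic SNP genotypes from a VCF
#'
#' Reads a VCF 4.x file (GT field required) into a
#' [GenotypeData-class] object. Phased (`|`) and unphased (`/`)
#' separators are treated identically -- the pipeline is unphased.
#' `./.` and half-missing calls map to missing. Multi-allelic records
#' are rejected with an error naming the record. REF/ALT orientation is
#' taken from the file as-is.
#'
#' @param vcfPath path to a VCF file.
#' @return a [GenotypeData-class] object.
#' @export
readGenotypeVcf <- function(vcfPath) {
    stopifnot(file.exists(vcfPath))
    v <- vcfR::read.vcfR(vcfPath, verbose = FALSE)
    fix <- rbind(vcfR::getFIX(v))   # stays a matrix for 1-record files
    multi <- grepl(",", fix[, "ALT"]) | nchar(fix[, "REF"]) > 1 |
        nchar(fix[, "ALT"]) > 1
    if (any(multi)) {
        i <- which(multi)[1]
        stop("multi-allelic (or non-SNP) record at ", fix[i, "CHROM"], ":",
             fix[i, "POS"], " (", fix[i, "ID"], ")")
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    gt[] <- gsub("|", "/", gt, fixed = TRUE)
    lut <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
    dose <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                   dimnames = dimnames(gt))
    known <- gt %in% names(lut)
    dose[known] <- lut[gt[known]]
    other <- !known & !is.na(gt) & !gt %in% c("./.", ".", "./0", "0/.",
                                              "./1", "1/.")
    if (any(other))
        stop("unsupported GT value '", gt[which(other)[1]], "'")
    ids <- fix[, "ID"]
    blank <- is.na(ids) | ids == "."
    ids[blank] <- paste0(fix[blank, "CHROM"], ":", fix[blank, "POS"])
    GenotypeData(dose,
                 data.frame(snp_id = ids, chrom = fix[, "CHROM"],
                            pos = as.integer(fix[, "POS"]),
                            ref = fix[, "REF"], alt = fix[, "ALT"],
                            stringsAsFactors = FALSE))
}

#' Write genotypes to a plain-text VCF 4.2 file
#'
#' Emits GT-only biallelic records (`0/0`, `0/1`, `1/1`, `./.`), which
#' round-trips exactly through [readGenotypeVcf()] including allele
#' orientation.
#'
#' @param g a [GenotypeData-class] object.
#' @param vcfPath output path.
#' @return invisibly, the path.
#' @export
writeGenotypeVcf <- function(g, vcfPath) {
    si <- snpInfo(g)
    d <- dosage(g)
    gt <- matrix("./.", nrow = nrow(d), ncol = ncol(d))
    gt[!is.na(d) & d == 0] <- "0/0"
    gt[!is.na(d) & d == 1] <- "0/1"
    gt[!is.na(d) & d == 2] <- "1/1"
    body <- vapply(seq_len(nrow(d)), function(j) {
        paste(c(si$chrom[j], si$pos[j], si$snp_id[j], si$ref[j], si$alt[j],
                ".", "PASS", ".", "GT", gt[j, ]), collapse = "\t")
    }, character(1))
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", colnames(d)), collapse = "\t"),
        body), vcfPath)
    invisible(vcfPath)
}

#' Read a sample-label TSV (`sample_id<TAB>label`)
#'
#' @param path TSV path, no header.
#' @return named character vector of labels.
#' @export
readSampleLabels <- function(path) {
    x <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
    if (ncol(x) != 2) stop("label file must have 2 tab-separated columns")
    setNames(x[[2]], x[[1]])
}

#' Read a cohort-split TSV (`sample_id<TAB>split_name`)
#'
#' Splits are caller-provided input (no randomization). Split names must
#' be DISCOVERY, VALIDATION or REPLICATION, and no sample may appear in
#' two splits.
#'
#' @param path TSV path, no header.
#' @return named character vector of split names.
#' @export
readCohortSplits <- function(path) {
    sp <- readSampleLabels(path)
    bad <- setdiff(unique(sp), c("DISCOVERY", "VALIDATION", "REPLICATION"))
    if (length(bad))
        stop("unknown split name(s): ", paste(bad, collapse = ", "))
    if (anyDuplicated(names(sp)))
        stop("sample(s) assigned to more than one split")
    sp
}
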