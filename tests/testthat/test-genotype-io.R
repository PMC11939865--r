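test_that("ped parsing codes dosage against the minor allele", {
    ped <- tempfile(fileext = ".ped")
    map <- tempfile(fileext = ".map")
    writeLines(c("F1 S1 0 0 0 -9 A A",
                 "F2 S2 0 0 0 -9 A G"), ped)
    writeLines("19\trs1\t0\t100", map)
    g <- readPlink(ped, map)
    expect_equal(unname(dosage(g)[1, ]), c(0L, 1L))
    expect_equal(snpInfo(g)$alt, "G")
    expect_equal(snpInfo(g)$ref, "A")
})

test_that("ped with more than two alleles at a SNP is rejected", {
    ped <- tempfile(fileext = ".ped")
    map <- tempfile(fileext = ".map")
    writeLines(c("F1 S1 0 0 0 -9 A G",
                 "F2 S2 0 0 0 -9 A T"), ped)
    writeLines("19\trs1\t0\t100", map)
    expect_error(readPlink(ped, map), "more than two alleles")
})

test_that("malformed ped lines and bad allele codes are named", {
    ped <- tempfile(fileext = ".ped")
    map <- tempfile(fileext = ".map")
    writeLines("19\trs1\t0\t100", map)
    writeLines("F1 S1 0 0 0 -9 A", ped)
    expect_error(readPlink(ped, map), "line 1")
    writeLines("F1 S1 0 0 0 -9 A X", ped)
    expect_error(readPlink(ped, map), "invalid allele")
})

test_that("plink round-trip preserves dosage, sample and SNP order", {
    # construct so the alternate allele is strictly minor at every SNP
    # (ped stores nucleotides only, so orientation is re-derived at load)
    set.seed(11)
    nS <- 10; nP <- 20
    d <- matrix(0L, nP, nS)
    for (j in seq_len(nP)) {
        repeat {
            x <- rbinom(nS, 2, 0.25)
            if (sum(x) >= 1 && sum(x) < nS) break
        }
        d[j, ] <- x
    }
    d[1, 1] <- NA  # missing survives the trip
    si <- data.frame(snp_id = sprintf("rs%d", 1:nP), chrom = "19",
                     pos = 1:nP * 50L,
                     ref = rep(c("A", "C"), length.out = nP),
                     alt = rep(c("G", "T"), length.out = nP))
    g <- GenotypeData(d, si)
    ped <- tempfile(fileext = ".ped"); map <- tempfile(fileext = ".map")
    writePlink(g, ped, map)
    g2 <- readPlink(ped, map)
    expect_identical(dosage(g2), dosage(g))
    expect_identical(snpInfo(g2)$snp_id, snpInfo(g)$snp_id)
    expect_identical(colnames(g2), colnames(g))
})

test_that("VCF GT parsing: unphased, phased and missing calls", {
    vcf <- tempfile(fileext = ".vcf")
    writeLines(c("##fileformat=VCFv4.2",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"G\">",
                 paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", "S1", "S2", "S3", "S4",
                       sep = "\t"),
                 paste("19", "100", "rs1", "A", "G", ".", "PASS", ".",
                       "GT", "0/1", "1|1", "0|0", "./.", sep = "\t"),
                 paste("19", "200", "rs2", "C", "T", ".", "PASS", ".",
                       "GT", "1/0", "0/0", "1|0", "1/1", sep = "\t")), vcf)
    g <- readGenotypeVcf(vcf)
    # phased and unphased separators are equivalent; ./. is missing
    expect_equal(unname(dosage(g)["rs1", ]), c(1L, 2L, 0L, NA))
    expect_equal(unname(dosage(g)["rs2", ]), c(1L, 0L, 1L, 2L))
    expect_equal(snpInfo(g)$ref, c("A", "C"))
})

test_that("multi-allelic VCF records are rejected by name", {
    vcf <- tempfile(fileext = ".vcf")
    writeLines(c("##fileformat=VCFv4.2",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"G\">",
                 paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", "S1", sep = "\t"),
                 paste("19", "100", "rsX", "A", "G,T", ".", "PASS", ".",
                       "GT", "0/1", sep = "\t")), vcf)
    expect_error(readGenotypeVcf(vcf), "rsX")
})

test_that("VCF round-trip is exact, including allele orientation", {
    g <- randomGenotypeData(15, 12, missing = 0.1, seed = 3)
    vcf <- tempfile(fileext = ".vcf")
    writeGenotypeVcf(g, vcf)
    g2 <- readGenotypeVcf(vcf)
    expect_identical(dosage(g2), dosage(g))
    expect_identical(snpInfo(g2)$ref, snpInfo(g)$ref)
    expect_identical(snpInfo(g2)$alt, snpInfo(g)$alt)
})

test_that("SNP missingness filter is a strict 'more than' rule", {
    d <- matrix(0L, 2, 10)
    d[1, 1] <- NA                    # 10% missing: retained at 0.10
    d[2, 1:2] <- NA                  # 20% missing: removed
    si <- data.frame(snp_id = c("a", "b"), chrom = "1", pos = 1:2,
                     ref = "A", alt = "G")
    g <- filterSnpsByMissingness(GenotypeData(d, si), 0.10)
    expect_identical(snpInfo(g)$snp_id, "a")
})

test_that("missingness filters match brute-force counts and are idempotent", {
    g <- randomGenotypeData(100, 50, missing = 0.12, seed = 4)
    thr <- 0.10
    f1 <- filterSnpsByMissingness(g, thr)
    keep <- apply(dosage(g), 1, function(x) mean(is.na(x)) <= thr)
    expect_identical(snpInfo(f1)$snp_id, snpInfo(g)$snp_id[keep])
    expect_identical(dosage(filterSnpsByMissingness(f1, thr)), dosage(f1))

    sub <- snpInfo(g)$snp_id[1:13]
    f2 <- filterSamplesByMissingness(g, sub, 0.30)
    keepS <- apply(dosage(g)[1:13, ], 2, function(x) mean(is.na(x)) <= 0.30)
    expect_identical(colnames(f2), colnames(g)[keepS])
    expect_identical(colnames(filterSamplesByMissingness(f2, sub, 0.30)),
                     colnames(f2))
})

test_that("sample filter boundary: 4/13 missing excluded, 3/13 retained", {
    d <- matrix(0L, 13, 2)
    d[1:4, 1] <- NA   # 30.8% > 30%: excluded
    d[1:3, 2] <- NA   # 23.1%: retained
    si <- data.frame(snp_id = sprintf("s%d", 1:13), chrom = "1",
                     pos = 1:13, ref = "A", alt = "G")
    g <- filterSamplesByMissingness(GenotypeData(d, si),
                                    maxMissingFraction = 0.30)
    expect_equal(ncol(g), 1L)
    expect_error(filterSamplesByMissingness(GenotypeData(d, si), "nope"),
                 "not present")
})

test_that("snp filter extremes: threshold 1 is identity, 0 keeps complete", {
    g <- randomGenotypeData(40, 20, missing = 0.1, seed = 5)
    expect_identical(dosage(filterSnpsByMissingness(g, 1)), dosage(g))
    f0 <- filterSnpsByMissingness(g, 0)
    expect_true(all(!is.na(dosage(f0))))
})

test_that("label and split files read as named vectors with checks", {
    f <- tempfile()
    writeLines(c("S1\tCASE", "S2\tCONTROL"), f)
    expect_equal(readSampleLabels(f), c(S1 = "CASE", S2 = "CONTROL"))
    writeLines(c("S1\tDISCOVERY", "S2\tHOLDOUT"), f)
    expect_error(readCohortSplits(f), "HOLDOUT")
    writeLines(c("S1\tDISCOVERY", "S1\tVALIDATION"), f)
    expect_error(readCohortSplits(f), "more than one")
})

test_that("missingness report flags samples above the nominal threshold", {
    g <- randomGenotypeData(100, 5, seed = 6)
    d <- dosage(g); d[1:2, 3] <- NA
    g <- GenotypeData(d, snpInfo(g))
    rep <- missingnessReport(g, 0.01)
    expect_equal(rep$flaggedSamples, colnames(g)[3])
    expect_equal(unname(rep$sampleMissing[3]), 0.02)
})
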