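test_that("identical SNPs give weight 1 on matching alleles, 0 across", {
    # homozygous-only copies: co-occurrence attains its maximum exactly
    d <- rbind(c(2L, 2L, 0L, 0L, 2L, 0L),
               c(2L, 2L, 0L, 0L, 2L, 0L))
    si <- data.frame(snp_id = c("a", "b"), chrom = "1", pos = 1:2,
                     ref = "A", alt = "G")
    w <- cccPair(GenotypeData(d, si), 1, 2)
    expect_equal(w["ALT", "ALT"], 1)
    expect_equal(w["REF", "REF"], 1)
    expect_equal(w["ALT", "REF"], 0)
    expect_equal(w["REF", "ALT"], 0)
})

test_that("4-sample toy matches hand-enumerated counts to 1e-12", {
    xi <- c(2L, 1L, 0L, 0L); xj <- c(2L, 2L, 0L, 0L)
    si <- data.frame(snp_id = c("a", "b"), chrom = "1", pos = 1:2,
                     ref = "A", alt = "G")
    w <- cccPair(GenotypeData(rbind(xi, xj), si), 1, 2)
    # frozen hand computation for columns (2,2,0,0) / (2,1,0,0):
    # p_alt_i = .5, p_alt_j = .375, p_AA = 6/16 -> excess .1875 over a
    # maximum of .1875 -> 1; REF/REF likewise 1; cross pairs negative
    hand <- matrix(c(1, 0, 0, 1), 2, 2,
                   dimnames = list(c("REF", "ALT"), c("REF", "ALT")))
    expect_equal(unclass(w), hand, tolerance = 1e-12)
    expect_equal(unclass(w), oracleCCC(xi, xj), tolerance = 1e-12)
})

test_that("independent SNPs have all four weights near zero", {
    set.seed(101)
    n <- 10000
    d <- rbind(rbinom(n, 2, 0.3), rbinom(n, 2, 0.4))
    si <- data.frame(snp_id = c("a", "b"), chrom = "1", pos = 1:2,
                     ref = "A", alt = "G")
    w <- cccPair(GenotypeData(d, si), 1, 2)
    expect_true(all(w < 0.05))
})

test_that("weights are symmetric, in [0,1], and invariant to sample order
           and duplication", {
    g <- randomGenotypeData(6, 40, missing = 0.05, seed = 7)
    for (j in 2:6) {
        w <- cccPair(g, 1, j)
        wt <- cccPair(g, j, 1)
        expect_equal(unclass(w), t(unclass(wt)))
        expect_true(all(w >= 0 & w <= 1))
    }
    perm <- sample(ncol(g))
    gp <- GenotypeData(dosage(g)[, perm], snpInfo(g))
    gd <- GenotypeData(cbind(dosage(g), dosage(g)), snpInfo(g))
    expect_equal(unclass(cccPair(gp, 1, 3)), unclass(cccPair(g, 1, 3)))
    expect_equal(unclass(cccPair(gd, 1, 3)), unclass(cccPair(g, 1, 3)))
})

test_that("pairwise-complete masking matches enumeration with missing data", {
    g <- randomGenotypeData(8, 60, missing = 0.15, seed = 8)
    d <- dosage(g)
    for (p in list(c(1, 2), c(3, 7), c(5, 6))) {
        expect_equal(unclass(cccPair(g, p[1], p[2])),
                     oracleCCC(d[p[1], ], d[p[2], ]), tolerance = 1e-12)
    }
})

test_that("fewer than 2 complete samples yields NA with a warning", {
    d <- rbind(c(1L, NA, 2L), c(NA, 1L, NA))
    si <- data.frame(snp_id = c("a", "b"), chrom = "1", pos = 1:2,
                     ref = "A", alt = "G")
    expect_warning(w <- cccPair(GenotypeData(d, si), 1, 2), "skipped")
    expect_true(all(is.na(w)))
})

test_that("ALT-ALT weight decays as a duplicated SNP is randomized", {
    set.seed(102)
    n <- 2000
    x <- rbinom(n, 2, 0.4)
    w <- sapply(c(0, 0.2, 0.5, 0.8), function(k) {
        y <- x
        idx <- sample(n, round(k * n))
        y[idx] <- rbinom(length(idx), 2, 0.4)
        si <- data.frame(snp_id = c("a", "b"), chrom = "1", pos = 1:2,
                         ref = "A", alt = "G")
        cccPair(GenotypeData(rbind(x, y), si), 1, 2)["ALT", "ALT"]
    })
    expect_true(all(diff(w) < 0.02))   # monotone decrease (small slack)
    expect_gt(w[1] - w[4], 0.3)
})

test_that("candidate network enumerates four edges per eligible pair", {
    g <- randomGenotypeData(3, 30, seed = 9)
    net <- buildNetwork(g)
    expect_equal(nrow(networkEdges(net)), 3 * 4)   # 3 pairs x 4
    expect_equal(net@nNodes, 6L)
    # windowed: count equals brute-force pair enumeration
    g2 <- randomGenotypeData(100, 25, seed = 10)
    win <- 20000
    net2 <- buildNetwork(g2, maxPairDistance = win)
    si <- snpInfo(g2)
    pairs <- 0L
    for (i in 1:99) for (j in (i + 1):100)
        if (abs(si$pos[i] - si$pos[j]) <= win) pairs <- pairs + 1L
    expect_equal(nrow(networkEdges(net2)), 4L * pairs)
})

test_that("empty genotype matrix gives an empty network", {
    si <- data.frame(snp_id = character(0), chrom = character(0),
                     pos = integer(0), ref = character(0),
                     alt = character(0))
    net <- buildNetwork(GenotypeData(matrix(0L, 0, 0), si))
    expect_equal(nrow(networkEdges(net)), 0L)
    expect_equal(net@nNodes, 0L)
})

test_that("network weights agree with cccPair on every pair", {
    g <- randomGenotypeData(10, 50, missing = 0.1, seed = 12)
    net <- buildNetwork(g)
    e <- networkEdges(net)
    for (r in sample(nrow(e), 20)) {
        w <- cccPair(g, e$snp_a[r], e$snp_b[r])
        expect_equal(e$weight[r], w[e$allele_a[r], e$allele_b[r]],
                     tolerance = 1e-12)
    }
})

test_that("mean-degree thresholding keeps floor(V/2) edges with the tie rule", {
    g <- randomGenotypeData(10, 80, seed = 13)
    net <- buildNetwork(g)
    thr <- thresholdToMeanDegree(net, 1.0)
    expect_equal(nrow(networkEdges(thr)), 10L)   # |V| = 20 -> 10 edges
    # sort-and-slice oracle under (weight desc, node a, node b)
    e <- networkEdges(net)
    e <- e[e$weight > 0, ]
    ids <- list(a = 2L * e$snp_a - (e$allele_a == "REF"),
                b = 2L * e$snp_b - (e$allele_b == "REF"))
    ord <- order(-e$weight, ids$a, ids$b)
    expect_equal(networkEdges(thr), e[ord[1:10], ],
                 ignore_attr = TRUE)
    # target 0 empties the edge set; degree bound holds in general
    expect_equal(nrow(networkEdges(thresholdToMeanDegree(net, 0))), 0L)
    for (t in c(0.3, 0.7, 1.5)) {
        thrT <- thresholdToMeanDegree(net, t)
        expect_lte(2 * nrow(networkEdges(thrT)) / thrT@nNodes, t)
    }
})

test_that("thresholding warns and keeps all when candidates run short", {
    g <- randomGenotypeData(3, 30, seed = 14)
    net <- buildNetwork(g)
    npos <- sum(networkEdges(net)$weight > 0)
    expect_warning(thr <- thresholdToMeanDegree(net, 100), "retaining all")
    expect_equal(nrow(networkEdges(thr)), npos)
})

test_that("edge list export writes nucleotide alleles", {
    g <- randomGenotypeData(4, 40, seed = 15)
    net <- thresholdToMeanDegree(buildNetwork(g), 1)
    f <- tempfile(fileext = ".tsv")
    writeEdgeList(net, f)
    x <- read.table(f, header = TRUE, sep = "\t")
    expect_equal(nrow(x), nrow(networkEdges(net)))
    expect_true(all(unlist(x[, c("allele_a", "allele_b")]) %in%
                    c("A", "C", "G", "T")))
})
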