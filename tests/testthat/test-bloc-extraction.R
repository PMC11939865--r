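test_that("a path component and an isolated node separate correctly", {
    # REF nodes of SNPs 1-2-3 chained; everything else singleton
    net <- makeNet(3, c(1, 2), c("REF", "REF"), c(2, 3), c("REF", "REF"),
                   c(0.9, 0.8))
    cc <- connectedComponents(net)
    expect_length(cc$components, 1)
    expect_equal(cc$components[[1]], c(1L, 3L, 5L))  # REF ids 2k-1
    expect_equal(cc$singletons, c(2L, 4L, 6L))
})

test_that("an empty edge set yields all singletons", {
    net <- makeNet(10, integer(0), character(0), integer(0), character(0),
                   numeric(0))
    cc <- connectedComponents(net)
    expect_length(cc$components, 0)
    expect_length(cc$singletons, 20)
    s <- summarizeNetwork(net)
    expect_equal(s$singleton_fraction, 1.0)
    expect_true(is.na(s$component_size_min))
})

test_that("BFS partition matches union-find on random graphs", {
    for (seed in 1:50) {
        nSnps <- sample(5:15, 1)
        net <- randomNet(nSnps, sample(5:40, 1), seed = seed)
        cc <- connectedComponents(net)
        got <- c(cc$components, as.list(cc$singletons))
        got <- got[order(vapply(got, min, integer(1)))]
        ids <- nodeIds(net)
        want <- oracleComponents(2L * nSnps, ids$a, ids$b)
        want <- lapply(want, sort)
        want <- want[order(vapply(want, min, integer(1)))]
        expect_equal(lapply(got, as.integer), lapply(want, as.integer))
    }
})

test_that("components are a true partition, independent of edge order", {
    net <- randomNet(12, 30, seed = 77)
    cc <- connectedComponents(net)
    all_nodes <- sort(c(unlist(cc$components), cc$singletons))
    expect_equal(all_nodes, seq_len(24L))
    e <- networkEdges(net)
    net2 <- makeNet(12, e$snp_a[30:1], e$allele_a[30:1], e$snp_b[30:1],
                    e$allele_b[30:1], e$weight[30:1])
    expect_equal(connectedComponents(net2), cc)
})

test_that("min-size screen: 10-node component excluded at 11, kept at 10", {
    # star over REF nodes of SNPs 1..10
    net <- makeNet(12, rep(1, 9), rep("REF", 9), 2:10, rep("REF", 9),
                   runif(9))
    cc <- connectedComponents(net)
    expect_length(componentsToBlocs(cc, net, minSize = 11), 0)
    bl <- componentsToBlocs(cc, net, minSize = 10)
    expect_length(bl, 1)
    expect_equal(blocSize(bl[[1]]), 10)
    expect_equal(bl[[1]]@sourceComponentSize, 10L)
})

test_that("a 23-node component over 23 SNPs becomes one 23-member bloc", {
    net <- makeNet(25, rep(1, 22), rep("ALT", 22), 2:23, rep("ALT", 22),
                   runif(22, 0.5, 1))
    bl <- componentsToBlocs(connectedComponents(net), net, minSize = 11)
    expect_length(bl, 1)
    expect_equal(blocSize(bl[[1]]), 23)
    # members in genomic order with the ALT nucleotide
    expect_equal(blocMembers(bl[[1]])$snp_id, sprintf("s%03d", 1:23))
    expect_true(all(blocMembers(bl[[1]])$allele == "G"))
})

test_that("both alleles of one SNP in a component: heavier allele kept,
           bloc flagged, component size preserved", {
    # snp1 REF and snp1 ALT both tied to snp2 REF; ALT edge is heavier
    net <- makeNet(2, c(1, 1), c("REF", "ALT"), c(2, 2), c("REF", "REF"),
                   c(0.4, 0.9))
    bl <- componentsToBlocs(connectedComponents(net), net, minSize = 2)
    expect_length(bl, 1)
    b <- bl[[1]]
    expect_true(b@multiAllelic)
    expect_equal(blocSize(b), 2)               # SNP count, not node count
    expect_equal(b@sourceComponentSize, 3L)
    m <- blocMembers(b)
    expect_equal(m$allele[m$snp_id == "s001"], "G")  # ALT kept
})

test_that("network summary matches direct recomputation", {
    net <- randomNet(15, 25, seed = 5)
    s <- summarizeNetwork(net)
    cc <- connectedComponents(net)
    expect_equal(s$n_nodes, 30L)
    expect_equal(s$n_edges, 25L)
    expect_equal(s$singleton_fraction, length(cc$singletons) / 30)
    expect_equal(s$component_size_min, min(lengths(cc$components)))
    expect_equal(s$component_size_max, max(lengths(cc$components)))
    # 4 nodes, one pair -> half singletons
    net2 <- makeNet(2, 1, "REF", 2, "REF", 0.5)
    s2 <- summarizeNetwork(net2)
    expect_equal(s2$singleton_fraction, 0.5)
    expect_equal(s2$component_size_max, 2L)
})

test_that("bloc tables round-trip through TSV", {
    net <- makeNet(25, rep(1, 22), rep("ALT", 22), 2:23, rep("ALT", 22),
                   runif(22, 0.5, 1))
    bl <- componentsToBlocs(connectedComponents(net), net, minSize = 11)
    f <- tempfile(fileext = ".tsv")
    writeBlocTable(bl, f)
    bl2 <- readBlocTable(f)
    expect_equal(blocMembers(bl2[[1]]), blocMembers(bl[[1]]))
    expect_equal(names(bl2), "bloc001")
})
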