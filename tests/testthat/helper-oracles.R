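# Independent oracles: deliberately naive implementations (explicit
# per-sample loops, union-find) against which the package's vectorized
# paths are checked.

# four allele-pair co-occurrence weights by direct enumeration
oracleCCC <- function(xi, xj) {
    ok <- !is.na(xi) & !is.na(xj)
    xi <- xi[ok]; xj <- xj[ok]
    n2 <- length(xi)
    w <- matrix(NA_real_, 2, 2,
                dimnames = list(c("REF", "ALT"), c("REF", "ALT")))
    if (n2 < 2) return(w)
    for (a in 1:2) for (b in 1:2) {
        da <- if (a == 2) xi else 2 - xi
        db <- if (b == 2) xj else 2 - xj
        pa <- sum(da) / (2 * n2)
        pb <- sum(db) / (2 * n2)
        pab <- sum(da * db) / (4 * n2)
        e <- pab - pa * pb
        den <- min(pa, pb) - pa * pb
        w[a, b] <- if (e > 0 && den > 0) min(1, e / den) else 0
    }
    w
}

# connected components by union-find over nv nodes
oracleComponents <- function(nv, a, b) {
    parent <- seq_len(nv)
    find <- function(x) {
        while (parent[x] != x) x <- parent[x]
        x
    }
    for (k in seq_along(a)) {
        ra <- find(a[k]); rb <- find(b[k])
        if (ra != rb) parent[ra] <- rb
    }
    roots <- vapply(seq_len(nv), find, integer(1))
    unname(split(seq_len(nv), roots))
}

# per-sample carrier scan: explicit loop over samples and bloc SNPs
oracleCarrier <- function(d, blocAlleleIsAlt, maxMiss) {
    out <- character(ncol(d))
    for (s in seq_len(ncol(d))) {
        x <- d[, s]
        if (mean(is.na(x)) > maxMiss) {
            out[s] <- "EXCLUDED"
            next
        }
        carrier <- TRUE
        for (j in seq_along(x)) {
            if (is.na(x[j])) next
            copies <- if (blocAlleleIsAlt[j]) x[j] else 2 - x[j]
            if (copies < 1) { carrier <- FALSE; break }
        }
        out[s] <- if (carrier) "CARRIER" else "NONCARRIER"
    }
    out
}

randomGenotypeData <- function(nSnps, nSamples, maf = 0.3, missing = 0,
                               seed = 1) {
    set.seed(seed)
    d <- matrix(rbinom(nSnps * nSamples, 2, maf), nrow = nSnps)
    if (missing > 0)
        d[runif(length(d)) < missing] <- NA
    si <- data.frame(snp_id = sprintf("s%03d", seq_len(nSnps)),
                     chrom = "19", pos = seq_len(nSnps) * 1000L,
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
    GenotypeData(d, si)
}

# an AlleleNetwork with an arbitrary edge set (for graph-level tests)
makeNet <- function(nSnps, snp_a, allele_a, snp_b, allele_b, weight) {
    si <- data.frame(snp_id = sprintf("s%03d", seq_len(nSnps)),
                     chrom = "19", pos = seq_len(nSnps) * 1000L,
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
    new("AlleleNetwork", snpInfo = si,
        edges = data.frame(snp_a = as.integer(snp_a), allele_a = allele_a,
                           snp_b = as.integer(snp_b), allele_b = allele_b,
                           weight = weight, stringsAsFactors = FALSE),
        nNodes = as.integer(2 * nSnps), thresholded = TRUE,
        targetMeanDegree = NA_real_)
}

randomNet <- function(nSnps, nEdges, seed) {
    set.seed(seed)
    pairs <- which(upper.tri(diag(nSnps)), arr.ind = TRUE)
    combos <- expand.grid(p = seq_len(nrow(pairs)), aa = c("REF", "ALT"),
                          ab = c("REF", "ALT"), stringsAsFactors = FALSE)
    pick <- combos[sample(nrow(combos), min(nEdges, nrow(combos))), ]
    makeNet(nSnps, pairs[pick$p, 1], pick$aa, pairs[pick$p, 2], pick$ab,
            runif(nrow(pick)))
}

# integer node ids matching the package convention
nodeIds <- function(net) {
    e <- networkEdges(net)
    list(a = 2L * e$snp_a - (e$allele_a == "REF"),
         b = 2L * e$snp_b - (e$allele_b == "REF"))
}

toyBloc <- function(g, snps = seq_len(nrow(g)), altAllele = TRUE) {
    si <- snpInfo(g)[snps, ]
    Bloc("toy", data.frame(snp_id = si$snp_id,
                           allele = if (altAllele) si$alt else si$ref,
                           chrom = si$chrom, pos = si$pos,
                           stringsAsFactors = FALSE))
}
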