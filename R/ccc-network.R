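## Allele co-occurrence kernel.
##
## For alleles a of SNP i and b of SNP j, over the n2 samples with
## non-missing genotypes at both SNPs:
##   p_a  = sum(dosage_a) / (2 n2)
##   p_ab = sum(dosage_a * dosage_b) / (4 n2)      (composite, unphased)
##   e    = p_ab - p_a p_b
##   w    = e / (min(p_a, p_b) - p_a p_b)  when e > 0 and denom > 0, else 0
## clipped to [0, 1]. Four values per SNP pair (REF/ALT x REF/ALT).
## The kernel is isolated here so an alternative can be swapped in.
.cccFromSums <- function(n2, sAi, sAj, sAA) {
    # sums over pairwise-complete samples of ALT dosages and products;
    # REF sums follow from dosage_ref = 2 - dosage_alt
    sAR <- 2 * sAi - sAA          # alt_i * ref_j
    sRA <- 2 * sAj - sAA          # ref_i * alt_j
    sRR <- 4 * n2 - 2 * sAi - 2 * sAj + sAA
    paA <- sAi / (2 * n2); paR <- 1 - paA
    pbA <- sAj / (2 * n2); pbR <- 1 - pbA
    one <- function(pab, pa, pb) {
        e <- pab - pa * pb
        den <- pmin(pa, pb) - pa * pb
        w <- ifelse(e > 0 & den > 0, e / den, 0)
        pmin(pmax(w, 0), 1)
    }
    list(RR = one(sRR / (4 * n2), paR, pbR),
         RA = one(sRA / (4 * n2), paR, pbA),
         AR = one(sAR / (4 * n2), paA, pbR),
         AA = one(sAA / (4 * n2), paA, pbA))
}

#' Allele-specific co-occurrence weights for one SNP pair
#'
#' Computes the four allele-pair correlation weights between two SNPs
#' from unphased dosages, using only samples non-missing at both SNPs.
#' Co-occurrence is composite (dosage products), never inferred phase,
#' so the statistic is defined on unphased genotypes; it is high when
#' two alleles are co-inherited and 0 when their co-occurrence does not
#' exceed the independence expectation. Symmetric under transposition:
#' `cccPair(g, i, j)[a, b] == cccPair(g, j, i)[b, a]`.
#'
#' @param g a [GenotypeData-class] object.
#' @param snpI,snpJ distinct SNP row indices (or snp_ids).
#' @return 2x2 numeric matrix, rows = alleles (`REF`, `ALT`) of `snpI`,
#'   columns = alleles of `snpJ`; `NA` throughout when fewer than 2
#'   samples are complete at both SNPs (with a warning).
#' @export
cccPair <- function(g, snpI, snpJ) {
    si <- snpInfo(g)
    ix <- function(s) if (is.character(s)) match(s, si$snp_id) else as.integer(s)
    i <- ix(snpI); j <- ix(snpJ)
    stopifnot(!is.na(i), !is.na(j), i >= 1, j >= 1,
              i <= nrow(si), j <= nrow(si))
    if (i == j) stop("snpI and snpJ must differ (no intra-SNP pairs)")
    d <- dosage(g)
    xi <- d[i, ]; xj <- d[j, ]
    ok <- !is.na(xi) & !is.na(xj)
    n2 <- sum(ok)
    out <- matrix(NA_real_, 2, 2, dimnames = list(c("REF", "ALT"),
                                                  c("REF", "ALT")))
    if (n2 < 2) {
        warning("fewer than 2 samples complete at both SNPs; pair skipped")
        return(out)
    }
    w <- .cccFromSums(n2, sum(xi[ok]), sum(xj[ok]), sum(xi[ok] * xj[ok]))
    out["REF", "REF"] <- w$RR; out["REF", "ALT"] <- w$RA
    out["ALT", "REF"] <- w$AR; out["ALT", "ALT"] <- w$AA
    out
}

#' Build the full candidate allele correlation network
#'
#' Computes, for every eligible SNP pair, the four allele-pair
#' co-occurrence weights and returns them as an (un-thresholded)
#' [AlleleNetwork-class]. All samples are used without labels, matching
#' a blind network construction over cases, intermediates and controls
#' alike. Pairs with fewer than 2 pairwise-complete samples are skipped
#' with a warning. Node and edge ordering is deterministic.
#'
#' @param g a [GenotypeData-class] object.
#' @param maxPairDistance optional base-pair window; when finite, only
#'   same-chromosome pairs within this distance are eligible (default
#'   `Inf`: all pairs, as in a whole-chromosome analysis).
#' @return an [AlleleNetwork-class] holding all candidate edges with
#'   weight > 0.
#' @export
buildNetwork <- function(g, maxPairDistance = Inf) {
    si <- snpInfo(g)
    p <- nrow(si)
    if (p == 0 || ncol(g) == 0)
        return(new("AlleleNetwork", snpInfo = si, edges = .emptyEdges(),
                   nNodes = 2L * p, thresholded = FALSE,
                   targetMeanDegree = NA_real_))
    d <- dosage(g)
    M <- (!is.na(d)) * 1
    A <- d; A[is.na(A)] <- 0L
    storage.mode(A) <- "double"
    MtM <- tcrossprod(M)
    AtM <- tcrossprod(A, M)
    AtA <- tcrossprod(A)
    ut <- which(upper.tri(MtM), arr.ind = TRUE)
    i <- ut[, 1]; j <- ut[, 2]
    if (is.finite(maxPairDistance)) {
        keep <- si$chrom[i] == si$chrom[j] &
            abs(si$pos[i] - si$pos[j]) <= maxPairDistance
        i <- i[keep]; j <- j[keep]
    }
    n2 <- MtM[cbind(i, j)]
    skip <- n2 < 2
    if (any(skip)) {
        warning(sum(skip), " SNP pair(s) with fewer than 2 complete ",
                "samples skipped")
        i <- i[!skip]; j <- j[!skip]; n2 <- n2[!skip]
    }
    if (!length(i))
        return(new("AlleleNetwork", snpInfo = si, edges = .emptyEdges(),
                   nNodes = 2L * p, thresholded = FALSE,
                   targetMeanDegree = NA_real_))
    w <- .cccFromSums(n2, AtM[cbind(i, j)], AtM[cbind(j, i)],
                      AtA[cbind(i, j)])
    edges <- data.frame(
        snp_a = rep(i, 4L), allele_a = rep(c("REF", "REF", "ALT", "ALT"),
                                           each = length(i)),
        snp_b = rep(j, 4L), allele_b = rep(c("REF", "ALT", "REF", "ALT"),
                                           each = length(i)),
        weight = c(w$RR, w$RA, w$AR, w$AA),
        stringsAsFactors = FALSE)
    edges <- edges[order(edges$snp_a, edges$snp_b,
                         edges$allele_a != "REF",
                         edges$allele_b != "REF"), , drop = FALSE]
    rownames(edges) <- NULL
    new("AlleleNetwork", snpInfo = si, edges = edges, nNodes = 2L * p,
        thresholded = FALSE, targetMeanDegree = NA_real_)
}

.emptyEdges <- function() {
    data.frame(snp_a = integer(0), allele_a = character(0),
               snp_b = integer(0), allele_b = character(0),
               weight = numeric(0), stringsAsFactors = FALSE)
}

## integer node id: REF node of SNP k is 2k-1, ALT node is 2k
.nodeId <- function(snp, allele) 2L * as.integer(snp) - (allele == "REF")

#' Truncate a network to a target mean node degree
#'
#' Retains the `floor(nNodes * targetMeanDegree / 2)` highest-weight
#' edges, where the node count includes both allele nodes of every SNP
#' (singletons included), so that the overall average node degree
#' `2 |E| / |V|` equals the target when enough candidates exist. Ties at
#' the cutoff weight are broken deterministically by (weight descending,
#' first node id, second node id), making edge selection reproducible
#' bit-for-bit.
#'
#' @param net an [AlleleNetwork-class] (candidate edges).
#' @param targetMeanDegree non-negative target; default 1.0.
#' @return the thresholded [AlleleNetwork-class].
#' @export
thresholdToMeanDegree <- function(net, targetMeanDegree = 1.0) {
    stopifnot(is(net, "AlleleNetwork"), targetMeanDegree >= 0)
    k <- floor(net@nNodes * targetMeanDegree / 2)
    # a floored weight of 0 means no positive co-occurrence excess --
    # such entries are non-edges, never candidates for retention
    e <- net@edges[net@edges$weight > 0, , drop = FALSE]
    if (nrow(e) < k) {
        warning("only ", nrow(e), " candidate edges for ", k,
                " requested; retaining all")
        k <- nrow(e)
    }
    ord <- order(-e$weight, .nodeId(e$snp_a, e$allele_a),
                 .nodeId(e$snp_b, e$allele_b))
    e <- e[ord[seq_len(k)], , drop = FALSE]
    rownames(e) <- NULL
    new("AlleleNetwork", snpInfo = net@snpInfo, edges = e,
        nNodes = net@nNodes, thresholded = TRUE,
        targetMeanDegree = targetMeanDegree)
}

#' @describeIn AlleleNetwork-class the edge data.frame (`snp_a`,
#'   `allele_a`, `snp_b`, `allele_b`, `weight`).
#' @export
setMethod("networkEdges", "AlleleNetwork", function(x) x@edges)

setMethod("show", "AlleleNetwork", function(object) {
    cat("AlleleNetwork:", object@nNodes, "nodes (2 per SNP),",
        nrow(object@edges), "edges\n")
    if (object@thresholded)
        cat(sprintf("  thresholded to mean degree %.3g (actual %.3f)\n",
                    object@targetMeanDegree,
                    2 * nrow(object@edges) / max(object@nNodes, 1)))
    else cat("  candidate network (not thresholded)\n")
})

#' Export the edge list as TSV
#'
#' Writes `snp_id_a allele_a snp_id_b allele_b weight`, with alleles as
#' nucleotides.
#'
#' @param net an [AlleleNetwork-class].
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
writeEdgeList <- function(net, path) {
    e <- net@edges
    si <- net@snpInfo
    nuc <- function(snp, al)
        ifelse(al == "REF", si$ref[snp], si$alt[snp])
    out <- data.frame(snp_id_a = si$snp_id[e$snp_a],
                      allele_a = nuc(e$snp_a, e$allele_a),
                      snp_id_b = si$snp_id[e$snp_b],
                      allele_b = nuc(e$snp_b, e$allele_b),
                      weight = e$weight)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
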