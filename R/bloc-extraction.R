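#' Connected components of an allele network
#'
#' Breadth-first search over the (undirected) edge set, partitioning all
#' `2 * nSnps` allele nodes into maximal connected sets. Components are
#' reported in deterministic order (by smallest member node id);
#' isolated nodes are reported separately as singletons. The result is
#' independent of edge insertion order.
#'
#' @param net an [AlleleNetwork-class] (normally thresholded).
#' @return a list with `components` (list of sorted integer node-id
#'   vectors, each of size >= 2) and `singletons` (integer node ids).
#'   Node id `2k-1` is the REF node of SNP `k`, `2k` its ALT node; see
#'   [decodeNodes()].
#' @export
connectedComponents <- function(net) {
    stopifnot(is(net, "AlleleNetwork"))
    nv <- net@nNodes
    e <- net@edges
    a <- .nodeId(e$snp_a, e$allele_a)
    b <- .nodeId(e$snp_b, e$allele_b)
    # adjacency as sorted-by-node edge endpoints
    deg <- tabulate(c(a, b), nbins = nv)
    adj <- vector("list", nv)
    if (length(a)) {
        ends <- c(b, a)
        idx <- order(c(a, b))
        ends <- ends[idx]
        starts <- cumsum(c(1L, deg))
        for (v in which(deg > 0))
            adj[[v]] <- ends[starts[v]:(starts[v + 1L] - 1L)]
    }
    comp <- integer(nv)
    nc <- 0L
    for (s in seq_len(nv)) {
        if (comp[s] != 0L) next
        nc <- nc + 1L
        comp[s] <- nc
        queue <- s
        while (length(queue)) {
            v <- queue[1L]; queue <- queue[-1L]
            nb <- adj[[v]]
            nb <- nb[comp[nb] == 0L]
            if (length(nb)) {
                comp[nb] <- nc
                queue <- c(queue, nb)
            }
        }
    }
    parts <- split(seq_len(nv), comp)        # ordered by smallest member
    sizes <- lengths(parts)
    list(components = unname(lapply(parts[sizes >= 2], sort)),
         singletons = sort(unlist(parts[sizes == 1], use.names = FALSE)))
}

#' Decode integer node ids into SNP/allele rows
#'
#' @param net an [AlleleNetwork-class].
#' @param nodes integer node ids as produced by [connectedComponents()].
#' @return data.frame with `snp` (row index), `snp_id`, `allele`
#'   (`REF`/`ALT`) and `nucleotide`.
#' @export
decodeNodes <- function(net, nodes) {
    snp <- (nodes + 1L) %/% 2L
    allele <- ifelse(nodes %% 2L == 1L, "REF", "ALT")
    si <- net@snpInfo
    data.frame(snp = snp, snp_id = si$snp_id[snp], allele = allele,
               nucleotide = ifelse(allele == "REF", si$ref[snp],
                                   si$alt[snp]),
               stringsAsFactors = FALSE)
}

#' Convert network components to blocs
#'
#' Each connected component with at least `minSize` nodes becomes one
#' [Bloc-class] (a genetic pattern: one designated allele per member
#' SNP, in genomic order). The default `minSize = 11` implements a
#' strict "more than 10 nodes" screen. If a component contains both
#' allele nodes of one SNP, the allele with the higher summed incident
#' edge weight within the component is kept (tie: REF) and the bloc is
#' flagged `multiAllelic`; the component's full node count is preserved
#' in `sourceComponentSize`.
#'
#' @param components result of [connectedComponents()] (or its
#'   `components` element).
#' @param net the [AlleleNetwork-class] the components came from.
#' @param minSize minimum component node count (>= 2); default 11.
#' @return list of [Bloc-class] objects, ids `bloc001`, `bloc002`, ...
#'   numbered over *all* components of sufficient size in component
#'   order.
#' @export
componentsToBlocs <- function(components, net, minSize = 11L) {
    stopifnot(minSize >= 2)
    if (is.list(components) && !is.null(components$components))
        components <- components$components
    e <- net@edges
    ea <- .nodeId(e$snp_a, e$allele_a)
    eb <- .nodeId(e$snp_b, e$allele_b)
    keep <- Filter(function(x) length(x) >= minSize, components)
    blocs <- vector("list", length(keep))
    for (k in seq_along(keep)) {
        nodes <- keep[[k]]
        dec <- decodeNodes(net, nodes)
        if (anyDuplicated(dec$snp)) {
            w <- numeric(length(nodes))
            for (t in seq_along(nodes)) {
                n <- nodes[t]
                w[t] <- sum(e$weight[ea == n | eb == n])
            }
            # keep the heavier allele per SNP; tie -> REF (lower node id)
            ord <- order(dec$snp, -w, nodes)
            dec <- dec[ord, , drop = FALSE]
            dec <- dec[!duplicated(dec$snp), , drop = FALSE]
            multi <- TRUE
        } else multi <- FALSE
        si <- net@snpInfo
        blocs[[k]] <- Bloc(
            id = sprintf("bloc%03d", k),
            members = data.frame(snp_id = dec$snp_id,
                                 allele = dec$nucleotide,
                                 chrom = si$chrom[dec$snp],
                                 pos = si$pos[dec$snp],
                                 stringsAsFactors = FALSE),
            sourceComponentSize = length(nodes),
            multiAllelic = multi)
    }
    blocs
}

#' Extract blocs from a thresholded network
#'
#' Convenience wrapper: [connectedComponents()] then
#' [componentsToBlocs()].
#'
#' @inheritParams componentsToBlocs
#' @export
extractBlocs <- function(net, minSize = 11L)
    componentsToBlocs(connectedComponents(net), net, minSize)

#' Summary statistics of an allele network
#'
#' @param net an [AlleleNetwork-class].
#' @return data.frame with `n_nodes`, `n_edges`, `singleton_fraction`
#'   and the min/max connected-component sizes (`NA` when every node is
#'   a singleton).
#' @export
summarizeNetwork <- function(net) {
    cc <- connectedComponents(net)
    sizes <- lengths(cc$components)
    data.frame(
        n_nodes = net@nNodes,
        n_edges = nrow(net@edges),
        singleton_fraction = length(cc$singletons) / max(net@nNodes, 1L),
        component_size_min = if (length(sizes)) min(sizes) else NA_integer_,
        component_size_max = if (length(sizes)) max(sizes) else NA_integer_)
}

#' @describeIn Bloc number of member SNPs.
#' @export
setMethod("blocSize", "Bloc", function(x) nrow(x@members))

#' @describeIn Bloc the member data.frame (`snp_id`, `allele`, `chrom`,
#'   `pos`), in genomic order.
#' @export
setMethod("blocMembers", "Bloc", function(x) x@members)

setMethod("show", "Bloc", function(object) {
    cat("Bloc", object@id, ":", nrow(object@members), "SNP alleles",
        if (object@multiAllelic) "(multi-allelic component, flagged)" else "",
        "\n")
    m <- object@members
    cat("  ", paste0(utils::head(m$snp_id, 4), "/",
                     utils::head(m$allele, 4), collapse = " "),
        if (nrow(m) > 4) "..." else "", "\n")
})

#' Write blocs to a TSV file
#'
#' One row per member: `bloc_id snp_id allele chrom pos`. This format is
#' also the input for the association and population stages.
#'
#' @param blocs a [Bloc-class] or list of them.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeBlocTable <- function(blocs, path) {
    if (is(blocs, "Bloc")) blocs <- list(blocs)
    rows <- do.call(rbind, lapply(blocs, function(b)
        cbind(bloc_id = b@id, b@members)))
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read blocs from a TSV file written by [writeBlocTable()]
#'
#' @param path TSV path with header
#'   `bloc_id snp_id allele chrom pos`.
#' @return named list of [Bloc-class] objects.
#' @export
readBlocTable <- function(path) {
    x <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "character",
                                          "character", "character",
                                          "integer"))
    out <- lapply(split(x, x$bloc_id), function(d)
        Bloc(d$bloc_id[1], d[, c("snp_id", "allele", "chrom", "pos")]))
    out[order(names(out))]
}
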