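#' Exclusive-region counts across 2-5 gene sets
#'
#' Enumerates all \code{2^m - 1} exclusive Venn regions and the full m-way
#' intersection membership.  Region counts sum to the size of the union.
#'
#' @param named_sets named list of 2-5 character vectors.
#' @return A list with \code{regions} (data.frame \code{region},
#'   \code{count}, where a region label like \code{"A&B"} means genes in
#'   exactly those sets) and \code{intersection} (members of the full
#'   m-way intersection).
#' @examples
#' intersectGeneSets(list(X = c("a", "b", "c"), Y = c("b", "c"), Z = "c"))
#' @export
intersectGeneSets <- function(named_sets) {
    m <- length(named_sets)
    if (m < 2 || m > 5)
        stop("parameter error: need between 2 and 5 sets")
    if (is.null(names(named_sets)) || anyDuplicated(names(named_sets)))
        stop("sets must be uniquely named")
    sets <- lapply(named_sets, function(g) unique(toupper(g)))
    universe <- sort(unique(unlist(sets)))
    memb <- vapply(sets, function(g) universe %in% g, logical(length(universe)))
    if (length(universe) == 1) memb <- matrix(memb, nrow = 1)
    patterns <- expand.grid(rep(list(c(FALSE, TRUE)), m))[-1, , drop = FALSE]
    names(patterns) <- names(sets)
    regions <- do.call(rbind, lapply(seq_len(nrow(patterns)), function(i) {
        pat <- unlist(patterns[i, ])
        inRegion <- rowSums(memb == matrix(pat, length(universe), m,
                                           byrow = TRUE)) == m
        data.frame(region = paste(names(sets)[pat], collapse = "&"),
                   count = sum(inRegion), stringsAsFactors = FALSE)
    }))
    rownames(regions) <- NULL
    full <- universe[rowSums(memb) == m]
    list(regions = regions, intersection = full)
}

#' Assemble a flow-profile matrix over multiple contexts
#'
#' Rows are genes (the union over contexts), columns are contexts, values
#' are node throughput in supply units; gene-context pairs absent from a
#' network are imputed 0 (a gene filtered out of one context genuinely
#' carries no flow there).
#'
#' @param solutions named list of \linkS4class{FlowSolution} objects.
#' @return Numeric matrix, genes x contexts, no missing cells.
#' @export
flowProfileMatrix <- function(solutions) {
    if (is.null(names(solutions)) || anyDuplicated(names(solutions)))
        stop("solutions must be uniquely named")
    genes <- sort(unique(unlist(lapply(solutions, function(s)
        names(s@nodeThroughput)))))
    out <- vapply(solutions, function(s) .flowOn(s, genes),
                  numeric(length(genes)))
    if (length(genes) == 1)
        out <- matrix(out, 1, dimnames = list(genes, names(solutions)))
    out
}

#' Average-linkage (UPGMA) clustering of a flow-profile matrix
#'
#' Euclidean distances and average-linkage agglomeration via
#' \code{stats::hclust}; items are ordered by label first so the result is
#' permutation-invariant, and merge heights are non-decreasing.  The
#' dendrogram is returned both as a merge table and as Newick text (via
#' ape, branch lengths from merge heights).
#'
#' @param mat numeric matrix (e.g. from \code{\link{flowProfileMatrix}}).
#' @param axis \code{"rows"} (default) or \code{"columns"}.
#' @return A list with \code{merge}, \code{height}, \code{order},
#'   \code{labels}, \code{newick} and the \code{hclust} object.
#' @export
upgmaCluster <- function(mat, axis = c("rows", "columns")) {
    axis <- match.arg(axis)
    m <- if (axis == "columns") t(mat) else mat
    if (nrow(m) < 2)
        stop("parameter error: need >= 2 items on the chosen axis")
    if (is.null(rownames(m))) rownames(m) <- paste0("item", seq_len(nrow(m)))
    m <- m[order(rownames(m)), , drop = FALSE]
    hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                        method = "average")
    list(merge = hc$merge, height = hc$height, order = hc$order,
         labels = hc$labels, newick = ape::write.tree(ape::as.phylo(hc)),
         hclust = hc)
}
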