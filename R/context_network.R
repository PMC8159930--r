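#' Co-expression weights for interactome edges
#'
#' For each interactome edge with both endpoints measured, the weight is
#' the absolute Pearson correlation of the two genes over the matrix's
#' samples.  Edges with a missing endpoint are dropped (count attached as
#' attribute \code{"dropped_missing"}); zero-variance genes give weight 0
#' with a warning rather than an error, since constant genes are common in
#' subsetted data.
#'
#' @param expr an \linkS4class{ExpressionMatrix} with >= 3 samples.
#' @param interactome an \linkS4class{Interactome}.
#' @return data.frame \code{from}, \code{to}, \code{w} with \code{w} in
#'   [0, 1].
#' @export
edgeCoexpression <- function(expr, interactome) {
    if (ncol(expr) < 3) stop("need >= 3 samples for co-expression")
    e <- interactomeEdges(interactome)
    measured <- geneIds(expr)
    keep <- e$from %in% measured & e$to %in% measured
    dropped <- sum(!keep)
    e <- e[keep, , drop = FALSE]
    v <- exprValues(expr)
    n <- ncol(v)
    sds <- apply(v, 1, stats::sd)
    zeroVar <- rownames(v)[sds == 0]
    touched <- unique(c(e$from, e$to))
    if (length(intersect(zeroVar, touched)))
        warning("zero-variance gene(s) on ",
                sum(e$from %in% zeroVar | e$to %in% zeroVar),
                " edge(s); their weights are 0")
    z <- v - rowMeans(v)
    safe <- ifelse(sds == 0, 1, sds)
    z <- z / safe
    w <- if (nrow(e)) {
        r <- rowSums(z[e$from, , drop = FALSE] * z[e$to, , drop = FALSE]) /
            (n - 1)
        r[e$from %in% zeroVar | e$to %in% zeroVar] <- 0
        pmin(abs(unname(r)), 1)
    } else numeric(0)
    out <- data.frame(from = e$from, to = e$to, w = w,
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    attr(out, "dropped_missing") <- dropped
    out
}

#' Retain edges at or above a correlation threshold
#'
#' The boundary is inclusive: an edge with \code{w} exactly equal to
#' \code{corThreshold} is retained.
#'
#' @param weighted_edges data.frame \code{from}, \code{to}, \code{w}.
#' @param corThreshold minimum weight in [0, 1] (default 0.5).
#' @return The retained subset, with attributes \code{"retained"} and
#'   \code{"dropped"} counts.
#' @export
applyCorThreshold <- function(weighted_edges, corThreshold = 0.5) {
    stopifnot(all(weighted_edges$w >= 0), all(weighted_edges$w <= 1))
    keep <- weighted_edges$w >= corThreshold
    out <- weighted_edges[keep, , drop = FALSE]
    rownames(out) <- NULL
    if (nrow(out) == 0) warning("no edge passed corThreshold = ", corThreshold)
    attr(out, "retained") <- sum(keep)
    attr(out, "dropped") <- sum(!keep)
    out
}

#' Functional neighborhood of a set of source genes
#'
#' For each source the absolute Pearson correlation with every other
#' measured gene is computed; genes at or above the \code{snf} empirical
#' quantile (type 1, lower) of that source's |r| distribution are kept.
#' The result is the union over sources, plus the sources themselves.
#' Raising \code{snf} never adds genes (nestedness).
#'
#' @param expr an \linkS4class{ExpressionMatrix}.
#' @param sources non-empty character vector of measured source genes.
#' @param snf quantile in [0, 1]; \code{snf = 0} keeps every measured gene.
#' @return Sorted character vector of neighborhood genes.
#' @export
functionalNeighborhood <- function(expr, sources, snf = 0.95) {
    if (snf < 0 || snf > 1) stop("parameter error: snf must be in [0, 1]")
    sources <- toupper(sources)
    if (!length(sources)) stop("sources must be non-empty")
    miss <- setdiff(sources, geneIds(expr))
    if (length(miss))
        stop("source gene(s) not measured: ", paste(miss, collapse = ", "))
    v <- exprValues(expr)
    kept <- character(0)
    for (s in sort(sources)) {
        others <- setdiff(rownames(v), s)
        r <- abs(suppressWarnings(
            stats::cor(v[s, ], t(v[others, , drop = FALSE]))))[1, ]
        r[is.na(r)] <- 0
        cutoff <- stats::quantile(r, probs = snf, type = 1, names = FALSE)
        kept <- union(kept, others[r >= cutoff])
    }
    sort(union(sources, kept))
}

# Largest-remainder apportionment of `total` integer units proportional to
# non-negative weights; ties broken by name (ascending).
.largestRemainder <- function(weights, total) {
    if (sum(weights) == 0) weights <- rep(1, length(weights))
    quota <- weights / sum(weights) * total
    base <- floor(quota)
    left <- total - sum(base)
    if (left > 0) {
        ord <- order(-(quota - base), names(weights))
        base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
    }
    base
}

#' Build a phenotype-specific capacitated flow network
#'
#' Restricts the retained co-expression edges to the functional
#' neighborhood, drops isolated genes, and attaches the super-source and
#' super-sink arcs: source arcs carry capacities proportional to |log2FC|
#' (equal in bypass mode), apportioned by largest remainder so they sum
#' exactly to \code{supply * integerScale}; every non-source retained gene
#' receives a terminal arc with capacity
#' \code{epsilonTerminal * weightedDegree * integerScale} and cost
#' \code{terminalCost * integerScale}.  Gene-gene arcs are antiparallel
#' with capacity \code{w * integerScale} and cost
#' \code{(1 - w + costFloor) * integerScale}, so flow prefers strongly
#' co-expressed routes and no zero-cost cycles exist.
#'
#' @param retained_edges data.frame \code{from}, \code{to}, \code{w}, as
#'   from \code{\link{applyCorThreshold}}.
#' @param neighborhood character vector of genes to keep (from
#'   \code{\link{functionalNeighborhood}}), or \code{NULL} to keep all.
#' @param source_set a \linkS4class{SourceSet}.
#' @param config an \linkS4class{AnalysisConfig}.
#' @param phenotype label stored in the network.
#' @return A \linkS4class{ContextFlowNetwork}.
#' @export
buildFlowNetwork <- function(retained_edges, neighborhood, source_set, config,
                             phenotype = "") {
    e <- retained_edges
    if (!is.null(neighborhood)) {
        keep <- e$from %in% neighborhood & e$to %in% neighborhood
        e <- e[keep, , drop = FALSE]
    }
    e <- e[order(e$from, e$to), , drop = FALSE]
    rownames(e) <- NULL
    nodes <- sort(unique(c(e$from, e$to)))
    sel <- selectedSources(source_set)
    srcs <- sort(intersect(sel, nodes))
    if (!length(srcs) || nrow(e) == 0)
        stop("sources disconnected from context network (",
             length(srcs), " of ", length(sel), " sources retained)")
    droppedSrc <- setdiff(sel, srcs)
    if (length(droppedSrc))
        message(length(droppedSrc),
                " source(s) absent from the context network: ",
                paste(head(droppedSrc, 5), collapse = ", "),
                if (length(droppedSrc) > 5) ", ..." else "")
    scale <- config@integerScale
    rec <- sourceRecords(source_set)
    wts <- if (source_set@bypass || all(is.na(rec$log2FC))) {
        setNames(rep(1, length(srcs)), srcs)
    } else {
        setNames(abs(rec$log2FC[match(srcs, rec$gene)]), srcs)
    }
    sCaps <- .largestRemainder(wts, round(config@supply * scale))
    edgeCap <- round(e$w * scale)
    edgeCost <- pmax(1, round((1 - e$w + config@costFloor) * scale))
    wdeg <- vapply(nodes, function(g)
        sum(e$w[e$from == g]) + sum(e$w[e$to == g]), numeric(1))
    nonSrc <- setdiff(nodes, srcs)
    arcs <- rbind(
        data.frame(tail = e$from, head = e$to, cap = edgeCap,
                   cost = edgeCost, stringsAsFactors = FALSE),
        data.frame(tail = e$to, head = e$from, cap = edgeCap,
                   cost = edgeCost, stringsAsFactors = FALSE),
        data.frame(tail = "<S>", head = srcs, cap = unname(sCaps),
                   cost = 1, stringsAsFactors = FALSE),
        data.frame(tail = nonSrc, head = "<T>",
                   cap = round(config@epsilonTerminal * wdeg[nonSrc] * scale),
                   cost = round(config@terminalCost * scale),
                   stringsAsFactors = FALSE))
    rownames(arcs) <- NULL
    new("ContextFlowNetwork", phenotype = phenotype, nodes = nodes,
        edges = e, sourceCaps = data.frame(gene = srcs, cap = unname(sCaps),
                                           stringsAsFactors = FALSE),
        arcs = arcs, config = config)
}
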