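.flowOn <- function(sol, genes) {
    out <- setNames(rep(0, length(genes)), genes)
    hit <- intersect(genes, names(sol@nodeThroughput))
    out[hit] <- sol@nodeThroughput[hit]
    out
}

.termOn <- function(sol, genes) {
    out <- setNames(rep(0, length(genes)), genes)
    hit <- intersect(genes, names(sol@terminalFlow))
    out[hit] <- sol@terminalFlow[hit]
    out
}

.degreeOf <- function(edges, genes) {
    d <- table(factor(c(edges$from, edges$to), levels = genes))
    setNames(as.integer(d), genes)
}

.neighborsOf <- function(edges, gene) {
    sort(unique(c(edges$to[edges$from == gene], edges$from[edges$to == gene])))
}

#' Node flow differences between two phenotypes
#'
#' Genes absent from one phenotype's network get flow 0 there; the table is
#' sorted by |flow_diff| descending with a deterministic tie-break by gene
#' symbol.  Swapping the phenotypes negates every difference and leaves the
#' ranking unchanged.
#'
#' @param solA,solB \linkS4class{FlowSolution} objects for phenotypes A
#'   and B.
#' @return data.frame \code{gene}, \code{flow_A}, \code{flow_B},
#'   \code{flow_diff} (\code{flow_B - flow_A}).
#' @export
nodeFlowDifference <- function(solA, solB) {
    genes <- sort(union(names(solA@nodeThroughput),
                        names(solB@nodeThroughput)))
    fa <- .flowOn(solA, genes); fb <- .flowOn(solB, genes)
    out <- data.frame(gene = genes, flow_A = unname(fa), flow_B = unname(fb),
                      flow_diff = unname(fb - fa), stringsAsFactors = FALSE)
    out <- out[order(-abs(out$flow_diff), out$gene), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Classify genes as sources, routers or targets
#'
#' Sources are selected source genes with nonzero throughput in either
#' phenotype; targets are non-source genes whose terminal flow reaches
#' \code{targetFraction * supply} in either phenotype; routers are the
#' remaining genes with nonzero throughput.  Role precedence is
#' source > target > router, so each gene gets exactly one role; genes with
#' zero throughput in both phenotypes are excluded.
#'
#' @param solA,solB \linkS4class{FlowSolution} objects.
#' @param source_set the \linkS4class{SourceSet} used to build the
#'   networks.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return data.frame \code{gene}, \code{role}, \code{flow_A},
#'   \code{flow_B}, \code{flow_diff}, \code{degree_A}, \code{degree_B},
#'   \code{impact}, sorted by role then |flow_diff| descending.
#' @export
classifyRoles <- function(solA, solB, source_set, config = AnalysisConfig()) {
    genes <- sort(union(names(solA@nodeThroughput),
                        names(solB@nodeThroughput)))
    fa <- .flowOn(solA, genes); fb <- .flowOn(solB, genes)
    ta <- .termOn(solA, genes); tb <- .termOn(solB, genes)
    active <- fa > 0 | fb > 0
    sel <- selectedSources(source_set)
    tau <- config@targetFraction * config@supply
    role <- ifelse(genes %in% sel & active, "source",
            ifelse((ta >= tau | tb >= tau) & active, "target",
            ifelse(active, "router", NA_character_)))
    keep <- !is.na(role)
    genes <- genes[keep]; role <- role[keep]
    fa <- fa[keep]; fb <- fb[keep]
    degA <- .degreeOf(solA@edges, genes)
    degB <- .degreeOf(solB@edges, genes)
    imp <- impactScore(solA, solB, genes)
    out <- data.frame(gene = genes, role = role, flow_A = unname(fa),
                      flow_B = unname(fb), flow_diff = unname(fb - fa),
                      degree_A = unname(degA), degree_B = unname(degB),
                      impact = unname(imp), stringsAsFactors = FALSE)
    out <- out[order(match(out$role, c("source", "router", "target")),
                     -abs(out$flow_diff), out$gene), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Network-rewiring impact score
#'
#' The mean of three components in [0, 1]: (i) degree shift
#' \code{|dB - dA| / max(dA, dB, 1)}; (ii) neighbor turnover
#' \code{1 - Jaccard(N_A, N_B)} (0 when both neighborhoods are empty);
#' (iii) flow shift \code{|flow_diff|} normalized by the maximum
#' |flow_diff| over all genes in the comparison.  A gene with identical
#' neighborhoods and flows in both phenotypes scores 0; phenotype swap
#' leaves the score unchanged.
#'
#' @param solA,solB \linkS4class{FlowSolution} objects (each carries its
#'   network's retained edges).
#' @param genes genes to score; each must appear in at least one network.
#' @return Named numeric vector of impact scores in [0, 1].
#' @export
impactScore <- function(solA, solB, genes) {
    universe <- sort(union(names(solA@nodeThroughput),
                           names(solB@nodeThroughput)))
    miss <- setdiff(genes, universe)
    if (length(miss))
        stop("gene(s) absent from both networks: ",
             paste(miss, collapse = ", "))
    fa <- .flowOn(solA, universe); fb <- .flowOn(solB, universe)
    maxDiff <- max(abs(fb - fa))
    vapply(genes, function(g) {
        nA <- .neighborsOf(solA@edges, g)
        nB <- .neighborsOf(solB@edges, g)
        dA <- length(nA); dB <- length(nB)
        degComp <- abs(dB - dA) / max(dA, dB, 1)
        uni <- length(union(nA, nB))
        turnComp <- if (uni == 0) 0 else 1 - length(intersect(nA, nB)) / uni
        flowComp <- if (maxDiff == 0) 0 else
            abs(fb[[g]] - fa[[g]]) / maxDiff
        (degComp + turnComp + flowComp) / 3
    }, numeric(1))
}

#' Key-edge detection across phenotypes
#'
#' For every retained edge carrying flow in either phenotype, the
#' cross-phenotype total-edge-flow ratio is computed with the smaller flow
#' floored at \code{1 / integerScale}; an edge is \emph{key} when the ratio
#' reaches \code{ratioThreshold} (inclusive) or the flow is exclusive to
#' one phenotype.
#'
#' @param solA,solB \linkS4class{FlowSolution} objects.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return data.frame \code{from}, \code{to}, \code{total_flow_A},
#'   \code{total_flow_B}, \code{ratio}, \code{exclusive} (\code{"A"},
#'   \code{"B"} or \code{"none"}), \code{key}, sorted by
#'   \code{max(total_flow_A, total_flow_B)} descending.
#' @export
keyEdges <- function(solA, solB, config = AnalysisConfig()) {
    ea <- solA@totalEdgeFlow; eb <- solB@totalEdgeFlow
    keyA <- paste(ea$from, ea$to); keyB <- paste(eb$from, eb$to)
    allKey <- sort(union(keyA, keyB))
    fA <- setNames(rep(0, length(allKey)), allKey)
    fB <- fA
    fA[keyA] <- ea$flow; fB[keyB] <- eb$flow
    nz <- fA > 0 | fB > 0
    allKey <- allKey[nz]; fA <- fA[nz]; fB <- fB[nz]
    parts <- strsplit(allKey, " ", fixed = TRUE)
    hi <- pmax(fA, fB); lo <- pmin(fA, fB)
    ratio <- hi / pmax(lo, 1 / config@integerScale)
    exclusive <- ifelse(fA > 0 & fB == 0, "A",
                 ifelse(fB > 0 & fA == 0, "B", "none"))
    out <- data.frame(from = vapply(parts, `[`, character(1), 1L),
                      to = vapply(parts, `[`, character(1), 2L),
                      total_flow_A = unname(fA), total_flow_B = unname(fB),
                      ratio = unname(ratio), exclusive = unname(exclusive),
                      key = unname(ratio >= config@ratioThreshold |
                                   exclusive != "none"),
                      stringsAsFactors = FALSE)
    out <- out[order(-pmax(out$total_flow_A, out$total_flow_B), out$from,
                     out$to), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Edges whose flow dominates in phenotype B
#'
#' Convenience filter of \code{\link{keyEdges}} records to edges with
#' \code{total_flow_B > total_flow_A}.
#'
#' @param edge_records output of \code{\link{keyEdges}}.
#' @return The filtered subset.
#' @export
dominantInB <- function(edge_records) {
    out <- edge_records[edge_records$total_flow_B >
                        edge_records$total_flow_A, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Extract the prioritized phenotype-contrast subnetwork
#'
#' Member genes are the active sources, all targets, the top
#' \code{topKRouters} routers by |flow_diff| (ties by symbol), and the
#' endpoints of key edges.  Member edges are the key edges plus retained
#' edges among members carrying nonzero flow in either phenotype.
#'
#' @param roles output of \code{\link{classifyRoles}} (non-empty).
#' @param edge_records output of \code{\link{keyEdges}}.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return A \linkS4class{PrioritizedSubnetwork}.
#' @export
prioritizedSubnetwork <- function(roles, edge_records,
                                  config = AnalysisConfig()) {
    if (nrow(roles) == 0) stop("roles must be non-empty")
    routers <- roles[roles$role == "router", , drop = FALSE]
    routers <- routers[order(-abs(routers$flow_diff), routers$gene), ,
                       drop = FALSE]
    topR <- head(routers$gene, config@topKRouters)
    keyE <- edge_records[edge_records$key, , drop = FALSE]
    members <- sort(unique(c(roles$gene[roles$role == "source"],
                             roles$gene[roles$role == "target"], topR,
                             keyE$from, keyE$to)))
    nodes <- roles[roles$gene %in% members, , drop = FALSE]
    induced <- edge_records$from %in% members & edge_records$to %in% members
    edges <- edge_records[edge_records$key | induced, , drop = FALSE]
    # endpoints of key edges are members by construction; restrict anyway
    edges <- edges[edges$from %in% nodes$gene & edges$to %in% nodes$gene, ,
                   drop = FALSE]
    rownames(nodes) <- rownames(edges) <- NULL
    counts <- table(factor(nodes$role, levels = c("source", "router",
                                                  "target")))
    new("PrioritizedSubnetwork", nodes = nodes, edges = edges,
        counts = setNames(as.integer(counts), names(counts)))
}

#' First-neighbor motif view of a gene in one phenotype
#'
#' @param solution the phenotype's \linkS4class{FlowSolution}.
#' @param gene a gene present in that phenotype's network.
#' @return A \linkS4class{MotifView} with incident retained edges, their
#'   weights and total edge flows, and the center's degree.
#' @export
extractMotif <- function(solution, gene) {
    gene <- toupper(gene)
    if (!gene %in% names(solution@nodeThroughput))
        stop("gene '", gene, "' not present in the ", solution@phenotype,
             " network")
    e <- solution@edges
    inc <- e$from == gene | e$to == gene
    ed <- e[inc, , drop = FALSE]
    tef <- solution@totalEdgeFlow
    fl <- tef$flow[match(paste(ed$from, ed$to), paste(tef$from, tef$to))]
    out <- data.frame(from = ed$from, to = ed$to, w = ed$w, flow = fl,
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    new("MotifView", center = gene, phenotype = solution@phenotype,
        edges = out, degree = nrow(out))
}
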