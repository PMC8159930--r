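# Exact integer minimum-cost maximum-flow by successive shortest augmenting
# paths with node potentials (Dijkstra on reduced costs).  All capacities
# and costs are integers well below 2^53, so double arithmetic is exact.
# Arc scan order and the smallest-index tie rule make the returned arc
# flows deterministic; only the objective is contractually unique.
.mcmf <- function(nNodes, tail, head, cap, cost, s, t) {
    m <- length(tail)
    to <- c(head, tail)
    res <- c(cap, rep(0, m))
    cst <- c(cost, -cost)
    adj <- split(seq_len(2 * m), factor(c(tail, head), levels = seq_len(nNodes)))
    pot <- numeric(nNodes)
    INF <- Inf
    repeat {
        dist <- rep(INF, nNodes)
        prevArc <- integer(nNodes)
        done <- logical(nNodes)
        dist[s] <- 0
        repeat {
            cand <- dist
            cand[done] <- INF
            u <- which.min(cand)    # smallest index on ties: deterministic
            if (!is.finite(cand[u])) break
            done[u] <- TRUE
            if (u == t) next
            for (a in adj[[u]]) {
                if (res[a] <= 0) next
                v <- to[a]
                nd <- dist[u] + cst[a] + pot[u] - pot[v]
                if (nd < dist[v]) { dist[v] <- nd; prevArc[v] <- a }
            }
        }
        if (!is.finite(dist[t])) break
        pot <- pot + ifelse(is.finite(dist), dist, 0)
        # bottleneck along the shortest path
        push <- INF
        v <- t
        while (v != s) {
            a <- prevArc[v]
            push <- min(push, res[a])
            v <- if (a <= m) tail[a] else to[a - m]
        }
        v <- t
        while (v != s) {
            a <- prevArc[v]
            res[a] <- res[a] - push
            rev <- if (a <= m) a + m else a - m
            res[rev] <- res[rev] + push
            v <- if (a <= m) tail[a] else to[a - m]
        }
    }
    flow <- cap - res[seq_len(m)]
    list(flow = flow, objective = sum(flow * cost))
}

#' Solve the minimum-cost maximum-flow problem on a context network
#'
#' Maximizes the flow delivered from the super-source to the super-sink,
#' then minimizes total cost among maximum flows, over exact integer flows.
#' When no source-to-sink path exists the solution has \code{delivered = 0}
#' and a warning is raised (not an error).
#'
#' @param network a \linkS4class{ContextFlowNetwork}.
#' @return A \linkS4class{FlowSolution}.
#' @export
solveMinCostFlow <- function(network) {
    validObject(network)
    a <- network@arcs
    labels <- c(network@nodes, "<S>", "<T>")
    idx <- setNames(seq_along(labels), labels)
    sol <- .mcmf(length(labels), unname(idx[a$tail]), unname(idx[a$head]),
                 a$cap, a$cost, idx[["<S>"]], idx[["<T>"]])
    scale <- network@config@integerScale
    flow <- sol$flow
    delivered <- sum(flow[a$head == "<T>"]) / scale
    if (delivered == 0)
        warning("no flow could be delivered from <S> to <T>")
    pos <- flow > 0
    arcFlows <- data.frame(tail = a$tail[pos], head = a$head[pos],
                           flow = flow[pos], stringsAsFactors = FALSE)
    inflow <- tapply(flow, a$head, sum)
    thr <- setNames(rep(0, length(network@nodes)), network@nodes)
    hit <- intersect(names(inflow), network@nodes)
    thr[hit] <- inflow[hit] / scale
    term <- setNames(rep(0, length(network@nodes)), network@nodes)
    tArc <- a$head == "<T>"
    term[a$tail[tArc]] <- flow[tArc] / scale
    e <- network@edges
    fwdKey <- paste(a$tail, a$head)
    f1 <- flow[match(paste(e$from, e$to), fwdKey)]
    f2 <- flow[match(paste(e$to, e$from), fwdKey)]
    tef <- data.frame(from = e$from, to = e$to,
                      flow = (f1 + f2) / scale, stringsAsFactors = FALSE)
    new("FlowSolution", phenotype = network@phenotype, arcFlows = arcFlows,
        nodeThroughput = thr, terminalFlow = term, totalEdgeFlow = tef,
        edges = e, objective = sol$objective / scale^2,
        delivered = delivered, supply = network@config@supply,
        integerScale = scale)
}

#' Summarize a flow solution into ranked tables
#'
#' @param solution a \linkS4class{FlowSolution}.
#' @return A list of data.frames \code{node_throughput},
#'   \code{terminal_flow} and \code{total_edge_flow}, each restricted to
#'   nonzero values, sorted descending (ties broken by name), in supply
#'   units.
#' @export
summarizeFlows <- function(solution) {
    thr <- solution@nodeThroughput
    thr <- thr[thr > 0]
    nodeTab <- data.frame(gene = names(thr), flow = unname(thr),
                          stringsAsFactors = FALSE)
    nodeTab <- nodeTab[order(-nodeTab$flow, nodeTab$gene), , drop = FALSE]
    term <- solution@terminalFlow
    term <- term[term > 0]
    termTab <- data.frame(gene = names(term), flow = unname(term),
                          stringsAsFactors = FALSE)
    termTab <- termTab[order(-termTab$flow, termTab$gene), , drop = FALSE]
    tef <- solution@totalEdgeFlow
    tef <- tef[tef$flow > 0, , drop = FALSE]
    tef <- tef[order(-tef$flow, tef$from, tef$to), , drop = FALSE]
    rownames(nodeTab) <- rownames(termTab) <- rownames(tef) <- NULL
    list(node_throughput = nodeTab, terminal_flow = termTab,
         total_edge_flow = tef)
}
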