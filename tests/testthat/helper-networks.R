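# Hand-constructed flow networks and an exhaustive enumeration oracle.
# Toy networks use integerScale = 100 and small arc capacities so that the
# oracle can enumerate every acyclic integral flow.

# Build a ContextFlowNetwork directly from an arc table.  `edges` must list
# each undirected gene pair once; both antiparallel arcs must appear in
# `arcs` (capacity 0 allowed).
makeArcNetwork <- function(edges, arcs, scale = 100, phenotype = "toy") {
    sArcs <- arcs[arcs$tail == "<S>", , drop = FALSE]
    supply <- sum(sArcs$cap) / scale
    cfg <- AnalysisConfig(supply = supply, integerScale = scale)
    nodes <- sort(unique(c(edges$from, edges$to)))
    new("ContextFlowNetwork", phenotype = phenotype, nodes = nodes,
        edges = edges,
        sourceCaps = data.frame(gene = sArcs$head, cap = sArcs$cap,
                                stringsAsFactors = FALSE),
        arcs = arcs, config = cfg)
}

# Convenience: linear chain <S> -> g1 -> ... -> gk -> <T> with given caps.
chainNetwork <- function(caps, costs = NULL, scale = 1e4) {
    k <- length(caps) - 1
    stopifnot(k >= 2)
    genes <- paste0("G", seq_len(k))
    if (is.null(costs)) costs <- rep(7, length(caps))
    edges <- data.frame(from = genes[-k], to = genes[-1], w = 1,
                        stringsAsFactors = FALSE)
    inner <- data.frame(tail = genes[-k], head = genes[-1],
                        cap = caps[2:(k)], cost = costs[2:(k)],
                        stringsAsFactors = FALSE)
    back <- data.frame(tail = genes[-1], head = genes[-k],
                       cap = 0, cost = costs[2:(k)],
                       stringsAsFactors = FALSE)
    arcs <- rbind(
        data.frame(tail = "<S>", head = genes[1], cap = caps[1],
                   cost = costs[1], stringsAsFactors = FALSE),
        inner, back,
        data.frame(tail = genes[k], head = "<T>", cap = caps[length(caps)],
                   cost = costs[length(costs)], stringsAsFactors = FALSE))
    makeArcNetwork(edges, arcs, scale = scale)
}

# Random small instance: <= 6 gene nodes, small caps, both antiparallel
# arcs per edge; regenerated until the simple-path count is oracle-sized.
randomToyNetwork <- function(seed) {
    set.seed(seed)
    repeat {
        k <- sample(3:6, 1)
        genes <- paste0("G", seq_len(k))
        pairs <- t(combn(genes, 2))
        pick <- sample(nrow(pairs), min(nrow(pairs), sample(k:(k + 2), 1)))
        edges <- data.frame(from = pairs[pick, 1], to = pairs[pick, 2],
                            w = round(runif(length(pick), 0.5, 1), 2),
                            stringsAsFactors = FALSE)
        edges <- edges[order(edges$from, edges$to), , drop = FALSE]
        fwd <- data.frame(tail = edges$from, head = edges$to,
                          cap = sample(0:4, nrow(edges), TRUE),
                          cost = sample(1:9, nrow(edges), TRUE),
                          stringsAsFactors = FALSE)
        bwd <- data.frame(tail = edges$to, head = edges$from,
                          cap = sample(0:4, nrow(edges), TRUE),
                          cost = sample(1:9, nrow(edges), TRUE),
                          stringsAsFactors = FALSE)
        nsrc <- sample(1:2, 1)
        srcs <- sample(genes, nsrc <- nsrc)
        nterm <- sample(1:3, 1)
        terms <- sample(setdiff(genes, srcs), min(nterm, k - nsrc))
        if (!length(terms)) next
        arcs <- rbind(fwd, bwd,
            data.frame(tail = "<S>", head = sort(srcs),
                       cap = sample(1:6, length(srcs), TRUE),
                       cost = sample(1:3, length(srcs), TRUE),
                       stringsAsFactors = FALSE),
            data.frame(tail = sort(terms), head = "<T>",
                       cap = sample(1:4, length(terms), TRUE),
                       cost = sample(5:15, length(terms), TRUE),
                       stringsAsFactors = FALSE))
        net <- makeArcNetwork(edges, arcs)
        paths <- enumerateSimplePaths(arcs)
        if (length(paths) >= 1 && length(paths) <= 7) return(net)
    }
}

# All simple <S> -> <T> paths as integer arc-index vectors.
enumerateSimplePaths <- function(arcs) {
    res <- list()
    recurse <- function(node, visited, arcIdx) {
        if (node == "<T>") {
            res[[length(res) + 1]] <<- arcIdx
            return(invisible())
        }
        out <- which(arcs$tail == node & arcs$cap > 0)
        for (a in out) {
            nxt <- arcs$head[a]
            if (nxt %in% visited) next
            recurse(nxt, c(visited, nxt), c(arcIdx, a))
        }
    }
    recurse("<S>", c("<S>"), integer(0))
    res
}

# Exhaustive oracle: every acyclic integral flow decomposes into simple
# <S> -> <T> paths with integer amounts, and (with strictly positive costs)
# some optimal flow is acyclic; so searching all path-amount combinations
# subject to joint arc capacities finds the exact maximum delivered flow
# and, among maximum flows, the exact minimum cost.
oracleMinCostMaxFlow <- function(network) {
    arcs <- network@arcs
    paths <- enumerateSimplePaths(arcs)
    best <- list(delivered = 0, cost = 0)
    usage <- rep(0L, nrow(arcs))
    recurse <- function(i, delivered, cost) {
        if (i > length(paths)) {
            if (delivered > best$delivered ||
                (delivered == best$delivered && cost < best$cost))
                best <<- list(delivered = delivered, cost = cost)
            return(invisible())
        }
        p <- paths[[i]]
        maxf <- min(arcs$cap[p] - usage[p])
        pcost <- sum(arcs$cost[p])
        for (f in 0:max(maxf, 0)) {
            usage[p] <<- usage[p] + f
            if (all(usage[p] <= arcs$cap[p]))
                recurse(i + 1, delivered + f, cost + f * pcost)
            usage[p] <<- usage[p] - f
        }
    }
    recurse(1, 0, 0)
    list(delivered = best$delivered / network@config@integerScale,
         objective = best$cost / network@config@integerScale^2)
}

# Exact integer conservation check at every gene node of a solution.
conservationViolations <- function(network, solution) {
    a <- network@arcs
    flow <- setNames(rep(0, nrow(a)), paste(a$tail, a$head))
    af <- solution@arcFlows
    if (nrow(af)) flow[paste(af$tail, af$head)] <- af$flow
    bad <- character(0)
    for (g in network@nodes) {
        inn <- sum(flow[a$head == g])
        out <- sum(flow[a$tail == g])
        if (inn != out) bad <- c(bad, g)
    }
    bad
}
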