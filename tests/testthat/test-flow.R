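test_that("chain networks route the bottleneck flow exactly", {
    net <- chainNetwork(caps = c(1e4, 1e4, 1e3))
    sol <- solveMinCostFlow(net)
    expect_equal(deliveredFlow(sol), 0.1)          # 1e3 / 1e4 supply units
    af <- sol@arcFlows
    expect_true(all(af$flow == 1e3))
    expect_equal(unname(nodeThroughput(sol)[c("G1", "G2")]), c(0.1, 0.1))
    expect_equal(unname(terminalFlow(sol)["G2"]), 0.1)
})

test_that("the diamond instance prefers the cheap branch and matches the oracle", {
    # S -> a; a-b (w = 0.9) and a-c (w = 0.5); b-d, c-d (w = 0.9); only d
    # exits.  The b branch is cheaper (cost ~ 1 - w), so all flow uses it
    # while supply stays below its capacity.
    genes <- c("GA", "GB", "GC", "GD")
    edges <- data.frame(from = c("GA", "GA", "GB", "GC"),
                        to = c("GB", "GC", "GD", "GD"),
                        w = c(0.9, 0.5, 0.9, 0.9), stringsAsFactors = FALSE)
    mk <- function(f, t, w) rbind(
        data.frame(tail = f, head = t, cap = round(w * 100),
                   cost = round((1 - w) * 100) + 1, stringsAsFactors = FALSE),
        data.frame(tail = t, head = f, cap = round(w * 100),
                   cost = round((1 - w) * 100) + 1, stringsAsFactors = FALSE))
    arcs <- rbind(mk("GA", "GB", 0.9), mk("GA", "GC", 0.5),
                  mk("GB", "GD", 0.9), mk("GC", "GD", 0.9),
                  data.frame(tail = "<S>", head = "GA", cap = 50, cost = 1,
                             stringsAsFactors = FALSE),
                  data.frame(tail = "GD", head = "<T>", cap = 80, cost = 100,
                             stringsAsFactors = FALSE))
    net <- makeArcNetwork(edges, arcs)
    sol <- solveMinCostFlow(net)
    expect_equal(deliveredFlow(sol), 0.5)
    af <- sol@arcFlows
    expect_equal(af$flow[af$tail == "GA" & af$head == "GB"], 50)
    expect_false(any(af$tail == "GA" & af$head == "GC"))
    orc <- oracleMinCostMaxFlow(net)
    expect_equal(deliveredFlow(sol), orc$delivered)
    expect_equal(flowObjective(sol), orc$objective)
})

test_that("solver matches the exhaustive oracle on random small instances", {
    for (seed in 1:12) {
        net <- randomToyNetwork(seed)
        sol <- suppressWarnings(solveMinCostFlow(net))
        orc <- oracleMinCostMaxFlow(net)
        expect_equal(deliveredFlow(sol), orc$delivered,
                     info = paste("seed", seed))
        expect_equal(flowObjective(sol), orc$objective,
                     info = paste("seed", seed))
    }
})

test_that("flow conservation and capacity bounds hold exactly", {
    for (seed in c(3, 4, 5)) {
        net <- randomToyNetwork(seed)
        sol <- suppressWarnings(solveMinCostFlow(net))
        expect_length(conservationViolations(net, sol), 0)
        a <- net@arcs
        af <- sol@arcFlows
        if (nrow(af)) {
            caps <- a$cap[match(paste(af$tail, af$head),
                                paste(a$tail, a$head))]
            expect_true(all(af$flow <= caps))
            expect_true(all(af$flow == round(af$flow)))
        }
        expect_equal(sum(terminalFlow(sol)), deliveredFlow(sol))
        expect_lte(deliveredFlow(sol), net@config@supply)
    }
})

test_that("no antiparallel edge carries wasted flow", {
    for (seed in c(1, 6, 9)) {
        net <- randomToyNetwork(seed)
        sol <- suppressWarnings(solveMinCostFlow(net))
        af <- sol@arcFlows
        key <- paste(af$tail, af$head)
        rev <- paste(af$head, af$tail)
        both <- key %in% rev & !af$tail %in% c("<S>", "<T>") &
            !af$head %in% c("<S>", "<T>")
        expect_false(any(both))
    }
})

test_that("solver output is deterministic", {
    net <- randomToyNetwork(2)
    s1 <- suppressWarnings(solveMinCostFlow(net))
    s2 <- suppressWarnings(solveMinCostFlow(net))
    expect_identical(s1@arcFlows, s2@arcFlows)
    expect_identical(s1@objective, s2@objective)
})

test_that("disconnected networks deliver zero with a warning", {
    edges <- data.frame(from = "G1", to = "G2", w = 0.9,
                        stringsAsFactors = FALSE)
    arcs <- rbind(
        data.frame(tail = "G1", head = "G2", cap = 90, cost = 11,
                   stringsAsFactors = FALSE),
        data.frame(tail = "G2", head = "G1", cap = 90, cost = 11,
                   stringsAsFactors = FALSE),
        data.frame(tail = "<S>", head = "G1", cap = 100, cost = 1,
                   stringsAsFactors = FALSE))
    net <- makeArcNetwork(edges, arcs)   # no terminal arc at all
    expect_warning(sol <- solveMinCostFlow(net), "no flow")
    expect_equal(deliveredFlow(sol), 0)
    s <- summarizeFlows(sol)
    expect_equal(nrow(s$node_throughput), 0)
    expect_equal(nrow(s$total_edge_flow), 0)
})

test_that("flow summaries are ranked and consistent with delivery", {
    res <- runContrast(5)
    s <- summarizeFlows(res$solB)
    expect_true(!is.unsorted(rev(s$node_throughput$flow)))
    expect_true(!is.unsorted(rev(s$terminal_flow$flow)))
    expect_equal(sum(s$terminal_flow$flow), deliveredFlow(res$solB))
    # every delivered unit crosses >= 1 gene-gene edge when the sources
    # have no terminal arcs
    expect_gte(sum(s$total_edge_flow$flow), deliveredFlow(res$solB))
})
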