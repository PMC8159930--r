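test_that("node flow differences handle absent genes and antisymmetry", {
    res <- runContrast(7)
    d <- nodeFlowDifference(res$solA, res$solB)
    expect_equal(d$flow_diff, d$flow_B - d$flow_A)
    expect_true(!is.unsorted(rev(abs(d$flow_diff))))
    # genes only in B's network carry zero flow in A
    onlyB <- setdiff(names(nodeThroughput(res$solB)),
                     names(nodeThroughput(res$solA)))
    expect_true(all(d$flow_A[d$gene %in% onlyB] == 0))
    # swap negates everything and keeps the ranking
    dSwap <- nodeFlowDifference(res$solB, res$solA)
    m <- match(d$gene, dSwap$gene)
    expect_equal(dSwap$flow_diff[m], -d$flow_diff)
    expect_true(all(nodeFlowDifference(res$solA, res$solA)$flow_diff == 0))
})

test_that("role classification follows the precedence and threshold rules", {
    # chain <S> -> G1 -> G2 -> <T> delivering 0.1 with tau = 0.05:
    # G1 is a source, G2 a target
    net <- chainNetwork(caps = c(1e4, 1e4, 1e3))
    sol <- solveMinCostFlow(net)
    src <- selectSources(NULL, NULL, gene_list = "G1")
    roles <- classifyRoles(sol, sol, src, AnalysisConfig())
    expect_identical(roles$role[roles$gene == "G1"], "source")
    expect_identical(roles$role[roles$gene == "G2"], "target")
    # zero-throughput genes are excluded entirely
    expect_false("G3" %in% roles$gene)
})

test_that("planted roles are recovered in the default scenario", {
    res <- runContrast(8)
    tr <- res$sim$truth
    roles <- res$roles
    expect_identical(roles$role[roles$gene == tr@target], "target")
    expect_identical(roles$role[roles$gene == tr@router], "router")
    rt <- roles[roles$role == "router", ]
    rank <- match(tr@router, rt$gene[order(-abs(rt$flow_diff))])
    expect_lte(rank, 3)
})

test_that("impact scores match the three-component formula", {
    # identical phenotypes: impact 0 for every gene
    res <- runContrast(9)
    same <- impactScore(res$solA, res$solA,
                        names(nodeThroughput(res$solA)))
    expect_true(all(same == 0))
    # hand-built case: d_A = 4, d_B = 6, |N_A intersect N_B| = 3,
    # |N_A union N_B| = 7, flow component 0.5
    nbA <- paste0("N", 1:4); nbB <- c(paste0("N", 1:3), paste0("M", 1:3))
    mkSol <- function(nb, flows) {
        edges <- data.frame(from = pmin("GX", nb), to = pmax("GX", nb),
                            w = 0.9, stringsAsFactors = FALSE)
        new("FlowSolution", phenotype = "t", arcFlows = data.frame(),
            nodeThroughput = flows, terminalFlow = numeric(0),
            totalEdgeFlow = data.frame(), edges = edges, objective = 0,
            delivered = 0, supply = 1, integerScale = 1e4)
    }
    solA <- mkSol(nbA, c(GX = 0.2, OTH = 0.0))
    solB <- mkSol(nbB, c(GX = 0.4, OTH = 0.4))
    imp <- impactScore(solA, solB, "GX")
    expect_equal(unname(imp), (2 / 6 + 4 / 7 + 0.5) / 3)
    expect_error(impactScore(solA, solB, "NOPE"), "absent")
    # swap invariance
    expect_equal(unname(impactScore(solB, solA, "GX")), unname(imp))
})

test_that("key edges honor inclusive ratio and exclusivity boundaries", {
    mkSol <- function(flows) {
        tef <- data.frame(from = names(flows), to = "GZ",
                          flow = unname(flows), stringsAsFactors = FALSE)
        thr <- setNames(rep(1, length(flows) + 1),
                        c(names(flows), "GZ"))
        new("FlowSolution", phenotype = "t", arcFlows = data.frame(),
            nodeThroughput = thr, terminalFlow = numeric(0),
            totalEdgeFlow = tef,
            edges = data.frame(from = names(flows), to = "GZ", w = 0.9,
                               stringsAsFactors = FALSE),
            objective = 0, delivered = 0, supply = 1, integerScale = 1e4)
    }
    solA <- mkSol(c(GA = 0.5, GB = 0.0, GC = 0.49))
    solB <- mkSol(c(GA = 0.1, GB = 0.2, GC = 0.10))
    ke <- keyEdges(solA, solB, AnalysisConfig())
    row <- function(g) ke[ke$from == g, ]
    expect_true(row("GA")$key)                  # ratio exactly 5: inclusive
    expect_equal(row("GA")$ratio, 5)
    expect_true(row("GB")$key)                  # exclusive to B
    expect_identical(row("GB")$exclusive, "B")
    expect_false(row("GC")$key)                 # ratio 4.9 < 5
    # swap maps exclusivity A <-> B
    keS <- keyEdges(solB, solA, AnalysisConfig())
    expect_identical(keS[keS$from == "GB", ]$exclusive, "A")
    expect_identical(dominantInB(ke)$from, "GB")
})

test_that("planted rewired edges surface as key and B-exclusive", {
    res <- runContrast(10)
    rw <- paste(res$sim$truth@rewiredEdges$from,
                res$sim$truth@rewiredEdges$to)
    hits <- res$edges[paste(res$edges$from, res$edges$to) %in% rw &
                      res$edges$key & res$edges$exclusive == "B", ]
    expect_gte(nrow(hits), 1)
})

test_that("prioritized subnetwork is a consistent role partition", {
    res <- runContrast(12)
    sub <- prioritizedSubnetwork(res$roles, res$edges, AnalysisConfig())
    expect_s4_class(sub, "PrioritizedSubnetwork")
    expect_equal(sum(sub@counts), nrow(sub@nodes))
    expect_true(all(c(sub@edges$from, sub@edges$to) %in% sub@nodes$gene))
    tr <- res$sim$truth
    expect_true(all(c(tr@router, tr@target) %in% sub@nodes$gene))
    # no routers requested and no key edges: active sources (plus targets)
    cfg0 <- AnalysisConfig(topKRouters = 0)
    ke0 <- res$edges[res$edges$key == FALSE & FALSE, ]
    sub0 <- prioritizedSubnetwork(res$roles, ke0, cfg0)
    expect_true(all(sub0@nodes$role %in% c("source", "target")))
    expect_error(prioritizedSubnetwork(res$roles[0, ], res$edges,
                                       AnalysisConfig()), "non-empty")
})

test_that("motif views agree with recorded degrees", {
    res <- runContrast(14)
    tr <- res$sim$truth
    mv <- extractMotif(res$solB, tr@router)
    expect_s4_class(mv, "MotifView")
    expect_equal(mv@degree,
                 res$roles$degree_B[res$roles$gene == tr@router])
    expect_true(all(mv@edges$from == tr@router | mv@edges$to == tr@router))
    expect_error(extractMotif(res$solB, "NOPE"), "NOPE")
})
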