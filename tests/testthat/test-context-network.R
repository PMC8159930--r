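test_that("edge co-expression weights match the Pearson formula", {
    # y = 2x + 1 and y = -x give |r| = 1; x=[1,2,3] vs [1,1,2] gives sqrt(3)/2
    x <- c(1, 2, 3)
    em <- mkExpr(rbind(x, 2 * x + 1, -x, c(1, 1, 2)),
                 genes = c("A", "B", "C", "D"))
    ia <- Interactome(c("A", "A", "A"), c("B", "C", "D"))
    we <- edgeCoexpression(em, ia)
    w <- setNames(we$w, paste(we$from, we$to))
    expect_equal(unname(w["A B"]), 1)
    expect_equal(unname(w["A C"]), 1)
    expect_equal(unname(w["A D"]), sqrt(3) / 2)
})

test_that("edges with unmeasured endpoints drop; constant genes weight 0", {
    em <- mkExpr(rbind(c(1, 2, 3), c(5, 5, 5)), genes = c("A", "K"))
    ia <- Interactome(c("A", "A"), c("K", "ZZZ"))
    expect_warning(we <- edgeCoexpression(em, ia), "zero-variance")
    expect_equal(nrow(we), 1)
    expect_equal(we$w, 0)
    expect_equal(attr(we, "dropped_missing"), 1)
    expect_error(edgeCoexpression(em[, 1:2], ia), ">= 3 samples")
})

test_that("correlation threshold boundary is inclusive", {
    we <- data.frame(from = c("A", "B", "C"), to = c("X", "Y", "Z"),
                     w = c(0.49, 0.50, 0.51), stringsAsFactors = FALSE)
    kept <- applyCorThreshold(we, 0.5)
    expect_equal(nrow(kept), 2)
    expect_equal(attr(kept, "dropped"), 1)
    expect_equal(nrow(applyCorThreshold(we, 0)), 3)
    expect_equal(suppressWarnings(nrow(applyCorThreshold(we, 1))), 0)
})

test_that("functional neighborhood follows the quantile rule and nests", {
    # one source, 21 candidates with distinct |r|: snf = 0.95 keeps the
    # top ceiling(21 * 0.05) = 2 candidates
    set.seed(1)
    n <- 40
    src <- rnorm(n)
    vals <- rbind(src)
    rho <- seq(0.04, 0.84, length.out = 21)
    for (i in seq_along(rho))
        vals <- rbind(vals, rho[i] * src + sqrt(1 - rho[i]^2) * rnorm(n))
    em <- mkExpr(vals, genes = c("SRC", sprintf("C%02d", 1:21)))
    nb <- functionalNeighborhood(em, "SRC", snf = 0.95)
    expect_equal(length(nb), 3)   # source + top 2
    expect_true("SRC" %in% nb)
    v <- exprValues(em)
    obs <- abs(cor(v["SRC", ], t(v[-1, , drop = FALSE])))[1, ]
    expect_setequal(setdiff(nb, "SRC"),
                    names(sort(obs, decreasing = TRUE))[1:2])

    expect_setequal(functionalNeighborhood(em, "SRC", snf = 0),
                    geneIds(em))
    nb90 <- functionalNeighborhood(em, "SRC", snf = 0.90)
    expect_true(all(nb %in% nb90))
    expect_error(functionalNeighborhood(em, "SRC", snf = 1.2),
                 "parameter error")
    expect_error(functionalNeighborhood(em, character(0)), "non-empty")
})

test_that("flow network construction unrolls the definition", {
    # one source G1, chain G1-G2 with w = 1, epsilonTerminal = 0.1
    cfg <- AnalysisConfig(epsilonTerminal = 0.1)
    src <- selectSources(NULL, NULL, gene_list = "G1")
    re <- data.frame(from = "G1", to = "G2", w = 1, stringsAsFactors = FALSE)
    net <- buildFlowNetwork(re, NULL, src, cfg)
    a <- networkArcs(net)
    expect_equal(a$cap[a$tail == "<S>"], 1e4)
    expect_equal(a$cap[a$tail == "G1" & a$head == "G2"], 1e4)
    expect_equal(a$cap[a$head == "<T>"], round(0.1 * 1 * 1e4))
    expect_equal(a$cost[a$tail == "G1" & a$head == "G2"], 1)
    expect_true(all(a$cost > 0))
    expect_true(all(a$cap == round(a$cap)))
})

test_that("source capacities use largest-remainder apportionment", {
    src <- new("SourceSet", records = data.frame(
        gene = c("G1", "G2"), log2FC = c(2, 1), p = 0, q = 0,
        selected = TRUE, stringsAsFactors = FALSE), bypass = FALSE)
    re <- data.frame(from = c("G1", "G2"), to = c("G3", "G3"),
                     w = c(0.8, 0.8), stringsAsFactors = FALSE)
    net <- buildFlowNetwork(re, NULL, src, AnalysisConfig())
    caps <- setNames(net@sourceCaps$cap, net@sourceCaps$gene)
    expect_equal(unname(caps["G1"]), 6667)
    expect_equal(unname(caps["G2"]), 3333)
    expect_equal(sum(caps), 1e4)
})

test_that("networks fail loudly when sources are filtered out", {
    src <- selectSources(NULL, NULL, gene_list = "G9")
    re <- data.frame(from = "G1", to = "G2", w = 0.9,
                     stringsAsFactors = FALSE)
    expect_error(buildFlowNetwork(re, NULL, src, AnalysisConfig()),
                 "sources disconnected")
    empty <- data.frame(from = character(), to = character(), w = numeric())
    expect_error(buildFlowNetwork(empty, NULL, src, AnalysisConfig()),
                 "sources disconnected")
})

test_that("construction is monotone in its thresholds", {
    sim <- defaultSim(2)
    we <- suppressWarnings(edgeCoexpression(sim$A, sim$interactome))
    e1 <- applyCorThreshold(we, 0.4); e2 <- applyCorThreshold(we, 0.6)
    expect_true(all(paste(e2$from, e2$to) %in% paste(e1$from, e1$to)))
    src <- selectSources(sim$A, sim$B)
    n1 <- functionalNeighborhood(sim$B, selectedSources(src), 0.90)
    n2 <- functionalNeighborhood(sim$B, selectedSources(src), 0.95)
    expect_true(all(n2 %in% n1))
})
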