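test_that("preferential attachment gives the forced edge count and connectivity", {
    ia <- generateInteractome(50, 2, seed = 1)
    expect_equal(nrow(interactomeEdges(ia)), 96)   # (50 - 2) * 2
    g <- igraph::graph_from_data_frame(interactomeEdges(ia),
                                       directed = FALSE)
    expect_true(igraph::is_connected(g))
    expect_equal(igraph::vcount(g), 50)

    ia2 <- generateInteractome(50, 2, seed = 1)
    expect_identical(interactomeEdges(ia), interactomeEdges(ia2))

    expect_error(generateInteractome(3, 3, seed = 1), "parameter error")
})

test_that("interactome degree distribution is heavy-tailed", {
    # frozen from a 20-seed sweep: max/median degree ratio ranged 10.5-18.5
    rat <- vapply(c(7, 8, 9), function(s) {
        e <- interactomeEdges(generateInteractome(500, 3, seed = s))
        d <- table(c(e$from, e$to))
        max(d) / stats::median(d)
    }, numeric(1))
    expect_true(all(rat >= 3))
})

test_that("null scenario gives exchangeable phenotypes", {
    sim <- defaultSim(11, deltaShift = 0, nRewiredPartners = 0)
    a <- exprValues(sim$A); b <- exprValues(sim$B)
    p <- vapply(rownames(a), function(g)
        stats::t.test(a[g, ], b[g, ])$p.value, numeric(1))
    # ~5% of genes reject at alpha = 0.05 (binomial sd ~ 1.3% at 300 genes)
    expect_lt(mean(p <= 0.05), 0.11)
    expect_gt(mean(p <= 0.05), 0.005)
})

test_that("planted correlations and fold changes are recovered", {
    # frozen from a 20-seed sweep at n = 100: rewired sample correlations
    # ranged [0.844, 0.937] in B and [-0.249, 0.171] in A
    for (s in c(2, 5)) {
        sim <- defaultSim(s, nSamplesPerPhenotype = 100)
        rw <- sim$truth@rewiredEdges
        for (i in seq_len(nrow(rw))) {
            rB <- cor(exprValues(sim$B)[rw$from[i], ],
                      exprValues(sim$B)[rw$to[i], ])
            rA <- cor(exprValues(sim$A)[rw$from[i], ],
                      exprValues(sim$A)[rw$to[i], ])
            expect_gt(rB, 0.8); expect_lt(rB, 0.96)
            expect_gt(rA, -0.3); expect_lt(rA, 0.3)
        }
    }
    # planted sources: empirical log2FC within delta +/- 0.6 (frozen range
    # over 20 seeds at n = 50: [1.46, 2.46])
    sim <- defaultSim(4)
    tg <- sim$truth@sources$gene
    lfc <- rowMeans(exprValues(sim$B)[tg, ]) -
        rowMeans(exprValues(sim$A)[tg, ])
    expect_true(all(abs(lfc - 2) < 0.6))
})

test_that("planted correlation contrast exceeds 0.5 on rewired edges", {
    sim <- defaultSim(6, nSamplesPerPhenotype = 100)
    rw <- sim$truth@rewiredEdges
    dB <- vapply(seq_len(nrow(rw)), function(i)
        cor(exprValues(sim$B)[rw$from[i], ], exprValues(sim$B)[rw$to[i], ]) -
        cor(exprValues(sim$A)[rw$from[i], ], exprValues(sim$A)[rw$to[i], ]),
        numeric(1))
    expect_gte(mean(dB), 0.5)
})

test_that("generation is deterministic and truth is consistent", {
    s1 <- defaultSim(9); s2 <- defaultSim(9)
    expect_identical(exprValues(s1$A), exprValues(s2$A))
    expect_identical(exprValues(s1$B), exprValues(s2$B))
    expect_identical(s1$truth@rewiredEdges, s2$truth@rewiredEdges)
    nodes <- interactomeNodes(s1$interactome)
    expect_true(all(c(s1$truth@router, s1$truth@target,
                      s1$truth@sources$gene) %in% nodes))
    ekey <- paste(interactomeEdges(s1$interactome)$from,
                  interactomeEdges(s1$interactome)$to)
    expect_true(all(paste(s1$truth@rewiredEdges$from,
                          s1$truth@rewiredEdges$to) %in% ekey))
    # phenotype labels attached
    expect_true(all(phenotypeLabels(s1$A) == "A"))
    expect_true(all(phenotypeLabels(s1$B) == "B"))
})

test_that("dependency generator plants a clean essential block", {
    for (s in c(1, 13)) {
        dt <- generateDependencyTable(paste0("G", 1:20), paste0("L", 1:10),
                                      "G1", seed = s)
        r <- dependencyRecords(dt)
        expect_equal(nrow(r), 200)
        expect_true(all(r$score[r$gene == "G1"] < -0.5))   # 6-sigma bound
        dt0 <- generateDependencyTable(paste0("G", 1:20), paste0("L", 1:10),
                                       character(0), seed = s)
        med <- tapply(dependencyRecords(dt0)$score,
                      dependencyRecords(dt0)$gene, stats::median)
        expect_true(all(med > -1))
    }
    dt1 <- generateDependencyTable("G1", "L1", "G1", seed = 2)
    dt2 <- generateDependencyTable("G1", "L1", "G1", seed = 2)
    expect_identical(dependencyRecords(dt1), dependencyRecords(dt2))
    expect_error(generateDependencyTable("G1", character(0), "G1", seed = 1),
                 "parameter error")
    expect_error(generateDependencyTable("G1", "L1", "G9", seed = 1),
                 "subset")
})
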