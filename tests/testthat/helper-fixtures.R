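# Small programmatic fixtures shared across test files.

exprFromMatrix <- function(values, phenotype = NULL) {
    ExpressionMatrix(values, phenotype = phenotype)
}

# genes x samples matrix with named rows G1..Gk, samples S1..Sn
mkExpr <- function(values, genes = NULL, samples = NULL) {
    if (is.null(genes)) genes <- paste0("G", seq_len(nrow(values)))
    if (is.null(samples)) samples <- paste0("S", seq_len(ncol(values)))
    dimnames(values) <- list(genes, samples)
    ExpressionMatrix(values)
}

writeTempLines <- function(lines, ext = ".tsv") {
    f <- tempfile(fileext = ext)
    writeLines(lines, f)
    f
}

defaultSim <- function(seed, ...) {
    sc <- syntheticScenario(seed = seed, ...)
    ppi <- generateInteractome(sc@nGenes, sc@mAttach, seed = sc@seed)
    sim <- generateTwoPhenotypeExpression(ppi, sc)
    c(sim, list(interactome = ppi, scenario = sc))
}

# full contrast for one scenario seed: networks, solutions, comparison layer
runContrast <- function(seed, config = AnalysisConfig(), ...) {
    sim <- defaultSim(seed, ...)
    src <- suppressWarnings(selectSources(sim$A, sim$B))
    build <- function(ex, ph) {
        we <- suppressWarnings(edgeCoexpression(ex, sim$interactome))
        re <- suppressWarnings(applyCorThreshold(we, config@corThreshold))
        nb <- functionalNeighborhood(ex, selectedSources(src), config@snf)
        suppressMessages(buildFlowNetwork(re, nb, src, config, ph))
    }
    netA <- build(sim$A, "A")
    netB <- build(sim$B, "B")
    solA <- solveMinCostFlow(netA)
    solB <- solveMinCostFlow(netB)
    list(sim = sim, sources = src, netA = netA, netB = netB,
         solA = solA, solB = solB,
         roles = classifyRoles(solA, solB, src, config),
         edges = keyEdges(solA, solB, config))
}
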