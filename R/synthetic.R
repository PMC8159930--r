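# Seeded evaluation that never leaks RNG state into the caller's session.
.withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(code)
}

#' Generate a scale-free synthetic interactome
#'
#' Preferential attachment: \code{mAttach} initial nodes, then each new node
#' attaches to \code{mAttach} distinct existing nodes with probability
#' proportional to degree + 1, giving exactly
#' \code{(nGenes - mAttach) * mAttach} edges, a connected graph, and the
#' heavy-tailed degree distribution typical of protein-protein interactomes.
#'
#' @param nGenes number of genes (> \code{mAttach}).
#' @param mAttach edges added per new node (>= 1).
#' @param seed integer seed; the construction is fully deterministic given
#'   it.
#' @return An \linkS4class{Interactome} over genes \code{"G0001"}, ...
#' @examples
#' generateInteractome(50, 2, seed = 1)
#' @export
generateInteractome <- function(nGenes, mAttach, seed) {
    if (mAttach < 1 || nGenes <= mAttach)
        stop("parameter error: need nGenes > mAttach >= 1")
    genes <- sprintf("G%04d", seq_len(nGenes))
    .withSeed(seed, {
        deg <- integer(nGenes)
        from <- integer(0); to <- integer(0)
        for (i in seq(mAttach + 1, nGenes)) {
            tg <- sample.int(i - 1L, mAttach,
                             prob = deg[seq_len(i - 1L)] + 1)
            from <- c(from, rep(i, mAttach)); to <- c(to, tg)
            deg[i] <- deg[i] + mAttach
            deg[tg] <- deg[tg] + 1L
        }
        Interactome(genes[from], genes[to])
    })
}

.autoPlant <- function(interactome, scenario) {
    e <- interactome@edges
    nodes <- interactomeNodes(interactome)
    deg <- table(factor(c(e$from, e$to), levels = nodes))
    byDeg <- nodes[order(-as.vector(deg), nodes)]
    tgt <- scenario@plantedTarget
    if (is.na(tgt)) tgt <- byDeg[1]
    if (!tgt %in% nodes) stop("planted target ", tgt, " not in interactome")
    nbr <- function(g) sort(unique(c(e$to[e$from == g], e$from[e$to == g])))
    tNbr <- nbr(tgt)
    rtr <- scenario@plantedRouter
    if (is.na(rtr)) {
        cand <- setdiff(tNbr, tgt)
        cand <- cand[order(-as.vector(deg[cand]), cand)]
        cand <- cand[as.vector(deg[cand]) >= 2]
        if (!length(cand))
            stop("no interactome neighbor of the target can act as router")
        rtr <- cand[1]
    }
    if (!rtr %in% nodes) stop("planted router ", rtr, " not in interactome")
    if (identical(rtr, tgt))
        stop("parameter error: planted router and target must be the same gene")
    rNbr <- setdiff(nbr(rtr), tgt)
    # low-degree partners keep the router's weighted degree below the
    # target-classification bound
    rNbr <- rNbr[order(as.vector(deg[rNbr]), rNbr)]
    partners <- head(rNbr, scenario@nRewiredPartners)
    # sources must not touch the router: a retained source-router edge
    # would inflate the router's weighted degree (and terminal capacity)
    # toward the target-classification bound
    srcCand <- setdiff(tNbr, c(rtr, partners, nbr(rtr)))
    srcCand <- srcCand[order(-as.vector(deg[srcCand]), srcCand)]
    if (length(srcCand) < scenario@nSources)
        stop("planted target has only ", length(srcCand),
             " usable interactome neighbors; reduce nSources (",
             scenario@nSources, ") or enlarge the interactome")
    sources <- sort(head(srcCand, scenario@nSources))
    list(target = tgt, router = rtr, partners = partners, sources = sources)
}

#' Generate two-phenotype expression with planted differential structure
#'
#' A Gaussian factor model on the interactome: every ordinary edge shares a
#' latent factor giving pairwise co-expression of about
#' \code{baselineRho} in both phenotypes; a shared anchor backbone ties each
#' planted source to the planted target at \code{backboneRho} in both
#' phenotypes; rewired edges around the planted router reach \code{rhoHi}
#' in phenotype B and carry no shared factor in phenotype A; planted
#' sources additionally gain a \code{deltaShift} log2 mean shift in B.
#' Generation is O(edges) and deterministic given the scenario seed.
#'
#' @param interactome an \linkS4class{Interactome}.
#' @param scenario a \linkS4class{SyntheticScenario}; unset router/target
#'   are auto-selected from high-degree nodes.
#' @return A list with elements \code{A}, \code{B}
#'   (\linkS4class{ExpressionMatrix}) and \code{truth}
#'   (\linkS4class{SyntheticTruth}).
#' @examples
#' ppi <- generateInteractome(100, 2, seed = 1)
#' sim <- generateTwoPhenotypeExpression(ppi,
#'     syntheticScenario(nGenes = 100, nSources = 5, seed = 1))
#' @export
generateTwoPhenotypeExpression <- function(interactome, scenario) {
    validObject(scenario)
    nodes <- interactomeNodes(interactome)
    named <- c(scenario@plantedRouter, scenario@plantedTarget)
    named <- named[!is.na(named)]
    if (!all(named %in% nodes))
        stop("scenario genes not in interactome: ",
             paste(setdiff(named, nodes), collapse = ", "))
    plant <- .autoPlant(interactome, scenario)
    e <- interactome@edges
    key <- paste(e$from, e$to)
    bbEdges <- data.frame(from = pmin(plant$sources, plant$target),
                          to = pmax(plant$sources, plant$target),
                          stringsAsFactors = FALSE)
    if (scenario@nRewiredPartners >= 1 && length(plant$partners)) {
        rwFrom <- c(plant$target, rep(plant$router, length(plant$partners)))
        rwTo <- c(plant$router, plant$partners)
        rwEdges <- data.frame(from = pmin(rwFrom, rwTo),
                              to = pmax(rwFrom, rwTo),
                              stringsAsFactors = FALSE)
    } else {
        rwEdges <- data.frame(from = character(), to = character())
    }
    planted <- c(paste(bbEdges$from, bbEdges$to), paste(rwEdges$from, rwEdges$to))
    baseIdx <- which(!key %in% planted)
    nG <- length(nodes); nS <- scenario@nSamplesPerPhenotype
    rho0 <- scenario@baselineRho
    gi <- setNames(seq_len(nG), nodes)
    # baseline incidence: genes x baseline-edges loading matrix
    inc <- matrix(0, nG, length(baseIdx))
    if (length(baseIdx)) {
        inc[cbind(gi[e$from[baseIdx]], seq_along(baseIdx))] <- 1
        inc[cbind(gi[e$to[baseIdx]], seq_along(baseIdx))] <- 1
    }
    dBase <- rowSums(inc)
    resid <- scenario@noiseSd^2 * pmax(1 - dBase * rho0, 0.05)
    popVar <- dBase * rho0 + resid
    drawPheno <- function(rewire) {
        f <- matrix(stats::rnorm(nS * length(baseIdx)), nS)
        eps <- matrix(stats::rnorm(nS * nG), nS)
        z <- (f %*% (sqrt(rho0) * t(inc)) +
              sweep(eps, 2, sqrt(resid), `*`))
        z <- sweep(z, 2, sqrt(popVar), `/`)
        colnames(z) <- nodes
        aBB <- scenario@backboneRho
        for (s in plant$sources)
            z[, s] <- aBB * z[, plant$target] + sqrt(1 - aBB^2) * z[, s]
        if (rewire && nrow(rwEdges)) {
            aHi <- scenario@rhoHi
            z[, plant$router] <- aHi * z[, plant$target] +
                sqrt(1 - aHi^2) * z[, plant$router]
            for (x in plant$partners)
                z[, x] <- aHi * z[, plant$router] + sqrt(1 - aHi^2) * z[, x]
        }
        z
    }
    .withSeed(scenario@seed, {
        mu <- stats::rnorm(nG, mean = 7, sd = 1.5)
        zA <- drawPheno(rewire = FALSE)
        zB <- drawPheno(rewire = nrow(rwEdges) > 0)
        zB[, plant$sources] <- zB[, plant$sources] + scenario@deltaShift
        mA <- t(zA + matrix(mu, nS, nG, byrow = TRUE))
        mB <- t(zB + matrix(mu, nS, nG, byrow = TRUE))
        colnames(mA) <- sprintf("A_S%03d", seq_len(nS))
        colnames(mB) <- sprintf("B_S%03d", seq_len(nS))
        exprA <- ExpressionMatrix(mA,
            phenotype = setNames(rep("A", nS), colnames(mA)))
        exprB <- ExpressionMatrix(mB,
            phenotype = setNames(rep("B", nS), colnames(mB)))
        truth <- new("SyntheticTruth",
            sources = data.frame(gene = plant$sources,
                                 log2FC = scenario@deltaShift,
                                 stringsAsFactors = FALSE),
            router = plant$router, target = plant$target,
            rewiredEdges = rwEdges, backboneEdges = bbEdges,
            seed = scenario@seed)
        list(A = exprA, B = exprB, truth = truth)
    })
}

#' Generate a synthetic gene-dependency table
#'
#' Emulates DEMETER2/Avana-style screens: genes in \code{essential_block}
#' score Normal(-1.4, 0.2) in every cell line, all others Normal(0, 0.3).
#'
#' @param genes gene symbols.
#' @param cell_lines cell-line identifiers (non-empty).
#' @param essential_block subset of \code{genes} planted as essential.
#' @param seed integer seed.
#' @param assay \code{"CRISPR"} or \code{"RNAi"}.
#' @return A \linkS4class{DependencyTable}.
#' @examples
#' generateDependencyTable(c("G1", "G2"), c("L1", "L2"), "G1", seed = 1)
#' @export
generateDependencyTable <- function(genes, cell_lines, essential_block,
                                    seed, assay = c("CRISPR", "RNAi")) {
    assay <- match.arg(assay)
    if (length(cell_lines) == 0)
        stop("parameter error: cell_lines must be non-empty")
    genes <- toupper(genes); essential_block <- toupper(essential_block)
    if (!all(essential_block %in% genes))
        stop("essential_block must be a subset of genes")
    .withSeed(seed, {
        grid <- expand.grid(cell_line = cell_lines, gene = genes,
                            stringsAsFactors = FALSE)
        ess <- grid$gene %in% essential_block
        score <- numeric(nrow(grid))
        score[ess] <- stats::rnorm(sum(ess), -1.4, 0.2)
        score[!ess] <- stats::rnorm(sum(!ess), 0, 0.3)
        DependencyTable(data.frame(gene = grid$gene,
                                   cell_line = grid$cell_line,
                                   score = score, assay = assay,
                                   stringsAsFactors = FALSE))
    })
}
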