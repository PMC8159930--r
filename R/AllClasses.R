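#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' ExpressionMatrix: log2-scale expression with optional phenotype labels
#'
#' A thin wrapper around \linkS4class{SummarizedExperiment} holding one
#' assay (\code{"exprs"}) of log2-normalized expression values, genes in
#' rows and samples in columns.  Gene symbols are uppercase and unique;
#' sample IDs are unique; all values are finite.  Phenotype labels, when
#' present, live in \code{colData(x)$phenotype}.
#'
#' @slot .  inherits all slots from SummarizedExperiment.
#' @export
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

.validExpressionMatrix <- function(object) {
    msg <- character()
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    g <- rownames(object)
    s <- colnames(object)
    if (is.null(g) || is.null(s))
        msg <- c(msg, "gene and sample names are required")
    if (anyDuplicated(g))
        msg <- c(msg, "duplicate gene symbols")
    if (anyDuplicated(s))
        msg <- c(msg, "duplicate sample IDs")
    if (!is.null(g) && !identical(g, toupper(g)))
        msg <- c(msg, "gene symbols must be uppercase")
    if (length(msg) == 0) {
        v <- SummarizedExperiment::assay(object, "exprs")
        if (!all(is.finite(v)))
            msg <- c(msg, "all expression values must be finite")
    }
    if (length(msg)) msg else TRUE
}
setValidity("ExpressionMatrix", .validExpressionMatrix)

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, genes x samples, with dimnames.  Values are
#'   assumed log2-scale (use \code{log2_transform = TRUE} in
#'   \code{\link{readExpressionMatrix}} for linear-scale inputs).
#' @param phenotype optional named character vector mapping sample ID to a
#'   phenotype label; names must cover all samples present in it.
#' @return An \linkS4class{ExpressionMatrix}.
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(c("G1","G2","G3"), c("S1","S2")))
#' ExpressionMatrix(m, phenotype = c(S1 = "A", S2 = "B"))
#' @export
ExpressionMatrix <- function(values, phenotype = NULL) {
    stopifnot(is.matrix(values), is.numeric(values))
    rownames(values) <- toupper(rownames(values))
    cd <- S4Vectors::DataFrame(row.names = colnames(values))
    if (!is.null(phenotype)) {
        if (is.null(names(phenotype)))
            stop("'phenotype' must be a named character vector (sample -> label)")
        cd$phenotype <- unname(phenotype[colnames(values)])
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = S4Vectors::SimpleList(exprs = values), colData = cd)
    new("ExpressionMatrix", se)
}

#' Interactome: an undirected protein-protein interaction edge set
#'
#' Stores a deduplicated, self-loop-free undirected edge list over uppercase
#' gene symbols.  Edges are kept in canonical form (\code{from < to},
#' lexicographically) and sorted, so two interactomes with the same edge set
#' are identical objects.
#'
#' @slot edges data.frame with character columns \code{from}, \code{to}.
#' @export
setClass("Interactome", representation(edges = "data.frame"))

setValidity("Interactome", function(object) {
    e <- object@edges
    msg <- character()
    if (!all(c("from", "to") %in% names(e)))
        msg <- c(msg, "edges must have columns 'from' and 'to'")
    else {
        if (any(e$from == e$to)) msg <- c(msg, "self-loops are not allowed")
        if (any(e$from > e$to)) msg <- c(msg, "edges must be canonical (from < to)")
        if (anyDuplicated(paste(e$from, e$to)))
            msg <- c(msg, "duplicate edges")
        up <- c(e$from, e$to)
        if (!identical(up, toupper(up))) msg <- c(msg, "symbols must be uppercase")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an Interactome from an edge list
#'
#' Symbols are uppercased, self-loops dropped (with a message when any are
#' found), and duplicate undirected edges collapsed.
#'
#' @param from,to character vectors of endpoint gene symbols.
#' @return An \linkS4class{Interactome}.
#' @examples
#' Interactome(c("a", "b"), c("b", "c"))
#' @export
Interactome <- function(from = character(), to = character()) {
    stopifnot(length(from) == length(to))
    from <- toupper(as.character(from)); to <- toupper(as.character(to))
    loops <- from == to
    if (any(loops))
        message(sum(loops), " self-loop(s) dropped")
    from2 <- pmin(from[!loops], to[!loops])
    to2 <- pmax(from[!loops], to[!loops])
    e <- unique(data.frame(from = from2, to = to2, stringsAsFactors = FALSE))
    e <- e[order(e$from, e$to), , drop = FALSE]
    rownames(e) <- NULL
    new("Interactome", edges = e)
}

#' GeneSetCollection: named gene sets for over-representation analysis
#'
#' @slot sets named list of uppercase character vectors (each non-empty,
#'   deduplicated).
#' @slot descriptions named character vector, parallel to \code{sets}.
#' @export
setClass("GeneSetCollection",
    representation(sets = "list", descriptions = "character"))

setValidity("GeneSetCollection", function(object) {
    msg <- character()
    if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
        msg <- c(msg, "sets must be uniquely named")
    if (any(lengths(object@sets) == 0))
        msg <- c(msg, "each set must be non-empty")
    if (!identical(names(object@sets), names(object@descriptions)))
        msg <- c(msg, "descriptions must parallel sets")
    if (length(msg)) msg else TRUE
})

#' Construct a GeneSetCollection
#' @param sets named list of character vectors.
#' @param descriptions optional named character vector of set descriptions.
#' @return A \linkS4class{GeneSetCollection}.
#' @export
GeneSetCollection <- function(sets, descriptions = NULL) {
    sets <- lapply(sets, function(g) unique(toupper(g)))
    if (is.null(descriptions))
        descriptions <- setNames(rep("", length(sets)), names(sets))
    new("GeneSetCollection", sets = sets,
        descriptions = descriptions[names(sets)])
}

#' DependencyTable: long-form gene-dependency scores
#'
#' One record per (gene, cell line, assay) with a finite dependency score.
#' Strongly negative scores indicate essentiality (DEMETER2 / Avana
#' convention).
#'
#' @slot records data.frame with columns \code{gene}, \code{cell_line},
#'   \code{score}, \code{assay} (one of \code{"RNAi"}, \code{"CRISPR"}).
#' @export
setClass("DependencyTable", representation(records = "data.frame"))

setValidity("DependencyTable", function(object) {
    r <- object@records
    msg <- character()
    need <- c("gene", "cell_line", "score", "assay")
    if (!all(need %in% names(r)))
        msg <- c(msg, "records need columns gene, cell_line, score, assay")
    else {
        if (!all(r$assay %in% c("RNAi", "CRISPR")))
            msg <- c(msg, "assay must be 'RNAi' or 'CRISPR'")
        if (!all(is.finite(r$score))) msg <- c(msg, "scores must be finite")
        if (anyDuplicated(paste(r$gene, r$cell_line, r$assay)))
            msg <- c(msg, "at most one record per (gene, cell_line, assay)")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a DependencyTable
#' @param records data.frame with columns gene, cell_line, score, assay.
#' @return A \linkS4class{DependencyTable}.
#' @export
DependencyTable <- function(records) {
    records$gene <- toupper(as.character(records$gene))
    records$cell_line <- as.character(records$cell_line)
    records <- records[order(records$gene, records$cell_line, records$assay), ,
                       drop = FALSE]
    rownames(records) <- NULL
    new("DependencyTable", records = records)
}

#' SourceSet: differential-expression statistics and source selection
#'
#' @slot records data.frame with columns \code{gene}, \code{log2FC},
#'   \code{p}, \code{q}, \code{selected}.  In bypass mode (a user-supplied
#'   gene list) the statistics are \code{NA} and all genes are selected.
#' @slot bypass logical scalar.
#' @export
setClass("SourceSet",
    representation(records = "data.frame", bypass = "logical"))

setValidity("SourceSet", function(object) {
    r <- object@records
    msg <- character()
    if (!all(c("gene", "log2FC", "p", "q", "selected") %in% names(r)))
        msg <- c(msg, "records need columns gene, log2FC, p, q, selected")
    else {
        ok <- is.na(r$p) | is.na(r$q) | r$q >= r$p - 1e-12
        if (!all(ok)) msg <- c(msg, "q must be >= p")
    }
    if (length(msg)) msg else TRUE
})

#' StratifiedLabels: a marker-median phenotype split
#'
#' @slot marker gene symbol used for stratification.
#' @slot medianValue the marker's median expression.
#' @slot high,low disjoint sample-ID sets covering all samples; samples
#'   strictly above the median are \code{high}.
#' @export
setClass("StratifiedLabels",
    representation(marker = "character", medianValue = "numeric",
                   high = "character", low = "character"))

setValidity("StratifiedLabels", function(object) {
    if (length(intersect(object@high, object@low)))
        "high and low must be disjoint" else TRUE
})

#' AnalysisConfig: tunable parameters of the flow pipeline
#'
#' Defaults follow the published protocol where one is stated
#' (\code{snf = 0.95}, \code{ratioThreshold = 5}, \code{corThreshold = 0.5},
#' top 20 routers, dependency threshold -1.0); the remaining knobs belong to
#' this package's flow formulation and are documented in the methods
#' vignette.
#'
#' @slot snf functional-neighborhood quantile in [0, 1].
#' @slot corThreshold minimum |Pearson r| for a retained edge.
#' @slot ratioThreshold minimum cross-phenotype flow ratio for a key edge.
#' @slot supply total flow injected at the super-source (supply units).
#' @slot epsilonTerminal fraction of a node's weighted degree usable as
#'   terminal capacity.
#' @slot terminalCost cost per unit on terminal arcs.
#' @slot costFloor small positive cost added to every gene-gene arc.
#' @slot integerScale weight-to-integer multiplier for exact arithmetic.
#' @slot topKRouters routers kept in the prioritized subnetwork.
#' @slot targetFraction terminal-flow share of supply defining a target.
#' @slot dependencyThreshold strict upper bound for a dependency call.
#' @slot seed integer seed recorded into run manifests.
#' @export
setClass("AnalysisConfig", representation(
    snf = "numeric", corThreshold = "numeric", ratioThreshold = "numeric",
    supply = "numeric", epsilonTerminal = "numeric", terminalCost = "numeric",
    costFloor = "numeric", integerScale = "numeric", topKRouters = "numeric",
    targetFraction = "numeric", dependencyThreshold = "numeric",
    seed = "numeric"))

setValidity("AnalysisConfig", function(object) {
    msg <- character()
    if (object@snf < 0 || object@snf > 1) msg <- c(msg, "snf must be in [0, 1]")
    if (object@corThreshold < 0 || object@corThreshold > 1)
        msg <- c(msg, "corThreshold must be in [0, 1]")
    if (object@ratioThreshold < 1) msg <- c(msg, "ratioThreshold must be >= 1")
    if (object@integerScale < 100) msg <- c(msg, "integerScale must be >= 100")
    if (object@costFloor <= 0) msg <- c(msg, "costFloor must be > 0")
    if (object@supply <= 0) msg <- c(msg, "supply must be > 0")
    if (object@epsilonTerminal <= 0)
        msg <- c(msg, "epsilonTerminal must be > 0")
    if (length(msg)) msg else TRUE
})

#' Construct an AnalysisConfig
#' @param snf,corThreshold,ratioThreshold,supply,epsilonTerminal,terminalCost
#'   see \linkS4class{AnalysisConfig}.
#' @param costFloor,integerScale,topKRouters,targetFraction see
#'   \linkS4class{AnalysisConfig}.
#' @param dependencyThreshold,seed see \linkS4class{AnalysisConfig}.
#' @return An \linkS4class{AnalysisConfig}.
#' @examples
#' AnalysisConfig()
#' @export
AnalysisConfig <- function(snf = 0.95, corThreshold = 0.5, ratioThreshold = 5,
                           supply = 1, epsilonTerminal = 0.01,
                           terminalCost = 1, costFloor = 1e-4,
                           integerScale = 1e4, topKRouters = 20,
                           targetFraction = 0.05, dependencyThreshold = -1,
                           seed = 1) {
    new("AnalysisConfig", snf = snf, corThreshold = corThreshold,
        ratioThreshold = ratioThreshold, supply = supply,
        epsilonTerminal = epsilonTerminal, terminalCost = terminalCost,
        costFloor = costFloor, integerScale = integerScale,
        topKRouters = topKRouters, targetFraction = targetFraction,
        dependencyThreshold = dependencyThreshold, seed = seed)
}

#' ContextFlowNetwork: a phenotype-specific capacitated, costed flow graph
#'
#' Retained co-expression edges become antiparallel integer-capacity arcs
#' (capacity proportional to |Pearson r|, cost to 1 - r plus a small floor);
#' a super-source feeds the selected source genes with capacities
#' proportional to |log2FC|; every non-source node carries a small costed
#' terminal arc to the super-sink.  All arc parameters are integers after
#' scaling by \code{integerScale}, so downstream flow arithmetic is exact.
#'
#' @slot phenotype label of the phenotype whose samples weighted the edges.
#' @slot nodes retained gene symbols (sorted).
#' @slot edges data.frame \code{from}, \code{to}, \code{w} of retained
#'   undirected edges (canonical order).
#' @slot sourceCaps data.frame \code{gene}, \code{cap} of super-source arc
#'   capacities (integer, summing to \code{supply * integerScale}).
#' @slot arcs data.frame \code{tail}, \code{head}, \code{cap}, \code{cost}
#'   with the special labels \code{"<S>"} and \code{"<T>"}.
#' @slot config the \linkS4class{AnalysisConfig} used.
#' @export
setClass("ContextFlowNetwork", representation(
    phenotype = "character", nodes = "character", edges = "data.frame",
    sourceCaps = "data.frame", arcs = "data.frame", config = "AnalysisConfig"))

setValidity("ContextFlowNetwork", function(object) {
    msg <- character()
    a <- object@arcs
    if (any(a$cap < 0)) msg <- c(msg, "arc capacities must be >= 0")
    if (any(a$cost <= 0)) msg <- c(msg, "arc costs must be > 0")
    if (any(a$cap != round(a$cap)) || any(a$cost != round(a$cost)))
        msg <- c(msg, "arc parameters must be integers")
    sArcs <- a[a$tail == "<S>", , drop = FALSE]
    want <- round(object@config@supply * object@config@integerScale)
    if (nrow(sArcs) && sum(sArcs$cap) != want)
        msg <- c(msg, "super-source capacities must sum to supply * integerScale")
    deg <- table(c(object@edges$from, object@edges$to))
    if (length(object@nodes) && !all(object@nodes %in% names(deg)))
        msg <- c(msg, "every retained gene must touch >= 1 retained edge")
    if (length(msg)) msg else TRUE
})

#' FlowSolution: an exact minimum-cost maximum-flow solution
#'
#' All exposed quantities are in supply units (integer flow divided by
#' \code{integerScale}); internal arc flows are integers, so conservation
#' holds exactly.
#'
#' @slot phenotype phenotype label inherited from the network.
#' @slot arcFlows data.frame \code{tail}, \code{head}, \code{flow} (integer
#'   units) for arcs carrying positive flow.
#' @slot nodeThroughput named numeric, total inflow per gene.
#' @slot terminalFlow named numeric, flow on each gene's terminal arc.
#' @slot totalEdgeFlow data.frame \code{from}, \code{to}, \code{flow}:
#'   f(u->v) + f(v->u) per undirected edge.
#' @slot edges the network's retained edge table (for degrees/motifs).
#' @slot objective total cost in (weight x supply) units.
#' @slot delivered flow reaching the super-sink, supply units.
#' @slot supply,integerScale copied from the network config.
#' @export
setClass("FlowSolution", representation(
    phenotype = "character", arcFlows = "data.frame",
    nodeThroughput = "numeric", terminalFlow = "numeric",
    totalEdgeFlow = "data.frame", edges = "data.frame",
    objective = "numeric", delivered = "numeric", supply = "numeric",
    integerScale = "numeric"))

#' SyntheticScenario: parameters of the two-phenotype generator
#'
#' See the methods vignette for the generative model.  Defaults define the
#' package's reference study conditions: 300 genes, preferential attachment
#' with m = 2, 50 samples per phenotype, baseline co-expression 0.3 on
#' interactome edges, a shared source-anchor backbone at 0.7, planted
#' rewired edges at 0.9 present only in phenotype B, 10 sources shifted by
#' delta = 2 log2 units.
#'
#' @slot nGenes,mAttach interactome size and preferential-attachment degree.
#' @slot nSamplesPerPhenotype samples drawn per phenotype (>= 10).
#' @slot baselineRho target co-expression on ordinary interactome edges.
#' @slot backboneRho shared source-anchor co-expression (both phenotypes).
#' @slot rhoHi co-expression of rewired edges in phenotype B.
#' @slot nSources number of planted differentially expressed sources.
#' @slot deltaShift mean shift of planted sources in B (log2 units).
#' @slot nRewiredPartners rewired first neighbors of the planted router
#'   (0 disables rewiring entirely).
#' @slot plantedRouter,plantedTarget gene symbols, or \code{NA} to
#'   auto-select from high-degree nodes.
#' @slot noiseSd residual noise multiplier.
#' @slot seed integer seed.
#' @export
setClass("SyntheticScenario", representation(
    nGenes = "numeric", mAttach = "numeric", nSamplesPerPhenotype = "numeric",
    baselineRho = "numeric", backboneRho = "numeric", rhoHi = "numeric",
    nSources = "numeric", deltaShift = "numeric", nRewiredPartners = "numeric",
    plantedRouter = "character", plantedTarget = "character",
    noiseSd = "numeric", seed = "numeric"))

setValidity("SyntheticScenario", function(object) {
    msg <- character()
    if (!(object@baselineRho > 0 && object@baselineRho < object@rhoHi &&
          object@rhoHi <= 0.99))
        msg <- c(msg, "need 0 < baselineRho < rhoHi <= 0.99")
    if (object@nSources >= object@nGenes)
        msg <- c(msg, "nSources must be < nGenes")
    if (object@nSamplesPerPhenotype < 10)
        msg <- c(msg, "need >= 10 samples per phenotype")
    if (!is.na(object@plantedRouter) && !is.na(object@plantedTarget) &&
        object@plantedRouter == object@plantedTarget)
        msg <- c(msg, "planted router and target must differ")
    if (length(msg)) msg else TRUE
})

#' Construct a SyntheticScenario
#' @param nGenes,mAttach,nSamplesPerPhenotype,baselineRho,backboneRho,rhoHi
#'   see \linkS4class{SyntheticScenario}.
#' @param nSources,deltaShift,nRewiredPartners,plantedRouter,plantedTarget
#'   see \linkS4class{SyntheticScenario}.
#' @param noiseSd,seed see \linkS4class{SyntheticScenario}.
#' @return A \linkS4class{SyntheticScenario}.
#' @examples
#' syntheticScenario(seed = 1)
#' @export
syntheticScenario <- function(nGenes = 300, mAttach = 2,
                              nSamplesPerPhenotype = 50, baselineRho = 0.3,
                              backboneRho = 0.7, rhoHi = 0.9, nSources = 10,
                              deltaShift = 2, nRewiredPartners = 3,
                              plantedRouter = NA_character_,
                              plantedTarget = NA_character_,
                              noiseSd = 1, seed = 1) {
    new("SyntheticScenario", nGenes = nGenes, mAttach = mAttach,
        nSamplesPerPhenotype = nSamplesPerPhenotype, baselineRho = baselineRho,
        backboneRho = backboneRho, rhoHi = rhoHi, nSources = nSources,
        deltaShift = deltaShift, nRewiredPartners = nRewiredPartners,
        plantedRouter = as.character(plantedRouter),
        plantedTarget = as.character(plantedTarget),
        noiseSd = noiseSd, seed = seed)
}

#' SyntheticTruth: the planted structure of a generated scenario
#'
#' @slot sources data.frame \code{gene}, \code{log2FC} of planted sources.
#' @slot router,target planted gene symbols.
#' @slot rewiredEdges data.frame \code{from}, \code{to}: edges with high
#'   co-expression only in phenotype B.
#' @slot backboneEdges data.frame \code{from}, \code{to}: shared
#'   source-anchor edges present in both phenotypes.
#' @slot seed the generator seed.
#' @export
setClass("SyntheticTruth", representation(
    sources = "data.frame", router = "character", target = "character",
    rewiredEdges = "data.frame", backboneEdges = "data.frame",
    seed = "numeric"))

#' PrioritizedSubnetwork: the compact phenotype-contrast subgraph
#'
#' @slot nodes node-role records (see \code{\link{classifyRoles}}) of member
#'   genes.
#' @slot edges edge-comparison records restricted to induced edges.
#' @slot counts named integer vector of member counts by role.
#' @export
setClass("PrioritizedSubnetwork", representation(
    nodes = "data.frame", edges = "data.frame", counts = "integer"))

setValidity("PrioritizedSubnetwork", function(object) {
    msg <- character()
    if (nrow(object@edges) &&
        !all(c(object@edges$from, object@edges$to) %in% object@nodes$gene))
        msg <- c(msg, "every edge endpoint must be a member node")
    if (nrow(object@nodes) &&
        sum(object@counts) != nrow(object@nodes))
        msg <- c(msg, "role counts must sum to the node count")
    if (length(msg)) msg else TRUE
})

#' MotifView: the first-neighbor subgraph around a gene in one phenotype
#'
#' @slot center the query gene.
#' @slot phenotype phenotype label.
#' @slot edges data.frame \code{from}, \code{to}, \code{w}, \code{flow} of
#'   incident retained edges with total edge flows.
#' @slot degree retained-edge degree of the center.
#' @export
setClass("MotifView", representation(
    center = "character", phenotype = "character", edges = "data.frame",
    degree = "integer"))
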