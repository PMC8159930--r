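#' Accessors for flowContrast classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an object.
#' @param ... passed to methods.
#' @return The accessed component; see the method-specific sections.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x, ...) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x, ...) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("exprValues", function(x, ...) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setGeneric("phenotypeLabels", function(x, ...) standardGeneric("phenotypeLabels"))
#' @rdname accessors
#' @export
setGeneric("interactomeEdges", function(x, ...) standardGeneric("interactomeEdges"))
#' @rdname accessors
#' @export
setGeneric("interactomeNodes", function(x, ...) standardGeneric("interactomeNodes"))
#' @rdname accessors
#' @export
setGeneric("geneSets", function(x, ...) standardGeneric("geneSets"))
#' @rdname accessors
#' @export
setGeneric("dependencyRecords", function(x, ...) standardGeneric("dependencyRecords"))
#' @rdname accessors
#' @export
setGeneric("sourceRecords", function(x, ...) standardGeneric("sourceRecords"))
#' @rdname accessors
#' @export
setGeneric("selectedSources", function(x, ...) standardGeneric("selectedSources"))
#' @rdname accessors
#' @export
setGeneric("networkArcs", function(x, ...) standardGeneric("networkArcs"))
#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x, ...) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setGeneric("nodeThroughput", function(x, ...) standardGeneric("nodeThroughput"))
#' @rdname accessors
#' @export
setGeneric("terminalFlow", function(x, ...) standardGeneric("terminalFlow"))
#' @rdname accessors
#' @export
setGeneric("totalEdgeFlow", function(x, ...) standardGeneric("totalEdgeFlow"))
#' @rdname accessors
#' @export
setGeneric("deliveredFlow", function(x, ...) standardGeneric("deliveredFlow"))
#' @rdname accessors
#' @export
setGeneric("flowObjective", function(x, ...) standardGeneric("flowObjective"))

#' Write a network to SIF or GraphML
#'
#' @param x a network-like object (\linkS4class{Interactome},
#'   \linkS4class{ContextFlowNetwork} or
#'   \linkS4class{PrioritizedSubnetwork}).
#' @param path output file path.
#' @param format \code{"SIF"} or \code{"GraphML"}.
#' @param ... passed to methods.
#' @return \code{path}, invisibly.
#' @export
setGeneric("writeNetwork",
    function(x, path, format = c("SIF", "GraphML"), ...)
        standardGeneric("writeNetwork"))

#' @rdname accessors
#' @export
setMethod("geneIds", "ExpressionMatrix", function(x, ...) rownames(x))
#' @rdname accessors
#' @export
setMethod("sampleIds", "ExpressionMatrix", function(x, ...) colnames(x))
#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionMatrix",
    function(x, ...) SummarizedExperiment::assay(x, "exprs"))
#' @rdname accessors
#' @export
setMethod("phenotypeLabels", "ExpressionMatrix", function(x, ...) {
    cd <- SummarizedExperiment::colData(x)
    if (!"phenotype" %in% names(cd)) return(NULL)
    setNames(cd$phenotype, rownames(cd))
})
#' @rdname accessors
#' @export
setMethod("geneIds", "Interactome",
    function(x, ...) sort(unique(c(x@edges$from, x@edges$to))))
#' @rdname accessors
#' @export
setMethod("interactomeEdges", "Interactome", function(x, ...) x@edges)
#' @rdname accessors
#' @export
setMethod("interactomeNodes", "Interactome",
    function(x, ...) sort(unique(c(x@edges$from, x@edges$to))))
#' @rdname accessors
#' @export
setMethod("geneSets", "GeneSetCollection", function(x, ...) x@sets)
#' @rdname accessors
#' @export
setMethod("dependencyRecords", "DependencyTable", function(x, ...) x@records)
#' @rdname accessors
#' @export
setMethod("sourceRecords", "SourceSet", function(x, ...) x@records)
#' @rdname accessors
#' @export
setMethod("selectedSources", "SourceSet",
    function(x, ...) x@records$gene[x@records$selected])
#' @rdname accessors
#' @export
setMethod("networkArcs", "ContextFlowNetwork", function(x, ...) x@arcs)
#' @rdname accessors
#' @export
setMethod("networkEdges", "ContextFlowNetwork", function(x, ...) x@edges)
#' @rdname accessors
#' @export
setMethod("geneIds", "ContextFlowNetwork", function(x, ...) x@nodes)
#' @rdname accessors
#' @export
setMethod("nodeThroughput", "FlowSolution", function(x, ...) x@nodeThroughput)
#' @rdname accessors
#' @export
setMethod("terminalFlow", "FlowSolution", function(x, ...) x@terminalFlow)
#' @rdname accessors
#' @export
setMethod("totalEdgeFlow", "FlowSolution", function(x, ...) x@totalEdgeFlow)
#' @rdname accessors
#' @export
setMethod("deliveredFlow", "FlowSolution", function(x, ...) x@delivered)
#' @rdname accessors
#' @export
setMethod("flowObjective", "FlowSolution", function(x, ...) x@objective)
#' @rdname accessors
#' @export
setMethod("networkEdges", "FlowSolution", function(x, ...) x@edges)

setMethod("show", "ExpressionMatrix", function(object) {
    ph <- phenotypeLabels(object)
    cat("ExpressionMatrix:", nrow(object), "genes x", ncol(object),
        "samples\n")
    if (!is.null(ph))
        cat("  phenotypes:", paste(sprintf("%s(%d)", names(table(ph)),
            table(ph)), collapse = ", "), "\n")
})

setMethod("show", "Interactome", function(object) {
    cat("Interactome:", nrow(object@edges), "undirected edges over",
        length(interactomeNodes(object)), "genes\n")
})

setMethod("show", "GeneSetCollection", function(object) {
    cat("GeneSetCollection:", length(object@sets), "sets;",
        "median size", stats::median(lengths(object@sets)), "\n")
})

setMethod("show", "DependencyTable", function(object) {
    r <- object@records
    cat("DependencyTable:", nrow(r), "records;",
        length(unique(r$gene)), "genes x", length(unique(r$cell_line)),
        "cell lines;", paste(unique(r$assay), collapse = "/"), "\n")
})

setMethod("show", "SourceSet", function(object) {
    cat("SourceSet:", nrow(object@records), "genes;",
        sum(object@records$selected), "selected",
        if (object@bypass) "(bypass mode)" else "", "\n")
})

setMethod("show", "StratifiedLabels", function(object) {
    cat("StratifiedLabels on", object@marker, "(median",
        format(object@medianValue), "):", length(object@high), "high /",
        length(object@low), "low\n")
})

setMethod("show", "ContextFlowNetwork", function(object) {
    cat("ContextFlowNetwork [", object@phenotype, "]: ",
        length(object@nodes), " genes, ", nrow(object@edges),
        " retained edges, ", nrow(object@sourceCaps), " sources, ",
        nrow(object@arcs), " arcs\n", sep = "")
})

setMethod("show", "FlowSolution", function(object) {
    cat("FlowSolution [", object@phenotype, "]: delivered ",
        format(object@delivered), " / ", format(object@supply),
        " supply units; objective ", format(object@objective), "\n", sep = "")
})

setMethod("show", "SyntheticScenario", function(object) {
    cat("SyntheticScenario:", object@nGenes, "genes,",
        object@nSamplesPerPhenotype, "samples/phenotype,",
        object@nSources, "sources (delta =", object@deltaShift,
        "), rhoHi =", object@rhoHi, ", seed =", object@seed, "\n")
})

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth: router", object@router, "; target", object@target,
        ";", nrow(object@sources), "sources;", nrow(object@rewiredEdges),
        "rewired edges\n")
})

setMethod("show", "PrioritizedSubnetwork", function(object) {
    cat("PrioritizedSubnetwork:", nrow(object@nodes), "genes (",
        paste(sprintf("%s: %d", names(object@counts), object@counts),
              collapse = ", "), ");", nrow(object@edges), "edges\n")
})

setMethod("show", "MotifView", function(object) {
    cat("MotifView [", object@phenotype, "] around ", object@center,
        ": degree ", object@degree, "\n", sep = "")
})
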