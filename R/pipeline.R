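.mergeConfig <- function(defaults, user) {
    for (nm in names(user)) {
        if (is.list(defaults[[nm]]) && is.list(user[[nm]]))
            defaults[[nm]] <- .mergeConfig(defaults[[nm]], user[[nm]])
        else defaults[[nm]] <- user[[nm]]
    }
    defaults
}

.defaultPipelineConfig <- function() {
    list(
        seed = 1,
        simulate = FALSE,
        scenario = list(),
        inputs = list(exprA = NULL, exprB = NULL, expr = NULL, marker = NULL,
                      interactome = NULL, phenotype_map = NULL,
                      log2_transform = FALSE),
        sources = list(lfc_min = 1, alpha = 0.05, gene_list = NULL),
        analysis = list(snf = 0.95, corThreshold = 0.5, ratioThreshold = 5,
                        supply = 1, epsilonTerminal = 0.01, terminalCost = 1,
                        costFloor = 1e-4, integerScale = 1e4,
                        topKRouters = 20, targetFraction = 0.05,
                        dependencyThreshold = -1),
        ora = list(gmt = NULL, reference = NULL),
        dependency = list(csv = NULL, assay = "CRISPR", simulate = FALSE)
    )
}

.writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
}

#' Run the full phenotype-contrast flow pipeline
#'
#' Orchestrates stratify/sources -> context-network build (A, B) -> flow ->
#' compare -> optional over-representation analysis -> optional dependency
#' integration -> flow-profile clustering, writing result tables, a
#' GraphML subnetwork and a reproducibility manifest to \code{out_dir}.
#' Rerunning with an identical configuration and seed reproduces all
#' outputs byte-for-byte.
#'
#' @param config a configuration list or path to a YAML file.  Top-level
#'   keys: \code{seed}; \code{simulate} (logical; use the synthetic
#'   generator) with \code{scenario} overrides; \code{inputs}
#'   (\code{exprA}/\code{exprB} paths, or \code{expr} plus \code{marker}
#'   for a median split, plus \code{interactome}); \code{sources}
#'   (\code{lfc_min}, \code{alpha}, optional \code{gene_list});
#'   \code{analysis} (any \linkS4class{AnalysisConfig} field);
#'   \code{ora} (\code{gmt}, \code{reference}); \code{dependency}
#'   (\code{csv}, \code{assay}, or \code{simulate}).
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the main in-memory results and the
#'   manifest.
#' @export
runPipeline <- function(config, out_dir) {
    if (is.character(config) && length(config) == 1)
        config <- yaml::read_yaml(config)
    cfg <- .mergeConfig(.defaultPipelineConfig(), config)
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    written <- character(0)
    stageCounts <- list()
    stage <- function(name, code) {
        t0 <- proc.time()[["elapsed"]]
        out <- tryCatch(force(code), error = function(e) {
            unlink(written)
            stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE)
        })
        message(sprintf("[%s] done in %.2fs", name,
                        proc.time()[["elapsed"]] - t0))
        out
    }
    ac <- do.call(AnalysisConfig,
                  c(cfg$analysis, list(seed = cfg$seed)))

    dat <- stage("inputs", {
        if (isTRUE(cfg$simulate)) {
            sc <- do.call(syntheticScenario,
                          c(cfg$scenario,
                            if (is.null(cfg$scenario$seed))
                                list(seed = cfg$seed) else NULL))
            ppi <- generateInteractome(sc@nGenes, sc@mAttach, sc@seed)
            sim <- generateTwoPhenotypeExpression(ppi, sc)
            list(exprA = sim$A, exprB = sim$B, interactome = ppi,
                 truth = sim$truth, scenario = sc)
        } else {
            inp <- cfg$inputs
            if (is.null(inp$interactome))
                stop("config must name an interactome (or set simulate: true)")
            ppi <- readInteractome(inp$interactome)
            if (!is.null(inp$expr) && !is.null(inp$marker)) {
                ex <- readExpressionMatrix(inp$expr, inp$phenotype_map,
                                           isTRUE(inp$log2_transform))
                lab <- splitByMarkerMedian(ex, inp$marker)
                list(exprA = ex[, lab@low], exprB = ex[, lab@high],
                     interactome = ppi, labels = lab)
            } else if (!is.null(inp$exprA) && !is.null(inp$exprB)) {
                list(exprA = readExpressionMatrix(inp$exprA, NULL,
                                                  isTRUE(inp$log2_transform)),
                     exprB = readExpressionMatrix(inp$exprB, NULL,
                                                  isTRUE(inp$log2_transform)),
                     interactome = ppi)
            } else stop("config must provide exprA/exprB or expr + marker")
        }
    })
    stageCounts$genes_A <- nrow(dat$exprA)
    stageCounts$genes_B <- nrow(dat$exprB)
    stageCounts$interactome_edges <- nrow(interactomeEdges(dat$interactome))

    srcSet <- stage("sources", {
        selectSources(dat$exprA, dat$exprB, lfc_min = cfg$sources$lfc_min,
                      alpha = cfg$sources$alpha,
                      gene_list = cfg$sources$gene_list)
    })
    stageCounts$sources_selected <- length(selectedSources(srcSet))
    written <- c(written,
                 .writeTsv(sourceRecords(srcSet), file.path(out_dir,
                                                            "sources.tsv")))

    nets <- stage("build", {
        exl <- list(A = dat$exprA, B = dat$exprB)
        lapply(setNames(names(exl), names(exl)), function(nm) {
            ex <- exl[[nm]]
            we <- edgeCoexpression(ex, dat$interactome)
            re <- applyCorThreshold(we, ac@corThreshold)
            nb <- functionalNeighborhood(ex, selectedSources(srcSet), ac@snf)
            ph <- unique(phenotypeLabels(ex))
            buildFlowNetwork(re, nb, srcSet, ac,
                             phenotype = if (length(ph)) ph[1] else nm)
        })
    })
    stageCounts$network_nodes <- vapply(nets, function(n) length(n@nodes), 0)
    stageCounts$network_edges <- vapply(nets, function(n) nrow(n@edges), 0)

    sols <- stage("flow", lapply(nets, solveMinCostFlow))
    stageCounts$delivered <- vapply(sols, deliveredFlow, 0)

    cmp <- stage("compare", {
        roles <- classifyRoles(sols$A, sols$B, srcSet, ac)
        edges <- keyEdges(sols$A, sols$B, ac)
        sub <- prioritizedSubnetwork(roles, edges, ac)
        diffs <- nodeFlowDifference(sols$A, sols$B)
        list(roles = roles, edges = edges, subnetwork = sub, diffs = diffs)
    })
    stageCounts$roles <- as.list(table(cmp$roles$role))
    stageCounts$key_edges <- sum(cmp$edges$key)
    written <- c(written,
        .writeTsv(cmp$roles, file.path(out_dir, "roles.tsv")),
        .writeTsv(cmp$edges, file.path(out_dir, "edges.tsv")),
        .writeTsv(cmp$diffs, file.path(out_dir, "node_flow_diff.tsv")),
        writeNetwork(cmp$subnetwork, file.path(out_dir, "subnetwork.graphml"),
                     "GraphML"))

    oraTab <- NULL
    if (!is.null(cfg$ora$gmt) && !is.null(cfg$ora$reference)) {
        oraTab <- stage("ora", {
            coll <- readGMT(cfg$ora$gmt)
            ref <- toupper(readLines(cfg$ora$reference))
            runORA(cmp$subnetwork@nodes$gene, coll, ref)
        })
        written <- c(written, .writeTsv(oraTab, file.path(out_dir, "ora.tsv")))
    }

    depTab <- NULL
    if (!is.null(cfg$dependency$csv) || isTRUE(cfg$dependency$simulate)) {
        depTab <- stage("dependency", {
            dt <- if (!is.null(cfg$dependency$csv))
                readDependencyTable(cfg$dependency$csv, cfg$dependency$assay)
            else
                generateDependencyTable(cmp$roles$gene,
                    sprintf("LINE%02d", 1:10),
                    essential_block = intersect(dat$truth@router,
                                                cmp$roles$gene),
                    seed = cfg$seed, assay = cfg$dependency$assay)
            fl <- flagDependencies(dt, cmp$roles$gene, ac@dependencyThreshold)
            summarizeByRole(fl, cmp$roles)
        })
        written <- c(written,
                     .writeTsv(depTab$genes, file.path(out_dir, "dep.tsv")))
    }

    clu <- stage("cluster", {
        fpm <- flowProfileMatrix(list(A = sols$A, B = sols$B))
        prof <- data.frame(gene = rownames(fpm), fpm, check.names = FALSE,
                           stringsAsFactors = FALSE)
        dn <- if (nrow(fpm) >= 2) upgmaCluster(fpm, "rows") else NULL
        list(profile = prof, dendrogram = dn)
    })
    written <- c(written, .writeTsv(clu$profile,
                                    file.path(out_dir, "flow_profile.tsv")))
    if (!is.null(clu$dendrogram)) {
        writeLines(clu$dendrogram$newick,
                   file.path(out_dir, "dendrogram.newick"))
        written <- c(written, file.path(out_dir, "dendrogram.newick"))
    }

    manifest <- list(
        tool = "flowContrast",
        version = as.character(utils::packageVersion("flowContrast")),
        seed = cfg$seed,
        config = cfg,
        inputs = if (isTRUE(cfg$simulate)) list(simulated = TRUE)
                 else lapply(Filter(Negate(is.null), cfg$inputs[
                     c("exprA", "exprB", "expr", "interactome")]),
                     function(p) unname(tools::md5sum(p))),
        stage_counts = stageCounts,
        outputs = as.list(tools::md5sum(sort(written)))
    )
    names(manifest$outputs) <- basename(names(manifest$outputs))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
    invisible(list(sources = srcSet, networks = nets, solutions = sols,
                   roles = cmp$roles, edges = cmp$edges,
                   subnetwork = cmp$subnetwork, ora = oraTab,
                   dependency = depTab, cluster = clu,
                   truth = dat$truth, manifest = manifest))
}

#' Validate a pipeline run manifest
#'
#' Checks that the manifest has the required fields and that every
#' recorded output file still exists next to it with a matching digest.
#'
#' @param path path to a \code{manifest.json}.
#' @return \code{TRUE} invisibly, or an error describing the mismatch.
#' @export
validateManifest <- function(path) {
    man <- jsonlite::read_json(path)
    need <- c("tool", "version", "seed", "config", "stage_counts", "outputs")
    miss <- setdiff(need, names(man))
    if (length(miss))
        stop("manifest missing field(s): ", paste(miss, collapse = ", "))
    dirn <- dirname(path)
    for (f in names(man$outputs)) {
        fp <- file.path(dirn, f)
        if (!file.exists(fp)) stop("manifest output missing: ", f)
        if (!identical(unname(tools::md5sum(fp)), man$outputs[[f]]))
            stop("digest mismatch for output: ", f)
    }
    invisible(TRUE)
}
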