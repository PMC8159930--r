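#' Read a gene x sample expression matrix from TSV
#'
#' The file must have a header row of sample IDs and gene symbols in the
#' first column.  Symbols are uppercased and duplicate gene rows collapsed
#' by their mean.  An optional two-column phenotype map (TSV with header:
#' sample, phenotype) attaches labels.
#'
#' @param path TSV file, genes in rows, samples in columns.
#' @param phenotype_map optional path to a two-column TSV (header required)
#'   mapping sample ID to phenotype label.
#' @param log2_transform set \code{TRUE} when the file holds linear-scale
#'   values (e.g. FPKM-UQ); \code{log2(x + 1)} is then applied.  Correlation
#'   is scale-sensitive, so the convention is explicit rather than guessed.
#' @return An \linkS4class{ExpressionMatrix}.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\tS1\tS2", "G1\t1\t2", "G2\t3\t4"), f)
#' readExpressionMatrix(f)
#' @export
readExpressionMatrix <- function(path, phenotype_map = NULL,
                                 log2_transform = FALSE) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    lines <- sub("\r$", "", lines)
    lines <- lines[nzchar(lines)]
    if (length(lines) < 2)
        stop("format error: expression file needs a header and >= 1 gene row")
    header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    samples <- header[-1]
    if (anyDuplicated(samples))
        stop("format error: duplicate sample ID(s): ",
             paste(unique(samples[duplicated(samples)]), collapse = ", "))
    body <- strsplit(lines[-1], "\t", fixed = TRUE)
    nfield <- lengths(body)
    if (any(nfield != length(header)))
        stop("format error: row ", which(nfield != length(header))[1] + 1,
             " has ", nfield[nfield != length(header)][1], " fields, expected ",
             length(header))
    genes <- toupper(vapply(body, `[`, character(1), 1L))
    vals <- matrix(NA_real_, length(genes), length(samples))
    for (j in seq_along(samples)) {
        cells <- vapply(body, `[`, character(1), j + 1L)
        num <- suppressWarnings(as.numeric(cells))
        bad <- which(is.na(num))
        if (length(bad))
            stop("parse error: non-numeric value '", cells[bad[1]],
                 "' at gene row '", genes[bad[1]], "', column '", samples[j],
                 "'")
        vals[, j] <- num
    }
    dimnames(vals) <- list(genes, samples)
    if (anyDuplicated(genes)) {
        vals <- rowsum(vals, group = genes) / as.vector(table(genes)[
            sort(unique(genes))])
    }
    vals <- vals[order(rownames(vals)), , drop = FALSE]
    if (log2_transform) vals <- log2(vals + 1)
    phen <- NULL
    if (!is.null(phenotype_map)) {
        pm <- utils::read.delim(phenotype_map, header = TRUE,
                                colClasses = "character")
        if (ncol(pm) < 2)
            stop("format error: phenotype map must have two columns")
        phen <- setNames(pm[[2]], pm[[1]])
    }
    ExpressionMatrix(vals, phenotype = phen)
}

#' Read an interactome from SIF or two-column TSV
#'
#' SIF lines are \code{"A <relation> B [C ...]"} (multiple targets allowed);
#' two-token lines are read as a tab-separated edge.  Edges are undirected
#' and deduplicated; self-loops are dropped with a reported count.
#'
#' @param path SIF or 2-column TSV file (no header).
#' @return An \linkS4class{Interactome}.
#' @examples
#' f <- tempfile(fileext = ".sif")
#' writeLines(c("A\tpp\tB", "B\tpp\tC"), f)
#' readInteractome(f)
#' @export
readInteractome <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- sub("\r$", "", readLines(path))
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) {
        warning("empty interactome file: ", path)
        return(Interactome())
    }
    from <- character(); to <- character()
    for (i in seq_along(lines)) {
        tok <- strsplit(lines[i], "[\t ]+")[[1]]
        tok <- tok[nzchar(tok)]
        if (length(tok) < 2)
            stop("format error: line ", i, " has fewer than 2 tokens")
        if (length(tok) == 2) {
            from <- c(from, tok[1]); to <- c(to, tok[2])
        } else {
            # SIF: source, relation, one or more targets
            from <- c(from, rep(tok[1], length(tok) - 2))
            to <- c(to, tok[-(1:2)])
        }
    }
    Interactome(from, to)
}

#' Read a GMT gene-set collection
#'
#' Each line is \code{name<TAB>description<TAB>gene1<TAB>gene2...}.
#' Duplicate genes within a set are deduplicated; duplicate set names are an
#' error.
#'
#' @param path GMT file.
#' @return A \linkS4class{GeneSetCollection}.
#' @export
readGMT <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- sub("\r$", "", readLines(path))
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(fields) < 3)
    if (length(short))
        stop("format error: line ", short[1], " has fewer than 3 fields")
    nm <- vapply(fields, `[`, character(1), 1L)
    if (anyDuplicated(nm))
        stop("duplicate set name: ",
             paste(unique(nm[duplicated(nm)]), collapse = ", "))
    sets <- lapply(fields, function(f) f[-(1:2)])
    names(sets) <- nm
    desc <- setNames(vapply(fields, `[`, character(1), 2L), nm)
    GeneSetCollection(sets, desc)
}

#' Read a DepMap-style gene-dependency table
#'
#' Accepts either the wide layout (rows = cell lines, columns = genes, with
#' DepMap-style \code{"SYMBOL (entrez)"} headers reduced to \code{SYMBOL})
#' or a long three-column layout (header: gene, cell_line, score).  Missing
#' value cells are skipped with a reported count.
#'
#' @param path CSV file.
#' @param assay \code{"RNAi"} (DEMETER2-style) or \code{"CRISPR"}
#'   (Avana-style).
#' @return A \linkS4class{DependencyTable}.
#' @export
readDependencyTable <- function(path, assay = c("CRISPR", "RNAi")) {
    assay <- match.arg(assay)
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                          colClasses = "character")
    if (ncol(df) == 3 &&
        all(tolower(names(df)) %in% c("gene", "cell_line", "score"))) {
        names(df) <- tolower(names(df))
        score <- suppressWarnings(as.numeric(df$score))
        bad <- which(is.na(score) & !is.na(df$score) & nzchar(df$score))
        if (length(bad))
            stop("parse error: unparseable score '", df$score[bad[1]],
                 "' at row ", bad[1], " (gene ", df$gene[bad[1]], ", line ",
                 df$cell_line[bad[1]], ")")
        keep <- !is.na(score)
        if (any(!keep))
            message(sum(!keep), " record(s) with missing scores skipped")
        rec <- data.frame(gene = df$gene[keep], cell_line = df$cell_line[keep],
                          score = score[keep], assay = assay,
                          stringsAsFactors = FALSE)
    } else {
        lines_cl <- df[[1]]
        genes <- sub("\\s*\\([0-9]+\\)\\s*$", "", names(df)[-1])
        rec_list <- vector("list", ncol(df) - 1)
        skipped <- 0L
        for (j in seq_along(genes)) {
            cells <- df[[j + 1]]
            score <- suppressWarnings(as.numeric(cells))
            bad <- which(is.na(score) & !is.na(cells) & nzchar(trimws(cells)) &
                         toupper(trimws(cells)) != "NA")
            if (length(bad))
                stop("parse error: unparseable score '", cells[bad[1]],
                     "' at cell line '", lines_cl[bad[1]], "', gene column '",
                     genes[j], "'")
            keep <- !is.na(score)
            skipped <- skipped + sum(!keep)
            rec_list[[j]] <- data.frame(gene = rep(genes[j], sum(keep)),
                                        cell_line = lines_cl[keep],
                                        score = score[keep],
                                        assay = rep(assay, sum(keep)),
                                        stringsAsFactors = FALSE)
        }
        if (skipped > 0)
            message(skipped, " record(s) with missing scores skipped")
        rec <- do.call(rbind, rec_list)
    }
    DependencyTable(rec)
}

.asIgraph <- function(x) {
    if (is(x, "Interactome")) {
        g <- igraph::graph_from_data_frame(x@edges, directed = FALSE)
    } else if (is(x, "ContextFlowNetwork")) {
        e <- x@edges
        g <- igraph::graph_from_data_frame(
            data.frame(from = e$from, to = e$to, weight = e$w),
            directed = FALSE)
    } else if (is(x, "PrioritizedSubnetwork")) {
        nd <- x@nodes
        ed <- x@edges
        vertices <- data.frame(name = nd$gene, role = nd$role,
                               flow_A = nd$flow_A, flow_B = nd$flow_B,
                               flow_diff = nd$flow_diff, impact = nd$impact)
        edges <- data.frame(from = ed$from, to = ed$to,
                            total_flow_A = ed$total_flow_A,
                            total_flow_B = ed$total_flow_B,
                            key = ed$key, exclusive = ed$exclusive)
        g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                           vertices = vertices)
    } else stop("unsupported network object of class ", class(x))
    g
}

.edgePairs <- function(x) {
    if (is(x, "Interactome") || is(x, "ContextFlowNetwork"))
        x@edges[, c("from", "to")]
    else if (is(x, "PrioritizedSubnetwork"))
        x@edges[, c("from", "to")]
    else stop("unsupported network object of class ", class(x))
}

#' @describeIn writeNetwork SIF uses the relation token \code{"pp"};
#'   GraphML (via igraph) carries node and edge attributes where the object
#'   provides them.
#' @export
setMethod("writeNetwork", "ANY", function(x, path,
                                          format = c("SIF", "GraphML"), ...) {
    if (is.character(format) && length(format) == 1 &&
        !format %in% c("SIF", "GraphML"))
        stop("unknown format '", format, "'; use \"SIF\" or \"GraphML\"")
    format <- match.arg(format)
    e <- .edgePairs(x)
    if (nrow(e) == 0) stop("cannot write an empty network")
    if (format == "SIF") {
        writeLines(paste(e$from, "pp", e$to, sep = "\t"), path)
    } else {
        g <- .asIgraph(x)
        igraph::write_graph(g, path, format = "graphml")
    }
    invisible(path)
})
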