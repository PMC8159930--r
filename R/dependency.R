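#' Flag gene dependencies from a screen table
#'
#' Per gene and assay, the median score across available cell lines is
#' compared to the threshold with a \emph{strict} less-than (a median of
#' exactly -1.0 is not flagged).  Genes absent from the table are reported
#' with \code{n_lines = 0} and \code{dependency = FALSE}.  The median is
#' chosen over the ambiguous per-line reading for robustness; per-line
#' counts below the threshold are also emitted.
#'
#' @param table a \linkS4class{DependencyTable}.
#' @param genes non-empty character vector of genes to assess.
#' @param threshold dependency threshold (default -1.0).
#' @return data.frame \code{gene}, \code{assay}, \code{n_lines},
#'   \code{n_lines_below}, \code{median_score}, \code{dependency}.
#' @export
flagDependencies <- function(table, genes, threshold = -1) {
    if (!length(genes)) stop("genes must be non-empty")
    genes <- unique(toupper(genes))
    r <- dependencyRecords(table)
    assays <- sort(unique(r$assay))
    if (!length(assays)) assays <- "CRISPR"
    grid <- expand.grid(gene = sort(genes), assay = assays,
                        stringsAsFactors = FALSE)
    res <- lapply(seq_len(nrow(grid)), function(i) {
        sub <- r[r$gene == grid$gene[i] & r$assay == grid$assay[i], ,
                 drop = FALSE]
        n <- nrow(sub)
        med <- if (n) stats::median(sub$score) else NA_real_
        data.frame(gene = grid$gene[i], assay = grid$assay[i], n_lines = n,
                   n_lines_below = sum(sub$score < threshold),
                   median_score = med,
                   dependency = n > 0 && med < threshold,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

#' Summarize dependency flags by network role
#'
#' @param flags output of \code{\link{flagDependencies}}.
#' @param roles output of \code{\link{classifyRoles}}.
#' @return A list with \code{summary} (role x assay contingency of flagged
#'   over total counts) and \code{genes} (the per-gene join, sorted by
#'   median score ascending: waterfall order).
#' @export
summarizeByRole <- function(flags, roles) {
    joined <- merge(flags, roles[, c("gene", "role", "flow_A", "flow_B",
                                     "flow_diff")], by = "gene")
    joined <- joined[order(joined$median_score, joined$gene), , drop = FALSE]
    rownames(joined) <- NULL
    combos <- unique(joined[, c("role", "assay")])
    summ <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
        sub <- joined[joined$role == combos$role[i] &
                      joined$assay == combos$assay[i], , drop = FALSE]
        data.frame(role = combos$role[i], assay = combos$assay[i],
                   n_flagged = sum(sub$dependency), n_total = nrow(sub),
                   stringsAsFactors = FALSE)
    }))
    if (is.null(summ))
        summ <- data.frame(role = character(), assay = character(),
                           n_flagged = integer(), n_total = integer())
    rownames(summ) <- NULL
    list(summary = summ[order(summ$role, summ$assay), , drop = FALSE],
         genes = joined)
}
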