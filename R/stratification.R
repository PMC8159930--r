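#' Stratify samples by a marker gene's median expression
#'
#' Samples with marker expression strictly greater than the median are
#' \code{high}; all others (including ties at the median) are \code{low}.
#' The strict-inequality tie rule makes "marker-high" mean unambiguously
#' above-median; the split is invariant to any strictly monotone transform
#' of the marker values.
#'
#' @param expr an \linkS4class{ExpressionMatrix} (>= 4 samples).
#' @param marker a gene present in \code{expr}.
#' @return A \linkS4class{StratifiedLabels}.
#' @examples
#' m <- matrix(c(1, 2, 3, 4), 1, 4,
#'             dimnames = list("CCN1", paste0("S", 1:4)))
#' splitByMarkerMedian(ExpressionMatrix(m), "CCN1")
#' @export
splitByMarkerMedian <- function(expr, marker) {
    marker <- toupper(marker)
    if (!marker %in% geneIds(expr))
        stop("marker gene '", marker, "' not found in expression matrix")
    if (ncol(expr) < 4)
        stop("need >= 4 samples to stratify")
    v <- exprValues(expr)[marker, ]
    if (max(v) == min(v))
        stop("degenerate stratification: marker '", marker,
             "' is constant across samples")
    med <- stats::median(v)
    new("StratifiedLabels", marker = marker, medianValue = med,
        high = names(v)[v > med], low = names(v)[v <= med])
}

# Welch two-sample t-test, closed form.  Zero pooled variance: p = 1 when
# the means agree (no evidence), 0 otherwise (infinite evidence).
.welch <- function(mA, mB, vA, vB, nA, nB) {
    se2 <- vA / nA + vB / nB
    diffs <- mB - mA
    p <- ifelse(se2 == 0, ifelse(diffs == 0, 1, 0), NA_real_)
    ok <- se2 > 0
    if (any(ok)) {
        tstat <- diffs[ok] / sqrt(se2[ok])
        df <- se2[ok]^2 / ((vA[ok] / nA)^2 / (nA - 1) +
                           (vB[ok] / nB)^2 / (nB - 1))
        p[ok] <- 2 * stats::pt(-abs(tstat), df)
    }
    p
}

#' Select differentially expressed source genes
#'
#' Per-gene log2 fold change (mean of phenotype B minus mean of A), Welch
#' two-sample t p-value and Benjamini-Hochberg q; a gene is selected when
#' \code{|log2FC| >= lfc_min} and \code{q <= alpha}.  A user-supplied
#' \code{gene_list} bypasses testing entirely (statistics \code{NA}, all
#' listed genes selected), mirroring the use of published differential
#' expression lists as flow sources.
#'
#' @param exprA,exprB \linkS4class{ExpressionMatrix} objects for the two
#'   phenotypes (>= 2 samples each) sharing a gene universe.
#' @param lfc_min minimum absolute log2 fold change (default 1).
#' @param alpha FDR cutoff (default 0.05).
#' @param gene_list optional character vector: bypass mode.
#' @return A \linkS4class{SourceSet}.
#' @export
selectSources <- function(exprA, exprB, lfc_min = 1, alpha = 0.05,
                          gene_list = NULL) {
    if (!is.null(gene_list)) {
        g <- unique(toupper(gene_list))
        rec <- data.frame(gene = g, log2FC = NA_real_, p = NA_real_,
                          q = NA_real_, selected = TRUE,
                          stringsAsFactors = FALSE)
        return(new("SourceSet", records = rec, bypass = TRUE))
    }
    if (ncol(exprA) < 2 || ncol(exprB) < 2)
        stop("each phenotype needs >= 2 samples")
    common <- intersect(geneIds(exprA), geneIds(exprB))
    if (!length(common)) stop("no common genes between phenotypes")
    common <- sort(common)
    a <- exprValues(exprA)[common, , drop = FALSE]
    b <- exprValues(exprB)[common, , drop = FALSE]
    mA <- rowMeans(a); mB <- rowMeans(b)
    vA <- apply(a, 1, stats::var); vB <- apply(b, 1, stats::var)
    p <- .welch(mA, mB, vA, vB, ncol(a), ncol(b))
    q <- stats::p.adjust(p, method = "BH")
    lfc <- mB - mA
    rec <- data.frame(gene = common, log2FC = lfc, p = p, q = q,
                      selected = abs(lfc) >= lfc_min & q <= alpha,
                      stringsAsFactors = FALSE)
    rownames(rec) <- NULL
    if (!any(rec$selected))
        warning("no gene passed lfc_min = ", lfc_min, ", alpha = ", alpha)
    new("SourceSet", records = rec, bypass = FALSE)
}

#' Correlate two genes across samples
#'
#' Rank (Spearman) or linear (Pearson) correlation with a two-sided
#' p-value.
#'
#' @param expr an \linkS4class{ExpressionMatrix} (>= 4 samples).
#' @param geneX,geneY genes present in \code{expr}.
#' @param method \code{"spearman"} (default, the rho convention) or
#'   \code{"pearson"}.
#' @return A list with \code{estimate} and \code{p.value}.
#' @export
markerCorrelation <- function(expr, geneX, geneY,
                              method = c("spearman", "pearson")) {
    method <- match.arg(method)
    geneX <- toupper(geneX); geneY <- toupper(geneY)
    miss <- setdiff(c(geneX, geneY), geneIds(expr))
    if (length(miss)) stop("gene(s) not found: ", paste(miss, collapse = ", "))
    if (ncol(expr) < 4) stop("need >= 4 samples")
    x <- exprValues(expr)[geneX, ]
    y <- exprValues(expr)[geneY, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("zero variance: cannot correlate a constant gene")
    ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                           exact = FALSE))
    list(estimate = unname(ct$estimate), p.value = ct$p.value)
}
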