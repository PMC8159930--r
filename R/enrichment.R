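.logSumExp <- function(x) {
    m <- max(x)
    m + log(sum(exp(x - m)))
}

#' Exact hypergeometric over-representation test
#'
#' Upper-tail probability of drawing at least \code{k} set members in a
#' query of size \code{n} from a reference universe of size \code{N}
#' containing \code{K} set members:
#' \deqn{p = \sum_{i=k}^{\min(n,K)} \binom{K}{i}\binom{N-K}{n-i} /
#'   \binom{N}{n}.}
#' Query and set are restricted to the reference before counting; the tail
#' sum is evaluated in log space so it does not underflow at
#' genome-scale N.
#'
#' @param query character vector of query genes.
#' @param gene_set character vector of set genes.
#' @param reference character vector: the gene universe.
#' @param set_name optional label carried into the result.
#' @return One-row data.frame with \code{set_name}, \code{k}, \code{n},
#'   \code{K}, \code{N}, \code{p}, \code{enrichment_ratio} =
#'   \code{(k/n)/(K/N)}.
#' @examples
#' hypergeometricORA(LETTERS[1:5], LETTERS[3:8], LETTERS)
#' @export
hypergeometricORA <- function(query, gene_set, reference,
                              set_name = NA_character_) {
    reference <- unique(toupper(reference))
    query <- intersect(unique(toupper(query)), reference)
    gene_set <- intersect(unique(toupper(gene_set)), reference)
    if (length(query) == 0)
        stop("empty query after restriction to the reference")
    if (length(gene_set) == 0)
        stop("empty gene set after restriction to the reference")
    N <- length(reference); n <- length(query); K <- length(gene_set)
    k <- length(intersect(query, gene_set))
    if (k == 0) {
        p <- 1
    } else {
        i <- k:min(n, K)
        p <- min(1, exp(.logSumExp(lchoose(K, i) + lchoose(N - K, n - i) -
                                   lchoose(N, n))))
    }
    data.frame(set_name = set_name, k = k, n = n, K = K, N = N, p = p,
               enrichment_ratio = (k / n) / (K / N),
               stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up BH with monotonicity enforcement, order-preserving
#' with the input (via \code{stats::p.adjust}); inputs outside [0, 1] are
#' an error.
#'
#' @param pvalues numeric vector of p-values.
#' @return q-values in input order.
#' @export
bhAdjust <- function(pvalues) {
    if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(pvalues, method = "BH")
}

#' Over-representation analysis against a gene-set collection
#'
#' One exact hypergeometric test per set with at least one member in the
#' reference, Benjamini-Hochberg adjustment across exactly those tests,
#' and results sorted by q ascending then enrichment ratio descending.
#'
#' @param query character vector of query genes.
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param reference character vector: the gene universe (a required
#'   explicit input; genome reference sets are version-dependent and never
#'   bundled).
#' @return data.frame with one row per tested set: \code{set_name},
#'   \code{k}, \code{n}, \code{K}, \code{N}, \code{p}, \code{q},
#'   \code{enrichment_ratio}, \code{neg_log10_fdr}.
#' @export
runORA <- function(query, collection, reference) {
    sets <- geneSets(collection)
    if (!length(sets)) stop("collection must be non-empty")
    reference <- unique(toupper(reference))
    testable <- names(sets)[vapply(sets, function(g)
        length(intersect(toupper(g), reference)) >= 1, logical(1))]
    if (!length(testable))
        stop("no set overlaps the reference universe")
    rows <- lapply(testable, function(nm)
        hypergeometricORA(query, sets[[nm]], reference, set_name = nm))
    out <- do.call(rbind, rows)
    out$q <- bhAdjust(out$p)
    out$neg_log10_fdr <- -log10(out$q)
    out <- out[order(out$q, -out$enrichment_ratio, out$set_name), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}
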