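#' @include AllClasses.R
NULL

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X` hypergeometric: the probability of drawing at least
#' `k` pathway genes when sampling `n` genes without replacement from a
#' background of `N` genes of which `K` belong to the pathway. Computed via
#' [stats::phyper] (numerically stable in log space). Vectorized over `k`.
#'
#' @param k observed overlap(s).
#' @param n input list size.
#' @param K pathway size within the background.
#' @param N background size.
#' @return p-value(s) in (0, 1].
#' @export
hypergeometricTail <- function(k, n, K, N) {
    if (any(k < 0) || any(k > pmin(n, K)) || K > N || n > N || N < 0)
        stop("invalid counts: need 0 <= k <= min(n, K) and n, K <= N")
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Pathway over-representation analysis of a gene list
#'
#' Hypergeometric over-representation test of a candidate gene list against
#' each pathway in a collection. The background universe defaults to all
#' genes annotated to at least one pathway in the collection. Gene ids are
#' matched case-insensitively after trimming whitespace; candidates outside
#' the background are dropped with a warning. One row is reported per
#' pathway with at least one candidate; `passes` marks pathways meeting
#' both reporting filters (`k >= minOverlap` and `p < pCutoff`).
#' `bh` optionally adds Benjamini-Hochberg adjusted p-values (the filters
#' still use the raw p-value).
#'
#' @param genes candidate gene ids.
#' @param collection a [PathwayCollection].
#' @param background optional background gene universe.
#' @param minOverlap minimum overlap filter (default 3).
#' @param pCutoff raw p-value cutoff (default 0.01).
#' @param bh add a `p_adjust` column (default `FALSE`).
#' @return a `data.frame` sorted by p-value with columns `pathway_id`,
#'   `pathway_name`, `pathway_size` (K), `overlap` (k), `input_size` (n),
#'   `background_size` (N), `candidate_pct` (100*k/K, one decimal),
#'   `p_value`, `passes` (and `p_adjust` when `bh = TRUE`).
#' @export
runOra <- function(genes, collection, background = NULL, minOverlap = 3,
                   pCutoff = 0.01, bh = FALSE) {
    stopifnot(is(collection, "PathwayCollection"))
    norm <- function(x) tolower(trimws(x))
    sets <- lapply(geneSets(collection), norm)
    if (is.null(background)) background <- unique(unlist(sets))
    background <- unique(norm(background))
    if (!length(background)) stop("background universe is empty")
    genes <- unique(norm(genes))
    outside <- setdiff(genes, background)
    if (length(outside)) {
        warning(sprintf("dropping %d candidate gene(s) not in the background",
                        length(outside)))
        genes <- setdiff(genes, outside)
    }
    n <- length(genes)
    N <- length(background)
    rows <- lapply(seq_along(sets), function(i) {
        members <- intersect(sets[[i]], background)
        K <- length(members)
        k <- length(intersect(genes, members))
        if (k < 1L) return(NULL)
        p <- hypergeometricTail(k, n, K, N)
        data.frame(pathway_id = pathwayIds(collection)[i],
                   pathway_name = pathwayNames(collection)[i],
                   pathway_size = K, overlap = k, input_size = n,
                   background_size = N,
                   candidate_pct = round(100 * k / K, 1),
                   p_value = p,
                   passes = k >= minOverlap && p < pCutoff)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        return(data.frame(pathway_id = character(), pathway_name = character(),
                          pathway_size = integer(), overlap = integer(),
                          input_size = integer(), background_size = integer(),
                          candidate_pct = numeric(), p_value = numeric(),
                          passes = logical()))
    out <- out[order(out$p_value, out$pathway_id), ]
    if (bh) out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
    rownames(out) <- NULL
    out
}
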