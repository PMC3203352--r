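## Candidate-edge reservoir: a multiset of unordered gene pairs whose copy
## numbers encode the prior linkage probability, max(1, Ceil(10 p_link)).
## The MCMC proposal draws pairs with probability proportional to their
## copies and orients them uniformly at random (p_link is undirected).

#' Build the candidate-edge reservoir
#'
#' Copy numbers follow `Ceil(10 * p_link)` with a floor of one copy, so
#' every pair appears at least once and at most 10 times.
#'
#' @param pLinkTable data.frame with columns `gene_a`, `gene_b` and
#'   `p_link` (e.g. the output of [pairFeatures()] plus [pLink()]), or a
#'   named numeric vector is not accepted -- pairs must be explicit.
#' @return An [EdgeReservoir-class].
#' @examples
#' tab <- data.frame(gene_a = c("a", "a"), gene_b = c("b", "c"),
#'                   p_link = c(0.35, 1.0))
#' reservoirCopies(buildReservoir(tab))   # 4 and 10
#' @export
buildReservoir <- function(pLinkTable) {
    if (nrow(pLinkTable) == 0L) stop("empty p_link table")
    p <- pLinkTable$p_link
    stopifnot(!is.null(p), all(p >= 0), all(p <= 1))
    a <- as.character(pLinkTable$gene_a)
    b <- as.character(pLinkTable$gene_b)
    swap <- a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    if (anyDuplicated(paste(a, b))) stop("duplicated pairs in p_link table")
    copies <- pmax(1L, as.integer(ceiling(10 * p)))
    new("EdgeReservoir", pairs = cbind(gene_a = a, gene_b = b),
        pLink = as.numeric(p), copies = copies)
}

#' Build a uniform (plain-BN) reservoir over all gene pairs
#'
#' One copy per pair: the proposal distribution of the plain Bayesian
#' network learner without prior knowledge.
#'
#' @param genes character vector of gene identifiers.
#' @return An [EdgeReservoir-class] with one copy per unordered pair.
#' @export
uniformReservoir <- function(genes) {
    stopifnot(length(genes) >= 2L)
    idx <- utils::combn(sort(genes), 2L)
    buildReservoir(data.frame(gene_a = idx[1L, ], gene_b = idx[2L, ],
                              p_link = 0, stringsAsFactors = FALSE))
}

#' Draw directed candidate edges from the reservoir
#'
#' Each draw selects an unordered pair with probability proportional to its
#' copy number, then orients it uniformly at random. Deterministic under
#' `set.seed()`.
#'
#' @param res an [EdgeReservoir-class].
#' @param n number of draws (default 1).
#' @return Character matrix (n x 2) of directed edges `from`, `to`.
#' @export
sampleEdge <- function(res, n = 1L) {
    pairs <- reservoirPairs(res)
    idx <- sample.int(nrow(pairs), n, replace = TRUE,
                      prob = reservoirCopies(res))
    flip <- stats::runif(n) < 0.5
    from <- ifelse(flip, pairs[idx, 2L], pairs[idx, 1L])
    to <- ifelse(flip, pairs[idx, 1L], pairs[idx, 2L])
    cbind(from = from, to = to)
}

#' Dump a reservoir as TSV (for audit)
#'
#' @param res an [EdgeReservoir-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeReservoir <- function(res, path) {
    utils::write.table(
        data.frame(gene_a = reservoirPairs(res)[, 1L],
                   gene_b = reservoirPairs(res)[, 2L],
                   p_link = res@pLink, copies = reservoirCopies(res)),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
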