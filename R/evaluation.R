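## Benchmark evaluation: recovered-edge counts against curated references,
## ROC/AUC of edge scores, 2x2 chi-square enrichment comparisons, and
## between-run consistency diagnostics.

#' Size of the possible-regulation universe
#'
#' Directed: `n (n - 1)` ordered pairs. Undirected: `n (n - 1) / 2`.
#' With `nRegulators` given, only regulator -> other-gene pairs count:
#' `nRegulators (n - 1)` (a TF can target any other gene).
#'
#' @param nGenes gene count.
#' @param directed count ordered pairs? Default `TRUE`.
#' @param nRegulators optional number of possible source nodes.
#' @return Integer count.
#' @examples
#' pairUniverseSize(76)                    # 5700
#' pairUniverseSize(107, directed = FALSE) # 5671
#' pairUniverseSize(107, nRegulators = 9)  # 954
#' @export
pairUniverseSize <- function(nGenes, directed = TRUE, nRegulators = NULL) {
    stopifnot(nGenes >= 2L)
    if (!is.null(nRegulators)) {
        stopifnot(nRegulators >= 1L, nRegulators <= nGenes)
        return(as.integer(nRegulators) * (as.integer(nGenes) - 1L))
    }
    n <- as.integer(nGenes)
    if (directed) n * (n - 1L) else (n * (n - 1L)) %/% 2L
}

.edgeKeys <- function(edges, directed) {
    edges <- as.matrix(edges)
    if (nrow(edges) == 0L) return(character(0))
    if (directed) paste(edges[, 1L], edges[, 2L], sep = "\r")
    else unique(.pairKey(edges[, 1L], edges[, 2L]))
}

#' Compare a predicted edge set to a benchmark
#'
#' In undirected mode both sets are canonicalized before intersecting
#' (appropriate for references that do not resolve direction, e.g.
#' protein-protein interaction annotations); in directed mode orientation
#' must match (e.g. TF -> target binding data).
#'
#' @param predicted two-column matrix of predicted edges.
#' @param benchmark two-column matrix of reference edges (non-empty).
#' @param directed respect edge orientation? Default `TRUE`.
#' @param possibleTotal size of the pair universe (see
#'   [pairUniverseSize()]); used for the random-selection baseline.
#' @return list with `truePositives`, `predictedTotal`, `benchmarkTotal`,
#'   `possibleTotal`, and `expectedRandom` (the closed-form expectation
#'   `predictedTotal * benchmarkTotal / possibleTotal` of true positives
#'   under random selection).
#' @export
compareToBenchmark <- function(predicted, benchmark, directed = TRUE,
                               possibleTotal) {
    if (is.null(benchmark) || nrow(as.matrix(benchmark)) == 0L)
        stop("benchmark must be non-empty")
    kp <- unique(.edgeKeys(predicted, directed))
    kb <- .edgeKeys(benchmark, directed)
    tp <- length(intersect(kp, kb))
    list(truePositives = tp, predictedTotal = length(kp),
         benchmarkTotal = length(kb), possibleTotal = possibleTotal,
         expectedRandom = length(kp) * length(kb) / possibleTotal)
}

#' ROC curve and AUC of an edge score
#'
#' Sensitivity versus 1 - specificity under a sweep over the unique score
#' values, higher scores ranking first; tied scores enter together. The
#' AUC is the trapezoidal integral, identical to the rank (concordance)
#' statistic with tie correction, so a random scoring gives 0.5.
#'
#' @param scoresPos scores of the positive edges.
#' @param scoresNeg scores of the negative edges.
#' @return list with `points` (data.frame `fpr`, `tpr`, from (0,0) to
#'   (1,1)) and `auc`.
#' @examples
#' rocAuc(scoresPos = c(0.9, 0.8, 0.4), scoresNeg = c(0.5, 0.3, 0.1))
#' @export
rocAuc <- function(scoresPos, scoresNeg) {
    stopifnot(length(scoresPos) > 0L, length(scoresNeg) > 0L)
    thr <- sort(unique(c(scoresPos, scoresNeg)), decreasing = TRUE)
    tpr <- c(0, vapply(thr, function(t) mean(scoresPos >= t), 0))
    fpr <- c(0, vapply(thr, function(t) mean(scoresNeg >= t), 0))
    auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
    list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Wraps [stats::chisq.test()] on the table `rbind(c(a, b), c(c, d))`, with
#' or without the Yates continuity correction. Both margins must be
#' positive; otherwise the test is undefined and `NA`s are returned with a
#' warning.
#'
#' @param a,b,c,d non-negative cell counts (first row a, b; second c, d).
#' @param yates apply the continuity correction? Default `TRUE`.
#' @return list with `statistic` and `p_value`.
#' @examples
#' chiSquare2x2(20, 30, 30, 20, yates = FALSE)   # statistic 4
#' @export
chiSquare2x2 <- function(a, b, c, d, yates = TRUE) {
    tab <- rbind(c(a, b), c(c, d))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
        warning("zero margin: chi-square undefined")
        return(list(statistic = NA_real_, p_value = NA_real_))
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = yates))
    list(statistic = unname(ct$statistic), p_value = unname(ct$p.value))
}

#' Recovery report for one method versus baselines
#'
#' Builds the 2x2 enrichment comparisons used to judge a method: recovered
#' versus missed benchmark edges for this method against a comparator
#' (another method, or the closed-form random-selection baseline). The
#' 2x2 table is (recovered, predicted-but-not-benchmark) per method.
#'
#' @param eval result of [compareToBenchmark()] for the method.
#' @param evalOther result for the comparator (for the random baseline use
#'   `randomBaselineEval(eval)`).
#' @param yates continuity correction flag, passed through.
#' @return list with both uncorrected and Yates-corrected statistics.
#' @export
enrichmentVs <- function(eval, evalOther, yates = TRUE) {
    a <- eval$truePositives
    b <- eval$predictedTotal - eval$truePositives
    c2 <- evalOther$truePositives
    d <- evalOther$predictedTotal - evalOther$truePositives
    list(plain = chiSquare2x2(a, b, round(c2), round(d), yates = FALSE),
         yates = chiSquare2x2(a, b, round(c2), round(d), yates = yates))
}

#' Expected performance of random edge selection
#'
#' Closed-form expectation: drawing `predictedTotal` edges uniformly from
#' the universe recovers `predictedTotal * benchmarkTotal / possibleTotal`
#' benchmark edges on average.
#'
#' @param eval result of [compareToBenchmark()].
#' @return An eval-like list for use with [enrichmentVs()].
#' @export
randomBaselineEval <- function(eval) {
    list(truePositives = eval$expectedRandom,
         predictedTotal = eval$predictedTotal,
         benchmarkTotal = eval$benchmarkTotal,
         possibleTotal = eval$possibleTotal,
         expectedRandom = eval$expectedRandom)
}

#' Empirical random-selection baseline
#'
#' Draws `predictedTotal` distinct directed edges uniformly at random from
#' the `nGenes (nGenes - 1)` universe and counts benchmark hits, repeated
#' `nReplicates` times.
#'
#' @param genes gene identifiers of the universe.
#' @param predictedTotal edges per draw.
#' @param benchmark two-column benchmark edge matrix.
#' @param directed orientation flag (see [compareToBenchmark()]).
#' @param nReplicates number of random draws (default 1000).
#' @return Numeric vector of hit counts, one per replicate.
#' @export
randomSelectionBaseline <- function(genes, predictedTotal, benchmark,
                                    directed = TRUE, nReplicates = 1000L) {
    n <- length(genes)
    all <- expand.grid(from = genes, to = genes,
                       stringsAsFactors = FALSE)
    all <- all[all$from != all$to, ]
    kb <- .edgeKeys(benchmark, directed)
    vapply(seq_len(nReplicates), function(r) {
        idx <- sample.int(nrow(all), predictedTotal)
        kp <- unique(.edgeKeys(all[idx, ], directed))
        length(intersect(kp, kb))
    }, numeric(1))
}

#' Between-run consistency of averaged networks
#'
#' Pearson correlation of the off-diagonal weight vectors for every pair
#' of runs; reports their mean and standard deviation. Pairs involving a
#' constant weight vector are excluded with a warning.
#'
#' @param runs list of [AveragedNetwork-class] (or [ChainRun-class])
#'   objects of identical shape.
#' @return list with `mean`, `sd` and the vector of pairwise
#'   `correlations`.
#' @export
runConsistency <- function(runs) {
    ws <- lapply(runs, function(r)
        if (is(r, "ChainRun")) edgeWeights(averagedNetwork(r))
        else edgeWeights(r))
    stopifnot(length(ws) >= 2L)
    off <- lapply(ws, function(w) w[row(w) != col(w)])
    cors <- c()
    for (a in seq_along(off)[-length(off)]) {
        for (b in seq((a + 1L), length(off))) {
            if (stats::sd(off[[a]]) == 0 || stats::sd(off[[b]]) == 0) {
                warning("constant weight vector in run pair (", a, ",",
                        b, "); excluded")
                next
            }
            cors <- c(cors, stats::cor(off[[a]], off[[b]]))
        }
    }
    if (length(cors) == 0L)
        return(list(mean = NA_real_, sd = NA_real_,
                    correlations = numeric(0)))
    list(mean = mean(cors), sd = if (length(cors) > 1L) stats::sd(cors)
         else 0, correlations = cors)
}
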