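## Prior-knowledge linkage model: GO information-content similarity,
## hypergeometric co-citation significance, their fusion into p_link with a
## naive Bayes classifier, and the LLS evidence-utility score.

#' Ancestor closure of every ontology term
#'
#' @param onto an [OntologyDAG-class].
#' @return Named list: term -> character vector of ancestors, including the
#'   term itself.
#' @export
termAncestors <- function(onto) {
    ord <- .topoOrder(ontoTerms(onto), termParents(onto))
    anc <- vector("list", length(ord))
    names(anc) <- ord
    for (t in ord) {
        up <- termParents(onto)[[t]]
        anc[[t]] <- unique(c(t, unlist(anc[up], use.names = FALSE)))
    }
    anc[ontoTerms(onto)]
}

## Per-term annotation frequency f(t): number of genes annotated to t or to
## any descendant of t (i.e. genes whose ancestor-closed annotation set
## contains t). Returns the frequency vector plus the closed per-gene sets.
.annotationFrequencies <- function(onto, ann, ancestors = NULL) {
    if (is.null(ancestors)) ancestors <- termAncestors(onto)
    closed <- lapply(ann, function(ts)
        unique(unlist(ancestors[ts], use.names = FALSE)))
    counts <- table(unlist(closed, use.names = FALSE))
    f <- stats::setNames(integer(length(ontoTerms(onto))), ontoTerms(onto))
    f[names(counts)] <- as.integer(counts)
    list(freq = f, closed = closed,
         nAnnotated = sum(lengths(closed) > 0L))
}

#' Information content of ontology terms
#'
#' \eqn{IC(t) = -\ln(f(t) / G)} where \eqn{f(t)} is the number of genes
#' annotated to `t` or any of its descendants and `G` is the total number
#' of annotated genes (the root frequency for a single-root ontology, so
#' `IC(root) = 0`). Terms annotating no gene have undefined IC (`NA`) and
#' contribute no information to similarities.
#'
#' @param onto an [OntologyDAG-class].
#' @param ann named list: gene -> character vector of annotated terms.
#' @param term optional term id(s); default all terms.
#' @return Named numeric vector of IC values (`NA` where undefined).
#' @examples
#' onto <- OntologyDAG(list(root = character(0), a = "root", b = "a"))
#' ann <- list(g1 = "b", g2 = "a", g3 = "root")
#' termInformationContent(onto, ann)
#' @export
termInformationContent <- function(onto, ann, term = NULL) {
    fr <- .annotationFrequencies(onto, ann)
    ic <- ifelse(fr$freq > 0L, -log(fr$freq / fr$nAnnotated), NA_real_)
    names(ic) <- names(fr$freq)
    if (is.null(term)) ic else {
        if (!all(term %in% names(ic))) stop("unknown term(s)")
        ic[term]
    }
}

## Lin-form term-pair similarity given IC vector and ancestor closure:
## sim(s,t) = 2 IC(MICA) / (IC(s) + IC(t)), 0 when the denominator is 0.
.termSimilarity <- function(s, t, ic, ancestors) {
    common <- intersect(ancestors[[s]], ancestors[[t]])
    if (!length(common)) return(0)
    mica <- suppressWarnings(max(ic[common], na.rm = TRUE))
    denom <- ic[[s]] + ic[[t]]
    if (!is.finite(mica) || is.na(denom) || denom <= 0) return(0)
    2 * mica / denom
}

#' GO semantic similarity between two genes
#'
#' Normalized shared-information-content similarity: each term pair `(s,t)`
#' across the two genes' annotation sets scores
#' \eqn{2\,IC(MICA(s,t)) / (IC(s) + IC(t))} (MICA = most informative common
#' ancestor), and the gene-pair similarity is the maximum over all term
#' pairs. The value lies in \[0,1\]: 1 when both genes share an informative
#' annotation, 0 when their only common ancestor is the root (or either
#' gene is unannotated).
#'
#' @param onto an [OntologyDAG-class].
#' @param ann named list: gene -> terms.
#' @param geneA,geneB gene identifiers.
#' @return Similarity in \[0,1\].
#' @export
pairGOSimilarity <- function(onto, ann, geneA, geneB) {
    ancestors <- termAncestors(onto)
    fr <- .annotationFrequencies(onto, ann, ancestors)
    ic <- ifelse(fr$freq > 0L, -log(fr$freq / fr$nAnnotated), NA_real_)
    names(ic) <- names(fr$freq)
    .geneSimilarity(ann[[geneA]], ann[[geneB]], ic, ancestors)
}

.geneSimilarity <- function(termsA, termsB, ic, ancestors) {
    if (is.null(termsA) || is.null(termsB) ||
        length(termsA) == 0L || length(termsB) == 0L) return(0)
    best <- 0
    for (s in termsA) for (t in termsB) {
        v <- .termSimilarity(s, t, ic, ancestors)
        if (v > best) best <- v
    }
    min(best, 1)
}

#' Hypergeometric co-citation p-value
#'
#' Upper-tail probability of observing `k` or more shared abstracts by
#' chance, when one gene appears in `n` of `N` abstracts and the other in
#' `m`. Computed with the log-space hypergeometric tail, so large corpora
#' are safe. `k = 0` gives 1 by the empty-sum convention; a `k` exceeding
#' `min(n, m)` is impossible overlap and returns 0 with a warning.
#'
#' @param k shared-abstract count.
#' @param n,m per-gene abstract counts.
#' @param N corpus size.
#' @return p-value in \[0,1\].
#' @examples
#' cocitationPValue(2, 3, 3, 10)   # 22/120
#' @export
cocitationPValue <- function(k, n, m, N) {
    stopifnot(k >= 0, n >= 0, m >= 0, n <= N, m <= N, N > 0)
    if (k > min(n, m)) {
        warning("k exceeds min(n, m): impossible overlap, returning 0")
        return(0)
    }
    if (k == 0) return(1)
    stats::phyper(k - 1, n, N - n, m, lower.tail = FALSE)
}

#' Bin the two prior-knowledge features
#'
#' GO similarity falls into one of `[1,1]`, `[0.2,1)`, `[0,0.2)`;
#' co-citation significance is binned on the \eqn{-\log_{10}(p)} scale into
#' `(4,inf)`, `(3,4]`, `(1,3]`, `[0,1]`. Vectorized.
#'
#' @param goSim similarity values in \[0,1\].
#' @param pPubmed co-citation p-values in (0,1\].
#' @return data.frame with character columns `go_bin` and `pubmed_bin`.
#' @export
binFeatures <- function(goSim, pPubmed) {
    stopifnot(all(goSim >= 0 & goSim <= 1), all(pPubmed > 0 & pPubmed <= 1))
    goBin <- ifelse(goSim == 1, .GO_BINS[1L],
             ifelse(goSim >= 0.2, .GO_BINS[2L], .GO_BINS[3L]))
    nl <- -log10(pPubmed)
    pmBin <- ifelse(nl > 4, .PUBMED_BINS[1L],
             ifelse(nl > 3, .PUBMED_BINS[2L],
             ifelse(nl > 1, .PUBMED_BINS[3L], .PUBMED_BINS[4L])))
    data.frame(go_bin = goBin, pubmed_bin = pmBin,
               stringsAsFactors = FALSE)
}

#' Compute prior-knowledge features for gene pairs
#'
#' For every pair: GO similarity, co-citation p-value, and their bins.
#' Unannotated genes get similarity 0 (lowest GO bin); uncited genes force
#' `k = 0` hence p = 1 (lowest PubMed bin).
#'
#' @param onto an [OntologyDAG-class].
#' @param ann named list: gene -> terms.
#' @param cit a [CitationIndex-class].
#' @param pairs two-column character matrix of gene pairs (order ignored;
#'   features are symmetric).
#' @return data.frame with columns `gene_a`, `gene_b`, `go_sim`,
#'   `p_pubmed`, `go_bin`, `pubmed_bin`.
#' @export
pairFeatures <- function(onto, ann, cit, pairs) {
    pairs <- as.matrix(pairs)
    ancestors <- termAncestors(onto)
    fr <- .annotationFrequencies(onto, ann, ancestors)
    ic <- ifelse(fr$freq > 0L, -log(fr$freq / fr$nAnnotated), NA_real_)
    names(ic) <- names(fr$freq)
    N <- totalAbstracts(cit)
    goSim <- numeric(nrow(pairs))
    pv <- numeric(nrow(pairs))
    for (r in seq_len(nrow(pairs))) {
        a <- pairs[r, 1L]; b <- pairs[r, 2L]
        goSim[r] <- .geneSimilarity(ann[[a]], ann[[b]], ic, ancestors)
        absA <- geneAbstracts(cit, a); absB <- geneAbstracts(cit, b)
        pv[r] <- cocitationPValue(length(intersect(absA, absB)),
                                  length(absA), length(absB), N)
    }
    cbind(data.frame(gene_a = pairs[, 1L], gene_b = pairs[, 2L],
                     go_sim = goSim, p_pubmed = pv,
                     stringsAsFactors = FALSE),
          binFeatures(goSim, pv))
}

## look up feature rows for a set of canonical pairs; error on gaps
.featureRows <- function(features, pairs) {
    keys <- .pairKey(features$gene_a, features$gene_b)
    want <- .pairKey(pairs[, 1L], pairs[, 2L])
    idx <- match(want, keys)
    if (anyNA(idx))
        stop(sum(is.na(idx)), " benchmark pair(s) missing from the ",
             "feature table")
    idx
}

#' Train the naive Bayes functional-linkage classifier
#'
#' Conditional bin frequencies for both classes are estimated from the
#' benchmark pairs with additive (Laplace) smoothing; the class prior
#' defaults to the benchmark's positive proportion and can be overridden
#' (useful when the benchmark is a subsample whose class balance is
#' arbitrary).
#'
#' @param features feature table from [pairFeatures()] covering at least
#'   every benchmark pair.
#' @param bench a [BenchmarkSet-class].
#' @param smoothing additive pseudocount (> 0; default 1).
#' @param classPriorOverride optional prior probability of linkage in (0,1).
#' @return A [LinkageModel-class].
#' @export
trainLinkageModel <- function(features, bench, smoothing = 1,
                              classPriorOverride = NULL) {
    stopifnot(smoothing > 0)
    pos <- benchmarkPositives(bench)
    neg <- benchmarkNegatives(bench)
    fpos <- features[.featureRows(features, pos), , drop = FALSE]
    fneg <- features[.featureRows(features, neg), , drop = FALSE]
    condRow <- function(levelsv, f) {
        counts <- table(factor(f, levels = levelsv))
        (as.numeric(counts) + smoothing) /
            (sum(counts) + smoothing * length(levelsv))
    }
    condGO <- rbind(linked = condRow(.GO_BINS, fpos$go_bin),
                    unlinked = condRow(.GO_BINS, fneg$go_bin))
    colnames(condGO) <- .GO_BINS
    condPM <- rbind(linked = condRow(.PUBMED_BINS, fpos$pubmed_bin),
                    unlinked = condRow(.PUBMED_BINS, fneg$pubmed_bin))
    colnames(condPM) <- .PUBMED_BINS
    prior <- if (is.null(classPriorOverride))
        nrow(pos) / (nrow(pos) + nrow(neg)) else classPriorOverride
    new("LinkageModel", classPrior = prior, condGO = condGO,
        condPubMed = condPM, smoothing = smoothing)
}

#' Posterior functional-linkage probability
#'
#' Naive Bayes posterior \eqn{P(L \mid go\_bin, pubmed\_bin)}. Strictly
#' inside (0,1) thanks to smoothing, and symmetric in gene order by
#' construction (the features are pair-symmetric). Vectorized over bins.
#'
#' @param model a [LinkageModel-class].
#' @param goBin,pubmedBin bin labels (see [goBins()], [pubmedBins()]), or
#'   pass a feature data.frame as `goBin` to use its `go_bin`/`pubmed_bin`
#'   columns.
#' @return Numeric vector of posterior probabilities.
#' @export
pLink <- function(model, goBin, pubmedBin = NULL) {
    if (is.data.frame(goBin)) {
        pubmedBin <- goBin$pubmed_bin
        goBin <- goBin$go_bin
    }
    stopifnot(all(goBin %in% .GO_BINS), all(pubmedBin %in% .PUBMED_BINS))
    lgL <- log(model@classPrior) + log(model@condGO["linked", goBin]) +
        log(model@condPubMed["linked", pubmedBin])
    lgU <- log(1 - model@classPrior) +
        log(model@condGO["unlinked", goBin]) +
        log(model@condPubMed["unlinked", pubmedBin])
    unname(1 / (1 + exp(lgU - lgL)))
}

#' Log-likelihood score (LLS) of an evidence-selected pair set
#'
#' \eqn{LLS = \ln\frac{P(L|D)/P(\sim L|D)}{P(L)/P(\sim L)}} where `D`
#' selects a subset of pairs (e.g. all pairs in one evidence bin) and the
#' probabilities are estimated from smoothed benchmark counts. 0 means the
#' selection is no more informative than random pairing; positive values
#' mean enrichment for linked pairs.
#'
#' @param selected two-column matrix of pairs "linked by the data".
#' @param bench a [BenchmarkSet-class].
#' @param smoothing additive pseudocount (default 1).
#' @return The LLS value; `NA` (with a warning) when no benchmark pair is
#'   selected.
#' @export
computeLLS <- function(selected, bench, smoothing = 1) {
    pos <- benchmarkPositives(bench)
    neg <- benchmarkNegatives(bench)
    kp <- .pairKey(pos[, 1L], pos[, 2L])
    kn <- .pairKey(neg[, 1L], neg[, 2L])
    selected <- as.matrix(selected)
    ks <- if (nrow(selected)) .pairKey(selected[, 1L], selected[, 2L])
          else character(0)
    posD <- sum(kp %in% ks)
    negD <- sum(kn %in% ks)
    if (posD + negD == 0L) {
        warning("no benchmark pairs selected; LLS undefined")
        return(NA_real_)
    }
    log((posD + smoothing) / (negD + smoothing)) -
        log((length(kp) + smoothing) / (length(kn) + smoothing))
}

#' Per-bin LLS table for both evidence types
#'
#' Applies [computeLLS()] to every GO-similarity bin and every co-citation
#' bin of a feature table, yielding a per-bin evidence-utility summary.
#'
#' @param features feature table from [pairFeatures()].
#' @param bench a [BenchmarkSet-class].
#' @param smoothing additive pseudocount.
#' @return data.frame with columns `evidence`, `bin`, `lls`, `n_selected`.
#' @export
llsTable <- function(features, bench, smoothing = 1) {
    rows <- list()
    for (b in .GO_BINS) {
        sel <- features[features$go_bin == b, c("gene_a", "gene_b")]
        rows[[length(rows) + 1L]] <- data.frame(
            evidence = "go_similarity", bin = b,
            lls = suppressWarnings(computeLLS(sel, bench, smoothing)),
            n_selected = nrow(sel), stringsAsFactors = FALSE)
    }
    for (b in .PUBMED_BINS) {
        sel <- features[features$pubmed_bin == b, c("gene_a", "gene_b")]
        rows[[length(rows) + 1L]] <- data.frame(
            evidence = "cocitation", bin = b,
            lls = suppressWarnings(computeLLS(sel, bench, smoothing)),
            n_selected = nrow(sel), stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
}

#' Dependence between the two evidence types
#'
#' Pearson correlation between GO similarity and \eqn{-\log_{10}} of the
#' co-citation p-value across the benchmark pairs, with Fisher's
#' z-transform test against zero (\eqn{z = \mathrm{atanh}(r)\sqrt{n-3}}).
#' Strong dependence would violate the naive Bayes independence assumption.
#'
#' @param features feature table from [pairFeatures()].
#' @param bench a [BenchmarkSet-class]; the test uses the union of its
#'   pairs.
#' @return list with elements `correlation`, `z`, `p_value`, `n`.
#' @export
attributeDependence <- function(features, bench) {
    pairs <- rbind(benchmarkPositives(bench), benchmarkNegatives(bench))
    if (nrow(pairs) < 4L) stop("need at least 4 benchmark pairs")
    f <- features[.featureRows(features, pairs), , drop = FALSE]
    x <- f$go_sim
    y <- -log10(f$p_pubmed)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        warning("constant feature; correlation undefined")
        return(list(correlation = NA_real_, z = NA_real_,
                    p_value = NA_real_, n = nrow(f)))
    }
    r <- stats::cor(x, y)
    n <- nrow(f)
    if (abs(r) >= 1) {
        z <- sign(r) * Inf
        p <- 0
    } else {
        z <- atanh(r) * sqrt(n - 3)
        p <- 2 * stats::pnorm(-abs(z))
    }
    list(correlation = r, z = z, p_value = p, n = n)
}

#' Write a pair-feature/p_link table to TSV
#'
#' @param features feature table from [pairFeatures()], optionally with a
#'   `p_link` column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(features, path) {
    utils::write.table(features, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
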