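## Synthetic study generator: a heavy-tailed regulator->target topology, a
## kinetic (Hill-type, lag-1) expression simulator with correlated root
## inputs and multiplicative log-normal noise, and prior-knowledge fixtures
## (ontology + annotations + citations) with planted signal for linked
## pairs. Defaults are the reference simulated-study conditions:
## 76 genes / 24 regulators / 124 edges / 50 time points / 50% correlated
## inputs.

#' Generate a synthetic regulatory topology
#'
#' Regulators are drawn at random; each receives one initial target, and
#' the remaining edges attach to regulators with probability proportional
#' to out-degree + 1 (preferential attachment), yielding the heavy-tailed
#' out-degree distribution characteristic of transcriptional networks.
#' No self-loops, no duplicate or antiparallel edges; signs are assigned
#' uniformly at random.
#'
#' @param nGenes,nRegulators,nEdges topology parameters (defaults 76, 24,
#'   124, the reference simulated-network condition).
#' @param seed RNG seed.
#' @return A [SyntheticNetwork-class] with exactly `nEdges` edges.
#' @export
generateNetwork <- function(nGenes = 76L, nRegulators = 24L,
                            nEdges = 124L, seed = 1L) {
    stopifnot(nRegulators < nGenes, nEdges >= nRegulators)
    if (nEdges > nRegulators * (nGenes - 1L) - choose(nRegulators, 2L))
        stop("infeasible: too many edges for this gene/regulator count")
    set.seed(seed)
    genes <- sprintf("g%03d", seq_len(nGenes))
    regs <- sort(sample(genes, nRegulators))
    edges <- matrix(character(0), 0L, 2L)
    keys <- character(0)
    addEdge <- function(from, to) {
        edges <<- rbind(edges, c(from, to))
        keys <<- c(keys, paste(from, to))
    }
    ok <- function(from, to) {
        from != to && !(paste(from, to) %in% keys) &&
            !(paste(to, from) %in% keys)
    }
    for (r in regs) {       # out-degree >= 1 for every regulator
        repeat {
            t <- sample(genes, 1L)
            if (ok(r, t)) { addEdge(r, t); break }
        }
    }
    outdeg <- stats::setNames(rep(1, nRegulators), regs)
    while (nrow(edges) < nEdges) {
        r <- sample(regs, 1L, prob = outdeg + 1)
        t <- sample(genes, 1L)
        if (ok(r, t)) {
            addEdge(r, t)
            outdeg[[r]] <- outdeg[[r]] + 1
        }
    }
    signs <- sample(c("activation", "repression"), nEdges, replace = TRUE)
    dimnames(edges) <- list(NULL, c("from", "to"))
    new("SyntheticNetwork", geneNames = genes, regulators = regs,
        edges = edges, signs = signs)
}

#' Simulate a kinetic expression time course
#'
#' Discrete-time dynamics on the topology: a regulated gene's level at
#' time `t` is the mean of saturating Hill responses (coefficient
#' `hill`, half-saturation `K`) to its regulators' levels at `t - 1`
#' (activators increase, repressors decrease the response). Unregulated
#' genes follow smooth sinusoidal trajectories with random period and
#' phase; a fraction of them additionally track a shared driver
#' ("correlated inputs"). Multiplicative log-normal noise with standard
#' deviation `noiseSd` is applied to every measurement.
#'
#' @param net a [SyntheticNetwork-class].
#' @param nTimepoints number of time points (default 50).
#' @param noiseSd log-scale noise SD (default 0.1).
#' @param correlatedInputFraction fraction of unregulated genes following
#'   the common driver (default 0.5).
#' @param hill Hill coefficient (default 2).
#' @param K half-saturation constant (default 0.5).
#' @param seed RNG seed.
#' @return A `SummarizedExperiment` (assay `"exprs"`, genes x time).
#' @export
simulateExpression <- function(net, nTimepoints = 50L, noiseSd = 0.1,
                               correlatedInputFraction = 0.5, hill = 2,
                               K = 0.5, seed = 1L) {
    stopifnot(nTimepoints >= 2L)
    set.seed(seed)
    genes <- networkGenes(net)
    n <- length(genes)
    edges <- networkEdges(net)
    signs <- net@signs
    regsOf <- split(seq_len(nrow(edges)), edges[, 2L])
    tt <- seq_len(nTimepoints)
    smoothTraj <- function() {
        period <- stats::runif(1, nTimepoints / 5, nTimepoints)
        phase <- stats::runif(1)
        0.5 + 0.4 * sin(2 * pi * (tt / period + phase))
    }
    driver <- smoothTraj()
    x <- matrix(0, n, nTimepoints, dimnames = list(genes, NULL))
    rooted <- !(genes %in% names(regsOf))
    for (g in which(rooted)) {
        own <- smoothTraj()
        x[g, ] <- if (stats::runif(1) < correlatedInputFraction)
            0.8 * driver + 0.2 * own else own
    }
    x[!rooted, 1L] <- stats::runif(sum(!rooted))
    hillUp <- function(v) v^hill / (K^hill + v^hill)
    for (t in 2L:nTimepoints) {
        for (g in genes[!rooted]) {
            ei <- regsOf[[g]]
            resp <- vapply(ei, function(e) {
                v <- x[edges[e, 1L], t - 1L]
                if (signs[e] == "activation") hillUp(v) else 1 - hillUp(v)
            }, numeric(1))
            x[match(g, genes), t] <- mean(resp)
        }
    }
    if (noiseSd > 0)
        x <- x * exp(matrix(stats::rnorm(n * nTimepoints, 0, noiseSd),
                            n, nTimepoints))
    colnames(x) <- sprintf("t%02d", tt)
    SummarizedExperiment::SummarizedExperiment(assays = list(exprs = x))
}

#' Generate prior-knowledge fixtures with planted signal
#'
#' Builds a random rooted term tree, baseline leaf annotations, and a
#' citation corpus, then plants signal: each truly linked gene pair (an
#' edge of `net`, undirected) shares a randomly chosen deep term with
#' probability `qLinked` (versus `qUnlinked` for unlinked pairs), and
#' receives extra shared abstracts at Poisson rate `lambdaCo`.
#'
#' @param net a [SyntheticNetwork-class].
#' @param qLinked,qUnlinked deep-term sharing probabilities (defaults 0.7
#'   and 0.05; `qLinked > qUnlinked` required).
#' @param lambdaCo mean extra shared abstracts per linked pair (default 2).
#' @param nTerms ontology size (default 80).
#' @param nAbstracts corpus size `N` (default 10000).
#' @param meanCitations mean abstracts per gene (default 20).
#' @param seed RNG seed.
#' @return list with `ontology` ([OntologyDAG-class]), `annotations`
#'   (named list) and `citations` ([CitationIndex-class]).
#' @export
generatePriorKnowledge <- function(net, qLinked = 0.7, qUnlinked = 0.05,
                                   lambdaCo = 2, nTerms = 80L,
                                   nAbstracts = 10000L,
                                   meanCitations = 20, seed = 1L) {
    stopifnot(qLinked >= qUnlinked, lambdaCo >= 0, nTerms >= 10L)
    set.seed(seed)
    genes <- networkGenes(net)
    terms <- sprintf("T%04d", seq_len(nTerms))
    parents <- stats::setNames(vector("list", nTerms), terms)
    parents[[1L]] <- character(0)
    depth <- stats::setNames(integer(nTerms), terms)
    for (i in 2L:nTerms) {
        p <- sample(seq_len(i - 1L), 1L)
        parents[[i]] <- terms[p]
        depth[i] <- depth[p] + 1L
    }
    onto <- OntologyDAG(parents)
    hasChild <- terms %in% unlist(parents, use.names = FALSE)
    leaves <- terms[!hasChild]
    deep <- terms[depth >= max(2L, stats::quantile(depth, 0.5))]
    if (length(deep) == 0L) deep <- terms[depth == max(depth)]
    ann <- lapply(stats::setNames(genes, genes), function(g)
        sample(leaves, sample(1:3, 1L)))
    linked <- unique(t(apply(networkEdges(net), 1L, sort)))
    linkedKeys <- paste(linked[, 1L], linked[, 2L])
    for (r in seq_len(nrow(linked))) {
        if (stats::runif(1) < qLinked) {
            tm <- sample(deep, 1L)
            ann[[linked[r, 1L]]] <- unique(c(ann[[linked[r, 1L]]], tm))
            ann[[linked[r, 2L]]] <- unique(c(ann[[linked[r, 2L]]], tm))
        }
    }
    if (qUnlinked > 0) {
        cmb <- utils::combn(genes, 2L)
        unlinkedIdx <- which(!(paste(cmb[1L, ], cmb[2L, ]) %in% linkedKeys))
        hits <- unlinkedIdx[stats::runif(length(unlinkedIdx)) < qUnlinked]
        for (ui in hits) {
            tm <- sample(deep, 1L)
            a <- cmb[1L, ui]; b <- cmb[2L, ui]
            ann[[a]] <- unique(c(ann[[a]], tm))
            ann[[b]] <- unique(c(ann[[b]], tm))
        }
    }
    abstracts <- sprintf("A%06d", seq_len(nAbstracts))
    cit <- lapply(stats::setNames(genes, genes), function(g) {
        k <- min(nAbstracts, stats::rpois(1L, meanCitations))
        sample(abstracts, k)
    })
    for (r in seq_len(nrow(linked))) {
        extra <- stats::rpois(1L, lambdaCo)
        if (extra > 0L) {
            shared <- sample(abstracts, extra)
            a <- linked[r, 1L]; b <- linked[r, 2L]
            cit[[a]] <- unique(c(cit[[a]], shared))
            cit[[b]] <- unique(c(cit[[b]], shared))
        }
    }
    list(ontology = onto, annotations = ann,
         citations = CitationIndex(cit, nAbstracts),
         params = list(qLinked = qLinked, qUnlinked = qUnlinked,
                       lambdaCo = lambdaCo, nTerms = nTerms,
                       nAbstracts = nAbstracts))
}

#' Benchmark set derived from a synthetic network
#'
#' Positives are the true edges (as unordered pairs); negatives are a
#' random sample of unlinked pairs.
#'
#' @param net a [SyntheticNetwork-class].
#' @param nNegatives number of negative pairs (default: three times the
#'   positives, mimicking a sparse-linkage benchmark).
#' @param seed RNG seed.
#' @return A [BenchmarkSet-class].
#' @export
benchmarkFromNetwork <- function(net, nNegatives = NULL, seed = 1L) {
    set.seed(seed)
    linked <- unique(t(apply(networkEdges(net), 1L, sort)))
    genes <- networkGenes(net)
    cmb <- utils::combn(genes, 2L)
    keys <- paste(cmb[1L, ], cmb[2L, ])
    unl <- which(!(keys %in% paste(linked[, 1L], linked[, 2L])))
    if (is.null(nNegatives)) nNegatives <- 3L * nrow(linked)
    nNegatives <- min(nNegatives, length(unl))
    pick <- sample(unl, nNegatives)
    benchmarkSet(linked, cbind(cmb[1L, pick], cmb[2L, pick]))
}

#' Full p_link table for a gene universe
#'
#' Convenience pipeline: features for all unordered pairs, classifier
#' training on the benchmark, and the posterior `p_link` per pair --
#' ready for [buildReservoir()].
#'
#' @param onto,ann,cit prior-knowledge inputs (see [pairFeatures()]).
#' @param genes gene universe (all unordered pairs are scored).
#' @param bench a [BenchmarkSet-class] for training.
#' @param smoothing,classPriorOverride passed to [trainLinkageModel()].
#' @return The feature data.frame with an extra `p_link` column, plus the
#'   fitted model in attribute `"model"`.
#' @export
pLinkTable <- function(onto, ann, cit, genes, bench, smoothing = 1,
                       classPriorOverride = NULL) {
    cmb <- utils::combn(sort(genes), 2L)
    features <- pairFeatures(onto, ann, cit, cbind(cmb[1L, ], cmb[2L, ]))
    model <- trainLinkageModel(features, bench, smoothing,
                               classPriorOverride)
    features$p_link <- pLink(model, features)
    attr(features, "model") <- model
    features
}

#' Write the full synthetic fixture set to a directory
#'
#' Files: `expression.tsv`, `ontology.obo`, `annotations.tsv`,
#' `citations.tsv` (+ `.total` sidecar with `N`), `true_edges.tsv`.
#'
#' @param dir output directory (created if needed).
#' @param nGenes,nRegulators,nEdges,nTimepoints,seed generator settings.
#' @param ... further arguments to [generatePriorKnowledge()].
#' @return `dir`, invisibly.
#' @export
writeFixtures <- function(dir, nGenes = 76L, nRegulators = 24L,
                          nEdges = 124L, nTimepoints = 50L, seed = 1L,
                          ...) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    net <- generateNetwork(nGenes, nRegulators, nEdges, seed = seed)
    se <- simulateExpression(net, nTimepoints, seed = seed + 1L)
    pk <- generatePriorKnowledge(net, seed = seed + 2L, ...)
    writeExpression(se, file.path(dir, "expression.tsv"))
    writeOBO(pk$ontology, file.path(dir, "ontology.obo"))
    ann <- pk$annotations
    utils::write.table(
        data.frame(gene = rep(names(ann), lengths(ann)),
                   term = unlist(ann, use.names = FALSE)),
        file.path(dir, "annotations.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
    cl <- pk$citations@citations
    utils::write.table(
        data.frame(gene = rep(names(cl), lengths(cl)),
                   abstract = unlist(cl, use.names = FALSE)),
        file.path(dir, "citations.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
    writeLines(as.character(totalAbstracts(pk$citations)),
               file.path(dir, "citations.tsv.total"))
    utils::write.table(networkEdges(net), file.path(dir, "true_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    invisible(dir)
}

#' Write an OntologyDAG in the minimal OBO dialect
#'
#' @param onto an [OntologyDAG-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeOBO <- function(onto, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("format-version: 1.2", con)
    for (t in ontoTerms(onto)) {
        writeLines(c("", "[Term]", paste0("id: ", t)), con)
        for (p in termParents(onto)[[t]])
            writeLines(paste0("is_a: ", p), con)
    }
    invisible(path)
}
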