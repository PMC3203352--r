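#' @import methods
#' @importFrom stats setNames
NULL

## Fixed evidence-bin labels used by the naive Bayes linkage classifier.
## GO similarity is binned on its raw [0,1] scale; co-citation on -log10(p).
.GO_BINS <- c("[1,1]", "[0.2,1)", "[0,0.2)")
.PUBMED_BINS <- c("(4,inf)", "(3,4]", "(1,3]", "[0,1]")

#' Evidence bin labels
#'
#' Bin labels used for the two prior-knowledge features: Gene Ontology
#' semantic similarity (three bins on the raw similarity scale) and PubMed
#' co-citation significance (four bins on the \eqn{-\log_{10}(p)} scale).
#'
#' @return A character vector of bin labels, ordered from strongest to
#'   weakest evidence.
#' @examples
#' goBins()
#' pubmedBins()
#' @export
goBins <- function() .GO_BINS

#' @rdname goBins
#' @export
pubmedBins <- function() .PUBMED_BINS

## ---------------------------------------------------------------------------
## OntologyDAG
## ---------------------------------------------------------------------------

#' OntologyDAG: a rooted acyclic term graph
#'
#' Container for an ontology (GO-like) term graph. Each term stores its set
#' of parent terms; terms with no parents are roots. The graph must be
#' acyclic, which the validity method enforces by topological sorting.
#'
#' @slot terms character vector of term identifiers.
#' @slot parents named list, one entry per term, each a character vector of
#'   parent term identifiers (empty for roots).
#' @slot roots character vector of terms with no parents.
#'
#' @seealso [readOBO()], [termAncestors()], [termInformationContent()]
#' @export
setClass("OntologyDAG",
    representation(terms = "character", parents = "list",
                   roots = "character"))

.topoOrder <- function(terms, parents) {
    ## Kahn's algorithm on the child->parent graph; returns NULL on a cycle,
    ## otherwise the terms in an order where parents precede children.
    indeg <- lengths(parents)[terms]
    children <- vector("list", length(terms))
    names(children) <- terms
    for (t in terms) {
        for (p in parents[[t]]) children[[p]] <- c(children[[p]], t)
    }
    queue <- terms[indeg == 0L]
    out <- character(0)
    while (length(queue)) {
        t <- queue[[1L]]; queue <- queue[-1L]
        out <- c(out, t)
        for (ch in children[[t]]) {
            indeg[[ch]] <- indeg[[ch]] - 1L
            if (indeg[[ch]] == 0L) queue <- c(queue, ch)
        }
    }
    if (length(out) != length(terms)) NULL else out
}

setValidity("OntologyDAG", function(object) {
    msgs <- character(0)
    if (length(object@terms) == 0L)
        msgs <- c(msgs, "ontology must contain at least one term")
    if (anyDuplicated(object@terms))
        msgs <- c(msgs, "duplicated term identifiers")
    if (!setequal(names(object@parents), object@terms))
        msgs <- c(msgs, "parents list must be named by exactly the terms")
    allp <- unique(unlist(object@parents, use.names = FALSE))
    if (length(allp) && !all(allp %in% object@terms))
        msgs <- c(msgs, "parent terms missing from the term set")
    if (!setequal(object@roots,
                  object@terms[lengths(object@parents[object@terms]) == 0L]))
        msgs <- c(msgs, "roots must be exactly the terms without parents")
    if (length(msgs) == 0L &&
        is.null(.topoOrder(object@terms, object@parents)))
        msgs <- c(msgs, "term graph contains a cycle")
    if (length(msgs)) msgs else TRUE
})

#' Construct an OntologyDAG
#'
#' @param parents named list mapping each term to a character vector of its
#'   parent terms (use `character(0)` for roots). Terms that appear only as
#'   parents are added with no parents of their own.
#' @return An [OntologyDAG-class] object.
#' @examples
#' onto <- OntologyDAG(list(root = character(0), a = "root", b = "a"))
#' ontoRoots(onto)
#' @export
OntologyDAG <- function(parents) {
    stopifnot(is.list(parents))
    extra <- setdiff(unique(unlist(parents, use.names = FALSE)),
                     names(parents))
    for (t in extra) parents[[t]] <- character(0)
    terms <- names(parents)
    new("OntologyDAG", terms = terms, parents = parents,
        roots = terms[lengths(parents) == 0L])
}

#' @describeIn OntologyDAG-class term identifiers
#' @param object,x an `OntologyDAG`
#' @export
ontoTerms <- function(object) object@terms

#' @describeIn OntologyDAG-class root terms (no parents)
#' @export
ontoRoots <- function(object) object@roots

#' @describeIn OntologyDAG-class named list of parent sets
#' @export
termParents <- function(object) object@parents

setMethod("show", "OntologyDAG", function(object) {
    cat("OntologyDAG with", length(object@terms), "terms,",
        length(object@roots), "root(s)\n")
})

## ---------------------------------------------------------------------------
## CitationIndex
## ---------------------------------------------------------------------------

#' CitationIndex: gene-to-abstract literature index
#'
#' Maps genes to the set of literature abstracts citing them, together with
#' the total number of abstracts in the corpus (the `N` of the
#' hypergeometric co-citation test).
#'
#' @slot citations named list, gene id -> character vector of abstract ids.
#' @slot totalAbstracts total abstract count `N` in the corpus.
#' @seealso [readCitations()], [cocitationPValue()]
#' @export
setClass("CitationIndex",
    representation(citations = "list", totalAbstracts = "integer"))

setValidity("CitationIndex", function(object) {
    n <- object@totalAbstracts
    if (length(n) != 1L || is.na(n) || n <= 0L)
        return("totalAbstracts must be a single positive integer")
    u <- length(unique(unlist(object@citations, use.names = FALSE)))
    if (n < u)
        return(sprintf("totalAbstracts (%d) < number of distinct cited abstracts (%d)",
                       n, u))
    TRUE
})

#' Construct a CitationIndex
#' @param citations named list of abstract-id character vectors per gene.
#' @param totalAbstracts corpus size `N`.
#' @return A [CitationIndex-class] object.
#' @export
CitationIndex <- function(citations, totalAbstracts) {
    new("CitationIndex", citations = lapply(citations, unique),
        totalAbstracts = as.integer(totalAbstracts))
}

#' @describeIn CitationIndex-class abstract ids citing `gene` (empty vector
#'   for unknown genes)
#' @param object a `CitationIndex`
#' @param gene gene identifier
#' @export
geneAbstracts <- function(object, gene) {
    if (gene %in% names(object@citations)) object@citations[[gene]]
    else character(0)
}

#' @describeIn CitationIndex-class corpus size `N`
#' @export
totalAbstracts <- function(object) object@totalAbstracts

setMethod("show", "CitationIndex", function(object) {
    cat("CitationIndex:", length(object@citations), "genes,",
        object@totalAbstracts, "total abstracts\n")
})

## ---------------------------------------------------------------------------
## LinkageModel
## ---------------------------------------------------------------------------

#' LinkageModel: naive Bayes functional-linkage classifier
#'
#' Holds the fitted naive Bayes model that fuses binned GO similarity and
#' binned co-citation significance into a posterior probability of
#' functional linkage, `p_link`. Conditional bin distributions are stored
#' for both classes (linked / unlinked) with additive smoothing.
#'
#' @slot classPrior prior probability of the linked class, in (0,1).
#' @slot condGO 2 x 3 matrix `P(go bin | class)`; rows linked/unlinked.
#' @slot condPubMed 2 x 4 matrix `P(pubmed bin | class)`.
#' @slot smoothing additive (Laplace) pseudocount used at fit time.
#' @seealso [trainLinkageModel()], [pLink()]
#' @export
setClass("LinkageModel",
    representation(classPrior = "numeric", condGO = "matrix",
                   condPubMed = "matrix", smoothing = "numeric"))

setValidity("LinkageModel", function(object) {
    msgs <- character(0)
    if (object@classPrior <= 0 || object@classPrior >= 1)
        msgs <- c(msgs, "classPrior must lie strictly inside (0,1)")
    for (nm in c("condGO", "condPubMed")) {
        m <- slot(object, nm)
        if (any(m <= 0))
            msgs <- c(msgs, paste(nm, "must be strictly positive (smoothed)"))
        if (any(abs(rowSums(m) - 1) > 1e-8))
            msgs <- c(msgs, paste(nm, "rows must sum to 1"))
    }
    if (!identical(colnames(object@condGO), .GO_BINS))
        msgs <- c(msgs, "condGO columns must be the GO bins")
    if (!identical(colnames(object@condPubMed), .PUBMED_BINS))
        msgs <- c(msgs, "condPubMed columns must be the PubMed bins")
    if (length(msgs)) msgs else TRUE
})

#' @describeIn LinkageModel-class prior probability of linkage
#' @param object a `LinkageModel`
#' @export
classPrior <- function(object) object@classPrior

setMethod("show", "LinkageModel", function(object) {
    cat("LinkageModel (naive Bayes, smoothing =", object@smoothing, ")\n")
    cat("  P(linked) =", format(object@classPrior, digits = 4), "\n")
    cat("  P(GO bin | class):\n")
    print(round(object@condGO, 4))
    cat("  P(PubMed bin | class):\n")
    print(round(object@condPubMed, 4))
})

## ---------------------------------------------------------------------------
## BenchmarkSet
## ---------------------------------------------------------------------------

#' BenchmarkSet: positive/negative functional-linkage gene pairs
#'
#' Unordered gene pairs known to be functionally linked (positives, e.g.
#' same-pathway pairs) or believed unlinked (negatives, e.g. pairs whose
#' proteins occupy different cellular compartments). Used to train the
#' naive Bayes linkage classifier and to score evidence utility (LLS).
#'
#' @slot positives character matrix (p x 2), canonicalized unordered pairs.
#' @slot negatives character matrix (n x 2), canonicalized, disjoint from
#'   the positives.
#' @seealso [trainLinkageModel()], [computeLLS()]
#' @export
setClass("BenchmarkSet",
    representation(positives = "matrix", negatives = "matrix"))

.pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

setValidity("BenchmarkSet", function(object) {
    msgs <- character(0)
    for (nm in c("positives", "negatives")) {
        m <- slot(object, nm)
        if (ncol(m) != 2L) msgs <- c(msgs, paste(nm, "must have 2 columns"))
        else {
            if (any(m[, 1L] == m[, 2L]))
                msgs <- c(msgs, paste("self-pairs in", nm))
            if (any(m[, 1L] > m[, 2L]))
                msgs <- c(msgs, paste(nm, "must be canonicalized"))
        }
    }
    if (length(msgs) == 0L) {
        kp <- .pairKey(object@positives[, 1L], object@positives[, 2L])
        kn <- .pairKey(object@negatives[, 1L], object@negatives[, 2L])
        if (length(intersect(kp, kn)))
            msgs <- c(msgs, "positives and negatives must be disjoint")
        if (nrow(object@positives) == 0L || nrow(object@negatives) == 0L)
            msgs <- c(msgs, "both classes must be non-empty")
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct a BenchmarkSet
#'
#' @param positives,negatives two-column character matrices of gene pairs;
#'   rows are canonicalized (lexicographic order) and deduplicated.
#' @return A [BenchmarkSet-class].
#' @export
benchmarkSet <- function(positives, negatives) {
    canon <- function(m) {
        m <- as.matrix(m)
        swap <- m[, 1L] > m[, 2L]
        m[swap, ] <- m[swap, c(2L, 1L)]
        m <- m[!duplicated(paste(m[, 1L], m[, 2L])), , drop = FALSE]
        dimnames(m) <- list(NULL, c("gene_a", "gene_b"))
        m
    }
    new("BenchmarkSet", positives = canon(positives),
        negatives = canon(negatives))
}

#' @describeIn BenchmarkSet-class positive pair matrix
#' @param object a `BenchmarkSet`
#' @export
benchmarkPositives <- function(object) object@positives

#' @describeIn BenchmarkSet-class negative pair matrix
#' @export
benchmarkNegatives <- function(object) object@negatives

setMethod("show", "BenchmarkSet", function(object) {
    cat("BenchmarkSet:", nrow(object@positives), "positive /",
        nrow(object@negatives), "negative pairs\n")
})

## ---------------------------------------------------------------------------
## EdgeReservoir
## ---------------------------------------------------------------------------

#' EdgeReservoir: multiset of candidate edges
#'
#' The candidate-edge reservoir: every unordered gene pair is present with a
#' copy number `max(1, ceiling(10 * p_link))`, so pairs with stronger prior
#' support are proposed more often during MCMC. Copy numbers are bounded in
#' \[1, 10\].
#'
#' @slot pairs character matrix (n pairs x 2), rows canonicalized so that
#'   the first gene sorts before the second.
#' @slot pLink numeric vector of linkage probabilities, one per pair.
#' @slot copies integer copy numbers per pair.
#' @seealso [buildReservoir()], [sampleEdge()]
#' @export
setClass("EdgeReservoir",
    representation(pairs = "matrix", pLink = "numeric", copies = "integer"))

setValidity("EdgeReservoir", function(object) {
    msgs <- character(0)
    if (nrow(object@pairs) == 0L)
        msgs <- c(msgs, "reservoir must contain at least one pair")
    if (ncol(object@pairs) != 2L)
        msgs <- c(msgs, "pairs must have two columns")
    if (any(object@pairs[, 1L] == object@pairs[, 2L]))
        msgs <- c(msgs, "self-pairs are not allowed")
    if (any(object@pairs[, 1L] > object@pairs[, 2L]))
        msgs <- c(msgs, "pairs must be canonicalized (first < second)")
    if (anyDuplicated(paste(object@pairs[, 1L], object@pairs[, 2L])))
        msgs <- c(msgs, "duplicated pairs")
    if (length(object@copies) != nrow(object@pairs) ||
        length(object@pLink) != nrow(object@pairs))
        msgs <- c(msgs, "pLink/copies length must match the pair count")
    else {
        if (any(object@copies < 1L) || any(object@copies > 10L))
            msgs <- c(msgs, "copy numbers must lie in [1, 10]")
        if (any(object@copies != pmax(1L, as.integer(ceiling(10 * object@pLink)))))
            msgs <- c(msgs, "copies must equal max(1, ceiling(10 * pLink))")
    }
    if (length(msgs)) msgs else TRUE
})

#' @describeIn EdgeReservoir-class canonicalized pair matrix
#' @param object an `EdgeReservoir`
#' @export
reservoirPairs <- function(object) object@pairs

#' @describeIn EdgeReservoir-class integer copy numbers
#' @export
reservoirCopies <- function(object) object@copies

#' @describeIn EdgeReservoir-class total multiset size (sum of copies) --
#'   the "size of the sampling reservoir" that the default burn-in and
#'   iteration counts are multiples of
#' @export
reservoirSize <- function(object) sum(object@copies)

setMethod("show", "EdgeReservoir", function(object) {
    cat("EdgeReservoir:", nrow(object@pairs), "pairs, total size",
        sum(object@copies), "\n")
})

## ---------------------------------------------------------------------------
## AveragedNetwork
## ---------------------------------------------------------------------------

#' AveragedNetwork: posterior edge-probability matrix
#'
#' Square matrix of directed edge weights in \[0,1\] with zero diagonal,
#' obtained by (posterior-weighted) averaging of recorded DAG samples.
#'
#' @slot weights numeric gene x gene matrix with dimnames.
#' @seealso [averageDAG()], [consensusNetwork()], [writeNetwork()]
#' @export
setClass("AveragedNetwork", representation(weights = "matrix"))

setValidity("AveragedNetwork", function(object) {
    w <- object@weights
    if (nrow(w) != ncol(w)) return("weights must be square")
    if (is.null(rownames(w)) || !identical(rownames(w), colnames(w)))
        return("weights must carry identical row/column gene names")
    if (any(w < 0 | w > 1)) return("weights must lie in [0,1]")
    if (any(diag(w) != 0)) return("diagonal must be zero")
    TRUE
})

#' Construct an AveragedNetwork from a weight matrix
#' @param weights square numeric matrix with gene dimnames.
#' @return An [AveragedNetwork-class] object.
#' @export
AveragedNetwork <- function(weights) new("AveragedNetwork", weights = weights)

#' @describeIn AveragedNetwork-class the weight matrix
#' @param object an `AveragedNetwork`
#' @export
edgeWeights <- function(object) object@weights

setMethod("show", "AveragedNetwork", function(object) {
    cat("AveragedNetwork over", nrow(object@weights), "genes;",
        sum(object@weights > 0.5), "edges with weight > 0.5\n")
})

## ---------------------------------------------------------------------------
## SyntheticNetwork
## ---------------------------------------------------------------------------

#' SyntheticNetwork: ground-truth regulatory topology
#'
#' A directed regulator -> target network used as simulation ground truth.
#' Regulator out-degrees are heavy-tailed (preferential attachment), every
#' regulator has out-degree at least one, and there are no self-loops.
#'
#' @slot geneNames character vector of gene identifiers.
#' @slot regulators subset of genes acting as regulators.
#' @slot edges character matrix (m x 2): regulator, target.
#' @slot signs character vector per edge, `"activation"` or `"repression"`.
#' @seealso [generateNetwork()], [simulateExpression()]
#' @export
setClass("SyntheticNetwork",
    representation(geneNames = "character", regulators = "character",
                   edges = "matrix", signs = "character"))

setValidity("SyntheticNetwork", function(object) {
    msgs <- character(0)
    e <- object@edges
    if (!all(e %in% object@geneNames))
        msgs <- c(msgs, "edge endpoints must be genes")
    if (!all(object@regulators %in% object@geneNames))
        msgs <- c(msgs, "regulators must be genes")
    if (any(e[, 1L] == e[, 2L])) msgs <- c(msgs, "self-loops not allowed")
    if (!all(e[, 1L] %in% object@regulators))
        msgs <- c(msgs, "edge sources must be regulators")
    if (!all(object@regulators %in% e[, 1L]))
        msgs <- c(msgs, "every regulator needs out-degree >= 1")
    if (anyDuplicated(paste(e[, 1L], e[, 2L])))
        msgs <- c(msgs, "duplicated edges")
    if (length(object@signs) != nrow(e) ||
        !all(object@signs %in% c("activation", "repression")))
        msgs <- c(msgs, "signs must be activation/repression, one per edge")
    if (length(msgs)) msgs else TRUE
})

#' @describeIn SyntheticNetwork-class directed edge matrix
#' @param object a `SyntheticNetwork`
#' @export
networkEdges <- function(object) object@edges

#' @describeIn SyntheticNetwork-class regulator gene set
#' @export
networkRegulators <- function(object) object@regulators

#' @describeIn SyntheticNetwork-class all gene identifiers
#' @export
networkGenes <- function(object) object@geneNames

setMethod("show", "SyntheticNetwork", function(object) {
    cat("SyntheticNetwork:", length(object@geneNames), "genes,",
        length(object@regulators), "regulators,", nrow(object@edges),
        "edges\n")
})

## ---------------------------------------------------------------------------
## ChainConfig and ChainRun
## ---------------------------------------------------------------------------

#' ChainConfig: MCMC chain settings
#'
#' Settings of one structure-MCMC chain. Defaults: burn-in 50x the
#' reservoir size, 80x iterations, samples every 1000 steps.
#'
#' @slot burnIn iterations discarded before sampling.
#' @slot nIteration total iterations.
#' @slot sampleInterval record a sample every this many post-burn-in steps.
#' @slot maxFanIn parent-count cap per node.
#' @slot ess BDeu equivalent sample size.
#' @slot priorLambda complexity-penalty coefficient of the structure prior
#'   `P(G) proportional to exp(-lambda |E|)`; 0 gives the uniform prior.
#' @slot seed RNG seed for the chain.
#' @seealso [chainConfig()], [runChain()]
#' @export
setClass("ChainConfig",
    representation(burnIn = "integer", nIteration = "integer",
                   sampleInterval = "integer", maxFanIn = "integer",
                   ess = "numeric", priorLambda = "numeric",
                   seed = "integer"))

setValidity("ChainConfig", function(object) {
    msgs <- character(0)
    if (object@burnIn < 0L) msgs <- c(msgs, "burnIn must be >= 0")
    if (object@burnIn > object@nIteration)
        msgs <- c(msgs, "burnIn must not exceed nIteration")
    if (object@sampleInterval < 1L)
        msgs <- c(msgs, "sampleInterval must be >= 1")
    if (object@maxFanIn < 1L) msgs <- c(msgs, "maxFanIn must be >= 1")
    if (object@ess <= 0) msgs <- c(msgs, "ess must be positive")
    if (object@priorLambda < 0) msgs <- c(msgs, "priorLambda must be >= 0")
    if (length(msgs)) msgs else TRUE
})

#' Build a chain configuration
#'
#' Defaults scale with the proposal distribution: `burnIn = 50 * size`,
#' `nIteration = 80 * size` where `size` is the reservoir's total copy
#' count, and `sampleInterval = 1000`.
#'
#' @param reservoir optional [EdgeReservoir-class] supplying the size the
#'   burn-in/iteration defaults are multiples of.
#' @param burnIn,nIteration,sampleInterval,maxFanIn,ess,priorLambda,seed
#'   see [ChainConfig-class]; any value given overrides the default.
#' @return A validated [ChainConfig-class] object.
#' @examples
#' chainConfig(burnIn = 100, nIteration = 1000, sampleInterval = 10)
#' @export
chainConfig <- function(reservoir = NULL, burnIn = NULL, nIteration = NULL,
                        sampleInterval = 1000L, maxFanIn = 3L, ess = 1.0,
                        priorLambda = 0.0, seed = 1L) {
    if (is.null(burnIn) || is.null(nIteration)) {
        if (is.null(reservoir))
            stop("either a reservoir or explicit burnIn/nIteration is required")
        size <- reservoirSize(reservoir)
        if (is.null(burnIn)) burnIn <- 50L * size
        if (is.null(nIteration)) nIteration <- 80L * size
    }
    new("ChainConfig", burnIn = as.integer(burnIn),
        nIteration = as.integer(nIteration),
        sampleInterval = as.integer(sampleInterval),
        maxFanIn = as.integer(maxFanIn), ess = as.numeric(ess),
        priorLambda = as.numeric(priorLambda), seed = as.integer(seed))
}

setMethod("show", "ChainConfig", function(object) {
    cat(sprintf(paste0("ChainConfig: %d iterations (burn-in %d), sample ",
                       "every %d, maxFanIn %d, ess %g, lambda %g, seed %d\n"),
                object@nIteration, object@burnIn, object@sampleInterval,
                object@maxFanIn, object@ess, object@priorLambda,
                object@seed))
})

#' ChainRun: result of one MCMC chain
#'
#' @slot samples list of recorded adjacency matrices (0/1 integer,
#'   gene x gene, entry \[i,j\] = 1 for edge i -> j).
#' @slot logPosteriors log posterior (sum of family scores plus log
#'   structure prior) of each recorded sample.
#' @slot acceptanceTrace data.frame with columns `iteration` (window end)
#'   and `ratio` (windowed acceptance ratio).
#' @slot averaged the posterior-weighted [AveragedNetwork-class].
#' @slot config the [ChainConfig-class] used.
#' @slot nAccepted,nInvalid accepted-move and invalid-proposal counts.
#' @seealso [runChain()]
#' @export
setClass("ChainRun",
    representation(samples = "list", logPosteriors = "numeric",
                   acceptanceTrace = "data.frame",
                   averaged = "AveragedNetwork", config = "ChainConfig",
                   nAccepted = "integer", nInvalid = "integer"))

#' @describeIn ChainRun-class recorded DAG samples
#' @param object a `ChainRun`
#' @export
chainSamples <- function(object) object@samples

#' @describeIn ChainRun-class log posteriors of the recorded samples
#' @export
chainLogPosteriors <- function(object) object@logPosteriors

#' @describeIn ChainRun-class windowed acceptance-ratio trace
#' @export
acceptanceTrace <- function(object) object@acceptanceTrace

#' @describeIn ChainRun-class the averaged network of this run
#' @export
averagedNetwork <- function(object) object@averaged

setMethod("show", "ChainRun", function(object) {
    cat("ChainRun:", length(object@samples), "samples;",
        object@nAccepted, "accepted moves;", object@nInvalid,
        "invalid proposals\n")
})

## ---------------------------------------------------------------------------
## DiscretizedExperiment
## ---------------------------------------------------------------------------

#' DiscretizedExperiment: 3-level expression matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] whose single assay
#' `"levels"` holds the per-gene mean/SD discretization of an expression
#' matrix: 0 below \eqn{\mu - SD}, 1 within \eqn{[\mu - SD, \mu + SD]},
#' 2 above \eqn{\mu + SD}.
#'
#' @seealso [discretizeExpression()]
#' @export
#' @import SummarizedExperiment
setClass("DiscretizedExperiment", contains = "SummarizedExperiment")

setValidity("DiscretizedExperiment", function(object) {
    if (!"levels" %in% SummarizedExperiment::assayNames(object))
        return("assay 'levels' is required")
    lv <- SummarizedExperiment::assay(object, "levels")
    if (anyNA(lv)) return("levels must not contain missing values")
    if (!all(lv %in% 0:2)) return("levels must be 0, 1 or 2")
    TRUE
})

#' @describeIn DiscretizedExperiment-class the integer level matrix
#' @param object a `DiscretizedExperiment`
#' @export
levelMatrix <- function(object) {
    m <- SummarizedExperiment::assay(object, "levels")
    storage.mode(m) <- "integer"
    m
}
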