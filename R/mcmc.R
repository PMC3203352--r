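## Structure MCMC over DAGs: BDe family scoring, reservoir-biased
## add/delete/reverse proposals with Metropolis-Hastings acceptance,
## posterior-weighted model averaging, and the multi-run consensus rule.
## The iteration loop itself is compiled (src/chain.cpp); the R functions
## here expose the individual moves for inspection and testing.

.levelsOf <- function(data) {
    m <- if (is(data, "DiscretizedExperiment")) levelMatrix(data)
         else data
    storage.mode(m) <- "integer"
    m
}

.nodeIndex <- function(m, node) {
    if (is.character(node)) {
        idx <- match(node, rownames(m))
        if (anyNA(idx)) stop("unknown gene(s): ",
                             paste(node[is.na(idx)], collapse = ", "))
        idx
    } else as.integer(node)
}

#' BDe (BDeu) family log score
#'
#' Log marginal likelihood of one node's discretized values given its
#' parents' configurations, under Dirichlet hyperparameters
#' \eqn{\alpha_{ijk} = ess/(r_i q_i)} (BDeu). The score is decomposable:
#' it depends only on the node and its parent set, which is what makes the
#' incremental MCMC updates exact.
#'
#' @param data a [DiscretizedExperiment-class] or an integer matrix
#'   (genes x samples) with values in `0:(nLevels-1)`.
#' @param node gene name or row index.
#' @param parents character or integer vector of parents (may be empty).
#' @param ess equivalent sample size (default 1).
#' @param nLevels number of discretization levels (default 3).
#' @return The family log score (0 for zero data columns).
#' @examples
#' d <- matrix(c(0L, 0L, 1L), 1, dimnames = list("g", NULL))
#' familyBDeLogScore(d, "g", character(0), ess = 2, nLevels = 2) # log(1/12)
#' @export
familyBDeLogScore <- function(data, node, parents, ess = 1, nLevels = 3L) {
    m <- .levelsOf(data)
    ni <- .nodeIndex(m, node)
    pi <- if (length(parents)) .nodeIndex(m, parents) else integer(0)
    if (length(ni) != 1L) stop("exactly one node required")
    if (ni %in% pi) stop("parent set must not contain the node itself")
    if (anyDuplicated(pi)) stop("duplicated parents")
    .familyScoreCpp(m, ni - 1L, pi - 1L, ess, as.integer(nLevels))
}

#' Deterministic move implied by a drawn edge
#'
#' Given the current adjacency and a drawn directed candidate `(i, j)`:
#' delete `(i, j)` if present, else reverse `(j, i)` into `(i, j)` if the
#' opposite edge is present, else add `(i, j)`.
#'
#' @param adj 0/1 adjacency matrix (`adj[i, j] = 1` for edge i -> j).
#' @param i,j gene names or indices, `i != j`.
#' @return list with elements `type` (`"delete"`, `"reverse"` or `"add"`),
#'   `from` and `to` (always the edge `(i, j)` the move concerns).
#' @export
proposeMove <- function(adj, i, j) {
    ii <- .nodeIndex(adj, i); jj <- .nodeIndex(adj, j)
    if (ii == jj) stop("i and j must differ")
    type <- if (adj[ii, jj] == 1) "delete"
            else if (adj[jj, ii] == 1) "reverse"
            else "add"
    list(type = type, from = i, to = j)
}

.pathExistsR <- function(adj, from, to, skip = NULL) {
    n <- nrow(adj)
    if (!is.null(skip)) adj[skip[1L], skip[2L]] <- 0L
    seen <- logical(n)
    stack <- from
    seen[from] <- TRUE
    while (length(stack)) {
        v <- stack[[length(stack)]]
        stack <- stack[-length(stack)]
        nxt <- which(adj[v, ] == 1L & !seen)
        if (to %in% nxt) return(TRUE)
        seen[nxt] <- TRUE
        stack <- c(stack, nxt)
    }
    FALSE
}

#' Validate a proposed move
#'
#' `TRUE` iff the move keeps the graph acyclic and within the fan-in cap
#' for the affected nodes. Deletions are always valid. An invalid proposal
#' consumes its chain iteration with the current DAG retained.
#'
#' @param adj 0/1 adjacency matrix.
#' @param move a move from [proposeMove()].
#' @param maxFanIn parent-count cap.
#' @return Logical.
#' @export
validateMove <- function(adj, move, maxFanIn = 3L) {
    ii <- .nodeIndex(adj, move$from); jj <- .nodeIndex(adj, move$to)
    switch(move$type,
        delete = TRUE,
        add = sum(adj[, jj]) + 1L <= maxFanIn &&
            !.pathExistsR(adj, jj, ii),
        reverse = sum(adj[, jj]) + 1L <= maxFanIn &&
            !.pathExistsR(adj, jj, ii, skip = c(jj, ii)),
        stop("unknown move type"))
}

#' Apply a validated move to an adjacency matrix
#' @inheritParams validateMove
#' @return The updated adjacency matrix.
#' @export
applyMove <- function(adj, move) {
    ii <- .nodeIndex(adj, move$from); jj <- .nodeIndex(adj, move$to)
    switch(move$type,
        delete = { adj[ii, jj] <- 0L },
        add = { adj[ii, jj] <- 1L },
        reverse = { adj[jj, ii] <- 0L; adj[ii, jj] <- 1L })
    adj
}

#' Metropolis-Hastings acceptance decision
#'
#' Accepts when `bf1 * bf2 * priorRatio >= u * rHM`, evaluated in log
#' space. Under the frozen-reservoir proposal the Hastings ratio `rHM` is
#' exactly 1: the move that undoes any move is triggered by drawing the
#' same unordered pair, so forward and reverse proposal probabilities
#' cancel.
#'
#' @param logRatio total log acceptance ratio
#'   (`log(bf1) + log(bf2) + log(priorRatio)`).
#' @param u uniform(0,1) draw (defaults to a fresh draw).
#' @param rHM Hastings ratio (default 1).
#' @return Logical.
#' @export
mhAccept <- function(logRatio, u = stats::runif(1), rHM = 1) {
    log(u) + log(rHM) <= logRatio
}

#' Run one structure-MCMC chain
#'
#' Starts from the empty DAG and iterates the reservoir-biased
#' add/delete/reverse sampler with BDe scoring, recording the current DAG
#' and its log posterior every `sampleInterval` iterations after burn-in.
#' Family scores are updated incrementally (decomposability) and the
#' returned object carries both cached and freshly recomputed scores so
#' the cache can be audited.
#'
#' @param data a [DiscretizedExperiment-class] or integer matrix with
#'   values 0/1/2; rownames are the gene universe.
#' @param res an [EdgeReservoir-class]; all its genes must be present in
#'   `data`.
#' @param config a [ChainConfig-class] (see [chainConfig()]).
#' @return A [ChainRun-class].
#' @seealso [averageDAG()], [consensusNetwork()]
#' @export
runChain <- function(data, res, config) {
    m <- .levelsOf(data)
    genes <- rownames(m)
    if (is.null(genes)) stop("data must carry gene rownames")
    pairs <- reservoirPairs(res)
    if (!all(pairs %in% genes))
        stop("reservoir gene(s) absent from the data: ",
             paste(utils::head(setdiff(as.vector(pairs), genes), 5L),
                   collapse = ", "))
    pairIdx <- cbind(match(pairs[, 1L], genes),
                     match(pairs[, 2L], genes)) - 1L
    storage.mode(pairIdx) <- "integer"
    traceWindow <- max(1L, min(1000L, as.integer(ceiling(
        config@nIteration / 100))))
    set.seed(config@seed)
    out <- .chainRunCpp(m, pairIdx, reservoirCopies(res), config@burnIn,
                        config@nIteration, config@sampleInterval,
                        config@maxFanIn, config@ess, config@priorLambda,
                        3L, traceWindow)
    samples <- lapply(out$samples, function(s) {
        dimnames(s) <- list(genes, genes)
        s
    })
    avg <- if (length(samples))
        averageDAG(samples, out$logPosteriors)
    else
        AveragedNetwork(matrix(0, length(genes), length(genes),
                               dimnames = list(genes, genes)))
    stopifnot(max(abs(out$familyScoresCached -
                      out$familyScoresRecomputed)) < 1e-8)
    new("ChainRun", samples = samples,
        logPosteriors = as.numeric(out$logPosteriors),
        acceptanceTrace = data.frame(iteration = out$traceIteration,
                                     ratio = out$traceRatio),
        averaged = avg, config = config,
        nAccepted = as.integer(out$nAccepted),
        nInvalid = as.integer(out$nInvalid))
}

#' Average recorded DAG samples into an edge-probability matrix
#'
#' With `weighted = TRUE` (the default rule) each sample contributes
#' with weight proportional to its posterior probability, normalized in
#' log space; with `weighted = FALSE` samples contribute equally, giving
#' the usual MCMC estimate of marginal edge probabilities.
#'
#' @param samples list of 0/1 adjacency matrices with gene dimnames.
#' @param logPosteriors log posterior per sample (required when
#'   `weighted = TRUE`).
#' @param weighted posterior-weight the samples? Default `TRUE`.
#' @return An [AveragedNetwork-class].
#' @export
averageDAG <- function(samples, logPosteriors = NULL, weighted = TRUE) {
    if (length(samples) == 0L) stop("at least one sample required")
    w <- if (weighted) {
        stopifnot(length(logPosteriors) == length(samples))
        ww <- exp(logPosteriors - max(logPosteriors))
        ww / sum(ww)
    } else rep(1 / length(samples), length(samples))
    acc <- samples[[1L]] * w[[1L]]
    for (s in seq_along(samples)[-1L])
        acc <- acc + samples[[s]] * w[[s]]
    acc <- pmin(pmax(acc, 0), 1)
    diag(acc) <- 0
    AveragedNetwork(acc)
}

#' Run several independent chains
#'
#' Seeds are `baseSeed + run index` so the runs are independent yet
#' reproducible as a set.
#'
#' @param data,res,config as in [runChain()]; `config@seed` is ignored in
#'   favour of the derived per-run seeds.
#' @param nRuns number of chains (default 20).
#' @param baseSeed base RNG seed.
#' @return list of [ChainRun-class] objects.
#' @export
runChains <- function(data, res, config, nRuns = 20L, baseSeed = 1L) {
    lapply(seq_len(nRuns), function(r) {
        cfg <- config
        cfg@seed <- as.integer(baseSeed + r)
        runChain(data, res, cfg)
    })
}

#' Consensus network over independent runs
#'
#' An edge counts as "observed" in a run when its averaged weight exceeds
#' `presenceThreshold`; it enters the consensus network when observed in
#' strictly more than `minRuns` runs (default: more than 15 of 20).
#'
#' @param runs list of [AveragedNetwork-class] (or [ChainRun-class])
#'   objects over the same gene universe.
#' @param presenceThreshold per-run weight cutoff (default 0.5).
#' @param minRuns strict lower bound on the observation count (default 15).
#' @return 0/1 integer adjacency matrix of consensus edges, with the
#'   per-edge observation counts in attribute `"counts"`.
#' @export
consensusNetwork <- function(runs, presenceThreshold = 0.5, minRuns = 15L) {
    ws <- lapply(runs, function(r)
        if (is(r, "ChainRun")) edgeWeights(averagedNetwork(r))
        else edgeWeights(r))
    if (minRuns >= length(ws)) {
        warning("minRuns >= number of runs: consensus network is empty")
    }
    counts <- Reduce(`+`, lapply(ws, function(w) (w > presenceThreshold) * 1L))
    keep <- (counts > minRuns) * 1L
    storage.mode(keep) <- "integer"
    attr(keep, "counts") <- counts
    keep
}

#' Top-k edges of an averaged network
#'
#' @param avg an [AveragedNetwork-class].
#' @param k number of edges.
#' @return Character matrix (k x 2) of the k highest-weight directed
#'   edges, columns `from`, `to`.
#' @export
topEdges <- function(avg, k) {
    w <- edgeWeights(avg)
    ord <- order(w, decreasing = TRUE)
    ord <- ord[!(((ord - 1L) %% nrow(w)) + 1L == ceiling(ord / nrow(w)))]
    ord <- utils::head(ord, k)
    rows <- ((ord - 1L) %% nrow(w)) + 1L
    cols <- ceiling(ord / nrow(w))
    cbind(from = rownames(w)[rows], to = colnames(w)[cols])
}
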