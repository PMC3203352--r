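test_that("BDe family scores match the closed-form oracle on random data", {
    set.seed(3)
    for (rep in 1:10) {
        n <- sample(3:5, 1)
        m <- matrix(sample(0:2, n * 40, replace = TRUE), n, 40,
                    dimnames = list(sprintf("g%d", 1:n), NULL))
        storage.mode(m) <- "integer"
        node <- sample(n, 1)
        parents <- sample(setdiff(seq_len(n), node),
                          sample(0:2, 1))
        ess <- runif(1, 0.5, 4)
        expect_equal(familyBDeLogScore(m, node, parents, ess),
                     dmFamilyLogScore(m, node, parents, ess))
    }
})

test_that("BDe anchors: empty data, unit-pseudocount tables", {
    empty <- matrix(integer(0), 1, 0, dimnames = list("g", NULL))
    expect_equal(familyBDeLogScore(empty, "g", character(0)), 0)
    d <- matrix(c(0L, 0L, 1L), 1, dimnames = list("g", NULL))
    # two levels, counts (2,1), alpha = 1 each (ess = 2)
    expect_equal(familyBDeLogScore(d, "g", character(0), ess = 2,
                                   nLevels = 2), log(1 / 12))
    # three levels, counts (2,1,0), alpha = 1 each (ess = 3)
    expect_equal(familyBDeLogScore(d, "g", character(0), ess = 3,
                                   nLevels = 3), log(1 / 30))
})

test_that("family scores depend only on sufficient statistics", {
    m <- chainData3(60, seed = 5)
    perm <- sample(ncol(m))
    expect_equal(familyBDeLogScore(m, "y", "x"),
                 familyBDeLogScore(m[, perm], "y", "x"))
    expect_error(familyBDeLogScore(m, "y", c("y", "x")), "node itself")
})

test_that("move proposal follows the delete/reverse/add precedence", {
    genes <- c("a", "b", "c")
    adj <- matrix(0L, 3, 3, dimnames = list(genes, genes))
    expect_identical(proposeMove(adj, "a", "b")$type, "add")
    adj["a", "b"] <- 1L
    expect_identical(proposeMove(adj, "a", "b")$type, "delete")
    expect_identical(proposeMove(adj, "b", "a")$type, "reverse")
    expect_error(proposeMove(adj, "a", "a"), "differ")
})

test_that("move validation enforces acyclicity and the fan-in cap", {
    genes <- c("a", "b", "c", "d", "e")
    adj <- matrix(0L, 5, 5, dimnames = list(genes, genes))
    adj["a", "b"] <- adj["b", "c"] <- 1L
    # adding c -> a would close the cycle a -> b -> c -> a
    expect_false(validateMove(adj, proposeMove(adj, "c", "a")))
    expect_true(validateMove(adj, proposeMove(adj, "a", "c")))
    # deletions are always valid
    expect_true(validateMove(adj, proposeMove(adj, "a", "b")))
    # fan-in cap: c, d, e already feed b
    adj2 <- matrix(0L, 5, 5, dimnames = list(genes, genes))
    adj2["c", "b"] <- adj2["d", "b"] <- adj2["e", "b"] <- 1L
    expect_false(validateMove(adj2, proposeMove(adj2, "a", "b"),
                              maxFanIn = 3L))
    expect_true(validateMove(adj2, proposeMove(adj2, "a", "b"),
                             maxFanIn = 4L))
    # reversing is allowed when removing the old edge breaks the cycle risk
    adj3 <- matrix(0L, 5, 5, dimnames = list(genes, genes))
    adj3["a", "b"] <- 1L
    expect_true(validateMove(adj3, proposeMove(adj3, "b", "a")))
    # but not when an alternative path sustains the cycle
    adj3["a", "c"] <- adj3["c", "b"] <- 1L
    expect_false(validateMove(adj3, proposeMove(adj3, "b", "a")))
})

test_that("acceptance rule accepts ratio >= u and tracks its probability", {
    expect_true(mhAccept(0, u = 0.999999))     # score-neutral move
    expect_false(mhAccept(-Inf, u = 1e-12))    # impossible configuration
    set.seed(8)
    hits <- mean(vapply(1:1e5, function(i) mhAccept(log(0.3)), logical(1)))
    expect_lt(abs(hits - 0.3), 3 * sqrt(0.3 * 0.7 / 1e5))
})

.tinyRun <- function(seed = 1L, nIteration = 4000L, data = NULL,
                     lambda = 0) {
    if (is.null(data)) data <- chainData3(80, seed = 2)
    res <- uniformReservoir(rownames(data))
    cfg <- chainConfig(burnIn = 500L, nIteration = nIteration,
                       sampleInterval = 20L, seed = seed,
                       priorLambda = lambda)
    list(run = runChain(data, res, cfg), data = data, cfg = cfg)
}

test_that("chains are reproducible and gene mismatches are rejected", {
    a <- .tinyRun(seed = 42L)
    b <- .tinyRun(seed = 42L)
    expect_identical(chainSamples(a$run), chainSamples(b$run))
    expect_identical(chainLogPosteriors(a$run),
                     chainLogPosteriors(b$run))
    c3 <- .tinyRun(seed = 43L)
    expect_false(identical(chainSamples(a$run), chainSamples(c3$run)))
    data <- chainData3(30)
    res <- uniformReservoir(c("x", "y", "nope"))
    expect_error(runChain(data, res, chainConfig(burnIn = 1,
                                                 nIteration = 10)),
                 "absent")
})

test_that("a chain with nIteration = burnIn yields a valid empty result", {
    data <- chainData3(30)
    res <- uniformReservoir(rownames(data))
    cfg <- chainConfig(burnIn = 100L, nIteration = 100L,
                       sampleInterval = 10L)
    run <- runChain(data, res, cfg)
    expect_length(chainSamples(run), 0L)
    expect_true(all(edgeWeights(averagedNetwork(run)) == 0))
})

test_that("every recorded sample is acyclic and within the fan-in cap", {
    out <- .tinyRun(seed = 7L)
    for (s in chainSamples(out$run)) {
        expect_true(all(colSums(s) <= 3))
        dags <- enumerateDAGs(3)      # sanity: sample is one of the DAGs
        expect_true(any(vapply(dags, identical, logical(1),
                               matrix(as.integer(s), 3, 3))))
    }
})

test_that("recorded log posteriors equal recomputed family-score sums", {
    out <- .tinyRun(seed = 9L, lambda = 0.3)
    samples <- chainSamples(out$run)
    lps <- chainLogPosteriors(out$run)
    for (i in seq_along(samples)) {
        s <- samples[[i]]
        recomputed <- sum(vapply(seq_len(nrow(s)), function(j)
            familyBDeLogScore(out$data, j, which(s[, j] == 1L)),
            numeric(1))) - 0.3 * sum(s)
        expect_equal(lps[i], recomputed)
    }
})

test_that("model averaging weights samples by posterior", {
    genes <- c("a", "b")
    s1 <- matrix(c(0L, 0L, 1L, 0L), 2, dimnames = list(genes, genes))
    s2 <- matrix(0L, 2, 2, dimnames = list(genes, genes))
    expect_equal(edgeWeights(averageDAG(list(s1), 0)), s1 + 0)
    avg <- averageDAG(list(s1, s2), c(-5, -5))
    expect_equal(edgeWeights(avg)["a", "b"], 0.5)
    # hand-computed three-sample weighted mean
    lp <- c(-1, -2, -4)
    w <- exp(lp - max(lp)); w <- w / sum(w)
    avg3 <- averageDAG(list(s1, s2, s1), lp)
    expect_equal(edgeWeights(avg3)["a", "b"], w[1] + w[3])
    # uniform mode is the plain frequency
    expect_equal(edgeWeights(averageDAG(list(s1, s2, s1),
                                        weighted = FALSE))["a", "b"],
                 2 / 3)
})

test_that("consensus keeps edges observed in strictly more than minRuns runs", {
    genes <- c("a", "b")
    mk <- function(w) {
        m <- matrix(0, 2, 2, dimnames = list(genes, genes))
        m["a", "b"] <- w
        AveragedNetwork(m)
    }
    runs16 <- c(replicate(16, mk(0.9), simplify = FALSE),
                replicate(4, mk(0.1), simplify = FALSE))
    expect_equal(consensusNetwork(runs16)[1, 2], 1L)
    runs15 <- c(replicate(15, mk(0.9), simplify = FALSE),
                replicate(5, mk(0.1), simplify = FALSE))
    expect_equal(consensusNetwork(runs15)[1, 2], 0L)
    runsAll <- replicate(20, mk(0.9), simplify = FALSE)
    expect_equal(consensusNetwork(runsAll)[1, 2], 1L)
    expect_warning(out <- consensusNetwork(runsAll, minRuns = 20L),
                   "empty")
    expect_true(all(out == 0L))
})

test_that("with uninformative data, edge marginals are symmetric", {
    # a detailed-balance smoke test: all-identical columns carry no signal,
    # so i->j and j->i must be equally probable up to sampling error
    set.seed(10)
    data <- matrix(sample(0:2, 4 * 30, replace = TRUE), 4, 30,
                   dimnames = list(sprintf("g%d", 1:4), NULL))
    storage.mode(data) <- "integer"
    res <- uniformReservoir(rownames(data))
    cfg <- chainConfig(burnIn = 2000L, nIteration = 80000L,
                       sampleInterval = 20L, seed = 3L)
    run <- runChain(data, res, cfg)
    freq <- edgeWeights(averageDAG(chainSamples(run), weighted = FALSE))
    expect_lt(max(abs(freq - t(freq))), 0.06)
})

test_that("acceptance trace exists and invalid proposals are counted", {
    out <- .tinyRun(seed = 12L)
    tr <- acceptanceTrace(out$run)
    expect_true(all(tr$ratio >= 0 & tr$ratio <= 1))
    expect_true(nrow(tr) > 0)
    expect_gte(out$run@nInvalid, 0L)
})

test_that("top-k edge extraction never returns diagonal entries", {
    genes <- c("a", "b", "c")
    w <- matrix(runif(9), 3, 3, dimnames = list(genes, genes))
    diag(w) <- 0
    te <- topEdges(AveragedNetwork(w), 4)
    expect_equal(nrow(te), 4L)
    expect_true(all(te[, 1] != te[, 2]))
    best <- te[1, ]
    expect_equal(w[best[1], best[2]], max(w))
})
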