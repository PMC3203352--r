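# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: scores are computed from count tables with the
# plain Dirichlet-multinomial closed form, and posteriors by exhaustive
# enumeration of all DAGs.

# Closed-form Dirichlet-multinomial marginal likelihood of one node given
# its parents, from scratch: tabulates parent configurations itself.
# data: integer matrix genes x samples; node/parents: row indices.
dmFamilyLogScore <- function(data, node, parents, ess, nLevels = 3L) {
    nS <- ncol(data)
    q <- nLevels^length(parents)
    aj <- ess / q
    ajk <- ess / (q * nLevels)
    cfg <- rep(0L, nS)
    for (p in parents) cfg <- cfg * nLevels + data[p, ]
    total <- 0
    for (cc in unique(cfg)) {
        xs <- data[node, cfg == cc]
        nij <- length(xs)
        total <- total + lgamma(aj) - lgamma(aj + nij)
        for (k in 0:(nLevels - 1L)) {
            nijk <- sum(xs == k)
            total <- total + lgamma(ajk + nijk) - lgamma(ajk)
        }
    }
    total
}

# All DAGs on n nodes (tiny n only), as a list of adjacency matrices.
enumerateDAGs <- function(n) {
    slots <- which(diag(n) == 0)
    out <- list()
    for (mask in 0:(2^length(slots) - 1L)) {
        adj <- matrix(0L, n, n)
        adj[slots] <- as.integer(intToBits(mask)[seq_along(slots)] == 1)
        # acyclic iff some power ordering exists: repeatedly strip sinks
        ok <- TRUE
        rem <- seq_len(n)
        while (length(rem)) {
            sinks <- rem[rowSums(adj[rem, rem, drop = FALSE]) == 0]
            if (!length(sinks)) { ok <- FALSE; break }
            rem <- setdiff(rem, sinks)
        }
        if (ok) out[[length(out) + 1L]] <- adj
    }
    out
}

# Exact posterior edge-probability matrix by enumeration (uniform structure
# prior), using the independent family-score oracle above.
exactEdgePosterior <- function(data, ess = 1, maxFanIn = 3L) {
    n <- nrow(data)
    dags <- enumerateDAGs(n)
    dags <- Filter(function(a) all(colSums(a) <= maxFanIn), dags)
    logp <- vapply(dags, function(adj) {
        s <- 0
        for (j in seq_len(n))
            s <- s + dmFamilyLogScore(data, j, which(adj[, j] == 1L), ess)
        s
    }, numeric(1))
    w <- exp(logp - max(logp))
    w <- w / sum(w)
    acc <- matrix(0, n, n)
    for (i in seq_along(dags)) acc <- acc + w[i] * dags[[i]]
    acc
}

# Discrete 3-level samples from a hand-specified 3-node chain x1 -> x2 -> x3.
chainData3 <- function(nSamples, seed = 1) {
    set.seed(seed)
    p1 <- c(0.5, 0.3, 0.2)
    trans <- rbind(c(0.7, 0.2, 0.1), c(0.15, 0.7, 0.15), c(0.1, 0.2, 0.7))
    x1 <- sample(0:2, nSamples, replace = TRUE, prob = p1)
    x2 <- vapply(x1, function(v)
        sample(0:2, 1, prob = trans[v + 1L, ]), integer(1))
    x3 <- vapply(x2, function(v)
        sample(0:2, 1, prob = trans[v + 1L, ]), integer(1))
    m <- rbind(x = x1, y = x2, z = x3)
    storage.mode(m) <- "integer"
    m
}

# Tiny hand-built ontology: root with two branches, each two levels deep.
#        root
#        /  \
#      b1    b2
#     /  \     \
#   l1a  l1b   l2a
toyOntology <- function() {
    OntologyDAG(list(root = character(0), b1 = "root", b2 = "root",
                     l1a = "b1", l1b = "b1", l2a = "b2"))
}

# A small synthetic study shared by heavier tests (built once per run).
smallStudy <- function(seed = 11L, nGenes = 20L, nRegulators = 6L,
                       nEdges = 24L, nTimepoints = 30L) {
    net <- generateNetwork(nGenes, nRegulators, nEdges, seed = seed)
    se <- simulateExpression(net, nTimepoints, seed = seed + 1L)
    pk <- generatePriorKnowledge(net, seed = seed + 2L)
    bench <- benchmarkFromNetwork(net, seed = seed + 3L)
    list(net = net, se = se, pk = pk, bench = bench)
}
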