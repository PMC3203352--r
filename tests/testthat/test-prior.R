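# Annotation map on the toy ontology used throughout:
#   g1, g2 -> l1a;  g3 -> l1b;  g4 -> l2a;  g5 -> root
.toyAnn <- list(g1 = "l1a", g2 = "l1a", g3 = "l1b", g4 = "l2a",
                g5 = "root")

# brute-force IC oracle: count annotated descendants by direct reachability
.icOracle <- function(onto, ann) {
    terms <- ontoTerms(onto)
    par <- termParents(onto)
    descendantsOf <- function(t) {
        out <- t
        repeat {
            more <- terms[vapply(terms, function(x)
                any(par[[x]] %in% out) && !(x %in% out), logical(1))]
            if (!length(more)) break
            out <- c(out, more)
        }
        out
    }
    G <- sum(vapply(ann, length, integer(1)) > 0)
    vapply(terms, function(t) {
        d <- descendantsOf(t)
        f <- sum(vapply(ann, function(ts) any(ts %in% d), logical(1)))
        if (f == 0) NA_real_ else -log(f / G)
    }, numeric(1))
}

test_that("information content matches brute-force descendant counting", {
    onto <- toyOntology()
    ic <- termInformationContent(onto, .toyAnn)
    expect_equal(ic[["root"]], 0)
    expect_equal(ic[["l1b"]], log(5))   # annotates 1 of 5 genes
    expect_equal(ic, .icOracle(onto, .toyAnn))
})

test_that("gene-pair GO similarity hits its anchors and the cross-pair max", {
    onto <- toyOntology()
    # identical informative leaf annotation -> maximal similarity
    expect_equal(pairGOSimilarity(onto, .toyAnn, "g1", "g2"), 1)
    # branches meeting only at the root -> no similarity
    expect_equal(pairGOSimilarity(onto, .toyAnn, "g1", "g4"), 0)
    # unannotated gene -> 0
    expect_equal(pairGOSimilarity(onto, .toyAnn, "g1", "missing"), 0)

    # 2x2 annotation sets: exhaustive term-pair oracle
    ann <- c(.toyAnn, list(gA = c("l1a", "b2"), gB = c("l1b", "l2a")))
    ic <- .icOracle(onto, ann)
    anc <- termAncestors(onto)
    simST <- function(s, t) {
        common <- intersect(anc[[s]], anc[[t]])
        mica <- suppressWarnings(max(ic[common], na.rm = TRUE))
        den <- ic[[s]] + ic[[t]]
        if (!is.finite(mica) || den <= 0) 0 else 2 * mica / den
    }
    expected <- max(outer(ann$gA, ann$gB, Vectorize(simST)))
    expect_equal(pairGOSimilarity(onto, ann, "gA", "gB"), expected)
    expect_gte(expected, 0)
    expect_lte(expected, 1)
})

test_that("co-citation p-value equals exhaustive subset enumeration", {
    enumOracle <- function(k, n, m, N) {
        # gene 1 cites abstracts 1..n; enumerate every size-m subset for
        # gene 2 and count overlaps of at least k
        subsets <- utils::combn(N, m)
        mean(apply(subsets, 2, function(s) sum(s <= n) >= k))
    }
    expect_equal(cocitationPValue(2, 3, 3, 10), 22 / 120)
    expect_equal(cocitationPValue(2, 3, 3, 10), enumOracle(2, 3, 3, 10))
    for (N in c(5L, 8L)) {
        for (n in 1:N) for (m in 1:N) for (k in 0:min(n, m)) {
            expect_equal(cocitationPValue(k, n, m, N),
                         enumOracle(k, n, m, N),
                         info = sprintf("k=%d n=%d m=%d N=%d", k, n, m, N))
        }
    }
})

test_that("co-citation boundary conventions hold", {
    expect_equal(cocitationPValue(0, 5, 7, 100), 1)
    expect_equal(cocitationPValue(4, 10, 4, 10), 1)  # n = N forces overlap
    expect_warning(p <- cocitationPValue(5, 3, 4, 10), "impossible")
    expect_equal(p, 0)
})

test_that("feature binning follows the fixed interval boundaries", {
    expect_identical(binFeatures(1, 1)$go_bin, "[1,1]")
    expect_identical(binFeatures(0.2, 1)$go_bin, "[0.2,1)")
    expect_identical(binFeatures(0.999, 1)$go_bin, "[0.2,1)")
    expect_identical(binFeatures(0, 1)$go_bin, "[0,0.2)")
    expect_identical(binFeatures(0, 10^-3.5)$pubmed_bin, "(3,4]")
    expect_identical(binFeatures(0, 10^-4.5)$pubmed_bin, "(4,inf)")
    expect_identical(binFeatures(0, 10^-3)$pubmed_bin, "(1,3]")
    expect_identical(binFeatures(0, 1)$pubmed_bin, "[0,1]")
    expect_identical(binFeatures(0, 0.5)$pubmed_bin, "[0,1]")
})

.handFeatures <- function(goBinsPos, goBinsNeg, pmBin = "[0,1]") {
    nP <- length(goBinsPos); nN <- length(goBinsNeg)
    data.frame(
        gene_a = sprintf("p%02d", seq_len(nP + nN)),
        gene_b = sprintf("q%02d", seq_len(nP + nN)),
        go_sim = 0, p_pubmed = 1,
        go_bin = c(goBinsPos, goBinsNeg),
        pubmed_bin = pmBin, stringsAsFactors = FALSE)
}

.handBench <- function(features, nPos) {
    benchmarkSet(as.matrix(features[seq_len(nPos), 1:2]),
                 as.matrix(features[-seq_len(nPos), 1:2]))
}

test_that("classifier training reproduces hand Laplace estimates", {
    f <- .handFeatures(rep("[1,1]", 4), rep("[0,0.2)", 4))
    bench <- .handBench(f, 4)
    model <- trainLinkageModel(f, bench, smoothing = 1)
    expect_equal(classPrior(model), 0.5)
    expect_equal(unname(model@condGO["linked", ]), c(5, 1, 1) / 7)
    expect_equal(unname(model@condGO["unlinked", ]), c(1, 1, 5) / 7)
    # PubMed evidence identical in both classes cancels: posterior is the
    # hand Bayes value 5/6 for the top GO bin
    expect_equal(pLink(model, "[1,1]", "[0,1]"), 5 / 6)
    expect_equal(pLink(model, "[0,0.2)", "[0,1]"), 1 / 6)
})

test_that("identical class distributions give p_link = class prior", {
    f <- .handFeatures(rep("[0.2,1)", 5), rep("[0.2,1)", 5))
    model <- trainLinkageModel(f, .handBench(f, 5), smoothing = 1)
    for (gb in goBins()) for (pb in pubmedBins())
        expect_equal(pLink(model, gb, pb), 0.5)
})

test_that("a flat class prior makes posterior odds the likelihood ratio", {
    f <- .handFeatures(rep("[1,1]", 6), rep("[0,0.2)", 2))
    model <- trainLinkageModel(f, .handBench(f, 6), smoothing = 1,
                               classPriorOverride = 0.5)
    p <- pLink(model, "[1,1]", "[0,1]")
    lr <- (model@condGO["linked", "[1,1]"] *
           model@condPubMed["linked", "[0,1]"]) /
          (model@condGO["unlinked", "[1,1]"] *
           model@condPubMed["unlinked", "[0,1]"])
    expect_equal(p / (1 - p), unname(lr))
})

test_that("p_link is symmetric in gene order and strictly inside (0,1)", {
    onto <- toyOntology()
    cit <- CitationIndex(list(g1 = c("A1", "A2"), g2 = "A1", g4 = "A3"),
                         50L)
    fAB <- pairFeatures(onto, .toyAnn, cit, cbind("g1", "g2"))
    fBA <- pairFeatures(onto, .toyAnn, cit, cbind("g2", "g1"))
    expect_equal(fAB$go_sim, fBA$go_sim)
    expect_equal(fAB$p_pubmed, fBA$p_pubmed)
    f <- .handFeatures(rep("[1,1]", 3), rep("[0,0.2)", 3))
    model <- trainLinkageModel(f, .handBench(f, 3))
    for (gb in goBins()) for (pb in pubmedBins()) {
        p <- pLink(model, gb, pb)
        expect_gt(p, 0); expect_lt(p, 1)
    }
})

test_that("p_link is monotone when conditionals are likelihood-ordered", {
    f <- .handFeatures(c(rep("[1,1]", 6), rep("[0.2,1)", 3),
                         rep("[0,0.2)", 1)),
                       c(rep("[1,1]", 1), rep("[0.2,1)", 3),
                         rep("[0,0.2)", 6)))
    model <- trainLinkageModel(f, .handBench(f, 10))
    lrGO <- model@condGO["linked", ] / model@condGO["unlinked", ]
    expect_true(all(diff(lrGO) < 0))      # ordered strongest -> weakest
    for (pb in pubmedBins()) {
        ps <- vapply(goBins(), function(gb) pLink(model, gb, pb),
                     numeric(1))
        expect_true(all(diff(ps) <= 0))
    }
})

test_that("LLS reproduces the hand value and the random-half null", {
    pos <- cbind(sprintf("a%02d", 1:10), sprintf("b%02d", 1:10))
    neg <- cbind(sprintf("c%02d", 1:10), sprintf("d%02d", 1:10))
    bench <- benchmarkSet(pos, neg)
    selected <- rbind(pos[1:8, ], neg[1:2, ])
    expect_equal(computeLLS(selected, bench, smoothing = 0), log(4))
    expect_warning(lls <- computeLLS(cbind("x", "y"), bench), "undefined")
    expect_true(is.na(lls))

    # a uniformly random half of a 1,000-pair benchmark is uninformative
    set.seed(1)
    genes <- sprintf("g%03d", 1:200)
    pairs <- t(utils::combn(genes, 2))[sample(choose(200, 2), 1000), ]
    bench2 <- benchmarkSet(pairs[1:500, ], pairs[501:1000, ])
    half <- pairs[sample(1000, 500), ]
    expect_lt(abs(computeLLS(half, bench2)), 0.1)
})

test_that("Fisher z dependence test matches its closed form", {
    f <- data.frame(gene_a = sprintf("a%d", 1:8),
                    gene_b = sprintf("b%d", 1:8),
                    go_sim = c(0.1, 0.9, 0.3, 0.7, 0.2, 0.8, 0.55, 0.4),
                    p_pubmed = 10^-c(1, 4, 2, 3, 1.5, 3.5, 2.5, 2),
                    go_bin = "[0.2,1)", pubmed_bin = "(1,3]",
                    stringsAsFactors = FALSE)
    bench <- benchmarkSet(as.matrix(f[1:4, 1:2]), as.matrix(f[5:8, 1:2]))
    res <- attributeDependence(f, bench)
    r <- cor(f$go_sim, -log10(f$p_pubmed))
    expect_equal(res$correlation, r)
    expect_equal(res$z, atanh(r) * sqrt(8 - 3))
    expect_equal(res$p_value, 2 * pnorm(-abs(res$z)))

    # exactly uncorrelated features -> z = 0, p = 1
    f0 <- f
    f0$go_sim <- rep(c(0.2, 0.8), 4)
    f0$p_pubmed <- 10^-rep(c(1, 1, 3, 3), 2)
    res0 <- attributeDependence(f0, bench)
    expect_equal(res0$z, 0)
    expect_equal(res0$p_value, 1)

    # perfectly correlated features -> degenerate guard
    f1 <- f
    f1$p_pubmed <- 10^-f1$go_sim
    res1 <- attributeDependence(f1, bench)
    expect_equal(res1$p_value, 0)
    # constant feature -> undefined with a warning
    f2 <- f
    f2$go_sim <- 0.5
    expect_warning(res2 <- attributeDependence(f2, bench), "constant")
    expect_true(is.na(res2$correlation))
})

test_that("planted-signal LLS is positive in the top GO bin, negative at the bottom", {
    study <- smallStudy()
    tab <- pLinkTable(study$pk$ontology, study$pk$annotations,
                      study$pk$citations, networkGenes(study$net),
                      study$bench)
    lt <- llsTable(tab, study$bench)
    top <- lt$lls[lt$evidence == "go_similarity" & lt$bin == "[1,1]"]
    bottom <- lt$lls[lt$evidence == "go_similarity" & lt$bin == "[0,0.2)"]
    expect_gt(top, 0)
    expect_lt(bottom, 0)
})
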