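test_that("topology generator hits its counts exactly and deterministically", {
    net <- generateNetwork(76, 24, 124, seed = 5)
    expect_length(networkGenes(net), 76L)
    expect_length(networkRegulators(net), 24L)
    expect_equal(nrow(networkEdges(net)), 124L)
    outdeg <- table(networkEdges(net)[, 1])
    expect_true(all(outdeg >= 1))
    expect_setequal(names(outdeg), networkRegulators(net))
    net2 <- generateNetwork(76, 24, 124, seed = 5)
    expect_identical(networkEdges(net), networkEdges(net2))
    expect_false(identical(networkEdges(net),
                           networkEdges(generateNetwork(76, 24, 124,
                                                        seed = 6))))
})

test_that("edge budget equal to regulator count gives one target each", {
    net <- generateNetwork(10, 4, 4, seed = 1)
    expect_true(all(table(networkEdges(net)[, 1]) == 1))
    expect_error(generateNetwork(5, 4, 30), "infeasible")
    expect_error(generateNetwork(5, 5, 5))
})

test_that("expression simulation has the right shape and lag-1 coupling", {
    net <- generateNetwork(76, 24, 124, seed = 2)
    se <- simulateExpression(net, 50, seed = 3)
    expect_equal(dim(SummarizedExperiment::assay(se)), c(76L, 50L))

    # noiseless single activator edge: target is a deterministic monotone
    # transform of the regulator's lagged trajectory
    tiny <- new("SyntheticNetwork", geneNames = c("R", "T"),
                regulators = "R",
                edges = cbind(from = "R", to = "T"),
                signs = "activation")
    m <- SummarizedExperiment::assay(
        simulateExpression(tiny, 40, noiseSd = 0, seed = 4))
    expect_equal(cor(m["R", -40], m["T", -1], method = "spearman"), 1)
    rep <- new("SyntheticNetwork", geneNames = c("R", "T"),
               regulators = "R", edges = cbind(from = "R", to = "T"),
               signs = "repression")
    mr <- SummarizedExperiment::assay(
        simulateExpression(rep, 40, noiseSd = 0, seed = 4))
    expect_equal(cor(mr["R", -40], mr["T", -1], method = "spearman"), -1)
})

test_that("true edges are more correlated than random non-edges", {
    net <- generateNetwork(40, 12, 60, seed = 6)
    m <- SummarizedExperiment::assay(
        simulateExpression(net, 50, noiseSd = 0.1, seed = 7))
    edges <- networkEdges(net)
    edgeCor <- mean(abs(vapply(seq_len(nrow(edges)), function(e)
        cor(m[edges[e, 1], ], m[edges[e, 2], ]), numeric(1))))
    set.seed(8)
    keys <- paste(edges[, 1], edges[, 2])
    genes <- networkGenes(net)
    rnd <- replicate(1000, {
        p <- sample(genes, 2)
        if (paste(p[1], p[2]) %in% keys) NA_real_
        else abs(cor(m[p[1], ], m[p[2], ]))
    })
    expect_gt(edgeCor, mean(rnd, na.rm = TRUE))
})

test_that("prior-knowledge generator plants the advertised signal", {
    study <- smallStudy(seed = 31L, nGenes = 30L, nRegulators = 8L,
                        nEdges = 40L)
    tab <- pLinkTable(study$pk$ontology, study$pk$annotations,
                      study$pk$citations, networkGenes(study$net),
                      study$bench)
    linked <- unique(t(apply(networkEdges(study$net), 1, sort)))
    keys <- paste(linked[, 1], linked[, 2])
    isLinked <- paste(tab$gene_a, tab$gene_b) %in% keys
    # linked pairs have clearly higher GO similarity (Welch t > 3)
    tstat <- t.test(tab$go_sim[isLinked], tab$go_sim[!isLinked])$statistic
    expect_gt(unname(tstat), 3)
    # and p_link ranks true-linked pairs above unlinked ones
    auc <- rocAuc(tab$p_link[isLinked], tab$p_link[!isLinked])$auc
    expect_gt(auc, 0.55)
})

test_that("a null construction carries no signal", {
    net <- generateNetwork(30, 8, 40, seed = 32)
    pk <- generatePriorKnowledge(net, qLinked = 0.05, qUnlinked = 0.05,
                                 lambdaCo = 0, seed = 33)
    bench <- benchmarkFromNetwork(net, seed = 34)
    tab <- pLinkTable(pk$ontology, pk$annotations, pk$citations,
                      networkGenes(net), bench)
    model <- attr(tab, "model")
    # posteriors hover near the class prior on average
    expect_lt(mean(abs(tab$p_link - classPrior(model))), 0.1)
    linked <- unique(t(apply(networkEdges(net), 1, sort)))
    isLinked <- paste(tab$gene_a, tab$gene_b) %in%
        paste(linked[, 1], linked[, 2])
    auc <- rocAuc(tab$p_link[isLinked], tab$p_link[!isLinked])$auc
    expect_lt(abs(auc - 0.5), 0.12)
})

test_that("generators are bit-identical under a fixed seed", {
    net <- generateNetwork(20, 6, 24, seed = 9)
    a <- generatePriorKnowledge(net, seed = 10)
    b <- generatePriorKnowledge(net, seed = 10)
    expect_identical(a$annotations, b$annotations)
    expect_identical(a$citations@citations, b$citations@citations)
    sa <- simulateExpression(net, 30, seed = 11)
    sb <- simulateExpression(net, 30, seed = 11)
    expect_identical(SummarizedExperiment::assay(sa),
                     SummarizedExperiment::assay(sb))
})

test_that("fixture writer produces a coherent, re-readable file set", {
    dir <- withr::local_tempdir()
    writeFixtures(dir, nGenes = 15L, nRegulators = 5L, nEdges = 18L,
                  nTimepoints = 12L, seed = 13L)
    se <- readExpression(file.path(dir, "expression.tsv"))
    expect_equal(dim(SummarizedExperiment::assay(se)), c(15L, 12L))
    onto <- readOBO(file.path(dir, "ontology.obo"))
    ann <- readAnnotations(file.path(dir, "annotations.tsv"), onto)
    expect_true(all(unlist(ann) %in% ontoTerms(onto)))
    cit <- readCitations(file.path(dir, "citations.tsv"))
    expect_gt(totalAbstracts(cit), 0L)
    edges <- readPairTable(file.path(dir, "true_edges.tsv"),
                           directed = TRUE)
    expect_equal(nrow(edges), 18L)
    expect_true(all(edges %in% rownames(se)))
})
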