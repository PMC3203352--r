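# priornet

Bayesian network (BN) modeling of gene expression time courses is
notoriously underpowered: a few dozen samples cannot pin down a regulatory
structure over even a modest gene set, and plain structure learning often
does no better than picking edges at random. `priornet` implements a
structure-MCMC learner that counters this by biasing the *proposal*
distribution — not the posterior — toward gene pairs with independent
evidence of functional linkage, so that biologically plausible edges are
visited far more often within a fixed simulation budget.

It is aimed at computational biologists reconstructing small regulatory
networks (tens to ~100 genes) from discretized microarray/RNA time
courses, with ontology annotations and literature co-citations as prior
evidence.

## Method

1. **Functional-linkage probability.** For every unordered gene pair the
   package computes
   - a GO semantic similarity: each term pair (s, t) across the two
     genes' annotations scores 2·IC(MICA)/(IC(s) + IC(t)), where
     IC(t) = −ln f(t)/f(root) is the information content from annotation
     frequencies and MICA is the most informative common ancestor; the
     gene-pair similarity is the maximum over term pairs, in [0, 1];
   - a co-citation p-value: the upper-tail hypergeometric probability
     P(#shared abstracts ≥ k | n, m, N) for genes cited in n and m of N
     abstracts.

   Both features are binned (similarity: [1,1], [0.2,1), [0,0.2);
   −log10 p: (4,∞), (3,4], (1,3], [0,1]) and fused by a naive Bayes
   classifier trained on a positive/negative benchmark of linked and
   unlinked pairs, giving `p_link(i, j) = p_link(j, i)`. Per-bin evidence
   utility is scored as `LLS = ln [P(L|D)/P(~L|D)] / [P(L)/P(~L)]`.

2. **Edge reservoir.** Each pair enters a candidate-edge multiset with
   `N(edge_ij) = Ceil(10 · p_link)` copies (at least 1, at most 10).

3. **Structure MCMC.** Starting from the empty DAG, each iteration draws
   a pair from the reservoir (probability ∝ copies, orientation uniform)
   and applies the induced move — delete the edge if present, reverse the
   opposite edge if present, otherwise add it. Proposals violating
   acyclicity or the fan-in cap are discarded with the current DAG kept.
   Moves are accepted by the Metropolis–Hastings rule on the BDe (BDeu)
   family-score ratio, `bf1·bf2·prior_new/prior_old ≥ u·R_HM`, with
   R_HM = 1 under the frozen reservoir. DAGs are recorded at fixed
   intervals after burn-in and averaged (posterior-weighted) into an edge
   probability matrix; independent runs are combined by a consensus rule
   (edge kept when observed in more than `minRuns` of the runs).

A fully-tested synthetic module generates the study conditions end to
end: a 76-gene / 24-regulator / 124-edge topology with heavy-tailed
out-degrees, Hill-kinetics expression over 50 time points with correlated
root inputs and log-normal noise, and ontology/citation fixtures whose
truly linked pairs carry planted signal.

## Worked example

```r
library(priornet)

net <- generateNetwork(40, 12, 60, seed = 101)      # ground truth
se  <- simulateExpression(net, 50, seed = 201)       # 40 x 50 time course
pk  <- generatePriorKnowledge(net, seed = 301)       # GO + citations
bench <- benchmarkFromNetwork(net, seed = 401)

tab <- pLinkTable(pk$ontology, pk$annotations, pk$citations,
                  networkGenes(net), bench)
res <- buildReservoir(tab)
res
#> EdgeReservoir: 780 pairs, total size 1373

de  <- discretizeExpression(imputeMissing(se))
cfg <- chainConfig(burnIn = 5000, nIteration = 20000,
                   sampleInterval = 100, seed = 511)
run <- runChain(de, res, cfg)
run
#> ChainRun: 150 samples; 590 accepted moves; 9157 invalid proposals

pred <- topEdges(averagedNetwork(run), 60)
compareToBenchmark(pred, networkEdges(net), directed = TRUE,
                   possibleTotal = pairUniverseSize(40))$truePositives
#> [1] 9
```

The reservoir holds all 780 pairs with 1373 total copies, so
prior-supported pairs are proposed up to 10× more often. Of the 60
top-weighted predicted edges, 9 are true regulatory edges — against an
expectation of 60·60/1560 ≈ 2.3 under random selection. A single short
chain is noisy; the test suite runs three chains per method over ten
generator seeds and verifies that the prior-informed learner recovers at
least 1.5× the true edges of the plain-BN baseline
(`uniformReservoir(networkGenes(net))`) at matched predicted-edge
counts.

The `priornet` script under `inst/scripts/` exposes the same pipeline as
shell subcommands (`simulate`, `prior`, `learn`, `consensus`,
`evaluate`), with YAML config support and per-run metadata JSON.

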