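# treesum

Posterior tree summarization and rogue-taxon diagnostics for Bayesian
tip-dated phylogenies.

## The problem

Total-evidence tip-dating of extinct clades (morphological characters, all
taxa fossils, a fossilized birth-death tree prior) typically yields posterior
tree samples with low clade support, not because the backbone signal is weak
but because a handful of *wildcard* (rogue) taxa reattach all over the tree
and dilute the posterior probability of every clade they wander through.
`treesum` implements the summarization and diagnostic toolkit for this
situation, aimed at paleo-phylogeneticists working with BEAST-style posterior
samples:

- **Clade support and MCC trees.** The posterior probability (PP) of a clade
  is the proportion of sampled trees containing it. The maximum clade
  credibility (MCC) tree is the sampled tree maximizing
  `sum(log PP(clade))` over its nontrivial clades; node heights are the
  selected tree's own heights ("keep target heights") and every node is
  annotated with its PP.
- **A-posteriori pruned MCC trees.** All but a chosen set of representative
  taxa are pruned from every posterior tree *before* summarization (no
  re-analysis). For each pruned-MCC clade, the *equivalent node* in the full
  MCC tree is the smallest clade containing the same taxa; the comparison
  quantifies how much support the wildcards were hiding, and flags
  *contradicting* nodes whose equivalent clade captures other retained taxa.
- **Tree similarities.** Normalized bipartition similarity
  (shared nontrivial clades / (n − 2); random-pair expectation 0) and
  quartet similarity (fraction of agreeing 4-taxon resolutions; random-pair
  expectation 1/3, affinely rescaled to 0), exact up to a configurable
  limit and seeded Monte Carlo beyond it.
- **Rogue diagnostics.** Per-taxon leaf stability indices
  (`lsDif = mean(f1 − f2)`, `lsMax = mean(f1)`,
  `lsEnt = mean(1 − H(f)/log 3)` over quartet resolution frequencies
  `f1 ≥ f2 ≥ f3`), and closest-tip node-distance profiles: the node
  distances from each taxon to its three closest MCC-tree neighbours,
  tracked through the whole posterior (mean, max, 95th percentile).
- **Synthetic posteriors.** A fossilized birth-death simulator with sampled
  ancestors (zero-length branches), stage-slice stratigraphic tip-age
  binning with fossil-site synchronization, and a pseudo-posterior
  generator with controllable wildcard taxa — the ground-truth test bed for
  all of the above.

Input/output is BEAST-dialect NEXUS/Newick with `[&key=value]` node
annotations, which are preserved verbatim and round-tripped.

## Worked example

```r
library(treesum)

backbone <- randomTimeTree(14, seed = 4)
s <- generatePseudoPosterior(backbone, wildcards = c("t3", "t8", "t12"),
                             nTrees = 100, locality = 0, seed = 5)

full <- mccTree(s)
meanCladePP(full)
#> [1] 0.4175

stable <- setdiff(backbone$tip.label, c("t3", "t8", "t12"))
pm <- prunedMcc(s, stable)
summarizeSupport(equivalentNodes(full, pm, stable))
#>   n meanPPFull meanPPPruned  meanDiff nContradicting
#> 1 9  0.5022222            1 0.4977778              0

head(stabilityReport(s, full, seed = 8)[, c("taxon", "lsDif", "ct1mean")], 4)
#>   taxon     lsDif ct1mean
#> 1    t1 0.6593706    1.33
#> 2   t10 0.5370629    4.39
#> 3   t11 0.6593357    1.33
#> 4   t12 0.3197902    4.91
```

Three uniform wildcards depress the mean clade PP of the full MCC tree to
0.42; pruning them from the posterior before summarization restores every
backbone clade to PP 1.0 (mean equivalent-node gain +0.50, no
contradictions). In the stability report the wildcard t12 shows the expected
signature: low `lsDif` (0.32 vs ~0.66 for stable taxa) and a large mean
node distance to its closest MCC neighbour (4.9 vs 1.3 for taxa whose
neighbourhood is itself stable — t10's distance is inflated because its
closest MCC neighbour happens to be a wildcard).

A YAML-driven end-to-end run (`runSummary("config.yaml")`) writes annotated
NEXUS trees, TSV report tables and a JSON manifest; see the methods
vignette (`vignettes/treesum-methods.Rmd`) and the thin CLI wrapper in
`inst/scripts/treesum-cli.R` (verbs `summarize`, `prune-mcc`, `compare`,
`stability`, `simulate`).

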