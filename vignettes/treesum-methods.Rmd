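---
title: "Summarizing tip-dated posteriors and diagnosing wildcard taxa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Summarizing tip-dated posteriors and diagnosing wildcard taxa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treesum)
```

## Scope and model

`treesum` operates downstream of Bayesian tip-dating: its input is a
posterior sample of rooted, time-calibrated binary trees whose tips are
fossil taxa, possibly including *sampled ancestors* — fossils that lie on an
internal lineage rather than at a terminal one. Following the convention of
BEAST-family software output, a sampled ancestor is represented as a tip
attached by a branch of length at most a small epsilon (default `1e-8` my);
no degree-2 nodes are used internally, which keeps clade extraction and
pruning uniform. All statistics treat sampled-ancestor tips as ordinary
tips; BEAST's sampled-ancestor summarization is known to depress clade
posterior probabilities slightly, and we document rather than correct this.

A `timeTree` stores node ages (time before present, my) as the primary
quantity; branch lengths are always derived as parent-child age differences
and the two are kept consistent to `1e-9` by construction. When a tree is
read from Newick without height annotations, ages are measured backward from
the youngest tip — fossil trees are not ultrametric, so there is no "present
tip set" to anchor on; explicit `height` annotations, when complete, win.
Negative branch lengths (which "keep target heights" MCC summaries can
produce under high root-age uncertainty) are preserved and flagged with a
warning, never clamped.

## Clade support, MCC and pruned MCC trees

The posterior probability (PP) of a clade is the proportion of sampled trees
containing that taxon subset as a rooted clade. Clades, not unrooted splits,
are the bookkeeping unit because tip-dated trees are rooted by construction
and support is conventionally reported per clade. The MCC tree is the
*sampled* tree maximizing the sum of log clade PPs over its nontrivial
clades (the product-of-PPs rule used by TreeAnnotator; the all-taxa root
clade is trivial and excluded), with ties broken by first occurrence in the
sample. Node heights are the selected tree's own sampled heights; no
common-ancestor or mean-height re-estimation is performed.

A-posteriori pruning removes all but a retained taxon set from *every*
posterior tree (suppressing degree-2 nodes; surviving node ages are
unchanged) and then summarizes the pruned sample. Because wildcard taxa no
longer fragment the bookkeeping, clade PPs can only benefit from the removal
of conflict they caused. The *equivalent node* of a pruned-MCC clade is the
MRCA clade of the same taxa in the full MCC tree — the smallest full-tree
clade containing them. We flag the record as *contradicting* when that MRCA
clade, restricted to the retained taxa, contains retained taxa outside the
pruned clade: the two summaries then disagree about the retained taxa
themselves, not merely about the pruned ones. For contradicting records the
full-tree PP reported is that of the MRCA clade (a best-matching-clade
definition would be equally defensible; the flag makes the choice
inspectable).

## Tree similarities

Both similarity metrics are normalized so that 1.0 means identically
resolved trees, and both are computed after restricting the pair to their
shared taxa.

*Bipartition similarity* is the number of nontrivial rooted clades resolved
in both trees divided by `n_shared - 2`, the count attained by a fully
resolved rooted binary tree. The denominator is fixed at `n_shared - 2`
rather than either tree's own resolved-clade count, so that partially
resolved inputs are penalized symmetrically. Two independent random trees
share almost no clades, so the expectation is near 0 — though not exactly 0
at finite size: under the uniform (PDA) model on 20 taxa the exact
expectation is `sum_k C(20,k) P_k^2 / 18 = 0.0090`, with
`P_k = (2k-3)!! (2(21-k)-3)!! / 37!!` the probability that a fixed k-subset
is a clade. The package's tests treat values in this range as "near zero".

*Quartet similarity* is the fraction of the `C(n,4)` shared-taxon quartets
whose induced unrooted resolution agrees between the trees. In a rooted
time tree the resolution of `{a,b,c,d}` is read off pairwise MRCA ages: the
pair whose MRCA is strictly youngest is a cherry of the induced quartet,
and the split containing it wins; an age tie across competing splits leaves
the quartet unresolved. This rule is deterministic, needs no rerooting, and
works on non-ultrametric trees. Unresolved quartets count as unshared
unless identically unresolved in both trees; MCC inputs are fully resolved
point estimates, so this path only matters for user-supplied consensus
trees. Agreement for two random trees has expectation exactly 1/3 (for any
label-exchangeable tree model, each of the three resolutions of a fixed
quartet is equally likely), motivating the affine rescaling
`(s - 1/3)/(2/3)` that maps the random expectation to 0 while fixing 1.

Exact enumeration is used up to 30 shared taxa (`C(30,4) = 27405` quartets);
beyond that a seeded Monte Carlo estimator samples quartets uniformly with
replacement (default `1e5`), reporting the binomial standard error
`sqrt(p(1-p)/m)`. The estimator is exactly unbiased and its seed is recorded
so runs are reproducible bit-for-bit.

## Leaf stability and closest-tip node distances

For a focal taxon `t`, every triplet `{a,b,c}` of other taxa defines a
quartet `{t,a,b,c}` whose resolution frequencies across the posterior,
sorted `f1 >= f2 >= f3` (summing to at most 1; the remainder is
unresolved), measure how consistently `t` is placed:

- `lsDif = mean(f1 - f2)` — the margin of the winning resolution;
- `lsMax = mean(f1)` — the winning frequency itself;
- `lsEnt = mean(1 - H(p)/log 3)` — one minus the normalized Shannon entropy
  of the frequencies renormalized over resolved quartets.

The rogue-detection literature describes these three indices as the
difference, maximum and entropy variants of leaf stability without printing
formulas; the definitions above are our operationalization and are
documented as such. Unresolved quartets contribute to none of `f1..f3` and
frequencies are *not* renormalized for `lsDif`/`lsMax` (so lack of
resolution is not mistaken for conflict), but are renormalized for `lsEnt`
(entropy over nothing being undefined; a fully unresolved triplet
contributes 0). Triplets are enumerated exhaustively up to 20 taxa;
above that a seeded uniform sample of triplets (default 1000 per taxon) is
used — exhaustive enumeration over hundreds of taxa times tens of thousands
of trees is not feasible, and the sampled estimator agrees with the
exhaustive one within Monte Carlo error on small fixtures.

Leaf stability says *that* a taxon is unstable but not *how far* it moves.
The complementary diagnostic fixes each taxon's three closest tips on the
full MCC tree (node distance = number of internal nodes on the tip-to-tip
path; 1 for sister pairs and for a tip with its zero-length sampled
ancestor; three neighbours, because that creates quartet statements) and
tracks the distances to those same tips through every posterior tree,
reporting mean, maximum and the 95th percentile (empirical order statistic
with linear interpolation). Wildcards show low `lsDif` *and* large mean
closest-tip distances; a stable taxon whose closest MCC neighbour happens to
be a wildcard inherits an inflated distance, which is worth remembering when
reading the report. Closest-tip ties are broken lexicographically for
determinism.

## The synthetic test bed

Because real posteriors of this kind are only reproducible by weeks of
MCMC, the package ships a generator whose outputs have analytic ground
truth.

`simulateFbdTree()` runs the fossilized birth-death process forward from the
origin (speciation `lambda`, extinction `mu`, fossil sampling `psi`, all
per lineage per my; the `(d, r, s)` reparametrization `d = lambda - mu`,
`r = mu/lambda`, `s = psi/(mu+psi)` is provided with exact inverse). Extant
sampling is fixed at 0 — the use case is fully extinct clades — so the
reconstructed tree spans fossil samples only, and fossils with sampled
descendants become zero-length sampled-ancestor tips. The simulator's truth
record (tip counts, sampled-ancestor flags) is what the I/O layer's
`countSampledAncestors()` is validated against. Rejection sampling
conditions on a minimum sample count, with an attempt cap that errors with
advice rather than spinning.

`stageSliceBoundaries()` implements equal-duration subdivision of geologic
stages (e.g. the Dapingian, 470.0–467.3 mya, three slices with boundaries
469.1 and 468.2 mya), and `assignTipAges()` draws tip ages uniformly within
their stage-slice interval, with tips from the same fossil site receiving a
single shared draw from the intersection of their intervals — fossils from
one horizon are contemporaneous, and leaving them independent would let
same-site tips drift apart by millions of years. Cambrian-style zone
schemes without printed absolute ages are supported by passing explicit
intervals rather than a named stratigraphy.

`generatePseudoPosterior()` emulates the *phenomenology* of such posteriors
rather than MCMC itself: a fixed backbone (optionally jittered by one
age-valid NNI per tree with probability `nniProb`), plus designated
wildcards that are detached and reattached every tree. Reattachment weight
is `exp(-locality * d)` over candidate branches, `d` being the node distance
from the wildcard's true attachment point: `locality = 0` is uniform
reattachment, `locality = Inf` pins the wildcard at home. (An equivalent
rate form `exp(-d/scale)` was considered; the concentration form was chosen
so that *larger* locality means *more* local, matching the parameter's
name and the pinned limit.) With no perturbation the generator is an exact
identity — every tree equals the backbone, every clade PP is 1, every
similarity is 1, every `lsDif` is 1 — which is tested end-to-end. The
generator reproduces the qualitative patterns the summarization procedure
is designed to expose (support recovery under pruning that grows with the
wildcard count; quartet similarity exceeding bipartition similarity under
NNI perturbation; wildcards in the low-`lsDif`, high-distance tail), but it
does not emulate character-data likelihoods, clock-rate variation, or the
correlated topology proposals of real MCMC, so passing these tests
validates the *statistics*, not any inference engine.

## Numerical and design choices

- Uniformly random rooted topologies (for null expectations) are drawn by
  sequential attachment — tip `k+1` subtends any of the `2k-1` existing
  branches including the root stem — which is exactly uniform over the
  `(2n-3)!!` labelled shapes; ages are topological heights, sufficient for
  topology-only statistics and free of cross-split MRCA-age ties.
- Burn-in is `floor(n * fraction)` leading trees per run, applied before
  concatenating runs, matching LogCombiner-style merging; `combineRuns()`
  therefore returns `sum(ceil((1-f) n_i))` trees deterministically.
- MCC ties (identical scores) go to the first occurrence in the sample;
  closest-tip and triplet ties are broken lexicographically.
- All Monte Carlo entry points (`quartetSimilarityMC()`, `leafStability()`
  sampling mode, the generators) take explicit seeds and restore the
  caller's RNG state, so pipelines are reproducible byte-for-byte — the
  run manifest written by `runSummary()` records every seed, burn-in count
  and estimator mode.
- Degenerate inputs error early and specifically: empty samples, pruning to
  fewer than 3 taxa, fewer than 4 shared taxa in comparisons, tip-age
  intervals that violate the parent node's age, non-invertible `(d, r, s)`
  corners (`r = 0, s = 1`).

## Problem sizes used in validation

The shipped test-and-acceptance suite exercises the package at desk scale,
chosen to make every statistic's expected behaviour checkable in minutes:
random-tree null expectations on 1000 pairs of 20-taxon trees; Monte Carlo
vs exact quartet equivalence on 1000 seeded trials over 12-taxon pairs;
pseudo-posteriors of 14 taxa x 100 trees with up to 3 wildcards; 1000
seeded FBD simulations for sampled-ancestor bookkeeping; 10^6 draws for the
origin-prior mean. Round-trip and consistency properties run over hundreds
of random trees per check.

## Known limitations

- The bipartition denominator `n_shared - 2` is a convention; comparisons
  against tools normalizing by each tree's own resolved-split count will
  differ on partially resolved inputs.
- Quartet similarity is computed by enumeration or sampling, not by the
  sub-quartic tqDist algorithm; at the package's intended scale (tens of
  taxa, thousands of trees) this is not limiting.
- Majority-rule consensus trees, HPD node-height annotation and rogue-taxon
  *removal* optimization (dropset search) are out of scope; the diagnostics
  identify wildcards but the pruning choice is the user's.
- The pseudo-posterior generator perturbs topology only; branch-length
  posteriors are not emulated beyond the attachment-age draws.
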