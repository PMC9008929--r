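Package: treesum
Title: Posterior Tree Summarization and Rogue-Taxon Diagnostics for Tip-Dated Phylogenies
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Summarizes Bayesian posterior samples of time-calibrated trees
    with sampled ancestors: maximum clade credibility (MCC) trees with
    clade posterior probabilities, a-posteriori pruned MCC trees and
    equivalent-node comparison, normalized bipartition and quartet tree
    similarities, and per-taxon rogue diagnostics (leaf stability indices
    and closest-tip node-distance profiles). Includes a fossilized
    birth-death simulator with sampled ancestors, stage-slice tip-age
    binning with fossil-site synchronization, and a pseudo-posterior
    generator with controllable wildcard taxa for method validation.
    Reads and writes NEXUS/Newick with BEAST-style node annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape,
    phangorn,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
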