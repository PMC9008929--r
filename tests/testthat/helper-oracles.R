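# independent oracles built on ape, used to cross-check treesum internals

# canonical signature of the induced unrooted quartet topology: the
# lexicographically smaller side of the split, read off the induced 4-tip
# tree's cherry clade
oracleQuartetSignature <- function(phy, tips4) {
  sub <- ape::keep.tip(phy, tips4)
  pp <- ape::prop.part(sub)
  sizes <- lengths(pp)
  cherry <- pp[[which(sizes == 2L)[1L]]]
  pair <- sort(attr(pp, "labels")[cherry])
  other <- sort(setdiff(tips4, pair))
  sides <- sort(c(paste(pair, collapse = ","), paste(other, collapse = ",")))
  paste(sides, collapse = "|")
}

# brute-force quartet similarity by enumerating every 4-subset via ape
oracleQuartetSimilarity <- function(a, b) {
  pa <- asPlainPhylo(a); pb <- asPlainPhylo(b)
  shared <- sort(intersect(pa$tip.label, pb$tip.label))
  subsets <- utils::combn(shared, 4L)
  agree <- vapply(seq_len(ncol(subsets)), function(i) {
    oracleQuartetSignature(pa, subsets[, i]) ==
      oracleQuartetSignature(pb, subsets[, i])
  }, logical(1))
  mean(agree)
}

# clade -> relative frequency via ape::prop.part (rooted clades)
oracleCladeFreqs <- function(sample) {
  phys <- lapply(sample, asPlainPhylo)
  class(phys) <- "multiPhylo"
  pp <- ape::prop.part(phys)
  labs <- attr(pp, "labels")
  key <- vapply(pp, function(ix) paste(sort(labs[ix]), collapse = ";"), character(1))
  stats::setNames(attr(pp, "number") / length(sample), key)
}

# internal nodes on the tip-to-tip path, via ape::nodepath
oracleNodeDistance <- function(tree, a, b) {
  phy <- asPlainPhylo(tree)
  path <- ape::nodepath(phy, match(a, phy$tip.label), match(b, phy$tip.label))
  length(path) - 2L
}

# leaf stability by enumerating induced quartet topologies with ape
oracleLeafStability <- function(sample, taxon) {
  tips <- sampleTipLabels(sample)
  others <- setdiff(tips, taxon)
  trips <- utils::combn(others, 3L)
  phys <- lapply(sample, asPlainPhylo)
  f <- t(vapply(seq_len(ncol(trips)), function(i) {
    tips4 <- c(taxon, trips[, i])
    sigs <- vapply(phys, oracleQuartetSignature, character(1), tips4 = tips4)
    sort(tabulate(factor(sigs, levels = unique(sigs)), nbins = 3) / length(phys),
         decreasing = TRUE)
  }, numeric(3)))
  s <- rowSums(f)
  p <- f / s
  plogp <- ifelse(p > 0, p * log(p), 0)
  c(lsDif = mean(f[, 1] - f[, 2]),
    lsEnt = mean(1 + rowSums(plogp) / log(3)),
    lsMax = mean(f[, 1]))
}

# exhaustive MCC selection: score every sampled tree by the sum of log clade
# frequencies computed with ape
oracleMccIndex <- function(sample) {
  freqs <- oracleCladeFreqs(sample)
  n <- length(sampleTipLabels(sample))
  scores <- vapply(sample, function(tr) {
    phy <- asPlainPhylo(tr)
    pp <- ape::prop.part(phy)
    labs <- attr(pp, "labels")
    keys <- vapply(pp, function(ix) paste(sort(labs[ix]), collapse = ";"), character(1))
    keys <- keys[lengths(pp) < n]  # nontrivial only
    sum(log(freqs[keys]))
  }, numeric(1))
  which.max(scores)
}
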