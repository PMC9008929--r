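#' Node distance between two tips
#'
#' Number of internal nodes on the path between two tips. Sister tips — and a
#' tip with its zero-length sampled-ancestor — are at the minimum distance of
#' 1, which always indicates a monophyletic sister-group relationship.
#'
#' @param tree a [timeTree()] or `phylo`.
#' @param tipA,tipB tip labels.
#' @return an integer count (>= 1 for distinct tips).
#' @export
nodeDistance <- function(tree, tipA, tipB) {
  D <- nodeDistanceMatrix(tree)
  for (t in c(tipA, tipB)) {
    if (!t %in% tree$tip.label) stop("tip absent from tree: ", t)
  }
  D[tipA, tipB]
}

# all-pairs tip node distances (internal nodes on path), labelled matrix
nodeDistanceMatrix <- function(tree, tips = sort(tree$tip.label)) {
  dep <- nodeDepthsEdges(tree)
  tipDep <- dep[match(tips, tree$tip.label)]
  Mm <- mrcaDepthMatrix(tree, tips)
  D <- outer(tipDep, tipDep, "+") - 2L * Mm - 1L
  diag(D) <- 0L
  dimnames(D) <- list(tips, tips)
  D
}

#' Closest tips of a taxon on a summary tree
#'
#' The `k` tips with the smallest node distance to `taxon` on the tree
#' (typically the full MCC tree); ties are broken by label order.
#'
#' @param mcc a [timeTree()].
#' @param taxon a tip label.
#' @param k how many neighbours (default 3, which creates quartet
#'   statements).
#' @return character vector of length `k`, nearest first.
#' @export
closestTips <- function(mcc, taxon, k = 3) {
  if (!taxon %in% mcc$tip.label) stop("tip absent from tree: ", taxon)
  if (k >= length(mcc$tip.label)) stop("k must be smaller than the number of tips")
  D <- nodeDistanceMatrix(mcc)
  d <- D[taxon, setdiff(colnames(D), taxon)]
  names(d)[order(d, names(d))][seq_len(k)]
}

#' Closest-tip node-distance profile across a posterior sample
#'
#' Fixes the `k` closest tips of `taxon` on the MCC tree, then tracks the
#' node distance between `taxon` and each of them through every posterior
#' tree. Large means relative to the MCC distances reveal unstable
#' (wildcard-like) placements.
#'
#' @param sample a [treeSample()].
#' @param mcc the summary tree defining the closest tips.
#' @param taxon a tip label.
#' @param k number of closest tips (default 3).
#' @param distanceMatrices optional precomputed list of node-distance
#'   matrices (one per tree, as produced internally); used by
#'   [stabilityReport()] to avoid recomputation.
#' @return a `data.frame` with one row per rank: `rank`, `closestTip`,
#'   `mccDistance`, `mean`, `max`, `q95` (95th percentile, linear
#'   interpolation).
#' @export
instabilityProfile <- function(sample, mcc, taxon, k = 3,
                               distanceMatrices = NULL) {
  ct <- closestTips(mcc, taxon, k = k)
  tips <- sampleTipLabels(sample)
  if (is.null(distanceMatrices)) {
    distanceMatrices <- lapply(sample, nodeDistanceMatrix, tips = tips)
  }
  mccD <- nodeDistanceMatrix(mcc)
  rows <- lapply(seq_len(k), function(r) {
    d <- vapply(distanceMatrices, function(D) D[taxon, ct[r]], numeric(1))
    data.frame(rank = r, closestTip = ct[r],
               mccDistance = mccD[taxon, ct[r]],
               mean = mean(d), max = max(d),
               q95 = unname(stats::quantile(d, 0.95)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Leaf stability indices of a taxon
#'
#' Over triplets \{a, b, c\} of other taxa, the quartet \{t, a, b, c\} takes
#' one of three resolutions in each tree of the sample, with frequencies
#' sorted `f1 >= f2 >= f3` (`f1 + f2 + f3 <= 1`; the remainder is
#' unresolved). The indices average over triplets:
#' `lsDif = mean(f1 - f2)`, `lsMax = mean(f1)`, and
#' `lsEnt = mean(1 - H(p) / log 3)` with `H` the Shannon entropy of the
#' frequencies renormalized over resolved quartets. A taxon resolved
#' identically in every tree scores 1 on all three.
#'
#' Triplets are enumerated exhaustively for up to `exhaustiveLimit` taxa,
#' otherwise `quartetBudget` triplets are sampled uniformly (seeded).
#'
#' @param sample a [treeSample()].
#' @param taxon a tip label.
#' @param quartetBudget triplets sampled per taxon when not exhaustive.
#' @param seed optional integer seed for triplet sampling.
#' @param exhaustiveLimit taxon count up to which all triplets are used
#'   (default 20).
#' @param ageMatrices optional precomputed MRCA-age matrices (internal reuse).
#' @return named numeric vector `c(lsDif, lsEnt, lsMax)`.
#' @export
leafStability <- function(sample, taxon, quartetBudget = 1000, seed = NULL,
                          exhaustiveLimit = 20, ageMatrices = NULL) {
  stopifnot(inherits(sample, "treeSample"), length(sample) >= 1L)
  tips <- sampleTipLabels(sample)
  if (!taxon %in% tips) stop("tip absent from sample: ", taxon)
  if (length(tips) < 4L) stop("need at least 3 other taxa")
  if (is.null(ageMatrices)) {
    ageMatrices <- lapply(sample, mrcaAgeMatrix, tips = tips)
  }
  t <- match(taxon, tips)
  others <- setdiff(seq_along(tips), t)
  trip <- tripletSet(others, length(tips) <= exhaustiveLimit, quartetBudget, seed)
  freq <- tripletFrequencies(ageMatrices, t, trip)
  leafStabilityFromFrequencies(freq)
}

# triplet index matrix (m x 3) over `others`
tripletSet <- function(others, exhaustive, budget, seed) {
  if (exhaustive) return(t(utils::combn(others, 3L)))
  stopifnot(budget >= 1)
  withSeed(seed, {
    draw <- function(m) {
      M <- cbind(sample(others, m, replace = TRUE), sample(others, m, replace = TRUE),
                 sample(others, m, replace = TRUE))
      M[M[, 1] != M[, 2] & M[, 1] != M[, 3] & M[, 2] != M[, 3], , drop = FALSE]
    }
    out <- draw(budget)
    while (nrow(out) < budget) out <- rbind(out, draw(budget - nrow(out) + 8L))
    out[seq_len(budget), , drop = FALSE]
  })
}

# per-triplet resolution frequencies over the sample: m x 4 matrix with
# columns f(ta|bc), f(tb|ac), f(tc|ab), f(unresolved)
tripletFrequencies <- function(ageMatrices, t, trip) {
  m <- nrow(trip)
  counts <- matrix(0L, m, 4L)
  for (M in ageMatrices) {
    s1 <- pmin(M[cbind(t, trip[, 1])], M[trip[, c(2, 3), drop = FALSE]])
    s2 <- pmin(M[cbind(t, trip[, 2])], M[trip[, c(1, 3), drop = FALSE]])
    s3 <- pmin(M[cbind(t, trip[, 3])], M[trip[, c(1, 2), drop = FALSE]])
    mn <- pmin(s1, s2, s3)
    h1 <- s1 <= mn; h2 <- s2 <= mn; h3 <- s3 <= mn
    nh <- h1 + h2 + h3
    code <- integer(m) + 4L
    code[h1 & nh == 1L] <- 1L
    code[h2 & nh == 1L] <- 2L
    code[h3 & nh == 1L] <- 3L
    counts[cbind(seq_len(m), code)] <- counts[cbind(seq_len(m), code)] + 1L
  }
  counts / length(ageMatrices)
}

leafStabilityFromFrequencies <- function(freq) {
  f <- t(apply(freq[, 1:3, drop = FALSE], 1L, sort, decreasing = TRUE))
  s <- rowSums(f)
  ent <- numeric(nrow(f))
  pos <- s > 0
  if (any(pos)) {
    p <- f[pos, , drop = FALSE] / s[pos]
    plogp <- ifelse(p > 0, p * log(p), 0)
    ent[pos] <- 1 + rowSums(plogp) / log(3)
  }
  c(lsDif = mean(f[, 1] - f[, 2]),
    lsEnt = mean(ent),
    lsMax = mean(f[, 1]))
}

#' Per-taxon stability report
#'
#' Assembles, for every taxon: tip age on the MCC tree, the three leaf
#' stability indices, and the closest-tip node-distance profile (mean, max
#' and 95th percentile of the distances to the MCC tree's three closest tips,
#' tracked across the posterior sample). Deterministic for a fixed seed.
#'
#' @inheritParams leafStability
#' @param mcc the annotated full MCC [timeTree()].
#' @param k number of closest tips per taxon (default 3).
#' @return a `data.frame` with one row per taxon: `taxon`, `ageMCC`,
#'   `lsDif`, `lsEnt`, `lsMax`, then `ct<r>mean`, `ct<r>max`, `ct<r>q95` for
#'   each rank r.
#' @export
stabilityReport <- function(sample, mcc, k = 3, quartetBudget = 1000,
                            seed = NULL, exhaustiveLimit = 20) {
  stopifnot(inherits(sample, "treeSample"))
  tips <- sampleTipLabels(sample)
  stopifnot(setequal(tips, mcc$tip.label))
  ageM <- lapply(sample, mrcaAgeMatrix, tips = tips)
  distM <- lapply(sample, nodeDistanceMatrix, tips = tips)
  mccAges <- tipAges(mcc)
  rows <- lapply(seq_along(tips), function(i) {
    taxon <- tips[i]
    ls <- leafStability(sample, taxon, quartetBudget = quartetBudget,
                        seed = if (is.null(seed)) NULL else seed + i,
                        exhaustiveLimit = exhaustiveLimit, ageMatrices = ageM)
    prof <- instabilityProfile(sample, mcc, taxon, k = k,
                               distanceMatrices = distM)
    ct <- numeric(0)
    for (r in seq_len(k)) {
      v <- c(prof$mean[r], prof$max[r], prof$q95[r])
      names(v) <- paste0("ct", r, c("mean", "max", "q95"))
      ct <- c(ct, v)
    }
    cbind(data.frame(taxon = taxon, ageMCC = unname(mccAges[taxon]),
                     lsDif = ls[["lsDif"]], lsEnt = ls[["lsEnt"]],
                     lsMax = ls[["lsMax"]], stringsAsFactors = FALSE),
          as.data.frame(as.list(ct)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
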