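#' Normalized bipartition similarity
#'
#' Both trees are first restricted to their shared taxa; the similarity is
#' the number of nontrivial rooted clades resolved in both trees divided by
#' the maximum possible number, `n_shared - 2` (a fully resolved rooted
#' binary tree on n taxa has n - 2 nontrivial clades). Identical topologies
#' give 1.0; two random trees are expected near 0.0.
#'
#' @param a,b [timeTree()] objects with at least 4 shared taxa.
#' @return a fraction in `[0, 1]`.
#' @export
bipartitionSimilarity <- function(a, b) {
  st <- sharedPair(a, b)
  tipIndex <- stats::setNames(seq_along(st$tips), st$tips)
  ka <- treeCladeKeys(st$a, tipIndex)
  kb <- treeCladeKeys(st$b, tipIndex)
  length(intersect(unique(ka), unique(kb))) / (length(st$tips) - 2L)
}

sharedPair <- function(a, b) {
  shared <- intersect(a$tip.label, b$tip.label)
  if (length(shared) < 4L) {
    stop("need at least 4 shared taxa, got ", length(shared))
  }
  if (!setequal(shared, a$tip.label)) a <- pruneTimeTree(a, shared)
  if (!setequal(shared, b$tip.label)) b <- pruneTimeTree(b, shared)
  list(a = a, b = b, tips = sort(shared))
}

# ages of pairwise tip MRCAs, rows/cols ordered by `tips`
mrcaAgeMatrix <- function(tree, tips = sort(tree$tip.label)) {
  n <- length(tips)
  ord <- match(tree$tip.label, tips)
  M <- matrix(0, n, n)
  ntip <- length(tree$tip.label)
  sets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- ord[i]
  # reverse preorder: a child's subtree is complete before its edge is merged
  for (e in rev(preorderEdges(tree))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    acc <- sets[[p]]; new <- sets[[ch]]
    if (!is.null(acc)) {
      M[acc, new] <- tree$node.age[p]
      M[new, acc] <- tree$node.age[p]
    }
    sets[[p]] <- c(acc, new)
  }
  diag(M) <- tree$node.age[match(tips, tree$tip.label)]
  M
}

# quartet resolution codes from an MRCA-age matrix: for quartet (i,j,k,l),
# the split whose within-pair minimum MRCA age is the strict minimum is the
# resolution (the pair with the youngest MRCA is a cherry); ties across
# splits -> 0 (unresolved)
quartetCodes <- function(M, Q) {
  s1 <- pmin(M[Q[, c(1, 2), drop = FALSE]], M[Q[, c(3, 4), drop = FALSE]])
  s2 <- pmin(M[Q[, c(1, 3), drop = FALSE]], M[Q[, c(2, 4), drop = FALSE]])
  s3 <- pmin(M[Q[, c(1, 4), drop = FALSE]], M[Q[, c(2, 3), drop = FALSE]])
  m <- pmin(s1, s2, s3)
  code <- integer(nrow(Q))
  hit1 <- s1 <= m; hit2 <- s2 <= m; hit3 <- s3 <= m
  nhit <- hit1 + hit2 + hit3
  code[hit1 & nhit == 1L] <- 1L
  code[hit2 & nhit == 1L] <- 2L
  code[hit3 & nhit == 1L] <- 3L
  code
}

#' Exact quartet similarity
#'
#' Fraction of the `choose(n, 4)` shared-taxon quartets whose unrooted
#' resolution agrees between the two trees. Resolutions are read off the
#' time trees by comparing pairwise MRCA ages (the pair with the strictly
#' youngest MRCA is the cherry; age ties leave the quartet unresolved).
#' Random tree pairs are expected near 1/3.
#'
#' @inheritParams bipartitionSimilarity
#' @param exactLimit maximum shared-taxon count for exact enumeration
#'   (default 30); larger inputs must use [quartetSimilarityMC()].
#' @return a fraction in `[0, 1]`.
#' @export
quartetSimilarityExact <- function(a, b, exactLimit = 30) {
  st <- sharedPair(a, b)
  n <- length(st$tips)
  if (n > exactLimit) {
    stop("n_shared = ", n, " exceeds exact limit ", exactLimit,
         "; use quartetSimilarityMC()")
  }
  Q <- t(utils::combn(n, 4L))
  Ma <- mrcaAgeMatrix(st$a, st$tips)
  Mb <- mrcaAgeMatrix(st$b, st$tips)
  mean(quartetCodes(Ma, Q) == quartetCodes(Mb, Q))
}

#' Monte Carlo quartet similarity
#'
#' Unbiased estimate of [quartetSimilarityExact()] from uniformly sampled
#' quartets (with replacement), with binomial standard error
#' `sqrt(p(1-p)/m)`. Deterministic for a fixed `seed`.
#'
#' @inheritParams bipartitionSimilarity
#' @param nSamples number of sampled quartets (at least 100).
#' @param seed optional integer seed (RNG state is restored on exit).
#' @return a list with `estimate`, `se`, `nSamples`.
#' @export
quartetSimilarityMC <- function(a, b, nSamples = 1e5, seed = NULL) {
  stopifnot(nSamples >= 100)
  st <- sharedPair(a, b)
  n <- length(st$tips)
  Q <- withSeed(seed, sampleQuartets(n, nSamples))
  Ma <- mrcaAgeMatrix(st$a, st$tips)
  Mb <- mrcaAgeMatrix(st$b, st$tips)
  p <- mean(quartetCodes(Ma, Q) == quartetCodes(Mb, Q))
  list(estimate = p, se = sqrt(p * (1 - p) / nSamples), nSamples = nSamples)
}

# m uniform 4-subsets of 1..n (sorted rows), with replacement across rows
sampleQuartets <- function(n, m) {
  draw <- function(m) {
    M <- cbind(sample.int(n, m, replace = TRUE), sample.int(n, m, replace = TRUE),
               sample.int(n, m, replace = TRUE), sample.int(n, m, replace = TRUE))
    ok <- M[, 1] != M[, 2] & M[, 1] != M[, 3] & M[, 1] != M[, 4] &
      M[, 2] != M[, 3] & M[, 2] != M[, 4] & M[, 3] != M[, 4]
    M[ok, , drop = FALSE]
  }
  out <- draw(m)
  while (nrow(out) < m) out <- rbind(out, draw(m - nrow(out) + 16L))
  t(apply(out[seq_len(m), , drop = FALSE], 1L, sort))
}

#' Rescaled quartet similarity
#'
#' Affine rescaling `(s - 1/3) / (2/3)` so that the expected similarity
#' between two random trees is 0.0 and identical trees remain at 1.0.
#'
#' @param s a quartet similarity in `[0, 1]`.
#' @return the rescaled value (can be negative, minimum -0.5).
#' @export
rescaleQuartet <- function(s) {
  stopifnot(all(s >= 0 & s <= 1))
  (s - 1 / 3) / (2 / 3)
}

#' Compare a reference tree to every tree of a posterior sample
#'
#' One similarity record per posterior tree, computed on the intersection of
#' tip sets (so a pruned reference can be compared against an unpruned
#' sample). Quartet similarity is exact up to `exactLimit` shared taxa,
#' seeded Monte Carlo above.
#'
#' @param reference a [timeTree()] (e.g. an MCC tree).
#' @param sample a [treeSample()].
#' @param metrics subset of `c("bipartition", "quartet")`.
#' @param exactLimit,mcSamples,seed estimator configuration, see
#'   [quartetSimilarityExact()] and [quartetSimilarityMC()].
#' @return a `data.frame` with one row per tree (`tree`, `sharedTaxa`,
#'   `bipartition`, `quartet`, `rescaledQuartet`, `estimator`, `mcSamples`);
#'   `attr(, "summary")` holds means and quantiles per metric.
#' @export
similarityToSample <- function(reference, sample,
                               metrics = c("bipartition", "quartet"),
                               exactLimit = 30, mcSamples = 1e5, seed = NULL) {
  stopifnot(inherits(sample, "treeSample"))
  metrics <- match.arg(metrics, several.ok = TRUE)
  rows <- withSeed(seed, lapply(seq_along(sample), function(i) {
    tr <- sample[[i]]
    shared <- length(intersect(reference$tip.label, tr$tip.label))
    bs <- if ("bipartition" %in% metrics) bipartitionSimilarity(reference, tr) else NA_real_
    if ("quartet" %in% metrics) {
      if (shared <= exactLimit) {
        qs <- quartetSimilarityExact(reference, tr, exactLimit = exactLimit)
        est <- "exact"; mcs <- 0L
      } else {
        qs <- quartetSimilarityMC(reference, tr, nSamples = mcSamples)$estimate
        est <- "montecarlo"; mcs <- as.integer(mcSamples)
      }
    } else {
      qs <- NA_real_; est <- NA_character_; mcs <- NA_integer_
    }
    data.frame(tree = i, sharedTaxa = shared, bipartition = bs, quartet = qs,
               rescaledQuartet = if (is.na(qs)) NA_real_ else rescaleQuartet(qs),
               estimator = est, mcSamples = mcs, stringsAsFactors = FALSE)
  }))
  out <- do.call(rbind, rows)
  qs <- function(x) if (all(is.na(x))) rep(NA_real_, 5) else
    stats::quantile(x, c(0.025, 0.25, 0.5, 0.75, 0.975), na.rm = TRUE)
  attr(out, "summary") <- data.frame(
    metric = c("bipartition", "quartet", "rescaledQuartet"),
    mean = c(mean(out$bipartition), mean(out$quartet), mean(out$rescaledQuartet)),
    rbind(qs(out$bipartition), qs(out$quartet), qs(out$rescaledQuartet))
  )
  out
}
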