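#' Combine posterior runs with per-run burn-in
#'
#' Discards the leading `floor(n * burninFraction)` trees of each run (the
#' burn-in) and concatenates the remainders, the operation performed by
#' LogCombiner when merging independent MCMC runs.
#'
#' @param samples a list of [treeSample()] objects (one per run), or a single
#'   `treeSample`.
#' @param burninFraction proportion of each run to discard, in `[0, 1)`.
#' @return a [treeSample()] with per-tree run labels preserved.
#' @examples
#' ## two runs of 100 trees at 10% burn-in leave 180 trees
#' @export
combineRuns <- function(samples, burninFraction = 0.1) {
  if (inherits(samples, "treeSample")) samples <- list(samples)
  stopifnot(length(samples) >= 1L)
  if (burninFraction < 0 || burninFraction >= 1) {
    stop("burninFraction must be in [0, 1)")
  }
  tips <- sampleTipLabels(samples[[1L]])
  for (i in seq_along(samples)) {
    ti <- sampleTipLabels(samples[[i]])
    if (!identical(ti, tips)) {
      d <- union(setdiff(ti, tips), setdiff(tips, ti))
      stop("tip sets differ between runs; symmetric difference: ",
           paste(sort(d), collapse = ", "))
    }
  }
  trees <- list(); runs <- character(0)
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    drop <- floor(length(s) * burninFraction)
    keep <- seq_len(length(s))[-seq_len(drop)]
    if (drop == 0L) keep <- seq_len(length(s))
    trees <- c(trees, unclass(s)[keep])
    runs <- c(runs, attr(s, "runId")[keep])
  }
  if (!length(trees)) stop("burn-in removed every tree")
  treeSample(trees, runId = runs, burninFraction = burninFraction)
}

#' Count sampled-ancestor tips
#'
#' Sampled ancestors are fossils lying on internal lineages, represented as
#' tips attached by a zero-length terminal branch. Counts tips whose terminal
#' branch length is at most `epsilon`.
#'
#' @param tree a [timeTree()].
#' @param epsilon branch-length threshold in my (default `1e-8`).
#' @return integer count.
#' @export
countSampledAncestors <- function(tree, epsilon = 1e-8) {
  stopifnot(epsilon >= 0)
  ntip <- length(tree$tip.label)
  term <- tree$edge[, 2] <= ntip
  sum(tree$edge.length[term] <= epsilon)
}
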