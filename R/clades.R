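#' Extract rooted clades from a tree
#'
#' One clade (taxon subset) per internal node. Singletons are never clades;
#' the all-taxa root clade is trivial and excluded by default. Sampled
#' ancestors participate as ordinary tips, per the zero-length-branch
#' convention.
#'
#' @param tree a `timeTree` or `phylo`.
#' @param includeTrivial include the root (all-taxa) clade.
#' @return a list of character vectors of sorted member labels, named by
#'   internal node number.
#' @export
extractClades <- function(tree, includeTrivial = FALSE) {
  sets <- nodeTipSets(tree)
  ntip <- length(tree$tip.label)
  out <- lapply(sets, function(ix) sort(tree$tip.label[ix]))
  names(out) <- as.character(ntip + seq_along(out))
  if (!includeTrivial) out[[1L]] <- NULL  # root is node ntip + 1
  out
}

# per internal node, integer tip indices below it (index = node - ntip)
nodeTipSets <- function(tree) {
  ntip <- length(tree$tip.label)
  sets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- i
  for (e in rev(preorderEdges(tree))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  lapply(sets[ntip + seq_len(tree$Nnode)], sort)
}

# canonical string keys of nontrivial clades (root excluded); `tipIndex` maps
# labels to a shared integer namespace so keys agree across trees
treeCladeKeys <- function(tree, tipIndex, includeRoot = FALSE) {
  sets <- nodeTipSets(tree)
  idx <- tipIndex[tree$tip.label]
  keys <- vapply(sets, function(ix) paste(sort(idx[ix]), collapse = ","), character(1))
  if (!includeRoot) keys <- keys[-1L]
  keys
}

keyToMembers <- function(key, tipLabels) {
  lapply(strsplit(key, ",", fixed = TRUE),
         function(ix) tipLabels[as.integer(ix)])
}

#' Clade posterior probabilities of a tree sample
#'
#' The posterior probability (PP) of a clade is the proportion of trees in
#' the posterior sample that contain it.
#'
#' @param sample a [treeSample()].
#' @return a `data.frame` of class `cladeTable` with columns `clade` (sorted
#'   member labels joined by `;`), `size`, `count` and `pp`, ordered by
#'   decreasing PP; the total tree count is in `attr(, "nTrees")`.
#' @export
cladePosteriors <- function(sample) {
  stopifnot(inherits(sample, "treeSample"))
  if (!length(sample)) stop("empty tree sample")
  tips <- sampleTipLabels(sample)
  tipIndex <- stats::setNames(seq_along(tips), tips)
  keys <- unlist(lapply(sample, treeCladeKeys, tipIndex = tipIndex),
                 use.names = FALSE)
  tab <- table(keys)
  members <- keyToMembers(names(tab), tips)
  out <- data.frame(
    clade = vapply(members, paste, character(1), collapse = ";"),
    size = lengths(members),
    count = as.integer(tab),
    pp = as.integer(tab) / length(sample),
    stringsAsFactors = FALSE
  )
  ord <- order(-out$pp, out$clade)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nTrees") <- length(sample)
  attr(out, "keys") <- names(tab)[ord]
  class(out) <- c("cladeTable", "data.frame")
  out
}

#' @rdname cladePosteriors
#' @param table a `cladeTable`.
#' @param file output TSV path.
#' @export
writeCladeTable <- function(table, file) {
  utils::write.table(as.data.frame(table)[c("clade", "size", "count", "pp")],
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Maximum clade credibility tree
#'
#' Selects the sampled tree maximizing the sum of log clade posterior
#' probabilities over its nontrivial clades (equivalently the product of
#' clade PPs, the TreeAnnotator convention); ties broken by first occurrence.
#' Node heights are the selected tree's own sampled heights ("keep target
#' heights" — no re-estimation), and every internal node is annotated with
#' its clade PP (`posterior`).
#'
#' @param sample a [treeSample()].
#' @return the MCC [timeTree()] with per-node `posterior` annotations and
#'   attributes `mccIndex` (index of the chosen tree) and `logScore`.
#' @export
mccTree <- function(sample) {
  stopifnot(inherits(sample, "treeSample"))
  if (!length(sample)) stop("empty tree sample")
  tips <- sampleTipLabels(sample)
  tipIndex <- stats::setNames(seq_along(tips), tips)
  allKeys <- lapply(sample, treeCladeKeys, tipIndex = tipIndex)
  counts <- table(unlist(allKeys, use.names = FALSE))
  n <- length(sample)
  scores <- vapply(allKeys, function(k) {
    sum(log(as.integer(counts[k]) / n))
  }, numeric(1))
  best <- which.max(scores)
  tree <- annotateCladePP(sample[[best]], counts, n, tipIndex)
  attr(tree, "mccIndex") <- best
  attr(tree, "logScore") <- scores[best]
  tree
}

# write clade PPs into `posterior` annotations of every internal node
annotateCladePP <- function(tree, counts, nTrees, tipIndex) {
  ntip <- length(tree$tip.label)
  keys <- treeCladeKeys(tree, tipIndex, includeRoot = TRUE)
  for (i in seq_along(keys)) {
    node <- ntip + i
    pp <- if (i == 1L) 1.0 else as.integer(counts[keys[i]]) / nTrees
    a <- tree$annotations[[node]]
    if (is.null(a)) a <- list()
    a$posterior <- pp
    tree$annotations[[node]] <- a
  }
  tree
}

#' Mean clade posterior probability of an annotated MCC tree
#'
#' Arithmetic mean of the `posterior` annotation over nontrivial internal
#' nodes (the root, PP 1 by construction, is excluded).
#'
#' @param mcc an annotated MCC [timeTree()], as returned by [mccTree()].
#' @return a probability.
#' @export
meanCladePP <- function(mcc) {
  ntip <- length(mcc$tip.label)
  nodes <- ntip + seq_len(mcc$Nnode)[-1L]
  pp <- vapply(nodes, function(v) {
    p <- mcc$annotations[[v]][["posterior"]]
    if (is.null(p)) NA_real_ else p
  }, numeric(1))
  if (anyNA(pp)) stop("tree has unannotated internal nodes; run mccTree() first")
  mean(pp)
}
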