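#' Prune a time tree to a taxon subset
#'
#' Removes all tips outside `retained`, suppressing the resulting degree-2
#' nodes (branch lengths are summed, i.e. node ages of surviving nodes are
#' unchanged). Annotations of surviving nodes are kept.
#'
#' @param tree a [timeTree()].
#' @param retained character vector of tip labels to keep (at least 2).
#' @return the pruned [timeTree()].
#' @export
pruneTimeTree <- function(tree, retained) {
  stopifnot(inherits(tree, "timeTree"))
  missing <- setdiff(retained, tree$tip.label)
  if (length(missing)) {
    stop("retained taxa absent from tree: ", paste(missing, collapse = ", "))
  }
  if (length(retained) < 2L) stop("need at least 2 retained taxa")
  if (setequal(retained, tree$tip.label)) return(tree)
  ntip <- length(tree$tip.label)
  keep <- tree$tip.label %in% retained

  # retained-descendant counts per node
  nkeep <- integer(ntip + tree$Nnode)
  nkeep[seq_len(ntip)] <- as.integer(keep)
  for (e in rev(preorderEdges(tree))) {
    nkeep[tree$edge[e, 1]] <- nkeep[tree$edge[e, 1]] + nkeep[tree$edge[e, 2]]
  }

  children <- split(tree$edge[, 2], tree$edge[, 1])
  # follow chains of single-survivor internals down to the next real node
  resolve <- function(v) {
    repeat {
      if (v <= ntip) return(v)
      ch <- children[[as.character(v)]]
      ch <- ch[nkeep[ch] > 0L]
      if (length(ch) >= 2L) return(v)
      v <- ch
    }
  }
  newRoot <- resolve(ntip + 1L)

  # assemble parent arrays of the pruned tree in preorder
  oldId <- integer(0); parent <- integer(0)
  emit <- function(v, parentPos) {
    pos <- length(oldId) + 1L
    oldId[pos] <<- v
    parent[pos] <<- parentPos
    if (v > ntip) {
      ch <- children[[as.character(v)]]
      for (c in ch[nkeep[ch] > 0L]) emit(resolve(c), pos)
    }
    pos
  }
  emit(newRoot, 0L)

  isTip <- oldId <= ntip
  label <- tree$tip.label[oldId]  # NA for internal nodes
  age <- tree$node.age[oldId]
  annot <- tree$annotations[oldId]
  assembleTimeTree(parent, label, isTip, age = age, annot = annot)
}

# renumber parent-array representation into an ape-conventional timeTree
assembleTimeTree <- function(parent, label, isTip, age, annot = NULL) {
  ntip <- sum(isTip)
  children <- split(seq_along(parent), parent)
  ord <- integer(length(parent))
  stack <- which(parent == 0L)
  k <- 0L
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    k <- k + 1L; ord[k] <- v
    ch <- children[[as.character(v)]]
    if (!is.null(ch)) stack <- c(ch, stack)
  }
  newId <- integer(length(parent))
  tipCount <- 0L; intCount <- 0L
  for (v in ord) {
    if (isTip[v]) {
      tipCount <- tipCount + 1L
      newId[v] <- tipCount
    } else {
      intCount <- intCount + 1L
      newId[v] <- ntip + intCount
    }
  }
  nonRoot <- ord[parent[ord] != 0L]
  phy <- structure(list(edge = cbind(newId[parent[nonRoot]], newId[nonRoot]),
                        edge.length = age[parent[nonRoot]] - age[nonRoot],
                        tip.label = label[isTip][order(newId[isTip])],
                        Nnode = length(parent) - ntip),
                   class = "phylo", order = "cladewise")
  newAges <- numeric(length(parent))
  newAges[newId] <- age
  newAnn <- vector("list", length(parent))
  if (!is.null(annot)) {
    for (v in seq_along(parent)) {
      if (!is.null(annot[[v]]) && length(annot[[v]])) newAnn[[newId[v]]] <- annot[[v]]
    }
  }
  timeTree(phy, ages = newAges, annotations = newAnn)
}

#' Prune every tree of a posterior sample
#'
#' A-posteriori pruning: all non-retained species are removed from each tree
#' of the posterior set (no re-analysis), the input from which pruned MCC
#' trees are computed.
#'
#' @param sample a [treeSample()].
#' @param retained taxa to keep; at least 3.
#' @return the pruned [treeSample()].
#' @export
pruneSample <- function(sample, retained) {
  stopifnot(inherits(sample, "treeSample"))
  if (length(unique(retained)) < 3L) stop("need at least 3 retained taxa")
  missing <- setdiff(retained, sampleTipLabels(sample))
  if (length(missing)) {
    stop("retained taxa absent from sample: ", paste(missing, collapse = ", "))
  }
  treeSample(lapply(sample, pruneTimeTree, retained = retained),
             runId = attr(sample, "runId"),
             burninFraction = attr(sample, "burninFraction"))
}

#' Pruned MCC tree
#'
#' [mccTree()] computed on [pruneSample()] output: clade PPs are those of the
#' pruned posterior, based on the same tree sample as the full MCC tree.
#'
#' @inheritParams pruneSample
#' @return an annotated [timeTree()] on the retained taxa.
#' @export
prunedMcc <- function(sample, retained) {
  mccTree(pruneSample(sample, retained))
}
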