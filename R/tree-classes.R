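#' Time-calibrated trees and posterior tree samples
#'
#' A `timeTree` is an [ape::phylo] tree augmented with node ages (time before
#' present, in my) and per-node annotation maps, the working representation of
#' a tip-dated tree with fossil tips and sampled ancestors. A `treeSample` is
#' an ordered collection of `timeTree`s on one shared taxon namespace,
#' typically a (burn-in filtered) Bayesian posterior sample.
#'
#' Sampled ancestors are represented as tips attached by a terminal branch of
#' length at most a small epsilon (default `1e-8` my); no degree-2 nodes are
#' kept internally.
#'
#' @param phy an object of class `phylo`.
#' @param ages optional numeric vector of node ages (tips then internal nodes,
#'   ape numbering). When missing, ages are computed from branch lengths with
#'   the youngest tip at age 0.
#' @param annotations optional list (length `Ntip + Nnode`) of named lists of
#'   node annotations.
#' @return `timeTree()` returns an object of class `c("timeTree", "phylo")`.
#' @examples
#' tr <- parseNewick("((A:1,B:1):1,C:2);")
#' nodeAges(tr)
#' @export
timeTree <- function(phy, ages = NULL, annotations = NULL) {
  stopifnot(inherits(phy, "phylo"))
  n <- length(phy$tip.label) + phy$Nnode
  if (is.null(ages)) {
    ages <- agesFromEdgeLengths(phy)
  }
  if (length(ages) != n) stop("'ages' must have one entry per node")
  if (is.null(annotations)) annotations <- vector("list", n)
  if (length(annotations) != n) stop("'annotations' must have one entry per node")
  phy$node.age <- as.numeric(ages)
  phy$annotations <- annotations
  # branch lengths are derived from ages so the two never disagree
  phy$edge.length <- phy$node.age[phy$edge[, 1]] - phy$node.age[phy$edge[, 2]]
  class(phy) <- c("timeTree", "phylo")
  validateTimeTree(phy)
  phy
}

#' @rdname timeTree
#' @param x,tree a `timeTree`.
#' @export
nodeAges <- function(tree) {
  stopifnot(inherits(tree, "timeTree"))
  tree$node.age
}

#' @rdname timeTree
#' @export
tipAges <- function(tree) {
  stopifnot(inherits(tree, "timeTree"))
  stats::setNames(tree$node.age[seq_along(tree$tip.label)], tree$tip.label)
}

#' @rdname timeTree
#' @param node node number (ape convention); `NULL` returns the full list.
#' @export
nodeAnnotations <- function(tree, node = NULL) {
  stopifnot(inherits(tree, "timeTree"))
  if (is.null(node)) tree$annotations else tree$annotations[[node]]
}

#' Coerce a phylo object to a timeTree
#'
#' Ages are measured backward from the youngest tip unless the tree carries
#' explicit `height` annotations (which win, matching BEAST output where
#' heights are authoritative).
#'
#' @param phy a `phylo` object with branch lengths.
#' @param annotations optional per-node annotation list.
#' @return a `timeTree`.
#' @export
asTimeTree <- function(phy, annotations = NULL) {
  if (inherits(phy, "timeTree")) return(phy)
  n <- length(phy$tip.label) + phy$Nnode
  ages <- NULL
  if (!is.null(annotations)) {
    h <- vapply(annotations, function(a) {
      v <- a[["height"]]
      if (is.null(v) || !is.numeric(v) || length(v) != 1L) NA_real_ else v
    }, numeric(1))
    if (!anyNA(h)) ages <- h
  }
  timeTree(phy, ages = ages, annotations = annotations)
}

# node ages from branch lengths: depth from root, youngest tip at age 0
agesFromEdgeLengths <- function(phy) {
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  ntip <- length(phy$tip.label)
  n <- ntip + phy$Nnode
  depth <- numeric(n)
  po <- preorderEdges(phy)
  for (i in po) {
    depth[phy$edge[i, 2]] <- depth[phy$edge[i, 1]] + phy$edge.length[i]
  }
  max(depth[seq_len(ntip)]) - depth
}

# edge indices in preorder (parents before children)
preorderEdges <- function(phy) {
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  children <- split(seq_len(nrow(phy$edge)), phy$edge[, 1])
  out <- integer(nrow(phy$edge))
  stack <- children[[as.character(root)]]
  k <- 0L
  while (length(stack)) {
    e <- stack[[1L]]
    stack <- stack[-1L]
    k <- k + 1L
    out[k] <- e
    ch <- phy$edge[e, 2]
    if (ch > ntip) stack <- c(children[[as.character(ch)]], stack)
  }
  out
}

# parent lookup: parent[node], 0 for the root
parentVector <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  p <- integer(n)
  p[tree$edge[, 2]] <- tree$edge[, 1]
  p
}

#' Validate a timeTree
#'
#' Checks the structural invariants: a single root, branch lengths equal to
#' parent-child age differences (tolerance 1e-9), unique non-empty tip
#' labels. Negative branch lengths (as produced by MCC summarization with
#' "keep target heights" under high root uncertainty) are preserved but
#' trigger a warning.
#'
#' @param tree a `timeTree`.
#' @return the tree, invisibly.
#' @export
validateTimeTree <- function(tree) {
  ntip <- length(tree$tip.label)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  if (any(!nzchar(tree$tip.label))) stop("empty tip label")
  p <- parentVector(tree)
  roots <- which(p == 0L)
  roots <- roots[roots > ntip | ntip == 1L]
  if (length(roots) != 1L) stop("tree must have exactly one root")
  bl <- tree$node.age[tree$edge[, 1]] - tree$node.age[tree$edge[, 2]]
  if (any(abs(bl - tree$edge.length) > 1e-9)) {
    stop("branch lengths inconsistent with node ages (tolerance 1e-9)")
  }
  if (any(bl < -1e-9)) {
    warning("tree contains negative branch lengths; preserved as-is")
  }
  invisible(tree)
}

#' @export
print.timeTree <- function(x, ...) {
  ntip <- length(x$tip.label)
  sa <- countSampledAncestors(x)
  cat(sprintf("timeTree: %d tips, %d internal nodes, root age %.4g\n",
              ntip, x$Nnode, x$node.age[ntip + 1L]))
  if (sa > 0) cat(sprintf("  sampled-ancestor tips (zero-length branch): %d\n", sa))
  nann <- sum(!vapply(x$annotations, is.null, logical(1)))
  if (nann > 0) cat(sprintf("  annotated nodes: %d\n", nann))
  invisible(x)
}

#' Build a posterior tree sample
#'
#' @param trees a list of `timeTree`s sharing one tip label set.
#' @param runId character vector (length 1 or `length(trees)`) labelling the
#'   MCMC run each tree came from.
#' @param burninFraction burn-in fraction already applied (bookkeeping only),
#'   in `[0, 1)`.
#' @return an object of class `c("treeSample", "multiPhylo")`.
#' @export
treeSample <- function(trees, runId = "run1", burninFraction = 0) {
  if (!length(trees)) stop("empty tree sample")
  trees <- lapply(trees, asTimeTree)
  tips <- sort(trees[[1L]]$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), tips)) {
      d <- union(setdiff(trees[[i]]$tip.label, tips), setdiff(tips, trees[[i]]$tip.label))
      stop("tree ", i, " tip set differs; symmetric difference: ",
           paste(d, collapse = ", "))
    }
  }
  if (burninFraction < 0 || burninFraction >= 1) stop("burninFraction must be in [0, 1)")
  runId <- rep_len(as.character(runId), length(trees))
  structure(trees,
            class = c("treeSample", "multiPhylo"),
            tipLabels = tips,
            runId = runId,
            burninFraction = burninFraction)
}

#' @rdname treeSample
#' @param x a `treeSample`.
#' @export
sampleTipLabels <- function(x) attr(x, "tipLabels")

#' @export
print.treeSample <- function(x, ...) {
  cat(sprintf("treeSample: %d trees, %d taxa, %d run(s), burn-in fraction %.3g\n",
              length(x), length(attr(x, "tipLabels")),
              length(unique(attr(x, "runId"))), attr(x, "burninFraction")))
  invisible(x)
}

#' @export
`[.treeSample` <- function(x, i) {
  treeSample(unclass(x)[i], runId = attr(x, "runId")[i],
             burninFraction = attr(x, "burninFraction"))
}
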