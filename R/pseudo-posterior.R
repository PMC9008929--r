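#' Uniformly random rooted binary time tree
#'
#' Draws a topology uniformly over all `(2n-3)!!` labelled rooted binary
#' topologies by sequential attachment (each new tip subtends any existing
#' edge, including the root stem, with equal probability). Node ages are set
#' to topological heights (tips at 0, each parent one unit older), which is
#' sufficient for topology-based statistics.
#'
#' @param n number of tips.
#' @param labels optional tip labels (default `t1..tn`).
#' @param seed optional integer seed.
#' @return a [timeTree()].
#' @export
randomTimeTree <- function(n, labels = NULL, seed = NULL) {
  stopifnot(n >= 2)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  stopifnot(length(labels) == n, !anyDuplicated(labels))
  withSeed(seed, {
    # parent array over working ids; node 1 = current root
    parent <- c(0L, 1L, 1L)
    isTip <- c(FALSE, TRUE, TRUE)
    tipOf <- c(NA_integer_, 1L, 2L)
    for (k in seq_len(n)[-(1:2)]) {
      edgeChildren <- seq_along(parent)  # child ends; index 1 = root stem
      v <- edgeChildren[sample.int(length(edgeChildren), 1L)]
      newInt <- length(parent) + 1L
      newTip <- length(parent) + 2L
      parent[newInt] <- parent[v]
      parent[v] <- newInt
      parent[newTip] <- newInt
      isTip[newInt] <- FALSE; isTip[newTip] <- TRUE
      tipOf[newInt] <- NA_integer_; tipOf[newTip] <- k
    }
    lab <- rep(NA_character_, length(parent))
    lab[isTip] <- labels[tipOf[isTip]]
    age <- topologicalAges(parent, isTip)
    assembleTimeTree(parent, lab, isTip, age = age)
  })
}

# age = max edge count to a descendant tip (tips at 0)
topologicalAges <- function(parent, isTip) {
  n <- length(parent)
  children <- split(seq_len(n), parent)
  age <- numeric(n)
  # process nodes in an order where children come first
  ord <- integer(0)
  stack <- which(parent == 0L)
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    ord <- c(ord, v)
    ch <- children[[as.character(v)]]
    if (!is.null(ch)) stack <- c(ch, stack)
  }
  for (v in rev(ord)) {
    ch <- children[[as.character(v)]]
    if (!is.null(ch)) age[v] <- max(age[ch]) + 1
  }
  age
}

# one random age-valid NNI move; returns the tree unchanged if none exists
applyRandomNNI <- function(tree) {
  ntip <- length(tree$tip.label)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  p <- parentVector(tree)
  age <- tree$node.age
  # candidate moves: internal edge (u, v); swap a child x of v with the
  # sibling w of v (valid when age(w) < age(v))
  moves <- list()
  for (e in seq_len(nrow(tree$edge))) {
    u <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    if (v <= ntip) next
    w <- setdiff(children[[as.character(u)]], v)
    for (wi in w) {
      if (age[wi] >= age[v]) next
      for (x in children[[as.character(v)]]) {
        moves[[length(moves) + 1L]] <- c(u = u, v = v, w = wi, x = x)
      }
    }
  }
  if (!length(moves)) return(tree)
  mv <- moves[[sample.int(length(moves), 1L)]]
  # swap subtrees x and w
  edge <- tree$edge
  edge[edge[, 1] == mv["v"] & edge[, 2] == mv["x"], 1] <- mv["u"]
  edge[edge[, 1] == mv["u"] & edge[, 2] == mv["w"], 1] <- mv["v"]
  # re-assemble through parent arrays to restore canonical numbering
  np <- integer(ntip + tree$Nnode)
  np[edge[, 2]] <- edge[, 1]
  lab <- c(tree$tip.label, rep(NA_character_, tree$Nnode))
  assembleTimeTree(np, lab, c(rep(TRUE, ntip), rep(FALSE, tree$Nnode)),
                   age = age, annot = tree$annotations)
}

# attach a new tip on the edge above `v` at `attachAge`
attachTipAt <- function(tree, label, v, attachAge, tipAge) {
  ntip <- length(tree$tip.label)
  n <- ntip + tree$Nnode
  p <- parentVector(tree)
  stopifnot(v != ntip + 1L)  # not above the root
  if (!(attachAge < tree$node.age[p[v]] && attachAge > tree$node.age[v]) ||
      tipAge > attachAge) {
    stop("attachment age outside the edge's age window")
  }
  parent <- c(p, p[v], 0L)
  newInt <- n + 1L; newTip <- n + 2L
  parent[v] <- newInt
  parent[newTip] <- newInt
  lab <- c(tree$tip.label, rep(NA_character_, tree$Nnode), NA_character_, label)
  isTip <- c(rep(TRUE, ntip), rep(FALSE, tree$Nnode), FALSE, TRUE)
  age <- c(tree$node.age, attachAge, tipAge)
  annot <- c(tree$annotations, list(NULL, NULL))
  assembleTimeTree(parent, lab, isTip, age = age, annot = annot)
}

#' Generate a pseudo-posterior with wildcard taxa
#'
#' Emulates a Bayesian posterior tree sample in which most taxa are stably
#' placed while designated wildcard taxa reattach across the tree. Per tree:
#' the backbone is optionally perturbed by one age-valid NNI (probability
#' `nniProb`), then each wildcard is detached and reattached to a branch
#' drawn with weight `exp(-locality * d)`, where `d` is the node distance of
#' the candidate branch from the wildcard's true attachment point.
#' `locality = 0` reattaches uniformly; large `locality` concentrates the
#' wildcard at (and in the limit never leaves) its true position. The
#' attachment age is uniform within the branch's valid age window.
#'
#' This is a stochastic topology perturbation, not MCMC output; it provides
#' analytic ground truth for every downstream statistic.
#'
#' @param backbone a [timeTree()]: the true tree, wildcards included.
#' @param wildcards character vector of wildcard tip labels (may be empty).
#' @param nTrees number of trees to generate.
#' @param locality reattachment concentration (>= 0; `Inf` pins wildcards to
#'   their true branch).
#' @param nniProb probability of one backbone NNI per tree, in `[0, 1]`.
#' @param seed optional integer seed.
#' @return a [treeSample()]; `attr(, "truth")` lists the wildcards, the
#'   backbone, and the backbone clades over the stable (non-wildcard) taxa.
#' @export
generatePseudoPosterior <- function(backbone, wildcards = character(0),
                                    nTrees = 100, locality = 0, nniProb = 0,
                                    seed = NULL) {
  stopifnot(inherits(backbone, "timeTree"), nTrees >= 1,
            locality >= 0, nniProb >= 0, nniProb <= 1)
  wildcards <- as.character(wildcards)
  if (length(setdiff(wildcards, backbone$tip.label))) {
    stop("wildcards must be backbone tips")
  }
  stable <- setdiff(backbone$tip.label, wildcards)
  if (length(stable) < 3L) stop("need at least 3 stable taxa")
  wcAges <- tipAges(backbone)[wildcards]
  # true sibling set of each wildcard: tips of its sister subtree, reduced to
  # stable taxa (walk rootward until non-empty)
  sibs <- lapply(wildcards, function(w) trueSiblingSet(backbone, w, stable))
  names(sibs) <- wildcards

  withSeed(seed, {
    trees <- vector("list", nTrees)
    for (i in seq_len(nTrees)) {
      tr <- backbone
      if (nniProb > 0 && stats::runif(1L) < nniProb) tr <- applyRandomNNI(tr)
      if (length(wildcards)) {
        tr <- pruneTimeTree(tr, setdiff(tr$tip.label, wildcards))
        for (w in wildcards) {
          tr <- reattachWildcard(tr, w, wcAges[[w]], sibs[[w]], locality)
        }
      }
      trees[[i]] <- tr
    }
    treeSample(trees, runId = "pseudo")
  }) -> sample
  attr(sample, "truth") <- list(
    wildcards = wildcards,
    backbone = backbone,
    stableTaxa = stable,
    backboneCladesStable = extractClades(pruneTimeTree(backbone, stable))
  )
  sample
}

# tips of the sister subtree of `w`, intersected with `stable`; widens to the
# grandparent clade if the direct sister contains no stable taxon
trueSiblingSet <- function(tree, w, stable) {
  ntip <- length(tree$tip.label)
  allSets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) allSets[[i]] <- i
  ts <- nodeTipSets(tree)
  for (i in seq_along(ts)) allSets[[ntip + i]] <- ts[[i]]
  p <- parentVector(tree)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  v <- match(w, tree$tip.label)
  repeat {
    u <- p[v]
    if (u == 0L) return(stable)  # degenerate: everything is a wildcard sister
    sib <- setdiff(children[[as.character(u)]], v)
    members <- tree$tip.label[unlist(allSets[sib])]
    keep <- intersect(members, stable)
    if (length(keep)) return(keep)
    v <- u
  }
}

# reattach wildcard `w` (tip age wcAge) onto `tree`, locality-weighted around
# the MRCA of its true sibling set
reattachWildcard <- function(tree, w, wcAge, sibSet, locality) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  p <- parentVector(tree)
  age <- tree$node.age
  cand <- setdiff(seq_len(ntip + tree$Nnode), root)
  lo <- pmax(age[cand], wcAge)
  hi <- age[p[cand]]
  ok <- hi - lo > 1e-12
  cand <- cand[ok]; lo <- lo[ok]; hi <- hi[ok]
  if (!length(cand)) stop("no age-valid attachment branch for wildcard ", w)
  target <- if (length(sibSet) == 1L) match(sibSet, tree$tip.label)
            else mrcaNode(tree, sibSet)
  d <- nodePathLengths(tree, target)[cand]
  wgt <- if (is.infinite(locality)) as.numeric(d == min(d)) else exp(-locality * d)
  pick <- sample.int(length(cand), 1L, prob = wgt)
  attachTipAt(tree, w, cand[pick], stats::runif(1L, lo[pick], hi[pick]), wcAge)
}

# edge-count distances from `target` to every node (BFS over the unrooted
# adjacency)
nodePathLengths <- function(tree, target) {
  n <- length(tree$tip.label) + tree$Nnode
  adj <- vector("list", n)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  d <- rep(NA_integer_, n)
  d[target] <- 0L
  queue <- target
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    for (u in adj[[v]]) {
      if (is.na(d[u])) {
        d[u] <- d[v] + 1L
        queue <- c(queue, u)
      }
    }
  }
  d
}
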