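# run expr under a temporary seed, restoring the caller's RNG state;
# seed = NULL uses (and advances) the current stream
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# node depths in edges from the root
nodeDepthsEdges <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  d <- integer(n)
  for (e in preorderEdges(tree)) {
    d[tree$edge[e, 2]] <- d[tree$edge[e, 1]] + 1L
  }
  d
}

# pairwise tip MRCA depths (in edges from root), rows/cols ordered by `tips`
mrcaDepthMatrix <- function(tree, tips = sort(tree$tip.label)) {
  n <- length(tips)
  ord <- match(tree$tip.label, tips)
  ntip <- length(tree$tip.label)
  dep <- nodeDepthsEdges(tree)
  M <- matrix(0L, n, n)
  sets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- ord[i]
  for (e in rev(preorderEdges(tree))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    acc <- sets[[p]]; new <- sets[[ch]]
    if (!is.null(acc)) {
      M[acc, new] <- dep[p]
      M[new, acc] <- dep[p]
    }
    sets[[p]] <- c(acc, new)
  }
  diag(M) <- dep[match(tips, tree$tip.label)]
  M
}
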