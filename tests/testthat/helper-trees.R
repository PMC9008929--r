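# fixtures are built in code; no binary data

balanced4 <- function() parseNewick("((A:1,B:1):1,(C:1,D:1):1);")
crossed4 <- function() parseNewick("((A:1,C:1):1,(B:1,D:1):1);")

caterpillar <- function(n) {
  labs <- LETTERS[seq_len(n)]
  nwk <- labs[1L]
  for (i in 2:n) nwk <- sprintf("(%s:%d,%s:1)", labs[i], i - 1L, nwk)
  parseNewick(paste0(nwk, ";"))
}

sampleFromNewick <- function(newicks, ...) {
  treeSample(lapply(newicks, parseNewick), ...)
}

# strip treesum extras so ape sees a plain phylo
asPlainPhylo <- function(tree) {
  tree$node.age <- NULL
  tree$annotations <- NULL
  class(tree) <- "phylo"
  tree
}
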