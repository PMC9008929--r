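#' Equivalent-node comparison between pruned and full MCC trees
#'
#' For each nontrivial clade of the pruned MCC tree, the equivalent node in
#' the full MCC tree is the smallest clade (the MRCA clade) containing the
#' same retained taxa. A record is flagged `contradicting` when the full MCC
#' tree, restricted to the retained taxa, places some retained taxon inside
#' the equivalent node but outside the pruned clade.
#'
#' @param fullMcc annotated full MCC [timeTree()] (from [mccTree()]).
#' @param prunedMcc annotated pruned MCC [timeTree()] (from [prunedMcc()]).
#' @param retained taxon subset of the pruned tree; defaults to its tip set.
#' @return a `data.frame` with one row per nontrivial pruned clade:
#'   `prunedClade`, `fullClade` (member labels joined by `;`), `ppPruned`,
#'   `ppFull`, `contradicting`.
#' @export
equivalentNodes <- function(fullMcc, prunedMcc, retained = NULL) {
  if (is.null(retained)) retained <- prunedMcc$tip.label
  stopifnot(setequal(retained, prunedMcc$tip.label))
  missing <- setdiff(retained, fullMcc$tip.label)
  if (length(missing)) {
    stop("retained taxa absent from full tree: ", paste(missing, collapse = ", "))
  }
  ntipP <- length(prunedMcc$tip.label)
  prunedSets <- nodeTipSets(prunedMcc)
  fullSets <- nodeTipSets(fullMcc)
  fullMembers <- lapply(fullSets, function(ix) fullMcc$tip.label[ix])

  rows <- lapply(seq_along(prunedSets)[-1L], function(i) {  # skip pruned root
    members <- prunedMcc$tip.label[prunedSets[[i]]]
    v <- mrcaNode(fullMcc, members)
    fullClade <- fullMembers[[v - length(fullMcc$tip.label)]]
    inside <- intersect(fullClade, retained)
    data.frame(
      prunedClade = paste(sort(members), collapse = ";"),
      fullClade = paste(sort(fullClade), collapse = ";"),
      ppPruned = annotationPP(prunedMcc, ntipP + i),
      ppFull = annotationPP(fullMcc, v),
      contradicting = length(setdiff(inside, members)) > 0L,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

annotationPP <- function(tree, node) {
  p <- tree$annotations[[node]][["posterior"]]
  if (is.null(p)) NA_real_ else p
}

# MRCA of a label set via deepest common ancestor
mrcaNode <- function(tree, labels) {
  ids <- match(labels, tree$tip.label)
  p <- parentVector(tree)
  anc <- function(v) {
    out <- v
    while (p[v] != 0L) { v <- p[v]; out <- c(out, v) }
    out
  }
  common <- anc(ids[1L])
  for (i in ids[-1L]) common <- intersect(common, anc(i))
  common[1L]
}

#' Summarize equivalent-node records
#'
#' @param records output of [equivalentNodes()], possibly row-bound across
#'   retained sets or datasets.
#' @return one-row `data.frame`: `n`, `meanPPFull`, `meanPPPruned`,
#'   `meanDiff` (pruned minus full), `nContradicting`.
#' @export
summarizeSupport <- function(records) {
  if (!NROW(records)) stop("no equivalent-node records")
  data.frame(
    n = nrow(records),
    meanPPFull = mean(records$ppFull),
    meanPPPruned = mean(records$ppPruned),
    meanDiff = mean(records$ppPruned - records$ppFull),
    nContradicting = sum(records$contradicting)
  )
}
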