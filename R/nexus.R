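#' Read a NEXUS tree file into a treeSample
#'
#' Handles the BEAST output dialect: a TREES block with an optional
#' `Translate` table and per-node `[&...]` annotation comments. Tree order is
#' preserved; translated labels are applied.
#'
#' @param path path to a NEXUS file.
#' @param runId run label attached to every tree; defaults to the file name.
#' @return a [treeSample()].
#' @export
readNexusTrees <- function(path, runId = NULL) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (is.null(runId)) runId <- basename(path)
  block <- extractTreesBlock(txt)
  translate <- parseTranslateTable(block)
  stmts <- treeStatements(block)
  if (!length(stmts)) stop("no tree statements in TREES block of ", path)
  trees <- lapply(stmts, function(s) {
    tr <- parseNewick(s)
    if (!is.null(translate)) tr <- applyTranslate(tr, translate) else tr
  })
  treeSample(trees, runId = runId)
}

extractTreesBlock <- function(txt) {
  m <- regexpr("(?is)begin\\s+trees\\s*;.*?\\bend\\s*;", txt, perl = TRUE)
  if (m == -1L) stop("no TREES block found")
  regmatches(txt, m)
}

parseTranslateTable <- function(block) {
  m <- regexpr("(?is)\\btranslate\\b(.*?);", block, perl = TRUE)
  if (m == -1L) return(NULL)
  body <- sub("(?is)^\\s*translate\\b", "", regmatches(block, m), perl = TRUE)
  body <- sub(";\\s*$", "", body)
  entries <- strsplit(body, ",", fixed = TRUE)[[1L]]
  entries <- trimws(entries)
  entries <- entries[nzchar(entries)]
  idx <- character(0); lab <- character(0)
  for (e in entries) {
    mm <- regmatches(e, regexec("^(\\S+)\\s+(?:'([^']*)'|(\\S+))\\s*$", e))[[1L]]
    if (!length(mm)) stop("malformed Translate entry (index without taxon?): '", e, "'")
    idx <- c(idx, mm[2L])
    lab <- c(lab, if (nzchar(mm[3L])) mm[3L] else mm[4L])
  }
  if (any(!nzchar(lab))) stop("Translate index without taxon")
  if (anyDuplicated(idx)) stop("duplicate Translate index")
  stats::setNames(lab, idx)
}

treeStatements <- function(block) {
  m <- gregexpr("(?is)\\btree\\s+\\S+\\s*=\\s*(\\[&[RU]\\]\\s*)?[^;]*;", block, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(character(0))
  stmts <- regmatches(block, list(m))[[1L]]
  vapply(stmts, function(s) {
    s <- sub("(?is)^\\s*tree\\s+\\S+\\s*=\\s*", "", s, perl = TRUE)
    sub("^\\s*\\[&[RUru]\\]\\s*", "", s, perl = TRUE)
  }, character(1), USE.NAMES = FALSE)
}

applyTranslate <- function(tree, translate) {
  unknown <- setdiff(tree$tip.label, names(translate))
  if (length(unknown)) {
    stop("tree references unknown Translate index: ", paste(unknown, collapse = ", "))
  }
  tree$tip.label <- unname(translate[tree$tip.label])
  if (anyDuplicated(tree$tip.label)) stop("Translate maps two indices to one taxon")
  tree
}

#' Write a treeSample to an annotated NEXUS file
#'
#' Emits TAXA and TREES blocks with a Translate table, re-parseable by
#' [readNexusTrees()].
#'
#' @param sample a [treeSample()].
#' @param file output path.
#' @param digits significant digits for branch lengths.
#' @return the path, invisibly.
#' @export
writeNexusTrees <- function(sample, file, digits = 12) {
  stopifnot(inherits(sample, "treeSample"))
  tips <- sampleTipLabels(sample)
  idx <- stats::setNames(seq_along(tips), tips)
  lines <- c("#NEXUS", "", sub("\n$", "", nexusHeader(tips)), "", "Begin trees;",
             "\tTranslate",
             paste0("\t\t", idx, " ", quoteLabel(tips),
                    c(rep(",", length(tips) - 1L), "")),
             "\t\t;")
  for (i in seq_along(sample)) {
    tr <- sample[[i]]
    lines <- c(lines, paste0("tree STATE_", i, " = [&R] ",
                             newickString(tr, digits = digits,
                                          translate = idx[tr$tip.label])))
  }
  lines <- c(lines, "End;")
  writeLines(lines, file)
  invisible(file)
}
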