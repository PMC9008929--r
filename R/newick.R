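#' Parse a Newick string with BEAST-style node annotations
#'
#' Reads Newick with branch lengths and optional `[&key=value,...]` hot
#' comments on nodes or branches (the dialect written by BEAST/TreeAnnotator).
#' Annotation keys are preserved verbatim and never interpreted, except that
#' a complete set of numeric `height` annotations overrides the age reference
#' computed from branch lengths. Rooting comments `[&R]`/`[&U]` are ignored.
#'
#' @param text a single Newick string ending in `;`.
#' @param namespace optional character vector of permitted tip labels.
#' @return a [timeTree()] with ages computed from branch lengths (youngest
#'   tip at age 0) unless height annotations are present.
#' @examples
#' tr <- parseNewick("((A:1,B:1)[&posterior=0.9]:1,C:2);")
#' nodeAnnotations(tr, 5)
#' @export
parseNewick <- function(text, namespace = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- newickTokens(text)
  if (!nrow(toks)) stop("empty Newick string")

  parent <- integer(0); label <- character(0)
  blen <- numeric(0); annot <- list(); hasChild <- logical(0)
  newNode <- function(p) {
    parent[length(parent) + 1L] <<- p
    label[length(label) + 1L] <<- NA_character_
    blen[length(blen) + 1L] <<- NA_real_
    annot[[length(annot) + 1L]] <<- NULL_PLACEHOLDER
    hasChild[length(hasChild) + 1L] <<- FALSE
    length(parent)
  }
  root <- newNode(0L)
  cur <- root
  expectLen <- FALSE
  done <- FALSE

  for (i in seq_len(nrow(toks))) {
    tok <- toks$tok[i]; off <- toks$off[i]
    if (tok == "(") {
      hasChild[cur] <- TRUE
      cur <- newNode(cur)
    } else if (tok == ",") {
      if (parent[cur] == 0L) {
        stop("parse error: ',' outside parentheses at character ", off)
      }
      cur <- newNode(parent[cur])
    } else if (tok == ")") {
      if (parent[cur] == 0L) {
        stop("parse error: unbalanced ')' at character ", off)
      }
      cur <- parent[cur]
    } else if (tok == ":") {
      expectLen <- TRUE
    } else if (tok == ";") {
      if (parent[cur] != 0L) {
        stop("parse error: unbalanced '(' (unclosed at character ", off, ")")
      }
      done <- TRUE
      break
    } else if (startsWith(tok, "[&")) {
      if (toupper(tok) %in% c("[&R]", "[&U]")) next
      a <- parseAnnotationString(tok)
      old <- annot[[cur]]
      annot[[cur]] <- if (is.list(old) && !inherits(old, "treesum_null")) {
        utils::modifyList(old, a)
      } else a
    } else if (startsWith(tok, "[")) {
      next  # ordinary comment
    } else {
      if (expectLen) {
        v <- suppressWarnings(as.numeric(tok))
        if (is.na(v)) stop("parse error: expected branch length at character ", off)
        blen[cur] <- v
        expectLen <- FALSE
      } else {
        label[cur] <- unquoteLabel(tok)
      }
    }
  }
  if (!done) stop("parse error: missing ';' terminator")

  isTip <- !hasChild
  tipLab <- label[isTip]
  if (anyNA(tipLab) || any(!nzchar(tipLab))) stop("unlabelled tip in Newick string")
  if (anyDuplicated(tipLab)) {
    stop("namespace error: duplicate tip label ",
         paste(unique(tipLab[duplicated(tipLab)]), collapse = ", "))
  }
  if (!is.null(namespace)) {
    bad <- setdiff(tipLab, namespace)
    if (length(bad)) stop("namespace error: unknown taxa ", paste(bad, collapse = ", "))
  }
  buildTimeTree(parent, label, blen, annot, isTip)
}

NULL_PLACEHOLDER <- structure(list(), class = "treesum_null")

# convert parser arrays (arbitrary numbering) to an ape-conventional timeTree
buildTimeTree <- function(parent, label, blen, annot, isTip) {
  ntip <- sum(isTip)
  nint <- sum(!isTip)
  children <- split(seq_along(parent), parent)
  # preorder walk from the root preserving child order
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
  edge <- cbind(newId[parent[nonRoot]], newId[nonRoot])
  el <- blen[nonRoot]
  el[is.na(el)] <- 0
  phy <- structure(list(edge = edge,
                        edge.length = el,
                        tip.label = label[isTip][order(newId[isTip])],
                        Nnode = nint),
                   class = "phylo", order = "cladewise")
  intLab <- label[!isTip]
  if (any(!is.na(intLab))) {
    nl <- character(nint)
    nl[newId[!isTip] - ntip] <- ifelse(is.na(intLab), "", intLab)
    phy$node.label <- nl
  }
  ann <- vector("list", ntip + nint)
  for (v in seq_along(parent)) {
    if (is.list(annot[[v]]) && !inherits(annot[[v]], "treesum_null")) {
      ann[[newId[v]]] <- annot[[v]]
    }
  }
  asTimeTree(phy, annotations = ann)
}

# tokens with 1-based character offsets
newickTokens <- function(text) {
  pat <- "\\[[^]]*\\]|'[^']*'|[(),;:]|[^\\s(),;:\\[\\]']+"
  m <- gregexpr(pat, text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(data.frame(tok = character(0), off = integer(0)))
  data.frame(tok = regmatches(text, list(m))[[1L]],
             off = as.integer(m),
             stringsAsFactors = FALSE)
}

unquoteLabel <- function(x) {
  if (startsWith(x, "'") && endsWith(x, "'")) substr(x, 2L, nchar(x) - 1L) else x
}

# "[&posterior=0.79,height_95%_HPD={1.2,3.4}]" -> named list
parseAnnotationString <- function(tok) {
  body <- substr(tok, 3L, nchar(tok) - 1L)
  if (!nzchar(body)) return(list())
  parts <- splitTopLevel(body)
  out <- list()
  for (p in parts) {
    eq <- regexpr("=", p, fixed = TRUE)
    if (eq == -1L) { out[[p]] <- TRUE; next }
    key <- substr(p, 1L, eq - 1L)
    val <- substr(p, eq + 1L, nchar(p))
    out[[key]] <- parseAnnotationValue(val)
  }
  out
}

parseAnnotationValue <- function(val) {
  if (startsWith(val, "{") && endsWith(val, "}")) {
    items <- splitTopLevel(substr(val, 2L, nchar(val) - 1L))
    num <- suppressWarnings(as.numeric(items))
    if (!anyNA(num)) return(num)
    return(gsub('^"|"$', "", items))
  }
  num <- suppressWarnings(as.numeric(val))
  if (!is.na(num)) return(num)
  gsub('^"|"$', "", val)
}

# split on commas not inside braces or quotes
splitTopLevel <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  depth <- 0L; inq <- FALSE; cut <- integer(0)
  for (i in seq_along(chars)) {
    c <- chars[i]
    if (c == '"') inq <- !inq
    else if (!inq && c == "{") depth <- depth + 1L
    else if (!inq && c == "}") depth <- depth - 1L
    else if (!inq && depth == 0L && c == ",") cut <- c(cut, i)
  }
  starts <- c(1L, cut + 1L)
  ends <- c(cut - 1L, length(chars))
  vapply(seq_along(starts),
         function(k) paste(chars[starts[k]:ends[k]], collapse = ""),
         character(1))
}

#' Serialize an annotated tree
#'
#' Writes Newick or single-tree NEXUS with `[&...]` annotation comments, such
#' that `parseNewick(writeAnnotatedTree(tree))` reproduces topology, branch
#' lengths (to 1e-9) and annotations.
#'
#' @param tree a [timeTree()].
#' @param format `"newick"` or `"nexus"`.
#' @param file optional path; when `NULL` the text is returned.
#' @param digits significant digits for branch lengths and numeric annotations.
#' @return the serialized text (invisibly when written to `file`).
#' @export
writeAnnotatedTree <- function(tree, format = c("newick", "nexus"),
                               file = NULL, digits = 12) {
  format <- match.arg(format)
  stopifnot(inherits(tree, "timeTree"))
  nwk <- newickString(tree, digits = digits)
  if (any(tree$edge.length < -1e-9)) {
    warning("writing tree with negative branch lengths")
  }
  txt <- if (format == "newick") nwk else {
    paste0("#NEXUS\n", nexusHeader(tree$tip.label),
           "Begin trees;\n\ttree TREE1 = [&R] ", nwk, "\nEnd;\n")
  }
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

nexusHeader <- function(tips) {
  paste0("Begin taxa;\n\tDimensions ntax=", length(tips), ";\n\tTaxlabels\n",
         paste0("\t\t", quoteLabel(tips), collapse = "\n"),
         "\n\t\t;\nEnd;\n")
}

newickString <- function(tree, digits = 12, translate = NULL) {
  ntip <- length(tree$tip.label)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  pv <- parentVector(tree)
  fmt <- function(x) sprintf("%.*g", digits, x)
  labelOf <- function(v) {
    if (!is.null(translate)) as.character(translate[v]) else quoteLabel(tree$tip.label[v])
  }
  annOf <- function(v) {
    a <- tree$annotations[[v]]
    if (is.null(a) || !length(a)) return("")
    vals <- vapply(seq_along(a), function(i) fmtAnnotationValue(a[[i]], digits), character(1))
    paste0("[&", paste0(names(a), "=", vals, collapse = ","), "]")
  }
  rec <- function(v) {
    if (v <= ntip) {
      core <- paste0(labelOf(v), annOf(v))
    } else {
      core <- paste0("(", paste(vapply(children[[as.character(v)]], rec, character(1)),
                                collapse = ","), ")", annOf(v))
    }
    if (v == ntip + 1L) return(core)  # root carries no branch length
    bl <- tree$node.age[pv[v]] - tree$node.age[v]
    paste0(core, ":", fmt(bl))
  }
  paste0(rec(ntip + 1L), ";")
}

fmtAnnotationValue <- function(v, digits = 12) {
  if (is.numeric(v)) {
    s <- sprintf("%.*g", digits, v)
    if (length(s) > 1L) return(paste0("{", paste(s, collapse = ","), "}"))
    return(s)
  }
  if (is.logical(v)) return(if (length(v) == 1L && v) "true" else "false")
  s <- ifelse(grepl("[,{}=\\[\\]]", v), paste0('"', v, '"'), v)
  if (length(s) > 1L) paste0("{", paste(s, collapse = ","), "}") else s
}

quoteLabel <- function(x) {
  bad <- grepl("[\\s(),;:\\[\\]']", x, perl = TRUE)
  ifelse(bad, paste0("'", x, "'"), x)
}
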