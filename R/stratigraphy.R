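#' Stage-slice boundaries
#'
#' Divides a geologic stage into equal-duration time bins, one per stage
#' slice, and returns the internal boundaries. E.g. the Dapingian
#' (470.0-467.3 mya, three slices Dp1-3) yields boundaries 469.1 and
#' 468.2 mya.
#'
#' @param start older limit of the stage, mya.
#' @param end younger limit, mya; must be less than `start`.
#' @param nSlices number of stage slices (>= 1).
#' @return decreasing numeric vector of the `nSlices - 1` internal
#'   boundaries (empty for a single slice).
#' @examples
#' stageSliceBoundaries(470.0, 467.3, 3)  # 469.1 468.2
#' @export
stageSliceBoundaries <- function(start, end, nSlices) {
  if (start <= end) stop("'start' must be older (larger) than 'end'")
  stopifnot(nSlices >= 1)
  if (nSlices == 1) return(numeric(0))
  start - seq_len(nSlices - 1) * (start - end) / nSlices
}

#' @rdname stageSliceBoundaries
#' @param stage stage name.
#' @return `stageSliceScheme()`: a list with the stage name, limits, and a
#'   two-column matrix `slices` of (older, younger) limits per slice.
#' @export
stageSliceScheme <- function(stage, start, end, nSlices) {
  b <- stageSliceBoundaries(start, end, nSlices)
  lims <- c(start, b, end)
  structure(list(stage = stage, start = start, end = end, nSlices = nSlices,
                 boundaries = b,
                 slices = cbind(older = lims[-length(lims)], younger = lims[-1L])),
            class = "stageSliceScheme")
}

#' Draw tip ages within stratigraphic intervals
#'
#' Each tip age is drawn uniformly within its stratigraphic interval (e.g.
#' the stage slices bounding its fossil occurrence). Tips sharing a fossil
#' site (`siteIds`) are contemporaneous and receive one shared draw, taken
#' uniformly from the intersection of their intervals. Internal node ages
#' are unchanged; branch lengths are recomputed.
#'
#' @param tree a [timeTree()].
#' @param intervals two-column numeric matrix (`min`, `max` age, mya) with
#'   one row per tip, rownames = tip labels. A degenerate interval fixes the
#'   age exactly.
#' @param siteIds optional named character vector (tip label -> site id);
#'   `NA`/absent tips are drawn independently.
#' @param seed optional integer seed.
#' @return the re-aged [timeTree()].
#' @export
assignTipAges <- function(tree, intervals, siteIds = NULL, seed = NULL) {
  stopifnot(inherits(tree, "timeTree"))
  tips <- tree$tip.label
  if (is.null(rownames(intervals)) || !all(tips %in% rownames(intervals))) {
    stop("'intervals' must have one named row per tip")
  }
  lo <- intervals[tips, 1]; hi <- intervals[tips, 2]
  if (any(lo > hi)) stop("interval minimum exceeds maximum")
  site <- rep(NA_character_, length(tips))
  if (!is.null(siteIds)) site[match(names(siteIds), tips)] <- siteIds
  grp <- ifelse(is.na(site), paste0(".solo.", seq_along(tips)), site)
  ages <- withSeed(seed, {
    out <- numeric(length(tips))
    for (g in unique(grp)) {
      ix <- which(grp == g)
      gl <- max(lo[ix]); gh <- min(hi[ix])
      if (gl > gh) {
        stop("tips of site '", g, "' have disjoint age intervals")
      }
      out[ix] <- stats::runif(1L, gl, gh)
    }
    out
  })
  newAges <- tree$node.age
  newAges[seq_along(tips)] <- ages
  p <- parentVector(tree)
  bad <- which(newAges[seq_along(tips)] > newAges[p[seq_along(tips)]] + 1e-12)
  if (length(bad)) {
    stop("drawn age violates parent node age for tip(s): ",
         paste(tips[bad], collapse = ", "))
  }
  timeTree(structure(tree[setdiff(names(tree), c("node.age", "annotations"))],
                     class = "phylo"),
           ages = newAges, annotations = tree$annotations)
}
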