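#' Fossilized birth-death parameter conversions
#'
#' The FBD process has speciation rate lambda, extinction rate mu and
#' fossil-sampling rate psi (all per lineage per my). The alternative
#' parametrization is net diversification `d = lambda - mu`, turnover
#' `r = mu / lambda` and sampling proportion `s = psi / (mu + psi)`
#' (`s = 0` when `mu + psi = 0`).
#'
#' @param lambda,mu,psi FBD rates; requires `lambda > mu >= 0`, `psi >= 0`.
#' @return `fbdConvert()`: a list `d`, `r`, `s`.
#' @examples
#' fbdConvert(2, 1, 1)  # d = 1, r = 0.5, s = 0.5
#' @export
fbdConvert <- function(lambda, mu, psi) {
  checkFbdRates(lambda, mu, psi)
  list(d = lambda - mu,
       r = mu / lambda,
       s = if (mu + psi == 0) 0 else psi / (mu + psi))
}

#' @rdname fbdConvert
#' @param d,r,s net diversification (> 0), turnover in `[0, 1)`, sampling
#'   proportion in `[0, 1]`.
#' @return `fbdInvert()`: a list `lambda`, `mu`, `psi`. The inverse is
#'   undefined at `r = 0, s = 1` (any `psi > 0` maps there) and rejected.
#' @export
fbdInvert <- function(d, r, s) {
  stopifnot(d > 0, r >= 0, r < 1, s >= 0, s <= 1)
  lambda <- d / (1 - r)
  mu <- r * lambda
  if (s == 1) {
    if (mu == 0) stop("(r = 0, s = 1) is not invertible: psi unidentifiable")
    stop("s = 1 requires infinite psi for mu > 0")
  }
  psi <- s * mu / (1 - s)
  if (mu == 0 && s > 0) stop("(r = 0, s > 0) is inconsistent: psi/(mu+psi) is 0 or 1")
  checkFbdRates(lambda, mu, psi)
  list(lambda = lambda, mu = mu, psi = psi)
}

checkFbdRates <- function(lambda, mu, psi) {
  if (mu < 0 || psi < 0) stop("rates must be non-negative")
  if (lambda <= mu) stop("non-positive diversification: lambda must exceed mu")
  invisible(TRUE)
}

#' FBD parameter bundle
#'
#' @inheritParams fbdConvert
#' @param origin origin time of the process, mya.
#' @return an object of class `fbdParams` carrying both parametrizations.
#' @export
fbdParams <- function(lambda, mu, psi, origin) {
  checkFbdRates(lambda, mu, psi)
  stopifnot(origin > 0)
  structure(c(list(lambda = lambda, mu = mu, psi = psi, origin = origin),
              fbdConvert(lambda, mu, psi)),
            class = "fbdParams")
}

#' @export
print.fbdParams <- function(x, ...) {
  cat(sprintf("FBD: lambda=%.4g mu=%.4g psi=%.4g origin=%.4g (d=%.4g r=%.4g s=%.4g)\n",
              x$lambda, x$mu, x$psi, x$origin, x$d, x$r, x$s))
  invisible(x)
}

#' Sample origin times from an offset exponential prior
#'
#' Draws `offset + Exponential(mean = meanExcess)`, the informative origin
#' prior used for tip-dating when the offset is the upper age limit of the
#' oldest unambiguous fossil of the clade.
#'
#' @param meanExcess mean of the exponential excess above the offset, my.
#' @param offset hard minimum age, mya.
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return numeric vector of ages (mya).
#' @examples
#' mean(sampleOriginPrior(0.1, 489.5, 1e4, seed = 1)) - 489.5  # ~ 0.1
#' @export
sampleOriginPrior <- function(meanExcess, offset, n, seed = NULL) {
  stopifnot(meanExcess >= 0, n >= 1)
  if (meanExcess == 0) return(rep(offset, n))
  withSeed(seed, offset + stats::rexp(n, rate = 1 / meanExcess))
}

#' Simulate a fossilized birth-death tree with sampled ancestors
#'
#' Forward birth-death-fossilization simulation from the origin: lineages
#' speciate (lambda), go extinct (mu) and leave fossil samples (psi); the
#' process stops at the present, and extant lineages are never sampled
#' (extant sampling probability is 0 — all samples are fossils). The
#' reconstructed tree retains only lineages ancestral to at least one fossil;
#' fossils with sampled descendants become sampled-ancestor tips on
#' zero-length branches. Rejection sampling conditions on a minimum number of
#' fossil tips.
#'
#' @param params an [fbdParams()] object.
#' @param minTips minimum number of fossil samples (rejection condition).
#' @param maxAttempts rejection-sampling cap.
#' @param seed optional integer seed; fixed seeds give bit-identical trees.
#' @return a [timeTree()] whose `attr(, "truth")` records
#'   `nSampledAncestors`, `nTips`, `attempts` and the per-tip
#'   sampled-ancestor flags.
#' @export
simulateFbdTree <- function(params, minTips = 5, maxAttempts = 1000, seed = NULL) {
  stopifnot(inherits(params, "fbdParams"), minTips >= 1, maxAttempts >= 1)
  withSeed(seed, {
    for (attempt in seq_len(maxAttempts)) {
      tr <- fbdForwardOnce(params)
      if (!is.null(tr) && length(tr$tip.label) >= minTips) {
        truth <- attr(tr, "truth")
        truth$attempts <- attempt
        attr(tr, "truth") <- truth
        return(tr)
      }
    }
    stop("rejection cap (", maxAttempts, ") exceeded before reaching ", minTips,
         " fossil samples; increase psi or the origin time, or lower minTips")
  })
}

# one unconditioned forward pass; NULL when no fossil was sampled
fbdForwardOnce <- function(params) {
  lambda <- params$lambda; mu <- params$mu; psi <- params$psi
  total <- lambda + mu + psi
  # lineage bookkeeping: birth age, end age, children lineage ids
  birth <- params$origin; end <- NA_real_
  kids <- list(integer(0))
  fossils <- list(numeric(0))
  active <- 1L
  ages <- params$origin  # current age of each active lineage (age counts down)
  nLin <- 1L
  nFossil <- 0L
  repeat {
    if (!length(active)) break
    if (nLin > 100000L) break  # runaway guard; caller rejects on condition
    i <- active[sample.int(length(active), 1L)]
    wait <- stats::rexp(1L, rate = total)
    newAge <- ages[i] - wait
    if (newAge <= 0) {
      end[i] <- 0
      ages[i] <- 0
      active <- setdiff(active, i)
      next
    }
    ages[i] <- newAge
    u <- stats::runif(1L)
    if (u < lambda / total) {
      end[i] <- newAge
      for (k in 1:2) {
        nLin <- nLin + 1L
        birth[nLin] <- newAge; end[nLin] <- NA_real_
        kids[[nLin]] <- integer(0)
        fossils[[nLin]] <- numeric(0)
        ages[nLin] <- newAge
        active <- c(active, nLin)
      }
      kids[[i]] <- c(nLin - 1L, nLin)
      active <- setdiff(active, i)
    } else if (u < (lambda + mu) / total) {
      end[i] <- newAge
      active <- setdiff(active, i)
    } else {
      fossils[[i]] <- c(fossils[[i]], newAge)
      nFossil <- nFossil + 1L
    }
  }
  if (nFossil == 0L) return(NULL)
  reconstructFbd(birth, kids, fossils)
}

# build the reconstructed sampled tree; fossils on lineages with sampled
# descendants become zero-length sampled-ancestor tips
reconstructFbd <- function(birth, kids, fossils) {
  parent <- integer(0); label <- character(0)
  age <- numeric(0); isTip <- logical(0); saFlag <- logical(0)
  tipCount <- 0L
  addNode <- function(a, lab = NA_character_, tip = FALSE, sa = FALSE) {
    k <- length(parent) + 1L
    parent[k] <<- 0L; label[k] <<- lab; age[k] <<- a
    isTip[k] <<- tip; saFlag[k] <<- sa
    k
  }
  nSA <- 0L
  rec <- function(l) {
    ch <- kids[[l]]
    subs <- integer(0)
    for (c in ch) {
      r <- rec(c)
      if (r != 0L) subs <- c(subs, r)
    }
    below <- 0L
    if (length(subs) == 2L) {
      # speciation age of l is the birth age of its children
      below <- addNode(birth[ch[1L]])
      parent[subs] <<- below
    } else if (length(subs) == 1L) {
      below <- subs
    }
    for (f in sort(fossils[[l]])) {  # youngest first
      tipCount <<- tipCount + 1L
      if (below == 0L) {
        below <- addNode(f, lab = paste0("F", tipCount), tip = TRUE)
      } else {
        tip <- addNode(f, lab = paste0("F", tipCount), tip = TRUE, sa = TRUE)
        nSA <<- nSA + 1L
        joint <- addNode(f)
        parent[c(below, tip)] <<- joint
        below <- joint
      }
    }
    below
  }
  root <- rec(1L)
  if (root == 0L) return(NULL)
  if (isTip[root]) return(NULL)  # single fossil: no tree to speak of
  tree <- assembleTimeTree(parent, label, isTip, age = age)
  saLabels <- label[isTip & saFlag]
  attr(tree, "truth") <- list(
    nSampledAncestors = nSA,
    nTips = sum(isTip),
    sampledAncestorTips = saLabels
  )
  tree
}
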