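test_that("FBD parametrizations convert exactly and invert", {
  expect_equal(fbdConvert(2, 1, 1), list(d = 1, r = 0.5, s = 0.5))
  expect_equal(fbdConvert(1, 0, 0), list(d = 1, r = 0, s = 0))
  expect_error(fbdConvert(1, 1.5, 0.2), "diversification")
  expect_error(fbdConvert(1, 1, 0), "diversification")
  set.seed(131)
  for (rep in 1:100) {
    lambda <- runif(1, 0.5, 3)
    mu <- runif(1, 0.01, lambda * 0.95)
    psi <- runif(1, 0.01, 2)
    drs <- fbdConvert(lambda, mu, psi)
    back <- fbdInvert(drs$d, drs$r, drs$s)
    expect_equal(back$lambda, lambda, tolerance = 1e-12)
    expect_equal(back$mu, mu, tolerance = 1e-12)
    expect_equal(back$psi, psi, tolerance = 1e-12)
  }
})

test_that("stage slices interpolate equal-duration bins", {
  expect_equal(stageSliceBoundaries(470.0, 467.3, 3), c(469.1, 468.2),
               tolerance = 1e-9)
  expect_equal(stageSliceBoundaries(470.0, 467.3, 1), numeric(0))
  expect_equal(stageSliceBoundaries(10, 0, 5), c(8, 6, 4, 2))
  expect_error(stageSliceBoundaries(467.3, 470.0, 3), "older")
  sch <- stageSliceScheme("Dapingian", 470.0, 467.3, 3)
  expect_equal(nrow(sch$slices), 3L)
  expect_equal(sch$slices[1, ], c(older = 470.0, younger = 469.1),
               tolerance = 1e-9)
})

test_that("origin prior draws are offset exponentials", {
  x <- sampleOriginPrior(0.1, 489.5, 1e5, seed = 132)
  expect_true(all(x >= 489.5))
  expect_lt(abs(mean(x) - 489.6), 0.005)
  expect_identical(x, sampleOriginPrior(0.1, 489.5, 1e5, seed = 132))
  expect_equal(sampleOriginPrior(0, 489.5, 10), rep(489.5, 10))
})

test_that("FBD simulation conditions, records truth and is seed-stable", {
  p <- fbdParams(1, 0.5, 2, origin = 6)
  tr <- simulateFbdTree(p, minTips = 5, seed = 133)
  expect_s3_class(tr, "timeTree")
  expect_gte(length(tr$tip.label), 5L)
  truth <- attr(tr, "truth")
  expect_equal(countSampledAncestors(tr), truth$nSampledAncestors)
  tr2 <- simulateFbdTree(p, minTips = 5, seed = 133)
  expect_identical(writeAnnotatedTree(tr2), writeAnnotatedTree(tr))
  # psi = 0 never samples and must hit the rejection cap
  expect_error(simulateFbdTree(fbdParams(1, 0.5, 0, origin = 6),
                               minTips = 2, maxAttempts = 5), "cap")
})

test_that("sampled-ancestor counts match simulator truth across seeds", {
  p <- fbdParams(1, 0.5, 2, origin = 6)
  for (seed in 1:1000) {
    tr <- simulateFbdTree(p, minTips = 3, seed = seed)
    truth <- attr(tr, "truth")
    expect_identical(countSampledAncestors(tr), truth$nSampledAncestors)
    expect_identical(length(tr$tip.label), truth$nTips)
    # age monotonicity along every branch
    bl <- nodeAges(tr)[tr$edge[, 1]] - nodeAges(tr)[tr$edge[, 2]]
    expect_gte(min(bl), 0)
  }
})

test_that("without extinction every internal-lineage fossil is an ancestor", {
  p <- fbdParams(1, 0, 3, origin = 4)
  tr <- simulateFbdTree(p, minTips = 5, seed = 134)
  truth <- attr(tr, "truth")
  termLen <- tr$edge.length[match(seq_along(tr$tip.label), tr$edge[, 2])]
  expect_setequal(truth$sampledAncestorTips, tr$tip.label[termLen <= 1e-8])
  expect_gt(truth$nSampledAncestors, 0L)
})

test_that("tip ages are drawn in-interval with fossil-site synchronization", {
  tr <- parseNewick("((A:1,B:1):2,(C:2,D:2):1);")
  iv <- matrix(c(0, 0.9, 0, 0.9, 0.5, 0.5, 0, 2.4), ncol = 2, byrow = TRUE,
               dimnames = list(c("A", "B", "C", "D"), c("min", "max")))
  aged <- assignTipAges(tr, iv, siteIds = c(A = "s1", B = "s1"), seed = 135)
  ages <- tipAges(aged)
  expect_equal(ages[["A"]], ages[["B"]])  # same fossil site
  expect_equal(ages[["C"]], 0.5)          # degenerate interval
  expect_true(ages[["D"]] >= 0 && ages[["D"]] <= 2.4)
  # branch lengths recomputed from the new ages
  expect_lt(max(abs((nodeAges(aged)[aged$edge[, 1]] -
                     nodeAges(aged)[aged$edge[, 2]]) - aged$edge.length)), 1e-9)
  # interval violating the parent age
  iv2 <- iv; iv2["A", ] <- c(2.5, 2.5)
  expect_error(assignTipAges(tr, iv2, seed = 136), "parent")
})

test_that("tip-age draws cover their interval uniformly", {
  tr <- parseNewick("((A:1,B:1):2,(C:2,D:2):1);")
  iv <- matrix(c(0, 1, 0, 1, 0, 2, 0, 2), ncol = 2, byrow = TRUE,
               dimnames = list(c("A", "B", "C", "D"), NULL))
  draws <- vapply(1:1000, function(s) {
    tipAges(assignTipAges(tr, iv, seed = s))[["A"]]
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(draws, "punif", 0, 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("uniform random topologies are uniform over labelled shapes", {
  set.seed(137)
  keys <- replicate(3000, {
    tr <- randomTimeTree(4)
    paste(sort(vapply(extractClades(tr), paste, "", collapse = ",")),
          collapse = "|")
  })
  tab <- table(keys)
  expect_length(tab, 15L)  # (2n-3)!! rooted shapes at n = 4
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("unperturbed pseudo-posteriors are exact copies of the backbone", {
  backbone <- randomTimeTree(10, seed = 138)
  s <- generatePseudoPosterior(backbone, nTrees = 20, seed = 139)
  expect_length(s, 20L)
  for (i in seq_along(s)) {
    expect_identical(writeAnnotatedTree(s[[i]]), writeAnnotatedTree(backbone))
  }
  tab <- cladePosteriors(s)
  expect_true(all(tab$pp == 1))
})

test_that("a uniform wildcard's clade PPs equal its reattachment fractions", {
  backbone <- randomTimeTree(10, seed = 140)
  s <- generatePseudoPosterior(backbone, wildcards = "t3", nTrees = 150,
                               locality = 0, seed = 141)
  tab <- cladePosteriors(s)
  # recomputation oracle: PP of any clade containing the wildcard equals the
  # fraction of trees in which the wildcard attaches inside it
  withW <- tab[grepl("(^|;)t3(;|$)", tab$clade), ]
  for (i in seq_len(nrow(withW))) {
    members <- strsplit(withW$clade[i], ";")[[1]]
    direct <- mean(vapply(s, function(tr) {
      any(vapply(extractClades(tr), setequal, logical(1), members))
    }, logical(1)))
    expect_equal(withW$pp[i], direct)
  }
  # excluding the wildcard restores full support
  tabS <- cladePosteriors(pruneSample(s, setdiff(backbone$tip.label, "t3")))
  expect_true(all(tabS$pp == 1))
})

test_that("infinite locality pins wildcards to their true neighbourhood", {
  backbone <- randomTimeTree(12, seed = 142)
  s <- generatePseudoPosterior(backbone, wildcards = "t7", nTrees = 60,
                               locality = Inf, seed = 143)
  m <- mccTree(s)
  profInf <- instabilityProfile(s, m, "t7")
  sU <- generatePseudoPosterior(backbone, wildcards = "t7", nTrees = 60,
                                locality = 0, seed = 143)
  profU <- instabilityProfile(sU, mccTree(sU), "t7")
  expect_lte(max(profInf$max), 3)  # never leaves its true clade
  expect_lt(mean(profInf$mean), mean(profU$mean))
})
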