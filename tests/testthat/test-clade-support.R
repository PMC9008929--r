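test_that("extractClades returns nontrivial rooted clades", {
  expect_equal(extractClades(parseNewick("((A:1,B:1):1,C:2);")),
               list(`5` = c("A", "B")))
  cat5 <- caterpillar(5)
  expect_length(extractClades(cat5), 3L)  # n - 2 for binary rooted
  expect_length(extractClades(cat5, includeTrivial = TRUE), 4L)
  # sampled-ancestor tip participates as an ordinary tip
  sa <- parseNewick("((A:1,B:0):1,C:2);")
  expect_equal(extractClades(sa), list(`5` = c("A", "B")))
})

test_that("clade posterior probabilities are occurrence proportions", {
  s <- sampleFromNewick(c(
    "((A:1,B:1):1,(C:1,D:1):1);",
    "((A:1,B:1):1,(C:1,D:1):1);",
    "(((A:1,B:1):1,C:2):1,D:3);",
    "((A:1,C:1):1,(B:1,D:1):1);"))
  tab <- cladePosteriors(s)
  expect_equal(tab$pp[tab$clade == "A;B"], 0.75)
  expect_equal(tab$pp[tab$clade == "C;D"], 0.5)
  expect_true(all(tab$pp > 0 & tab$pp <= 1))
  expect_equal(attr(tab, "nTrees"), 4L)
})

test_that("clade table equals ape::prop.part frequencies on random samples", {
  set.seed(81)
  for (rep in 1:5) {
    s <- treeSample(lapply(1:10, function(i) randomTimeTree(7)))
    tab <- cladePosteriors(s)
    oracle <- oracleCladeFreqs(s)
    oracle <- oracle[!names(oracle) == paste(sort(sampleTipLabels(s)), collapse = ";")]
    got <- stats::setNames(tab$pp, tab$clade)
    expect_mapequal(as.list(got), as.list(oracle))
  }
})

test_that("mccTree picks the dominant topology and annotates PPs", {
  t1 <- "((A:1,B:1):1,(C:1,D:1):1);"
  t2 <- "((A:1,C:1):1,(B:1,D:1):1);"
  s <- sampleFromNewick(c(t1, t1, t1, t2))
  m <- mccTree(s)
  expect_equal(attr(m, "mccIndex"), 1L)
  expect_equal(sort(extractClades(m)[[1]]), c("A", "B"))
  # all trees identical -> every PP 1
  s2 <- sampleFromNewick(rep(t1, 5))
  m2 <- mccTree(s2)
  expect_equal(meanCladePP(m2), 1.0)
})

test_that("MCC selection equals the exhaustive argmax on small samples", {
  set.seed(82)
  for (rep in 1:5) {
    s <- treeSample(lapply(1:20, function(i) randomTimeTree(6)))
    m <- mccTree(s)
    expect_equal(attr(m, "mccIndex"), oracleMccIndex(s))
  }
})

test_that("MCC node heights come from the selected tree itself", {
  s <- generatePseudoPosterior(randomTimeTree(8, seed = 5), wildcards = "t1",
                               nTrees = 30, seed = 6)
  m <- mccTree(s)
  expect_equal(nodeAges(m), nodeAges(s[[attr(m, "mccIndex")]]))
})

test_that("meanCladePP averages annotated nontrivial nodes", {
  tr <- parseNewick(
    "(((A:1,B:1)[&posterior=0.5]:1,C:2)[&posterior=1.0]:1,D:3);")
  expect_equal(meanCladePP(tr), 0.75)
  expect_error(meanCladePP(parseNewick("(((A:1,B:1):1,C:2):1,D:3);")),
               "unannotated")
})

test_that("pruning removes tips and sums branch lengths through", {
  tr <- parseNewick("((A:1,B:1):1,(C:1,D:1):1);")
  pr <- pruneTimeTree(tr, c("A", "C", "D"))
  expect_identical(writeAnnotatedTree(pr), "(A:2,(C:1,D:1):1);")
  # retain all = identity
  expect_identical(writeAnnotatedTree(pruneTimeTree(tr, c("A", "B", "C", "D"))),
                   writeAnnotatedTree(tr))
})

test_that("pruned samples keep ages consistent and match ape topologies", {
  set.seed(83)
  s <- generatePseudoPosterior(randomTimeTree(12, seed = 7),
                               wildcards = c("t2", "t9"), nTrees = 100, seed = 8)
  keep <- paste0("t", c(1, 3, 4, 5, 6, 7, 8))
  ps <- pruneSample(s, keep)
  for (i in seq_along(ps)) {
    tr <- ps[[i]]
    expect_setequal(tr$tip.label, keep)
    bl <- nodeAges(tr)[tr$edge[, 1]] - nodeAges(tr)[tr$edge[, 2]]
    expect_lt(max(abs(bl - tr$edge.length)), 1e-9)
  }
  # topology oracle on a few trees
  for (i in c(1L, 50L, 100L)) {
    ours <- asPlainPhylo(ps[[i]])
    apes <- ape::keep.tip(asPlainPhylo(s[[i]]), keep)
    expect_equal(as.numeric(suppressWarnings(ape::dist.topo(ours, apes))), 0)
  }
  expect_error(pruneSample(s, c("t1", "t3")), "at least 3")
  expect_error(pruneSample(s, c("t1", "t3", "nope")), "absent")
})

test_that("pruning commutes with clade extraction and restriction", {
  set.seed(84)
  for (rep in 1:300) {
    tr <- randomTimeTree(sample(6:12, 1))
    keep <- sort(sample(tr$tip.label, sample(4:5, 1)))
    direct <- extractClades(pruneTimeTree(tr, keep))
    restricted <- lapply(extractClades(tr, includeTrivial = TRUE),
                         function(cl) sort(intersect(cl, keep)))
    restricted <- unique(Filter(function(cl) {
      length(cl) >= 2L && length(cl) < length(keep)
    }, restricted))
    expect_setequal(vapply(direct, paste, "", collapse = ";"),
                    vapply(restricted, paste, "", collapse = ";"))
  }
})

test_that("equivalent nodes are MRCA clades with a contradiction flag", {
  full <- parseNewick("((A:1,B:1):2,(C:2,(D:1,E:1):1):1);")
  prunedA <- parseNewick("(A:2,(D:1,E:1):1);")   # pruned clade {D,E}
  recA <- equivalentNodes(full, prunedA)
  expect_equal(recA$fullClade, "D;E")
  expect_false(recA$contradicting)
  prunedB <- parseNewick("((A:1,D:1):1,E:2);")   # pruned clade {A,D}
  recB <- equivalentNodes(full, prunedB)
  expect_equal(recB$fullClade, "A;B;C;D;E")
  expect_true(recB$contradicting)  # retained E falls inside the MRCA clade
})

test_that("pruned MCC support exceeds full-MCC support for stable clades", {
  s <- generatePseudoPosterior(randomTimeTree(12, seed = 9),
                               wildcards = c("t4", "t11"), nTrees = 120, seed = 10)
  stable <- setdiff(sampleTipLabels(s), c("t4", "t11"))
  full <- mccTree(s)
  pm <- prunedMcc(s, stable)
  expect_equal(meanCladePP(pm), 1.0)  # only wildcards move
  rec <- equivalentNodes(full, pm)
  nc <- rec[!rec$contradicting, ]
  expect_gte(mean(nc$ppPruned - nc$ppFull), 0)
})

test_that("summarizeSupport reports means and contradiction counts", {
  rec <- data.frame(ppPruned = c(0.8, 0.9, 1.0), ppFull = c(0.6, 0.5, 0.4),
                    contradicting = c(FALSE, TRUE, TRUE))
  out <- summarizeSupport(rec)
  expect_equal(out$meanDiff, mean(c(0.2, 0.4, 0.6)))
  expect_equal(out$nContradicting, 2L)
  expect_error(summarizeSupport(rec[0, ]), "no equivalent-node")
})

test_that("support recovery grows with the number of excluded wildcards", {
  backbone <- randomTimeTree(14, seed = 11)
  wcs <- c("t3", "t8", "t12")
  diffs <- vapply(0:3, function(k) {
    s <- generatePseudoPosterior(backbone, wildcards = wcs[seq_len(k)],
                                 nTrees = 100, locality = 0, seed = 12)
    stable <- setdiff(backbone$tip.label, wcs)
    rec <- equivalentNodes(mccTree(s), prunedMcc(s, stable))
    summarizeSupport(rec)$meanDiff
  }, numeric(1))
  expect_equal(diffs[1], 0)
  expect_true(all(diff(diffs) >= -1e-9))
  expect_gt(diffs[4], diffs[1])
})
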