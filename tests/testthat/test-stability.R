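test_that("node distance counts internal nodes on the tip-to-tip path", {
  tr <- parseNewick("((A:1,B:1):1,C:2);")
  expect_equal(nodeDistance(tr, "A", "B"), 1L)  # sisters
  expect_equal(nodeDistance(tr, "A", "C"), 2L)
  expect_error(nodeDistance(tr, "A", "Z"), "absent")
  # a tip and its zero-length sampled ancestor are at distance 1
  sa <- parseNewick("((A:1,B:0):1,C:2);")
  expect_equal(nodeDistance(sa, "A", "B"), 1L)
})

test_that("caterpillar extremes are n - 1 apart and match path enumeration", {
  for (n in c(5L, 8L, 11L)) {
    tr <- caterpillar(n)
    expect_equal(nodeDistance(tr, "A", LETTERS[n]), n - 1L)
  }
  set.seed(111)
  for (rep in 1:20) {
    tr <- randomTimeTree(10)
    pair <- sample(tr$tip.label, 2)
    expect_equal(nodeDistance(tr, pair[1], pair[2]),
                 oracleNodeDistance(tr, pair[1], pair[2]))
  }
})

test_that("closestTips ranks by node distance with lexicographic ties", {
  tr <- parseNewick("((A:1,B:1):1,C:2);")
  expect_equal(closestTips(tr, "A", k = 1), "B")
  bal <- balanced4()
  expect_equal(closestTips(bal, "A", k = 3), c("B", "C", "D"))
  expect_error(closestTips(bal, "A", k = 4), "smaller")
  set.seed(112)
  for (rep in 1:20) {
    tr <- randomTimeTree(12)
    taxon <- sample(tr$tip.label, 1)
    others <- setdiff(sort(tr$tip.label), taxon)
    d <- vapply(others, oracleNodeDistance, numeric(1), tree = tr, a = taxon)
    expect_equal(closestTips(tr, taxon, k = 3),
                 others[order(d, others)][1:3])
  }
})

test_that("instability profiles are degenerate for identically placed taxa", {
  ref <- randomTimeTree(10, seed = 113)
  s <- treeSample(rep(list(ref), 8))
  prof <- instabilityProfile(s, ref, "t1")
  expect_equal(prof$mean, as.numeric(prof$mccDistance))
  expect_equal(prof$max, as.numeric(prof$mccDistance))
  expect_equal(prof$q95, as.numeric(prof$mccDistance))
})

test_that("wildcards show larger closest-tip distances than stable taxa", {
  backbone <- randomTimeTree(12, seed = 114)
  s <- generatePseudoPosterior(backbone, wildcards = "t5", nTrees = 80,
                               locality = 0, seed = 115)
  m <- mccTree(s)
  profW <- instabilityProfile(s, m, "t5")
  stableMeans <- vapply(c("t1", "t2", "t3"), function(tx) {
    mean(instabilityProfile(s, m, tx)$mean)
  }, numeric(1))
  expect_gt(mean(profW$mean), max(stableMeans))
})

test_that("profile quantiles equal direct order statistics of the distances", {
  s <- generatePseudoPosterior(randomTimeTree(9, seed = 116), wildcards = "t2",
                               nTrees = 20, seed = 117)
  m <- mccTree(s)
  ct <- closestTips(m, "t2", k = 3)
  prof <- instabilityProfile(s, m, "t2")
  d <- vapply(seq_along(s), function(i) nodeDistance(s[[i]], "t2", ct[1]), numeric(1))
  expect_equal(prof$mean[1], mean(d))
  expect_equal(prof$max[1], max(d))
  expect_equal(prof$q95[1], unname(quantile(d, 0.95)))
})

test_that("leaf stability is 1 for identically resolved taxa", {
  ref <- randomTimeTree(8, seed = 118)
  s <- treeSample(rep(list(ref), 6))
  ls <- leafStability(s, "t3")
  expect_equal(unname(ls), c(1, 1, 1))
})

test_that("a 50:50 topology split gives lsDif 0 and lsMax 0.5", {
  # every quartet containing A resolves differently in the two trees
  s <- sampleFromNewick(c(
    "((A:1,B:1):1,(C:1,D:1):1);",
    "((A:1,C:1):1,(B:1,D:1):1);"))
  ls <- leafStability(s, "A")
  expect_equal(ls[["lsDif"]], 0)
  expect_equal(ls[["lsMax"]], 0.5)
})

test_that("leaf stability matches manual quartet enumeration", {
  s <- sampleFromNewick(c(
    "(((A:1,B:1):1,C:2):1,(D:1,E:1):1);",
    "(((A:1,C:1):1,B:2):1,(D:1,E:1):1);"))
  for (tx in c("A", "D", "E")) {
    expect_equal(leafStability(s, tx), oracleLeafStability(s, tx))
  }
  set.seed(119)
  s2 <- treeSample(lapply(1:10, function(i) randomTimeTree(8)))
  for (tx in c("t1", "t5")) {
    expect_equal(leafStability(s2, tx), oracleLeafStability(s2, tx))
  }
})

test_that("sampled and exhaustive leaf stability agree within 3 SE", {
  s <- generatePseudoPosterior(randomTimeTree(12, seed = 120),
                               wildcards = "t6", nTrees = 40, seed = 121)
  exact <- leafStability(s, "t6")
  mc <- leafStability(s, "t6", quartetBudget = 400, seed = 122,
                      exhaustiveLimit = 4)
  # per-triplet spread of f1 - f2 bounds the sampling error
  tips <- sampleTipLabels(s)
  expect_lt(abs(mc[["lsDif"]] - exact[["lsDif"]]), 3 * 0.5 / sqrt(400) + 0.02)
  expect_lt(abs(mc[["lsMax"]] - exact[["lsMax"]]), 3 * 0.5 / sqrt(400) + 0.02)
})

test_that("uniform wildcards take the lsDif minimum and the ct1 maximum", {
  backbone <- randomTimeTree(14, seed = 123)
  s <- generatePseudoPosterior(backbone, wildcards = c("t4", "t10"),
                               nTrees = 100, locality = 0, seed = 124)
  m <- mccTree(s)
  rep <- stabilityReport(s, m, seed = 125)
  expect_equal(nrow(rep), 14L)
  wc <- rep$taxon %in% c("t4", "t10")
  expect_lt(max(rep$lsDif[wc]), min(rep$lsDif[!wc]))
  expect_gt(mean(rep$ct1mean[wc]), mean(rep$ct1mean[!wc]))
  # stable taxa whose MCC neighbourhood is itself stable stay close
  clean <- !wc & vapply(rep$taxon, function(tx) {
    !any(closestTips(m, tx) %in% c("t4", "t10"))
  }, logical(1))
  expect_gt(min(rep$ct1mean[wc]), max(rep$ct1mean[clean]))
  # the paper's Fig 8B pattern: stability anti-correlates with distance
  expect_lt(cor(rep$lsDif, rep$ct1mean, method = "spearman"), 0)
  # invariant: 0 <= lsDif <= lsMax <= 1
  expect_true(all(rep$lsDif >= 0 & rep$lsDif <= rep$lsMax & rep$lsMax <= 1))
})

test_that("stability reports on identical samples are fully degenerate", {
  ref <- randomTimeTree(7, seed = 126)
  s <- treeSample(rep(list(ref), 5))
  m <- mccTree(s)
  rep <- stabilityReport(s, m)
  expect_equal(nrow(rep), 7L)
  expect_equal(rep$lsDif, rep(1, 7))
  expect_equal(rep$ct1mean, rep$ct1max)
})
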