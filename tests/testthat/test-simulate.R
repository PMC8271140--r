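test_that("tree simulation is deterministic and hits the tip count", {
  t1 <- simulateTree(20, seed = 9)
  t2 <- simulateTree(20, seed = 9)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  t3 <- simulateTree(20, seed = 10)
  expect_false(identical(ape::write.tree(t1), ape::write.tree(t3)))
  for (n in c(4, 17, 120))
    expect_equal(length(simulateTree(n, seed = n)$tip.label), n)
  expect_error(simulateTree(3), ">= 4")
})

test_that("pure-birth tree height matches the Yule expectation", {
  set.seed(30)
  n <- 50
  h <- replicate(200,
    max(ape::node.depth.edgelength(simulateTree(n, birth = 1, death = 0))))
  expected <- sum(1 / (2:n))   # E[height | n] for a Yule tree, lambda = 1
  expect_lt(abs(mean(h) - expected) / expected, 0.15)
})

test_that("phenotype simulation honours the origin target exactly", {
  tr <- simulateTree(100, seed = 31)
  ph <- simulatePhenotype(tr, gain = 0.05, loss = 0.1,
                          targetOrigins = c(7, 7), seed = 32)
  expect_equal(ph$origins, 7L)
  expect_equal(sum(ph$events$from == "0" & ph$events$to == "1"), 7L)
  # tip states consistent with the recorded history
  expect_true(all(ph$tipStates %in% c(0L, 1L)))
  expect_equal(unname(ph$tipStates), ph$nodeStates[1:100])
  # zero gain rate: all tips background, no origins
  ph0 <- simulatePhenotype(tr, gain = 0, loss = 0.1,
                           targetOrigins = c(0, 0), seed = 33)
  expect_true(all(ph0$tipStates == 0L))
  expect_equal(ph0$origins, 0L)
  # unreachable target errors with advice
  expect_error(simulatePhenotype(tr, gain = 0, loss = 0.1,
                                 targetOrigins = c(5, 5), maxTries = 5),
               "adjust")
})

test_that("alignment simulation has the contracted rate behaviour", {
  tr <- simulateTree(40, seed = 34)
  # zero-rate sites are constant columns
  sim0 <- simulateAlignment(tr, nSites = 5, siteRates = rep(0, 5),
                            seed = 35)
  expect_true(all(apply(alignmentMatrix(sim0$alignment), 2,
                        function(x) length(unique(x))) == 1))
  expect_equal(nrow(sim0$events), 0L)
  # doubling the rate doubles the mean event count (within 10%)
  sim1 <- simulateAlignment(tr, nSites = 1000, siteRates = rep(0.02, 1000),
                            seed = 36)
  sim2 <- simulateAlignment(tr, nSites = 1000, siteRates = rep(0.04, 1000),
                            seed = 37)
  m1 <- nrow(sim1$events) / 1000
  m2 <- nrow(sim2$events) / 1000
  expect_lt(abs(m2 / m1 - 2), 0.2)
  # determinism under the seed
  simA <- simulateAlignment(tr, nSites = 20, seed = 38)
  simB <- simulateAlignment(tr, nSites = 20, seed = 38)
  expect_identical(alignmentMatrix(simA$alignment),
                   alignmentMatrix(simB$alignment))
  expect_identical(simA$events, simB$events)
})

test_that("long-branch tip states approach the stationary distribution", {
  set.seed(39)
  long <- ape::rtree(300)
  long$edge.length[] <- 50   # every branch far past mixing time
  m <- lgModel()
  sim <- simulateAlignment(long, nSites = 10, model = m,
                           siteRates = rep(1, 10))
  obs <- table(factor(as.vector(alignmentMatrix(sim$alignment)),
                      levels = aaAlphabet()))
  p <- stats::chisq.test(as.numeric(obs),
                         p = unname(stationaryFrequencies(m)))$p.value
  expect_gt(p, 0.01)
})

test_that("datasets are deterministic under (config, seed)", {
  d1 <- simulateDataset(nTips = 30, nSites = 40, targetOrigins = c(2, 8),
                        seed = 40)
  d2 <- simulateDataset(nTips = 30, nSites = 40, targetOrigins = c(2, 8),
                        seed = 40)
  expect_identical(alignmentMatrix(datasetAlignment(d1)),
                   alignmentMatrix(datasetAlignment(d2)))
  expect_identical(datasetPhenotypes(d1), datasetPhenotypes(d2))
  expect_identical(d1@siteEvents, d2@siteEvents)
  d3 <- simulateDataset(nTips = 30, nSites = 40, targetOrigins = c(2, 8),
                        seed = 41)
  expect_false(identical(alignmentMatrix(datasetAlignment(d1)),
                         alignmentMatrix(datasetAlignment(d3))))
})

test_that("convergent planting follows its construction contract", {
  set.seed(42)
  ds <- simulateDataset(nTips = 80, nSites = 30, targetOrigins = c(7, 7))
  gains <- sum(ds@phenoEvents$from == "0")
  expect_equal(gains, 7L)

  # full coupling: at least (origins - shadowing) changes to fgAA on gain
  # branches, and the ledger reports the realised count
  pl <- plantConvergentSite(ds, site = 5, fgAA = "W", pCouple = 1)
  led <- plantedLedger(pl)[[1]]
  expect_equal(length(led$coupledBranches), 7L)
  ev <- pl@siteEvents[pl@siteEvents$site == 5, ]
  gainBranches <- ds@phenoEvents$child[ds@phenoEvents$from == "0"]
  realised <- sum(ev$child %in% gainBranches & ev$to == "W")
  expect_equal(realised, led$realizedChanges)
  expect_gte(realised, 6L)  # nested-clade shadowing can absorb a gain

  # zero coupling leaves the site untouched
  pl0 <- plantConvergentSite(ds, site = 6, fgAA = "W", pCouple = 0)
  expect_identical(pl0@siteStates[, 6], ds@siteStates[, 6])
  expect_identical(alignmentMatrix(datasetAlignment(pl0))[, 6],
                   alignmentMatrix(datasetAlignment(ds))[, 6])

  # re-planting the same site is an error
  expect_error(plantConvergentSite(pl, site = 5, fgAA = "Y"),
               "already planted")
})

test_that("profile-change planting moves foreground residue usage", {
  set.seed(43)
  lib <- defaultProfileLibrary()
  prof <- profileMatrix(lib)
  ok <- replicate(20, {
    ds <- simulateDataset(nTips = 120, nSites = 2,
                          targetOrigins = c(4, 12), loss = 0.02)
    if (sum(datasetPhenotypes(ds)) < 30) return(NA)
    ds <- plantProfileChangeSite(ds, 1, prof[, "KR"], prof[, "DE"],
                                 rate = 1)
    m <- alignmentMatrix(datasetAlignment(ds))
    fgTips <- names(datasetPhenotypes(ds))[datasetPhenotypes(ds) == 1]
    obs <- table(factor(m[fgTips, 1], levels = aaAlphabet()))
    obs <- as.numeric(obs) / sum(obs)
    tvFg <- sum(abs(obs - prof[, "KR"])) / 2
    tvBg <- sum(abs(obs - prof[, "DE"])) / 2
    tvFg < tvBg
  })
  ok <- ok[!is.na(ok)]
  expect_gte(mean(ok), 0.95)

  # identical profiles are rejected
  ds <- simulateDataset(nTips = 30, nSites = 2, targetOrigins = c(1, 10),
                        seed = 44)
  expect_error(plantProfileChangeSite(ds, 1, prof[, "KR"], prof[, "KR"]),
               "must differ")

  # a dataset whose phenotype never reaches state 1 cannot take a planted
  # profile switch
  ds0 <- simulateDataset(nTips = 30, nSites = 2, gain = 0,
                         targetOrigins = c(0, 0), seed = 45)
  expect_error(plantProfileChangeSite(ds0, 1, prof[, "KR"], prof[, "DE"]),
               "foreground")
})
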