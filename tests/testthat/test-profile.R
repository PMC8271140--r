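test_that("branch partition follows the child-node phenotype state", {
  tr <- fixtureTree8()
  m <- binaryModel(0.5, 0.5)
  # all tips background
  sm0 <- marginalAncestralStates(tr, setNames(rep("0", 8), tr$tip.label),
                                 m, rootPrior = c(0.5, 0.5))
  p0 <- partitionBranches(tr, sm0)
  expect_equal(length(p0$foreground), 0L)
  expect_equal(length(p0$background), nrow(tr$edge))

  # single foreground cherry (t1,t2): stem + two tip branches
  states <- setNames(c("1", "1", rep("0", 6)), tr$tip.label)
  sm <- marginalAncestralStates(tr, states, m, rootPrior = c(0.5, 0.5))
  p <- partitionBranches(tr, sm)
  labels <- c(tr$tip.label, paste0("N", seq_len(tr$Nnode)))
  expect_setequal(labels[p$foreground], c("t1", "t2", "N3"))
  expect_equal(length(p$foreground) + length(p$background), nrow(tr$edge))
  expect_length(intersect(p$foreground, p$background), 0)
})

test_that("equal profiles reduce to the single-profile pruning likelihood", {
  set.seed(21)
  tr <- ape::rtree(8)
  prof <- profileMatrix(defaultProfileLibrary())[, "KR"]
  part <- list(isForeground = rep(c(TRUE, FALSE),
                                  length.out = nrow(tr$edge)))
  ts <- setNames(sample(aaAlphabet(), 8, replace = TRUE), tr$tip.label)
  mixed <- siteProfileLikelihood(tr, ts, part, prof, prof, rate = 0.7)
  single <- pruneLogLikelihood(tr, ts,
                               poissonModel(setNames(prof, aaAlphabet()),
                                            rate = 0.7),
                               rootPrior = unname(prof))
  expect_equal(mixed, single, tolerance = 1e-9)
})

test_that("branch-class likelihood matches enumeration on small trees", {
  skip_if_not_installed("Matrix")
  set.seed(22)
  alpha <- c("A", "C", "G", "T")
  for (i in 1:20) {
    n <- sample(3:5, 1)
    tr <- ape::rtree(n)
    fgProf <- setNames(c(0.7, 0.1, 0.1, 0.1), alpha)
    bgProf <- setNames(c(0.05, 0.45, 0.45, 0.05), alpha)
    isFg <- sample(c(TRUE, FALSE), nrow(tr$edge), replace = TRUE)
    ts <- setNames(sample(alpha, n, replace = TRUE), tr$tip.label)
    got <- siteProfileLikelihood(tr, ts, list(isForeground = isFg),
                                 fgProf, bgProf, rate = 1)
    Qfg <- rateMatrix(poissonModel(fgProf))
    Qbg <- rateMatrix(poissonModel(bgProf))
    want <- oracleEnumerationMixed(tr, ts, Qfg, Qbg, isFg,
                                   unname(bgProf), alpha)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("zero-propensity observed residues floor the likelihood", {
  tr <- ape::rtree(4)
  alpha <- c("A", "C", "G", "T")
  prof0 <- setNames(c(0, 0.5, 0.25, 0.25), alpha)
  prof1 <- setNames(rep(0.25, 4), alpha)
  ts <- setNames(c("A", "A", "A", "A"), tr$tip.label)
  expect_warning(
    ll <- siteProfileLikelihood(tr, ts,
                                list(isForeground = rep(TRUE,
                                                        nrow(tr$edge))),
                                prof0, prof0, rate = 1))
  expect_equal(ll, -1e10)
  expect_true(is.finite(
    siteProfileLikelihood(tr, ts,
                          list(isForeground = rep(TRUE, nrow(tr$edge))),
                          prof1, prof1, rate = 1)))
})

test_that("profile-change posterior is a proper, label-invariant probability", {
  set.seed(23)
  tr <- simulateTree(40)
  ph <- .simPhenoForTest(tr, 0.05, 0.1)
  rec <- suppressWarnings(reconstructPhenotype(tr, ph))
  part <- partitionBranches(tr, rec$stateMap)
  lib <- defaultProfileLibrary()
  ts <- setNames(sample(aaAlphabet(), 40, replace = TRUE), tr$tip.label)
  r <- profileChangePosterior(tr, ts, part, lib)
  expect_gte(r$posterior, 0)
  expect_lte(r$posterior, 1)
  # posterior(change) + posterior(no change) = 1 by construction
  pNull <- 1 / (1 + exp(r$logLikChange - r$logLikNull))
  expect_equal(r$posterior + pNull, 1, tolerance = 1e-12)
  # permuting library columns leaves the posterior unchanged
  perm <- sample(nProfiles(lib))
  libP <- profileLibrary(profileMatrix(lib)[, perm],
                         weights = lib@weights[perm])
  rP <- profileChangePosterior(tr, ts, part, libP, rate = r$rate)
  expect_equal(rP$posterior, r$posterior, tolerance = 1e-9)
  # a single-profile library cannot support a change
  lib1 <- profileLibrary(profileMatrix(lib)[, 1, drop = FALSE])
  expect_equal(profileChangePosterior(tr, ts, part, lib1)$posterior, 0)
  # empty foreground set is an error
  expect_error(profileChangePosterior(
    tr, ts, list(foreground = integer(0), background = tr$edge[, 2],
                 isForeground = rep(FALSE, nrow(tr$edge))), lib),
    "foreground")
})

test_that("constant sites do not favour a profile change", {
  set.seed(24)
  tr <- simulateTree(40)
  ph <- .simPhenoForTest(tr, 0.05, 0.1)
  rec <- suppressWarnings(reconstructPhenotype(tr, ph))
  part <- partitionBranches(tr, rec$stateMap)
  ts <- setNames(rep("A", 40), tr$tip.label)
  r <- profileChangePosterior(tr, ts, part, defaultProfileLibrary())
  expect_lt(r$posterior, 0.5)
})

test_that("planted profile switches are recovered with high posterior", {
  set.seed(25)
  lib <- defaultProfileLibrary()
  prof <- profileMatrix(lib)
  post <- replicate(10, {
    ds <- simulateDataset(nTips = 200, nSites = 2,
                          targetOrigins = c(3, 10))
    ds <- plantProfileChangeSite(ds, 2, prof[, "KR"], prof[, "DE"],
                                 rate = 0.15)
    rec <- suppressWarnings(reconstructPhenotype(datasetTree(ds),
                                                 datasetPhenotypes(ds)))
    part <- partitionBranches(datasetTree(ds), rec$stateMap)
    m <- alignmentMatrix(datasetAlignment(ds))
    profileChangePosterior(datasetTree(ds),
                           setNames(m[, 2], rownames(m)), part,
                           lib)$posterior
  })
  expect_gte(mean(post > 0.5), 0.9)
})

test_that("quadrant Fisher test matches exact hypergeometric arithmetic", {
  # perfectly independent table
  even <- quadrantFisher(rep(c(0, 5), each = 20),
                         rep(c(0.2, 0.8), times = 20), simCutoff = 3)
  expect_equal(even$pValue, 1)
  # diagonal table [[5,0],[0,5]]
  diag <- quadrantFisher(rep(c(0, 5), each = 5), rep(c(0.2, 0.8), each = 5),
                         simCutoff = 3)
  expect_equal(diag$pValue, 2 / choose(10, 5), tolerance = 1e-12)
  # degenerate margin
  expect_warning(deg <- quadrantFisher(rep(5, 10), runif(10),
                                       simCutoff = 3))
  expect_equal(deg$pValue, 1)
  # equivalence with direct enumeration on random small tables
  set.seed(26)
  for (i in 1:50) {
    n <- sample(8:40, 1)
    sim <- sample(0:6, n, replace = TRUE)
    pc <- runif(n)
    q <- suppressWarnings(quadrantFisher(sim, pc, simCutoff = 3))
    if (any(rowSums(q$table) == 0) || any(colSums(q$table) == 0)) next
    expect_equal(q$pValue, fisherOracle(q$table), tolerance = 1e-9)
  }
  expect_error(quadrantFisher(1:3, runif(4)), "equal length")
})
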