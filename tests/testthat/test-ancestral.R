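test_that("two-tip pruning likelihood matches the closed form", {
  tr <- ape::read.tree(text = "(a:0.3,b:0.7);")
  m <- binaryModel(1, 1)   # symmetric two-state chain
  ll <- pruneLogLikelihood(tr, c(a = "0", b = "0"), m,
                           rootPrior = c(0.5, 0.5))
  p00 <- function(t) 0.5 + 0.5 * exp(-2 * t)   # P(0->0) for gain=loss=1
  p10 <- function(t) 0.5 - 0.5 * exp(-2 * t)
  byHand <- log(0.5 * p00(0.3) * p00(0.7) + 0.5 * p10(0.3) * p10(0.7))
  expect_equal(ll, byHand, tolerance = 1e-10)
})

test_that("pruning and marginals match joint enumeration on small trees", {
  skip_if_not_installed("Matrix")
  set.seed(42)
  alpha <- c("A", "C", "G", "T")
  for (i in 1:50) {
    n <- sample(3:5, 1)
    tr <- ape::rtree(n)
    m <- randomModel(alpha)
    ts <- setNames(sample(alpha, n, replace = TRUE), tr$tip.label)
    o <- oracleEnumeration(tr, ts, rateMatrix(m), m@frequencies, alpha)
    expect_equal(pruneLogLikelihood(tr, ts, m), o$logLik,
                 tolerance = 1e-8)
    sm <- marginalAncestralStates(tr, ts, m)
    expect_equal(max(abs(posteriorMatrix(sm) - o$marginals)), 0,
                 tolerance = 1e-8)
  }
})

test_that("posteriors are proper and certain at observed tips", {
  set.seed(7)
  tr <- ape::rtree(6)
  m <- randomModel(c("A", "C", "G", "T"))
  ts <- setNames(sample(c("A", "C", "G", "T"), 6, replace = TRUE),
                 tr$tip.label)
  sm <- marginalAncestralStates(tr, ts, m)
  post <- posteriorMatrix(sm)
  expect_true(all(abs(rowSums(post) - 1) < 1e-9))
  for (tip in tr$tip.label)
    expect_equal(unname(post[tip, ts[tip]]), 1, tolerance = 1e-9)
  # missing data: likelihood unchanged by an 'X' tip marginalisation
  tsX <- ts; tsX[1] <- "X"
  expect_true(is.finite(pruneLogLikelihood(tr, tsX, m)))
})

test_that("long-branch limit approaches stationary frequencies", {
  tr <- ape::read.tree(text = "(a:500,b:500);")
  m <- randomModel(c("A", "C", "G", "T"))
  ll <- pruneLogLikelihood(tr, c(a = "A", b = "C"), m)
  f <- stationaryFrequencies(m)
  expect_equal(ll, log(f[["A"]] * f[["C"]]), tolerance = 1e-6)
})

test_that("likelihood is invariant under re-rooting for a reversible model", {
  set.seed(13)
  for (i in 1:5) {
    tr <- ape::rtree(7)
    m <- randomModel(c("A", "C", "G", "T"))
    ts <- setNames(sample(c("A", "C", "G", "T"), 7, replace = TRUE),
                   tr$tip.label)
    ll <- pruneLogLikelihood(tr, ts, m)
    rerooted <- ape::root(tr, outgroup = sample(tr$tip.label, 1),
                          resolve.root = TRUE)
    expect_equal(pruneLogLikelihood(rerooted, ts, m), ll,
                 tolerance = 1e-8)
  }
})

test_that("constant characters reconstruct constant and eventless", {
  tr <- fixtureTree8()
  m <- lgModel()
  ts <- setNames(rep("K", 8), tr$tip.label)
  sm <- marginalAncestralStates(tr, ts, m)
  expect_true(all(mapStates(sm) == "K"))
  post <- posteriorMatrix(sm)
  expect_true(all(post[, "K"] > apply(post[, colnames(post) != "K"], 1,
                                      max)))
  expect_equal(nrow(extractBranchEvents(tr, sm)), 0L)
})

test_that("a symmetric four-tip configuration gives a 50/50 root posterior", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  m <- binaryModel(1, 1)
  sm <- marginalAncestralStates(tr, c(A = "1", B = "1", C = "0", D = "0"),
                                m, rootPrior = c(0.5, 0.5))
  root <- posteriorMatrix(sm)["N1", ]
  expect_equal(unname(root), c(0.5, 0.5), tolerance = 1e-9)
})

test_that("branch events are called where parent and child MAP differ", {
  tr <- ape::read.tree(text = "(a:0.1,b:2);")
  m <- lgModel()
  sm <- marginalAncestralStates(tr, c(a = "H", b = "Y"), m)
  ev <- extractBranchEvents(tr, sm)
  # short branch pins the root at 'H'; the long branch carries H -> Y
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$branch, "b")
  expect_equal(ev$from, "H")
  expect_equal(ev$to, "Y")
})

test_that("reconstructed event counts track the true simulated counts", {
  set.seed(99)
  tr <- simulateTree(50)
  m <- lgModel()
  trueN <- reconN <- numeric(100)
  sim <- simulateAlignment(tr, nSites = 100, model = m, baseRate = 0.02,
                           gammaShape = NULL, hyperFraction = 0)
  anc <- ancestralAlignment(tr, sim$alignment, model = m)
  trueN <- tabulate(sim$events$site, 100)
  reconN <- tabulate(branchEvents(anc)$site, 100)
  expect_lt(abs(mean(reconN) - mean(trueN)) / max(mean(trueN), 1), 0.2)
})

test_that("binary phenotype ML fitting behaves across regimes", {
  # clade-consistent phenotype: MAP history has exactly one gain
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  ph <- c(A = 1L, B = 1L, C = 0L, D = 0L)
  rec <- suppressWarnings(reconstructPhenotype(tr, ph))
  expect_equal(nrow(rec$events), 1L)
  expect_equal(rec$events$from, "0")

  # monomorphic phenotype is an error
  expect_error(fitBinaryPhenotypeModel(tr, c(A = 1L, B = 1L, C = 1L,
                                             D = 1L)),
               "no phenotype variation")

  # parameter recovery within a factor of two (median over replicates)
  set.seed(5)
  tr200 <- simulateTree(200)
  ratios <- replicate(20, {
    ph <- .simPhenoForTest(tr200, 0.1, 0.1)
    fit <- suppressWarnings(fitBinaryPhenotypeModel(tr200, ph))
    c(fit$gain / 0.1, fit$loss / 0.1)
  })
  med <- apply(ratios, 1, median)
  expect_true(all(med > 0.5 & med < 2))
})
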