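#' @include AllClasses.R
NULL

#' Simulate a birth-death tree with a fixed number of tips
#'
#' Thin wrapper over `ape::rphylo()` (conditioned on the number of tips),
#' with bounded retries for parameter combinations under which the
#' simulation can fail.  Deterministic under `set.seed()`.
#'
#' @param nTips number of tips (>= 4).
#' @param birth,death speciation and extinction rates.
#' @param seed optional integer seed.
#' @param maxTries retry bound.
#' @return a rooted `phylo` with tip labels `t1..tN`.
#' @export
simulateTree <- function(nTips, birth = 1, death = 0, seed = NULL,
                         maxTries = 100L) {
  if (nTips < 4) stop("nTips must be >= 4")
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_len(maxTries)) {
    tree <- tryCatch(ape::rphylo(nTips, birth, death, fossils = FALSE),
                     error = function(e) NULL)
    if (!is.null(tree) && length(tree$tip.label) == nTips) {
      tree$tip.label <- paste0("t", seq_len(nTips))
      return(tree)
    }
  }
  stop("tree simulation failed after ", maxTries,
       " tries (all lineages extinct?); lower the death rate")
}

# Two-state Gillespie simulation along the tree (cladewise), recording
# every jump.  Returns node states and the jump history.
.simBinaryHistory <- function(tree, gain, loss, rootState = 0L) {
  cw <- .cladewise(tree)
  nN <- .nNodes(tree)
  states <- integer(nN)
  root <- cw$edge[1, 1]
  states[root] <- rootState
  evChild <- integer(0); evFrom <- integer(0); evTo <- integer(0)
  for (e in seq_len(nrow(cw$edge))) {
    p <- cw$edge[e, 1]; ch <- cw$edge[e, 2]
    s <- states[p]; t <- 0; L <- cw$length[e]
    repeat {
      r <- if (s == 0L) gain else loss
      if (r <= 0) break
      t <- t + stats::rexp(1, r)
      if (t >= L) break
      evChild <- c(evChild, ch); evFrom <- c(evFrom, s)
      s <- 1L - s
      evTo <- c(evTo, s)
    }
    states[ch] <- s
  }
  labels <- .nodeLabels(tree)
  list(nodeStates = states,
       events = data.frame(branch = labels[evChild], child = evChild,
                           from = as.character(evFrom),
                           to = as.character(evTo),
                           stringsAsFactors = FALSE))
}

#' Simulate a binary phenotype with a controlled number of origins
#'
#' Continuous-time two-state simulation along the branches (root in the
#' background state 0), rejection-sampled until the number of independent
#' gains (0 to 1 jumps) falls within `targetOrigins`.
#'
#' @param tree rooted `phylo`.
#' @param gain,loss per-unit-branch-length transition rates.
#' @param targetOrigins inclusive integer range `c(lo, hi)` of accepted
#'   origin counts.
#' @param seed optional integer seed.
#' @param maxTries rejection bound; exceeding it is an error suggesting a
#'   rate change.
#' @return list with `tipStates` (named 0/1 integer vector), `nodeStates`
#'   (per ape node id), `events` (true jump history), `origins`.
#' @export
simulatePhenotype <- function(tree, gain = 0.035, loss = 0.1,
                              targetOrigins = c(7, 7), seed = NULL,
                              maxTries = 1000L) {
  .checkTree(tree)
  if (gain < 0 || loss < 0) stop("rates must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_len(maxTries)) {
    h <- .simBinaryHistory(tree, gain, loss)
    origins <- sum(h$events$from == "0")
    if (origins >= targetOrigins[1] && origins <= targetOrigins[2]) {
      nTip <- length(tree$tip.label)
      return(list(
        tipStates = setNames(h$nodeStates[seq_len(nTip)], tree$tip.label),
        nodeStates = h$nodeStates, events = h$events, origins = origins))
    }
  }
  stop("no draw with ", targetOrigins[1], "-", targetOrigins[2],
       " origins in ", maxTries,
       " tries; adjust the gain/loss rates to match the target")
}

#' Simulate a site-heterogeneous amino acid alignment
#'
#' Per-site Gillespie simulation along the tree under a reversible model.
#' Site rates are gamma-distributed multipliers of `baseRate` (expected
#' substitutions per unit branch length); a fraction of sites is
#' "hypervariable" with an extra rate multiplier.  The full true
#' substitution history is returned.
#'
#' @param tree rooted `phylo`.
#' @param nSites number of alignment columns.
#' @param model a [SubstitutionModel-class] (default [lgModel()]).
#' @param baseRate expected substitutions per unit branch length at rate
#'   multiplier 1.
#' @param gammaShape shape of the mean-1 gamma rate distribution
#'   (`NULL` = homogeneous).
#' @param hyperFraction fraction of sites given the hypervariable
#'   multiplier.
#' @param hyperMultiplier rate multiplier of hypervariable sites.
#' @param siteRates optional explicit per-site rates (overrides the above;
#'   absolute, not multipliers of `baseRate`).
#' @param seed optional integer seed.
#' @return list with `alignment` ([AAAlignment-class]), `nodeStates`
#'   (character matrix nodes x sites), `events` (data.frame `site`,
#'   `branch`, `child`, `from`, `to`), `siteRates`.
#' @export
simulateAlignment <- function(tree, nSites = 2000L, model = lgModel(),
                              baseRate = 0.015, gammaShape = 0.8,
                              hyperFraction = 0.05, hyperMultiplier = 10,
                              siteRates = NULL, seed = NULL) {
  .checkTree(tree)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(siteRates)) {
    mult <- if (is.null(gammaShape)) rep(1, nSites)
            else rgamma(nSites, shape = gammaShape, rate = gammaShape)
    nHyper <- floor(hyperFraction * nSites)
    if (nHyper > 0) {
      hyperIdx <- sample.int(nSites, nHyper)
      mult[hyperIdx] <- hyperMultiplier *
        (if (is.null(gammaShape)) rep(1, nHyper)
         else rgamma(nHyper, shape = gammaShape, rate = gammaShape))
    }
    siteRates <- baseRate * mult
  }
  stopifnot(length(siteRates) == nSites)
  cw <- .cladewise(tree)
  Q <- rateMatrix(model)
  sim <- cpp_sim_sites(cw$edge, cw$length, .nNodes(tree), Q,
                       siteRates * model@rate, model@frequencies)
  labels <- .nodeLabels(tree)
  alpha <- model@alphabet
  nodeStates <- matrix(alpha[sim$nodeStates + 1L], nrow = .nNodes(tree),
                       dimnames = list(labels, NULL))
  events <- data.frame(site = sim$site, branch = labels[sim$child],
                       child = sim$child, from = alpha[sim$from + 1L],
                       to = alpha[sim$to + 1L], stringsAsFactors = FALSE)
  nTip <- length(tree$tip.label)
  m <- nodeStates[seq_len(nTip), , drop = FALSE]
  aln <- new("AAAlignment", matrix = m, retained = seq_len(nSites),
             originalWidth = as.integer(nSites))
  list(alignment = aln, nodeStates = nodeStates, events = events,
       siteRates = siteRates)
}

#' Simulate a complete dataset (tree, phenotype, alignment)
#'
#' The default configuration mirrors the shape of a mitochondrial
#' protein-coding study: 200 tips, 2,000 sites, a binary trait with 7
#' independent origins, gamma site-rate heterogeneity with 5% hypervariable
#' sites at a 10x rate.  Without planting (see [plantConvergentSite()],
#' [plantProfileChangeSite()]) genotype and phenotype are simulated
#' independently, so the dataset is exactly null for genotype-phenotype
#' coupling.
#'
#' @param nTips,nSites dataset dimensions.
#' @param birth,death tree simulation rates.
#' @param gain,loss phenotype transition rates.
#' @param targetOrigins accepted range of phenotype origin counts.
#' @param model substitution model for the alignment.
#' @param baseRate,gammaShape,hyperFraction,hyperMultiplier site-rate
#'   settings, see [simulateAlignment()].
#' @param seed optional integer seed.
#' @return a [SimulatedDataset-class].
#' @export
simulateDataset <- function(nTips = 200L, nSites = 2000L, birth = 1,
                            death = 0, gain = 0.035, loss = 0.1,
                            targetOrigins = c(7, 7), model = lgModel(),
                            baseRate = 0.015, gammaShape = 0.8,
                            hyperFraction = 0.05, hyperMultiplier = 10,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- simulateTree(nTips, birth, death)
  ph <- simulatePhenotype(tree, gain, loss, targetOrigins)
  al <- simulateAlignment(tree, nSites, model, baseRate, gammaShape,
                          hyperFraction, hyperMultiplier)
  new("SimulatedDataset", tree = tree, alignment = al$alignment,
      tipPhenotypes = ph$tipStates,
      nodePhenotypes = as.integer(ph$nodeStates),
      phenoEvents = ph$events, siteStates = al$nodeStates,
      siteEvents = al$events, siteRates = al$siteRates,
      ledger = list(),
      config = list(nTips = nTips, nSites = nSites, birth = birth,
                    death = death, gain = gain, loss = loss,
                    targetOrigins = targetOrigins, baseRate = baseRate,
                    gammaShape = gammaShape,
                    hyperFraction = hyperFraction,
                    hyperMultiplier = hyperMultiplier, seed = seed))
}

# Recompute one site's event list from its node states (single change per
# branch by construction after planting).
.eventsFromStates <- function(tree, states, site) {
  labels <- .nodeLabels(tree)
  e <- tree$edge
  changed <- which(states[e[, 1]] != states[e[, 2]])
  data.frame(site = rep(as.integer(site), length(changed)),
             branch = labels[e[changed, 2]], child = e[changed, 2],
             from = states[e[changed, 1]], to = states[e[changed, 2]],
             stringsAsFactors = FALSE)
}

.replaceSite <- function(dataset, site, states, tree) {
  dataset@siteStates[, site] <- states
  nTip <- length(tree$tip.label)
  m <- dataset@alignment@matrix
  m[, site] <- states[seq_len(nTip)]
  dataset@alignment@matrix <- m
  ev <- dataset@siteEvents
  ev <- ev[ev$site != site, , drop = FALSE]
  ev <- rbind(ev, .eventsFromStates(tree, states, site))
  ev <- ev[order(ev$site), , drop = FALSE]
  rownames(ev) <- NULL
  dataset@siteEvents <- ev
  dataset
}

#' Plant a convergent amino acid site coupled to phenotype gains
#'
#' On each branch carrying a true phenotype gain, with probability
#' `pCouple`, the site's state is overwritten with the foreground amino
#' acid along the entire descendant subtree; background evolution elsewhere
#' is preserved.  The ledger records which gain branches were coupled and
#' how many of them realised an actual change to `fgAA` (nested foreground
#' clades can shadow each other).
#'
#' @param dataset a [SimulatedDataset-class].
#' @param site site index to modify.
#' @param fgAA foreground amino acid planted on coupled branches; `NULL`
#'   (default) picks the first residue in alphabet order that differs from
#'   the site's true root state, so the plant always introduces changes.
#' @param pCouple per-gain-branch coupling probability in `[0,1]`.
#' @param seed optional integer seed.
#' @return the modified [SimulatedDataset-class] with an updated ledger.
#' @export
plantConvergentSite <- function(dataset, site, fgAA = NULL, pCouple = 1,
                                seed = NULL) {
  stopifnot(is(dataset, "SimulatedDataset"))
  if (!is.null(seed)) set.seed(seed)
  if (any(vapply(dataset@ledger, function(x) x$site == site, logical(1))))
    stop("site ", site, " already planted")
  tree <- dataset@tree
  if (is.null(fgAA)) {
    rootState <- dataset@siteStates[length(tree$tip.label) + 1L, site]
    fgAA <- setdiff(aaAlphabet(), rootState)[1]
  }
  pe <- dataset@phenoEvents
  gains <- unique(pe$child[pe$from == "0" & pe$to == "1"])
  coupled <- gains[runif(length(gains)) <= pCouple]
  states <- dataset@siteStates[, site]
  if (length(coupled) > 0) {
    cw <- .cladewise(tree)
    pre <- unique(as.vector(t(cw$edge)))   # preorder node visit order
    for (g in pre[pre %in% coupled]) {
      below <- c(g, unlist(phangorn::Descendants(tree, g, type = "all")))
      states[below] <- fgAA
    }
  }
  parentOf <- setNames(tree$edge[, 1], tree$edge[, 2])
  realized <- sum(states[parentOf[as.character(coupled)]] != fgAA)
  dataset <- .replaceSite(dataset, site, states, tree)
  dataset@ledger <- c(dataset@ledger, list(list(
    kind = "convergent", site = site, fgAA = fgAA, pCouple = pCouple,
    gainBranches = gains, coupledBranches = coupled,
    realizedChanges = realized)))
  dataset
}

#' Plant a profile-change site
#'
#' Re-simulates one site with the background profile on background branches
#' and the foreground profile on foreground branches (branch class = true
#' phenotype state of the child node; the root draws from the background
#' profile).  Uniform exchangeabilities, matching the profile-change
#' model's assumptions.
#'
#' @param dataset a [SimulatedDataset-class].
#' @param site site index to replace.
#' @param fgProfile,bgProfile distinct propensity simplexes named by amino
#'   acid (or unnamed over [aaAlphabet()]).
#' @param rate site rate in expected substitutions per unit branch length.
#'   The default (`NULL`) scales the rate so that the expected number of
#'   substitutions in the *smaller* branch class is `targetEvents`: like
#'   the convergent planter, the plant then guarantees its signal is
#'   expressed in the data rather than leaving it to rate luck (capped
#'   at 2).
#' @param targetEvents expected substitutions in the smaller branch class
#'   under the default rate.
#' @param seed optional integer seed.
#' @return the modified [SimulatedDataset-class] with an updated ledger.
#' @export
plantProfileChangeSite <- function(dataset, site, fgProfile, bgProfile,
                                   rate = NULL, targetEvents = 5,
                                   seed = NULL) {
  stopifnot(is(dataset, "SimulatedDataset"))
  if (!is.null(seed)) set.seed(seed)
  if (any(vapply(dataset@ledger, function(x) x$site == site, logical(1))))
    stop("site ", site, " already planted")
  fg <- as.numeric(fgProfile); bg <- as.numeric(bgProfile)
  if (isTRUE(all.equal(fg, bg)))
    stop("foreground and background profiles must differ")
  if (sum(dataset@nodePhenotypes == 1L) == 0)
    stop("no foreground branches: phenotype never reaches state 1")
  tree <- dataset@tree
  alpha <- names(fgProfile)
  if (is.null(alpha)) alpha <- aaAlphabet()
  if (is.null(rate)) {
    phenChild <- dataset@nodePhenotypes[tree$edge[, 2]]
    fgLen <- sum(tree$edge.length[phenChild == 1L])
    bgLen <- sum(tree$edge.length[phenChild == 0L])
    rate <- min(targetEvents / max(min(fgLen, bgLen), 1e-8), 2)
  }
  Qfg <- rateMatrix(poissonModel(setNames(fg, alpha)))
  Qbg <- rateMatrix(poissonModel(setNames(bg, alpha)))
  cw <- .cladewise(tree)
  nN <- .nNodes(tree)
  states <- character(nN)
  root <- cw$edge[1, 1]
  states[root] <- sample(alpha, 1, prob = bg)
  phen <- dataset@nodePhenotypes
  for (e in seq_len(nrow(cw$edge))) {
    p <- cw$edge[e, 1]; ch <- cw$edge[e, 2]
    Q <- if (phen[ch] == 1L) Qfg else Qbg
    s <- match(states[p], alpha)
    t <- 0; L <- cw$length[e]
    repeat {
      out <- -Q[s, s] * rate
      if (out <= 0) break
      t <- t + stats::rexp(1, out)
      if (t >= L) break
      probs <- Q[s, ]; probs[s] <- 0
      s <- sample.int(length(alpha), 1, prob = probs)
    }
    states[ch] <- alpha[s]
  }
  dataset <- .replaceSite(dataset, site, states, tree)
  dataset@ledger <- c(dataset@ledger, list(list(
    kind = "profile-change", site = site, fgProfile = fg, bgProfile = bg,
    rate = rate)))
  dataset
}
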