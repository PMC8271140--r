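#' @include AllClasses.R
NULL

#' Pruning log-likelihood of a single character
#'
#' Felsenstein pruning for one character on a rooted tree under a reversible
#' model.  Missing tip states (`X`, `-`, `?` or `NA`) contribute all-ones
#' partial likelihoods.
#'
#' @param tree rooted ape `phylo` with branch lengths.
#' @param tipStates named character vector of tip symbols.
#' @param model a [SubstitutionModel-class]; its `rate` multiplies branch
#'   lengths.
#' @param rootPrior optional root state distribution; defaults to the
#'   model's stationary frequencies (under which the likelihood is invariant
#'   to the root position for a reversible model).
#' @return log-likelihood (scalar).
#' @export
pruneLogLikelihood <- function(tree, tipStates, model, rootPrior = NULL) {
  .checkTree(tree)
  po <- .postorder(tree)
  tips <- .tipStateMatrix(tree, tipStates, model@alphabet)
  if (is.null(rootPrior)) rootPrior <- model@frequencies
  P <- .pmatCube(model, po$length * model@rate)
  as.numeric(cpp_prune(po$edge, .nNodes(tree), P, tips, rootPrior))
}

#' Marginal ancestral state reconstruction
#'
#' Per-node marginal posteriors by the standard two-pass (up/down) algorithm
#' and MAP states with a deterministic tie-break (lowest alphabet index).
#' Ties within 1e-12 posterior mass are counted and reported via a message.
#'
#' @inheritParams pruneLogLikelihood
#' @return a [CharacterStateMap-class] covering all nodes (tips included).
#' @export
marginalAncestralStates <- function(tree, tipStates, model,
                                    rootPrior = NULL) {
  .checkTree(tree)
  po <- .postorder(tree)
  tips <- .tipStateMatrix(tree, tipStates, model@alphabet)
  if (is.null(rootPrior)) rootPrior <- model@frequencies
  P <- .pmatCube(model, po$length * model@rate)
  res <- cpp_marginal(po$edge, .nNodes(tree), P, tips, rootPrior,
                      full = TRUE)
  post <- t(res$posterior[, 1, ])   # nodes x states
  labels <- .nodeLabels(tree)
  dimnames(post) <- list(labels, model@alphabet)
  states <- setNames(model@alphabet[res$map[, 1] + 1L], labels)
  maxp <- apply(post, 1, max)
  ties <- sum(rowSums(abs(post - maxp) < 1e-12) > 1)
  if (ties > 0)
    message(ties, " node(s) had tied MAP states; lowest alphabet index used")
  new("CharacterStateMap", states = states, posterior = post,
      alphabet = model@alphabet, ties = as.integer(ties))
}

#' Branch events implied by a node-state map
#'
#' One event per branch whose parent MAP state differs from its child MAP
#' state.  Branches are identified by their child node (label and ape node
#' id).
#'
#' @param tree rooted `phylo`.
#' @param stateMap a [CharacterStateMap-class] covering all nodes, or a
#'   character vector of states ordered by ape node id.
#' @return data.frame with columns `branch`, `child`, `from`, `to` (zero
#'   rows for a constant character).
#' @export
extractBranchEvents <- function(tree, stateMap) {
  .checkTree(tree)
  labels <- .nodeLabels(tree)
  states <- if (is(stateMap, "CharacterStateMap")) {
    s <- mapStates(stateMap)
    if (!all(labels %in% names(s)))
      stop("state map does not cover all nodes of the tree")
    unname(s[labels])
  } else {
    if (length(stateMap) != .nNodes(tree))
      stop("state vector must have one entry per node")
    as.character(stateMap)
  }
  e <- tree$edge
  changed <- states[e[, 1]] != states[e[, 2]]
  data.frame(branch = labels[e[changed, 2]],
             child = e[changed, 2],
             from = states[e[changed, 1]],
             to = states[e[changed, 2]],
             stringsAsFactors = FALSE)
}

#' Fit a two-state model to a binary phenotype by maximum likelihood
#'
#' Bounded two-parameter search for the gain (0 to 1) and loss (1 to 0)
#' rates of a continuous-time two-state chain, with an equal-probability
#' root prior (also used for the subsequent reconstruction).  Rates are
#' constrained to `[1e-6, 100]`; hitting a bound triggers a warning.
#'
#' @param tree rooted `phylo`.
#' @param phenotypes named 0/1 vector covering all tips (see
#'   [readPhenotypes()]).
#' @return list with `model` (a [SubstitutionModel-class]), `gain`, `loss`,
#'   `logLik` and `hitBound`.
#' @export
fitBinaryPhenotypeModel <- function(tree, phenotypes) {
  .checkTree(tree)
  ph <- phenotypes[tree$tip.label]
  if (any(is.na(ph))) stop("phenotype missing for some tips")
  if (length(unique(ph)) < 2)
    stop("no phenotype variation: all tips share state ", ph[1])
  po <- .postorder(tree)
  tips <- .tipStateMatrix(tree, setNames(as.character(ph), names(ph)),
                          c("0", "1"))
  rootPrior <- c(0.5, 0.5)
  nll <- function(par) {
    m <- binaryModel(exp(par[1]), exp(par[2]))
    P <- .pmatCube(m, po$length)
    -as.numeric(cpp_prune(po$edge, .nNodes(tree), P, tips, rootPrior))
  }
  L <- sum(tree$edge.length)
  start <- log(pmax(pmin(c(sum(ph == 1), sum(ph == 0)) / L, 50), 1e-3))
  fit <- optim(start, nll, method = "L-BFGS-B",
               lower = log(1e-6), upper = log(100))
  rates <- exp(fit$par)
  hit <- any(abs(fit$par - log(1e-6)) < 1e-8 | abs(fit$par - log(100)) < 1e-8)
  if (hit) warning("rate estimate hit the optimisation bounds [1e-6, 100]")
  list(model = binaryModel(rates[1], rates[2]), gain = rates[1],
       loss = rates[2], logLik = -fit$value, hitBound = hit)
}

#' Reconstruct the phenotype history on the tree
#'
#' Convenience wrapper: fits the two-state model, reconstructs marginal
#' ancestral phenotype states with an equal-prior root, and extracts gain
#' and loss branch events.
#'
#' @inheritParams fitBinaryPhenotypeModel
#' @return list with `stateMap` ([CharacterStateMap-class]), `events`
#'   (data.frame as in [extractBranchEvents()]), `gain`, `loss`, `fit`.
#' @export
reconstructPhenotype <- function(tree, phenotypes) {
  fit <- fitBinaryPhenotypeModel(tree, phenotypes)
  sm <- marginalAncestralStates(
    tree, setNames(as.character(phenotypes[tree$tip.label]),
                   tree$tip.label),
    fit$model, rootPrior = c(0.5, 0.5))
  list(stateMap = sm, events = extractBranchEvents(tree, sm),
       gain = fit$gain, loss = fit$loss, fit = fit)
}

#' Batched ancestral reconstruction for every alignment site
#'
#' Reconstructs marginal MAP states for all sites of a (gap-free) alignment
#' under a shared substitution model with a per-site rate multiplier chosen
#' by maximum likelihood over a fixed log-spaced grid.  Sites are grouped by
#' selected rate and reconstructed in batched pruning passes.
#'
#' @param tree rooted `phylo` whose tips match the alignment rows.
#' @param aln an [AAAlignment-class]; gap columns must have been removed
#'   (`X` is treated as missing data).
#' @param model a [SubstitutionModel-class]; default LG with
#'   alignment-observed frequencies.
#' @param rateGrid positive rate multipliers searched per site.
#' @param rootPrior optional root distribution (default: model stationary).
#' @return an [AncestralAlignment-class].
#' @export
ancestralAlignment <- function(tree, aln, model = NULL,
                               rateGrid = 2^seq(-3, 3, length.out = 7),
                               rootPrior = NULL) {
  .checkTree(tree)
  stopifnot(is(aln, "AAAlignment"))
  m <- alignmentMatrix(aln)
  if (any(m == "-"))
    stop("alignment contains gap columns; apply dropGapColumns() first")
  if (is.null(model)) model <- lgModel(observedFrequencies(aln))
  if (is.null(rootPrior)) rootPrior <- model@frequencies
  po <- .postorder(tree)
  tips <- .tipStateMatrix(tree, m, model@alphabet)
  es <- .modelEigen(model)
  len <- po$length * model@rate
  grid <- sort(as.numeric(rateGrid))
  ll <- cpp_loglik_grid(po$edge, .nNodes(tree), es$U, es$lam, es$sqrtpi,
                        len, grid, tips, rootPrior)
  best <- max.col(ll, ties.method = "first")
  nNodes <- .nNodes(tree)
  nSite <- ncol(m)
  mapIdx <- matrix(0L, nNodes, nSite)
  mapP <- matrix(0, nNodes, nSite)
  for (r in unique(best)) {
    cols <- which(best == r)
    P <- cpp_pmats(es$U, es$lam, es$sqrtpi, len * grid[r])
    res <- cpp_marginal(po$edge, nNodes, P,
                        tips[, cols, drop = FALSE], rootPrior)
    mapIdx[, cols] <- res$map
    mapP[, cols] <- res$mapProb
  }
  labels <- .nodeLabels(tree)
  mapChar <- matrix(model@alphabet[mapIdx + 1L], nNodes, nSite,
                    dimnames = list(labels, NULL))
  # events: every branch whose parent and child MAP states differ
  e <- tree$edge
  diffs <- mapChar[e[, 1], , drop = FALSE] != mapChar[e[, 2], , drop = FALSE]
  hit <- which(diffs, arr.ind = TRUE)
  events <- data.frame(
    site = as.integer(hit[, 2]),
    branch = labels[e[hit[, 1], 2]],
    child = e[hit[, 1], 2],
    from = mapChar[cbind(e[hit[, 1], 1], hit[, 2])],
    to = mapChar[cbind(e[hit[, 1], 2], hit[, 2])],
    stringsAsFactors = FALSE)
  events <- events[order(events$site, events$child), , drop = FALSE]
  rownames(events) <- NULL
  new("AncestralAlignment", map = mapChar, mapProb = mapP,
      siteRates = grid[best], events = events, nodeLabels = labels,
      alphabet = model@alphabet)
}
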