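# Independent oracles used across the suite.  These deliberately avoid the
# package's computational paths: likelihoods come from joint enumeration
# over internal-node assignments with Matrix::expm() transition matrices,
# scores from explicit per-branch set logic, and Fisher p-values from
# direct hypergeometric enumeration.

# Joint enumeration over all internal-node state assignments (feasible for
# <= 5 tips and <= 4 symbols).
oracleEnumeration <- function(tree, tipStates, Q, rootPrior, alphabet) {
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    as.matrix(Matrix::expm(Q * tree$edge.length[e])))
  nTip <- length(tree$tip.label)
  nN <- nTip + tree$Nnode
  internals <- (nTip + 1):nN
  s <- length(alphabet)
  tipIdx <- match(tipStates[tree$tip.label], alphabet)
  grid <- as.matrix(expand.grid(rep(list(seq_len(s)), length(internals))))
  tot <- 0
  marg <- matrix(0, nN, s)
  for (g in seq_len(nrow(grid))) {
    asg <- integer(nN)
    asg[seq_len(nTip)] <- tipIdx
    asg[internals] <- grid[g, ]
    lik <- rootPrior[asg[nTip + 1]]
    for (e in seq_len(nrow(tree$edge)))
      lik <- lik * P[[e]][asg[tree$edge[e, 1]], asg[tree$edge[e, 2]]]
    tot <- tot + lik
    marg[cbind(seq_len(nN), asg)] <- marg[cbind(seq_len(nN), asg)] + lik
  }
  list(logLik = log(tot), marginals = marg / tot)
}

# Enumeration likelihood for branch-class (foreground/background) models.
oracleEnumerationMixed <- function(tree, tipStates, Qfg, Qbg, isFg,
                                   rootPrior, alphabet) {
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    as.matrix(Matrix::expm((if (isFg[e]) Qfg else Qbg) *
                             tree$edge.length[e])))
  nTip <- length(tree$tip.label)
  nN <- nTip + tree$Nnode
  internals <- (nTip + 1):nN
  s <- length(alphabet)
  tipIdx <- match(tipStates[tree$tip.label], alphabet)
  grid <- as.matrix(expand.grid(rep(list(seq_len(s)), length(internals))))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    asg <- integer(nN)
    asg[seq_len(nTip)] <- tipIdx
    asg[internals] <- grid[g, ]
    lik <- rootPrior[asg[nTip + 1]]
    for (e in seq_len(nrow(tree$edge)))
      lik <- lik * P[[e]][asg[tree$edge[e, 1]], asg[tree$edge[e, 2]]]
    tot <- tot + lik
  }
  log(tot)
}

# Random reversible model over `alphabet`.
randomModel <- function(alphabet) {
  s <- length(alphabet)
  E <- matrix(0, s, s)
  E[lower.tri(E)] <- runif(s * (s - 1) / 2, 0.2, 2)
  E <- E + t(E)
  f <- rgamma(s, 2)
  substitutionModel(alphabet, E, f / sum(f))
}

# Brute-force simultaneous scores by explicit branch loops.
bruteScores <- function(branches, phenoEvents, aaEvents, fgAA) {
  gains <- phenoEvents$child[phenoEvents$from == "0"]
  losses <- phenoEvents$child[phenoEvents$from == "1"]
  conv <- 0L; gwas <- 0L; all3 <- 0L
  for (b in branches) {
    aa <- aaEvents[aaEvents$child == b, , drop = FALSE]
    if (nrow(aa) == 0) next
    if (b %in% gains && any(aa$to == fgAA)) conv <- conv + 1L
    if ((b %in% gains && any(aa$to == fgAA)) ||
        (b %in% losses && any(aa$from == fgAA))) gwas <- gwas + 1L
    if (b %in% c(gains, losses)) all3 <- all3 + 1L
  }
  c(convergence = conv, gwas = gwas, allchanges = all3)
}

# Independent reimplementation of the null-site sampler in plain R (used
# for the distribution cross-check; different code path from the C++ one).
nullSimulatorR <- function(tree, phenoEvents, dist, nSites) {
  bl <- tree$edge.length
  child <- tree$edge[, 2]
  alpha <- aaAlphabet()
  gains <- phenoEvents$child[phenoEvents$from == "0"]
  losses <- phenoEvents$child[phenoEvents$from == "1"]
  vapply(seq_len(nSites), function(i) {
    k <- dist$count[sample.int(nrow(dist), 1, prob = dist$freq)]
    k <- min(k, length(bl))
    if (k == 0) return(0L)
    idx <- sample(seq_along(bl), k, prob = bl)
    st <- sample(20L, 1)
    tos <- integer(k)
    for (d in seq_len(k)) {
      st <- sample(setdiff(seq_len(20L), st), 1)
      tos[d] <- st
    }
    onGain <- child[idx] %in% gains
    if (!any(onGain)) return(0L)
    max(tabulate(tos[onGain], nbins = 20L))
  }, integer(1))
}

ksDistance <- function(x, y) {
  v <- sort(unique(c(x, y)))
  max(abs(ecdf(x)(v) - ecdf(y)(v)))
}

# Two-sided Fisher exact p by hypergeometric enumeration (n <= 40).
fisherOracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  x <- tab[1, 1]
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  pObs <- dhyper(x, m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}
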