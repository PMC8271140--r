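#' @include AllClasses.R
NULL

#' Construct a profile library
#'
#' @param profiles numeric matrix, alphabet x profiles, columns summing
#'   to 1; rownames give the alphabet.
#' @param weights optional prior weights (default uniform).
#' @return a [ProfileLibrary-class].
#' @export
profileLibrary <- function(profiles, weights = NULL) {
  if (is.null(rownames(profiles)))
    stop("profile matrix must have the alphabet as rownames")
  if (is.null(weights)) weights <- rep(1 / ncol(profiles), ncol(profiles))
  if (is.null(colnames(profiles)))
    colnames(profiles) <- paste0("P", seq_len(ncol(profiles)))
  new("ProfileLibrary", profiles = profiles, weights = weights,
      alphabet = rownames(profiles))
}

#' Default library of ten amino acid propensity profiles
#'
#' Ten fixed, data-independent profiles in the spirit of the CAT C10
#' categories: each concentrates most of its mass (0.95) uniformly on one
#' group of biochemically similar amino acids and spreads the remainder over
#' the other residues, so no amino acid ever has zero propensity.  Groups:
#' \{A,S,T\}, \{C\}, \{D,E\}, \{N,Q\}, \{K,R\}, \{F,Y,W\}, \{H\}, \{I,V\},
#' \{L,M\}, \{G,P\}.
#'
#' @return a [ProfileLibrary-class] with uniform prior weights.
#' @export
defaultProfileLibrary <- function() {
  groups <- list(AST = c("A", "S", "T"), C = "C", DE = c("D", "E"),
                 NQ = c("N", "Q"), KR = c("K", "R"),
                 FYW = c("F", "Y", "W"), H = "H", IV = c("I", "V"),
                 LM = c("L", "M"), GP = c("G", "P"))
  alpha <- aaAlphabet()
  P <- vapply(groups, function(g) {
    p <- rep(0.05 / (20 - length(g)), 20)
    p[match(g, alpha)] <- 0.95 / length(g)
    p
  }, numeric(20))
  rownames(P) <- alpha
  profileLibrary(P)
}

#' Partition branches into foreground and background by phenotype state
#'
#' A branch is foreground when the MAP phenotype of its *child* node is 1;
#' branches on which the phenotype changes are therefore assigned by the
#' state reconstructed below the change.
#'
#' @param tree rooted `phylo`.
#' @param phenoStateMap [CharacterStateMap-class] of the phenotype (states
#'   "0"/"1"), or a character vector ordered by ape node id.
#' @return list with `foreground` and `background` (disjoint child-node id
#'   vectors whose union covers all branches) and `isForeground`, a logical
#'   vector aligned with `tree$edge` rows.
#' @export
partitionBranches <- function(tree, phenoStateMap) {
  .checkTree(tree)
  labels <- .nodeLabels(tree)
  states <- if (is(phenoStateMap, "CharacterStateMap"))
    unname(mapStates(phenoStateMap)[labels]) else as.character(phenoStateMap)
  if (length(states) != .nNodes(tree))
    stop("phenotype states must cover all nodes")
  child <- tree$edge[, 2]
  isFg <- states[child] == "1"
  list(foreground = child[isFg], background = child[!isFg],
       isForeground = isFg)
}

# Transition cubes for a fg/bg profile pair on the postorder edges, plus
# tip data, shared by the likelihood functions below.
.profilePrep <- function(tree, siteStates, alphabet) {
  po <- .postorder(tree)
  tips <- .tipStateMatrix(tree, siteStates, alphabet)
  list(po = po, tips = tips)
}

.profileCube <- function(profile, alphabet, lengths, rate) {
  m <- poissonModel(setNames(as.numeric(profile), alphabet))
  .pmatCube(m, lengths * rate)
}

#' Site log-likelihood under branch-class amino acid profiles
#'
#' Pruning likelihood in which foreground branches use a reversible model
#' with stationary frequencies `fgProfile` and background branches
#' `bgProfile` (uniform exchangeabilities in both classes; only the
#' propensity profile changes).  The root prior is the background profile.
#' A profile with zero mass on an observed tip symbol would give zero
#' likelihood; the result is floored at `-1e10` and flagged by a warning.
#'
#' @param tree rooted `phylo`.
#' @param siteStates named character vector of tip symbols at the site.
#' @param partition branch partition from [partitionBranches()].
#' @param fgProfile,bgProfile propensity vectors (simplexes) named by state
#'   symbol, or unnamed over [aaAlphabet()].
#' @param rate positive site rate multiplier.
#' @return log-likelihood (scalar).
#' @export
siteProfileLikelihood <- function(tree, siteStates, partition, fgProfile,
                                  bgProfile, rate = 1) {
  .checkTree(tree)
  alphabet <- names(fgProfile)
  if (is.null(alphabet)) alphabet <- aaAlphabet()
  pp <- .profilePrep(tree, siteStates, alphabet)
  # postorder edge order must match the partition flags (tree$edge order)
  isFg <- partition$isForeground[match(pp$po$edge[, 2], tree$edge[, 2])]
  # a tip whose observed symbol has zero propensity in its branch-class
  # profile makes the likelihood exactly zero: floor and flag
  tipClassFg <- isFg[match(seq_len(nrow(pp$tips)), pp$po$edge[, 2])]
  obs <- pp$tips[, 1]
  fgv <- as.numeric(fgProfile)
  bgv <- as.numeric(bgProfile)
  seen <- which(obs >= 0)
  classProf <- ifelse(tipClassFg[seen], fgv[obs[seen] + 1L],
                      bgv[obs[seen] + 1L])
  if (any(classProf == 0)) {
    warning("zero-likelihood profile assignment; log-likelihood floored")
    return(-1e10)
  }
  Pfg <- .profileCube(fgProfile, alphabet, pp$po$length, rate)
  Pbg <- .profileCube(bgProfile, alphabet, pp$po$length, rate)
  bg <- as.numeric(bgProfile)
  ll <- as.numeric(cpp_prune_mixed(pp$po$edge, .nNodes(tree), Pbg, Pfg,
                                   as.integer(isFg), pp$tips,
                                   bg / sum(bg)))
  if (!is.finite(ll) || ll < -1e10) {
    warning("zero-likelihood profile assignment; log-likelihood floored")
    ll <- -1e10
  }
  ll
}

#' Posterior probability of a site-specific profile change
#'
#' Compares, in a Bayesian framework with equal prior odds, a "profile
#' change" model (foreground and background branch classes draw different
#' profiles from the library, uniform over ordered pairs) against a "no
#' change" model (one shared profile).  The site rate is first estimated by
#' maximum likelihood under the no-change model and then held fixed for
#' both models, so rate and profile differences are not confounded.
#'
#' @param tree rooted `phylo`.
#' @param siteStates named character vector of tip symbols at the site.
#' @param partition branch partition from [partitionBranches()]; at least
#'   one foreground and one background branch are required.
#' @param library a [ProfileLibrary-class] (default
#'   [defaultProfileLibrary()]).
#' @param rate `"ml"` (default) or a fixed positive rate multiplier.
#' @param rateInterval search interval for the ML rate.
#' @return one-row data.frame: `posterior` (P(profile change)), `bestFg`,
#'   `bestBg` (library column names of the best ordered pair), `rate`,
#'   `logLikChange`, `logLikNull`.
#' @export
profileChangePosterior <- function(tree, siteStates, partition,
                                   library = defaultProfileLibrary(),
                                   rate = "ml",
                                   rateInterval = c(0.01, 50)) {
  .checkTree(tree)
  if (length(partition$foreground) == 0)
    stop("empty foreground branch set")
  if (length(partition$background) == 0)
    stop("empty background branch set")
  prof <- profileMatrix(library)
  K <- ncol(prof)
  w <- library@weights
  alphabet <- library@alphabet
  pp <- .profilePrep(tree, siteStates, alphabet)
  isFg <- as.integer(
    partition$isForeground[match(pp$po$edge[, 2], tree$edge[, 2])])
  nNodes <- .nNodes(tree)

  cubes <- function(r) lapply(seq_len(K), function(k)
    .profileCube(prof[, k], alphabet, pp$po$length, r))
  sharedLL <- function(cu, k)
    as.numeric(cpp_prune(pp$po$edge, nNodes, cu[[k]], pp$tips,
                         prof[, k]))
  nullMarginal <- function(r) {
    cu <- cubes(r)
    .logSumExp(log(w) + vapply(seq_len(K), function(k) sharedLL(cu, k),
                               numeric(1)))
  }
  r <- if (identical(rate, "ml")) {
    exp(optimize(function(lr) -nullMarginal(exp(lr)),
                 log(rateInterval), tol = 0.05)$minimum)
  } else as.numeric(rate)

  cu <- cubes(r)
  llShared <- vapply(seq_len(K), function(k) sharedLL(cu, k), numeric(1))
  logLikNull <- .logSumExp(log(w) + llShared)
  if (K < 2) {
    return(data.frame(posterior = 0, bestFg = NA_character_,
                      bestBg = NA_character_, rate = r,
                      logLikChange = -Inf, logLikNull = logLikNull))
  }
  pairs <- expand.grid(fg = seq_len(K), bg = seq_len(K))
  pairs <- pairs[pairs$fg != pairs$bg, ]
  llPair <- mapply(function(f, b) {
    as.numeric(cpp_prune_mixed(pp$po$edge, nNodes, cu[[b]], cu[[f]],
                               isFg, pp$tips, prof[, b]))
  }, pairs$fg, pairs$bg)
  wPair <- w[pairs$fg] * w[pairs$bg]
  wPair <- wPair / sum(wPair)
  logLikChange <- .logSumExp(log(wPair) + llPair)
  posterior <- 1 / (1 + exp(logLikNull - logLikChange))
  best <- which.max(llPair)
  data.frame(posterior = posterior,
             bestFg = colnames(prof)[pairs$fg[best]],
             bestBg = colnames(prof)[pairs$bg[best]],
             rate = r, logLikChange = logLikChange,
             logLikNull = logLikNull)
}

#' Profile-change posteriors for alignment sites
#'
#' Applies [profileChangePosterior()] site by site.
#'
#' @param tree rooted `phylo`.
#' @param aln gap-free [AAAlignment-class].
#' @param partition branch partition from [partitionBranches()].
#' @param library a [ProfileLibrary-class].
#' @param sites site indices to analyse (default all).
#' @param gene optional gene label.
#' @return data.frame with `gene`, `site`, `column`, `posterior`, `bestFg`,
#'   `bestBg`, `rate`.
#' @export
profileChangeAlignment <- function(tree, aln, partition,
                                   library = defaultProfileLibrary(),
                                   sites = NULL, gene = NA_character_) {
  stopifnot(is(aln, "AAAlignment"))
  m <- alignmentMatrix(aln)
  if (is.null(sites)) sites <- seq_len(ncol(m))
  rows <- lapply(sites, function(j) {
    r <- profileChangePosterior(tree, setNames(m[, j], rownames(m)),
                                partition, library)
    cbind(data.frame(gene = gene, site = j,
                     column = retainedColumns(aln)[j]), r)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Quadrant Fisher cross-test of simultaneous score vs profile change
#'
#' Dichotomises paired per-site simultaneous scores and profile-change
#' posteriors (defaults: posterior cut at 0.5, the middle of its scale;
#' score cut at the rounded-up mid-range of the observed scores) and tests
#' independence of the resulting 2x2 table with a two-sided Fisher exact
#' test.  A degenerate table (an empty margin) yields p = 1 with a warning.
#'
#' @param simScores integer per-site simultaneous scores.
#' @param pcScores per-site profile-change posteriors in `[0,1]`.
#' @param simCutoff integer cutoff; scores `>= simCutoff` are "high".
#'   Default `ceiling(max(simScores)/2)`.
#' @param pcCutoff posteriors `> pcCutoff` are "high".
#' @return list with `table` (2x2 contingency), `pValue`, `simCutoff`,
#'   `pcCutoff`.
#' @export
quadrantFisher <- function(simScores, pcScores, simCutoff = NULL,
                           pcCutoff = 0.5) {
  if (length(simScores) != length(pcScores))
    stop("score vectors must have equal length")
  if (is.null(simCutoff)) simCutoff <- ceiling(max(simScores) / 2)
  simHigh <- factor(simScores >= simCutoff, levels = c(FALSE, TRUE))
  pcHigh <- factor(pcScores > pcCutoff, levels = c(FALSE, TRUE))
  tab <- table(sim = simHigh, pc = pcHigh)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate contingency table; p-value set to 1")
    p <- 1
  } else {
    p <- fisher.test(tab)$p.value
  }
  list(table = tab, pValue = p, simCutoff = simCutoff, pcCutoff = pcCutoff)
}
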