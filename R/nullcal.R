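#' @include AllClasses.R
NULL

#' Empirical distribution of substitutions per site
#'
#' Histogram of per-site branch-event counts over all analysed sites
#' (zero-event sites included), used to condition the null simulation.
#'
#' @param x an [AncestralAlignment-class], or an integer vector of per-site
#'   event counts.
#' @return data.frame with columns `count` and `freq` (frequencies sum
#'   to 1).
#' @export
empiricalSubstDistribution <- function(x) {
  counts <- if (is(x, "AncestralAlignment")) {
    tabulate(branchEvents(x)$site, nbins = ncol(x@map))
  } else {
    as.integer(x)
  }
  if (length(counts) < 1) stop("at least one site is required")
  tab <- table(counts)
  data.frame(count = as.integer(names(tab)),
             freq = as.numeric(tab) / length(counts))
}

#' Simulate null sites and their simultaneous scores
#'
#' For each null site a substitution count is drawn from the empirical
#' distribution; that many events are placed on distinct branches with
#' probability proportional to branch length, event states follow a random
#' walk over a uniform 20-symbol alphabet, and the site's best simultaneous
#' score against the *fixed* empirical phenotype events is recorded (the
#' phenotype is never re-simulated).  The maximisation over candidate
#' foreground amino acids matches [siteBestScore()] exactly.
#'
#' @param tree rooted `phylo` (the empirical tree).
#' @param phenoEvents empirical phenotype branch events.
#' @param dist substitutions-per-site distribution
#'   ([empiricalSubstDistribution()]).
#' @param nSites number of null sites to simulate.
#' @param approach one of [approachKinds()].
#' @param seed optional integer seed (`set.seed`) for bit-reproducibility.
#' @param nAA alphabet size of the random walk.
#' @return a [NullScoreDistribution-class].
#' @export
simulateNullSites <- function(tree, phenoEvents, dist, nSites,
                              approach = c("convergence", "gwas",
                                           "allchanges"),
                              seed = NULL, nAA = 20L) {
  approach <- match.arg(approach)
  m <- .nullScoreMatrix(tree, phenoEvents, dist, nSites, seed = seed,
                        nAA = nAA)
  new("NullScoreDistribution", approach = approach,
      scores = m[, match(approach, approachKinds())],
      nBranches = nrow(tree$edge),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

# Shared placement sampler: returns an integer matrix nSites x 3 with the
# best scores of every approach on identical null placements.
.nullScoreMatrix <- function(tree, phenoEvents, dist, nSites, seed = NULL,
                             nAA = 20L) {
  .checkTree(tree)
  if (!is.data.frame(dist) || nrow(dist) == 0 || sum(dist$freq) <= 0)
    stop("empty substitutions-per-site distribution")
  if (nSites < 1) stop("nSites must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  e <- tree$edge
  ps <- .phenoSets(phenoEvents)
  gain <- as.integer(e[, 2] %in% ps$gain)
  loss <- as.integer(e[, 2] %in% ps$loss)
  k <- dist$count[sample.int(nrow(dist), nSites, replace = TRUE,
                             prob = dist$freq)]
  m <- cpp_null_scores(tree$edge.length, gain, loss, as.integer(k),
                       as.integer(nAA))
  colnames(m) <- approachKinds()
  m
}

#' Significance threshold from a null score distribution
#'
#' The threshold is the smallest integer score `s` whose null tail
#' probability `P(score >= s)` does not exceed the Bonferroni-corrected
#' level: `alpha / nSites` (correction 1) or `alpha / (nSites * nTests)`
#' (correction 2, `nTests = 3` for the three approaches).  If the corrected
#' level is below the Monte-Carlo resolution (`1/replicates`) a warning is
#' issued; a threshold beyond the observed support (max score + 1) is
#' flagged as resolution-limited.
#'
#' @param null a [NullScoreDistribution-class].
#' @param alpha nominal familywise level in (0, 1).
#' @param nSites number of tested sites (Bonferroni denominator).
#' @param nTests number of test types for correction 2.
#' @param correction `"correction1"` or `"correction2"`.
#' @return one-row data.frame: `approach`, `alpha`, `correction`,
#'   `correctedAlpha`, `threshold`, `resolutionLimited`.
#' @export
significanceThreshold <- function(null, alpha = 0.05, nSites,
                                  nTests = 3L,
                                  correction = c("correction1",
                                                 "correction2")) {
  stopifnot(is(null, "NullScoreDistribution"))
  correction <- match.arg(correction)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  corrected <- alpha / nSites / (if (correction == "correction2") nTests else 1)
  sc <- nullScores(null)
  n <- length(sc)
  if (corrected < 1 / n)
    warning("corrected level ", signif(corrected, 3),
            " is below the Monte-Carlo resolution 1/", n)
  maxObs <- max(sc)
  tabs <- rev(cumsum(rev(tabulate(sc + 1L, nbins = maxObs + 1L)))) / n
  ok <- which(tabs <= corrected)   # tail P(score >= s) for s = 0..maxObs
  threshold <- if (length(ok)) min(ok) - 1L else maxObs + 1L
  data.frame(approach = null@approach, alpha = alpha,
             correction = correction, correctedAlpha = corrected,
             threshold = as.integer(threshold),
             resolutionLimited = threshold > maxObs)
}

#' Annotate site scores with significance flags
#'
#' Flags each site score under both Bonferroni corrections: a record is
#' significant when its score reaches the threshold of its approach.
#'
#' @param scores per-site score table ([scoreAlignment()]).
#' @param thresholds data.frame of thresholds (rows from
#'   [significanceThreshold()], both corrections per approach).
#' @return `scores` with logical columns `significantCorrection1` and
#'   `significantCorrection2` (NA when no threshold for the approach).
#' @export
classifySites <- function(scores, thresholds) {
  if (nrow(scores) == 0) {
    scores$significantCorrection1 <- logical(0)
    scores$significantCorrection2 <- logical(0)
    return(scores)
  }
  thr <- function(ap, corr) {
    row <- thresholds$approach == ap & thresholds$correction == corr
    if (!any(row)) return(NA_integer_)
    thresholds$threshold[row][1]
  }
  t1 <- vapply(scores$approach, thr, integer(1), corr = "correction1")
  t2 <- vapply(scores$approach, thr, integer(1), corr = "correction2")
  scores$significantCorrection1 <- scores$score >= t1
  scores$significantCorrection2 <- scores$score >= t2
  scores
}

#' Write a null score distribution to TSV
#'
#' @param null a [NullScoreDistribution-class].
#' @param path output path; two columns, `score` and `count`.
#' @return `path`, invisibly.
#' @export
writeNullDistribution <- function(null, path) {
  stopifnot(is(null, "NullScoreDistribution"))
  tab <- table(nullScores(null))
  write.table(data.frame(score = as.integer(names(tab)),
                         count = as.integer(tab)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
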