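#' @include AllClasses.R
NULL

#' Run the simultaneous test end to end
#'
#' Reconstructs the phenotype history and per-site amino acid ancestral
#' states, scores every site under the requested approaches, calibrates the
#' null score distribution (null sites share event placements across
#' approaches), derives significance thresholds under both Bonferroni
#' corrections, and flags significant sites.
#'
#' @param tree rooted `phylo` whose tips match the alignment.
#' @param aln an [AAAlignment-class]; gap columns are removed if present.
#' @param phenotypes named 0/1 tip phenotype vector
#'   (see [readPhenotypes()]).
#' @param model substitution model (default LG with observed frequencies).
#' @param approaches subset of [approachKinds()].
#' @param alpha nominal familywise significance level.
#' @param nullReplicates number of simulated null sites.
#' @param nTests Bonferroni denominator factor of correction 2.
#' @param rateGrid per-site rate grid, see [ancestralAlignment()].
#' @param seed optional integer seed (makes the null calibration
#'   bit-reproducible).
#' @param gene optional gene label carried into the score table.
#' @return list with `scores` (annotated per-site table), `thresholds`,
#'   `nulls` (per-approach [NullScoreDistribution-class]), `phenoEvents`,
#'   `phenotype` (reconstruction), `ancestral`, `dist`
#'   (substitutions-per-site distribution) and `nSites`.
#' @export
runSimultaneousTest <- function(tree, aln, phenotypes, model = NULL,
                                approaches = approachKinds(),
                                alpha = 0.05, nullReplicates = 1e5,
                                nTests = 3L,
                                rateGrid = 2^seq(-3, 3, length.out = 7),
                                seed = NULL, gene = NA_character_) {
  .checkTree(tree)
  stopifnot(is(aln, "AAAlignment"))
  approaches <- match.arg(approaches, approachKinds(), several.ok = TRUE)
  if (any(alignmentMatrix(aln) == "-")) {
    message("removing gap columns before analysis")
    aln <- dropGapColumns(aln)
  }
  ph <- reconstructPhenotype(tree, phenotypes)
  anc <- ancestralAlignment(tree, aln, model = model, rateGrid = rateGrid)
  scores <- scoreAlignment(anc, ph$events, approaches = approaches,
                           retained = retainedColumns(aln), gene = gene)
  dist <- empiricalSubstDistribution(anc)
  nullMat <- .nullScoreMatrix(tree, ph$events, dist, nullReplicates,
                              seed = seed)
  nb <- nrow(tree$edge)
  nulls <- lapply(approaches, function(ap)
    new("NullScoreDistribution", approach = ap,
        scores = nullMat[, ap], nBranches = nb,
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed)))
  names(nulls) <- approaches
  nSite <- nSites(aln)
  thresholds <- do.call(rbind, unlist(lapply(approaches, function(ap)
    lapply(c("correction1", "correction2"), function(corr)
      significanceThreshold(nulls[[ap]], alpha = alpha, nSites = nSite,
                            nTests = nTests, correction = corr))),
    recursive = FALSE))
  scores <- classifySites(scores, thresholds)
  list(scores = scores, thresholds = thresholds, nulls = nulls,
       phenoEvents = ph$events, phenotype = ph, ancestral = anc,
       dist = dist, nSites = nSite)
}

#' Write a per-site score table to TSV
#'
#' @param scores annotated score table from [runSimultaneousTest()] or
#'   [classifySites()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeScoreTable <- function(scores, path) {
  write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
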