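#' @include AllClasses.R
NULL

#' The canonical amino acid alphabet
#'
#' Twenty standard amino acids in alphabetical one-letter order.  This
#' ordering defines the deterministic tie-break used for MAP states and
#' foreground amino acid selection (lowest index wins).
#'
#' @return character vector of length 20.
#' @export
#' @examples
#' aaAlphabet()
aaAlphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' The three simultaneous-score approaches
#'
#' @return character vector `c("convergence", "gwas", "allchanges")`.
#' @export
approachKinds <- function() c("convergence", "gwas", "allchanges")

#' @describeIn AAAlignment-class underlying character matrix.
#' @param x,object an `AAAlignment`.
#' @export
alignmentMatrix <- function(x) {
  stopifnot(is(x, "AAAlignment"))
  x@matrix
}

#' @describeIn AAAlignment-class map from current to original 1-based columns.
#' @export
retainedColumns <- function(x) {
  stopifnot(is(x, "AAAlignment"))
  x@retained
}

#' @describeIn AAAlignment-class number of sequences / sites.
#' @export
nSequences <- function(x) nrow(alignmentMatrix(x))

#' @describeIn AAAlignment-class number of alignment columns.
#' @export
nSites <- function(x) ncol(alignmentMatrix(x))

setMethod("show", "AAAlignment", function(object) {
  cat("AAAlignment:", nrow(object@matrix), "sequences x",
      ncol(object@matrix), "sites")
  if (ncol(object@matrix) < object@originalWidth)
    cat(" (filtered from", object@originalWidth, "original columns)")
  cat("\n")
})

#' @describeIn SubstitutionModel-class assembled rate matrix (rows sum to 0).
#' @export
rateMatrix <- function(x) {
  stopifnot(is(x, "SubstitutionModel"))
  .assembleQ(x@exchangeabilities, x@frequencies, x@normalized)
}

#' @describeIn SubstitutionModel-class stationary frequencies.
#' @export
stationaryFrequencies <- function(x) {
  stopifnot(is(x, "SubstitutionModel"))
  setNames(x@frequencies, x@alphabet)
}

#' @describeIn SubstitutionModel-class state alphabet.
#' @export
modelAlphabet <- function(x) {
  stopifnot(is(x, "SubstitutionModel"))
  x@alphabet
}

setMethod("show", "SubstitutionModel", function(object) {
  cat("SubstitutionModel:", length(object@alphabet), "states, rate",
      format(object@rate, digits = 4),
      if (object@normalized) "(mean-rate normalised)" else "", "\n")
})

#' @describeIn CharacterStateMap-class MAP state per node (named by label).
#' @export
mapStates <- function(x) {
  stopifnot(is(x, "CharacterStateMap"))
  x@states
}

#' @describeIn CharacterStateMap-class marginal posterior matrix (nodes x states).
#' @export
posteriorMatrix <- function(x) {
  stopifnot(is(x, "CharacterStateMap"))
  x@posterior
}

setMethod("show", "CharacterStateMap", function(object) {
  cat("CharacterStateMap:", length(object@states), "nodes over alphabet {",
      paste(head(object@alphabet, 5), collapse = ","),
      if (length(object@alphabet) > 5) ",..." else "", "}",
      if (object@ties > 0) paste0("; ", object@ties, " MAP tie(s)") else "",
      "\n")
})

#' @describeIn AncestralAlignment-class MAP state matrix (nodes x sites).
#' @export
mapMatrix <- function(x) {
  stopifnot(is(x, "AncestralAlignment"))
  x@map
}

#' @describeIn AncestralAlignment-class branch events implied by MAP states.
#' @export
branchEvents <- function(x) {
  stopifnot(is(x, "AncestralAlignment"))
  x@events
}

#' @describeIn AncestralAlignment-class per-site ML rate multipliers.
#' @export
siteRates <- function(x) {
  stopifnot(is(x, "AncestralAlignment"))
  x@siteRates
}

setMethod("show", "AncestralAlignment", function(object) {
  cat("AncestralAlignment:", nrow(object@map), "nodes x", ncol(object@map),
      "sites;", nrow(object@events), "branch events\n")
})

#' @describeIn NullScoreDistribution-class sampled null scores.
#' @export
nullScores <- function(x) {
  stopifnot(is(x, "NullScoreDistribution"))
  x@scores
}

setMethod("show", "NullScoreDistribution", function(object) {
  cat("NullScoreDistribution (", object@approach, "): ",
      length(object@scores), " null sites, max score ",
      max(object@scores), "\n", sep = "")
})

#' @describeIn ProfileLibrary-class profile matrix (alphabet x profiles).
#' @export
profileMatrix <- function(x) {
  stopifnot(is(x, "ProfileLibrary"))
  x@profiles
}

#' @describeIn ProfileLibrary-class number of profiles.
#' @export
nProfiles <- function(x) ncol(profileMatrix(x))

setMethod("show", "ProfileLibrary", function(object) {
  cat("ProfileLibrary:", ncol(object@profiles), "profiles over",
      length(object@alphabet), "states\n")
})

setMethod("show", "SimulatedDataset", function(object) {
  cat("SimulatedDataset:", length(object@tree$tip.label), "tips,",
      ncol(object@siteStates), "sites,",
      sum(object@phenoEvents$from == "0" & object@phenoEvents$to == "1"),
      "phenotype origin(s),", length(object@ledger), "planted site(s)\n")
})

#' @describeIn SimulatedDataset-class simulated tip alignment.
#' @param x,object a `SimulatedDataset`.
#' @export
datasetAlignment <- function(x) {
  stopifnot(is(x, "SimulatedDataset"))
  x@alignment
}

#' @describeIn SimulatedDataset-class simulated tree (`phylo`).
#' @export
datasetTree <- function(x) {
  stopifnot(is(x, "SimulatedDataset"))
  x@tree
}

#' @describeIn SimulatedDataset-class named tip phenotype vector.
#' @export
datasetPhenotypes <- function(x) {
  stopifnot(is(x, "SimulatedDataset"))
  x@tipPhenotypes
}

#' @describeIn SimulatedDataset-class ledger of planted sites.
#' @export
plantedLedger <- function(x) {
  stopifnot(is(x, "SimulatedDataset"))
  x@ledger
}
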