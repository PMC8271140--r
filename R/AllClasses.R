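#' @include phyloConv-package.R
NULL

#' Amino acid alignment with original-column bookkeeping
#'
#' A character matrix of aligned amino acid symbols (rows = sequences,
#' columns = sites) over the 20-letter alphabet plus gap `-` and unknown
#' `X`, together with the map from current columns back to the 1-based
#' columns of the alignment as read from file.  [dropGapColumns()] updates
#' the map so downstream reports can cite original coordinates.
#'
#' @slot matrix character matrix of single-letter symbols; rownames are the
#'   (unique) sequence identifiers.
#' @slot retained integer vector, one per current column, giving the 1-based
#'   original column index; strictly increasing.
#' @slot originalWidth integer, number of columns before any filtering.
#' @exportClass AAAlignment
setClass("AAAlignment",
  representation(matrix = "matrix", retained = "integer",
                 originalWidth = "integer"))

setValidity("AAAlignment", function(object) {
  m <- object@matrix
  if (!is.character(m)) return("alignment matrix must be character")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    return("sequence identifiers must be present and unique")
  if (length(object@retained) != ncol(m))
    return("retained-column map length must equal the number of columns")
  if (ncol(m) > 0 && (any(diff(object@retained) <= 0) ||
                      any(object@retained < 1) ||
                      any(object@retained > object@originalWidth)))
    return("retained-column map must be strictly increasing within the original width")
  bad <- setdiff(unique(as.vector(m)), c(aaAlphabet(), "-", "X"))
  if (length(bad))
    return(paste0("invalid symbols in alignment: ",
                  paste(bad, collapse = ", ")))
  TRUE
})

#' Time-reversible substitution model
#'
#' A continuous-time reversible Markov model assembled from symmetric
#' exchangeabilities and stationary frequencies, \eqn{Q_{ij} = s_{ij}\pi_j}.
#' The rate matrix may be normalised so that the expected number of
#' substitutions per unit branch length equals the `rate` slot.
#'
#' @slot alphabet ordered character vector of state symbols.
#' @slot exchangeabilities symmetric nonnegative matrix (diagonal ignored).
#' @slot frequencies stationary frequencies, strictly positive, sum to 1.
#' @slot rate positive overall rate multiplier applied to branch lengths.
#' @slot normalized logical; whether Q was scaled to mean rate 1.
#' @exportClass SubstitutionModel
setClass("SubstitutionModel",
  representation(alphabet = "character", exchangeabilities = "matrix",
                 frequencies = "numeric", rate = "numeric",
                 normalized = "logical"))

setValidity("SubstitutionModel", function(object) {
  s <- length(object@alphabet)
  if (s < 2) return("alphabet needs at least two symbols")
  if (anyDuplicated(object@alphabet)) return("alphabet symbols must be unique")
  E <- object@exchangeabilities
  if (!all(dim(E) == c(s, s))) return("exchangeability matrix dimension mismatch")
  if (any(E < 0)) return("exchangeabilities must be nonnegative")
  if (max(abs(E - t(E))) > 1e-9) return("exchangeabilities must be symmetric")
  f <- object@frequencies
  if (length(f) != s) return("frequency vector length mismatch")
  if (any(f <= 0)) return("stationary frequencies must be strictly positive")
  if (abs(sum(f) - 1) > 1e-12) return("stationary frequencies must sum to 1")
  if (length(object@rate) != 1 || object@rate <= 0)
    return("rate must be a positive scalar")
  TRUE
})

#' Per-node state map from marginal ancestral reconstruction
#'
#' Maximum a posteriori (MAP) state and full marginal posterior for every
#' node of the tree (tips included).  The MAP state is the first argmax of
#' the posterior, i.e. ties are broken towards the lowest alphabet index.
#'
#' @slot states named character vector of MAP states, one per node, named by
#'   node label.
#' @slot posterior numeric matrix, nodes x alphabet, rows sum to 1.
#' @slot alphabet ordered state alphabet.
#' @slot ties integer, number of nodes whose MAP state was a tie within
#'   `1e-12` posterior mass.
#' @exportClass CharacterStateMap
setClass("CharacterStateMap",
  representation(states = "character", posterior = "matrix",
                 alphabet = "character", ties = "integer"))

setValidity("CharacterStateMap", function(object) {
  P <- object@posterior
  if (nrow(P) != length(object@states)) return("states/posterior mismatch")
  if (ncol(P) != length(object@alphabet)) return("posterior/alphabet mismatch")
  if (any(abs(rowSums(P) - 1) > 1e-9)) return("posterior rows must sum to 1")
  if (!all(object@states %in% object@alphabet))
    return("MAP states must lie in the alphabet")
  TRUE
})

#' Batched ancestral reconstruction of an alignment
#'
#' MAP states and their posteriors for all sites at once, plus the per-site
#' rate multipliers selected by maximum likelihood and the branch events
#' implied by the MAP assignment.
#'
#' @slot map character matrix, nodes x sites, MAP state per node and site.
#' @slot mapProb numeric matrix of the MAP states' posterior probabilities.
#' @slot siteRates numeric vector of per-site ML rate multipliers.
#' @slot events data.frame with columns `site`, `branch` (child node label),
#'   `child` (child node id), `from`, `to`.
#' @slot nodeLabels character vector of node labels (tips then internals).
#' @slot alphabet ordered state alphabet.
#' @exportClass AncestralAlignment
setClass("AncestralAlignment",
  representation(map = "matrix", mapProb = "matrix", siteRates = "numeric",
                 events = "data.frame", nodeLabels = "character",
                 alphabet = "character"))

#' Null distribution of the simultaneous score
#'
#' Maximum-per-site simultaneous scores of simulated null sites, used to set
#' significance thresholds.
#'
#' @slot approach one of `"convergence"`, `"gwas"`, `"allchanges"`.
#' @slot scores integer vector of null site scores.
#' @slot nBranches integer, number of branches of the calibrating tree.
#' @slot seed integer seed used for the simulation (NA if inherited RNG).
#' @exportClass NullScoreDistribution
setClass("NullScoreDistribution",
  representation(approach = "character", scores = "integer",
                 nBranches = "integer", seed = "integer"))

setValidity("NullScoreDistribution", function(object) {
  if (!object@approach %in% approachKinds()) return("unknown approach")
  if (length(object@scores) < 1) return("empty null distribution")
  if (any(object@scores < 0) || any(object@scores > object@nBranches))
    return("null scores must lie in [0, number of branches]")
  TRUE
})

#' Library of amino acid propensity profiles
#'
#' A finite set of propensity profiles (columns, each a simplex over the
#' alphabet) with prior weights, playing the role of CAT-style profile
#' categories in the profile-change posterior.
#'
#' @slot profiles numeric matrix, alphabet x profiles; columns sum to 1.
#' @slot weights prior weights over profiles, sum to 1.
#' @slot alphabet ordered state alphabet (rownames of `profiles`).
#' @exportClass ProfileLibrary
setClass("ProfileLibrary",
  representation(profiles = "matrix", weights = "numeric",
                 alphabet = "character"))

setValidity("ProfileLibrary", function(object) {
  P <- object@profiles
  if (nrow(P) != length(object@alphabet)) return("profile/alphabet mismatch")
  if (ncol(P) < 1) return("library must contain at least one profile")
  if (any(P < 0)) return("profile entries must be nonnegative")
  if (any(abs(colSums(P) - 1) > 1e-9)) return("profiles must sum to 1")
  if (length(object@weights) != ncol(P) ||
      abs(sum(object@weights) - 1) > 1e-9)
    return("weights must match the profiles and sum to 1")
  TRUE
})

#' Synthetic dataset with full ground truth
#'
#' A simulated tree, binary phenotype history, and alignment, with the true
#' node states and substitution events per site, plus a ledger of every
#' planted deviation from neutral simulation.
#'
#' @slot tree ape `phylo`, rooted with branch lengths.
#' @slot alignment [AAAlignment-class] of tip sequences.
#' @slot tipPhenotypes named integer vector of tip states in \{0,1\}.
#' @slot nodePhenotypes integer vector of true phenotype states per node.
#' @slot phenoEvents data.frame of true phenotype jumps (`branch`, `child`,
#'   `from`, `to`).
#' @slot siteStates character matrix, nodes x sites, true states.
#' @slot siteEvents data.frame of true substitution jumps (`site`, `branch`,
#'   `child`, `from`, `to`).
#' @slot siteRates numeric per-site rate (expected substitutions per unit
#'   branch length).
#' @slot ledger list describing planted sites.
#' @slot config list of generator settings.
#' @exportClass SimulatedDataset
setClass("SimulatedDataset",
  representation(tree = "ANY", alignment = "AAAlignment",
                 tipPhenotypes = "integer", nodePhenotypes = "integer",
                 phenoEvents = "data.frame", siteStates = "matrix",
                 siteEvents = "data.frame", siteRates = "numeric",
                 ledger = "list", config = "list"))
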