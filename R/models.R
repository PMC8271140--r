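#' @include AllClasses.R
NULL

# Assemble Q_ij = s_ij * pi_j, zero row sums; optionally scale so the mean
# rate (-sum_i pi_i Q_ii) is 1, making branch lengths expected substitutions.
.assembleQ <- function(E, freqs, normalize) {
  Q <- E * rep(freqs, each = length(freqs))
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  if (normalize) {
    mu <- -sum(freqs * diag(Q))
    if (mu <= 0) stop("degenerate rate matrix (zero mean rate)")
    Q <- Q / mu
  }
  Q
}

#' Construct a time-reversible substitution model
#'
#' Assembles \eqn{Q_{ij} = s_{ij}\pi_j} from symmetric exchangeabilities
#' `s` and stationary frequencies \eqn{\pi}; the resulting chain satisfies
#' detailed balance by construction.  With `normalize = TRUE` (default) Q is
#' scaled to one expected substitution per unit branch length, and `rate`
#' multiplies branch lengths.
#'
#' @param alphabet ordered character vector of state symbols.
#' @param exchangeabilities symmetric nonnegative matrix (diagonal ignored).
#' @param frequencies stationary frequencies (strictly positive, sum to 1).
#' @param rate positive overall rate multiplier.
#' @param normalize scale Q to mean rate 1?
#' @return a [SubstitutionModel-class].
#' @export
#' @examples
#' m <- substitutionModel(c("0", "1"), matrix(1, 2, 2), c(0.5, 0.5))
#' rateMatrix(m)
substitutionModel <- function(alphabet, exchangeabilities, frequencies,
                              rate = 1, normalize = TRUE) {
  frequencies <- as.numeric(frequencies)
  new("SubstitutionModel", alphabet = as.character(alphabet),
      exchangeabilities = exchangeabilities,
      frequencies = frequencies / sum(frequencies),
      rate = rate, normalized = normalize)
}

# LG exchangeabilities and frequencies fetched once through phangorn's
# exported pml() interface and re-ordered to the package's alphabetical
# amino acid alphabet.
.lgCache <- new.env(parent = emptyenv())

.lgData <- function() {
  if (!is.null(.lgCache$E)) return(list(E = .lgCache$E, bf = .lgCache$bf))
  ord <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  m <- matrix(c("A", "R", "A", "R"), 2, 2,
              dimnames = list(c("t1", "t2"), NULL))
  dat <- phangorn::phyDat(m, type = "AA")
  tr <- ape::read.tree(text = "(t1:1,t2:1);")
  fit <- phangorn::pml(tr, dat, model = "LG")
  E <- matrix(0, 20, 20, dimnames = list(ord, ord))
  E[lower.tri(E)] <- fit$Q
  E <- E + t(E)
  bf <- setNames(as.numeric(fit$bf), ord)
  perm <- match(aaAlphabet(), ord)
  .lgCache$E <- E[perm, perm]
  .lgCache$bf <- bf[perm]
  list(E = .lgCache$E, bf = .lgCache$bf)
}

#' LG amino acid model
#'
#' The LG empirical exchangeability matrix with either its published
#' stationary frequencies or user-supplied (e.g. alignment-observed, "+F")
#' frequencies.
#'
#' @param frequencies optional stationary frequencies named by amino acid;
#'   default LG frequencies.
#' @param rate overall rate multiplier.
#' @return a [SubstitutionModel-class] over [aaAlphabet()].
#' @export
lgModel <- function(frequencies = NULL, rate = 1) {
  lg <- .lgData()
  f <- if (is.null(frequencies)) lg$bf else {
    if (!is.null(names(frequencies))) frequencies <- frequencies[aaAlphabet()]
    as.numeric(frequencies)
  }
  substitutionModel(aaAlphabet(), lg$E, f, rate = rate)
}

#' Poisson (equal-exchangeability) model over an arbitrary alphabet
#'
#' All exchangeabilities equal; the stationary distribution is the supplied
#' profile.  This is the CAT-style model used for branch-class propensity
#' profiles.
#'
#' @param frequencies stationary frequencies, named by state symbol.
#' @param rate overall rate multiplier.
#' @param floor frequencies of exactly zero are clamped to this value (with
#'   a warning) so the model remains irreducible.
#' @return a [SubstitutionModel-class].
#' @export
poissonModel <- function(frequencies, rate = 1, floor = 1e-12) {
  if (is.null(names(frequencies)))
    stop("frequencies must be named by state symbol")
  f <- as.numeric(frequencies)
  if (any(f == 0)) {
    warning("zero-frequency state(s) clamped to ", floor)
    f[f == 0] <- floor
  }
  s <- length(f)
  substitutionModel(names(frequencies), matrix(1, s, s), f, rate = rate)
}

#' Two-state (binary trait) model with gain and loss rates
#'
#' A continuous-time Markov chain on \{0,1\} with instantaneous gain
#' (0 to 1) rate `gain` and loss (1 to 0) rate `loss`; branch lengths are
#' used as-is (no mean-rate normalisation), so rates are per unit branch
#' length.
#'
#' @param gain,loss positive rates.
#' @return a [SubstitutionModel-class] over `c("0","1")`.
#' @export
binaryModel <- function(gain, loss) {
  stopifnot(gain > 0, loss > 0)
  freqs <- c(loss, gain) / (gain + loss)
  m <- substitutionModel(c("0", "1"), matrix(gain + loss, 2, 2), freqs,
                         rate = 1, normalize = FALSE)
  attr(m, "gain") <- gain
  attr(m, "loss") <- loss
  m
}

#' Observed amino acid frequencies of an alignment
#'
#' Frequencies with a small pseudocount so every amino acid has positive
#' mass (required for a well-defined reversible model); gaps and `X` are
#' ignored.
#'
#' @param aln an [AAAlignment-class].
#' @param pseudocount added to each amino acid count.
#' @return named numeric vector over [aaAlphabet()], summing to 1.
#' @export
observedFrequencies <- function(aln, pseudocount = 0.5) {
  m <- alignmentMatrix(aln)
  counts <- table(factor(as.vector(m), levels = aaAlphabet()))
  f <- as.numeric(counts) + pseudocount
  setNames(f / sum(f), aaAlphabet())
}
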