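#' @include AllClasses.R
NULL

# Deterministic node labels: tip labels, then internal labels.  Internal
# labels come from the tree when present, otherwise "N<k>" where k is the
# ape internal node index (root = N1), which is deterministic for a given
# edge matrix.
.nodeLabels <- function(tree) {
  nTip <- length(tree$tip.label)
  internal <- tree$node.label
  if (is.null(internal) || length(internal) != tree$Nnode ||
      any(!nzchar(internal)))
    internal <- paste0("N", seq_len(tree$Nnode))
  c(tree$tip.label, internal)
}

.nNodes <- function(tree) length(tree$tip.label) + tree$Nnode

# Postorder edge matrix + matching edge lengths (children before parents).
.postorder <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  list(edge = po$edge, length = po$edge.length)
}

# Cladewise (parent-before-child) ordering, used by the simulators.
.cladewise <- function(tree) {
  cw <- ape::reorder.phylo(tree, "cladewise")
  list(edge = cw$edge, length = cw$edge.length)
}

# Map per-tip symbols to 0-based alphabet indices (-1 = missing).
# `states` is either a named character vector (one character) or a
# character matrix tips x sites with rownames; row order follows
# tree$tip.label.
.tipStateMatrix <- function(tree, states, alphabet,
                            missing = c("X", "-", "?")) {
  tips <- tree$tip.label
  if (is.matrix(states)) {
    if (!all(tips %in% rownames(states)))
      stop("tip(s) missing from the state matrix: ",
           paste(setdiff(tips, rownames(states)), collapse = ", "))
    m <- states[tips, , drop = FALSE]
  } else {
    if (!all(tips %in% names(states)))
      stop("tip(s) missing from the state vector: ",
           paste(setdiff(tips, names(states)), collapse = ", "))
    m <- matrix(states[tips], ncol = 1, dimnames = list(tips, NULL))
  }
  known <- m %in% c(alphabet, missing) | is.na(m)
  if (!all(known))
    stop("state symbol(s) outside the model alphabet: ",
         paste(unique(m[!known]), collapse = ", "))
  idx <- match(m, alphabet) - 1L
  idx[is.na(idx)] <- -1L
  matrix(idx, nrow = nrow(m), ncol = ncol(m))
}

# Symmetric eigen-system of a reversible rate matrix, for cpp_pmats/pruning.
.modelEigen <- function(model) {
  Q <- rateMatrix(model)
  sp <- sqrt(model@frequencies)
  A <- diag(sp) %*% Q %*% diag(1 / sp)
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  list(U = e$vectors, lam = e$values, sqrtpi = sp)
}

# Transition-probability cube for the given branch lengths (already
# multiplied by any rate factors).
.pmatCube <- function(model, lengths) {
  es <- .modelEigen(model)
  cpp_pmats(es$U, es$lam, es$sqrtpi, lengths)
}

.logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Validate an ape tree for use in this package.
.checkTree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  invisible(tree)
}
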