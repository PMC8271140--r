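#' @include AllClasses.R
NULL

#' Read an amino acid alignment from FASTA
#'
#' Symbols are upper-cased; the 20 standard amino acids plus gap `-` and
#' unknown `X` are accepted.  Stop (`*`), dot and any other symbols are
#' rejected, as are ragged alignments and duplicated identifiers.  Sequence
#' identifiers are the first whitespace-delimited token of each header.
#'
#' @param path path to a FASTA file.
#' @return an [AAAlignment-class] with columns indexed 1..width.
#' @seealso [dropGapColumns()], [writeAlignment()]
#' @export
readAlignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) stop("no sequences in ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicated sequence identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  w <- Biostrings::width(seqs)
  if (length(unique(w)) != 1)
    stop("ragged alignment: sequence lengths ",
         paste(sort(unique(w)), collapse = ", "))
  chars <- toupper(as.character(seqs))
  m <- matrix(unlist(strsplit(chars, "", fixed = TRUE), use.names = FALSE),
              nrow = length(seqs), ncol = w[1], byrow = TRUE,
              dimnames = list(ids, NULL))
  bad <- setdiff(unique(as.vector(m)), c(aaAlphabet(), "-", "X"))
  if (length(bad))
    stop("non-amino-acid symbol(s) in alignment: ",
         paste(bad, collapse = ", "))
  new("AAAlignment", matrix = m, retained = seq_len(ncol(m)),
      originalWidth = ncol(m))
}

#' Write an alignment to FASTA
#'
#' @param aln an [AAAlignment-class].
#' @param path output file path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
writeAlignment <- function(aln, path, width = 60L) {
  stopifnot(is(aln, "AAAlignment"))
  m <- alignmentMatrix(aln)
  seqs <- Biostrings::BStringSet(apply(m, 1, paste, collapse = ""))
  names(seqs) <- rownames(m)
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Drop alignment columns containing gaps
#'
#' Removes every column in which at least one sequence has `-` and updates
#' the retained-column map, so results can be reported against original
#' coordinates.  `X` is kept (treated as missing data downstream).  The
#' operation is idempotent.
#'
#' @param aln an [AAAlignment-class].
#' @return a gap-free [AAAlignment-class].
#' @export
dropGapColumns <- function(aln) {
  stopifnot(is(aln, "AAAlignment"))
  m <- alignmentMatrix(aln)
  keep <- colSums(m == "-") == 0
  if (!any(keep)) stop("all alignment columns contain gaps")
  new("AAAlignment", matrix = m[, keep, drop = FALSE],
      retained = aln@retained[keep], originalWidth = aln@originalWidth)
}

#' Read a rooted phylogeny from newick
#'
#' The tree must have branch lengths and be rooted (a basal trifurcation is
#' rejected).  Zero-length branches are replaced by `epsilon` (with a
#' warning) so that pruning likelihoods are defined.
#'
#' @param path path to a newick file.
#' @param epsilon replacement length for zero-length branches.
#' @return an ape `phylo` object.
#' @export
readTree <- function(path, epsilon = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick in ", path)
  if (anyDuplicated(tree$tip.label))
    stop("duplicated tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (!ape::is.rooted(tree))
    stop("tree is unrooted (trifurcating root); root it before use")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  nz <- tree$edge.length == 0
  if (any(nz)) {
    warning(sum(nz), " zero-length branch(es) replaced by epsilon = ",
            epsilon)
    tree$edge.length[nz] <- epsilon
  }
  tree
}

#' Read a binary phenotype table
#'
#' Two-column TSV (tip identifier, state in \{0,1\}), header optional.
#' Every tree tip must be covered exactly once; extra or missing tips and
#' states outside \{0,1\} are errors.
#'
#' @param path path to the TSV file.
#' @param tree the `phylo` whose tips the table must cover.
#' @return named integer vector of 0/1 states, ordered as `tree$tip.label`.
#' @export
readPhenotypes <- function(path, tree) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.table(path, sep = "\t", header = FALSE,
                    colClasses = "character", strip.white = TRUE)
  if (ncol(tab) < 2) stop("phenotype table must have two columns")
  if (nrow(tab) > 0 && !(tab[1, 2] %in% c("0", "1")))
    tab <- tab[-1, , drop = FALSE]  # header row
  ids <- tab[[1]]
  states <- tab[[2]]
  if (anyDuplicated(ids))
    stop("duplicated phenotype records for: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  bad <- !(states %in% c("0", "1"))
  if (any(bad))
    stop("phenotype states outside {0,1}: ",
         paste(unique(states[bad]), collapse = ", "))
  missing <- setdiff(tree$tip.label, ids)
  if (length(missing))
    stop("phenotype missing for tip(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(ids, tree$tip.label)
  if (length(extra))
    stop("phenotype records for unknown tip(s): ",
         paste(extra, collapse = ", "))
  setNames(as.integer(states[match(tree$tip.label, ids)]), tree$tip.label)
}

#' Write a node-state map to TSV
#'
#' Serialises a [CharacterStateMap-class] as three columns: node label, MAP
#' state, and the posterior probability of the MAP state.
#'
#' @param stateMap a [CharacterStateMap-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeStateMap <- function(stateMap, path) {
  stopifnot(is(stateMap, "CharacterStateMap"))
  post <- posteriorMatrix(stateMap)
  mapP <- post[cbind(seq_len(nrow(post)),
                     match(stateMap@states, stateMap@alphabet))]
  df <- data.frame(node = names(mapStates(stateMap)),
                   state = unname(mapStates(stateMap)),
                   posterior = mapP)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
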