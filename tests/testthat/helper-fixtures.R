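# Shared fixtures, all built in code at test time.

# Balanced 8-tip tree with unit branch lengths.
fixtureTree8 <- function() {
  ape::read.tree(text = paste0(
    "(((t1:1,t2:1):1,(t3:1,t4:1):1):1,",
    "((t5:1,t6:1):1,(t7:1,t8:1):1):1);"))
}

# Branch-event layout realising the worked three-approach example: three
# phenotype gains (branches to t1, t3, t5) and one loss (branch to t7);
# amino acid gains of the foreground residue W coincide with two of the
# gains, a loss of W coincides with the phenotype loss, and a third
# coincident branch carries an unrelated A->G change.
fixtureFig5 <- function() {
  tree <- fixtureTree8()
  pheno <- data.frame(
    branch = c("t1", "t3", "t5", "t7"),
    child = match(c("t1", "t3", "t5", "t7"), tree$tip.label),
    from = c("0", "0", "0", "1"),
    to = c("1", "1", "1", "0"), stringsAsFactors = FALSE)
  aa <- data.frame(
    branch = c("t1", "t3", "t5", "t7"),
    child = match(c("t1", "t3", "t5", "t7"), tree$tip.label),
    from = c("A", "A", "A", "W"),
    to = c("W", "W", "G", "Y"), stringsAsFactors = FALSE)
  list(tree = tree, phenoEvents = pheno, aaEvents = aa, fgAA = "W")
}

# Write a small FASTA from named sequences; returns the path.
writeFastaFixture <- function(seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(names(seqs), function(n)
    c(paste0(">", n), seqs[[n]]))), path)
  path
}

writePhenotypeFixture <- function(states,
                                  path = tempfile(fileext = ".tsv"),
                                  header = FALSE) {
  lines <- paste(names(states), states, sep = "\t")
  if (header) lines <- c("tip\tstate", lines)
  writeLines(lines, path)
  path
}

# Random branch-event tables on a tree (for score property tests).
randomEventTables <- function(tree, nPheno = 5, nAA = 5) {
  child <- tree$edge[, 2]
  labels <- c(tree$tip.label, paste0("N", seq_len(tree$Nnode)))
  pb <- sample(child, min(nPheno, length(child)))
  dirs <- sample(c("gain", "loss"), length(pb), replace = TRUE)
  pheno <- data.frame(branch = labels[pb], child = pb,
                      from = ifelse(dirs == "gain", "0", "1"),
                      to = ifelse(dirs == "gain", "1", "0"),
                      stringsAsFactors = FALSE)
  ab <- sample(child, min(nAA, length(child)))
  aaFrom <- sample(aaAlphabet()[1:4], length(ab), replace = TRUE)
  aaTo <- vapply(aaFrom, function(f)
    sample(setdiff(aaAlphabet()[1:4], f), 1), character(1))
  aa <- data.frame(branch = labels[ab], child = ab, from = aaFrom,
                   to = unname(aaTo), stringsAsFactors = FALSE)
  list(pheno = pheno, aa = aa)
}

# Binary tip states under a two-state chain, rejecting monomorphic draws.
.simPhenoForTest <- function(tree, gain, loss) {
  repeat {
    h <- simulatePhenotype(tree, gain, loss, targetOrigins = c(1, 10000))
    if (length(unique(h$tipStates)) == 2) return(h$tipStates)
  }
}
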