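#' @include AllClasses.R
NULL

# Events are counted per branch: if a caller supplies several events on the
# same branch (cannot happen for MAP-derived events), only the first is kept.
.onePerBranch <- function(events) {
  if (nrow(events) == 0) return(events)
  events[!duplicated(events$child), , drop = FALSE]
}

.phenoSets <- function(phenoEvents) {
  pe <- .onePerBranch(phenoEvents)
  list(gain = pe$child[pe$from == "0" & pe$to == "1"],
       loss = pe$child[pe$from == "1" & pe$to == "0"])
}

.scoreRecord <- function(approach, fgAA, branches, labels) {
  data.frame(approach = approach,
             fgAA = if (is.null(fgAA)) NA_character_ else fgAA,
             score = length(branches),
             contributing = paste(labels, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Convergence simultaneous score
#'
#' Counts branches on which the foreground phenotype is gained (0 to 1) and
#' the amino acid site simultaneously changes *to* the foreground amino
#' acid.
#'
#' @param phenoEvents data.frame of phenotype branch events (`child`,
#'   `from`, `to`; see [extractBranchEvents()]).
#' @param aaEvents data.frame of amino acid branch events at one site.
#' @param fgAA the foreground amino acid symbol.
#' @return one-row data.frame: `approach`, `fgAA`, `score`, `contributing`
#'   (semicolon-joined branch labels).
#' @export
convergenceScore <- function(phenoEvents, aaEvents, fgAA) {
  ps <- .phenoSets(phenoEvents)
  ae <- .onePerBranch(aaEvents)
  hit <- ae$child %in% ps$gain & ae$to == fgAA
  .scoreRecord("convergence", fgAA, ae$child[hit], ae$branch[hit])
}

#' GWAS simultaneous score
#'
#' Counts branches on which the foreground phenotype and the foreground
#' amino acid are both gained, plus branches on which both are lost (the
#' amino acid event's from-state equals the foreground amino acid).
#'
#' @inheritParams convergenceScore
#' @return one-row data.frame as in [convergenceScore()].
#' @export
gwasScore <- function(phenoEvents, aaEvents, fgAA) {
  ps <- .phenoSets(phenoEvents)
  ae <- .onePerBranch(aaEvents)
  hit <- (ae$child %in% ps$gain & ae$to == fgAA) |
         (ae$child %in% ps$loss & ae$from == fgAA)
  .scoreRecord("gwas", fgAA, ae$child[hit], ae$branch[hit])
}

#' All-changes simultaneous score
#'
#' Counts branches carrying at least one phenotype change (either
#' direction) and at least one amino acid change (any states).
#'
#' @inheritParams convergenceScore
#' @return one-row data.frame with `fgAA = NA`.
#' @export
allChangesScore <- function(phenoEvents, aaEvents) {
  pe <- .onePerBranch(phenoEvents)
  ae <- .onePerBranch(aaEvents)
  hit <- ae$child %in% pe$child
  .scoreRecord("allchanges", NULL, ae$child[hit], ae$branch[hit])
}

#' Best per-site simultaneous score over candidate foreground amino acids
#'
#' With no a priori knowledge of which amino acid change is associated with
#' the phenotype, every amino acid observed in the site's events is
#' evaluated as foreground and the maximum-score record returned (ties
#' towards the lowest alphabet index).  For the all-changes approach the
#' single record is returned.  The identical maximisation is applied to the
#' simulated null sites, so statistic and null match.
#'
#' @inheritParams convergenceScore
#' @param approach one of [approachKinds()].
#' @return one-row data.frame as in [convergenceScore()].
#' @export
siteBestScore <- function(phenoEvents, aaEvents,
                          approach = c("convergence", "gwas", "allchanges")) {
  approach <- match.arg(approach)
  if (approach == "allchanges")
    return(allChangesScore(phenoEvents, aaEvents))
  ae <- .onePerBranch(aaEvents)
  cand <- if (approach == "convergence") unique(ae$to)
          else unique(c(ae$from, ae$to))
  cand <- cand[order(match(cand, aaAlphabet()))]
  if (length(cand) == 0)
    return(.scoreRecord(approach, NA_character_, integer(0), character(0)))
  recs <- lapply(cand, function(a) {
    if (approach == "convergence") convergenceScore(phenoEvents, ae, a)
    else gwasScore(phenoEvents, ae, a)
  })
  scores <- vapply(recs, function(r) r$score, numeric(1))
  if (max(scores) == 0)
    return(.scoreRecord(approach, NA_character_, integer(0), character(0)))
  recs[[which.max(scores)]]   # first max = lowest alphabet index
}

#' Score every site of a reconstructed alignment
#'
#' Applies [siteBestScore()] to the MAP-derived branch events of each site
#' under the requested approaches.
#'
#' @param ancestral an [AncestralAlignment-class].
#' @param phenoEvents phenotype branch events (see
#'   [reconstructPhenotype()]).
#' @param approaches subset of [approachKinds()].
#' @param retained optional map from site index to original alignment
#'   column (see [retainedColumns()]); reported in the `column` field.
#' @param gene optional gene label carried into the output.
#' @return data.frame with one row per site and approach: `gene`, `site`,
#'   `column`, `approach`, `fgAA`, `score`, `contributing`.
#' @export
scoreAlignment <- function(ancestral, phenoEvents,
                           approaches = approachKinds(),
                           retained = NULL, gene = NA_character_) {
  stopifnot(is(ancestral, "AncestralAlignment"))
  approaches <- match.arg(approaches, approachKinds(), several.ok = TRUE)
  nSite <- ncol(ancestral@map)
  alpha <- ancestral@alphabet
  ev <- branchEvents(ancestral)
  ps <- .phenoSets(phenoEvents)
  siteF <- factor(ev$site, levels = seq_len(nSite))
  onGain <- ev$child %in% ps$gain
  onLoss <- ev$child %in% ps$loss

  # per-site counts of foreground-candidate hits, vectorised across sites;
  # max.col(ties = "first") reproduces the lowest-alphabet-index tie-break
  tg <- unclass(table(siteF[onGain], factor(ev$to[onGain], levels = alpha)))
  tl <- unclass(table(siteF[onLoss], factor(ev$from[onLoss], levels = alpha)))
  contribStr <- function(sel) {
    sp <- split(ev$branch[sel], siteF[sel])
    vapply(sp, paste, character(1), collapse = ";")
  }
  rows <- list()
  if ("convergence" %in% approaches) {
    bi <- max.col(tg, ties.method = "first")
    sc <- tg[cbind(seq_len(nSite), bi)]
    fg <- ifelse(sc > 0, alpha[bi], NA_character_)
    sel <- onGain & ev$to == fg[ev$site] & !is.na(fg[ev$site])
    rows$convergence <- data.frame(site = seq_len(nSite),
                                   approach = "convergence", fgAA = fg,
                                   score = as.integer(sc),
                                   contributing = contribStr(sel),
                                   stringsAsFactors = FALSE)
  }
  if ("gwas" %in% approaches) {
    tgw <- tg + tl
    bi <- max.col(tgw, ties.method = "first")
    sc <- tgw[cbind(seq_len(nSite), bi)]
    fg <- ifelse(sc > 0, alpha[bi], NA_character_)
    sel <- !is.na(fg[ev$site]) &
      ((onGain & ev$to == fg[ev$site]) | (onLoss & ev$from == fg[ev$site]))
    rows$gwas <- data.frame(site = seq_len(nSite), approach = "gwas",
                            fgAA = fg, score = as.integer(sc),
                            contributing = contribStr(sel),
                            stringsAsFactors = FALSE)
  }
  if ("allchanges" %in% approaches) {
    sel <- onGain | onLoss
    sc <- as.integer(table(siteF[sel]))
    rows$allchanges <- data.frame(site = seq_len(nSite),
                                  approach = "allchanges",
                                  fgAA = NA_character_, score = sc,
                                  contributing = contribStr(sel),
                                  stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows[approaches])
  res <- res[order(res$site, match(res$approach, approachKinds())), ]
  rownames(res) <- NULL
  res$column <- if (is.null(retained)) res$site else retained[res$site]
  res$gene <- gene
  res[, c("gene", "site", "column", "approach", "fgAA", "score",
          "contributing")]
}
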