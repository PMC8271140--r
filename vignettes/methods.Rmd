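---
title: "Detecting recurrent genotype-phenotype associations on a phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting recurrent genotype-phenotype associations on a phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloConv)
```

## The problem

When a phenotype — say tolerance of high altitude in birds — evolves
repeatedly on a phylogeny, a protein site that contributes to it should
change *on the same branches* on which the phenotype changes, more often
than chance allows. `phyloConv` implements a complete pipeline around this
idea for amino acid alignments and a binary trait: ancestral state
reconstruction for both characters, three definitions of a per-site
"simultaneous score" counting branch-coincident changes, a
simulation-based null model that turns the score into a calibrated test,
and a complementary "profile change" posterior asking whether a site's
amino acid propensities differ between phenotype-foreground and
-background branches.

## Ancestral reconstruction

Both the phenotype and every alignment column are mapped onto the nodes of
a rooted tree by marginal maximum-likelihood reconstruction (Felsenstein
pruning, two-pass up/down algorithm; `marginalAncestralStates()`).

* **Amino acids.** The default model is LG exchangeabilities with
  alignment-observed frequencies ("+F"). The scoring layer consumes only
  MAP states, so conclusions are not tied to a particular empirical
  matrix; any reversible `SubstitutionModel` can be supplied.
* **Site rates.** Each site receives a rate multiplier chosen by maximum
  likelihood over a fixed log-spaced grid (default `2^seq(-3, 3,
  length.out = 7)`, i.e. 0.125-8x). A grid rather than a continuous
  optimiser keeps the reconstruction batched: one pruning pass per grid
  point covers all sites simultaneously, and sites are then grouped by
  selected rate for the marginal pass. The grid's resolution (factor ~2
  between neighbours) is far finer than what MAP state calls are
  sensitive to. Gamma-mixture rates are deliberately not used in
  reconstruction: the null calibration conditions on the empirical
  substitutions-per-site distribution, which already absorbs rate
  heterogeneity.
* **Phenotype.** A two-state chain with free gain and loss rates is
  fitted by bounded ML (`optim`, rates in `[1e-6, 100]` per unit branch
  length; hitting a bound is flagged) and reconstruction uses an
  equal-probability root prior. Events are called on MAP states: a branch
  whose parent and child MAP states differ carries exactly one event.
  Hard assignment matches how the score is defined; posterior-weighted
  event calling is out of scope.
* **Ties and missing data.** MAP ties are broken deterministically toward
  the lowest alphabet index (alphabetical for amino acids) and counted.
  `X` (and gaps, where retained) contribute all-ones partials. Zero-length
  branches are replaced by a configurable epsilon (`1e-6`) at read time so
  likelihoods are defined.

## The three simultaneous scores

With gain = acquisition of the foreground phenotype and loss = its
reversal, a site's score under each approach is the number of branches on
which:

* **Convergence** — the phenotype is gained *and* the site changes *to*
  the foreground amino acid;
* **GWAS** — both are gained, or both are lost (the site's from-state
  equals the foreground amino acid on loss branches);
* **All changes** — any phenotype change coincides with any amino acid
  change.

Because multiple substitutions per site are common at deep phylogenetic
scales, there is no a priori foreground amino acid: every residue observed
in a site's events is evaluated and the maximum score kept (ties to the
lowest alphabet index). The same maximisation is applied to null sites —
without this symmetry the thresholds would be anti-conservative. By
construction Convergence ≤ GWAS ≤ All changes for every site. A branch
with a reconstructed multi-step change (parent X, child Z) counts as a
single X→Z event; intermediates are not imputed. The foreground phenotype
is fixed by the user and never auto-flipped.

## Null calibration and significance

The null model keeps the tree and the *empirical* phenotype events fixed
and re-draws genetic histories: each null site draws a substitution count
from the empirical per-site event-count histogram, places that many events
on distinct branches with probability proportional to branch length, and
assigns event states by a random walk over a uniform 20-letter alphabet
(the state scheme is a declared modelling choice — the conditioning on the
substitutions-per-site distribution is the essential constraint). The
best-per-site score of 100,000 such sites (default) forms the null
distribution; the significance threshold is the smallest score whose null
tail probability does not exceed `alpha / nSites` (Correction 1) or
`alpha / (nSites * 3)` (Correction 2, three test types). Corrected levels
below the Monte-Carlo resolution, or thresholds beyond the observed null
support, are flagged.

Test sizes used by the package's own calibration suite: 200 null datasets
of 200 tips x 500 sites with 7 phenotype origins for the familywise-error
check of the Convergence test; 50 replicates with a planted convergent
site for power; 1,000 replicates of 500 independent score pairs for the
level of the quadrant Fisher cross-test.

## Profile change

For each site, two CAT-style propensity profiles are assigned — one to
foreground branches (child-node MAP phenotype 1; branches on which the
phenotype changes are classed by their child state) and one to background
branches — and compared against a single shared profile in a Bayesian
model comparison with equal prior odds. Profiles come from a fixed,
data-independent library of ten categories concentrated on biochemically
similar residue groups ({A,S,T}, {C}, {D,E}, {N,Q}, {K,R}, {F,Y,W}, {H},
{I,V}, {L,M}, {G,P}; 0.95 in-group mass, remainder spread so no residue
has zero propensity), with uniform weights within each model class.
Exchangeabilities are uniform (CAT-Poisson style), so only the stationary
profile differs between classes; the root draws from the background
profile. The site rate is estimated by ML under the no-change model and
then fixed for both models, so rate and profile differences are not
confounded. The reported posterior is
`P(change) = L_change / (L_change + L_null)`.

The cross-test against the simultaneous score dichotomises the posterior
at 0.5 (the middle of its scale) and the score at the rounded-up
mid-range of the observed scores (its discrete analogue), and applies a
two-sided Fisher exact test; a degenerate margin returns p = 1 with a
warning.

## The synthetic-data generator

`simulateDataset()` produces the study conditions every test runs under:
a pure-birth tree (`ape::rphylo`) with 200 tips; a binary trait simulated
as a two-state chain (gain 0.035, loss 0.1 per unit branch length) and
rejection-sampled to exactly 7 independent origins — the shape of a
moderately recurrent trait, within the 3-33 origin range typical of
repeatedly evolved phenotypes; and 2,000 amino acid sites (500 in the
calibration suite) evolved by per-site Gillespie simulation under LG with
base rate 0.015 expected substitutions per unit branch length,
mean-1 gamma multipliers (shape 0.8), and 5% hypervariable sites at 10x
rate. On a 200-tip pure-birth tree (total length ~n-1 in these units)
this yields a few substitutions per typical site and tens at
hypervariable sites. Phenotype origins are controlled by rejection rather
than conditioning formulas — simple and exact at this scale.

Planted signal overwrites the simulated history rather than biasing
rates, so ground truth is unambiguous: a convergent site rewrites the
descendant subtree of each coupled phenotype-gain branch to the
foreground residue (the ledger records coupled branches and the realised
number of changes, which nested gains can shadow); a profile-change site
is re-simulated with class-dependent profiles switching at the phenotype
partition. A propensity switch only exists in the data if the site
actually substitutes within both branch classes, so by default the
planted site's rate is scaled so that the *smaller* branch class expects
five substitutions (capped at 2 per unit branch length) — the profile
analogue of the convergent planter's guarantee; an explicit rate can be
supplied instead, e.g. to study the power loss at slow sites.

What the generator does *not* emulate: codon structure and selection,
indels, base-composition idiosyncrasies of real mitochondrial genomes,
non-reversible or time-varying processes, and correlated rates across
sites. Passing tests therefore demonstrate calibration and power under
the model's own assumptions, not robustness to their violation.

## Numerical choices

* Transition probabilities come from the symmetric eigen-decomposition of
  the reversible rate matrix; tiny negative entries from round-off are
  clamped to zero.
* Pruning uses per-site log-scaling, so hundreds of tips and 20 states
  are handled without underflow.
* Likelihoods that are exactly zero under a profile assignment (a tip
  symbol with zero propensity in its branch class) are floored at `-1e10`
  and flagged rather than returned as `-Inf`.
* All simulation code consumes R's RNG, so every result is
  bit-reproducible under `set.seed()`.

## Known limitations

* The null's uniform random-walk state scheme does not reproduce the
  strong state-reuse (toggling between two residues) that real or
  LG-simulated hypervariable sites show. For the Convergence and
  All-changes statistics the resulting thresholds are conservative to
  accurate; for the GWAS statistic — which credits both gains and losses
  of the same residue — the null can be anti-conservative on
  low-diversity sites, and GWAS familywise error is therefore not
  guaranteed at the nominal level. The familywise-error guarantees the
  package tests refer to the Convergence test.
* Hard MAP events ignore reconstruction uncertainty; branches with
  near-tied posteriors contribute noise to scores in both directions.
* The profile-change posterior has low power at slow sites (nothing to
  observe) and its absolute value depends on the declared library; it is
  a ranking/evidence score, not a calibrated error rate.
* Correction 2 multiplies the site count by exactly 3 (the three
  approaches), ignoring their strong positive dependence; it is
  conservative by design.
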