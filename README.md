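# phyloConv

Detection of recurrent (convergent) genotype–phenotype associations in
protein-coding genes on a phylogeny.

When a binary phenotype (high-altitude tolerance, diving, flightlessness,
…) evolves repeatedly across a clade, amino acid sites that contribute to
it should change on the same branches as the phenotype more often than
chance allows. `phyloConv` implements that test end to end for an amino
acid alignment, a rooted tree, and a binary trait:

* **Ancestral reconstruction** — marginal maximum-likelihood states for
  every site (LG + observed frequencies by default, per-site ML rate) and
  for the phenotype (two-state chain with ML gain/loss rates), by
  Felsenstein pruning; branch events are called where parent and child
  MAP states differ.
* **Simultaneous scores** — per site, the number of branches on which
  genotype and phenotype change together, under three definitions:
  *Convergence* (foreground phenotype gained and foreground amino acid
  gained), *GWAS* (both gained or both lost), *All changes* (any change
  coincides with any change). With multiple substitutions per site there
  is no a priori foreground residue, so every observed residue is tried
  and the per-site maximum kept.
* **Null calibration** — null sites are simulated on the same tree with
  the same phenotype events, substitution counts drawn from the empirical
  per-site distribution and placed on branches proportionally to branch
  length; significance thresholds are the null-tail quantiles at the
  Bonferroni-corrected level `alpha/nSites` (Correction 1) or
  `alpha/(3·nSites)` (Correction 2).
* **Profile change** — per site, the posterior probability that amino
  acid propensity profiles differ between phenotype-foreground and
  -background branches (CAT-style profile library, Bayesian model
  comparison with equal prior odds), plus the quadrant Fisher cross-test
  between the two scores.
* **Synthetic data** — a generator for birth–death trees, binary traits
  with an exact number of independent origins, site-heterogeneous
  alignments (hypervariable sites included), and *planted* convergent or
  profile-change sites with a ground-truth ledger, so calibration and
  power are testable without any external data.

See `vignettes/methods.Rmd` for the models, parameter choices and known
limitations.

## Worked example

Simulate a null dataset shaped like a mitochondrial protein study
(200 tips, 500 sites, 7 independent phenotype origins), plant one
convergent site, and run the Convergence test:

```r
library(phyloConv)
ds  <- simulateDataset(nTips = 200, nSites = 500, targetOrigins = c(7, 7),
                       seed = 1)
ds  <- plantConvergentSite(ds, site = 250, pCouple = 1)
res <- runSimultaneousTest(datasetTree(ds), datasetAlignment(ds),
                           datasetPhenotypes(ds),
                           approaches = "convergence",
                           nullReplicates = 1e5, seed = 2)
subset(res$scores, significantCorrection1)
```

```
    site    approach fgAA score significantCorrection2
250  250 convergence    A     7                   TRUE
```

The planted site — seven gains of the foreground residue `A`, one per
phenotype origin — scores 7 against a null threshold of 3 and is the only
site flagged under both corrections:

```
     approach  correction correctedAlpha threshold
1 convergence correction1        1.0e-04         3
2 convergence correction2        3.3e-05         3
```

Recurrent gains also shift the site's residue propensities between branch
classes, and the profile-change posterior agrees:

```r
part <- partitionBranches(datasetTree(ds), res$phenotype$stateMap)
m    <- alignmentMatrix(datasetAlignment(ds))
profileChangePosterior(datasetTree(ds), setNames(m[, 250], rownames(m)),
                       part)$posterior
#> 0.99
```

For file-based workflows use `readAlignment()` / `dropGapColumns()` /
`readTree()` / `readPhenotypes()`; results serialise with
`writeScoreTable()`, `writeNullDistribution()` and `writeStateMap()`.

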