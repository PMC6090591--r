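---
title: "Models and methods behind phasecycle"
author: "phasecycle maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phasecycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasecycle)
```

# The scientific setting

Colonies of the clonal raider ant alternate between a reproductive phase and
a brood-care phase, and either transition can be triggered experimentally by
adding or removing larvae. `phasecycle` analyzes brain gene expression time
courses across the two induced transitions — reproduction to brood care (RB)
and brood care to reproduction (BR) — sampled at 12, 24, 48 and 96 h after
the brood swap, with untreated phase controls coded as time 0. The package
asks three questions of such data:

1. **Which genes change over time, and differently so between transitions?**
   (spline negative-binomial likelihood-ratio tests)
2. **When do co-expressed groups of genes change?** (P-spline mixture
   clustering of trajectories and maximum change vectors)
3. **Are the two transitions mirror images of each other?** (cluster
   membership networks, a permutation-defined conserved sub-network, and
   enrichment analyses)

Every stage can be exercised on synthetic data with known ground truth via
`simulateExperiment()`, which is how the package tests itself.

# Differential expression over time

## Model

Counts for each gene are modeled as negative binomial with log link,

$$y_{gj} \sim \mathrm{NB}(\mu_{gj},\ \alpha_g), \qquad
  \mathrm{Var}(y) = \mu + \alpha\mu^2, \qquad
  \log \mu_{gj} = x_j^\top\beta_g + \log s_j,$$

where $s_j$ are median-of-ratios size factors (`computeSizeFactors()`). The
time course enters through a cubic B-spline basis with three degrees of
freedom, no interior knots and boundary knots at 0 and 96 h
(`buildSplineBasis()`, evaluated by the Cox–de Boor recursion; controls sit
at the left boundary where all three basis functions vanish). Two contrasts
are provided by `lrtContrast()`:

* **per-transition time effect** (`RB_time`, `BR_time`):
  full design `colony + bs(time, df = 3)` against reduced design `colony`,
  fitted on that transition's samples only. This flags genes that change at
  *any* point of the time course, not only relative to the control.
* **time-by-transition interaction** (`interaction`): full design
  `colony + transition + bs(time, df = 3) + transition:bs(time, df = 3)`
  against the same design without the interaction, on all samples. This is
  the conservative contrast: genes responding identically in both
  transitions — including disturbance responses to the manipulation
  itself — cancel out.

Both contrasts have 3 degrees of freedom, and `2(\ell_\mathrm{full} -
\ell_\mathrm{reduced})` is referred to $\chi^2_3$, with Benjamini–Hochberg
adjustment (`bhAdjust()`) over all tested genes.

## Fitting and numerical choices

Coefficients are fitted by iteratively reweighted least squares with step
halving on the log-likelihood (tolerance $10^{-8}$, at most 100 iterations);
non-converged genes are excluded from testing with a warning. The per-gene
dispersion is estimated once under the full model by maximizing the
**Cox–Reid adjusted** profile likelihood over $\alpha \in [10^{-8}, 30]$ and
shared with the reduced fit. The adjustment matters: with 72 samples and
~15 coefficients, the unadjusted profile maximum biases $\hat\alpha$ low by
roughly the ratio of residual to total degrees of freedom, which visibly
inflates the type-I error of the LRT. With the adjustment the rejection rate
at nominal 0.05 on null simulations sits near 0.06. The asymptotic
$\chi^2_3$ reference remains *mildly* liberal at these sample sizes (about
2% of null p-values fall below 0.01 rather than 1%), which is shared by the
standard tools built on the same approximation and should be kept in mind
when interpreting marginal calls.

Genes with fewer than 10 total counts across the used samples are excluded
from testing (`minCount`, configurable): such fits are degenerate and their
p-values meaningless. No empirical-Bayes shrinkage of dispersions is
attempted — it is out of scope and unnecessary at eight replicates per time
point for calibration purposes.

# Sample structure

`foldChangeScreen()` computes per-gene max/min ratios of group
(transition × time) means on the linear scale, with group means taken on
the variance-stabilized scale `log2(count/sf + 1)` (`vstCounts()`); the +1
offset keeps zero-count groups finite. `outlierImpact()` quantifies the
sensitivity cost of dropping the 6-h samples: the percentage of
early-responding candidate genes (twofold between 6-h control and treatment)
that are no longer recovered by the screen once the 6-h time points are
removed.

`ordinateTimepoints()` works on the mean expression profile of each
transition × time group (not individual samples, matching how the sample
structure is summarized): a centered PCA of the group profiles, k-means with
k = 3 (the reproductive-like, intermediate and brood-care-like sample
groups) and 50 restarts under a fixed seed, the Euclidean distance matrix
between groups, and an average-linkage dendrogram exported as Newick.

# Trajectory clustering

## P-spline mixture model

For each transition, the per-gene trajectory is the vector of
variance-stabilized means at the design times (replicate variation is
absorbed before clustering). Trajectories are modeled as a K-component
mixture: component k has a smooth mean curve $B\theta_k$ on a rich cubic
B-spline basis (five equally spaced interior knots, nine basis functions)
with a second-order difference penalty $\lambda\,\theta^\top D^\top D\theta$,
and genes deviate from their component curve by a random intercept
(variance $\tau^2$) plus independent noise (variance $\sigma^2$), giving a
compound-symmetric trajectory covariance. `fitPsplineMixture()` runs EM:

* E-step: responsibilities from the Gaussian trajectory densities;
* M-step: penalized weighted least squares for each $\theta_k$, closed-form
  updates for $\sigma^2$, $\tau^2$ (with the boundary case $\tau^2 = 0$
  handled by the pooled-variance MLE so the objective never decreases) and
  the mixing proportions.

Initialization is k-means++ style on the trajectories; five independent
restarts are run (all seeded from one argument) and the best final penalized
objective wins, which in practice removes the label-merging local optima a
single EM start occasionally falls into. An emptied component is
re-initialized once, then the fit aborts with a diagnostic. Convergence is
declared when the penalized objective moves by less than $10^{-6}$.

## The penalty default

The penalty weight defaults to $\lambda = 1$. With five design times and
nine basis functions the penalty's role is to pin down the four excess basis
dimensions, not to smooth away signal: heavy smoothing flattens cluster
means toward straight lines in time, which silently relocates the largest
fitted change into the widest (48–96 h) interval and corrupts the
maximum-change-vector logic downstream. Cross-validating $\lambda$ on the
single-component fit (`selectLambda()`, provided) is unreliable on exactly
the data this package targets: planted or real up- and down-regulated
clusters cancel in the grand mean, leaving GCV indifferent to fit quality
and free to drift to maximal smoothing. A fixed light penalty is the
defensible default; users who believe their trajectories are heavily
oversampled can raise it.

## Choosing K and summarizing timing

`bicScan()` fits one mixture per candidate K (the study scans even values
from 2 upward) with a shared $\lambda$, counting
$p = K m + (K-1) + 2$ parameters (spline coefficients, mixing proportions,
two variances) in $\mathrm{BIC} = -2\ell + p\log n$. `selectK()` applies a
plateau rule: the smallest K within a tolerance (0.5% of the scanned BIC
range) of the global minimum that no later K exceeds by more than the
tolerance — i.e. the first K on the stable plateau, robust to single
fluctuations before stabilization.

The **maximum change vector** (`computeMcv()`) of a trajectory is the
interval, magnitude and direction of its largest change between consecutive
time points; exact ties take the earliest interval and a zero-magnitude
change is reported as "+", so the summary is deterministic.
`intervalGeneCounts()` accumulates, over clusters enriched for DEGs, each
cluster's size into its cluster-level MCV interval, and
`chi2Homogeneity()` compares the two transitions' interval distributions by
Pearson chi-square (no continuity correction, columns with zero totals
dropped). Gene-level MCVs feed `mcvConcordance()` for the same-MCV
percentage among DEGs shared by both transitions (same interval *and*
direction; the continuous magnitude is deliberately ignored when calling two
MCVs "the same").

# The cluster-membership network

`buildClusterNetwork()` connects each RB cluster with each BR cluster that
shares at least one gene, over the genes clustered in both transitions. By
construction the graph is bipartite and each shared gene lies on exactly one
edge, so edge weights sum to the shared universe — both invariants are
validated on every object. Edge similarity is the Jaccard index of the two
member sets.

`nullJaccardDistribution()` builds the reference distribution by uniformly
permuting genes into clusters of the *original sizes*, independently for the
two transitions, pooling the Jaccard indices of **all** cross-transition
pairs (including zero-overlap pairs — the null describes all node pairs, not
only realized edges) over R = 1000 replicates. An edge is **conserved** when
its Jaccard index strictly exceeds the 95th percentile of the pooled null
scores. On the smallest non-trivial case (two clusters of two genes in a
four-gene universe) the pooled null distribution is enumerable exactly and
the permutation estimate matches it; the test suite checks this.

`edgeDirectionClasses()` labels each edge "opposite" when its two clusters'
MCV directions differ, and `compareDirectionProportions()` compares the
opposite-direction proportion between the conserved edges and the remaining
(non-conserved) edges of the complete network with a 2×2 Pearson chi-square.
Using the disjoint split — rather than conserved versus the full complete
network, which contains the conserved edges — keeps the table's independence
assumption intact; the proportion over the full complete network is still
reported for readability.

# Enrichment

`fisherEnrichment()` performs the one-sided (enrichment) hypergeometric test
of a cluster against a gene set within the declared universe; depletion is
deliberately not flagged. `enrichAllClusters()` applies it across all
(cluster, set) pairs and adjusts with Benjamini–Hochberg *within the
family it is called on* — one call per annotation source per transition, so
DEG enrichment and GO enrichment are corrected separately. Odds ratios get a
0.5 continuity addition (all cells) for reporting only when a cell is zero.

`scanPwm()` scores every window of a promoter on both strands with log2
odds against a uniform 0.25 background (`N` scores as background, i.e. 0),
normalizes by the achievable score range into a relative score in [0, 1],
and reports windows at or above the threshold (default 0.95 — the threshold
is a floor, so comparison is inclusive; it is interpreted relative to the
PWM's own maximum, the standard reading of a "95% minimum score").
`genesWithSite()` reduces hits to the gene set carrying at least one site,
which then enters `fisherEnrichment()` like any other gene set. Position
weight matrices come from JASPAR-format text via `readJasparPwm()` with a
uniform pseudocount (default 0.8, a common motif-scanning choice,
configurable); the background model and promoter window (the bundled
synthetic fixture uses 500 bases) are documented, configurable choices since
upstream motif tools do not agree on them.

# The synthetic-data generator

`simulateExperiment()` draws a complete two-transition experiment:

* **Design**: 4 control replicates at 0 h and 8 replicates at 12/24/48/96 h
  per transition (72 samples), 8 colonies as batch levels; optionally 6-h
  samples (4 replicates) carrying a disturbance shock (±2 log2 in 10% of
  genes, shared across transitions) to exercise the outlier screen.
* **Trajectories**: each transition has a "phase position" curve from the
  starting state to the opposite one, piecewise linear between the design
  times. With `timingAsymmetry = TRUE` (the default) the RB curve makes its
  largest move in the 0–12 or 12–24 h interval and the BR curve in the
  48–96 h interval — early response to larvae added, late response to larvae
  removed. A fraction `fracInteractionDegs` (default 0.1) of genes is
  dynamic in exactly one transition, following one of
  `nClustersPerTransition` cluster shapes (alternating direction and timing
  variant) scaled to span `effectSizeLog2` (default 2) log2 units; all other
  genes are flat. Dynamic-in-one-transition genes are the planted
  time-by-transition interaction DEGs.
* **Noise**: negative binomial counts with per-gene dispersion drawn
  uniformly from `dispersionRange`, gene × colony log-normal batch effects
  (sd 0.15) and per-sample log-normal size factors (sd 0.15). The default
  dispersion range is [0.01, 0.2]: every library pools ten brains of clonal,
  age-matched workers, which suppresses biological variance well below what
  single-individual RNA-seq shows. (Dispersions several times larger are
  easy to request, but they genuinely destroy the information needed to
  detect a 2-log2 trajectory change — the noncentrality of the interaction
  test at $\alpha \approx 0.4$ is below 10 — so they do not describe this
  design.)
* **Ground truth** for every stage: per-transition cluster labels and mean
  trajectories, DEG flags, per-sample phase positions (which
  `simulateOvaryScores()` maps monotonically onto the 0–4 ovary activation
  scale with clipping and optional noise), colony effects, size factors and
  dispersions. `simulatePromoters()` plants motif consensus words into
  chosen genes' promoters on an i.i.d. uniform background.

What the generator deliberately does **not** emulate: read-level artifacts
(GC and length bias), correlated gene-gene noise beyond cluster membership,
dispersion-mean trends, partially overlapping cluster structure between
transitions, and drop-out. Passing tests on this generator therefore
demonstrate correctness of the statistical machinery under the stated model,
not robustness to every artifact of real libraries.

# Problem sizes used by the test suite

The packaged checks run the null and power calibrations at 2000 genes × 72
samples, trajectory-cluster recovery at 400 genes with four planted clusters
(4 VST units apart, noise 0.5), conserved-network recovery at 500 genes with
10 matched clusters, 20% reshuffled membership and 1000 permutation
replicates, and the qualitative timing/ordination reproduction at 600 genes
with a quarter of genes planted as DEGs. These sizes give stable metrics
(sensitivities and rates move by well under their tolerance across seeds)
while keeping a full run in the order of a minute or two.

# Known limitations

* The LRT's $\chi^2_3$ reference is asymptotic; at 36–72 samples it is
  mildly liberal in the extreme tail (see above).
* The mixture treats per-gene trajectories as exchangeable given their
  component; genes within a real co-expression module are correlated, so
  effective sample sizes for BIC are optimistic and selected K should be
  read as a resolution parameter, not an estimate of a true module count.
* The random effect is an intercept only; gene-specific amplitude
  differences within a cluster load on $\sigma^2$.
* The permutation null preserves cluster sizes but not any within-transition
  gene correlation; its 95th percentile is a screening threshold, not a
  family-wise error control.
* PWM scanning assumes a uniform background and independent positions, as
  simple motif scanners do; it does not reproduce background-corrected
  z-score statistics of dedicated promoter tools.

# A compact end-to-end run

```{r, eval = FALSE}
sim <- simulateExperiment(simulationSpec(nGenes = 600,
                                         fracInteractionDegs = 0.25,
                                         seed = 11))
pe <- sim$experiment

de <- lrtContrast(pe, "interaction")
degs <- with(resultsTable(de), gene_id[!is.na(padj) & padj < 0.05])

asg <- lapply(c(RB = "RB", BR = "BR"), function(tr) {
  Y <- trajectoryMatrix(pe, tr)
  hardAssignment(fitPsplineMixture(Y, as.numeric(colnames(Y)), K = 7,
                                   seed = 5), Y, tr)
})
net <- buildClusterNetwork(asg$RB, asg$BR)
null <- nullJaccardDistribution(table(clusterLabels(asg$RB)),
                                table(clusterLabels(asg$BR)),
                                length(intersect(names(clusterLabels(asg$RB)),
                                                 names(clusterLabels(asg$BR)))),
                                R = 1000, seed = 13)
net <- conservedNetwork(net, null)
net <- edgeDirectionClasses(net, clusterMcvs(asg$RB), clusterMcvs(asg$BR))
compareDirectionProportions(net)
```
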