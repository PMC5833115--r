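---
title: "Detecting and attributing pairwise trait associations across species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and attributing pairwise trait associations across species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(TraitNet)
```

## The problem

Taxonomic compendia of microbial growth phenotypes — can species X grow on
sucrose? at 37 °C? ferment galactose? — record hundreds of species scored
for dozens of binary traits under uniform protocols. Such traits do not
vary independently: carbon sources sharing an enzyme or a pathway tend to
be utilized together, and habitats select for whole suites of traits.
`TraitNet` quantifies pairwise positive and negative associations among
binary traits across species and attributes them to three candidate
drivers: shared phylogenetic history, intrinsic biological properties of
the traits (molecular structures, pathway overlap), and the isolation
environments species were recorded from.

## Data model and preprocessing

A `TraitMatrix` holds the species × trait table. Raw cells use four codes:
growth (`+`), no growth (`-`), variable among strains (`v`), and no data
(`n`). Variable scores reflect growth in at least some type-material
strains, so `applyVariableRule()` recodes them as presence. Coverage
filtering then removes traits evaluated in fewer than 80% of species and
species with data for fewer than 20% of the remaining traits
(`filterByCoverage()`, both thresholds configurable; traits are filtered
first, then species — both drop lists are reported).

Remaining gaps are filled by `imputeTraits()` with a probabilistic rule:
for a missing cell the zero probability is

$$P(0) = T(z)\; P(s)\; P(t),$$

where $P(s)$ and $P(t)$ are the zero fractions over the species' and the
trait's observed cells and $T(z)$ the global zero fraction with the full
$n_r \times n_c$ matrix as denominator. Cells with $P(0) > 0.5$ become 0,
otherwise 1 (an exact tie imputes 1; ties are logged). All statistics are
frozen on the pre-imputation matrix, making the result independent of
fill order. Two numerical consequences deserve note. First, $P(0)$ is a
product of three fractions, so it exceeds 0.5 only when the matrix, the
species, and the trait are all strongly zero-rich; on homogeneous
matrices most missing cells impute to presence. The rule beats the all-0
and all-1 constant encodings exactly when rows and columns are
heterogeneous — common traits paired with rare ones — which is the regime
of real compendia and of our recovery tests. Second, because the rule
uses only margins, it cannot exploit trait correlations; model-based
imputation is deliberately out of scope.

## The permutation null and association calls

Association significance comes from a fixed-margin null: the binary
matrix is randomized by checkerboard swaps — flipping random
$2{\times}2$ submatrices of the form $\begin{smallmatrix}1&0\\0&1\end{smallmatrix}$
or $\begin{smallmatrix}0&1\\1&0\end{smallmatrix}$ — which preserves every
row and column sum, i.e. each species' trait richness and each trait's
prevalence. For each pair the observed statistics are

$$\mathrm{Positive}_{obs} = \#(1,1), \qquad
  \mathrm{Negative}_{obs} = \#(1,0) + \#(0,1),$$

compared against their null means over the ensemble; the association
strength is $|\mathrm{obs} - \overline{\mathrm{exp}}|$. One-sided
empirical p-values use the add-one form $(1+k)/(n_{perm}+1)$ and are
Benjamini–Hochberg corrected separately within the positive-test and
negative-test families (a pooled family is available via `bhFamily`);
$q < 0.05$ is the default call, and a $q < 0.01$ sensitivity run is one
argument away. Non-significant pairs report the side with the larger
observed-minus-expected difference. A Wilson confidence interval on the
exceedance proportion accompanies every call as a stability diagnostic.
Trait–environment associations use the identical machinery with the
environment columns held fixed: only the trait matrix is randomized, and
environments with fewer than four member species are excluded.

### Swap counting and chain mixing

Two design points matter here. First, *what counts as a swap*. If failed
checkerboard draws are redrawn until `nSwaps` flips succeed, the chain's
transition probability out of a matrix is $1/c(A)$ per neighbour, where
$c(A)$ is that matrix's number of checkerboard units; detailed balance
then weights each matrix by $c(A)$. On the fully enumerable
$3{\times}3$ class with margins (2,1,1)/(2,1,1) the five members have
$c = 4,3,3,3,3$ and the bias shifts pair-count means by several percent.
Counting *attempted* draws instead (the trial-swap chain, our default
`swapMode = "attempts"`) makes the kernel symmetric and the stationary
distribution uniform on the margin class; the biased variant remains
available as `swapMode = "successful"` for comparison with legacy
pipelines.

Second, *how many swaps*. Each replicate restarts from the observed
matrix, so `nSwaps` is a burn-in and must scale with the number of 1s in
the matrix for the chain to forget its start. The function default of
1000 swaps matches the setting commonly used with compendium-scale
matrices, but our calibration experiments on 500 × 20 matrices
(≈5000 ones) use 20,000 attempted swaps, at which point null means agree
with exhaustive enumeration and with an independent trial-swap
implementation. Under-mixing is conservative — null means stay anchored
near the observed counts, deflating significance — so it costs power, not
type-I control.

A worked pipeline on synthetic data:

```{r pipeline, eval = FALSE}
sim <- simulateTraitMatrix(nSpecies = 500, nTraits = 20,
  modules = list(1:4), negativePairs = cbind(5, 6),
  missingRate = 0.06)
tm <- imputeTraits(filterByCoverage(applyVariableRule(sim$traits)))
assoc <- associateAllTraits(tm, nPerm = 10000, nSwaps = 20000)
head(significantPairs(assoc))
```

## Clustering association profiles

Traits with similar association patterns are grouped by building, for
each trait, a signed profile over all other traits (+strength for
significant positive pairs, −strength for negative, 0 otherwise;
`associationProfiles()`), computing Euclidean distances between profiles
and clustering with Ward's method (`ward.D2` by default; `ward.D` is
offered because historical implementations disagree). Cluster confidence
is a plain bootstrap probability: profile coordinates are resampled with
replacement, the clustering repeated, and each reference node scored by
how often its exact trait set reappears (`clusterSupport()`). The
multiscale/approximately-unbiased refinement is deliberately not
implemented: the plain bootstrap is sufficient for flagging the planted
block structure our tests require, and support values are reported as
probabilities, not p-values.

## Phylogenetic signal: the D statistic

For each binary trait, `dStatistic()` measures phylogenetic dispersion:
tip states are averaged up the rooted tree (each internal node the
unweighted mean of its daughters — branch lengths deliberately do not
enter the nodal estimation), and $d$ is the sum over nodes of absolute
daughter differences; a polytomy contributes the mean over its daughter
pairs, which keeps the scaling of resolved and unresolved nodes
comparable. $d_{obs}$ is scaled between two nulls,

$$D = \frac{d_{obs} - \overline{d_{Brownian}}}{\overline{d_{random}} -
  \overline{d_{Brownian}}},$$

so $D \approx 1$ for tip-shuffled (signal-free) traits and $D \approx 0$
for traits evolved by threshold Brownian motion: a continuous character
accrues Normal increments with variance proportional to branch length
and is thresholded at the quantile reproducing the observed prevalence
exactly. Departures from 1 and from 0 get two-sided permutation
p-values, $2\min(\text{tail}, 1-\text{tail})$ capped at 1. Both null
distributions depend on the states only through the tree and the number
of present tips, so `dStatisticAll()` caches them by prevalence — an
exact shortcut that makes genome-scale trait sets cheap. Species absent
from the tree are dropped per analysis with a logged count. Calibration
on 200-tip pure-birth trees (unit depth, 200 traits per mode, 500
simulations per null) centers $D$ within a few hundredths of 0 and 1.

## Variance partitioning

To attribute association structure, the species-level response is the
pair-indicator matrix: one column per trait pair, 1 when a species
carries both traits, 0 otherwise — the both-absent completion is the only
consistent binary choice (`buildResponse()`; its column sums equal the
positive pair counts). Explained variance is the linear redundancy
statistic with Ezekiel's adjustment,

$$R^2_a = 1 - (1 - R^2)\frac{n-1}{n-p-1},$$

computed for the seven unions of three predictor sets and decomposed by
inclusion–exclusion into unique, pairwise-shared, three-way and residual
fractions (`partition3()`; the seven fractions reproduce the full-model
$R^2_a$ to numerical precision, and mildly negative fractions are an
expected adjusted-$R^2$ artifact, reported as computed). The predictor
sets are: principal-coordinate axes of the tree's cophenetic distances,
retaining positive-eigenvalue axes to 95% cumulative mass (feeding a raw
$n \times n$ distance matrix to a regression would saturate the
adjustment — the retention rule is the main open choice here, so
`cumMass` is exposed and sensitivity across it is cheap to run);
per-species counts of utilized carbon sources per molecular category;
and the binary environment matrix. The regression is linear on the
binary response, matching standard redundancy-analysis practice, not a
logistic model.

## Environment deviations and the random-draw control

Whether associations persist *within* an isolation environment is tested
by restricting the matrix to the environment's members, building a fresh
swap ensemble on the submatrix (restricting global permutations would
not preserve the subset's margins), and averaging observed-minus-expected
deviations over the globally significant pairs — positive-direction pairs
contribute their co-occurrence counts, negative-direction pairs their
single-presence counts, reported separately (`environmentDeviation()`;
evaluating all pairs instead is a flag away). The control removes the
environment by drawing species at random at sizes 4, 11, 26, 47, 76,
147, 217 and running the *identical* code path — the control literally
calls the environment routine with an explicit species list
(`randomSamplingControl()`). On synthetic data where environments select
trait suites (traits independent given the environment), environment
deviations sit near zero while equal-sized random draws deviate by many
counts: the signature that associations ride on the environment. The
function default of 1000 draws per size matches the published design;
our test runs use 8–20 draws per size, which already separates the two
regimes by many standard deviations.

## Carbon-trait networks, communities, enrichment

Significant same-sign pairs among carbon traits form a weighted network
(`buildNetwork()`, weight = strength; vertices inserted in sorted order
so results are input-order invariant). Communities come from greedy
agglomerative modularity maximization (Clauset–Newman–Moore /
fast-greedy) on the weighted graph, with an unweighted mode available.
Greedy maximization is a heuristic: it provably attains the brute-force
maximum on the small structured graphs in our test battery, but it can
stop one merge short of a degenerate optimum (e.g. a star whose best
partition is the single community), which is a known property of the
algorithm and not corrected for. Community–category enrichment and the
positive-vs-negative enrichment among carbon pairs use two-sided Fisher
exact tests; the enrichment table is {carbon–carbon, other significant
pairs} × {positive, negative}, with a binomial 50/50 alternative behind
`method = "binomial"`.

## Gene presence and growth

`geneGrowthChi2()` tests gene presence against growth per carbon source
on the full 2×2 table without continuity correction (the Same/Different
columns it reports are summaries of that table, not the test input), BH
corrected across pairs. `coOccurrenceTest()` compares how often two
genes co-occur in a genome when they belong to the same trait community
versus different communities: events pooled over species × pairs
(per-pair averaging behind `pooled = FALSE`), equal-proportions
chi-squared with Yates correction by default. Closely related paralogs
should be collapsed into one column before testing, as is conventional
for gene families whose members cross-hybridize in homology searches.

## The synthetic-data generator

`simulateTraitMatrix()` draws species from a pairwise log-linear model —
the simplest generative family with controllable pairwise structure:
baseline log-odds target each trait's prevalence (with a mean-field
correction for interaction pressure), traits within a planted module
share interaction $+2$ (an $e^2$ odds boost), exclusion pairs $-2$
(chosen symmetric to the boost), sampled by 100 Gibbs sweeps from
independent starts. Defaults mirror the shape of the curated yeast
compendium: 784 species, 48 traits, 6% missing cells completely at
random, 6% of positive cells coded variable. `simulateTreeAndTraits()`
grows a unit-depth pure-birth tree and emits threshold-Brownian
(clumped) or tip-shuffled (signal-free) traits.
`simulateEnvironmentsAndGenes()` selects each environment's members as
the top scorers under a logistic perturbation of a trait-suite score —
sizes are exact and by default recycle the 4–217 control grid over 50
environments — and links genes to traits with a 5% flip noise.

What the generator does *not* emulate: phylogenetically correlated trait
matrices (traits and tree are generated independently unless you route
threshold-Brownian states into the matrix), non-random missingness
(real compendia lose data preferentially for rarely tested species), and
the curated dataset's exact margins. Tests passing on these fixtures
therefore validate the statistical machinery — margin preservation,
calibration, power, algebraic identities — not the biology of any
particular dataset.

## Problem sizes used in the validation suite

The shipped tests and the acceptance script run: margin checks on 50
random matrices; enumeration agreement on the 3×3 class with a
100,000-replicate ensemble (large enough that Monte-Carlo noise sits
well below the 1% agreement band); type-I and power runs on 500 × 20
matrices over 20 seeds at 1000 permutations × 20,000 attempted swaps;
D calibration on a 200-tip tree with 200 traits per mode and 500
simulations per null; brute-force modularity on six graphs of up to
eight nodes; exact-test agreement over all 1507 two-by-two tables with
n ≤ 12; and an environment-deviation contrast on a 300-species planted
scenario with 20 random draws. These sizes are the package's own
validation design; every default argument keeps the published analysis
settings (10,000 permutations, 1000 swaps, 1000 draws).

## Known limitations

* The imputation rule is margin-based and was adopted verbatim from the
  published procedure, including the $n_r \times n_c$ denominator of
  $T(z)$; it is not a statistical model of the data and its 0.5
  threshold is rarely crossed on homogeneous matrices.
* Empirical p-values are floor-limited at $1/(n_{perm}+1)$, so single
  isolated effects cannot clear FDR correction when the pair family is
  large and `nPerm` small; plan permutation counts accordingly.
* Greedy modularity can miss degenerate optima (see above); exact
  maximization is exponential and only used as a test oracle.
* Linear redundancy analysis on binary responses ignores the link
  function; fractions are comparative, not absolute variance shares of
  a generative model.
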