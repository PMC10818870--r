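---
title: "Methods: RMT-thresholded co-occurrence networks, stability and cohesion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RMT-thresholded co-occurrence networks, stability and cohesion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micronet)
```

# The analysis model

`micronet` treats a two-group amplicon study as a chain of estimators on a
taxa × samples count table.  This vignette documents the statistical model
behind each stage, the tunable parameters and their defaults, the
numerical choices that affect results, and what the synthetic generator
does and does not emulate.

## Preprocessing

Counts are rarefied to a common depth by multivariate hypergeometric
subsampling (without replacement); samples below the target depth are
dropped, not padded, because padding would fabricate reads.  The default
depth of 8509 reads matches the smallest per-sample ASV count of the kind
of dataset the package targets; it is a property of the data at hand and
should be set per study.  Prevalence filtering keeps taxa detected in at
least a fraction of samples — default 1/3, *inclusive* at the boundary
(8 of 24 samples passes), reading "at least a third" as a minimum.

Alpha diversity uses the standard definitions: Shannon
$H = -\sum_i p_i \ln p_i$ in natural-log units (some upstream pipelines
use $\log_2$; the base is an argument because the choice is a convention,
not a modelling decision), bias-corrected Chao1
$S_{obs} + F_1(F_1-1)/(2(F_2+1))$, and Good's coverage $1 - F_1/N$.
Shannon is conventionally an evenness-sensitive richness measure and
Chao1 a richness estimator; field usage sometimes swaps those labels, so
the functions are named for the estimator, not the interpretation.

Correlation inputs are $\ln(\text{relative abundance} + c)$ with
pseudocount $c$ equal to half the smallest nonzero relative abundance in
the table.  This rule is invariant to the table's overall scale and puts
zeros strictly below every observed value; a fixed pseudocount is
available when comparability across tables matters more.

## RMT threshold selection

The co-occurrence graph keeps taxon pairs with $|r| \ge s$, where $r$ is
the Pearson correlation of log abundances and $s$ is chosen by a random
matrix theory criterion rather than by convention.  The reasoning: a
correlation matrix dominated by sampling noise behaves like a Gaussian
orthogonal ensemble (GOE) matrix, whose unfolded eigenvalue spacings $d$
repel each other (Wigner surmise, $P(d) = \frac{\pi d}{2}
e^{-\pi d^2/4}$); a matrix reduced to genuine modular structure has
uncorrelated eigenvalues with Poisson spacings ($P(d) = e^{-d}$).
Scanning $s$ over a grid (default 0.30–0.95 in steps of 0.01) and testing
the spacing distribution at each point locates the noise-to-signal
transition.

Numerical choices, all exposed as arguments:

* **Unfolding.** The empirical cumulative spectral function is smoothed
  by a monotone piecewise-cubic (Fritsch–Carlson) spline through
  $\max(5, \lfloor\sqrt{n}\rfloor)$ knots and each eigenvalue is mapped
  through it, giving spacings with unit mean density.  Monotone splines
  avoid the oscillation that global polynomial fits produce at spectrum
  edges.
* **Spacing histogram.** 20 equal bins on $[0, 3]$ plus one overflow
  cell; chi-square statistics against both reference laws use the
  overflow cell too, so no spacing is silently discarded or
  double-counted.
* **Decision rule.** The selected threshold is the smallest $s$ with
  Poisson goodness-of-fit $p > 0.05$ *and* GOE chi-square above Poisson
  chi-square, among scans retaining at least `min_eigs = 50` taxa
  (spacing statistics below ~50 eigenvalues are too noisy to test).  If
  no grid point qualifies the scan returns the Poisson-chi-square
  minimiser flagged `degraded`; if nothing survives anywhere it returns
  `NA` flagged `unreliable`.  Thresholds whose surviving spectrum is too
  degenerate to unfold (a handful of identical components) are treated
  as unfittable rather than as evidence.
* **Sign handling.** Thresholding is on $|r|$; the signed correlation is
  kept as an edge attribute because the stability stage needs it.

With 24 samples the sampling spread of $r$ is wide
($\mathrm{sd} \approx (n-3)^{-1/2} \approx 0.22$), so even pure-noise
tables contain pairs correlated above 0.5.  The scan therefore cannot —
for any implementation — produce networks free of noise edges at this
sample size; what it does guarantee, and what the tests assert, is that
planted strongly-correlated structure ($\rho \approx 0.95$) is retained
essentially completely, and that with adequate sampling (n = 100) noise
tables yield near-empty networks.

## Topology and node roles

Average degree is the exact identity $2E/N$; average distance is the mean
shortest-path length over *connected* node pairs, because RMT-thresholded
networks routinely have several components and averaging over
disconnected pairs would be infinite or arbitrary (the component count is
reported alongside).  Modules come from fast-greedy modularity
maximisation on the unweighted graph — deterministic, so repeated fits
agree without seed juggling.  Node roles use the molecular-ecology
Zi–Pi plane: within-module degree z-score
$Z_i = (k_{i,\text{within}} - \bar{k}_m)/s_m$ (zero when a module's
within-degrees have no spread) and participation coefficient
$P_i = 1 - \sum_m (k_{im}/k_i)^2$, with module hubs at $Z_i > 2.5$,
$P_i \le 0.62$ — the published cut-offs that the hub-removal simulations
presuppose.

## Robustness

Robustness is the proportion of the original nodes that remain after a
removal event plus secondary extinctions.  Two removal modes: random
(default 50% of nodes, 100 replicates, replicate values kept so groups
can be compared by Student's t) and targeted (the top 3 module hubs,
ranked by Zi descending with ties broken by Pi ascending then node id —
fully deterministic).  Two cascade rules are shipped because the
literature uses both and the choice is consequential:

* `degree_zero` (default): a node whose last neighbour disappears goes
  extinct.  One pass suffices — removing an isolated node cannot isolate
  another.
* `abundance_threshold`: a node goes extinct when its abundance-weighted
  link sum falls below `theta` (default 0.5) of its original value,
  iterated to a fixed point.

With cascades off, robustness is identically $1 - \lfloor fN \rfloor/N$,
which the tests use as an exact contract, and Monte-Carlo robustness is
checked against exhaustive enumeration over all removal sets on small
graphs.

## Connectedness and cohesion

For each taxon pair, observed Pearson correlations of relative abundances
are corrected by a taxa-shuffle null: each taxon's abundance vector is
permuted across samples independently (200 iterations by default; the
null-mean standard error is below 0.01 at 24 samples) and the mean null
correlation is subtracted.  A taxon's positive (negative) connectedness
is the mean of its positive (negative) corrected correlations; a sample's
cohesion is the abundance-weighted sum
$C^\pm_i = \sum_j a_{ij} c^\pm_j$.  Cohesion is therefore linear in
abundance, bounded by the extreme connectedness values, and sign-fixed
($C^+ \ge 0 \ge C^-$) by construction.

Because $c^+$ averages only the positive half of the corrected
correlations, its magnitude under pure noise is the half-normal mean
$\approx 0.8/\sqrt{n-1}$ — about 0.08 at 100 samples — and shrinks to
zero only as $n$ grows.  The meaningful null-consistency statement, which
the tests assert, is that the *net* connectedness $c^+ + c^-$ is centred
at zero: the null correction removes systematic (e.g. compositional)
signal, not sampling noise.  Cohesion correlations are computed on
relative abundances without log transform, following the cohesion
literature rather than the network pipeline; a log-scale variant can be
obtained by passing a transformed table.  By default all
prevalence-filtered taxa enter the calculation, not only network members.

## Group statistics

The Wilcoxon rank-sum test uses exact enumeration of all group
assignments (with midrank ties) when the combined sample size is at most
12, and the tie- and continuity-corrected normal approximation above
that; 12 + 12 designs use the approximation, where tied ranks from zero
counts are common.  BH adjustment is applied within one feature family at
a time (each community analysed separately).  PERMANOVA uses Anderson's
sums-of-squared-distances pseudo-F with free label permutations
(single-factor design) and $p = (1 + \#\{F^\* \ge F\})/(B+1)$, or the
exact proportion over all distinct splits when enumeration is feasible.
Note that BH re-applied to already-adjusted values is *not* the identity
(step-up re-averages the sorted sequence); the invariants worth testing
are monotonicity, `adjusted >= raw`, and the fixed point on all-equal
inputs.

## The synthetic generator

`synthetic_design()` emulates the target study's shape: two groups of 12
samples, log-normal sequencing depths (mean 15623, sd 2217, floored at
1000), 150 taxa with log-normal baseline abundances (sd 1.5 on the ln
scale), two planted blocks of 15 taxa at within-block latent correlation
0.95, ten differential taxa at $\pm$2 log2-fold change, and one taxon
structurally absent from the LFS group.  Latent log abundances are
multivariate Gaussian with an exchangeable within-block factor structure
($z = \sqrt{\rho}\,g_b + \sqrt{1-\rho}\,\varepsilon$, per-sample noise sd
0.7 — roughly two-fold sample-to-sample variation, typical of a stable
genus-level community), mapped to a composition by softmax and realised
by one multinomial draw per sample, so column sums equal the sampled
depths exactly.  Structural zeros are imposed on the composition before
the draw.  Planted structure (block members, differential and absent
taxa) is given baseline log abundance $N(1, 0.5)$ — the 0.2–1.6%
relative-abundance scale at which such taxa are actually observed — so
the planted signal is identifiable rather than censored by sequencing
depth; the remaining taxa carry the full abundance spread, including the
rare tail.

What the generator does **not** emulate: taxonomic structure, phylogeny
(hence no UniFrac), overdispersion beyond multinomial (no Dirichlet
noise), depth-abundance artefacts, chimeras, or batch effects.  Passing
tests on synthetic data therefore demonstrate that the estimators recover
known structure under compositional multinomial sampling — not that any
particular biological conclusion from real data is correct.

## Problem sizes and determinism

The test and acceptance runs use the study-scale community (150 taxa,
24 samples) for end-to-end checks, 500×500 matrices for the
random-matrix limits, graphs of up to 8 nodes for exhaustive removal
enumeration, and 20–50 seed replicates for Monte-Carlo properties —
sizes at which every check runs in seconds to a few minutes on one CPU.
All randomness flows through explicit integer seeds; `run_pipeline()`
derives per-stage seeds from one global seed by fixed offsets, and
identical configurations produce byte-identical artifacts.

## Known limitations

* Pearson-on-log-abundance correlation does not correct for
  compositionality (SparCC/SPIEC-EASI-style estimators are out of
  scope); the cohesion null model absorbs the mean compositional bias
  but not its variance.
* Spacing statistics need ~50 surviving taxa; small communities fall
  back to the degraded selection rule.
* The scan's decision rule fires at the *onset* of Poisson behaviour;
  with few samples that onset can sit at moderate thresholds where some
  noise edges remain (see the RMT section).
* PERMANOVA is single-factor with free permutations; stratified or
  repeated-measures designs are not supported.
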