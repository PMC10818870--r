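# micronet

Co-occurrence network inference and stability analysis for microbial
communities, built for two-group amplicon studies (e.g. diarrheic vs
healthy animals sampled at 16S ASV resolution).

Microbiome group comparisons increasingly rest not on which taxa differ in
abundance but on how the *community network* differs: how densely taxa
co-occur, how modular the network is, how it degrades when members are
removed, and whether the community behaves cooperatively or competitively.
`micronet` implements that analysis chain end to end:

1. **Preprocessing** — prevalence filtering (taxa detected in ≥ ⅓ of
   samples), rarefaction without replacement, alpha diversity (Shannon,
   bias-corrected Chao1, Good's coverage).
2. **Network inference** — Pearson correlations of log-transformed
   relative abundances, with the correlation cut-off *s* chosen
   automatically by a random matrix theory (RMT) criterion: the
   nearest-neighbour spacing distribution (NNSD) of the thresholded
   matrix's unfolded eigenvalues transitions from the GOE Wigner surmise
   `P(d) = (πd/2)·exp(−πd²/4)` (noise-dominated) to Poisson
   `P(d) = exp(−d)` (modular signal); the selected cut-off is the smallest
   *s* where the Poisson fit is accepted (χ² goodness of fit, p > 0.05)
   and beats the GOE fit.
3. **Topology** — node/edge counts, average degree `2E/N`, average
   shortest-path distance, greedy-modularity modules, and Zi–Pi node
   roles (within-module degree z-score vs participation coefficient,
   module hubs at `Zi > 2.5`, `Pi ≤ 0.62`).
4. **Stability** — robustness (proportion of nodes remaining) under
   random removal of 50% of nodes or targeted removal of the top module
   hubs, with secondary-extinction cascades; per-sample positive and
   negative **cohesion** `C±_i = Σ_j a_ij · c±_j`, where a taxon's
   connectedness `c±_j` is its average positive/negative pairwise
   correlation after subtracting a taxa-shuffle null model.
5. **Statistics** — Wilcoxon rank-sum with Benjamini–Hochberg FDR (exact
   enumeration with midrank ties at small n), Spearman screens against
   phenotypes, Bray–Curtis distances, one-factor PERMANOVA
   (`pseudo-F = (SS_A/(a−1))/(SS_W/(n−a))` with permutation or exhaustive
   p), and Student's t for stability metrics.
6. **Digestibility** — apparent total-tract digestibility from the
   acid-insoluble-ash marker: `ATTD% = (1 − (Ad·Nf)/(Af·Nd)) × 100`.

A synthetic two-group generator plants known correlated taxon blocks,
differential taxa, structural zeros and phenotype couplings into
compositional count tables, so the whole chain is testable against known
truth without any external data.

## Worked example

```r
library(micronet)

sim <- generate_counts(synthetic_design(seed = 1))  # 150 taxa, 12+12 samples
fit <- conet(sim$counts)                            # full network fit
fit
#> Co-occurrence network (RMT-thresholded Pearson correlations)
#>   taxa: 150 supplied, 150 after prevalence filter
#>   threshold: 0.48
#>   nodes: 139  edges: 444  avg degree: 6.39  avg distance: 4.53
#>   modules: 9 (modularity 0.661); hubs: 1 module, 0 network

rob <- robustness_random(fit$graph, fraction = 0.5, replicates = 100,
                         seed = 1)
rob
#> Network robustness (random removal, cascade = degree_zero): 0.4192 +/- 0.0227 sd over 100 replicates

rel  <- relative_abundance(sim$counts)
coh  <- cohesion(rel, connectedness(rel, null_reps = 200, seed = 1))
head(coh, 3)
#>   sample_id cohesion_pos cohesion_neg
#> 1    LFS_01    0.2080605   -0.1698501
#> 2    LFS_02    0.1830263   -0.1655565
#> 3    LFS_03    0.2063905   -0.1703326
```

The threshold 0.48 is where the correlation matrix's eigenvalue spacings
stop looking like a random (GOE) matrix; the robustness value 0.42 means
that after removing half the nodes at random, a further ~8% of nodes on
average lose all partners and go secondarily extinct.  Positive cohesion
around 0.2 reflects the planted co-occurring blocks; its sign contracts
(`C+ ≥ 0 ≥ C−`) hold on any input.

`run_pipeline(config, out_dir)` drives the whole chain (simulate → prep →
per-group networks → topology → stability → statistics → digestibility)
from one YAML/JSON config and writes per-stage TSVs plus a checksummed
manifest; reruns with the same config are byte-identical.

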