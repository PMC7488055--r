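# coaldelim

Coalescent-based species delimitation for multilocus data: single-threshold
GMYC on ultrametric gene trees, guided Bayesian delimitation under the
multispecies coalescent (MSC) by reversible-jump MCMC on a guide tree, a
censored-coalescent data simulator, and an integrative-evidence stage.

## What it does

Taxonomists testing candidate species limits — for example in a genus of
cyanobacterial lichens sampled for one mitochondrial and three nuclear loci —
typically combine two coalescent approaches:

1. **GMYC.** On one ultrametric gene tree, fit a threshold age `T` such that
   nodes older than `T` are speciation events of a Yule process with rate
   `lambda1 * n^p1` and each subtree younger than `T` is an independent
   coalescent cluster with rate `lambda2 * [n_j(n_j - 1)]^p2`; each
   inter-node interval contributes `b_i * exp(-b_i x_i)` with `b_i` the
   combined rate. The maximum-likelihood threshold delimits entities
   (clusters plus singletons), tested against a one-species null
   (`2 * (logL - logL0) ~ chi-square, df = 3`).

2. **Guided MSC delimitation.** Given a rooted binary guide tree over
   candidate species, every assignment of collapsed/split states to its
   internal nodes (a node may be split only if its parent is) is a
   delimitation model; the 8-species guide shape used in the examples admits
   21 models. With per-locus gene trees treated as data, the censored
   coalescent gives the exact likelihood; thetas (`4*Ne*u`) carry
   inverse-gamma priors with shape 2 and mean 0.1 or 0.01 and are integrated
   out analytically; the root age has the same prior family and interior
   ages a flat order-constrained prior. A reversible-jump sampler moves
   across models, and support for each split is summarised as a posterior
   probability under every combination of the prior grid. A split is
   *well supported* only at PP > 0.95 under **all four** prior settings.

Everything is verifiable without external data through a synthetic
generator (Yule species trees, censored-coalescent gene trees, JC69
alignments, categorical traits with tunable species fidelity) whose
defaults emulate an 8-species / 63-individual / 4-locus study.

## Worked example

```r
library(coaldelim)

# simulate one study-scale dataset with known truth
sc <- sim_scenario(s = 4, tau_root = 0.5, theta_scale = 0.01,
                   n_per_species = c(4, 3, 3, 2), n_loci = 2,
                   heredity = c(0.25, 1), trait_fidelity = 1, seed = 3)
cfg <- pipeline_config(scenario = sc, generations = 3000, pre_burnin = 300,
                       runs_per = 2, seed = 11)
rep <- run_pipeline(cfg)
rep$msc$table
#>                    combo tau_mean theta_mean best_model best_pp max_split_discrepancy converged
#> 1   tau(0.1), theta(0.1)     0.10       0.10        111 1.00000                0.0000      TRUE
#> 2  tau(0.1), theta(0.01)     0.10       0.01        111 1.00000                0.0000      TRUE
#> 3  tau(0.01), theta(0.1)     0.01       0.10        111 0.99475                0.0015      TRUE
#> 4 tau(0.01), theta(0.01)     0.01       0.01        111 0.99900                0.0020      TRUE
rep$evidence$supported$supported
#> [1] "5" "6" "7"
rep$evidence$trait_test$p
#> [1] 0.002
```

The four rows are the prior-grid combinations (tau mean, theta mean), each
averaged over two chains; `best_model = "111"` means all three guide-tree
nodes split, i.e. the simulated 4-species truth; the three supported splits
are the guide-tree nodes (ape ids 5-7) whose PP exceeds 0.95 under every
prior; the permutation test confirms the trait-partition association
(fidelity 1 in this scenario).

Individual stages are available directly: `fit_gmyc()`, `gmyc_lrt()`,
`gmyc_confidence_set()`, `gmyc_partition()`; `run_rjmcmc()`,
`exhaustive_posterior()` (the small-tree validation oracle),
`prior_sensitivity_scan()`; `simulate_truth_bundle()`;
`adjusted_rand_index()`, `trait_association_test()`,
`aggregate_supported_species()`. A thin command-line wrapper ships in
`inst/cli/coaldelim.R`.

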