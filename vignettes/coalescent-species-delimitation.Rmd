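---
title: "Coalescent species delimitation with coaldelim: models, priors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coalescent species delimitation with coaldelim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coaldelim)
```

## The problem

Candidate species boundaries inferred from morphology are routinely tested
against multilocus sequence data with two complementary coalescent methods:

* **GMYC** (generalized mixed Yule-coalescent): on a single ultrametric gene
  tree, find the threshold age separating between-species (Yule) branching
  from within-species (coalescent) branching, and test the resulting
  delimitation against a one-species null.
* **Guided Bayesian delimitation under the multispecies coalescent (MSC)**:
  on a fixed guide tree over candidate species, compare every "collapse some
  nodes" model by reversible-jump MCMC, using multilocus gene trees.

`coaldelim` implements both, together with a censored-coalescent simulator
that generates data with known truth at the scale of a small multilocus
study of lichen-forming fungi (8 candidate species, 63 individuals sampled
unevenly, 4 loci of which one is mitochondrial), and an integrative-evidence
stage that confronts the molecular delimitations with categorical traits
such as photobiont (*Nostoc*) morphotypes.

## The GMYC model

The input is a binary ultrametric tree with node ages measured from the
present in expected substitutions per site (`clock_tree`). For a threshold
age $T$, every node at or above $T$ is a speciation event among the
"species-level" branches and every maximal subtree younger than $T$ is a
coalescent cluster. Between successive node ages (interval $i$, waiting time
$x_i$) the total branching rate is

$$b_i = \lambda_1\, n_i^{p_1} + \lambda_2 \sum_j \left[n_{ij}(n_{ij}-1)\right]^{p_2},$$

where $n_i$ counts the species-level branches present in the interval and
$n_{ij}$ the lineages of cluster $j$. Each interval contributes
$b_i e^{-b_i x_i}$, the classic single-threshold mixed likelihood. The
threshold is profiled over every internal-node age *plus* the above-root
configuration; the latter is exactly the one-species null (a single
coalescent), so the null is nested in the candidate set and
$\log L \ge \log L_0$ by construction. The likelihood-ratio test uses
$2(\log L - \log L_0) \sim \chi^2_3$ by default (configurable `df`), with
the usual `*`/`**`/`***` stars at 0.05/0.01/0.001, and the
2-log-likelihood confidence set reports the range of entity counts within
`delta = 2` of the maximum.

**Why the exponents are fixed by default.** The fully flexible variant
estimates $p_1, p_2$. We found, by simulation, that a free diversification
exponent lets extreme thresholds mimic the null ($n^{p_1}$ with
$p_1 \approx 2$ reproduces pairwise coalescent rates), which inflates the
type-I error of the LR test (0.14 instead of ~0.05 in 150 null
simulations) and drags recovery of a known 5-species truth down to ~0.7.
With $p_1 = p_2 = 1$ — a pure Yule process against pure Kingman
coalescents — the same simulations give type-I error within the nominal
band and >0.9 recovery. `fit_gmyc(..., fix_exponents = FALSE)` restores
the flexible variant.

**What recovery requires.** GMYC can only separate processes whose time
scales differ. In our simulations with 5 species, 4 individuals each, the
ML solution recovers the true number of species >90% of the time when the
*youngest* speciation is still well above the within-species coalescent
depths (we use root age 2 with theta 0.005, i.e. a 400-fold scale
separation). When the scales overlap (root age / theta near 20, so that
the most recent Yule split falls inside the coalescent depths), no
threshold method can recover the truth reliably; the package's tests
exercise the separated regime and the vignette flags the other one as an
intrinsic limit, not an implementation artefact.

## The multispecies-coalescent stage

### Model space

A `guide_tree` is a rooted binary tree over candidate species. A
delimitation model assigns split/collapsed to each internal node, a node
being splittable only if its parent is split. The number of such models
satisfies $f(\mathrm{tip}) = 1$, $f(v) = 1 + f(l)f(r)$; the 8-species guide
shape used throughout the examples (a two-species clade sister to two
three-species clades) admits exactly 21 models. Model prior 1 is uniform
over the models; prior 0 weights each model by the number of labelled
histories of its induced species tree, $(n-1)!/\prod_v k_v$.

### Likelihood: gene trees as data

The package deliberately treats the per-locus ultrametric gene trees as
*data* (they are estimated upstream by clock-model Bayesian inference, or
simulated), so the MSC likelihood is the exact censored-coalescent density
of the gene trees given the delimitation, the divergence ages $\tau$ and the
population sizes $\theta = 4N_e u$:

$$\log L = \sum_{p,\ell} \left[c_{p\ell}\,\log\frac{2}{h_\ell \theta_p}
  - \frac{B_{p\ell}}{h_\ell \theta_p}\right],$$

with $c_{p\ell}$ the number of coalescences in population $p$ at locus
$\ell$, $B_{p\ell} = \sum n(n-1)\Delta t$ the pairwise waiting integral
(ages rescaled by the locus rate $r_\ell$), and $h_\ell$ the per-locus
heredity scalar (1/4 for a haploid maternally inherited mitochondrial
locus; a `diploid` switch doubles all scalars for the corresponding
sensitivity analysis). A coalescence joining populations that have not yet
merged makes the configuration infeasible (likelihood zero) — this is the
"censoring" at the heart of the MSC. Sequence-level likelihoods (sampling
gene trees inside the chain) are out of scope by design; this keeps every
stage exact and desk-scale.

### Priors and analytic theta integration

Every $\theta$ has an inverse-gamma prior with shape $\alpha = 2$ (diffuse)
and rate chosen so the mean is 0.1 or 0.01 — the standard two-magnitude
grid. Because the inverse gamma is conjugate to the coalescent density,
$\theta$ integrates out analytically per population:

$$M_p = 2^{C_p}\,\prod_\ell h_\ell^{-c_{p\ell}}\;
  \frac{\beta^\alpha\,\Gamma(\alpha + C_p)}
       {\Gamma(\alpha)\,(\beta + B'_p)^{\alpha + C_p}},$$

with $C_p = \sum_\ell c_{p\ell}$ and $B'_p = \sum_\ell B_{p\ell}/h_\ell$.
The tests verify this against adaptive quadrature to 1e-8 relative error.
The root age has the inverse-gamma prior; conditional on it the interior
split ages are jointly flat on the order-compatible region, with the exact
normaliser $\prod_v n_v / \tau_\mathrm{root}^k$ ($n_v$ = split nodes in the
clade of $v$). The exact normaliser matters: reversible-jump moves compare
states of different dimension, and an unnormalised interior prior would
bias the model posterior. A Monte-Carlo order-probability test checks the
constant for 3-5 species.

### The sampler and its oracle

The chain alternates dimension moves and within-model moves. A split move
picks a splittable node uniformly and proposes its age uniformly on
$(0, \min(\tau_\mathrm{parent}, U_v))$ where $U_v$ is the youngest
coalescence (across loci) whose species MRCA is that node — proposals
outside that range would be rejected with certainty, so the bound is used
and appears in the Hastings ratio. The root age, which has no parent bound,
is proposed from its prior. Join moves are the exact reverse. Within a
model, ages get log-scale multiplier updates. When $\theta$ is sampled
instead of integrated, dimension moves draw the affected $\theta$s from
their conditional inverse-gamma posteriors (conjugate proposals) and
within-model moves mix multiplier updates with a periodic conjugate
refresh. Algorithm 1 differs from algorithm 0 by an extra multiplier
refresh of the parent age after each accepted dimension move; both target
the same posterior.

Correctness is established against `exhaustive_posterior()`, which
computes each model's marginal likelihood on guide trees of up to 4
species by tensor Gauss-Legendre quadrature over the divergence ages
($\theta$ integrated analytically). Two numerical points matter: each age
is integrated only over its feasible range so the integrand is smooth (the
feasibility cutoff is otherwise a discontinuity that Gauss-Legendre
resolves poorly), and the quadrature order is raised for low dimension
(256/96/40 nodes for 1/2/3 dimensions) because the likelihood is sharply
peaked relative to the prior. The acceptance tests require total-variation
distance below 0.05 between sampler and oracle on strongly and weakly
informative scenarios, prior recovery with zero loci, and agreement within
0.02 per-split PP between the integrated and sampled-theta chains.

### Prior sensitivity and the conservative support rule

`prior_sensitivity_scan()` runs the four (tau mean, theta mean)
combinations of the 0.1/0.01 grid, each with two independent chains; the
per-split posterior probabilities are averaged per combination and the
maximum between-run discrepancy is reported, never silently hidden. A
split is *well supported* only when its PP exceeds 0.95 under **all four**
prior settings (strict inequality); splits crossing the threshold under
some settings only are flagged prior-sensitive. Supports are generally
expected to weaken as the theta prior mean grows — a larger assumed
population size explains shared polymorphism without speciation — and the
scan output lets the user see that directionality rather than asserting it.

## The synthetic-data generator

`sim_scenario()` fixes the study conditions; `simulate_truth_bundle()`
draws one replicate. Defaults emulate the target study's scale:

| parameter | default | meaning |
|---|---|---|
| `s` | 8 | candidate species |
| `n_per_species` | 14,12,10,8,7,5,4,3 (sum 63) | uneven sampling |
| `n_loci` | 4 | one mitochondrial + three nuclear |
| `heredity` | 1/4, 1, 1, 1 | effective-theta scalars |
| `tau_root` | 0.1 | root divergence (subst./site) |
| `theta_scale` | 0.05 | mean of IG(2, ·) for true thetas |
| `locus_rates` | Dirichlet, mean exactly 1 | relative rates |
| `trait_fidelity` | 0.9 | P(individual shows modal trait) |
| `seq_lengths` | 825, 624, 621, 1962 | locus widths for JC69 alignments |

The species tree is Yule (uniform labelled histories; waiting times
rescaled so the root age is exact). Gene trees follow the censored
coalescent: within a population, each lineage pair coalesces at rate
$2/(h_\ell\theta)$; at each divergence age surviving lineages merge into
the ancestral population; ages are finally multiplied by the locus rate.
Sequences evolve under JC69 (via `phangorn::simSeq`) and traits are
categorical with a per-species modal level shown with probability
`trait_fidelity`.

What the generator does *not* emulate: gene-tree estimation error (gene
trees are handed to the MSC stage exactly), recombination within loci,
gene flow after divergence, and selection. Passing tests therefore
demonstrate correctness of the inference machinery under the model's own
assumptions, not robustness to their violation on real data.

## Numerical choices and degenerate inputs

* Ultrametricity: trees whose relative root-to-tip spread exceeds the
  tolerance (default 1e-6) are rejected; within tolerance, ages are
  snapped by averaging. Polytomies are rejected with a pointer to
  `resolve_polytomies()`, which orders them deterministically with small
  age offsets.
* Tied node ages in GMYC are separated by a deterministic relative jitter
  of 1e-9 before profiling.
* Per-threshold GMYC optimisation uses box-constrained quasi-Newton from
  three deterministic starts (one-dimensional cases use Brent), exponents
  bounded to [0.05, 4] when estimated.
* Populations with no coalescent content contribute factor 1 to the
  marginal likelihood and carry no theta when integrated; the
  theta-sampling chain carries a prior-distributed theta for every current
  population (harmless, and it keeps the dimension bookkeeping simple).
* The parsimony-informative counter treats only unambiguous A/C/G/T as
  states; gaps and IUPAC ambiguity codes never contribute. The definition
  is deliberately the common convention, stated here because published
  counts rarely specify their handling.
* All samplers and simulators are exactly reproducible given a seed;
  pipeline stages derive per-stage seeds from the global seed by fixed
  offsets modulo $2^{31}-1$.

## Problem sizes used by the test-suite

Unit and acceptance tests run scaled-down schedules chosen as the smallest
sizes at which each property is decisively measurable: oracle comparisons
use 3-species, 2-locus scenarios with 40,000-60,000 generations; GMYC
calibration uses 500 null trees of 20 lineages; parameter-recovery
coverage uses 100 replicates of the full 8-species scenario with 3,000
generations at the true model (the conjugate structure makes the
fixed-model posterior mix in hundreds of iterations). The full-scale
schedule mirroring common practice (10,000 + 200,000 generations sampled
every 2; 100,000 + 1,000,000 sampled every 5 for 13-species-scale runs)
remains the default of `mcmc_config()` and `build_config_matrix()`.

## Known limitations

* Unguided delimitation (joint species-tree inference, "A11") and its
  topology priors 2-3 are not implemented; the model space is always
  conditional on a guide tree, and `build_config_matrix()` marks unguided
  entries as unsupported by the core sampler.
* Locus rates are inputs, not parameters of the chain; with real data they
  must come from the upstream gene-tree analysis.
* The GMYC stage analyses one tree; uncertainty in the gene tree itself is
  not propagated.
* Treating gene trees as data ignores their estimation error; posterior
  probabilities on real data are accordingly optimistic, one reason the
  evidence stage insists on support under all prior settings and on
  independent trait evidence.
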