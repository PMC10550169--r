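---
title: "Inferring connectome wiring rules with simulation-based inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring connectome wiring rules with simulation-based inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wiresbi)
```

# The inference problem

A wiring rule is a stochastic recipe that turns the *structure* of neural
tissue into a *connectome*. The structural substrate here is synapse-free:
a regular 3D grid of cubic subvolumes in which every neuron deposits
counts of presynaptic boutons (`pre`) or postsynaptic targets (`post`),
with `postAll` the per-subvolume total of postsynaptic counts. A rule with
parameters $\theta$ maps this substrate to synapse counts; summarizing the
simulated connectome the way experimenters measure it — population
connection probabilities from ~50 probed pairs — yields simulated data
$x$ comparable to a measured vector $x_{\mathrm{obs}}$. Because the
likelihood $p(x \mid \theta)$ of that pipeline is intractable, we estimate
the posterior $p(\theta \mid x_{\mathrm{obs}})$ from simulations alone:
draw $\theta_i$ from the prior, simulate $x_i$, and train a conditional
density estimator $q_\phi(\theta \mid x)$ on the pairs. This is neural
posterior estimation (NPE); it is amortized, meaning one trained estimator
serves any observation without retraining.

# The three wiring rules

**Parametrized dense structural overlap.** Synapse counts per
neuron-pair-subvolume combination are
$c_{ijk} \sim \mathrm{Poisson}\!\big(\mathrm{DSO}_{ijk}(\theta)\big)$ with
$$\mathrm{DSO}_{ijk}(\theta) =
\frac{pre_{ik}^{\theta_{pre}} \cdot post_{jk}^{\theta_{post}}}
     {postAll_k^{\theta_{postAll}}},$$
equivalently a Poisson GLM with log-link on the feature vector
$X_{ijk} = (\log pre_{ik},\, \log post_{jk},\, -\log postAll_k)$. The
identity $\exp(\theta^\top X_{ijk}) = \mathrm{DSO}_{ijk}(\theta)$ is the
module's central invariant and is tested to $10^{-9}$ relative tolerance.
$\theta = (1,1,1)$ recovers the unparametrized rule. Combinations with
`pre = 0` or `post = 0` contribute rate zero and never enter the feature
matrix, so logs of zero are never evaluated. Rates are clipped at $10^6$
before sampling (with a warning): the Gaussian prior
$\theta \sim \mathcal N\big((1,1,1)^\top, 0.05\,I\big)$ admits draws whose
exponentiated rates would otherwise overflow.

**Neuron-level threshold rule.** With $v_{ij}$ the number of subvolumes
containing presynaptic structure of $i$ *and* postsynaptic structure of
$j$, the rule connects the pair iff $v_{ij} > \theta_{thres}$ (strict
inequality, applied literally), $\theta_{thres} \sim U(0, 100)$. Note the
boundary subtlety: at $\theta_{thres} = 1$ the strict rule requires
$v \ge 2$, whereas Peters' proximity hypothesis is the predicate
$v \ge 1$. We expose the latter separately as `peters_rule_neuron()`
rather than conflating the two.

**Synapse-level Bernoulli rule.** Every co-occupied $(i,j,k)$ carries an
independent $\mathrm{Bernoulli}(\theta_{prob})$ synapse,
$\theta_{prob} \sim \mathrm{Beta}(2,2)$. A pair with $m$ co-occupancies
connects with probability $1 - (1-\theta_{prob})^m$; $\theta_{prob} = 1$
is Peters' rule at the subcellular scale.

All Poisson and Bernoulli draws are independent given the substrate.
Pairwise connectivity means "at least one synapse", so for the DSO rule
the summary simulator draws the pair indicator exactly as
$\mathrm{Bernoulli}\!\big(1 - e^{-\Lambda_{ij}}\big)$ with
$\Lambda_{ij} = \sum_k \mathrm{DSO}_{ijk}(\theta)$ — distributionally
identical to materializing every count, at a fraction of the cost. The
50 probed pairs per population are resampled per simulation (without
replacement, matching paired-recording practice), so pair-sampling noise
is part of the data-generating process the estimator learns.

# The synthetic structural substrate

The structural model the original analyses run on — a reconstruction-based
digital tissue model with hundreds of thousands of neurons — is not
redistributable, so the package generates a synthetic substrate with the
same statistical interfaces. Defaults (the package's study conditions,
chosen once):

* grid $20^3$ subvolumes of 5 µm edge (a 100 µm tissue block); subvolume
  centers at $(\mathrm{idx} + 0.5)\cdot\mathrm{edge}$ with 0-based
  indices; the z axis doubles as cortical depth for depth profiles;
* one presynaptic thalamic-like population (40 neurons) plus seven
  postsynaptic cortical populations (23 neurons each) restricted to
  layer-like depth bands;
* footprints are *sparse spherical envelopes*: all subvolumes within a
  radius of a uniformly placed soma form the envelope, and each is
  occupied independently with probability `occupancy` (axons: wide radius
  30 µm, sparse 0.07; dendrites: radius 25 µm, denser 0.7). Sparse
  occupancy emulates branching arbors, which visit only a fraction of
  their envelope; it is what lets a pair overlap with high probability
  while sharing only a handful of subvolumes;
* counts per occupied subvolume are shifted negative binomial,
  $1 + \mathrm{NB}(\mu - 1, \mathrm{size})$ with means 2 (pre) / 3 (post)
  and dispersion 2 — occupancy implies at least one structure, and counts
  are overdispersed as subcellular counts tend to be. Dispersion
  $\infty$ gives the shifted-Poisson special case.

These values were fixed by a prior-predictive criterion, not fitted: under
the $\mathcal N((1,1,1), 0.05 I)$ prior the simulated connection
probabilities should sweep a wide range (here roughly 0 to 0.55) with
per-pair Poisson totals $\Lambda_{ij}$ concentrated in the informative
transition zone $\approx 0.3$–$3$ rather than saturating at 0 or 1. A
substrate outside that zone makes every rule look like a pure proximity
rule and the exponents unidentifiable. What the synthetic substrate does
*not* emulate: real morphologies, cell-type-specific arbor shapes,
inhibitory/excitatory asymmetries, or the true (unpublished) marginal
count distributions — so passing tests certify the inference machinery,
not any biological claim about real tissue.

Seeding is hierarchical: one master seed, with independent named
substreams (model generation, observation simulation, training, posterior
draws), all below $2^{31}$.

# The estimator

No flow-based SBI engine exists for R, so the conditional density
estimator is authored in the package as a mixture-density network (MDN) —
one of the two standard NPE families. A two-hidden-layer tanh MLP (50
units per layer) maps the z-scored observation to the parameters of a
mixture of $K$ full-covariance Gaussians over the z-scored, unconstrained
parameters; each component's covariance is parametrized by a
lower-triangular precision factor $A$ with positive diagonal
($z = A(\theta - \mu) \sim \mathcal N(0, I)$), which keeps the density
exactly normalized and the analytic gradients cheap (they are verified
against numerical differentiation in the test suite). Training minimizes
the negative conditional log-likelihood with Adam (learning rate $10^{-3}$),
batch size 1,000, a 10% validation split and early stopping after 20
epochs without improvement — the training regime of the study this
package operationalizes. The default is $K = 1$: the wiring-rule
posteriors here are near-Gaussian after the unconstrained transform, and
a single full-covariance component proved better calibrated than larger
mixtures (which can overfit at these budgets); `n_components` remains a
config knob. Bounded priors (uniform, Beta) are handled by a scaled-logit
transform, so posterior draws respect the prior support by construction.

Budgets: $10^4$ simulations for test-scale runs, $3\times 10^4$ for the
calibration and recovery studies; the original analyses used $10^6$.

The sequential variant `snpe()` focuses the budget on one observation by
truncated refinement: after each round, the prior is restricted to the box
containing essentially all posterior mass at $x_{\mathrm{obs}}$
(per-dimension 0.05%/99.95% quantiles, 10% padding, intersected with the
prior support), the next round draws parameters from the truncated prior
by rejection, and the estimator retrains on all accumulated draws inside
the current box (all of which are valid truncated-prior draws). This
avoids the importance-weighted "atomic" proposal correction while keeping
the estimate statistically valid on the retained region; with
`n_rounds = 1` it is exactly `npe()`. The equal per-round budget split is
a package decision (the original round split is unpublished).

# Validation machinery

* **Reference posterior.** The reduced simulator applies the DSO rule to
  10 frozen feature rows (drawn once from the synthetic generator,
  shipped as `inst/extdata/reduced_features_synthetic.csv`) and returns
  raw counts, so the likelihood is an analytic Poisson product.
  `mcmc_reference_posterior()` samples it by slice-sampling-within-Gibbs
  in the unconstrained space, 10 chains initialized from the prior,
  burn-in half, convergence enforced at split-$\hat R < 1.01$ (a
  diagnostic error otherwise). Agreement between NPE and this reference
  is scored by C2ST and improves with simulation budget.
* **C2ST.** Held-out accuracy (5-fold CV, balanced classes) of a small
  neural classifier with one hidden layer of $10\times$ the input
  dimension (via `nnet`); 0.5 is indistinguishable. Unit Gaussians two
  SDs apart reproduce the Bayes accuracy $\Phi(1) \approx 0.841$.
* **SBC.** Ranks of prior-drawn ground truths among $L$ posterior draws
  at their own simulated observations are uniform iff the posterior is
  calibrated on average. The programmatic criterion is a KS test on the
  randomized normalized ranks (exactly continuous under the null),
  passing at $p > 0.01$ per parameter; a deliberately overconfident
  control (posterior SD halved) must fail it. A rank-ECDF plot with a 99%
  band is available for the visual check.
* **Predictive checks.** Prior predictive: flag an observation outside
  the simulated range. Posterior predictive: z-distance
  $|\mathrm{mean}(x_p) - x_{\mathrm{obs}}|/\mathrm{sd}(x_p)$ per
  dimension, pass at $\le 1$. Under the package's study conditions this
  per-population event is stochastic even for an oracle simulating at the
  true parameters (the observation itself carries 50-pair binomial
  noise), so occasional single-population excursions above 1 are expected
  and not evidence of a broken posterior — calibration is what SBC
  certifies.
* **Posterior geometry.** Pearson correlations of posterior draws;
  conditional correlations with one parameter held fixed, computed
  either exactly from the Gaussian-mixture conditional of a fitted
  estimator or from raw samples via an adaptive slab ($\varepsilon$ grown
  until $\ge 500$ draws fall inside; conditioning value defaulting to
  the fixed parameter's marginal MAP). The marginal MAP itself is the
  argmax of a kernel density estimate on a 1,000-point grid spanning the
  sample range.
* **Leave-one-measurement-out.** Retrain with one data dimension removed,
  condition on the reduced observation, simulate full vectors, and
  compare the held-out coordinate (z-distance) plus a C2ST between
  full-posterior and held-out-posterior predictions — chance accuracy
  means the measurement was redundant given the others.

# Numerical choices and degenerate inputs

Log-diagonal entries of the precision factor are clamped to $[-7, 7]$
(with zeroed gradients outside) to keep early training stable; non-finite
simulator outputs are dropped with a warning and training aborts only if
nothing survives; zero-variance dimensions in correlation and predictive
computations are flagged (`NA` entries, `degenerate` flags) rather than
silently propagated; populations with fewer candidate pairs than
requested fall back to exhaustive enumeration with a warning; coarsening
requires the factor to divide the grid and recomputes `postAll` on the
coarse grid; `marginal_map()` of constant samples returns that constant.
MCMC works in the unconstrained space with the transform Jacobian, so
bounded priors never produce boundary rejections.

# Known limitations

The MDN family is unimodal per component and the default $K = 1$ cannot
represent genuinely multimodal posteriors; the wiring-rule posteriors
examined here are unimodal, but other simulators may need larger `K`.
The sequential scheme estimates the posterior restricted to its
truncation box — adequate when the box captures $\ge 99.9\%$ of the mass,
by construction of the quantile box, but not a general-purpose proposal
correction. The synthetic substrate, while statistically matched in
interface, is far smaller than real reconstruction-based models (about
$6{,}000$ candidate pairs rather than millions), so population
probabilities carry more sampling noise relative to signal than a
full-scale analysis would see. Finally, results conditioned on real
measured data require the real structural model; everything in this
package is validated on synthetic observations with known ground truth.

# A compact run

```{r example, eval = FALSE}
model <- generate_structural_model(model_config(seed = 7))
sim <- dso_summary_simulator(model)
x_obs <- with_seed(42, sim(c(1.1, 0.95, 1.05)))
fit <- npe(sim, prior_gaussian(),
           training_config(n_simulations = 10000, seed = 1),
           observation = x_obs)
summary(fit)
plot(fit)                       # posterior marginals with MAP markers
residuals(fit)                  # predictive z-residuals per population
sbc <- run_sbc(fit, prior_gaussian(), sim, N = 200, L = 500, seed = 2)
plot(sbc)                       # rank-ECDFs against the 99% uniform band
```

The same workflow, orchestrated with provenance (config hash, substream
seeds, package version) and plain-text artifacts, is available as
`run_pipeline(pipeline_config(...), out_dir)`, with `resume = TRUE`
reusing completed stages.
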