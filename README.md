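# phylomc

Bayesian phylodynamic inference on rooted time trees, in a compact and fully
testable R package.

Epidemiologists and macroevolutionary biologists routinely infer *time
trees* — rooted phylogenies whose node ages are measured in calendar time —
from serially sampled molecular sequences: pathogen genomes collected through
an outbreak, or extant-species data combined with fossils.  The quantities of
interest (effective reproductive numbers, sampling proportions, divergence
times, substitution-model structure) are posterior functionals of

P(T, θ | D) ∝ P(D | T, θ) · P(T | θ) · P(θ),

where `D` is the sequence alignment, `T` the time tree, and `θ` the model
parameters.  `phylomc` implements the full stack needed to sample this
posterior and to *prove that the sampler is correct*:

* **Time trees with sampled ancestors.**  A sampled individual that is a
  direct ancestor of a later sample is a degree-2 node on a branch.  Trees
  round-trip through Newick/NEXUS using the zero-length-branch convention.
* **Tree priors.**  The constant-rate birth–death serial-sampling density
  with removal probability `r ∈ [0,1]` and present-day sampling `ρ`
  (so `r = 0` gives the fossilized birth–death process), its
  piecewise-constant **skyline** generalization, both in the canonical
  `(λ, μ, ψ)` and epidemiological `(Re = λ/δ, δ = μ + ψr, p = ψ/δ)`
  parameterizations, and the heterochronous coalescent.
* **Phylogenetic likelihood.**  Felsenstein pruning over compressed site
  patterns with discrete-gamma rate heterogeneity and a
  proportion-of-invariable-sites fast path (the rate-zero class is evaluated
  analytically for invariant-capable patterns), strict and discretized
  lognormal relaxed clocks, and a naive reference implementation kept as the
  in-package oracle.
* **Substitution-model averaging.**  The 203 time-reversible nucleotide
  models indexed by six-digit rate-grouping codes (`121121` = HKY,
  `123456` = GTR), with reversible-jump split/merge moves, indicator flips
  for frequencies/gamma/invariable sites, and 95% credible model sets.
* **MCMC.**  Metropolis–Hastings with scale, node-height, wide-exchange,
  Wilson–Balding, sampled-node date, and sampled-ancestor jump operators,
  all Hastings ratios validated by sampling-from-the-prior against direct
  simulation.
* **Model selection and adequacy.**  Nested sampling (with the
  `sqrt(H/n_live)` uncertainty estimate), path sampling, stepping-stone, and
  posterior-predictive checks of tree statistics.
* **Simulators.**  Event-driven (Gillespie) birth–death-sampling simulation,
  serial coalescent, two-species multispecies-coalescent divergence, and
  sequence simulation — the generative counterparts of every density in the
  package, used for well-calibrated validation studies.

## Worked example

Simulate an epidemic tree with sampled ancestors, then recover the birth
rate from the tree under the serial-sampling birth–death prior:

```r
library(phylomc)
set.seed(1)
truth <- bd_params(t0 = 2, lambda = 1.5, mu = 0.3, psi = 0.6, r = 0.5)
tree <- simulate_bd_tree(truth, condition_min_samples = 6)
tree
#> timetree: 6 tips, 2 sampled ancestors, root height 1.685, origin 2

log_target <- function(s)
  dlnorm(s$params$lambda, log(1.5), 0.5, log = TRUE) +
  bd_serial_log_density(s$tree, bd_params(2, s$params$lambda, 0.3, 0.6, 0.5))
res <- run_mcmc(list(tree = tree, params = list(lambda = 1)), log_target,
                list(op_scale_param("lambda", 1)),
                chain_length = 20000, log_every = 20, seed = 2,
                sample_trees = FALSE)
post <- res$trace$lambda[-(1:100)]
round(c(mean = mean(post), hpd_interval(post), ess = compute_ess(post)), 3)
#>    mean                     ess
#>   2.026   0.956   3.169 901.000
```

The posterior mean birth rate is 2.03 per lineage per time unit with 95%
HPD interval (0.96, 3.17) — wide, as it must be for a six-sample tree — and
the true value 1.5 sits comfortably inside it; the effective sample size of
the chain is ~900.

A command-line wrapper over the same functions lives at
`inst/cli/phylomc.R` with subcommands `run`, `ns`, `ps`, `simulate`,
`validate` and `summarize`, driven by a small YAML configuration
(see `?load_config`).

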