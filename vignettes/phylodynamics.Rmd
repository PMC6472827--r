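---
title: "Models, algorithms and validation in phylomc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, algorithms and validation in phylomc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylomc)
```

`phylomc` samples the joint posterior of a rooted time tree `T` and model
parameters `θ` given a nucleotide alignment `D`,
`P(T, θ | D) ∝ P(D | T, θ) P(T | θ) P(θ)`.  This vignette is the package's
own account of the models it implements, the numerical and design choices
behind them, and — because most of the package's value lies in being
*demonstrably correct* — the validation logic that the test suite runs.

## Time trees and sampled ancestors

Node ages ("heights") are measured backwards from the latest sampled tip,
which sits at height 0; an edge's duration is the height difference between
its endpoints.  Serially sampled data make it possible for one sample to be
the direct ancestor of another, so trees admit *sampled-ancestor* nodes:
degree-2 nodes (exactly one child) carrying a taxon.  On disk these follow
the common interchange convention of a zero-length terminal branch; a
terminal branch counts as zero when it is shorter than `1e-10` times the
root height.  Newick output anchors heights at the deepest tip, so absolute
calendar offsets (e.g. the gap between the last sample and the present when
`ρ = 0`) travel separately, via tip-date tables or the origin parameter.
All-gap or all-ambiguous alignment columns are treated as missing data and
are therefore compatible with every nucleotide, contributing the full
invariable-class term to the likelihood.

## Tree priors

**Birth–death with serial sampling.**  A single lineage arises at the
origin height `t0`; each lineage bifurcates at rate `λ`, dies at rate `μ`,
is sampled serially at rate `ψ` (removed on sampling with probability `r`),
and extant lineages are sampled at height 0 with probability `ρ`.  `r < 1`
puts sampled ancestors in the support; `r = 0` is the fossilized
birth–death setting.  The density is evaluated through the standard pair of
interval functions: `p(t)`, the probability that a lineage at height `t`
leaves no sampled descendant, which solves
`dp/dt = μ − (λ+μ+ψ) p + λ p²` with `p(0) = 1 − ρ`, and the edge factor
`q(t)` with `d(log q)/dt = −(λ+μ+ψ) + 2 λ p(t)`.  Bifurcations at height
`x` contribute `2 λ q(x)`, serial tips at `y` contribute
`ψ (r + (1−r) p(y)) / q(y)`, sampled ancestors contribute `ψ (1−r)`, and
present-day tips contribute `ρ`; the whole density is conditioned on the
origin and on at least one sample, i.e. divided by `1 − p(t0)`.  The factor
2 per bifurcation is the orientation multiplicity that makes the density of
a *labeled* tree consistent across dimension classes — without it, trees
with different sampled-ancestor counts would be weighted inconsistently,
which the prior-sampling tests would detect immediately.  The critical case
`ψ = 0, λ = μ` uses the rational-function limit of the closed form.

**Skyline.**  Rates are piecewise-constant between user-fixed change
heights (estimating change times is out of scope).  `p` and `log q` are
continued across interval boundaries by re-solving the same ODEs with the
boundary value as the new initial condition; a single interval reduces
exactly to the constant-rate closed form, and the test suite additionally
checks the interval machinery against black-box numerical ODE integration
(`deSolve::lsoda`).  The epidemiological reparameterization
`Re = λ/δ`, `δ = μ + ψ r`, `p = ψ/δ` is provided as an exact, invertible
map; `p·r` combinations implying a negative death rate are rejected.

**Coalescent.**  The heterochronous constant-size coalescent with pairwise
rate `1/Ne` (time units of the tree).  Its support excludes sampled
ancestors.

## Likelihood

Felsenstein pruning runs over compressed site patterns, per gamma rate
category, with tip ambiguity codes entering as indicator vectors and
sampled-ancestor sequences entering as constraints at their degree-2 nodes.
The proportion-of-invariable-sites class is the mixture's rate-zero
component: for a pattern, it equals `p_inv · Σ π_x` over the nucleotides
`x` compatible with every taxon in the column, which is evaluated directly
from precomputed invariant-capability flags instead of an extra pruning
pass.  Because this shortcut is a reconstruction rather than a specified
algorithm, the package keeps `log_likelihood_naive()` — uncompressed, with
an explicit rate-zero category — as a permanent oracle; the two paths agree
to `1e-10` in the tests, and both agree with exhaustive enumeration over
all internal state assignments on trees of up to five taxa.

Discrete gamma categories use mean-of-bin rates (the conditional mean of a
`Gamma(α, α)` on each probability bin), so the mixture mean is exactly 1
and the normalization is testable, rather than the quantile-median variant.
Per-pattern rescaling activates when partials underflow below `1e-200`.
The relaxed clock is the discretized uncorrelated lognormal: one category
integer per branch, quantile rates renormalized to mean 1 before scaling by
the mean rate.

## MCMC

The kernel is plain Metropolis–Hastings over a state list; every operator
returns its proposal and log Hastings ratio (Jacobian included).  Tree
moves: uniform node height, root height, whole-tree scaling of unsampled
heights, wide exchange (an involution, so its ratio is 1), Wilson–Balding
prune–regraft (candidate counts and attachment-interval lengths in both
directions enter the ratio), a sampled-node date move, and the
sampled-ancestor jump, a dimension-matching move that collapses a leaf's
parent bifurcation or re-draws it uniformly below the ancestor's parent.
Scalar scale moves draw a log-uniform multiplier `s` on `[1/S, S]`; the
change-of-variables gives Hastings ratio `s^m` when `m` coordinates are
scaled.  Scale-type operators auto-tune toward 0.234 acceptance during the
first 10% of the chain only, and the engine snapshots and restores operator
tuning state so that equal seeds give bit-identical chains.  The cached
posterior is re-derived from scratch every 1000 steps and compared at
`1e-8`.

Substitution-model averaging moves along the partition lattice of the six
exchangeabilities: a split draws the new group's rate from its
Exponential(1) prior (so the proposal density cancels against the prior
factor and the acceptance ratio reduces to counting terms), and a merge
keeps the surviving group's rate while deleting the other.  Merging by
averaging rates was considered and rejected: the prior-draw design needs no
auxiliary variable to reverse and its bookkeeping is validated globally by
the data-free uniformity test, which requires the chain to visit all 203
reversible codes in exactly uniform proportion.  Frequency, gamma and
invariable-site indicators flip over a saturated space (switched-off
parameters keep their values and priors), making the flips symmetric.  The
restricted transition/transversion model set contains
`2 · B(4) + 1 = 31` codes; only the fully merged `111111` (JC69/F81) is
re-admitted as an exception, the conservative reading of the credible-set
convention.

## Marginal likelihoods

Nested sampling uses likelihood-thresholded subchains (the same operators,
targeting the prior) to replace the worst of `n_live` points, the
geometric shrinkage `E[log X_i] = −i/n_live`, termination when the
remaining-evidence bound falls below `1e-6` of the accumulated evidence,
and reports `stderr = sqrt(H/n_live)`.  Replacement subchains that never
move are counted, not fatal — under a constant likelihood *no* subchain can
exceed the threshold, yet the estimator must (and does) return `log c`
exactly.  Path sampling and stepping-stone share a Beta(0.3, 1)-quantile
power schedule, dense near the prior where the integrand moves fastest;
rungs are run consecutively, each seeded from the previous rung's state.
On the conjugate-normal benchmark all three estimators agree with the
closed form within reported uncertainties, and the trapezoid bias of the
path estimate decays as the rung count grows (checked with exact rung
expectations, isolating the quadrature from Monte Carlo noise).

## Simulators and validation doctrine

Each density has a generative twin: event-driven forward simulation of the
(skyline) birth–death sampling process from the origin, with pruning of
unsampled lineages (serially sampled, non-removed individuals ancestral to
later samples become degree-2 nodes); the serial coalescent; sequence
evolution down the tree; and the two-species multispecies-coalescent check
in which one gene lineage per species coalesces at rate `1/(2 Ne)` per
generation behind the speciation time, the diploid convention under which
the expected divergence excess is exactly `2 Ne` generations.  Forward
simulation caps the living population at `1e6` and aborts the replicate at
the cap rather than truncating; conditioning on a minimum number of
samples is by resimulation with the retry count reported.

Correctness of the whole stack rests on a three-way consistency triangle,
run in the test suite at fixed seeds: (i) direct simulation conditioned on
the number of samples, (ii) MCMC with the likelihood forced to 1 (whose
stationary law is the tree prior; tip dates are then sampled too, so both
sides target the same conditional distribution), and (iii) closed-form
conditionals where available (two-tip quadrature).  Root height, tree
length and sampled-ancestor count are compared by Kolmogorov–Smirnov and
chi-square tests at a Bonferroni-adjusted 1% level for the coalescent,
birth–death with `r ∈ {0, 0.5, 1}`, and a two-interval skyline.  This is
the strongest practical test of the Hastings ratios: the Wilson–Balding
interval ratio and the sampled-ancestor Jacobian each shift these
distributions detectably when perturbed.

The package's validation doctrine culminates in the well-calibrated study:
parameters drawn from the inference priors, data simulated from them,
inference run, and nominal 95% HPD coverage checked against the exact
binomial band.  The bundled study infers `(λ, t0)` from *observed trees*
under the serial-sampling density (lognormal prior on `λ` centred on 1.5,
uniform origin prior on (1, 2.5), `μ = 0.3`, `ψ = 0.4`, `r = 0.5`), 100
replicates at chain length 15,000.  Treating the tree as data is a
deliberate design choice: it tests the prior density, simulator and scalar
samplers end to end while keeping a 100-replicate study at desk scale; the
same function accepts any scalar subset of the birth–death parameters.
Full sequence-to-posterior calibration is exercised separately, at smaller
scale, through the likelihood oracles and the posterior-predictive
machinery.

The simulators emulate the generative models exactly — which is the point —
but therefore share their idealizations: a single unstructured population,
no rate variation between what the clock model describes, no alignment
error, no selection.  Passing tests show the inference machinery is
self-consistent under the stated models, not that those models fit any
particular real dataset; model adequacy for real data is what
`posterior_predictive_check()` (two-sided p-value with +1 continuity
correction on root height or tree length) is for.

## Numerical choices and degenerate inputs

Probability machinery runs in log space throughout; `p`/`q` evaluations use
the `log1p`/`logsumexp` forms; matrix exponentials come from the symmetric
eigendecomposition of the similarity-transformed generator (exact for
reversible models) with rows renormalized against round-off.  Ties in node
ordering are broken by processing samples before coalescences at equal
heights; ties in the MCC summary by first occurrence in the log; ties in
credible-set membership lexicographically by code.  Degenerate cases are
pinned by tests: `t = 0` transition matrices are the identity, a
single-interval skyline equals the closed form, `r = 1` assigns `−Inf` (not
an error) to sampled-ancestor trees, `ψ = 0` densities are independent of
`r`, constant traces have ESS 0, and one-simulation posterior-predictive
checks return `p = 1`.

## Problem sizes

The shipped tests run at sizes chosen to make every statistical check sharp
at desk scale: enumeration oracles to five taxa, triangle comparisons with
four-sample trees, 1,500 simulated trees and 300,000-step prior chains per
setting, a 100-replicate calibration study, 500,000-step model-averaging
chains, and 20,000-replicate simulator expectations.  All sizes are
arguments, so any of them can be scaled up.

## Known limitations

Single-locus likelihoods only; no structured populations, transmission
models, or parametric epidemic trajectories; no codon, amino-acid or
morphology models; random-local-clock and estimated skyline change times
are out of scope; the Newick writer anchors heights at the deepest tip, so
`ρ = 0` trees need their origin carried separately.  The exchange operator
is the wide variant; on very large trees mixing of topology would benefit
from an additional narrow exchange, which the operator interface makes easy
to add.
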