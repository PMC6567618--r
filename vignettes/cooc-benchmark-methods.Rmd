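---
title: "Simulation-based benchmarking of microbial co-occurrence network inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation-based benchmarking of microbial co-occurrence network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coocbench)
```

## The question the package addresses

Co-occurrence networks — graphs of statistical associations between taxa
inferred from relative-abundance profiles across samples — are routinely
read as evidence about ecological *interactions*. Whether that reading is
justified cannot be decided on real data, where the true interaction
network is unknown. `coocbench` therefore builds the whole evaluation loop
in silico: a known interaction network is planted, abundances are generated
by population dynamics on that network, association networks are inferred
from the (compositional) abundances by several standard methods, and
recovery of the planted network is quantified.

The pipeline has five stages, each an exported function family:

1. **Network generation** (`generate_network()`): a ground-truth undirected
   graph with `n` species and average degree ⟨k⟩ = 2m/n.
2. **Interaction matrices** (`build_interactions()`): a signed matrix `M`
   placed on the graph, one of six ecological community types.
3. **Abundance synthesis** (`generate_dataset()`): steady states of
   generalized Lotka–Volterra (GLV) dynamics, converted to compositions.
4. **Inference** (`infer_scores()`): seven methods producing symmetric
   pair-confidence matrices.
5. **Evaluation** (`evaluate_scores()`): area under the precision–recall
   curve (AUPR) against the planted adjacency, with a baseline correction
   for edge prevalence.

`run_iteration()` / `run_experiment()` orchestrate the grid sweeps, and
`preset()` bundles the figure-level experiment designs.

## The population model

Abundances follow the n-species generalized Lotka–Volterra equations

$$\frac{dN_i}{dt} = N_i\Big(r_i + \sum_j M_{ij} N_j\Big),$$

with self-regulation fixed at \(M_{ii} = -1\), so a species in isolation
follows logistic growth with carrying capacity equal to its growth rate
\(r_i\). Growth rates are i.i.d. Uniform(0, 1]; initial abundances are
i.i.d. Poisson with mean 100 (about 100·n individuals to start); the system
is integrated to \(t = 1000\) model-time units and the final state recorded.
One *sample* is one such steady state; the process repeats — with fresh
\(r\) and \(N_0\) — until the requested number of samples is collected.
Relative abundances are \(P_i = N_i / \sum_j N_j\). Environmental
perturbation is deliberately absent.

**Why redraw the growth rates per sample.** With `M` and `r` both fixed, a
stable interior fixed point is independent of the initial abundances, so
all samples would be essentially identical and every correlation undefined.
Between-sample variation must come from the growth-rate draws (and from
extinctions driven by initial conditions). `generate_dataset()` therefore
redraws `r` for every sample by default; `redraw_growth = FALSE` switches
to a single draw per dataset for sensitivity analysis.

**Numerical choices.** Integration uses an embedded Dormand–Prince 5(4)
adaptive stepper (relative tolerance 1e-8, absolute 1e-10) implemented in
compiled code, with two model-specific behaviours built into the step loop:
abundances falling below `extinction_eps` (default 1e-8) are clamped to
exact zero, and any abundance exceeding `divergence_cap` (default 1e8) or
turning non-finite aborts the run with a divergence flag, upon which the
caller resamples (budget: 10× the requested sample count, with the resample
count reported). At high average degree (⟨k⟩ ≳ 12 with `s_max = 0.5`) a
small fraction of *random*-type communities contains positive feedback
strong enough to defeat the self-limitation term, so every integration
diverges and the budget is exhausted; the benchmark runner records such
communities as failed cells and continues, and sweep summaries condition on
dynamically bounded communities. The integrator is validated in the test suite against an
independent stiff-capable solver (`deSolve::lsoda` at tolerance 1e-10) and
against the closed-form one- and two-species fixed points.

**What "steady state" means here.** Convergence is assessed on the
right-hand side of the ODE: \(|dN_i/dt| = |N_i(r_i + (MN)_i)|\) at
\(t = 1000\). At the default parameters a substantial minority of runs
contain a species *en route* to extinction — per-capita rate around −0.01,
abundance around 1e-3 — whose per-capita rate is not small even though its
effect on the community is negligible and shrinking exponentially. The
right-hand-side residual weights the rate by the abundance and is the
quantity that actually vanishes at an attractor with extinct species;
`glv_residual()` reports both forms. Roughly 98–99% of accepted 50-species
samples at default parameters have every \(|dN_i/dt| < 10^{-6}\).

## Ground-truth networks

Three generators, all returning simple undirected graphs with exactly
`m = round(n k_avg / 2)` edges:

* **Random** (`generate_er()`): `m` pairs drawn uniformly without
  replacement — the G(n, m) ensemble, with approximately Poisson degrees.
* **Small-world** (`generate_sw()`): ring lattice with `k_avg/2` neighbours
  per side, then exactly ⌊p_WS·m + 0.5⌋ edges rewired (one endpoint
  redrawn uniformly, self-loops and duplicates rejected). Default
  `p_ws = 0.05`; the edge count is preserved exactly.
* **Scale-free** (`generate_sf()`): static-model sampling with node weights
  \(w_i \propto (i + i_0 - 1)^{-\xi}\), \(\xi = 1/(\gamma-1)\), rejecting
  self-loops and duplicates, giving a degree tail \(P(k) \propto
  k^{-\gamma}\) with default \(\gamma = 2.2\). When \(\xi \ge 1/\sqrt 2\)
  the finite-size constant is
  \(i_0 = n^{1 - 1/(2\xi)}\,(10\sqrt{2}\,(1-\xi))^{1/\xi}\) (else
  \(i_0 = 1\)); because published formulations of this correction differ in
  the constant, `i0` is exposed as an argument and the degree-tail exponent
  of the resulting ensemble is checked by a maximum-likelihood fit in the
  test suite rather than assumed.

A note on the Poisson-degree property: at small `n` the G(n, m) degree
variance carries a factor \(1 - k/(n-1)\), so variance equals the mean only
in the large-`n` limit; the property test runs at `n = 200` where the
correction is below 2%.

## Community types

`build_interactions()` draws interaction magnitudes uniformly with bound
`s_max` (default 0.5) and signs by community type: mutualistic (+,+),
competitive (−,−), predator–prey (opposite signs, direction decided by a
fair coin), random (both entries Uniform[−s_max, s_max], which yields
mutualism : competition : predation in the 1:1:2 ratio for large m), and
two mixtures. In both mixtures the parameter `p_C` is the **competitive
fraction**: a pair is competitive with probability `p_C` and otherwise
mutualistic (`mix_mut_comp`) or predator–prey (`mix_comp_pp`). Magnitudes
of the two directed entries are always drawn independently; only the sign
decision is shared. Exact zeros are rejected so the support is literally
open at 0, keeping `M_ij = 0 ⇔ no edge` unambiguous.

Because negligible mutual magnitudes act as missing edges, the expected
fraction of such false-negative edges under a cutoff `s_c` is
\((s_c/s_{\max})^2\) (`expected_false_negative_ratio()`); at `s_c = 0.01`,
`s_max = 0.5` this is 0.04% — too rare to matter for evaluation.

## Inference methods

All methods consume a species × samples `abundance_table` (relative by
default) and emit a symmetric `score_matrix` in [0, 1]:

* **Pearson / Spearman** (`correlation_scores()`): absolute pairwise
  correlations (`stats::cor`).
* **MIC** (`mic_scores()`): maximal information coefficient, computed by
  the MINE approximation (y-axis equipartition, x-axis optimised by dynamic
  programming over clumps, both orientations, grid budget `n^alpha` with
  `alpha = 0.6`, clump budget factor `c = 15`), implemented in compiled
  code.
* **Partial correlations** (`partial_correlation_scores()`): full-order
  partial correlations via the precision matrix,
  \(\rho_{ij\cdot k} = -\Omega_{ij}/\sqrt{\Omega_{ii}\Omega_{jj}}\), on the
  Pearson or Spearman correlation matrix; a Moore–Penrose pseudoinverse is
  used (with a warning) when the matrix is singular, e.g. with fewer
  samples than species. The precision-matrix route is mathematically
  identical to recursive order-k formulas but better conditioned.
* **SparCC** (`sparcc_scores()`): basis correlations of the latent absolute
  abundances from log-ratio variances \(t_{ij} = \mathrm{Var}\,
  \log(x_i/x_j)\) under the sparsity approximation
  \(\sum_j t_{ij} \approx (n-2)\omega_i + \sum_j \omega_j\); iterative
  exclusion of the most correlated pair above 0.1 (up to 10 rounds, with
  the system matrix adjusted per exclusion); averaged over 20 Dirichlet
  resamples of the compositions. Relative abundances are rescaled by the
  known total (100·n) to pseudo-counts, plus a pseudocount of 1, because
  the resampling is defined on counts.
* **Neighborhood selection with stability selection**
  (`spieceasi_mb_scores()`): centered-log-ratio transform
  (`clr_transform()`), then per-node lasso regressions (glmnet) along 20
  log-spaced penalties from \(\lambda_{\max}\) (the largest absolute
  pairwise correlation) down to \(0.01\,\lambda_{\max}\); edges by the
  "or" rule (either direction selecting suffices — the union is the more
  sensitive of the two standard symmetrizations). The penalty is chosen by
  stability (StARS): 20 subsamples of 80% of samples, total instability
  \(\overline{2\theta(1-\theta)}\) monotonized from the sparse end, and
  the densest penalty with instability ≤ 0.05 selected. Edge selection
  frequencies at that penalty are the confidence scores. Subsampling is
  keyed to sorted sample identifiers, so column order cannot change the
  result for a fixed seed.
* **External adapter** (`external_scores()`): any square symmetric score
  matrix computed outside the package (e.g. by REBACCA or CCLasso) can be
  evaluated by the same machinery.

## Evaluation

The strictly-lower-triangle entries of the score matrix and the adjacency
are vectorized in a fixed pair order and the precision–recall curve swept
over all distinct score thresholds; tied scores enter at a single
threshold, so no within-tie ordering can leak ground truth. The area is
integrated with the continuous interpolation that is exact in PR space
(confusion counts continued linearly between operating points; the
per-segment integral has a closed form). Linear interpolation of precision
itself would systematically overestimate the area, which is why the
closed-form route is validated in the tests against an independent
quadrature oracle (to 1e-9) and against the property that exchangeable
random scores attain AUPR equal to the edge prevalence \(2m/[n(n-1)]\).

Because prevalence varies across conditions, results are also reported as
the baseline-corrected AUPR
\((\mathrm{AUPR}_{obs} - \mathrm{AUPR}_{rand})/(1 - \mathrm{AUPR}_{rand})\)
with \(\mathrm{AUPR}_{rand} = 2m/[n(n-1)] = \langle k\rangle/(n-1)\);
negative values (worse than random) are preserved. Method contrasts use
Welch's t-test on raw per-iteration values (`compare_methods()`); trends
against a swept condition use Spearman rank correlation on raw, unaveraged
values (`trend_correlation()`).

## Reproducibility and problem sizes

Every stochastic stage accepts a seed; the benchmark runner derives one
seed per (condition, iteration) cell by hashing the root seed with the
condition values (`child_seed()`), so cells are reproducible in isolation
and execution order is immaterial. The package's own test suite and the
`scripts/acceptance.R` report run the full pipeline at 10 iterations per
condition with 300 samples of 50 species — a deliberate desk-scale design
that keeps a complete run in minutes while leaving the Monte-Carlo error of
condition means around ±0.02 AUPR; the full 50-iteration experiment designs
are available through `preset()`.

## What the generator does and does not emulate

The synthetic data reproduce the statistical structure population dynamics
impose on cross-sectional abundance snapshots: nonlinear dependence between
interacting species, extinctions, the constant-sum constraint of
compositions, and prevalence set by the planted network. They do **not**
emulate sequencing: no multinomial read sampling, no rarefaction, no
overdispersed count noise, and no environmental perturbation or time-series
structure. Passing benchmarks here therefore speaks to the
population-dynamics-to-composition link, not to robustness against
measurement noise in real surveys.

Two further scale effects are worth knowing. The constant-sum artifact
that motivates compositional methods scales like \(1/(n-1)\), so on *null*
communities with many species it is smaller than the sampling noise of the
estimators themselves; the suppression of the artifact by the SparCC
estimator is demonstrable at small n (around 10 species) and is tested
there. And in *small* networks the degrees of freedom are few, so all
methods sit close to the random baseline — the benchmark's informative
regime is n of a few tens and above.

## Known limitations

* The GLV model with uniform interaction weights is a stylized community;
  real ecosystems have structured, time-varying interactions.
* REBACCA and CCLasso are supported only through the external score
  adapter, not reimplemented.
* MIC is excluded from the default benchmark method set on runtime grounds
  (`available_methods(include_mic = TRUE)` opts in).
* Stability scores depend mildly on the penalty-path construction; the
  path bounds and resolution are exposed in `method_config()` and recorded
  in each `score_matrix`'s `params`.
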