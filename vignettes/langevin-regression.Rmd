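---
title: "Langevin regression: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Langevin regression: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(langreg)
```

## The model class and its assumptions

`langreg` fits scalar stochastic differential equations

$$\dot x = f(x) + \sigma(x)\, w(t),$$

with Gaussian white noise $w$, drift $f$ and noise amplitude $\sigma$
expanded over polynomial candidate libraries,
$f(x) = \Theta_f(x)^\top \xi_f$, $\sigma(x) = \Theta_\sigma(x)^\top \xi_\sigma$.
The diffusion is $a(x) = \sigma(x)^2/2$. For radial coordinates of an
isotropic planar system the drift carries the additional structural term
$\sigma(r)^2/2r$ (Itô's lemma under the change of variables); it is
coefficient-free, recomputed from the current $\xi_\sigma$ at every
evaluation, and never a sparsification candidate.

The estimation pipeline assumes:

1. **Stationarity and ergodicity** — one long trajectory stands in for the
   ensemble.
2. **Effective Markovianity at the working sampling interval.** The raw
   signal may be driven by time-correlated ("coloured") forcing or carry
   latent degrees of freedom; the method *requires* subsampling past the
   Einstein–Markov decorrelation scale so that the forcing appears white
   at the retained rate. `markov_scan()` provides the diagnostic: the
   lag-one autocorrelation of the subsampled increment sequence, with a
   default admissibility threshold of $|\rho| < 0.05$. This is a proxy
   criterion — a full Chapman–Kolmogorov test is out of scope — chosen
   because increment decorrelation is the property the downstream
   estimator actually relies on.
3. **A scale gap** $\omega \ll 1/\tau \ll \alpha$ between the macroscopic
   drift dynamics and the forcing decorrelation rate. When no such gap
   exists the subsampled-and-corrected estimates degrade; the scan
   reports this honestly (no stride passes the threshold, `NA`
   recommendation with a warning, and the pipelines fall back to the
   least-correlated candidate).

## Finite-time corrections

Binned conditional moments of the increment $\Delta = x(t+\tau) - x(t)$,

$$\hat m^{(1)}_i = \langle \Delta \rangle_{x \in \mathrm{bin}_i}, \qquad
  \hat m^{(2)}_i = \langle \Delta^2 \rangle_{x \in \mathrm{bin}_i},$$

converge to $f\tau$ and $2a\tau$ only as $\tau \to 0$. At the coarse
$\tau$ the Markov requirement forces on us, they are systematically
distorted (the benchmark shows drift underestimated by a factor of two at
$\tau = 0.5$). The model-implied moments at finite $\tau$ are exact
functionals of the adjoint Fokker–Planck generator
$\mathcal L^\dagger = f\,\partial_x + a\,\partial_{xx}$:
with $w_n(x,t)$ solving $\partial_t w_n = \mathcal L^\dagger w_n$,
$w_n(x,0) = x^n$,

$$m^{(1)}_\tau(x) = w_1(x,\tau) - x, \qquad
  m^{(2)}_\tau(x) = w_2(x,\tau) - 2x\,w_1(x,\tau) + x^2.$$

Note the $+x^2$: expanding $\langle (x'-x)^2\rangle$ requires it, and the
implementation is verified against the closed-form OU transition moments
to machine precision. (`m2` is everywhere the *raw* second conditional
moment, not the centred variance — the correction formula is written for
raw moments; the distinction is documented because the two are easy to
conflate.)

## The cost and its optimization

$$J(\xi) = \sum_{n=1,2}\sum_i w^{(n)}_i
  \left[ m^{(n)}_\tau(x_i;\xi) - \hat m^{(n)}_i \right]^2
  + \eta\, D_{KL}\!\left(\hat p \,\|\, p(\cdot;\xi)\right).$$

* **Weights.** $w^{(n)}_i = \mathrm{count}_i / \mathrm{var}_i$, the
  inverse squared standard error of each bin statistic, floored at
  machine epsilon; bins with fewer than `min_count = 10` pairs are
  excluded. The exact weighting rule is a package choice (only its
  intent — pointwise uncertainty — is prescribed); uniform weights are
  available by configuration.
* **KL regularization.** Subsampled moment matching alone can be poorly
  conditioned: distinct $(f, \sigma)$ pairs produce nearly identical
  coarse-time moments. Pinning the model's stationary density to the
  empirical histogram restores identifiability. In one dimension the
  stationary density has the exact closed form
  $p \propto a^{-1} \exp \int f/a\,dx$ (the constant-$\sigma$ formula
  generalized to state-dependent noise), evaluated by cumulative
  trapezoidal quadrature — this is the default. A numeric null-vector
  solver (shift-invert inverse iteration on the discretized forward
  operator) is provided behind the same interface as the route that
  generalizes beyond 1D; it is cross-validated against the analytic form
  (KL $< 10^{-4}$). Its exact discrete null vector can oscillate slightly
  negative where the cell Péclet number $f h / a$ exceeds 2; negatives up
  to $10^{-3}$ of the peak are clipped, larger ones are a solver failure.
* **Choosing $\eta$.** With `eta = "auto"`, an unregularized fit is run
  first and $\eta$ is set to the power of ten nearest its minimum cost,
  so both terms enter with comparable weight; floored at $10^{-6}$ for
  the degenerate noiseless case. "Power of ten" is our reading of an
  ambiguous "multiple of 10" prescription — it matches the stated intent
  of roughly equal weighting across problems whose cost scales differ by
  orders of magnitude.
* **Optimizer.** Nelder–Mead with up to three restarts: from the
  no-adjoint linearized baseline (the natural warm start), from twice it,
  and from a seeded random perturbation. One-parameter problems use Brent
  instead (a 1-simplex is unreliable). Infeasible parameter vectors
  ($\sigma \le 0$ somewhere on the operator grid) receive a large finite
  penalty ($10^{10}$) rather than an error, keeping the simplex
  well-defined while letting the search cross sign-indefinite regions.
* **No-adjoint baseline.** `fit_no_adjoint()` regresses
  $\hat m^{(1)}/\tau$ on the drift library and $\sqrt{\hat m^{(2)}/\tau}$
  (the implied noise amplitude — a linearization that keeps the problem
  linear in $\xi_\sigma$) on the diffusion library, by weighted least
  squares. It is both the uncorrected reference method and the warm
  start.

## Discretization

* **Grid.** 40 uniform bins spanning the 0.05th–99.95th percentile range
  of the subsampled data: robust to rare excursions, covers the
  stationary support. Binning is half-open $[e_i, e_{i+1})$ with the last
  edge closed.
* **Operators.** The adjoint uses second-order central differences with
  second-order one-sided stencils at the two boundary rows. The forward
  operator is discretized independently in conservative flux form with
  zero-flux boundaries, so column sums vanish and discrete probability is
  conserved exactly; in the interior this flux form is the exact
  transpose of the central adjoint stencil, so discrete duality
  $\langle \mathcal Lp, q\rangle = \langle p, \mathcal L^\dagger q\rangle$
  holds to machine precision for interior-supported fields.
* **Extension.** Operators are built on the data grid extended by 25% of
  its span per side (same spacing, truncated at $r > 0$ for polar
  models); moments are restricted back to the data bins. This keeps the
  one-sided boundary treatment of the propagated observables away from
  the bins that enter the cost.
* **Semigroup.** $e^{\tau \mathcal L^\dagger}$ by dense
  scaling-and-squaring Padé (`Matrix::expm`); at the 60–100 point grids
  used here one exponential costs a few milliseconds, so the whole
  Nelder–Mead fit takes seconds.

## Sparse structure discovery

`ssr()` starts from the full candidate model and repeatedly removes the
active term whose removal yields the smallest *refitted* total cost —
the cost criterion, not coefficient magnitude, because a small
coefficient on a steep library column can carry large dynamical weight.
$\eta$ is fixed once (on the full model) along the path so level costs
are comparable; each refit is warm-started from its parent's
coefficients with a single simplex start (the restart battery is
reserved for standalone fits — along a path the parent optimum is an
excellent start, and this keeps the $O(k^2)$ refit count affordable).
Ties are broken by removing the higher-degree term (prefer simpler
models). The structural Itô term is exempt. Selection takes the smallest
model whose cost stays within `knee_factor = 2` of the path minimum; the
full path is always reported because knees are ultimately judged by
inspection.

## What the generators emulate — and what they do not

`simulate_colored_pitchfork()` realizes the bistable normal form
$\dot x = \lambda x - \mu x^3 + \eta$ forced by an OU process with
relaxation rate $\alpha$; defaults $\lambda = \mu = 1$, $\alpha = 100$,
$\sigma_\eta = 50$ (so the effective white-noise amplitude is
$\sigma_\eta/\alpha = 0.5$), $10^7$ samples at $\Delta t = 10^{-2}$ — the
benchmark's stated condition. One integration subtlety: a raw
Euler–Maruyama step at $\alpha\,\Delta t = 1$ turns the OU recursion into
i.i.d. draws — *white* forcing — silently deleting the coloured-noise
physics the benchmark exists to probe. The reference results were
produced with an adaptive stochastic Runge–Kutta integrator and then
*sampled* at $\Delta t$; we reproduce that stated world with 10 internal
Euler–Maruyama substeps per retained sample ($\alpha h = 0.1$). The
substep count is a fixed documented default, not a tuning knob.

`simulate_double_well()` integrates the second-order particle
$\ddot x + 2\dot x = (\epsilon - x^2)x + \sigma w$ and returns only the
position: the velocity is deliberately latent, making the recorded
series non-Markovian at fine sampling — the order-reduction benchmark.
The default forcing follows $\sigma = (\epsilon + \sqrt\epsilon)/2$
(read from an ambiguously typeset rule via the fixed-point amplitude
$\sqrt\epsilon$; $\sigma$ remains an explicit argument so either reading
is reproducible).

`simulate_wake_surrogate()` integrates the symmetric planar pitchfork
with isotropic noise $\sigma(r) = \sigma_0 + \sigma_1 r^2$ in Cartesian
coordinates and returns the radius, so the $\sigma^2/2r$ Itô term
emerges exactly rather than from a singular radial SDE. The experimental
turbulent-wake data behind the original application are not public, and
the fitted wake coefficients are not printed; the generator's defaults
$\lambda = \mu = 1$, $\sigma_0 = 0.4$, $\sigma_1 = 0.2$ were chosen once
as a realistic stand-in (limit-cycle radius 1, noise about 40% of it,
quadratic noise contributing half the constant term at $r = 1$) and are
documented as synthetic. Consequently a green wake test establishes that
the *method* recovers a known multiplicative-noise radial model from its
own trajectory — a round trip — not that it reproduces any experimental
measurement. None of the generators emulate measurement noise,
non-stationarity, or non-Gaussian forcing jumps; real data carrying
those features are outside the validated envelope.

## Numerical edge cases

* $\tau = 0$ short-circuits the exponential and returns exactly zero
  corrections.
* Infeasible diffusion signals a catchable `infeasible_model` condition
  at evaluation; only the fitting layer converts it into a penalty.
* Constant (zero-variance) bins get standard-error weights via the
  machine-epsilon floor; degenerate near-constant inputs widen the data
  grid symmetrically rather than erroring.
* Dwell-time detection uses hysteresis (two thresholds, defaults at
  $\pm$ half the deterministic equilibrium amplitude) to suppress
  within-well chatter; the censored interval before the first observed
  switch is discarded.
* Seeds: every stochastic routine takes an explicit integer seed
  (defaults are fixed constants, never time-based); identical
  inputs + seed give bitwise-identical trajectories, fits and SSR paths.

## Known limitations

Scalar state only (the formalism generalizes; the histogram and dense
solvers do not, beyond 2–3 dimensions). Polynomial libraries only, plus
the structural $1/r$ term. Euler–Maruyama only (weak order 1; the
acceptance tolerances absorb its bias at $\Delta t = 10^{-2}$).
Coefficient uncertainty is available only as multi-seed spread; no
asymptotic standard errors. The Markov diagnostic is a lag-one increment
proxy, not a full Markov-property test.
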