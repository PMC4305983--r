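---
title: "Structure-based power-law models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based power-law models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usystem)
```

## The model class

`usystem` works with Generalized Mass Action (GMA) systems from Biochemical
Systems Theory: every biochemical process is a product of power laws, the
result of Taylor-approximating arbitrary rate laws in logarithmic space
around an operating point. For dependent species $X_1,\dots,X_n$ and
independent species $Y_1,\dots,Y_m$ (enzyme activities, clamped external
substrates), each balance equation is

$$\frac{dX_i}{dt} \;=\; \sum_k S_{ik}\, \alpha_k \prod_j X_j^{f_{kj}}
\prod_j Y_j^{F_{kj}},$$

with $S$ the signed stoichiometric matrix over fluxes. Two representation
choices matter and are worth stating explicitly:

* **Flux-centric parameters.** Each flux carries one rate constant and one
  exponent per participating species. A conversion flux appears with a minus
  sign in its substrate's equation and a plus sign in its product's equation
  as the *same* term, so mass consistency between the classic per-equation
  $\alpha/\beta$ and $g/h$ parameter families holds by construction rather
  than by bookkeeping.
* **A species that is both substrate and regulator of one flux** gets a
  single combined exponent (the orders add). Power-law algebra forces this:
  $X^a \cdot X^b = X^{a+b}$, so two separate entries would be unidentifiable.

Stoichiometric coefficients are integers $\ge 1$ and multiply the flux in the
balance equation; they do not change default kinetic orders. A flux with no
substrates and no regulators is a constant influx equal to its rate constant
(the mass-action degenerate case).

## The U-system convention

The central idea is a parameterization that requires no estimation: all rate
constants 1, substrate (and independent-species) orders 1, inhibition $-0.5$,
activation $+0.5$. `unity_parameters()` lays these down from the topology
alone; overrides replace individual entries afterwards. The resulting
concentrations are not physical — they are indicators of trajectory *shape*.
The convention rests on two empirical observations that the test suite and
the acceptance script quantify on the bundled branched reference pathway:

* **Rate constants mostly stretch time.** Multiplying *all* rate constants by
  $c$ is exactly a change of time unit ($X_c(t) = X(ct)$; asserted to
  $10^{-4}$ relative on the reference model and 20 random networks).
  Single-constant sweeps over the reference grid
  (0.5, 1, 5, 10, 15, 20, 25, 50, 75, 100) move relaxation-time statistics
  far more than normalized amplitudes.
* **Kinetic orders mostly rescale magnitudes.** Sweeping the influx-inhibition
  order over magnitudes 0.1–1.0 doubles the dynamic excursion of the
  pass-through species while its peak time barely moves.

The dichotomy is a tendency, not a theorem. Orders that govern a species' own
dominant efflux (e.g. the substrate order of the main conversion, or a strong
activation of a drain) *do* change time scales noticeably; the quantified
acceptance check therefore uses the influx/drain rate constants and the
regulatory inhibition order — the paradigm cases — and the package exposes
`relaxation_stats()` so users can measure any sweep themselves.

## Dynamics and steady states

Integration uses `deSolve::lsoda` (automatic stiff/non-stiff switching) with
the analytic Jacobian $J_{ij} = \sum_k S_{ik} v_k f_{kj} / X_j$. Default
tolerances are `rtol = 1e-8`, `atol = 1e-10`; the default horizon for
settling checks is 100 time units, matching the observation period the
package's data layout emulates. States below $-10^{-9}$ abort with a
"non-physical state" error; smaller negative round-off is clamped to zero.

`find_steady_state()` runs damped Newton iteration in log-concentration
space: with $z = \log X$ the iterate stays strictly positive for any step,
which matters because negative kinetic orders make the right-hand side
singular at zero. The step is damped by halving (up to $\sim 30$ times, 200
iterations maximum) whenever the residual norm fails to decrease; if Newton
stalls, a relaxation fallback integrates with doubling horizons (50, 100,
..., 1600) and polishes the end state. Newton and relaxation agree to
$10^{-6}$ relative on every fixture — this cross-check is part of the test
suite, with the branched fixture's root verified independently by algebraic
elimination (and in closed form for the U-system variant, where
$X_1 = 0.5^{0.8}$).

Degenerate inputs are first-class: pure accumulators (influx, no efflux) are
reported by `validate_network()` as warnings, fail `is_stable()` with
diagnosis "no settling", and make `find_steady_state()` error after both
strategies.

## Monte-Carlo ensembles

`sample_parameters()` draws rate constants uniformly from $[0.5, 20]$ and
kinetic-order magnitudes uniformly from $[0.2, 0.8]$, signs forced by role
(substrate $+$, inhibitor $-$, activator $+$); 1000 draws by default. One
source states 0.2 as the lower rate-constant bound and another 0.5; the
default is 0.5, and the range is a plain argument. Draws are deterministic
per seed, and all seeding is local (the caller's RNG stream is never
disturbed).

Stability filtering is *behavioral*, not spectral: a draw is kept when
integration over the horizon completes with finite, positive states and the
end state has settled ($\max_i |dX_i/dt|/(1+|X_i|) < 10^{-4}$). This matches
the observable used to discard runs — failure to return to a steady state —
and works identically for any GMA model; the Jacobian's leading eigenvalue at
the end state is reported as a secondary diagnostic. The settling horizon is
100 time units regardless of the display grid, since a trajectory can be
slow *and* stable.

Each stable draw is simulated from the fold-initial condition relative to
*its own* steady state (reference folds 3, 1, 0.5, 2) and normalized by that
steady state — the only reading under which every ensemble member starts
exactly at the fold vector in normalized units, which is also what makes the
min/max `envelope()` meaningful. At 200 draws the envelope contains both the
reference-parameter and the U-system normalized curves at every grid point
(the acceptance check requires $\ge 95\%$ of points per species).

## Perturbations

* **Knockdown** multiplies one flux's rate constant by a remaining fraction
  (0.1 = 90% knockdown). The record stores the original value, so
  `invert_knockdown()` restores the parameters bit-exactly.
* **Supplementation** adds Fick's-law uptake, reduced to the linear gradient
  term $k\,(C_\mathrm{medium} - X)$ active from `start_time`. The term is
  deliberately unclamped — back-diffusion when the cell exceeds the medium is
  physical. The medium is a constant reservoir by default (bulk
  supplementation dwarfs cellular uptake); `medium_depletion = TRUE` adds a
  medium state drained symmetrically. `fit_uptake()` estimates the
  permeability (optionally also the medium concentration) by least squares on
  log-scaled parameters, Brent for one parameter, Nelder–Mead for two.
* **Branch adjustment** (the "modified U-system") is a coordinate-wise grid
  search: for each declared flux group in order, each value of the grid
  (default 0.005, 0.01, 0.05, 0.1, 0.5, 1, 5, 10, 50) is tried and scored by
  the mean Pearson correlation of the re-simulated model against all observed
  series; the best value is kept before moving to the next group. Greedy
  search matches the order-of-magnitude spirit of the adjustment and keeps
  runtime linear in groups × grid; it can miss interacting optima, which is
  why the full score table is returned for audit.
* **Direction prediction** compares steady states with a 1% relative dead
  band (no principled cutoff exists; 1% is well below any biologically
  resolvable change and above solver noise). The perturbed root is seeded by
  relaxing *from the base steady state*, so in multi-stable systems the
  dynamically reached branch is compared; if the perturbed system does not
  settle (a knockdown can destabilize a feedback loop), the function errors
  rather than report a root the dynamics never visit.

## Observed data and statistics

Observations are tidy TSV (`time, species, replicate, group, value`); the
emulated design is 11 sampling times (0, 2, 6, 12, 24, 36, 48, 60, 72, 84,
96 h) in triplicate, treated vs control. Derived statistics use the sample
standard deviation ($n-1$). Relative concentrations are treated mean minus
control mean on the shared time grid — subtracting the control removes
growth and other common-mode trends. CV flagging uses a strict 20% threshold
(the boundary itself is not flagged; the source leaves the boundary open).

`correlate()` interpolates the simulation linearly at observation times and
uses Pearson's $r$ with the exact transform
$t = r\sqrt{(n-2)/(1-r^2)}$ against Student's $t$ with $n-2$ degrees of
freedom (two-sided, survival function). Pearson — not Spearman — because the
$t$-based significance machinery presumes it, and because its affine
invariance is precisely what licenses comparing arbitrary-unit U-system
concentrations with relative peak intensities. The p-value matches direct
numerical integration of the $t$ density to $10^{-10}$.

## The synthetic-observation generator

`synth_observations()` emulates the supplementation experiment's data
*structure*: treated = simulated trajectory at the design times, control =
steady state, both times lognormal noise with the requested CV (σ chosen so
the noise factor has mean 1 and the prescribed CV; multiplicative error is
the standard model for positive MS peak intensities). Defaults: CV 10% —
between the "reliable" (<20%) and flagged (>20%) regimes of real
metabolome data — and 3 replicates.

What it does **not** emulate: growth trends in the control, heteroscedastic
or correlated replicate error, detection limits/missingness, batch effects,
and internal-standard normalization artifacts. Passing recovery tests on
this generator therefore demonstrates correctness of the estimation
machinery under the stated noise model, not robustness to everything real
LC-MS/GC-MS data can do.

## Problem sizes used in tests

The test and acceptance computations run on the bundled small fixtures: 100
random states for equation fidelity, 20 random networks for rescaling
invariance, 200 Monte-Carlo draws for the envelope (the envelope statement
stabilizes well below that), sweeps of 10 values on a 2001-point grid, 20
seeds for noisy-recovery medians, and 50 random knockdowns. These sizes give
Monte-Carlo statements comfortable margins while keeping the whole suite in
the tens of seconds on one core.

## Known limitations

* The U-system is a *qualitative* instrument: it predicts shapes,
  directions, and orderings, never absolute concentrations or real time
  constants (those enter only through the modified-U-system adjustment).
* The rate/order dichotomy has documented exceptions (efflux-dominating
  orders); conclusions drawn from single-parameter sweeps should check
  `relaxation_stats()` rather than assume the tendency.
* GMA systems can be multi-stable; steady-state-based statements are local
  to the dynamically reached branch.
* Steady-state search with depleting uptake treats the medium as a constant
  reservoir during root finding; with depletion the true late-time state has
  medium equal to cell concentration, so use long simulation instead.
* Stoichiometric coefficients > 1 follow the simplest consistent reading
  (multiplying the balance term only); systems where the coefficient should
  also steepen the kinetic order need explicit overrides.
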