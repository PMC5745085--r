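---
title: "Kinetics of Vg1-Nodal heterodimer formation: models, oracles and design choices"
author: "vg1nodal authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetics of Vg1-Nodal heterodimer formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vg1nodal)
```

## The scientific question

Mesendoderm induction in the zebrafish embryo is driven by Nodal, a
TGF-beta-family ligand whose active form is a disulfide-linked dimer. The
embryo inherits a large maternal pool of Vg1 (Dvr1/Gdf3) monomers, while
Nodal itself is only produced zygotically, from about 4 hours
post-fertilization (hpf). This package quantifies a kinetic argument about
why that maternal pool matters: if the active ligand is a Vg1-Nodal
*heterodimer*, every newly translated Nodal monomer meets a waiting excess
of partner and dimerizes essentially at once; if instead Nodal had to
*homodimerize* from a cold start, two rare monomers would have to find each
other, and dimer formation would lag behind the narrow 4-6 hpf patterning
window.

## The two models

Both schemes are deterministic mass-action systems for the Nodal monomer
$N$, the Vg1 monomer $V$, and the dimer $D$ (concentrations in M, time in
s).

**Primed (heterodimer) model.** Vg1 is maternally deposited and enters
only through the initial condition $V(0) = V_0$:

$$
\frac{dN}{dt} = \lambda_N(t) - \beta_N N - \lambda_D N V, \qquad
\frac{dV}{dt} = -\beta_V V - \lambda_D N V, \qquad
\frac{dD}{dt} = \lambda_D N V .
$$

**Cold-start (homodimer) model.** No Vg1; Nodal accumulates and
homodimerizes:

$$
\frac{dN}{dt} = \lambda_N(t) - \beta_N N - \lambda_D N^2, \qquad
\frac{dD}{dt} = \lambda_D N^2 .
$$

Synthesis is windowed and piecewise constant,
$\lambda_N(t) = \lambda_N^{\mathrm{on}}$ for
$t_\mathrm{on} < t < t_\mathrm{off}$ and 0 otherwise, representing the
onset of zygotic transcription at 4 hpf and the close of mesendodermal
patterning at 6 hpf. Degradation is first order; dimers are not degraded
and are never consumed. At exactly $t_\mathrm{on}$ and $t_\mathrm{off}$ we
define $\lambda_N = 0$: the value on a measure-zero set cannot change any
integral, and a fixed convention makes `production_rate()` deterministic
and testable.

### A note on stoichiometry

The cold-start equations remove **one** unit of $N$ per unit of $D$ formed
($-\lambda_D N^2$ in $dN/dt$, $+\lambda_D N^2$ in $dD/dt$). Chemical 2:1
stoichiometry would remove $2\lambda_D N^2$. We implement the equations
exactly as written above; the bookkeeping identity used by
`mass_ledger()` (one produced monomer is always either free, dimerized, or
degraded) relies on that convention, and the stochastic twin is built to
match it (see below). A physically stoichiometric variant is deliberately
out of scope: fidelity to one declared model is the contract every oracle
in the package checks against.

## Parameters

| Field | Meaning | Default | Units |
|---|---|---|---|
| `lambda_N_on` | Nodal synthesis rate in the window | 2e-13 | M s$^{-1}$ |
| `beta_N` | Nodal degradation rate | 1.16e-4 | s$^{-1}$ |
| `beta_V` | Vg1 degradation rate | 1.16e-4 | s$^{-1}$ |
| `lambda_D` | dimerization rate | 1e6 | M$^{-1}$ s$^{-1}$ |
| `V0` | maternal Vg1 pool | 100 | nM |
| `t_on`, `t_off` | production window | 4, 6 | hpf |
| `t_end` | simulation horizon | 10 | hpf |

The degradation rate corresponds to a component half-life of
$\ln 2 / \beta \approx 1.66$ h. All internal computation is in SI (M, s);
user-facing I/O uses nM and hpf with exact conversions (1 nM = 1e-9 M,
1 hpf = 3600 s), because the natural parameter table mixes molar rates
with hour-scale windows and nanomolar pools. The horizon of 10 hpf is our
choice, not a model constant: it covers the post-window decay of both
trajectories and is configurable.

Two scales worth internalizing: during the window the primed model's free
Nodal settles near $\lambda_N / (\lambda_D V) \sim 2$ pM — virtually every
monomer is captured by the Vg1 pool — while the cold-start monomer must
climb to its quasi-steady state
$N^* = \bigl(-\beta_N + \sqrt{\beta_N^2 + 4\lambda_D\lambda_N}\bigr)/
(2\lambda_D) \approx 0.393$ nM before homodimerization runs at full speed.
That climb is the onset delay the metrics module measures.

## Numerical integration

`integrate_model()` wraps `deSolve::lsoda`, but never hands the solver a
discontinuous right-hand side: integration is split at $t_\mathrm{on}$ and
$t_\mathrm{off}$ and the state is passed across segment boundaries, because
adaptive step-size controllers mis-handle jumps inside a step. Three
cumulative integrals (production, and both degradation losses) are
co-integrated so that conservation can be checked after the fact rather
than assumed.

Default tolerances are `rel_tol = 1e-8` and `abs_tol = 1e-15` M, several
orders below the nanomolar signal. Negative concentrations beyond
tolerance raise an error; we do not clip, since clipping hides solver
failure. The default output grid reports every 60 s.

Correctness is established against three independent oracles rather than
by inspection:

* **Closed forms.** With $\lambda_D = 0$ the monomer equation is linear
  with piecewise-constant forcing and solves in elementary terms
  (`monomer_closed_form()`, `vg1_decay_closed_form()`); the integrator
  matches to better than 1e-6 relative pointwise. At window close the
  no-dimerization monomer is
  $(\lambda_N/\beta_N)(1 - e^{-\beta_N \cdot 7200}) \approx 0.976$ nM.
* **Fixed-step RK4.** The test suite carries a deliberately independent
  classical RK4 integrator (equations restated inline, 1 s steps) and
  requires agreement on both dimer curves. For these oracle comparisons
  the adaptive solver is run at `rel_tol = 1e-10`, `abs_tol = 1e-20` so
  the check probes the solution rather than the default atol cushion —
  relevant because the primed monomer lives at picomolar scale.
* **Conservation ledgers.** `mass_ledger()` residuals stay below
  $10^{-6} V_0$ along the whole default run.

For the quasi-steady-state regression test we require the cold-start
monomer to sit within 5% of $N^*$ throughout the final quarter of the
production window; both the 5% and the assessment region are our own
robustness choices, not model claims.

## The stochastic twin

The deterministic models say nothing about copy-number noise, so the
package carries an exact Gillespie (direct method) realization of both
networks as a cross-validation oracle (`ssa_run()`, `ssa_ensemble()`;
compiled via Rcpp). Design choices:

* **Volume.** The default $\Omega$ maps the 100 nM Vg1 pool to $10^5$
  molecules ($\Omega = 10^5/(100\times 10^{-9} N_A) \approx 1.66$ pL),
  keeping ensemble runs fast while fluctuations remain visible.
* **Time-varying production.** The production propensity
  $\lambda_N(t)\,\Omega N_A$ is piecewise constant, so each realization is
  segmented at the window boundaries and the plain direct method stays
  exact — no time-inhomogeneous thinning needed.
* **Cold-start event.** Homodimerization fires with propensity
  $\lambda_D\, n_N (n_N - 1) / (\Omega N_A)$ and consumes **one** N. A
  chemically standard $N + N \to D$ event would not have the printed
  equations as its mean field; oracle fidelity outranks physical realism
  here. With near-Poisson monomer statistics the $n_N(n_N-1)$ propensity
  also makes the ensemble mean track $N^2$ without a finite-size
  correction at leading order.
* **Reproducibility.** All randomness flows through R's RNG; replicate
  seeds are drawn deterministically from the configuration seed, so
  ensembles are bit-for-bit reproducible.

The central check: with 1000 replicates at the default volume, the
ensemble-mean dimer lies within 3 standard errors of the deterministic
trajectory at essentially all of 50 recorded times, for both models.

## Synthetic observations and parameter recovery

No trajectory-level measurements of this system exist, so the recovery
stage runs on data the package generates itself
(`generate_noisy_trajectories()`): the deterministic dimer trajectory
observed through multiplicative lognormal noise,
$y_{rt} = D(t)\,e^{\varepsilon_{rt}}$,
$\varepsilon_{rt} \sim \mathcal N(0, \sigma^2)$ i.i.d. The noise model is
a declared choice — multiplicative errors are the norm for fluorescence
intensity measurements — and it fixes the fitting objective: least squares
on $\log y$ (`fit_parameters()`), which is maximum likelihood under that
noise. Observation times where the noiseless dimer is exactly zero are
excluded, since their log-residual is undefined.

The default observation design (`default_obs_times()`) is one observation
per 60 s from just after production onset to the end of the run, matching
the simulator's reporting cadence and a realistic time-lapse acquisition
rate. Density matters: the dimer curve is only weakly sensitive to
$\lambda_D$ at the default operating point (root-mean-square
$\partial \log D / \partial \log \lambda_D \approx 0.02$, because
dimerization is far from rate-limiting when $\lambda_D V \gg \beta_N$), so
sparse designs inflate the $\lambda_D$ estimate's sampling error roughly
as $1/\sqrt{\text{points}}$. With the default design, $\sigma = 0.1$ and
20 replicates, $\lambda_D$ comes back within a few percent of its
generating value; with noiseless data, single-parameter refits of
$\lambda_N^{\mathrm{on}}$, $\beta_N$ and $\lambda_D$ recover the truth to
much better than 0.1%.

Optimization is bounded, deterministic and local over log10 parameters:
Brent's method for one free parameter, L-BFGS-B otherwise. Joint
multi-parameter fits run, but dimer-only data do not guarantee joint
identifiability (e.g. $\lambda_N^{\mathrm{on}}$ and $V_0$ trade off
against each other in the primed flux), so only single-parameter recovery
is treated as a package-level guarantee.

## Metrics

`compare_models()` turns the qualitative comparison into numbers: first
crossing times of a dimer threshold $\theta$ (linear interpolation on the
recorded grid, first bracketing interval), the cold-minus-primed onset
delay, dimer levels at window close, and a dominance flag
($D_\mathrm{primed} \ge D_\mathrm{cold}$ at every shared grid point). No
signaling threshold is dictated by the models, so $\theta$ is free with
default 0.1 nM, and the ordering claims are required to hold across
$\theta$ from 0.01 to 1 nM — the conclusion is an ordering, not a number.
Under the defaults the primed model crosses 0.1 nM about 0.49 h before the
cold-start model and holds more dimer at every instant.

## What the synthetic data do and do not show

The generator emulates exactly the structure the models assume: windowed
constitutive synthesis, first-order decay, mass-action dimerization,
lognormal observation noise, dimer-only observability. Passing tests
therefore demonstrate *internal* consistency — integrator against closed
forms and RK4, stochastic means against deterministic trajectories,
estimator against generator — not that the models describe an embryo.
Real data would add features the package deliberately does not simulate:
spatial transport and gradients, receptor binding and Lefty-mediated
inhibition, dimer turnover, cell-to-cell variability in synthesis rates,
and measurement backgrounds that are additive rather than multiplicative.

## Problem sizes

Default runs integrate 601-point grids over 0-10 hpf; ensemble
cross-validation uses 1000 replicates at $10^5$ molecules per 100 nM and
50 recorded times; recovery uses 20 replicates at 360 observations each.
A full test run plus the acceptance computation completes in well under a
minute on one core.
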