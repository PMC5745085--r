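# vg1nodal

Kinetic models of TGF-beta ligand dimerization in the early zebrafish
embryo: Vg1-Nodal **heterodimer** formation from a maternally preloaded
Vg1 pool (the *primed* scheme) versus Nodal **homodimer** formation from a
*cold start*.

Nodal signaling patterns the mesendoderm in a narrow window (~4-6 hours
post-fertilization), yet Nodal is only produced zygotically. The embryo,
however, inherits a large maternal pool of Vg1 monomers. This package
implements and tests the kinetic argument that the preloaded pool is what
makes a rapid response possible: with ~100 nM Vg1 waiting, each new Nodal
monomer heterodimerizes almost immediately, whereas homodimerization
requires two rare Nodal monomers to meet and is delayed past the
patterning window's opening.

## The models

Mass-action systems for Nodal monomer *N*, Vg1 monomer *V*, dimer *D*
(M, s), with windowed synthesis
λ_N(t) = λ_N^on for t_on < t < t_off, else 0:

Primed:      dN/dt = λ_N(t) − β_N N − λ_D N V
             dV/dt = −β_V V − λ_D N V
             dD/dt = λ_D N V

Cold-start:  dN/dt = λ_N(t) − β_N N − λ_D N²
             dD/dt = λ_D N²

Defaults: λ_N^on = 2e-13 M/s (4-6 hpf), β_N = β_V = 1.16e-4 /s,
λ_D = 1e6 /M/s, V(0) = 100 nM.

The package provides:

* `integrate_model()` — piecewise ODE integration (deSolve) with
  conservation ledgers (`mass_ledger()`);
* `monomer_closed_form()`, `vg1_decay_closed_form()`,
  `cold_start_qss_monomer()` — closed-form oracles in degenerate limits;
* `ssa_run()`, `ssa_ensemble()` — exact Gillespie realization of both
  networks at integer molecule counts (Rcpp), the stochastic
  cross-validation of the deterministic solutions;
* `compare_models()`, `time_to_threshold()`, `dominance_margin()` —
  onset-delay and dominance metrics for the primed vs cold-start
  comparison;
* `generate_noisy_trajectories()`, `fit_parameters()` — synthetic noisy
  dimer observations and log-least-squares parameter recovery;
* CSV/JSON/YAML I/O plus a thin command-line wrapper
  (`inst/cli/vg1nodal.R` with subcommands `simulate`, `compare`, `ssa`,
  `synth`, `fit`).

See the vignette `vignettes/dimerization-kinetics.Rmd` for the modeling
assumptions, stoichiometry conventions, and design rationale.

## Worked example

```r
library(vg1nodal)

params <- default_parameters()
report <- compare_models(params, theta = nM_to_M(0.1))
report
#> Primed (Vg1-Nodal heterodimer) vs cold-start (Nodal homodimer):
#>   threshold:          0.1 nM
#>   t(theta), primed:   4.1554 hpf
#>   t(theta), cold:     4.6457 hpf
#>   onset delay:        0.4903 h
#>   D at window close:  1.399 (primed) vs 0.7861 (cold) nM
#>   primed dominates everywhere: TRUE
```

The primed model crosses a 0.1 nM dimer threshold ~9 minutes after
production starts; the cold-start model needs ~39 minutes — a 0.49 h onset
delay — and by the close of the production window (6 hpf) holds only
0.79 nM of dimer against 1.40 nM for the primed scheme, which leads at
every time point. The delay reflects the cold-start monomer having to
climb to its quasi-steady state before homodimerization runs at speed:

```r
M_to_nM(cold_start_qss_monomer(params))
#> [1] 0.392959
```

Plot the comparison (requires ggplot2):

```r
plot_comparison(report)
```

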