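# actokin

Kinetic modelling and fitting for the actomyosin ATPase cycle and its
modulation by small-molecule effectors.

Beta-cardiac myosin turns over ATP through a cycle of actin-detached and
actin-attached states: ATP binding (apparent second-order constant
*K₁k₊₂*, saturating at the isomerisation rate *k₊₂*), hydrolysis
(*k₊₃ + k₋₃*), actin-activated phosphate release (*k₊₄*, the
rate-limiting step), and ADP release (*k₋D* detached, *k₋AD* attached).
Steady-state activity follows the activation hyperbola
*v*([A]) = *v₀* + (*k*<sub>cat</sub> − *v₀*)[A]/(*K*<sub>M</sub> + [A]),
and allosteric activators such as the thiadiazinone EMD 57033 change
several steps at once — including a chaperone-like rescue of
heat-inactivated motors whose kinetics follow
*k*<sub>obs</sub> = *k*<sub>rescue</sub>·[EMD] + *k*<sub>off</sub>.

The package is aimed at kinetics practitioners who need this full
analysis chain in one place:

* an eight-state ODE model of the cycle (`simulate_cycle`,
  `steady_state_rate`, `project_observable`) with stationary-flux and
  conservation guarantees;
* fitting stages for every standard experiment class, each returning a
  classed `kin_fit` object with `print`/`summary`/`coef`/`predict`/
  `plot`/`simulate`/`residuals` methods: multi-exponential stopped-flow
  transients (`fit_exponentials`, `analyze_atp_dependence`,
  `active_site_titration`), actin activation
  (`fit_actin_activation`), Hill dose-response and binding isotherms
  (`fit_dose_response`, `fit_binding_isotherm`), Arrhenius series
  (`arrhenius_fit`), Boltzmann thermal melts (`fit_melt`, `delta_tm`),
  shelf-life decay (`fit_shelf_life`), refolding recovery
  (`fit_recovery`, `fit_rescue_line`, `simulate_refolding`), and
  motility velocity distributions (`analyze_velocities`);
* a seeded synthetic-data generator for each experiment class
  (`synth_spec`, `synth_generate`) so the whole chain is testable as a
  parameter-recovery exercise;
* a config-driven pipeline (`run_pipeline`) that generates, fits, and
  compares every recovered constant and fold change against the
  reference table (`reference_constants`), plus a thin command-line
  wrapper in `exec/actokin`.

## A worked example

Simulate a noisy actin-activation titration with the control-condition
constants as truth and fit it back:

```r
library(actokin)

steady_state_rate(reference_rates("control"), atp_conc = 1000,
                  actin_conc = 30)
#> [1] 0.04762785

sp <- synth_spec("actin_titration",
                 list(basal = 0.049, kcat = 0.12, KM = 36.8),
                 noise_sd = 0.01, seed = 1)
d <- synth_generate(sp)
fit <- fit_actin_activation(d$x, d$y)
fit
#> <kin_fit: actin activation>
#>   kcat               0.12 +/- 0.001317   s^-1
#>   KM                36.29 +/- 1.889      uM
#>   basal           0.04886 +/- 0.0003772  s^-1
fit$extra$coupling_ratio
#> [1] 0.003307443
```

The fitted maximal turnover (0.12 s⁻¹), apparent actin affinity
(36.3 µM against a generating truth of 36.8 µM) and coupling constant
(0.0033 µM⁻¹s⁻¹) come back at the 1% noise level of the synthetic
titration. The full report over every experiment class:

```r
rep <- run_pipeline(seed = 1)
rep          # aligned table: estimate, SE, reference, pass/fail
rep$folds    # fold changes between control and treated conditions
```

See `vignettes/actomyosin-kinetics.Rmd` for the model, the fitting
stages, and the design choices behind the generator defaults.

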