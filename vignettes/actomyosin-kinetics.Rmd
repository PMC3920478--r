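---
title: "Modelling and recovering actomyosin ATPase kinetics with actokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and recovering actomyosin ATPase kinetics with actokin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actokin)
```

## The scientific problem

Myosin motors convert ATP hydrolysis into force along actin filaments
through a cyclic reaction: ATP binds the motor and detaches it from
actin, the motor hydrolyses ATP in the detached state, rebinding to
actin accelerates phosphate release, and ADP release completes the
cycle. Small-molecule effectors such as the thiadiazinone EMD 57033
bind an allosteric pocket in the motor domain of beta-cardiac myosin
and change several of these steps at once: they accelerate ATP binding,
hydrolysis and phosphate release, tighten the functional coupling
between the actin and nucleotide binding sites, stabilise the folded
motor against thermal denaturation, and can even restore activity to
heat-inactivated motors (a "pharmacological chaperone" effect).

Characterising such an effector means fitting a dozen different
experiment classes — stopped-flow fluorescence transients, steady-state
actin-activation curves, compound dose-response and binding isotherms,
Arrhenius temperature series, thermal melts, refolding time courses and
motility velocity distributions — each with its own standard model
curve. `actokin` packages all of these stages behind one consistent
fitting interface, adds a mechanistic ODE model of the full cycle, and
ships a seeded synthetic-data generator so that the entire analysis
chain can be validated end to end as a parameter-recovery exercise: the
published constants are used as generating truths, data are simulated
at realistic noise, and the fitting stages must give them back.

## The cycle model

`simulate_cycle()` integrates an eight-state network: the four
nucleotide states of the motor (M, M·T, M·D·Pi, M·D) in a detached and
an actin-attached branch.

* **ATP binding** is a rapid equilibrium followed by an isomerisation,
  so the effective pseudo-first-order rate saturates:
  $k_\mathrm{bind}([T]) = K_1k_{+2}[T]\,k_{+2}/(K_1k_{+2}[T]+k_{+2})$.
  The observed fast-phase rate therefore never exceeds $k_{+2}$.
* **Hydrolysis** is one lumped relaxation $k_{+3}+k_{-3}$ treated as
  irreversible for flux purposes (the published tables report only the
  combined relaxation rate).
* **Phosphate release** is fast ($k_{+4}$) only from the attached
  A·M·D·Pi state; the detached pathway releases phosphate at a slow
  basal rate (`k4_basal`, default 0.02 s⁻¹). This asymmetry is what
  produces actin activation in the model.
* **ADP release** is $k_{-D}$ detached and $k_{-AD}$ attached.
* **Actin binding** is pseudo-first-order (`actin_on`, default
  1 µM⁻¹ s⁻¹) for every detached state; the weak-binding states detach
  at `actin_off_weak`, the strong states are treated as
  non-dissociating on the modelled time scales.

`actin_on`, `actin_off_weak` and `k4_basal` are free parameters: they
are not measurable from the assays modelled here and no published
values exist for them. The default `actin_off_weak = 42.3` s⁻¹ was
fixed once with `calibrate_actin_off()` so that the simulated apparent
actin affinity of the control condition matches the measured
$K_M(\mathrm{actin}) = 36.8$ µM; `k4_basal` is a typical basal
phosphate-release rate for a class-2 myosin.

Two consistency properties tie the model together and are enforced by
the test suite: occupancies are conserved to $10^{-9}$ at every time
point, and the stationary flux computed from the null space of the rate
matrix (`steady_state_rate()`) agrees with the long-time ODE flux to
$10^{-6}$ relative on random rate sets spanning six orders of
magnitude. When actin binding is made fast and irreversible the network
flux collapses to the series-of-steps closed form
$1/\sum_i 1/k_i$; with the control constants this gives
$\approx 0.086$ s⁻¹, which deliberately remains below the measured
$k_\mathrm{cat} = 0.12$ s⁻¹ — the published microscopic constants do
not arithmetically reproduce the published steady-state maximum, and
the package keeps both numbers rather than reconciling them (the model
check uses a 30% band).

In single-turnover mode ATP is a dynamic species consumed by binding
(`head_conc` sets the scale), and projecting the trajectory through the
mant-nucleotide observable channel reproduces the characteristic
rise–plateau–decay shape, with the decay roughly twofold faster under
the treated rate set.

## The fitting stages

Every stage returns a `kin_fit` object (coefficients, standard errors,
residual norm, flags) supporting `print`, `summary`, `coef`, `predict`,
`residuals`, `plot` and `simulate`. Internals are
Levenberg–Marquardt least squares (`minpack.lm`) behind a multi-start
wrapper; ties are broken by residual norm.

* `fit_exponentials()` — one or two phases
  $y(t) = y_0 + \sum_i A_i(1-e^{-k_i t})$; data-driven initial values
  plus eight log-spaced rate initialisations; phases reported fast to
  slow; flat traces return a diagnosable failed fit. On 200-point
  traces the multi-start optimum matches an exhaustive
  coarse-grid-plus-polish search to well under 0.5%.
* `analyze_atp_dependence()` — fast-phase $k_{obs}$ versus [ATP] is
  fitted with a rectangular hyperbola; its plateau is $k_{+2}$ and its
  initial slope (plateau over half-saturation) is the second-order
  binding constant $K_1k_{+2}$. The straight-line slope over the
  low-concentration regime (predicted $k_{obs}\le 0.3\,k_{+2}$) is also
  reported (`K1k2_linear`): it is what slope plots display, but it is
  biased low by residual curvature — the lm slope approximates the
  local derivative of the hyperbola, a factor
  $(k_{+2}/(K_1k_{+2}[T]+k_{+2}))^2$ — so the hyperbola-derived value
  is the primary estimate. Ratios of the linear slopes between
  conditions are still meaningful because the bias largely cancels.
  The slow-phase plateau gives the hydrolysis rate and is flagged
  unreliable if the data reach less than 80% of it.
* `fit_actin_activation()` — $v([A]) = v_0 + (k_\mathrm{cat}-v_0)
  [A]/(K_M+[A])$. The coupling constant is reported both ways the field
  prints it: the ratio $k_\mathrm{cat}/K_M$ and the initial slope
  $(k_\mathrm{cat}-v_0)/K_M$. They coincide exactly when the basal
  offset is zero; with the reference values they differ (0.00326 vs
  0.00193 µM⁻¹s⁻¹), which pins the unpublished basal rate at
  $\approx 0.049$ s⁻¹ (control) and $\approx 0.081$ s⁻¹ (treated) —
  these are the generator defaults.
* `fit_dose_response()` / `fit_binding_isotherm()` — Hill curves with a
  free coefficient bounded to [0.5, 4] (the source analyses state "Hill
  equation" without printing an exponent).
* `arrhenius_fit()` — `lm` of $\ln k$ on $1/T$; $E_a = -R\,\cdot$slope.
* `fit_melt()` — signals are normalized to [0, 1] and oriented so 0 is
  the folded baseline, then fitted with the Boltzmann sigmoid
  $y = b + s/(1+e^{(T_m-T)/w})$; $T_m$ is invariant under affine
  transforms of the raw signal, including sign flips. The same form is
  applied to circular-dichroism unfolding and light-scattering
  aggregation curves, as in the source analyses.
* `fit_recovery()` — refolding time courses are fitted with a
  rectangular hyperbola in time, $y = b + (p-b)t/(t_{1/2}+t)$, and the
  observed rate is reported as $k_{obs} = 1/t_{1/2}$. The published
  analysis says only "hyperbola" and plots "observed rate constants"
  without defining the transform; this choice is applied consistently
  to synthetic truths and fits, so recovery targets are
  self-consistent. A saturating-exponential alternative is available
  (`model = "exponential"`) with a residual-norm comparison
  (`compare = TRUE`).
* `fit_rescue_line()` — weighted line through $k_{obs}$ versus compound
  concentration; slope $k_\mathrm{rescue}$, intercept the dissociation
  rate.
* `active_site_titration()` — two-segment (linear-then-flat) model
  profiled over the breakpoint; the breakpoint concentration estimates
  the competent-site concentration.
* `analyze_velocities()` — filaments above a stall threshold (default
  0.1 µm s⁻¹, a documented choice: the source defines no criterion for
  "moving") are histogrammed (Freedman–Diaconis widths, 0.05 µm s⁻¹
  fallback) and fitted with a Gaussian, falling back to sample moments.

`fold_change()` propagates standard errors into treated/control ratios;
affinity-like parameters ($K_M$, $E_a$) are reported in the
control/treated direction to match the conventional "n-fold decrease"
framing, and the direction is recorded in the output.

## The synthetic-data generator

`synth_spec()` + `synth_generate()` produce every experiment class from
named true parameters, a sampling grid, a noise level and a seed.
Design choices:

* **Noise** is additive, homoscedastic Gaussian, by default 1% of the
  noiseless signal span. Instrument noise in stopped-flow and
  plate-reader traces is approximately signal-independent, and the
  source figures do not print noise magnitudes, so 1% is a choice, not
  a derived value. Heteroscedastic noise is deliberately out of scope.
* **Grids** mirror the standard instrument regimes: fast transients
  0–10 s at 1 kHz, slow (phosphate-release) transients 0–200 s at
  10 Hz, melts 25–90 °C in 1 °C steps, refolding series 0–2 h sampled
  every 5 min.
* **Seeding**: a dataset's seed fully determines its bytes, generation
  never touches the caller's RNG state, and multi-dataset runs derive
  per-dataset seeds from a global seed by a fixed rule
  (`seed + 10007 * index` mod $2^{31}-1$), so adding a dataset never
  perturbs earlier ones.

What the generator deliberately does **not** emulate: raw instrument
file formats, photobleaching and shutter artefacts, heteroscedastic or
correlated noise, pipetting/concentration errors, and day-to-day
preparation variability. Passing recovery tests therefore demonstrate
that the fitting stages are correct and well-conditioned at realistic
noise — not that every systematic error of a real instrument is
handled.

## The refolding state model

`simulate_refolding()` integrates the four-state rescue scheme:
conformationally trapped soluble aggregates bind the compound
(`k_on`, µM⁻¹s⁻¹) and become a nucleotide-binding-competent but
hydrolysis-incompetent state, which matures into the rescued, fully
competent state; trapped protein can also be lost irreversibly to
insoluble aggregates. Only the slope and intercept of the linear
rescue analysis are published; the remaining rates are free parameters
used for property tests. When maturation and its reverse are fast
compared to binding, the bound states quasi-equilibrate and the scheme
reduces to two states with apparent relaxation
$k_\mathrm{on}[\mathrm{EMD}] + k_\mathrm{off}^\mathrm{eff}$, where
$k_\mathrm{off}^\mathrm{eff} = k_\mathrm{off,1}k_\mathrm{off,2} /
(k_\mathrm{mature}+k_\mathrm{off,2})$. The defaults sit in that regime
with $k_\mathrm{off}^\mathrm{eff} = 2.3\times10^{-4}$ s⁻¹, so the
simulator's concentration dependence reproduces the linear analysis
within 5% over 10–100 µM — the consistency the tests enforce.

## Numerical choices

* ODE integration: `deSolve::lsoda` (adaptive, stiff-capable) with
  relative tolerance $10^{-8}$ and absolute $10^{-10}$; rate constants
  span five orders of magnitude, so a stiff solver is required.
* Stationary distributions: direct solve of $Qx=0$ with the
  conservation row; SVD null-space fallback for singular (absorbing)
  networks, which report zero flux instead of raising.
* Long-time flux checks integrate to 40 relaxation times of the
  slowest network eigenvalue, excluding the conservation eigenvalue on
  a scale relative to the fastest rate.
* Units are fixed throughout: seconds, micromolar; temperatures enter
  in °C and are converted to Kelvin internally.
* Report-layer rounding is 2 significant figures for fold changes;
  full precision is retained internally.

## The pipeline and its tolerances

`run_pipeline()` executes a configured list of experiments
(generate → fit → compare), derives per-experiment seeds from the
global seed, and emits a machine-readable JSON report (byte-stable
under a fixed seed) plus an aligned text table. The default
configuration covers every reference constant at module default noise.
Per-parameter pass tolerances are set at roughly three times the
single-realization sampling spread of each estimator at that noise
level (10% default; 20% for $K_M$, the most weakly constrained
parameter; 15%/30% for the rescue slope/intercept; 10% for $E_a$, 5%
for $T_m$; fold-change rows use $\sqrt{2}$ times the parameter band
since they compound two estimates) — a single-seed run is a smoke
check, while the statistical
recovery guarantees (medians over 100 seeds within 10%, 5% for
Arrhenius and Boltzmann fits) are enforced in the test suite and the
acceptance script at problem sizes that keep the full run under a few
minutes on one CPU.

## A worked example

```{r example}
rates <- reference_rates("control")
steady_state_rate(rates, atp_conc = 1000, actin_conc = 30)

sp <- synth_spec("actin_titration",
                 list(basal = 0.049, kcat = 0.12, KM = 36.8),
                 noise_sd = 0.01, seed = 1)
d <- synth_generate(sp)
fit <- fit_actin_activation(d$x, d$y)
fit
fit$extra$coupling_ratio
```

## Known limitations

* The cycle model has no force generation, no load dependence, and no
  Ca²⁺ regulation; it describes solution kinetics only.
* The hydrolysis step is lumped and irreversible, so phosphate-burst
  amplitudes (which depend on the hydrolysis equilibrium constant) are
  not meaningful in the model.
* The actin-binding parameters are calibrated, not measured; simulated
  absolute occupancies of weak versus strong attached states should not
  be over-interpreted.
* The published microscopic constants imply a maximal cycle flux ~30%
  below the published $k_\mathrm{cat}$; both are retained as stated.
* The apo melting midpoint is quoted as 45.8 °C in one place and
  45.1 °C in another in the source material; the reference table keeps
  the 45.1 value and the discrepancy is left unreconciled.
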