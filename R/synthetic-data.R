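## Seeded synthetic-data generation for every experiment class handled
## by the fitting modules. A SyntheticSpec fully determines a dataset:
## identical specs yield identical data, and per-dataset seeds are
## derived from a global seed by a fixed rule (see derive_seed()).

SYNTH_KINDS <- c("transient_biphasic", "single_turnover", "pi_release",
                 "actin_titration", "dose_response", "binding_isotherm",
                 "arrhenius_series", "melt_curve", "refolding_series",
                 "velocity_sample", "shelf_life")

#' Specification of a synthetic dataset
#'
#' Bundles the experiment kind, the generating (true) parameters, the
#' sampling grid, the noise level and the seed. Noise is additive,
#' homoscedastic Gaussian on the signal; `noise_sd` is interpreted as a
#' fraction of the noiseless signal span by default
#' (`noise_type = "fraction"`) or in signal units
#' (`noise_type = "absolute"`).
#'
#' @param kind one of the supported experiment kinds (see Details)
#' @param true_params named list of generating parameters with the
#'   units used throughout the package (s, uM, degC)
#' @param grid sampling points (s, uM, or degC depending on kind);
#'   `NULL` selects the kind's default grid
#' @param noise_sd noise level (default 0.01 = 1% of span)
#' @param noise_type `"fraction"` or `"absolute"`
#' @param seed integer seed for this dataset
#' @details Supported kinds: `transient_biphasic`, `single_turnover`,
#'   `pi_release`, `actin_titration`, `dose_response`,
#'   `binding_isotherm`, `arrhenius_series`, `melt_curve`,
#'   `refolding_series`, `velocity_sample`, `shelf_life`.
#' @return an object of class `synth_spec`
#' @export
synth_spec <- function(kind, true_params = list(), grid = NULL,
                       noise_sd = 0.01, noise_type = c("fraction",
                                                       "absolute"),
                       seed = 1L) {
  kind <- match.arg(kind, SYNTH_KINDS)
  noise_type <- match.arg(noise_type)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (is.null(grid)) grid <- default_grid(kind, true_params)
  if (kind != "velocity_sample") {
    if (length(grid) == 0 || is.unsorted(grid))
      stop("grid must be non-empty and sorted", call. = FALSE)
  }
  structure(list(kind = kind, true_params = true_params, grid = grid,
                 noise_sd = noise_sd, noise_type = noise_type,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

## Default sampling grids mirror the standard instrument regimes:
## fast stopped-flow transients 0-10 s at 1 kHz, slow (phosphate
## release) transients 0-200 s at 10 Hz, recovery series 0-2 h sampled
## every 5 min, melts 25-90 degC in 1 degC steps.
default_grid <- function(kind, true_params = list()) {
  switch(kind,
    transient_biphasic = seq(0, 10, by = 1e-3),
    single_turnover = seq(0, 200, by = 0.1),
    pi_release = seq(0, 200, by = 0.1),
    actin_titration = c(0, 2.5, 5, 10, 20, 40, 70, 100),
    dose_response = c(0, 0.5, 1, 2, 5, 10, 20, 50, 100),
    binding_isotherm = 10^seq(log10(0.01), log10(200), length.out = 12),
    arrhenius_series = seq(25, 45, by = 5),
    melt_curve = seq(25, 90, by = 1),
    refolding_series = seq(0, 7200, by = 300),
    shelf_life = seq(0, 28, by = 2),
    velocity_sample = NULL)
}

#' @export
print.synth_spec <- function(x, ...) {
  cat(sprintf("<synth_spec: %s, %d grid points, noise %g (%s), seed %d>\n",
              x$kind,
              length(x$grid %||% integer()), x$noise_sd, x$noise_type,
              x$seed))
  invisible(x)
}

new_dataset <- function(x, y, spec) {
  stopifnot(length(x) == length(y), all(is.finite(y)))
  structure(list(x = x, y = y, spec = spec), class = "kin_dataset")
}

#' @export
print.kin_dataset <- function(x, ...) {
  cat(sprintf("<kin_dataset: %s, n = %d>\n", x$spec$kind, length(x$x)))
  invisible(x)
}

#' @export
as.data.frame.kin_dataset <- function(x, ...) data.frame(x = x$x, y = x$y)

add_noise <- function(y, spec) {
  if (spec$noise_sd == 0) return(y)
  sd_abs <- if (spec$noise_type == "absolute") spec$noise_sd
            else {
              span <- diff(range(y))
              if (span <= 0) span <- max(abs(y), 1)
              spec$noise_sd * span
            }
  y + stats::rnorm(length(y), 0, sd_abs)
}

missing_params <- function(true_params, required) {
  miss <- setdiff(required, names(true_params))
  if (length(miss))
    stop("configuration error: missing parameter(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Generate a synthetic dataset from a spec
#'
#' Dispatches to the kind-specific generator. All generation is
#' bit-reproducible: the same spec always returns the same dataset, and
#' generation does not disturb the caller's RNG state.
#'
#' @param spec a [synth_spec()]
#' @param rates an optional [microscopic_rates()] object for kinds that
#'   can derive their phase rates from the cycle model
#' @return a `kin_dataset` (list with `x`, `y`, `spec`)
#' @export
synth_generate <- function(spec, rates = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  switch(spec$kind,
    transient_biphasic = ,
    pi_release = gen_transient(spec, rates),
    single_turnover = gen_single_turnover(spec, rates),
    velocity_sample = gen_velocity_sample(spec),
    gen_titration(spec))
}

#' Generate an exponential stopped-flow transient
#'
#' For `transient_biphasic`, generates
#' `y(t) = baseline + sum_i A_i (1 - exp(-k_i t))` with one or two
#' phases. Phase rates are either given directly (`k1`, `A1`, `k2`,
#' `A2`) or derived from a [microscopic_rates()] object and an
#' `atp_conc` parameter: the fast phase follows
#' `k_fast = K1k2 [ATP] k2 / (K1k2 [ATP] + k2)` and the slow phase
#' `k_slow = k_hyd K1k2 [ATP] / (K1k2 [ATP] + k2)` (saturating at
#' `k_hyd`). For `pi_release`, a single exponential with rate `k` (or
#' the `k4` of the rates object).
#'
#' @inheritParams synth_generate
#' @return a `kin_dataset`; negative generating amplitudes are allowed
#'   (decays) and noted in `spec$true_params`
#' @export
gen_transient <- function(spec, rates = NULL) {
  tp <- spec$true_params
  t <- spec$grid
  baseline <- tp$baseline %||% 0
  if (spec$kind == "pi_release") {
    k <- tp$k %||% (if (!is.null(rates)) rates$k4 else NULL)
    if (is.null(k)) stop("configuration error: missing parameter(s): k",
                         call. = FALSE)
    A <- tp$A %||% 1
    y <- baseline + A * (1 - exp(-k * t))
    used <- list(baseline = baseline, A = A, k = k)
  } else {
    if (!is.null(rates)) {
      missing_params(tp, "atp_conc")
      kf <- atp_binding_rate(rates, tp$atp_conc)
      ks <- rates$k_hyd * rates$K1k2 * tp$atp_conc /
        (rates$K1k2 * tp$atp_conc + rates$k2)
      A1 <- tp$A1 %||% 0.7
      A2 <- tp$A2 %||% 0.3
      used <- list(baseline = baseline, A1 = A1, k1 = kf, A2 = A2,
                   k2 = ks, atp_conc = tp$atp_conc)
    } else {
      ks_names <- grep("^k[0-9]$", names(tp), value = TRUE)
      if (length(ks_names) > 2)
        stop("unsupported: more than 2 phases", call. = FALSE)
      missing_params(tp, c("A1", "k1"))
      A1 <- tp$A1; kf <- tp$k1
      A2 <- tp$A2 %||% NULL; ks <- tp$k2 %||% NULL
      used <- list(baseline = baseline, A1 = A1, k1 = kf, A2 = A2,
                   k2 = ks)
    }
    y <- baseline + used$A1 * (1 - exp(-used$k1 * t))
    if (!is.null(used$A2) && !is.null(used$k2))
      y <- y + used$A2 * (1 - exp(-used$k2 * t))
  }
  amps <- unlist(used[grep("^A", names(used))])
  if (any(amps < 0)) used$negative_amplitude <- TRUE
  spec$true_params <- used
  yn <- with_seed(spec$seed, add_noise(y, spec))
  new_dataset(t, yn, spec)
}

#' Generate a single-turnover fluorescence trace
#'
#' Runs the cycle model in single-turnover mode (finite ATP pool,
#' dynamically depleted) and projects the trajectory through the mant
#' observable channel, yielding the characteristic rise (binding),
#' plateau (hydrolysis/turnover) and decay (product release after pool
#' exhaustion) shape.
#'
#' @inheritParams synth_generate
#' @export
gen_single_turnover <- function(spec, rates = NULL) {
  if (is.null(rates))
    stop("configuration error: single-turnover generation requires rates",
         call. = FALSE)
  tp <- spec$true_params
  missing_params(tp, c("atp_pool", "head_conc"))
  if (tp$atp_pool > 5 * tp$head_conc)
    stop("single-turnover mode requires atp_pool <= 5 * head_conc",
         call. = FALSE)
  actin <- tp$actin_conc %||% 0
  tr <- simulate_cycle(rates, atp_conc = tp$atp_pool,
                       actin_conc = actin, time_grid = spec$grid,
                       single_turnover = TRUE,
                       head_conc = tp$head_conc)
  sig <- project_observable(tr, observable_map(), "mant")
  amp <- tp$amplitude %||% 1
  y <- amp * sig$signal
  yn <- with_seed(spec$seed, add_noise(y, spec))
  new_dataset(spec$grid, yn, spec)
}

titration_curve <- function(kind, tp, x) {
  switch(kind,
    actin_titration = {
      missing_params(tp, c("basal", "kcat", "KM"))
      tp$basal + (tp$kcat - tp$basal) * x / (tp$KM + x)
    },
    dose_response = {
      missing_params(tp, c("baseline", "fold_max", "AC50"))
      n <- tp$n %||% 1
      tp$baseline * (1 + (tp$fold_max - 1) * x^n / (tp$AC50^n + x^n))
    },
    binding_isotherm = {
      missing_params(tp, c("KD"))
      n <- tp$n %||% 1
      amp <- tp$amplitude %||% 1
      amp * x^n / (tp$KD^n + x^n)
    },
    arrhenius_series = {
      missing_params(tp, c("Ea", "rate_ref"))
      t_ref <- celsius_to_kelvin(tp$T_ref %||% 25)
      tk <- celsius_to_kelvin(x)
      tp$rate_ref * exp(-tp$Ea * 1000 / .R_GAS * (1 / tk - 1 / t_ref))
    },
    melt_curve = {
      missing_params(tp, c("Tm"))
      s <- tp$slope %||% 2.5
      base <- tp$base %||% 0
      span <- tp$span %||% 1
      base + span / (1 + exp((tp$Tm - x) / s))
    },
    refolding_series = {
      missing_params(tp, c("base", "plateau", "t_half"))
      tp$base + (tp$plateau - tp$base) * x / (tp$t_half + x)
    },
    shelf_life = {
      missing_params(tp, c("rate"))
      y0 <- tp$y0 %||% 1
      y0 * exp(-tp$rate * x)
    },
    stop("unsupported titration kind: ", kind, call. = FALSE))
}

#' Generate a titration / temperature-series dataset
#'
#' Deterministic model curve for the named functional form plus
#' additive Gaussian noise. Covers actin activation (hyperbola with
#' basal offset), Hill dose-response and binding isotherms, Arrhenius
#' temperature series, Boltzmann melt curves, hyperbolic refolding
#' recovery series, and exponential shelf-life decay.
#'
#' @inheritParams synth_generate
#' @export
gen_titration <- function(spec, rates = NULL) {
  y <- titration_curve(spec$kind, spec$true_params, spec$grid)
  yn <- with_seed(spec$seed, add_noise(y, spec))
  new_dataset(spec$grid, yn, spec)
}

#' Generate an in vitro motility velocity sample
#'
#' Mixture sample: a `motile_fraction` share of filaments draw from a
#' Normal(mean, sd) truncated at zero; the rest are assigned velocities
#' uniformly below the stall threshold.
#'
#' @inheritParams synth_generate
#' @export
gen_velocity_sample <- function(spec, rates = NULL) {
  tp <- spec$true_params
  missing_params(tp, c("mean", "sd", "n"))
  if (tp$n <= 0)
    stop("configuration error: n must be positive", call. = FALSE)
  mf <- tp$motile_fraction %||% 1
  stopifnot(mf >= 0, mf <= 1)
  stall <- tp$stall_threshold %||% 0.1
  y <- with_seed(spec$seed, {
    n_mot <- round(tp$n * mf)
    v <- numeric(0)
    while (length(v) < n_mot) {
      draw <- stats::rnorm(n_mot, tp$mean, tp$sd)
      v <- c(v, draw[draw > 0])
    }
    v <- v[seq_len(n_mot)]
    vn <- stats::runif(tp$n - n_mot, 0, stall * 0.9)
    sample(c(v, vn))
  })
  spec$grid <- seq_along(y)
  new_dataset(seq_along(y), y, spec)
}
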