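## Thermal stability analyses: Boltzmann melting curves, ligand-induced
## Tm shifts, and shelf-life decay.

boltzmann_curve <- function(x, p) {
  p[["base"]] + p[["span"]] / (1 + exp((p[["Tm"]] - x) / p[["slope"]]))
}

#' Fit a thermal melting curve with a Boltzmann sigmoid
#'
#' The raw signal is first normalized to [0, 1] (0 = folded baseline,
#' 1 = unfolded), then fitted with
#' `y(T) = base + span / (1 + exp((Tm - T) / s))`. The transition
#' midpoint `Tm` is invariant under affine transforms of the raw signal.
#' Applies equally to circular-dichroism unfolding curves and
#' light-scattering aggregation curves.
#'
#' @param temp_c temperatures, degrees Celsius
#' @param signal raw melt signal (any affine scale)
#' @param normalize normalize the signal to [0, 1] first (default TRUE)
#' @return a `kin_fit` of subclass `melt_fit` with coefficients `Tm`
#'   (degC), `slope` (degC), `base`, `span`
#' @examples
#' tc <- seq(25, 90)
#' y <- 1 / (1 + exp((53.6 - tc) / 2.5))
#' coef(fit_melt(tc, y))["Tm"]
#' @export
fit_melt <- function(temp_c, signal, normalize = TRUE) {
  stopifnot(length(temp_c) == length(signal))
  if (length(temp_c) < 10)
    stop("need at least 10 points spanning both baselines", call. = FALSE)
  o <- order(temp_c)
  x <- temp_c[o]; y <- signal[o]
  span_raw <- diff(range(y))
  if (span_raw <= 0)
    return(failed_kin_fit("Boltzmann melt", c("Tm", "slope", "base", "span"),
                          x, y, flags = "degenerate: flat melt curve",
                          subclass = "melt_fit"))
  if (normalize) {
    y <- (y - min(y)) / span_raw
    ## orient so 0 = folded (low T), 1 = unfolded (high T); makes Tm
    ## invariant under sign flips of the raw signal
    if (stats::cor(x, y) < 0) y <- 1 - y
  }
  flags <- character()
  ## warn if the curve is non-monotone well beyond the noise band
  noise <- stats::sd(diff(y)) / sqrt(2)
  if (any(-diff(y) > max(6 * noise, 0.2)))
    warning("melt curve violates monotonicity beyond noise band",
            call. = FALSE)

  Tm0 <- x[which.min(abs(y - (min(y) + max(y)) / 2))]
  starts <- lapply(c(1, 3, 8), function(s)
    c(Tm = Tm0, slope = s, base = min(y), span = diff(range(y))))
  ans <- ls_multistart(x, y, boltzmann_curve, starts,
                       lower = c(-Inf, 1e-6, -Inf, 1e-12))
  if (is.null(ans))
    return(failed_kin_fit("Boltzmann melt", c("Tm", "slope", "base", "span"),
                          x, y, flags = "fit failure",
                          subclass = "melt_fit"))
  p <- ans$par
  if (p[["Tm"]] < min(x) || p[["Tm"]] > max(x))
    flags <- c(flags, "Tm extrapolated: midpoint outside scanned range")
  ## baselines present? require data beyond both half-transition sides
  if (min(boltzmann_curve(min(x), p), na.rm = TRUE) > 0.25 ||
      boltzmann_curve(max(x), p) < 0.75)
    flags <- c(flags, "Tm flagged: missing pre- or post-transition baseline")
  units <- c(Tm = "degC", slope = "degC", base = "", span = "")
  new_kin_fit("Boltzmann melt", p, ans$se, x, y, boltzmann_curve,
              fit = ans$fit, flags = flags, units = units,
              subclass = "melt_fit")
}

#' Ligand-induced shift in melting temperature
#'
#' @param apo,liganded `melt_fit` objects for the free and
#'   ligand-bound protein
#' @return a list of class `delta_tm` with the shift in degC and its
#'   propagated standard error
#' @export
delta_tm <- function(apo, liganded) {
  d <- unname(coef(liganded)["Tm"] - coef(apo)["Tm"])
  se <- sqrt(sum(c(apo$se["Tm"], liganded$se["Tm"])^2, na.rm = TRUE))
  structure(list(delta_tm = d, se = se,
                 tm_apo = unname(coef(apo)["Tm"]),
                 tm_liganded = unname(coef(liganded)["Tm"])),
            class = "delta_tm")
}

#' @export
print.delta_tm <- function(x, ...) {
  cat(sprintf("delta Tm = %+.3g +/- %.2g degC (%.4g -> %.4g)\n",
              x$delta_tm, x$se, x$tm_apo, x$tm_liganded))
  invisible(x)
}

#' Fit the shelf-life decay of enzymatic activity
#'
#' Single-exponential decay fit of residual activity against storage
#' time: `y(t) = y0 exp(-k t)`. The half-life is `ln 2 / k`; a series
#' with no measurable decay reports rate 0 and an infinite half-life.
#' An increasing series is flagged as a rescue (chaperone) regime, not
#' a decay.
#'
#' @param days storage times, days
#' @param activity residual activity fractions (0 to ~1)
#' @return a `kin_fit` of subclass `decay_fit` with coefficients `rate`
#'   (day^-1) and `y0`; `$extra$half_life_days` carries ln2/rate
#'   (`Inf` for no decay)
#' @export
fit_shelf_life <- function(days, activity) {
  stopifnot(length(days) == length(activity))
  if (any(activity < 0 | activity > 1.05))
    stop("activities must lie in [0, 1.05]", call. = FALSE)
  flags <- character()
  trend <- stats::coef(stats::lm(activity ~ days))[2]
  if (trend > 0 && max(activity) > activity[which.min(days)] + 1e-9)
    flags <- c(flags, "increasing activity: rescue regime, not decay")
  fn <- function(x, p) p[["y0"]] * exp(-p[["rate"]] * x)
  k0 <- max(-trend / max(mean(activity), 1e-9), 1e-6)
  starts <- lapply(c(0.2, 1, 5), function(f)
    c(y0 = max(activity), rate = k0 * f))
  ans <- ls_multistart(days, activity, fn, starts, lower = c(1e-12, 0))
  if (is.null(ans))
    return(failed_kin_fit("shelf-life decay", c("y0", "rate"), days,
                          activity, flags = "fit failure",
                          subclass = "decay_fit"))
  rate <- ans$par[["rate"]]
  half <- if (rate <= 1e-10) Inf else log(2) / rate
  units <- c(y0 = "", rate = "day^-1")
  new_kin_fit("shelf-life decay", ans$par, ans$se, days, activity, fn,
              fit = ans$fit, flags = flags, units = units,
              extra = list(half_life_days = half),
              subclass = "decay_fit")
}
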