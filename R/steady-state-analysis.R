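## Steady-state analyses: actin activation, dose-response, binding
## isotherms, Arrhenius temperature dependence, and fold changes.

#' Fit the actin activation of steady-state ATP turnover
#'
#' Fits `v([A]) = basal + (kcat - basal) [A] / (KM + [A])`. The coupling
#' (apparent second-order) constant is computed both ways the field
#' reports it: as the ratio `kcat / KM` and as the initial slope of the
#' fitted curve, `(kcat - basal) / KM`; both coincide when `basal = 0`.
#'
#' @param actin_conc F-actin concentrations, uM (should include 0)
#' @param rate turnover rates, s^-1
#' @param basal `"fit"` (default) to fit the zero-actin offset, or a
#'   fixed numeric value (e.g. 0 for basal-subtracted data)
#' @return a `kin_fit` of subclass `actin_fit` with coefficients `kcat`,
#'   `KM`, `basal` and extras `coupling_ratio`, `coupling_slope`
#' @examples
#' a <- c(0, 2.5, 5, 10, 20, 40, 70, 100)
#' v <- 0.049 + (0.12 - 0.049) * a / (36.8 + a)
#' f <- fit_actin_activation(a, v)
#' coef(f); f$extra$coupling_ratio
#' @export
fit_actin_activation <- function(actin_conc, rate, basal = "fit") {
  stopifnot(length(actin_conc) == length(rate))
  if (length(actin_conc) < 5)
    stop("need at least 5 actin concentrations", call. = FALSE)
  flags <- character()
  fit_basal <- identical(basal, "fit")
  span <- diff(range(rate))
  if (span <= max(abs(rate)) * 1e-10) {
    ## flat curve: KM unidentifiable
    f <- failed_kin_fit("actin activation", c("kcat", "KM", "basal"),
                        actin_conc, rate,
                        flags = "KM unidentifiable: flat activation curve",
                        subclass = "actin_fit")
    f$coefficients[c("kcat", "basal")] <- mean(rate)
    return(f)
  }
  K0 <- {
    i <- which(rate >= min(rate) + span / 2)[1]
    max(actin_conc[i], min(actin_conc[actin_conc > 0]))
  }
  if (fit_basal) {
    fn <- function(x, p)
      p[["basal"]] + (p[["kcat"]] - p[["basal"]]) * x / (p[["KM"]] + x)
    starts <- lapply(c(0.3, 1, 3, 10), function(f)
      c(kcat = max(rate) * 1.1, KM = K0 * f, basal = min(rate)))
    lower <- c(1e-12, 1e-12, 0)
  } else {
    b0 <- as.numeric(basal)
    fn <- function(x, p)
      b0 + (p[["kcat"]] - b0) * x / (p[["KM"]] + x)
    starts <- lapply(c(0.3, 1, 3, 10), function(f)
      c(kcat = max(rate) * 1.1, KM = K0 * f))
    lower <- c(1e-12, 1e-12)
  }
  ans <- ls_multistart(actin_conc, rate, fn, starts, lower = lower)
  if (is.null(ans))
    return(failed_kin_fit("actin activation", c("kcat", "KM", "basal"),
                          actin_conc, rate, flags = "fit failure",
                          subclass = "actin_fit"))
  p <- ans$par; se <- ans$se
  if (!fit_basal) {
    p <- c(p, basal = as.numeric(basal))
    se <- c(se, basal = 0)
  }
  p <- p[c("kcat", "KM", "basal")]; se <- se[c("kcat", "KM", "basal")]
  if (p[["KM"]] > 10 * max(actin_conc))
    flags <- c(flags, "KM extrapolated: no curvature within data range")
  coupling_ratio <- p[["kcat"]] / p[["KM"]]
  coupling_slope <- (p[["kcat"]] - p[["basal"]]) / p[["KM"]]
  pf <- function(x, p)
    p[["basal"]] + (p[["kcat"]] - p[["basal"]]) * x / (p[["KM"]] + x)
  units <- c(kcat = "s^-1", KM = "uM", basal = "s^-1")
  f <- new_kin_fit("actin activation", p, se, actin_conc, rate, pf,
                   fit = ans$fit, flags = flags, units = units,
                   extra = list(coupling_ratio = coupling_ratio,
                                coupling_slope = coupling_slope),
                   subclass = "actin_fit")
  f
}

hill_curve <- function(x, p) {
  p[["baseline"]] * (1 + (p[["fold_max"]] - 1) * x^p[["n"]] /
                       (p[["AC50"]]^p[["n"]] + x^p[["n"]]))
}

#' Fit a Hill dose-response curve for compound activation
#'
#' Fits `v(c) = baseline (1 + (fold_max - 1) c^n / (AC50^n + c^n))`,
#' i.e. a Hill activation curve expressed as fold change over the
#' zero-compound baseline. The Hill coefficient is free, bounded to
#' [0.5, 4]. A flat response reports `fold_max = 1` with AC50 flagged
#' undefined; a monotone decreasing response is flagged as inhibition
#' and `fold_max >= 1` is not enforced.
#'
#' @param conc compound concentrations, uM
#' @param rate observed rates, s^-1 (or any activity measure)
#' @return a `kin_fit` of subclass `hill_fit` with coefficients
#'   `AC50`, `fold_max`, `n`, `baseline`
#' @export
fit_dose_response <- function(conc, rate) {
  stopifnot(length(conc) == length(rate))
  if (sum(conc > 0) < 4)
    stop("need at least 5 concentrations spanning the response",
         call. = FALSE)
  flags <- character()
  base0 <- if (any(conc == 0)) mean(rate[conc == 0]) else min(rate)
  span <- diff(range(rate))
  if (span <= max(abs(rate)) * 0.02) {
    f <- failed_kin_fit("Hill dose-response",
                        c("AC50", "fold_max", "n", "baseline"),
                        conc, rate,
                        flags = "AC50 undefined: flat response",
                        subclass = "hill_fit")
    f$coefficients[c("fold_max", "baseline")] <- c(1, base0)
    f$fitted.values <- rep(base0, length(conc))
    f$residuals <- rate - base0
    return(f)
  }
  if (stats::cor(conc, rate) < 0)
    flags <- c(flags, "inhibition: monotone decreasing response")
  cpos <- conc[conc > 0]
  ac0 <- exp(mean(log(range(cpos))))
  starts <- lapply(c(0.2, 1, 5), function(f)
    c(AC50 = ac0 * f, fold_max = max(rate) / max(base0, 1e-12), n = 1,
      baseline = base0))
  ans <- ls_multistart(conc, rate, hill_curve, starts,
                       lower = c(1e-9, 0, 0.5, 1e-12),
                       upper = c(Inf, Inf, 4, Inf))
  if (is.null(ans))
    return(failed_kin_fit("Hill dose-response",
                          c("AC50", "fold_max", "n", "baseline"),
                          conc, rate, flags = "fit failure",
                          subclass = "hill_fit"))
  units <- c(AC50 = "uM", fold_max = "fold", n = "", baseline = "s^-1")
  new_kin_fit("Hill dose-response", ans$par, ans$se, conc, rate,
              hill_curve, fit = ans$fit, flags = flags, units = units,
              subclass = "hill_fit")
}

#' Fit a Hill binding isotherm
#'
#' Fits normalized binding signals (e.g. thermophoresis amplitudes)
#' with `y(c) = amplitude c^n / (KD^n + c^n)`. A zero-amplitude
#' isotherm is reported as a no-binding result.
#'
#' @param conc ligand concentrations, uM
#' @param response normalized binding signal
#' @return a `kin_fit` of subclass `binding_fit` with coefficients
#'   `KD`, `amplitude`, `n`
#' @export
fit_binding_isotherm <- function(conc, response) {
  stopifnot(length(conc) == length(response))
  span <- diff(range(response))
  if (span <= 0.02 * max(abs(response), 1)) {
    f <- failed_kin_fit("Hill binding isotherm",
                        c("KD", "amplitude", "n"), conc, response,
                        flags = "no binding: zero amplitude",
                        subclass = "binding_fit")
    f$coefficients["amplitude"] <- 0
    return(f)
  }
  fn <- function(x, p)
    p[["amplitude"]] * x^p[["n"]] / (p[["KD"]]^p[["n"]] + x^p[["n"]])
  cpos <- conc[conc > 0]
  kd0 <- exp(mean(log(range(cpos))))
  starts <- lapply(c(0.2, 1, 5), function(f)
    c(KD = kd0 * f, amplitude = max(response), n = 1))
  ans <- ls_multistart(conc, response, fn, starts,
                       lower = c(1e-9, 1e-12, 0.5),
                       upper = c(Inf, Inf, 4))
  if (is.null(ans))
    return(failed_kin_fit("Hill binding isotherm",
                          c("KD", "amplitude", "n"), conc, response,
                          flags = "fit failure", subclass = "binding_fit"))
  units <- c(KD = "uM", amplitude = "a.u.", n = "")
  new_kin_fit("Hill binding isotherm", ans$par, ans$se, conc, response,
              fn, fit = ans$fit, units = units, subclass = "binding_fit")
}

#' Arrhenius analysis of the temperature dependence of a rate
#'
#' Linear fit of `ln(rate)` against `1/T` (T in Kelvin); the activation
#' energy is `Ea = -slope * R` with R = 8.314 J mol^-1 K^-1. Rates that
#' are not strictly positive are excluded with a warning.
#'
#' @param temp_c temperatures, degrees Celsius
#' @param rate rates, s^-1
#' @return a `kin_fit` of subclass `arrhenius_fit` with coefficients
#'   `Ea` (kJ mol^-1) and `lnA` (log pre-exponential); extras carry
#'   `pre_exponential` and the temperature range
#' @examples
#' # rates doubling per 10 K around 300 K
#' tc <- c(25, 30, 35, 40, 45)
#' r <- 1e8 * exp(-50e3 / (8.314 * (tc + 273.15)))
#' coef(arrhenius_fit(tc, r))
#' @export
arrhenius_fit <- function(temp_c, rate) {
  stopifnot(length(temp_c) == length(rate))
  ok <- is.finite(rate) & rate > 0
  if (any(!ok)) {
    warning("excluding ", sum(!ok), " non-positive rate(s)",
            call. = FALSE)
    temp_c <- temp_c[ok]; rate <- rate[ok]
  }
  if (length(rate) < 3)
    stop("need at least 3 temperatures with positive rates",
         call. = FALSE)
  tk <- celsius_to_kelvin(temp_c)
  lf <- stats::lm(log(rate) ~ I(1 / tk))
  sl <- stats::coef(lf)[2]
  sm <- suppressWarnings(summary(lf)$coefficients)
  Ea <- unname(-sl * .R_GAS / 1000)         # kJ/mol
  Ea_se <- unname(sm[2, 2] * .R_GAS / 1000)
  lnA <- unname(stats::coef(lf)[1])
  lnA_se <- unname(sm[1, 2])
  p <- c(Ea = Ea, lnA = lnA)
  se <- c(Ea = Ea_se, lnA = lnA_se)
  pf <- function(x, p)
    exp(p[["lnA"]] - p[["Ea"]] * 1000 / (.R_GAS * celsius_to_kelvin(x)))
  units <- c(Ea = "kJ mol^-1", lnA = "")
  new_kin_fit("Arrhenius", p, se, temp_c, rate, pf,
              units = units,
              extra = list(pre_exponential = exp(lnA),
                           temp_range_K = range(tk)),
              subclass = "arrhenius_fit")
}

#' Fold change between two fitted parameters
#'
#' Ratio of a parameter between a treated and a control fit, with the
#' standard error propagated from both fits. For affinity-like
#' parameters that decrease on activation (e.g. `KM`), pass
#' `direction = "control/treated"` to match the conventional
#' "n-fold decrease" framing; the direction used is recorded in the
#' result.
#'
#' @param control,treated `kin_fit` objects (or lists with
#'   `coefficients`/`se`) containing `param`
#' @param param parameter name present in both fits
#' @param direction `"treated/control"` (default) or `"control/treated"`
#' @return a list of class `fold_change` with `fold`, `se`, `direction`
#' @examples
#' a <- c(0, 2.5, 5, 10, 20, 40, 70, 100)
#' f1 <- fit_actin_activation(a, 0.05 + 0.07 * a / (36.8 + a))
#' f2 <- fit_actin_activation(a, 0.08 + 0.11 * a / (3.6 + a))
#' fold_change(f1, f2, "kcat")
#' @export
fold_change <- function(control, treated, param,
                        direction = c("treated/control",
                                      "control/treated")) {
  direction <- match.arg(direction)
  getp <- function(f) {
    cf <- if (inherits(f, "kin_fit")) coef(f) else f$coefficients
    se <- f$se
    if (!param %in% names(cf))
      stop("parameter '", param, "' not present in both fits",
           call. = FALSE)
    c(cf[[param]], if (param %in% names(se)) se[[param]] else NA_real_)
  }
  a <- getp(treated); b <- getp(control)
  if (direction == "control/treated") { tmp <- a; a <- b; b <- tmp }
  if (!is.finite(b[1]) || b[1] <= 0)
    stop("undefined ratio: denominator estimate is zero or negative",
         call. = FALSE)
  fold <- a[1] / b[1]
  se <- if (all(is.finite(c(a[2], b[2])))) ratio_se(a[1], b[1], a[2], b[2])
        else NA_real_
  structure(list(param = param, fold = fold, se = se,
                 direction = direction),
            class = "fold_change")
}

#' @export
print.fold_change <- function(x, ...) {
  cat(sprintf("%s fold change (%s): %.4g", x$param, x$direction, x$fold))
  if (is.finite(x$se)) cat(sprintf(" +/- %.3g", x$se))
  cat("\n")
  invisible(x)
}
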