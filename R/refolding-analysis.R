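## Chaperone-mediated refolding kinetics: hyperbolic recovery fits, the
## linear rescue analysis of observed rates versus compound
## concentration, and a four-state refolding scheme simulator used to
## validate the linear analysis.

#' Fit a recovery time course
#'
#' Activity or motility recovery after addition of the refolding
#' compound is fitted with a rectangular hyperbola in time,
#' `y(t) = base + (plateau - base) t / (t_half + t)`; the observed rate
#' constant is reported as `kobs = 1 / t_half`. A saturating
#' exponential alternative, `y(t) = base + (plateau - base)
#' (1 - exp(-k t))`, is available via `model = "exponential"`; with
#' `compare = TRUE` both are fitted and their residual norms reported.
#'
#' @param time incubation times, s
#' @param y recovered activity (fraction) or velocity (um s^-1)
#' @param model `"hyperbola"` (default) or `"exponential"`
#' @param compare also fit the alternative model and attach the
#'   residual-norm comparison
#' @return a `kin_fit` of subclass `recovery_fit` with coefficients
#'   `base`, `plateau`, `t_half` (or `k`); extras carry `kobs` and, if
#'   requested, the model comparison
#' @export
fit_recovery <- function(time, y, model = c("hyperbola", "exponential"),
                         compare = FALSE) {
  model <- match.arg(model)
  stopifnot(length(time) == length(y))
  if (length(time) < 6)
    stop("need at least 6 time points", call. = FALSE)
  flags <- character()
  noise <- stats::sd(diff(y)) / sqrt(2)
  if (any(-diff(y[order(time)]) > max(6 * noise, 0.25 * diff(range(y)))))
    warning("recovery series non-monotone beyond noise band",
            call. = FALSE)

  span <- diff(range(y))
  i_half <- which(y >= min(y) + span / 2)[1]
  th0 <- max(time[i_half], min(time[time > 0]))

  if (model == "hyperbola") {
    fn <- function(x, p)
      p[["base"]] + (p[["plateau"]] - p[["base"]]) * x / (p[["t_half"]] + x)
    starts <- lapply(c(0.3, 1, 3, 10), function(f)
      c(base = min(y), plateau = max(y) * 1.2, t_half = th0 * f))
    lower <- c(-Inf, -Inf, 1e-9)
    rate_name <- "t_half"
  } else {
    fn <- function(x, p)
      p[["base"]] + (p[["plateau"]] - p[["base"]]) * (1 - exp(-p[["k"]] * x))
    starts <- lapply(c(0.3, 1, 3, 10), function(f)
      c(base = min(y), plateau = max(y), k = log(2) / (th0 * f)))
    lower <- c(-Inf, -Inf, 1e-12)
    rate_name <- "k"
  }
  ans <- ls_multistart(time, y, fn, starts, lower = lower)
  if (is.null(ans))
    return(failed_kin_fit("recovery", c("base", "plateau", rate_name),
                          time, y, flags = "fit failure",
                          subclass = "recovery_fit"))
  p <- ans$par
  kobs <- if (model == "hyperbola") 1 / p[["t_half"]] else p[["k"]]
  kobs_se <- if (model == "hyperbola")
    ans$se[["t_half"]] / p[["t_half"]]^2 else ans$se[["k"]]
  extra <- list(kobs = kobs, kobs_se = kobs_se, model_form = model)
  if (compare) {
    alt <- fit_recovery(time, y,
                        model = setdiff(c("hyperbola", "exponential"),
                                        model),
                        compare = FALSE)
    extra$comparison <- data.frame(
      model = c(model, alt$extra$model_form),
      residual_norm = c(ans$deviance, alt$residual_norm))
    extra$preferred <- extra$comparison$model[
      which.min(extra$comparison$residual_norm)]
  }
  units <- stats::setNames(c("", "", "s"), c("base", "plateau", rate_name))
  new_kin_fit(paste0("recovery (", model, ")"), p, ans$se, time, y, fn,
              fit = ans$fit, flags = flags, units = units, extra = extra,
              subclass = "recovery_fit")
}

#' Linear analysis of recovery rates versus compound concentration
#'
#' Fits a (optionally weighted) line through the observed recovery rate
#' constants as a function of compound concentration. The slope is the
#' second-order rescue constant `k_rescue` (uM^-1 s^-1) and the
#' intercept the first-order dissociation rate `k_off` (s^-1).
#'
#' @param conc compound concentrations, uM (at least 3)
#' @param kobs observed recovery rates, s^-1
#' @param se optional standard errors of `kobs`; if given, the fit is
#'   weighted by `1/se^2`
#' @return a `kin_fit` of subclass `rescue_fit` with coefficients
#'   `k_rescue`, `k_off`
#' @export
fit_rescue_line <- function(conc, kobs, se = NULL) {
  stopifnot(length(conc) == length(kobs))
  if (length(conc) < 3)
    stop("need at least 3 concentrations", call. = FALSE)
  w <- if (!is.null(se) && all(is.finite(se)) && all(se > 0)) 1 / se^2
       else NULL
  lf <- if (is.null(w)) stats::lm(kobs ~ conc)
        else stats::lm(kobs ~ conc, weights = w)
  cf <- stats::coef(lf)
  sm <- suppressWarnings(summary(lf)$coefficients)
  flags <- character()
  if (cf[2] < 0) flags <- "rescue absent: negative fitted slope"
  p <- c(k_rescue = unname(cf[2]), k_off = unname(cf[1]))
  pse <- c(k_rescue = unname(sm[2, 2]), k_off = unname(sm[1, 2]))
  pf <- function(x, p) p[["k_off"]] + p[["k_rescue"]] * x
  units <- c(k_rescue = "uM^-1 s^-1", k_off = "s^-1")
  new_kin_fit("rescue line", p, pse, conc, kobs, pf, flags = flags,
              units = units, subclass = "rescue_fit")
}

#' Refolding scheme rate constants
#'
#' Rate constants for the four-state refolding scheme: conformationally
#' trapped soluble aggregates (`trapped`) bind the compound and convert
#' to a nucleotide-binding-competent but hydrolysis-incompetent state
#' (`compromised`), which matures to the rescued, fully competent state
#' (`rescued`); trapped protein is also lost irreversibly to insoluble
#' aggregates (`aggregated`).
#'
#' When maturation and its reverse are fast compared to compound
#' binding, compromised and rescued form one quasi-equilibrated bound
#' pool and the scheme reduces to two states with apparent relaxation
#' `k_on [EMD] + k_off_eff`, where
#' `k_off_eff = k_off_1 k_off_2 / (k_mature + k_off_2)`. The defaults
#' are chosen in that regime with `k_off_eff = 2.3e-4 s^-1`, matching
#' the measured intercept of the linear rescue analysis.
#'
#' @param k_on compound-dependent trapped -> compromised rate, uM^-1 s^-1
#' @param k_mature compromised -> rescued rate, s^-1
#' @param k_off_1 compromised -> trapped reverse rate, s^-1
#' @param k_off_2 rescued -> compromised reverse rate, s^-1
#' @param k_agg trapped -> aggregated (irreversible), s^-1
#' @return an object of class `refolding_scheme`
#' @export
refolding_scheme <- function(k_on = 2e-5, k_mature = 0.05,
                             k_off_1 = 4.6e-4, k_off_2 = 0.05,
                             k_agg = 0) {
  v <- c(k_on = k_on, k_mature = k_mature, k_off_1 = k_off_1,
         k_off_2 = k_off_2, k_agg = k_agg)
  if (any(!is.finite(v)) || any(v < 0))
    stop("scheme rates must be non-negative and finite", call. = FALSE)
  structure(as.list(v), class = "refolding_scheme")
}

#' Simulate the refolding scheme
#'
#' Integrates the four-state refolding scheme at a given compound
#' concentration. State fractions are conserved
#' (trapped + compromised + rescued + aggregated = 1); aggregation is
#' irreversible. The derived observable is the rescued fraction versus
#' time.
#'
#' @param scheme a [refolding_scheme()]
#' @param emd_conc compound concentration, uM
#' @param t_grid time points, s (increasing, starting at 0)
#' @param init named initial fractions (default: all trapped)
#' @return a data.frame of class `refolding_trajectory` with columns
#'   `time`, `trapped`, `compromised`, `rescued`, `aggregated`
#' @export
simulate_refolding <- function(scheme, emd_conc, t_grid, init = NULL) {
  if (!inherits(scheme, "refolding_scheme"))
    stop("'scheme' must be a refolding_scheme", call. = FALSE)
  if (emd_conc < 0) stop("emd_conc must be >= 0", call. = FALSE)
  states <- c("trapped", "compromised", "rescued", "aggregated")
  x0 <- stats::setNames(c(1, 0, 0, 0), states)
  if (!is.null(init)) {
    x0[names(init)] <- init
    x0 <- x0 / sum(x0)
  }
  kon <- scheme$k_on * emd_conc
  Q <- matrix(0, 4, 4, dimnames = list(states, states))
  add <- function(from, to, k) {
    Q[to, from] <<- Q[to, from] + k
    Q[from, from] <<- Q[from, from] - k
  }
  add("trapped", "compromised", kon)
  add("compromised", "trapped", scheme$k_off_1)
  add("compromised", "rescued", scheme$k_mature)
  add("rescued", "compromised", scheme$k_off_2)
  add("trapped", "aggregated", scheme$k_agg)
  deriv <- function(t, y, p) list(as.vector(Q %*% y))
  out <- tryCatch(
    deSolve::lsoda(x0, t_grid, deriv, parms = NULL,
                   rtol = 1e-8, atol = 1e-10),
    warning = function(w)
      stop("integration error in simulate_refolding: ",
           conditionMessage(w), call. = FALSE),
    error = function(e)
      stop("integration error in simulate_refolding: ",
           conditionMessage(e), call. = FALSE))
  out <- as.data.frame(out)
  names(out)[1] <- "time"
  structure(out, class = c("refolding_trajectory", "data.frame"),
            scheme = scheme, emd_conc = emd_conc)
}

#' Apparent recovery rate of the refolding scheme
#'
#' Exponential relaxation rate of the rescued fraction produced by
#' [simulate_refolding()]; used to check that the scheme's
#' concentration dependence reduces to the linear rescue analysis
#' (`kobs ~ k_on [EMD] + k_off`) when the reverse rates are small and
#' maturation is fast.
#'
#' @inheritParams simulate_refolding
#' @param t_end integration horizon, s (default: several relaxation
#'   times of the two-state reduction)
#' @return apparent rate, s^-1
#' @export
apparent_recovery_rate <- function(scheme, emd_conc, t_end = NULL) {
  k_off_eff <- if (scheme$k_mature + scheme$k_off_2 > 0)
    scheme$k_off_1 * scheme$k_off_2 / (scheme$k_mature + scheme$k_off_2)
  else scheme$k_off_1
  k2s <- scheme$k_on * emd_conc + k_off_eff
  if (is.null(t_end)) t_end <- 6 / max(k2s, 1e-9)
  tg <- seq(0, t_end, length.out = 200)
  tr <- simulate_refolding(scheme, emd_conc, tg)
  f <- fit_exponentials(time = tr$time, signal = tr$rescued, n_phases = 1)
  unname(coef(f)["k1"])
}
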