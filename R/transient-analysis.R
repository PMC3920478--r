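## Fitting of stopped-flow transients and the secondary analyses that
## extract microscopic rate constants from their concentration
## dependence.

exp_model <- function(n_phases) {
  function(x, p) {
    y <- p[["baseline"]]
    for (i in seq_len(n_phases))
      y <- y + p[[paste0("A", i)]] * (1 - exp(-p[[paste0("k", i)]] * x))
    y
  }
}

#' Fit a one- or two-exponential model to a transient
#'
#' Least-squares fit of
#' `y(t) = baseline + sum_i A_i (1 - exp(-k_i t))`
#' with data-driven initial values plus multi-start refinement over
#' log-spaced rate initialisations (ties broken by lowest residual
#' norm). Phases are reported fast to slow. A flat or degenerate trace
#' yields a failed-fit result carrying a diagnostic flag rather than an
#' exception.
#'
#' @param trace a [kin_timeseries()], a data.frame with `time`/`signal`
#'   (or two columns), or `NULL` if `time` and `signal` are given
#' @param n_phases 1 or 2
#' @param time,signal alternative vector interface
#' @param n_starts number of log-spaced rate initialisations (default 8)
#' @return a `kin_fit` of subclass `exp_fit`; coefficients `baseline`,
#'   `A1`, `k1` (fast) and for two phases `A2`, `k2obs` (slow)
#' @examples
#' t <- seq(0, 5, 0.01)
#' y <- 1 - exp(-1.3 * t)
#' coef(fit_exponentials(time = t, signal = y, n_phases = 1))
#' @export
fit_exponentials <- function(trace = NULL, n_phases = 1, time = NULL,
                             signal = NULL, n_starts = 8) {
  if (!is.null(trace)) {
    trace <- as.data.frame(trace)
    time <- trace[[1]]
    signal <- trace[[2]]
  }
  stopifnot(n_phases %in% c(1, 2))
  if (length(time) < 10 * n_phases)
    stop("need at least ", 10 * n_phases, " points", call. = FALSE)
  if (any(diff(time) <= 0))
    stop("time must be strictly increasing", call. = FALSE)

  par_names <- c("baseline",
                 as.vector(rbind(paste0("A", seq_len(n_phases)),
                                 paste0("k", seq_len(n_phases)))))
  span <- diff(range(signal))
  if (!is.finite(span) || span <= .Machine$double.eps * 100 ||
      span < 1e-12 * max(abs(signal), 1e-300)) {
    return(failed_kin_fit("exponential", par_names, time, signal,
                          flags = "degenerate trace: flat signal",
                          subclass = "exp_fit"))
  }

  ## data-driven rate scale: time to half total change
  amp0 <- signal[length(signal)] - signal[1]
  half_idx <- which(abs(signal - signal[1]) >= abs(amp0) / 2)[1]
  t_half <- if (!is.na(half_idx) && time[half_idx] > 0) time[half_idx]
            else stats::median(time)
  k0 <- log(2) / t_half

  fn <- exp_model(n_phases)
  starts <- list()
  factors <- 10^seq(-1.5, 1.5, length.out = n_starts)
  for (f in factors) {
    if (n_phases == 1)
      starts[[length(starts) + 1]] <-
        c(baseline = signal[1], A1 = amp0, k1 = k0 * f)
    else
      starts[[length(starts) + 1]] <-
        c(baseline = signal[1], A1 = 0.7 * amp0, k1 = k0 * f * 5,
          A2 = 0.3 * amp0, k2 = k0 * f / 2)
  }
  lower <- if (n_phases == 1) c(-Inf, -Inf, 1e-12)
           else c(-Inf, -Inf, 1e-12, -Inf, 1e-12)
  ans <- ls_multistart(time, signal, fn, starts, lower = lower)
  if (is.null(ans))
    return(failed_kin_fit("exponential", par_names, time, signal,
                          flags = "fit failure: no start converged",
                          subclass = "exp_fit"))

  p <- ans$par
  se <- ans$se
  flags <- character()
  if (n_phases == 2) {
    ## order phases fast -> slow
    if (p[["k2"]] > p[["k1"]]) {
      p <- p[c("baseline", "A2", "k2", "A1", "k1")]
      se <- se[c("baseline", "A2", "k2", "A1", "k1")]
    }
    names(p) <- names(se) <- c("baseline", "A1", "k1", "A2", "k2obs")
  } else names(p) <- names(se) <- c("baseline", "A1", "k1")
  if (any(p[grep("^A", names(p))] < 0))
    flags <- c(flags, "negative amplitude (decaying phase)")

  pf <- if (n_phases == 1) exp_model(1) else function(x, p) {
    p2 <- c(p[["baseline"]], p[["A1"]], p[["k1"]], p[["A2"]],
            p[["k2obs"]])
    names(p2) <- c("baseline", "A1", "k1", "A2", "k2")
    exp_model(2)(x, p2)
  }
  units <- stats::setNames(
    c("a.u.", rep(c("a.u.", "s^-1"), n_phases)), names(p))
  new_kin_fit(sprintf("%d-exponential transient", n_phases), p, se,
              time, signal, pf, fit = ans$fit, flags = flags,
              units = units, subclass = "exp_fit")
}

#' Secondary analysis of the ATP dependence of transient rates
#'
#' Extracts microscopic constants from the concentration dependence of
#' biphasic tryptophan transients: the fast-phase observed rates follow
#' `kobs = K1k2 [ATP] k2 / (K1k2 [ATP] + k2)`. A hyperbolic fit over
#' the full range gives the saturation value `k2`, and the second-order
#' constant `K1k2` is reported as the initial slope of that hyperbola,
#' `plateau / K_half` (the limiting linear dependence at low ATP). An
#' unweighted straight-line fit over the low-concentration regime
#' (points with predicted `kobs <= 0.3 k2`) is also reported as
#' `K1k2_linear`; it is the slope plotted in the field's slope figures
#' but is biased low by residual curvature within the regime. The
#' slow-phase rates saturate hyperbolically at the hydrolysis rate
#' `k_hyd`. If the fastest observed slow-phase rate is below 80% of the
#' fitted plateau, the plateau is flagged unreliable.
#'
#' @param atp_conc ATP concentrations, uM
#' @param fits list of `exp_fit` objects (two-phase) at those
#'   concentrations, or `NULL` if rate vectors are given directly
#' @param k_fast,k_slow observed fast/slow phase rates, s^-1
#'   (alternative to `fits`; `k_slow` optional)
#' @return an object of class `atp_dependence` with elements `K1k2`,
#'   `K1k2_linear`, `k2`, `k_hyd`, their standard errors, component
#'   fits, and flags
#' @export
analyze_atp_dependence <- function(atp_conc, fits = NULL, k_fast = NULL,
                                   k_slow = NULL) {
  if (!is.null(fits)) {
    k_fast <- vapply(fits, function(f) unname(coef(f)["k1"]), numeric(1))
    k_slow <- vapply(fits, function(f) {
      cf <- coef(f)
      if ("k2obs" %in% names(cf)) unname(cf["k2obs"]) else NA_real_
    }, numeric(1))
    if (all(is.na(k_slow))) k_slow <- NULL
  }
  if (length(atp_conc) < 4)
    stop("need at least 4 ATP concentrations", call. = FALSE)
  flags <- character()

  ## fast phase: hyperbolic saturation -> k2, half-saturation = k2/K1k2
  hyp <- fit_hyperbola(atp_conc, k_fast, origin = TRUE)
  if (hyp$converged) {
    k2 <- unname(coef(hyp)["plateau"])
    k2_se <- unname(hyp$se["plateau"])
    Khalf <- unname(coef(hyp)["K"])
    K1k2 <- k2 / Khalf
    K1k2_se <- ratio_se(k2, Khalf, k2_se, unname(hyp$se["K"]))
    pred <- predict(hyp)
  } else {
    ## no saturation in sight: fall back to the line over all points
    k2 <- max(k_fast)
    k2_se <- NA_real_
    K1k2 <- K1k2_se <- NA_real_
    pred <- rep(0, length(atp_conc))
    flags <- c(flags, "fast-phase saturation not observed; k2 = max kobs")
  }

  ## diagnostic: straight-line slope over the low-concentration regime
  ## (predicted kobs <= 0.3 * k2)
  lin <- pred <= 0.3 * k2
  if (sum(lin) < 2) {
    lin <- rank(atp_conc) <= 3
    flags <- c(flags, "few points in linear regime; using 3 lowest [ATP]")
  }
  lf <- stats::lm(k_fast[lin] ~ atp_conc[lin])
  if (!is.finite(K1k2)) {
    K1k2 <- unname(stats::coef(lf)[2])
    K1k2_se <- suppressWarnings(unname(summary(lf)$coefficients[2, 2]))
  }
  K1k2_linear <- unname(stats::coef(lf)[2])
  K1k2_linear_se <- suppressWarnings(
    unname(summary(lf)$coefficients[2, 2]))

  k_hyd <- k_hyd_se <- NA_real_
  slow_fit <- NULL
  if (!is.null(k_slow)) {
    ok <- is.finite(k_slow)
    slow_fit <- fit_hyperbola(atp_conc[ok], k_slow[ok], origin = TRUE)
    k_hyd <- unname(coef(slow_fit)["plateau"])
    k_hyd_se <- unname(slow_fit$se["plateau"])
    if (max(k_slow[ok]) < 0.8 * k_hyd)
      flags <- c(flags, "slow-phase plateau unreliable: no saturation observed")
  }
  structure(list(K1k2 = K1k2, K1k2_se = K1k2_se,
                 K1k2_linear = K1k2_linear,
                 K1k2_linear_se = K1k2_linear_se,
                 k2 = k2, k2_se = k2_se,
                 k_hyd = k_hyd, k_hyd_se = k_hyd_se,
                 fast_hyperbola = hyp, fast_line = lf,
                 slow_hyperbola = slow_fit, atp_conc = atp_conc,
                 k_fast = k_fast, k_slow = k_slow, flags = flags),
            class = "atp_dependence")
}

#' @export
print.atp_dependence <- function(x, ...) {
  cat("ATP dependence of transient rates\n")
  cat(sprintf("  K1k2  %10.4g +/- %-8.3g uM^-1 s^-1 (hyperbola initial slope)\n",
              x$K1k2, x$K1k2_se))
  cat(sprintf("        %10.4g +/- %-8.3g uM^-1 s^-1 (low-[ATP] line, biased low)\n",
              x$K1k2_linear, x$K1k2_linear_se))
  cat(sprintf("  k2    %10.4g +/- %-8.3g s^-1 (fast-phase saturation)\n",
              x$k2, x$k2_se))
  if (is.finite(x$k_hyd))
    cat(sprintf("  k_hyd %10.4g +/- %-8.3g s^-1 (slow-phase plateau)\n",
                x$k_hyd, x$k_hyd_se))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

## Rectangular hyperbola fit: y = basal + (plateau - basal) x / (K + x),
## optionally through the origin (basal fixed at 0).
fit_hyperbola <- function(x, y, origin = FALSE) {
  ymax <- max(y)
  Khalf0 <- {
    i <- which(y >= (min(y) + ymax) / 2)[1]
    max(x[i], min(x[x > 0], na.rm = TRUE))
  }
  if (origin) {
    fn <- function(x, p) p[["plateau"]] * x / (p[["K"]] + x)
    starts <- lapply(c(0.5, 1, 2, 5), function(f)
      c(plateau = ymax * 1.2, K = Khalf0 * f))
    lower <- c(1e-12, 1e-12)
    par_names <- c("plateau", "K")
  } else {
    fn <- function(x, p)
      p[["basal"]] + (p[["plateau"]] - p[["basal"]]) * x / (p[["K"]] + x)
    starts <- lapply(c(0.5, 1, 2, 5), function(f)
      c(basal = min(y), plateau = ymax * 1.1, K = Khalf0 * f))
    lower <- c(-Inf, -Inf, 1e-12)
    par_names <- c("basal", "plateau", "K")
  }
  ans <- ls_multistart(x, y, fn, starts, lower = lower)
  if (is.null(ans))
    return(failed_kin_fit("hyperbola", par_names, x, y,
                          flags = "fit failure", subclass = "hyperbola_fit"))
  new_kin_fit("hyperbola", ans$par, ans$se, x, y, fn, fit = ans$fit,
              subclass = "hyperbola_fit")
}

#' Active-site titration
#'
#' Estimates the fraction of catalytically competent myosin heads from
#' the saturation of the mantATP binding amplitude. The amplitude rises
#' linearly with [mantATP] until every competent active site is occupied
#' and then plateaus; the breakpoint concentration estimates the
#' concentration of competent sites. Fitted with a two-segment
#' (linear-then-flat) model by profiled least squares over the
#' breakpoint.
#'
#' @param mant_conc mantATP concentrations, uM
#' @param amplitudes fluorescence amplitudes at those concentrations, a.u.
#' @param head_conc total myosin head concentration, uM
#' @return a list of class `active_site_titration` with `fraction_active`
#'   (capped at 1 with a warning if the implied site concentration
#'   exceeds `head_conc`), `sites`, `breakpoint` diagnostics and `flags`
#' @export
active_site_titration <- function(mant_conc, amplitudes, head_conc) {
  stopifnot(length(mant_conc) == length(amplitudes), head_conc > 0)
  o <- order(mant_conc)
  x <- mant_conc[o]; y <- amplitudes[o]
  flags <- character()

  ## profile the breakpoint L0 on a fine grid; for each L0 the best
  ## amplitude scale is linear least squares on min(x, L0)/L0
  grid <- seq(min(x[x > 0]), max(x), length.out = 400)
  sse <- vapply(grid, function(L0) {
    b <- pmin(x, L0) / L0
    a <- sum(b * y) / sum(b * b)
    sum((y - a * b)^2)
  }, numeric(1))
  L0 <- grid[which.min(sse)]
  b <- pmin(x, L0) / L0
  amp <- sum(b * y) / sum(b * b)

  if (max(x) < 1.2 * L0)
    flags <- c(flags, "unreliable: no plateau detected (titration does not saturate)")
  fraction <- L0 / head_conc
  if (fraction > 1) {
    warning("implied site concentration exceeds head concentration; ",
            "fraction capped at 1", call. = FALSE)
    flags <- c(flags, sprintf("raw fraction %.3g capped at 1", fraction))
    fraction <- 1
  }
  structure(list(fraction_active = fraction, sites = L0,
                 head_conc = head_conc, amplitude = amp,
                 breakpoint_sse = min(sse), flags = flags,
                 data = data.frame(mant_conc = x, amplitude = y)),
            class = "active_site_titration")
}

#' @export
print.active_site_titration <- function(x, ...) {
  cat("Active-site titration\n")
  cat(sprintf("  competent sites  %8.4g uM of %.4g uM heads\n",
              x$sites, x$head_conc))
  cat(sprintf("  fraction active  %8.3g\n", x$fraction_active))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
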