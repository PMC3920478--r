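## Eight-state model of the actomyosin ATPase cycle.
##
## States: M, M.T, M.D.Pi, M.D (detached branch) and A.M, A.M.T,
## A.M.D.Pi, A.M.D (actin-attached branch). ATP binding is treated as a
## rapid equilibrium followed by an isomerisation, so the effective
## pseudo-first-order binding rate saturates hyperbolically at k2:
##   k_bind([ATP]) = K1k2 [ATP] k2 / (K1k2 [ATP] + k2).
## Hydrolysis is a single lumped, effectively irreversible relaxation
## (k_hyd); phosphate release (k4) and ADP release (kD detached, kAD
## attached) complete the cycle. Actin association is pseudo-first-order
## (actin_on * [actin]) for every detached state; the weak-binding
## states (A.M.T, A.M.D.Pi) detach at actin_off_weak, the strong states
## are treated as non-dissociating on the time scales modelled.

CYCLE_STATES <- c("M", "M.T", "M.D.Pi", "M.D",
                  "A.M", "A.M.T", "A.M.D.Pi", "A.M.D")

## effective pseudo-first-order ATP binding rate, s^-1
atp_binding_rate <- function(rates, atp_conc) {
  denom <- rates$K1k2 * atp_conc + rates$k2
  if (denom <= 0) return(0)
  rates$K1k2 * atp_conc * rates$k2 / denom
}

## Generator matrix Q such that dx/dt = Q %*% x for the occupancy
## vector x over CYCLE_STATES. Columns sum to zero.
cycle_rate_matrix <- function(rates, atp_conc, actin_conc) {
  if (!inherits(rates, "microscopic_rates"))
    rates <- do.call(microscopic_rates, as.list(rates))
  if (atp_conc < 0 || actin_conc < 0)
    stop("concentrations must be non-negative", call. = FALSE)
  kb  <- atp_binding_rate(rates, atp_conc)
  kon <- rates$actin_on * actin_conc
  koff <- rates$actin_off_weak
  n <- length(CYCLE_STATES)
  Q <- matrix(0, n, n, dimnames = list(CYCLE_STATES, CYCLE_STATES))
  add <- function(from, to, k) {
    Q[to, from] <<- Q[to, from] + k
    Q[from, from] <<- Q[from, from] - k
  }
  ## nucleotide steps, detached branch (slow basal phosphate release)
  add("M", "M.T", kb)
  add("M.T", "M.D.Pi", rates$k_hyd)
  add("M.D.Pi", "M.D", rates$k4_basal)
  add("M.D", "M", rates$kD)
  ## nucleotide steps, attached branch
  add("A.M", "A.M.T", kb)
  add("A.M.T", "A.M.D.Pi", rates$k_hyd)
  add("A.M.D.Pi", "A.M.D", rates$k4)
  add("A.M.D", "A.M", rates$kAD)
  ## actin association / dissociation
  add("M", "A.M", kon)
  add("M.T", "A.M.T", kon)
  add("M.D.Pi", "A.M.D.Pi", kon)
  add("M.D", "A.M.D", kon)
  add("A.M.T", "M.T", koff)
  add("A.M.D.Pi", "M.D.Pi", koff)
  Q
}

#' Simulate the actomyosin ATPase cycle
#'
#' Integrates the eight-state cycle under pseudo-first-order ligand
#' conditions (multiple turnover, the default) or with an explicitly
#' depleting ATP pool (single turnover). The returned trajectory also
#' carries the cumulative phosphate released per head (`cum_pi`), which
#' backs the phosphate-sensor observable, and the remaining `atp`
#' concentration in single-turnover mode.
#'
#' @param rates a [microscopic_rates()] object
#' @param atp_conc ATP concentration, uM
#' @param actin_conc F-actin concentration, uM
#' @param time_grid strictly increasing time points starting at 0, s
#' @param single_turnover if `TRUE`, ATP is a dynamic species depleted
#'   by binding; requires `head_conc`
#' @param head_conc myosin head concentration, uM (single-turnover mode)
#' @param init named initial occupancies (default: all heads in `M`)
#' @return a data.frame of class `cycle_trajectory` with columns `time`,
#'   the eight state occupancies, `cum_pi`, and `atp` (single turnover)
#' @examples
#' tr <- simulate_cycle(reference_rates("control"), atp_conc = 500,
#'                      actin_conc = 50, time_grid = seq(0, 50, 0.1))
#' head(tr)
#' @export
simulate_cycle <- function(rates, atp_conc, actin_conc, time_grid,
                           single_turnover = FALSE, head_conc = NULL,
                           init = NULL) {
  if (!inherits(rates, "microscopic_rates"))
    rates <- do.call(microscopic_rates, as.list(rates))
  if (length(time_grid) < 2L || time_grid[1] != 0 ||
      any(diff(time_grid) <= 0))
    stop("time_grid must be strictly increasing and start at 0",
         call. = FALSE)
  if (atp_conc < 0 || actin_conc < 0)
    stop("concentrations must be non-negative", call. = FALSE)
  if (single_turnover && is.null(head_conc))
    stop("single-turnover mode requires 'head_conc'", call. = FALSE)

  x0 <- stats::setNames(rep(0, 8), CYCLE_STATES)
  if (is.null(init)) x0["M"] <- 1 else {
    bad <- setdiff(names(init), CYCLE_STATES)
    if (length(bad)) stop("unknown states in init: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    x0[names(init)] <- init
    x0 <- x0 / sum(x0)
  }

  if (single_turnover) {
    y0 <- c(x0, cum_pi = 0, atp = atp_conc)
    deriv <- function(t, y, p) {
      Q <- cycle_rate_matrix(rates, max(y["atp"], 0), actin_conc)
      dx <- as.vector(Q %*% y[CYCLE_STATES])
      kb <- atp_binding_rate(rates, max(y["atp"], 0))
      dpi <- rates$k4_basal * y["M.D.Pi"] + rates$k4 * y["A.M.D.Pi"]
      datp <- -kb * (y["M"] + y["A.M"]) * head_conc
      list(c(dx, dpi, datp))
    }
  } else {
    Q <- cycle_rate_matrix(rates, atp_conc, actin_conc)
    y0 <- c(x0, cum_pi = 0)
    deriv <- function(t, y, p) {
      dx <- as.vector(Q %*% y[CYCLE_STATES])
      dpi <- rates$k4_basal * y["M.D.Pi"] + rates$k4 * y["A.M.D.Pi"]
      list(c(dx, dpi))
    }
  }

  out <- tryCatch(
    deSolve::lsoda(y0, time_grid, deriv, parms = NULL,
                   rtol = 1e-8, atol = 1e-10, maxsteps = 50000),
    warning = function(w)
      stop("integration error in simulate_cycle: ", conditionMessage(w),
           call. = FALSE),
    error = function(e)
      stop("integration error in simulate_cycle: ", conditionMessage(e),
           call. = FALSE))
  out <- as.data.frame(out)
  names(out)[1] <- "time"
  if (anyNA(out))
    stop("integration error in simulate_cycle: solver returned NA",
         call. = FALSE)
  structure(out, class = c("cycle_trajectory", "data.frame"),
            rates = rates, atp_conc = atp_conc, actin_conc = actin_conc,
            single_turnover = single_turnover)
}

#' Steady-state ATP turnover rate of the cycle
#'
#' Computes the per-head turnover rate (the flux through phosphate
#' release) from the stationary distribution of the cycle's rate
#' matrix. A network in which a zero rate disconnects or absorbs the
#' cycle reports zero flux rather than raising an error.
#'
#' @inheritParams simulate_cycle
#' @return turnover rate, s^-1
#' @examples
#' steady_state_rate(reference_rates("control"), atp_conc = 1000,
#'                   actin_conc = 30)
#' @export
steady_state_rate <- function(rates, atp_conc, actin_conc) {
  if (!inherits(rates, "microscopic_rates"))
    rates <- do.call(microscopic_rates, as.list(rates))
  if (atp_conc < 0 || actin_conc < 0)
    stop("concentrations must be non-negative", call. = FALSE)
  if (atp_conc == 0) return(0)
  Q <- cycle_rate_matrix(rates, atp_conc, actin_conc)
  x <- stationary_distribution(Q)
  as.numeric(rates$k4_basal * x["M.D.Pi"] + rates$k4 * x["A.M.D.Pi"])
}

## Stationary occupancies of a generator matrix. Solves Q x = 0 with the
## conservation constraint sum(x) = 1; falls back to the SVD null space
## for singular (disconnected/absorbing) networks.
stationary_distribution <- function(Q) {
  n <- nrow(Q)
  A <- Q
  A[n, ] <- 1
  b <- c(rep(0, n - 1), 1)
  x <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(x) || any(!is.finite(x)) || any(x < -1e-6)) {
    sv <- svd(Q)
    x <- sv$v[, n]
    x <- x / sum(x)
  }
  x[x < 0] <- 0
  x <- x / sum(x)
  stats::setNames(x, rownames(Q))
}

## Long-time ODE flux, used to cross-check the stationary solution.
## Integrates to a horizon set by the slowest relaxation of the network.
ode_flux <- function(rates, atp_conc, actin_conc, horizon = NULL) {
  if (!inherits(rates, "microscopic_rates"))
    rates <- do.call(microscopic_rates, as.list(rates))
  Q <- cycle_rate_matrix(rates, atp_conc, actin_conc)
  if (is.null(horizon)) {
    ev <- Re(eigen(Q, only.values = TRUE)$values)
    ## the conservation eigenvalue is 0 up to roundoff; exclude it on a
    ## scale relative to the fastest rate in the network
    nz <- ev[ev < -1e-9 * max(abs(ev))]
    relax <- if (length(nz)) -max(nz) else NA_real_
    horizon <- if (is.finite(relax) && relax > 0) 40 / relax else
      1e3 / max(abs(diag(Q)), 1e-12)
    horizon <- min(horizon, 1e8)
  }
  tr <- simulate_cycle(rates, atp_conc, actin_conc,
                       time_grid = c(0, horizon / 2, horizon))
  x <- tr[nrow(tr), CYCLE_STATES]
  as.numeric(rates$k4_basal * x[["M.D.Pi"]] + rates$k4 * x[["A.M.D.Pi"]])
}

#' Steady-state actin activation parameters from the cycle model
#'
#' Runs the cycle model over an actin concentration grid, fits the
#' resulting turnover rates with the standard activation hyperbola and
#' returns `kcat`, `KM_actin`, the basal rate and the coupling constant
#' computed by the ratio method (`kcat / KM_actin`).
#'
#' @inheritParams simulate_cycle
#' @param actin_grid actin concentrations, uM (must include 0)
#' @return a list of class `steady_state_params`
#' @export
simulated_actin_activation <- function(rates, atp_conc = 1000,
                                       actin_grid = c(0, 2.5, 5, 10, 20,
                                                      40, 70, 100, 150)) {
  v <- vapply(actin_grid, function(a)
    steady_state_rate(rates, atp_conc, a), numeric(1))
  fit <- fit_actin_activation(actin_grid, v)
  structure(list(kcat = unname(coef(fit)["kcat"]),
                 KM_actin = unname(coef(fit)["KM"]),
                 basal_rate = unname(coef(fit)["basal"]),
                 coupling = unname(coef(fit)["kcat"] / coef(fit)["KM"]),
                 fit = fit),
            class = "steady_state_params")
}

#' @export
print.steady_state_params <- function(x, ...) {
  cat("Steady-state actin activation (model-derived)\n")
  cat(sprintf("  kcat      %8.4g s^-1\n", x$kcat))
  cat(sprintf("  KM_actin  %8.4g uM\n", x$KM_actin))
  cat(sprintf("  basal     %8.4g s^-1\n", x$basal_rate))
  cat(sprintf("  coupling  %8.4g uM^-1 s^-1 (ratio method)\n", x$coupling))
  invisible(x)
}

#' Calibrate the weak-actin dissociation rate against a target KM
#'
#' The actin association/dissociation constants of the cycle are free
#' parameters. This helper solves for the `actin_off_weak` value at
#' which the simulated apparent actin affinity matches `km_target`.
#'
#' @param rates a [microscopic_rates()] object (its `actin_off_weak` is
#'   ignored)
#' @param km_target desired apparent KM(actin), uM
#' @param interval search interval for `actin_off_weak`, s^-1
#' @return the calibrated `actin_off_weak`, s^-1
#' @export
calibrate_actin_off <- function(rates, km_target,
                                interval = c(1e-2, 1e4)) {
  f <- function(off) {
    r <- rates
    r$actin_off_weak <- off
    simulated_actin_activation(r)$KM_actin - km_target
  }
  stats::uniroot(f, interval, tol = 1e-3)$root
}

#' Observable map: per-state fluorescence coefficients
#'
#' Maps cycle-state occupancies to the optical probe channels used in
#' transient experiments: intrinsic tryptophan fluorescence (rises on
#' ATP binding and further on hydrolysis), mant-nucleotide fluorescence
#' (reports all nucleotide-bound states), and the phosphate sensor
#' (MDCC-labelled phosphate binding protein; reports cumulative released
#' phosphate and is therefore monotone non-decreasing).
#'
#' @param tryptophan,mant named coefficient vectors over the cycle
#'   states, a.u. per unit occupancy; missing states default to 0
#' @param phosphate_sensor single scale coefficient for cumulative Pi
#' @return an object of class `observable_map`
#' @export
observable_map <- function(tryptophan = NULL, mant = NULL,
                           phosphate_sensor = 1) {
  coef_vec <- function(x, default) {
    out <- stats::setNames(rep(0, 8), CYCLE_STATES)
    if (is.null(x)) out[names(default)] <- default
    else {
      bad <- setdiff(names(x), CYCLE_STATES)
      if (length(bad)) stop("unknown states: ",
                            paste(bad, collapse = ", "), call. = FALSE)
      out[names(x)] <- x
    }
    if (any(!is.finite(out))) stop("coefficients must be finite",
                                   call. = FALSE)
    out
  }
  trp_default <- c(M.T = 0.7, A.M.T = 0.7, M.D.Pi = 1, A.M.D.Pi = 1,
                   M.D = 0.2, A.M.D = 0.2)
  mant_default <- c(M.T = 1, A.M.T = 1, M.D.Pi = 1, A.M.D.Pi = 1,
                    M.D = 1, A.M.D = 1)
  structure(list(tryptophan = coef_vec(tryptophan, trp_default),
                 mant = coef_vec(mant, mant_default),
                 phosphate_sensor = phosphate_sensor),
            class = "observable_map")
}

#' Project a cycle trajectory onto an optical observable
#'
#' @param trajectory a `cycle_trajectory` from [simulate_cycle()]
#' @param map an [observable_map()]
#' @param channel `"tryptophan"`, `"mant"`, or `"phosphate_sensor"`
#' @return a `kin_timeseries` (data.frame with `time`, `signal`)
#' @export
project_observable <- function(trajectory, map = observable_map(),
                               channel = c("tryptophan", "mant",
                                           "phosphate_sensor")) {
  if (!inherits(map, "observable_map"))
    stop("'map' must be an observable_map", call. = FALSE)
  if (!is.character(channel) || !all(channel %in% names(map)))
    stop("configuration error: unknown channel '",
         paste(setdiff(channel, names(map)), collapse = ", "), "'",
         call. = FALSE)
  channel <- match.arg(channel)
  if (channel == "phosphate_sensor") {
    sig <- map$phosphate_sensor * trajectory$cum_pi
  } else {
    co <- map[[channel]]
    sig <- as.matrix(trajectory[, CYCLE_STATES]) %*% co
  }
  kin_timeseries(trajectory$time, as.numeric(sig), channel = channel)
}

#' A sampled optical signal
#'
#' @param time time points, s
#' @param signal signal values, a.u.
#' @param channel probe channel label
#' @param units signal units label
#' @return a data.frame of class `kin_timeseries`
#' @export
kin_timeseries <- function(time, signal, channel = "signal",
                           units = "a.u.") {
  stopifnot(length(time) == length(signal))
  structure(data.frame(time = time, signal = signal),
            class = c("kin_timeseries", "data.frame"),
            channel = channel, units = units)
}

#' Write a cycle trajectory as CSV
#'
#' Header row is `time_s,<state names...>` (plus auxiliary columns).
#'
#' @param trajectory a `cycle_trajectory`
#' @param path output file
#' @export
write_trajectory <- function(trajectory, path) {
  out <- as.data.frame(trajectory)
  names(out)[1] <- "time_s"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
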