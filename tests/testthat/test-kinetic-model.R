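test_that("occupancies are conserved along trajectories", {
  rates <- reference_rates("control")
  for (conds in list(c(1000, 0), c(50, 10), c(5000, 200))) {
    tr <- simulate_cycle(rates, conds[1], conds[2],
                         time_grid = seq(0, 60, 0.5))
    sums <- rowSums(tr[, actokin:::CYCLE_STATES])
    expect_true(all(abs(sums - 1) < 1e-9))
  }
})

test_that("blocking phosphate release stops the flux and piles up M.D.Pi", {
  r <- microscopic_rates(K1k2 = 0.19, k2 = 46, k_hyd = 1.9, k4 = 0,
                         kD = 0.15, kAD = 25.5, k4_basal = 0)
  expect_equal(steady_state_rate(r, 1000, 30), 0, tolerance = 1e-12)
  tr <- simulate_cycle(r, 1000, 30, time_grid = seq(0, 500, 1))
  last <- tr[nrow(tr), ]
  expect_gt(last$M.D.Pi + last$A.M.D.Pi, 0.999)
  expect_equal(max(tr$cum_pi), 0)
})

test_that("long-time flux matches the series-of-steps closed form at saturation", {
  r <- reference_rates("control")
  cf <- linear_cycle_flux(c(r$k2, r$k_hyd, r$k4, r$kAD))
  expect_equal(cf, 0.0855, tolerance = 0.01)
  ss <- steady_state_rate(r, atp_conc = 1e5, actin_conc = 1e5)
  expect_equal(ss, cf, tolerance = 0.01)
  ## and exactly when actin binding is made fast and irreversible
  r2 <- reference_rates("control", actin_on = 1e6, actin_off_weak = 0)
  ss2 <- steady_state_rate(r2, atp_conc = 1e7, actin_conc = 1e4)
  cf2 <- linear_cycle_flux(c(actokin:::atp_binding_rate(r2, 1e7),
                             r2$k_hyd, r2$k4, r2$kAD))
  expect_equal(ss2, cf2, tolerance = 1e-6)
})

test_that("basal pathway flux is bounded by ADP release from myosin", {
  r <- reference_rates("control")
  expect_lte(steady_state_rate(r, 1000, 0), r$kD)
  expect_equal(steady_state_rate(r, 0, 50), 0)
})

test_that("stationary flux agrees with long-time ODE flux on random rate sets", {
  for (s in 1:25) {
    r <- random_rate_set(s)
    atp <- 10^runif(1, 0, 3)
    actin <- 10^runif(1, 0, 2)
    ss <- steady_state_rate(r, atp, actin)
    ode <- actokin:::ode_flux(r, atp, actin)
    denom <- max(abs(ss), 1e-12)
    expect_lt(abs(ss - ode) / denom, 1e-6)
  }
})

test_that("rate matrix homogeneity: doubling every rate doubles the flux", {
  r <- reference_rates("control")
  r2 <- do.call(microscopic_rates, lapply(unclass(r), `*`, 2))
  ## ATP binding saturates, so double the ATP-dependent part via conc too
  v1 <- steady_state_rate(r, 200, 30)
  ## with all rates doubled the same occupancies solve the stationary
  ## system, every flux doubles; the effective binding rate doubles when
  ## both K1k2 and k2 double at fixed [ATP]
  v2 <- steady_state_rate(r2, 200, 30)
  expect_equal(v2, 2 * v1, tolerance = 1e-9)
})

test_that("steady-state flux never exceeds the slowest saturating step", {
  for (s in 1:10) {
    cs <- saturating_bound_case(s + 100)
    r <- cs$rates
    ss <- steady_state_rate(r, cs$atp, cs$actin)
    expect_lte(ss, min(r$k2, r$k_hyd, r$k4, r$kAD) * (1 + 1e-6))
  }
})

test_that("model-derived actin activation approximates the measured kcat and KM", {
  sa <- simulated_actin_activation(reference_rates("control"))
  expect_equal(sa$kcat, 0.12, tolerance = 0.3)
  expect_equal(sa$KM_actin, 36.8, tolerance = 0.1)
  expect_equal(sa$coupling, sa$kcat / sa$KM_actin, tolerance = 1e-9)
})

test_that("observable projection behaves per channel", {
  tr <- simulate_cycle(reference_rates("control"), 100, 20,
                       time_grid = seq(0, 30, 0.1))
  zero_map <- observable_map(tryptophan = c(M.T = 0), mant = c(M.T = 0),
                             phosphate_sensor = 0)
  expect_true(all(project_observable(tr, zero_map, "tryptophan")$signal == 0))
  pi_sig <- project_observable(tr, observable_map(), "phosphate_sensor")
  expect_true(all(diff(pi_sig$signal) >= -1e-12))
  ## cumulative Pi matches the trapezoid integral of the release flux
  r <- attr(tr, "rates")
  flux <- r$k4_basal * tr$M.D.Pi + r$k4 * tr$A.M.D.Pi
  trap <- cumsum(c(0, diff(tr$time) * (head(flux, -1) + tail(flux, -1)) / 2))
  expect_equal(pi_sig$signal, trap, tolerance = 1e-5)
  expect_error(project_observable(tr, observable_map(), "nonsense"),
               "channel")
})

test_that("single-turnover mant signal shows rise, plateau and decay", {
  rates_c <- reference_rates("control")
  tr <- simulate_cycle(rates_c, atp_conc = 1.5, actin_conc = 500,
                       time_grid = seq(0, 120, 0.05),
                       single_turnover = TRUE, head_conc = 1)
  sig <- project_observable(tr, observable_map(), "mant")$signal
  i_max <- which.max(sig)
  expect_gt(sig[i_max], 0.5)               # rise to a bound plateau
  expect_gt(tr$time[i_max], 1)             # not instantaneous
  expect_lt(sig[length(sig)], 0.02 * sig[i_max])  # full decay
  ## ATP pool is consumed
  expect_lt(tr$atp[nrow(tr)], 0.01 * 1.5)
})

test_that("compound-treated rates double the single-turnover product release", {
  half_decay_time <- function(rates) {
    tr <- simulate_cycle(rates, atp_conc = 1.5, actin_conc = 500,
                         time_grid = seq(0, 200, 0.05),
                         single_turnover = TRUE, head_conc = 1)
    sig <- project_observable(tr, observable_map(), "mant")$signal
    i_max <- which.max(sig)
    tail_t <- tr$time[-seq_len(i_max)]
    tail_s <- sig[-seq_len(i_max)]
    tail_t[which(tail_s <= sig[i_max] / 2)[1]]
  }
  ratio <- half_decay_time(reference_rates("control")) /
    half_decay_time(reference_rates("emd"))
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.5)
})

test_that("invalid inputs are rejected with informative errors", {
  expect_error(microscopic_rates(K1k2 = NaN, k2 = 1, k_hyd = 1, k4 = 1,
                                 kD = 1, kAD = 1), "finite")
  r <- reference_rates("control")
  expect_error(simulate_cycle(r, 100, 10, time_grid = c(0, 2, 1)),
               "increasing")
  expect_error(simulate_cycle(r, -1, 10, time_grid = c(0, 1)),
               "non-negative")
  expect_error(simulate_cycle(r, 1, 0, time_grid = c(0, 1),
                              single_turnover = TRUE), "head_conc")
})

test_that("observed fast-phase binding rate saturates at k2", {
  r <- reference_rates("control")
  expect_lt(actokin:::atp_binding_rate(r, 1e9), r$k2)
  expect_equal(actokin:::atp_binding_rate(r, 50),
               0.19 * 50 * 46 / (0.19 * 50 + 46), tolerance = 1e-12)
})

test_that("trajectories round-trip through CSV with the documented header", {
  tr <- simulate_cycle(reference_rates("control"), 100, 10,
                       time_grid = seq(0, 5, 0.5))
  path <- tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  header <- readLines(path, n = 1)
  expect_match(header, "^time_s,M,")
  back <- utils::read.csv(path)
  expect_equal(back$M.D.Pi, tr$M.D.Pi, tolerance = 1e-12)
})
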