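test_that("noiseless exponentials are recovered essentially exactly", {
  t <- seq(0, 8, 0.01)
  f1 <- fit_exponentials(time = t, signal = 2 + 1.5 * (1 - exp(-t)),
                         n_phases = 1)
  expect_equal(unname(coef(f1)["k1"]), 1, tolerance = 1e-8)
  expect_equal(unname(coef(f1)["baseline"]), 2, tolerance = 1e-8)
  ## two well-separated phases
  y2 <- 0.7 * (1 - exp(-100 * t)) + 0.3 * (1 - exp(-10 * t))
  f2 <- fit_exponentials(time = t, signal = y2, n_phases = 2)
  expect_equal(unname(coef(f2)[c("k1", "k2obs")]), c(100, 10),
               tolerance = 1e-6)
  expect_equal(unname(coef(f2)[c("A1", "A2")]), c(0.7, 0.3),
               tolerance = 1e-6)
})

test_that("refitting from a fitted curve reproduces the parameters", {
  t <- seq(0, 5, 0.01)
  set.seed(1)
  y <- 0.5 * (1 - exp(-3 * t)) + rnorm(length(t), 0, 0.005)
  f <- fit_exponentials(time = t, signal = y, n_phases = 1)
  f2 <- fit_exponentials(time = t, signal = fitted(f), n_phases = 1)
  expect_equal(coef(f2), coef(f), tolerance = 1e-6)
})

test_that("flat traces produce a diagnosable failed fit, not an error", {
  t <- seq(0, 5, 0.01)
  f <- fit_exponentials(time = t, signal = rep(1, length(t)), n_phases = 1)
  expect_false(f$converged)
  expect_match(f$flags, "degenerate")
  expect_true(all(is.na(coef(f))))
})

test_that("multi-start least squares matches a coarse-grid + polish oracle", {
  ## oracle: exhaustive rate grid, amplitudes by linear least squares,
  ## then local polish from the grid optimum
  oracle_1exp <- function(t, y) {
    ks <- 10^seq(-2, 3, length.out = 400)
    sse <- vapply(ks, function(k) {
      X <- cbind(1, 1 - exp(-k * t))
      r <- stats::lm.fit(X, y)$residuals
      sum(r^2)
    }, numeric(1))
    k0 <- ks[which.min(sse)]
    stats::optimize(function(k) {
      X <- cbind(1, 1 - exp(-k * t))
      sum(stats::lm.fit(X, y)$residuals^2)
    }, interval = c(k0 / 2, k0 * 2))$minimum
  }
  t <- seq(0, 4, length.out = 200)
  for (s in 1:12) {
    set.seed(s)
    k_true <- 10^runif(1, -0.5, 1.5)
    y <- runif(1, 0.5, 2) * (1 - exp(-k_true * t)) +
      rnorm(length(t), 0, 0.01)
    k_fit <- unname(coef(fit_exponentials(time = t, signal = y,
                                          n_phases = 1))["k1"])
    k_or <- oracle_1exp(t, y)
    expect_equal(k_fit, k_or, tolerance = 0.005)
  }
})

test_that("ATP dependence analysis recovers binding and hydrolysis constants", {
  rates <- reference_rates("control")
  atp <- c(10, 25, 50, 100, 250, 500, 1000, 2000)
  kf <- vapply(atp, function(a) actokin:::atp_binding_rate(rates, a),
               numeric(1))
  ks <- rates$k_hyd * rates$K1k2 * atp / (rates$K1k2 * atp + rates$k2)
  set.seed(5)
  an <- analyze_atp_dependence(atp,
                               k_fast = kf * (1 + rnorm(8, 0, 0.01)),
                               k_slow = ks * (1 + rnorm(8, 0, 0.01)))
  expect_equal(an$K1k2, 0.19, tolerance = 0.1)
  expect_equal(an$k2, 46, tolerance = 0.1)
  expect_equal(an$k_hyd, 1.9, tolerance = 0.1)
  expect_gte(an$k2, max(kf))
})

test_that("constant fast-phase rates give zero slope", {
  an <- analyze_atp_dependence(c(10, 50, 100, 500),
                               k_fast = rep(5, 4) + c(1, -1, 1, -1) * 1e-9)
  expect_equal(an$K1k2_linear, 0, tolerance = 1e-6)
})

test_that("non-saturating slow phases are flagged unreliable", {
  atp <- c(5, 10, 20, 40)
  ks <- 2 * atp / (1000 + atp)  # far from plateau
  an <- analyze_atp_dependence(atp, k_fast = 0.2 * atp, k_slow = ks)
  expect_match(paste(an$flags, collapse = " "), "unreliable")
})

test_that("active-site titrations recover the competent fraction", {
  head_conc <- 1
  make_titration <- function(frac, noise, seed) {
    set.seed(seed)
    L <- seq(0.05, 2, by = 0.05)
    amp <- pmin(L, frac * head_conc) / (frac * head_conc)
    list(L = L, amp = amp + rnorm(length(L), 0, noise))
  }
  d <- make_titration(1, 0, 1)
  expect_equal(active_site_titration(d$L, d$amp, head_conc)$fraction_active,
               1, tolerance = 0.03)
  d <- make_titration(0.74, 0.01, 2)
  est <- active_site_titration(d$L, d$amp, head_conc)$fraction_active
  expect_equal(est, 0.74, tolerance = 0.06)
  expect_gte(est, 0.34 - 0.05)  # inside the observed preparation range
  expect_lte(est, 0.74 + 0.05)
})

test_that("fitted breakpoints agree with a brute-force breakpoint search", {
  brute <- function(L, amp) {
    cand <- seq(min(L), max(L), length.out = 2000)
    sse <- vapply(cand, function(L0) {
      b <- pmin(L, L0) / L0
      a <- sum(b * amp) / sum(b * b)
      sum((amp - a * b)^2)
    }, numeric(1))
    cand[which.min(sse)]
  }
  for (s in 1:25) {
    set.seed(s)
    frac <- runif(1, 0.3, 0.95)
    L <- seq(0.05, 2, by = 0.05)
    amp <- pmin(L, frac) / frac + rnorm(length(L), 0, 0.02)
    fit <- active_site_titration(L, amp, 1)
    expect_equal(fit$sites, brute(L, amp), tolerance = 0.02)
  }
})

test_that("titrations without a plateau are flagged", {
  L <- seq(0.05, 0.5, by = 0.05)   # saturation at 0.74 never reached
  amp <- pmin(L, 0.74) / 0.74
  fit <- active_site_titration(L, amp, 1)
  expect_match(paste(fit$flags, collapse = " "), "plateau")
})

test_that("transient constants are recovered within 10% median error at 1% noise", {
  ## parameter-recovery study at the module's stated conditions:
  ## 200-point traces, 1% noise, many seeds
  rates <- reference_rates("control")
  n_seeds <- 40
  res <- vapply(seq_len(n_seeds), function(s) {
    atp <- c(10, 25, 50, 100, 250, 500, 1000, 2000)
    fits <- lapply(seq_along(atp), function(i) {
      a <- atp[i]
      kf <- actokin:::atp_binding_rate(rates, a)
      ks <- rates$k_hyd * rates$K1k2 * a / (rates$K1k2 * a + rates$k2)
      grid <- sort(unique(c(seq(0, 5 / kf, length.out = 100),
                            seq(0, 6 / ks, length.out = 101)[-1])))
      sp <- synth_spec("transient_biphasic", list(atp_conc = a),
                       grid = grid, noise_sd = 0.01,
                       seed = actokin:::derive_seed(s, i))
      fit_exponentials(as.data.frame(synth_generate(sp, rates)),
                       n_phases = 2)
    })
    an <- analyze_atp_dependence(atp, fits = fits)
    c(an$K1k2, an$k2, an$k_hyd)
  }, numeric(3))
  med <- apply(res, 1, median)
  expect_equal(med[1], 0.19, tolerance = 0.1)
  expect_equal(med[2], 46, tolerance = 0.1)
  expect_equal(med[3], 1.9, tolerance = 0.1)
})
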