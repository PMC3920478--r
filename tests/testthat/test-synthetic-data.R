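test_that("identical specs yield bit-identical datasets; RNG state untouched", {
  sp <- synth_spec("melt_curve", list(Tm = 50, slope = 2.5),
                   noise_sd = 0.02, seed = 42)
  set.seed(999)
  before <- .Random.seed
  d1 <- synth_generate(sp)
  expect_identical(before, .Random.seed)
  d2 <- synth_generate(sp)
  expect_identical(serialize(d1, NULL), serialize(d2, NULL))
  d3 <- synth_generate(synth_spec("melt_curve", list(Tm = 50, slope = 2.5),
                                  noise_sd = 0.02, seed = 43))
  expect_false(identical(d1$y, d3$y))
})

test_that("noiseless single-phase transient follows the closed form", {
  sp <- synth_spec("transient_biphasic", list(A1 = 1, k1 = 1),
                   grid = seq(0, 5, 0.1), noise_sd = 0)
  d <- synth_generate(sp)
  expect_equal(d$y[d$x == 1], 1 - exp(-1), tolerance = 1e-12)
})

test_that("rates-derived phase rates follow the hyperbolic binding law", {
  rates <- reference_rates("control")
  sp <- synth_spec("transient_biphasic", list(atp_conc = 50),
                   grid = seq(0, 10, 0.01), noise_sd = 0)
  d <- synth_generate(sp, rates)
  expect_equal(d$spec$true_params$k1,
               0.19 * 50 * 46 / (0.19 * 50 + 46), tolerance = 1e-9)
  ## slow phase plateaus at k_hyd for saturating ATP
  sp_sat <- synth_spec("transient_biphasic", list(atp_conc = 1e6),
                       grid = seq(0, 10, 0.01), noise_sd = 0)
  d_sat <- synth_generate(sp_sat, rates)
  expect_equal(d_sat$spec$true_params$k2, rates$k_hyd, tolerance = 1e-3)
})

test_that("phosphate-release traces use k4 as the single-exponential rate", {
  d <- synth_generate(synth_spec("pi_release", list(),
                                 grid = seq(0, 60, 0.5), noise_sd = 0),
                      reference_rates("emd"))
  expect_equal(d$spec$true_params$k, 0.15)
  f <- fit_exponentials(as.data.frame(d), n_phases = 1)
  expect_equal(unname(coef(f)["k1"]), 0.15, tolerance = 1e-6)
})

test_that("titration generators hit their definitional midpoints", {
  ## dose-response at x = AC50 sits midway between baseline and max
  sp <- synth_spec("dose_response",
                   list(baseline = 1, fold_max = 2.5, AC50 = 7, n = 1),
                   grid = c(0, 7, 1e6), noise_sd = 0)
  y <- synth_generate(sp)$y
  expect_equal(y[2], (y[1] + y[3]) / 2, tolerance = 1e-5)
  ## melt curve at Tm is at half the normalized span
  spm <- synth_spec("melt_curve", list(Tm = 53.6), grid = seq(25, 90, 0.1),
                    noise_sd = 0)
  dm <- synth_generate(spm)
  expect_equal(dm$y[abs(dm$x - 53.6) < 1e-9], 0.5, tolerance = 1e-3)
})

test_that("two-point Arrhenius series encodes the closed-form Ea", {
  ## r(308) = e * r(298) implies Ea = R ln(r2/r1) / (1/T1 - 1/T2)
  ea <- two_point_ea(1, exp(1), 298.15, 308.15)
  sp <- synth_spec("arrhenius_series",
                   list(Ea = ea, rate_ref = 1, T_ref = 25),
                   grid = c(25, 35), noise_sd = 0)
  d <- synth_generate(sp)
  expect_equal(d$y[2] / d$y[1], exp(1), tolerance = 1e-9)
  expect_equal(ea, 76.31, tolerance = 1e-3)
})

test_that("missing generator parameters raise a configuration error naming them", {
  sp <- synth_spec("actin_titration", list(basal = 0, kcat = 0.1))
  expect_error(synth_generate(sp), "missing parameter.*KM")
  expect_error(synth_generate(synth_spec("transient_biphasic", list()),
                              NULL), "A1")
})

test_that("velocity samples are a truncated-normal/stalled mixture", {
  sp <- synth_spec("velocity_sample",
                   list(mean = 0.86, sd = 0.15, n = 1e5,
                        motile_fraction = 1), seed = 7)
  d <- synth_generate(sp)
  expect_true(all(d$y > 0))
  expect_equal(mean(d$y), 0.86, tolerance = 3 * 0.15 / sqrt(1e5) / 0.86)
  ## sd -> 0 collapses to the mean
  d0 <- synth_generate(synth_spec("velocity_sample",
                                  list(mean = 1, sd = 0, n = 50,
                                       motile_fraction = 1), seed = 1))
  expect_true(all(d0$y == 1))
  ## non-motile share sits below the stall threshold
  dm <- synth_generate(synth_spec("velocity_sample",
                                  list(mean = 0.86, sd = 0.15, n = 1000,
                                       motile_fraction = 0.75), seed = 2))
  expect_equal(sum(dm$y < 0.1) / 1000, 0.25, tolerance = 0.1)
  expect_error(synth_generate(synth_spec("velocity_sample",
                                         list(mean = 1, sd = 0.1, n = 0))),
               "n must be positive")
})

test_that("zero-noise datasets are fixed points of their fitters", {
  cases <- list(
    list(sp = synth_spec("actin_titration",
                         list(basal = 0.049, kcat = 0.12, KM = 36.8),
                         noise_sd = 0),
         fit = function(d) coef(fit_actin_activation(d$x, d$y)),
         truth = c(kcat = 0.12, KM = 36.8, basal = 0.049)),
    list(sp = synth_spec("binding_isotherm", list(KD = 7.3, n = 1),
                         noise_sd = 0),
         fit = function(d) coef(fit_binding_isotherm(d$x, d$y))[c("KD", "n")],
         truth = c(KD = 7.3, n = 1)),
    list(sp = synth_spec("melt_curve", list(Tm = 45.1, slope = 2.5),
                         noise_sd = 0),
         fit = function(d) coef(fit_melt(d$x, d$y))[c("Tm", "slope")],
         truth = c(Tm = 45.1, slope = 2.5)),
    list(sp = synth_spec("refolding_series",
                         list(base = 0, plateau = 0.4, t_half = 900),
                         noise_sd = 0),
         fit = function(d) coef(fit_recovery(d$x, d$y))[c("plateau", "t_half")],
         truth = c(plateau = 0.4, t_half = 900)),
    list(sp = synth_spec("shelf_life", list(rate = 0.1, y0 = 1),
                         noise_sd = 0),
         fit = function(d) coef(fit_shelf_life(d$x, d$y))[c("rate", "y0")],
         truth = c(rate = 0.1, y0 = 1)))
  for (cs in cases) {
    est <- cs$fit(synth_generate(cs$sp))
    expect_equal(unname(est), unname(cs$truth[names(est)]),
                 tolerance = 1e-6)
  }
})

test_that("fitted-parameter uncertainty grows with the configured noise", {
  se_at <- function(noise) {
    med <- sapply(1:8, function(s) {
      sp <- synth_spec("melt_curve", list(Tm = 50, slope = 2.5),
                       noise_sd = noise, seed = s)
      d <- synth_generate(sp)
      fit_melt(d$x, d$y)$se[["Tm"]]
    })
    median(med)
  }
  ses <- vapply(c(0.005, 0.01, 0.02, 0.05), se_at, numeric(1))
  expect_true(all(diff(ses) > 0))
})

test_that("datasets round-trip through CSV including their spec", {
  sp <- synth_spec("dose_response",
                   list(baseline = 0.08, fold_max = 2.5, AC50 = 7, n = 1),
                   noise_sd = 0.01, seed = 11)
  d <- synth_generate(sp)
  path <- tempfile(fileext = ".csv")
  write_dataset(d, path)
  back <- read_dataset(path)
  expect_equal(back$x, d$x, tolerance = 1e-12)
  expect_equal(back$y, d$y, tolerance = 1e-12)
  expect_equal(back$spec$kind, "dose_response")
  expect_equal(back$spec$true_params$AC50, 7)
  expect_equal(back$spec$seed, 11L)
})
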