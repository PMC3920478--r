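## Shared fixtures built in code.

## random but reproducible rate sets, log-uniform over [1e-3, 1e3]
random_rate_set <- function(seed) {
  set.seed(seed)
  v <- 10^runif(9, -3, 3)
  microscopic_rates(K1k2 = v[1], k2 = v[2], k_hyd = v[3], k4 = v[4],
                    kD = v[5], kAD = v[6], actin_on = v[7],
                    actin_off_weak = v[8], k4_basal = v[9])
}

## random rates in the physical regime for the rate-limiting-bound
## property: basal Pi release no faster than the actin-activated one,
## and an actin concentration that truly saturates attachment
saturating_bound_case <- function(seed) {
  r <- random_rate_set(seed)
  r$k4_basal <- min(r$k4_basal, r$k4)
  actin <- 1e4 * max(r$actin_off_weak, 1) / r$actin_on
  list(rates = r, atp = 1e9, actin = actin)
}

## closed-form series-of-steps flux for a linear four-step cycle
linear_cycle_flux <- function(k) 1 / sum(1 / k)

## two-point Arrhenius closed form, kJ/mol
two_point_ea <- function(r1, r2, t1_k, t2_k) {
  8.314 * log(r2 / r1) / (1 / t1_k - 1 / t2_k) / 1000
}
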