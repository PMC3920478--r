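#' Microscopic rate constants of the actomyosin ATPase cycle
#'
#' Container for the per-condition rate constants of the eight-state
#' actomyosin ATPase cycle. The constants are the ones measured by
#' transient kinetics: the apparent second-order ATP binding constant
#' (`K1k2`), the maximal ATP-binding isomerisation rate (`k2`), the ATP
#' hydrolysis relaxation rate (`k_hyd`, forward plus reverse lumped into
#' one effectively irreversible step), the actin-activated phosphate
#' release rate (`k4`), ADP release from myosin (`kD`) and from
#' actomyosin (`kAD`). Actin association (`actin_on`), dissociation
#' from the weak-binding states (`actin_off_weak`) and the slow basal
#' (actin-detached) phosphate release rate (`k4_basal`) are free model
#' parameters: they are not measurable from the assays modelled here
#' and are exposed so that the simulated apparent actin affinity and
#' basal turnover can be calibrated (see [calibrate_actin_off()]).
#' Actin activation arises because phosphate release is fast (`k4`)
#' only from the attached A.M.D.Pi state.
#'
#' @param K1k2 second-order ATP binding constant, uM^-1 s^-1
#' @param k2 maximal ATP-binding isomerisation rate, s^-1
#' @param k_hyd ATP hydrolysis relaxation rate, s^-1
#' @param k4 actin-activated phosphate release rate, s^-1
#' @param kD ADP release from myosin, s^-1
#' @param kAD ADP release from actomyosin, s^-1
#' @param actin_on apparent actin association rate, uM^-1 s^-1
#' @param actin_off_weak actin dissociation from weak-binding states, s^-1
#' @param k4_basal phosphate release from detached M.D.Pi, s^-1
#' @return an object of class `microscopic_rates` (a named list)
#' @examples
#' r <- microscopic_rates(K1k2 = 0.19, k2 = 46, k_hyd = 1.9, k4 = 0.09,
#'                        kD = 0.15, kAD = 25.5)
#' r
#' @export
microscopic_rates <- function(K1k2, k2, k_hyd, k4, kD, kAD,
                              actin_on = 1, actin_off_weak = 42.3,
                              k4_basal = 0.02) {
  r <- list(K1k2 = K1k2, k2 = k2, k_hyd = k_hyd, k4 = k4,
            kD = kD, kAD = kAD, actin_on = actin_on,
            actin_off_weak = actin_off_weak, k4_basal = k4_basal)
  vals <- unlist(r)
  if (any(!is.finite(vals)))
    stop("invalid model: all rate constants must be finite", call. = FALSE)
  if (any(vals < 0))
    stop("invalid model: rate constants must be non-negative", call. = FALSE)
  ## k4 = 0 etc. are allowed (blocked-step experiments); the main
  ## binding constants must be strictly positive for a live cycle.
  structure(r, class = "microscopic_rates")
}

#' @export
print.microscopic_rates <- function(x, ...) {
  cat("Actomyosin cycle rate constants\n")
  units <- c(K1k2 = "uM^-1 s^-1", k2 = "s^-1", k_hyd = "s^-1", k4 = "s^-1",
             kD = "s^-1", kAD = "s^-1", actin_on = "uM^-1 s^-1",
             actin_off_weak = "s^-1", k4_basal = "s^-1")
  for (nm in names(units))
    cat(sprintf("  %-15s %10.4g %s\n", nm, x[[nm]], units[nm]))
  invisible(x)
}

#' Reference rate constants for beta-cardiac myosin
#'
#' Literature values for porcine beta-cardiac myosin S1 measured by
#' stopped-flow and steady-state kinetics, without (`"control"`) and with
#' (`"emd"`) 25 uM of the thiadiazinone activator EMD 57033. These are
#' the generating truths used throughout the synthetic-data module and
#' the reference column of the pipeline report.
#'
#' @param condition `"control"` or `"emd"`
#' @param actin_on,actin_off_weak,k4_basal free model parameters passed
#'   to [microscopic_rates()]; the default `actin_off_weak` is
#'   calibrated so the simulated apparent actin affinity of the control
#'   condition matches the measured one (see [calibrate_actin_off()]).
#' @return a `microscopic_rates` object
#' @seealso [reference_constants()] for the full table including
#'   steady-state and stability parameters.
#' @export
reference_rates <- function(condition = c("control", "emd"),
                            actin_on = 1, actin_off_weak = NULL,
                            k4_basal = 0.02) {
  condition <- match.arg(condition)
  off <- actin_off_weak %||% 42.3
  switch(condition,
    control = microscopic_rates(K1k2 = 0.19, k2 = 46, k_hyd = 1.9,
                                k4 = 0.09, kD = 0.15, kAD = 25.5,
                                actin_on = actin_on, actin_off_weak = off,
                                k4_basal = k4_basal),
    emd     = microscopic_rates(K1k2 = 0.65, k2 = 174, k_hyd = 24.5,
                                k4 = 0.15, kD = 0.16, kAD = 26.9,
                                actin_on = actin_on, actin_off_weak = off,
                                k4_basal = k4_basal))
}

#' Reference kinetic and stability constants for beta-cardiac myosin
#'
#' The full table of measured constants for beta-cardiac myosin with and
#' without EMD 57033: microscopic cycle rates, steady-state actin
#' activation parameters, the two coupling estimates, activation energy,
#' compound affinity and activation potency, thermal melting midpoints,
#' and the refolding rescue kinetics. Used as generating truths by the
#' synthetic-data module and as the reference column of pipeline reports.
#'
#' @return a data.frame with columns `parameter`, `units`, `control`,
#'   `emd`, `fold` (the reported fold change, `NA` where not applicable).
#' @export
reference_constants <- function() {
  df <- data.frame(
    parameter = c("KM_actin", "kcat", "coupling_ratio", "coupling_slope",
                  "K1k2", "k2", "k_hyd", "k4", "kD", "kAD", "Ea",
                  "AC50", "fold_max_actin", "fold_max_basal", "KD_S1",
                  "KD_Dd2", "Tm_apo", "Tm_emd", "Tm_actomyosin_apo",
                  "Tm_actomyosin_emd", "k_rescue", "k_off_rescue",
                  "velocity_Dd2", "velocity_sd_Dd2", "velocity_Dd2_emd",
                  "velocity_sd_Dd2_emd", "basal_rate"),
    units = c("uM", "s^-1", "uM^-1 s^-1", "uM^-1 s^-1", "uM^-1 s^-1",
              "s^-1", "s^-1", "s^-1", "s^-1", "s^-1", "kJ mol^-1", "uM",
              "fold", "fold", "uM", "uM", "degC", "degC", "degC", "degC",
              "uM^-1 s^-1", "s^-1", "um s^-1", "um s^-1", "um s^-1",
              "um s^-1", "s^-1"),
    control = c(36.8, 0.12, 0.00326, 0.00193, 0.19, 46, 1.9, 0.09, 0.15,
                25.5, 47, NA, NA, NA, NA, NA, 45.1, NA, 55.5, NA, NA, NA,
                0.86, 0.15, NA, NA, 0.049),
    emd = c(3.6, 0.19, 0.0528, 0.0304, 0.65, 174, 24.5, 0.15, 0.16, 26.9,
            31, 7.0, 2.5, 1.5, 7.3, 23.0, NA, 53.6, NA, 66.4, 2e-5,
            2.3e-4, NA, NA, 1.35, 0.2, 0.081),
    fold = c(10, 1.6, 16, 15.8, 3.4, 3.8, 12.9, 1.7, NA, NA, 1.5, NA, NA,
             NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
  df
}
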