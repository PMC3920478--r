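## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `code` under a fixed RNG seed without disturbing the caller's
## RNG state. All stochastic generators go through this so that identical
## specs yield identical datasets and adding a dataset never perturbs
## earlier ones.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Seed derivation rule: dataset i under global seed s uses
## (s + 10007 * i) mod (2^31 - 1). Documented so that report runs are
## reproducible and per-dataset streams are decoupled.
derive_seed <- function(global_seed, index) {
  s <- (as.numeric(global_seed) + 10007 * as.numeric(index)) %% 2147483647
  as.integer(s)
}

stopifnot_positive <- function(x, name = deparse(substitute(x))) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop(sprintf("'%s' must be strictly positive and finite", name),
         call. = FALSE)
  invisible(x)
}

## Gas constant, J mol^-1 K^-1
.R_GAS <- 8.314

celsius_to_kelvin <- function(temp_c) temp_c + 273.15

## 2-significant-figure rounding used by the report layer only.
signif2 <- function(x) signif(x, 2)

## standard error of a ratio a/b from independent SEs
ratio_se <- function(a, b, sa, sb) {
  r <- a / b
  abs(r) * sqrt((sa / a)^2 + (sb / b)^2)
}
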