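## The `kin_fit` class: every fitting stage in the package returns one.
## A kin_fit carries the parameter estimates with standard errors, the
## residual norm, the data, a prediction function, and any diagnostic
## flags, and supports the usual modelling generics.

new_kin_fit <- function(model, coefficients, se, x, y, predict_fun,
                        fit = NULL, flags = character(), units = NULL,
                        extra = list(), subclass = character()) {
  fitted <- if (all(is.finite(coefficients))) predict_fun(x, coefficients)
            else rep(NA_real_, length(x))
  res <- y - fitted
  npar <- length(coefficients)
  df <- max(length(y) - npar, 1L)
  sigma <- sqrt(sum(res^2) / df)
  structure(
    list(model = model,
         coefficients = coefficients,
         se = se,
         residual_norm = sum(res^2),
         sigma = sigma,
         df.residual = df,
         data = data.frame(x = x, y = y),
         fitted.values = fitted,
         residuals = res,
         predict_fun = predict_fun,
         fit = fit,
         flags = flags,
         units = units,
         extra = extra,
         converged = all(is.finite(coefficients))),
    class = c(subclass, "kin_fit"))
}

#' @export
coef.kin_fit <- function(object, ...) object$coefficients

#' @export
vcov.kin_fit <- function(object, ...) {
  if (!is.null(object$fit)) return(stats::vcov(object$fit))
  diag(object$se^2, nrow = length(object$se))
}

#' @export
fitted.kin_fit <- function(object, ...) object$fitted.values

#' @export
residuals.kin_fit <- function(object, ...) object$residuals

#' @export
predict.kin_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x
       else if (is.data.frame(newdata)) newdata[[1]]
       else newdata
  object$predict_fun(x, object$coefficients)
}

#' @export
simulate.kin_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(object$data)
  out <- replicate(nsim,
                   object$fitted.values + stats::rnorm(n, 0, object$sigma),
                   simplify = FALSE)
  as.data.frame(stats::setNames(out, paste0("sim_", seq_len(nsim))))
}

#' @export
print.kin_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<kin_fit: %s>\n", x$model))
  if (!x$converged) {
    cat("  fit failed:", paste(x$flags, collapse = "; "), "\n")
    return(invisible(x))
  }
  est <- signif(x$coefficients, digits)
  se <- signif(x$se, digits)
  for (i in seq_along(est))
    cat(sprintf("  %-10s %12.6g +/- %-10.4g %s\n", names(est)[i], est[i],
                se[i], x$units[names(est)[i]] %||% ""))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.kin_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se)
  structure(list(model = object$model, coefficients = tab,
                 residual_norm = object$residual_norm,
                 sigma = object$sigma, df = object$df.residual,
                 flags = object$flags, converged = object$converged),
            class = "summary.kin_fit")
}

#' @export
print.summary.kin_fit <- function(x, ...) {
  cat(sprintf("Model: %s\n", x$model))
  stats::printCoefmat(x$coefficients)
  cat(sprintf("Residual norm: %.6g on %d degrees of freedom\n",
              x$residual_norm, x$df))
  if (length(x$flags)) cat("Flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
plot.kin_fit <- function(x, ..., n_curve = 200) {
  plot(x$data$x, x$data$y, pch = 16, cex = 0.6,
       xlab = "x", ylab = "y", main = x$model, ...)
  if (x$converged) {
    xs <- seq(min(x$data$x), max(x$data$x), length.out = n_curve)
    graphics::lines(xs, x$predict_fun(xs, x$coefficients), col = "red3",
                    lwd = 2)
  }
  invisible(x)
}

## Failed-fit constructor: downstream code receives a diagnosable object
## rather than an exception (flat traces, rank-deficient problems).
failed_kin_fit <- function(model, par_names, x, y, flags, units = NULL,
                           subclass = character()) {
  cf <- stats::setNames(rep(NA_real_, length(par_names)), par_names)
  new_kin_fit(model, cf, cf, x, y,
              predict_fun = function(x, p) rep(NA_real_, length(x)),
              flags = flags, units = units, subclass = subclass)
}

## Core least-squares engine: minpack.lm Levenberg-Marquardt with a list
## of start values; ties broken by lowest residual norm. `fn(x, pars)`
## is the model curve; `lower`/`upper` are box constraints.
ls_multistart <- function(x, y, fn, starts, lower = NULL, upper = NULL,
                          weights = NULL, maxiter = 200) {
  best <- NULL
  best_dev <- Inf
  resid_fun <- function(p) {
    r <- y - fn(x, p)
    if (!is.null(weights)) r <- r * sqrt(weights)
    r
  }
  for (st in starts) {
    ans <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fun,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ftol = 1e-14,
                           ptol = 1e-14)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(ans)) next
    dev <- ans$deviance
    if (is.finite(dev) && dev < best_dev) {
      best <- ans
      best_dev <- dev
    }
  }
  if (is.null(best)) return(NULL)
  p <- unlist(best$par)
  se <- tryCatch({
    sm <- summary(best)
    stats::setNames(sm$coefficients[, "Std. Error"], names(p))
  }, error = function(e) stats::setNames(rep(NA_real_, length(p)),
                                         names(p)))
  list(par = p, se = se, deviance = best_dev, fit = best)
}
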