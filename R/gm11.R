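#' Fit the even GM(1,1) grey model
#'
#' Estimates the grey differential equation
#' \deqn{x(k) + a\,z(k) = b, \qquad k = 2..n,}
#' where `z` is the consecutive-neighbour mean of the 1-AGO series, by
#' ordinary least squares (the grey normal equations). `a` is the
#' *development coefficient* — the per-step exponential rate of the restored
#' model, with `a > 0` meaning decay and `a < 0` growth — and `b` the *grey
#' action quantity*, the constant driving term.
#'
#' The time-response function of the whitenized equation,
#' \deqn{\hat x^{(1)}(k) = (C - b/a)\,e^{-a(k-1)} + b/a,}
#' needs an initial condition `C` on the accumulated scale. The classic
#' choice is the first observation, `C = x(1)`; `init = "optimized"`
#' (the default) instead minimizes the sum of squared relative simulation
#' errors over `C` (see [optimize_initial()]).
#'
#' Estimation always runs at full floating precision; printed parameters
#' are conventionally rounded to 3 decimals.
#'
#' @param x an [annual_series()] with `n >= 4` strictly positive values
#'   (zeros are tolerated for fitting but break relative-error based
#'   operations downstream).
#' @param init `"optimized"` (default), `"classic"`, or a numeric initial
#'   condition supplied directly.
#' @param objective_k1 treatment of the first-year term in the
#'   initial-value objective; see [gm11_objective()]. Ignored unless
#'   `init = "optimized"`.
#' @return An object of class `gm11_fit` with components `a`, `b`,
#'   `b_over_a`, `init` (an `initial_value`), `series`, `z` (the mean
#'   sequence) and `call`.
#' @section Applicability: the restored GM(1,1) model is classically
#'   considered usable only for `|a| < 2` (beyond that the one-step ratio
#'   `e^{-a}` changes sign behaviour); fits with `|a| >= 2` succeed but
#'   raise a warning. When `|a|` is numerically zero the model degenerates
#'   to constant per-step increments `b`; all downstream formulas use the
#'   analytic limit rather than dividing by `a`.
#' @examples
#' w1 <- annual_series(c(5.58, 5.10, 4.00, 3.04, 2.69, 2.61, 2.12), 2008,
#'                     label = "W1", units = "10^8 tons")
#' fit <- gm11(w1)
#' fit
#' predict(fit, h = 6)
#' @export
gm11 <- function(x, init = c("optimized", "classic"),
                 objective_k1 = c("ratio_to_first", "restored_formula",
                                  "exclude")) {
  x <- validate_series(x)
  n <- length(x)
  z <- mean_generation(ago(x))
  y <- as.numeric(x)[-1L]
  if (length(unique(z)) < 2L)
    stop("singular GM(1,1) design: mean sequence is constant", call. = FALSE)
  # grey normal equations: y = -a z + b, solved by QR for stability
  ab <- stats::lm.fit(cbind(neg_z = -z, const = 1), y)$coefficients
  a <- unname(ab[1L]); b <- unname(ab[2L])
  if (abs(a) >= 2)
    warning("development coefficient |a| = ", format(abs(a)),
            " >= 2: outside the classic GM(1,1) applicability range",
            call. = FALSE)
  fit <- structure(
    list(a = a, b = b,
         b_over_a = if (abs(a) > .gm_a_tol) b / a else NA_real_,
         init = NULL, series = x, z = z, call = match.call()),
    class = "gm11_fit")
  fit$init <- if (is.numeric(init)) {
    initial_value(init[1L], variant = "supplied",
                  objective_value = gm11_objective(fit, init[1L]))
  } else if (match.arg(init) == "optimized") {
    optimize_initial(fit, objective_k1 = objective_k1)
  } else {
    initial_value(as.numeric(x)[1L], variant = "classic",
                  objective_value = gm11_objective(fit, as.numeric(x)[1L]))
  }
  fit
}

# numeric guard below which a is treated as exactly zero (analytic limits)
.gm_a_tol <- 1e-12

# restored-model coefficient phi(k) = (1 - e^a) e^{-a(k-1)}, with the a -> 0
# limit phi -> -a (so phi * (C - b/a) -> b) handled by the callers
gm_phi <- function(a, k) (1 - exp(a)) * exp(-a * (k - 1))

# restored (original-scale) model value at index k >= 2:
# (1 - e^a)(C - b/a) e^{-a(k-1)}; constant b in the a -> 0 limit
gm_restored <- function(a, b, C, k) {
  if (abs(a) < .gm_a_tol) rep(b, length(k))
  else gm_phi(a, k) * (C - b / a)
}

#' @export
print.gm11_fit <- function(x, ...) {
  cat("GM(1,1) fit for series '", series_label(x$series), "' (n = ",
      length(x$series), ")\n", sep = "")
  cat("  development coefficient a:", format(round(x$a, 3), nsmall = 3), "\n")
  cat("  grey action quantity   b:", format(round(x$b, 3), nsmall = 3), "\n")
  cat("  initial condition      C:", format(round(initial_condition(x), 4)),
      paste0("(", x$init$variant, ")"), "\n")
  r <- if (abs(x$a) < .gm_a_tol) 0 else expm1(-x$a)
  cat("  one-step change e^(-a) - 1:",
      sprintf("%+.1f%%", 100 * r), "\n")
  invisible(x)
}

#' @export
coef.gm11_fit <- function(object, ...) {
  c(a = object$a, b = object$b, C = initial_condition(object))
}

#' Initial condition of a fit
#'
#' @param fit a `gm11_fit`.
#' @return The numeric initial condition `C` the fit carries.
#' @export
initial_condition <- function(fit) fit$init$C

#' Time-response function of a GM(1,1) fit
#'
#' Returns the closed-form solution of the whitenized equation as an
#' evaluable function of the index `k` (accumulated scale):
#' `(C - b/a) e^{-a(k-1)} + b/a`, or the linear limit `C + b (k - 1)` when
#' `a` is numerically zero. At `k = 1` it equals `C` exactly.
#'
#' @param fit a `gm11_fit`.
#' @param C initial condition; defaults to the one stored in the fit.
#' @return A function `k -> x1_hat(k)` accepting vector `k`.
#' @export
time_response <- function(fit, C = initial_condition(fit)) {
  a <- fit$a; b <- fit$b
  force(C)
  if (abs(a) < .gm_a_tol) {
    function(k) C + b * (k - 1)
  } else {
    function(k) (C - b / a) * exp(-a * (k - 1)) + b / a
  }
}

#' Restored in-sample simulation of a GM(1,1) fit
#'
#' Evaluates the restored (original-scale) model over the observation
#' window: `fitted(k) = (1 - e^a)(C - b/a) e^{-a(k-1)}` for `k = 2..n`.
#' By reporting convention the first fitted value equals the first
#' observation (zero first-year error); the formula value at `k = 1` is
#' used only inside the initial-value objective.
#'
#' @param fit a `gm11_fit`.
#' @param C initial condition; defaults to the fit's.
#' @return A `gm11_simulation`: list with `fitted`, `residuals`
#'   (observed - fitted), `relative_errors` (`|residual/observed|`),
#'   `series` and `C`.
#' @examples
#' w1 <- annual_series(c(5.58, 5.10, 4.00, 3.04, 2.69, 2.61, 2.12), 2008)
#' sim <- gm11_simulate(gm11(w1))
#' round_display(sim$fitted)
#' @export
gm11_simulate <- function(fit, C = initial_condition(fit)) {
  x <- as.numeric(fit$series)
  n <- length(x)
  fitted <- c(x[1L], gm_restored(fit$a, fit$b, C, 2:n))
  residuals <- x - fitted
  rel <- abs(residuals / x)
  structure(list(fitted = series_like(fit$series, fitted),
                 residuals = residuals, relative_errors = rel,
                 series = fit$series, C = C),
            class = "gm11_simulation")
}

#' @export
print.gm11_simulation <- function(x, ...) {
  df <- data.frame(year = series_years(x$series),
                   observed = as.numeric(x$series),
                   fitted = round(as.numeric(x$fitted), 2),
                   residual = round(x$residuals, 4),
                   rel_error = round(x$relative_errors, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
fitted.gm11_fit <- function(object, ...) gm11_simulate(object)$fitted

#' @export
residuals.gm11_fit <- function(object, ...) gm11_simulate(object)$residuals

#' Out-of-sample GM(1,1) forecast
#'
#' Extrapolates the restored model beyond the observation window:
#' `k = n+1, ..., n+h`, mapped to calendar years. Forecast levels are
#' log-linear — consecutive values have the constant ratio `e^{-a}` — so
#' they decrease monotonically when `a > 0` and grow when `a < 0`.
#'
#' @param object a `gm11_fit`.
#' @param h forecast horizon in years, a positive integer.
#' @param C initial condition; defaults to the fit's.
#' @param ... unused.
#' @return A `gm11_forecast` data frame with columns `year` and `value`.
#' @export
predict.gm11_fit <- function(object, h = 6, C = initial_condition(object),
                             ...) {
  if (length(h) != 1L || !is.finite(h) || h < 1)
    stop("forecast horizon must be a positive integer", call. = FALSE)
  h <- as.integer(h)
  n <- length(object$series)
  k <- n + seq_len(h)
  out <- data.frame(year = start_year(object$series) + k - 1L,
                    value = gm_restored(object$a, object$b, C, k))
  class(out) <- c("gm11_forecast", "data.frame")
  attr(out, "label") <- series_label(object$series)
  attr(out, "units") <- series_units(object$series)
  out
}

#' @export
print.gm11_forecast <- function(x, digits = 2, ...) {
  u <- attr(x, "units")
  cat("GM(1,1) forecast for '", attr(x, "label"), "'",
      if (nzchar(u)) paste0(" [", u, "]"), "\n", sep = "")
  df <- data.frame(year = x$year, value = round(x$value, digits))
  print(df, row.names = FALSE)
  invisible(x)
}
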