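#' Average relative simulation error
#'
#' Mean of the absolute relative errors `|residual / observed|` of a
#' restored GM(1,1) simulation. Because the first fitted value equals the
#' first observation by convention, its relative error is identically zero;
#' the default therefore averages the informative terms `k = 2..n` with
#' divisor `n - 1`. `divisor = "n"` instead averages all `n` terms
#' (including the zero), which deflates the statistic by `(n-1)/n`.
#'
#' @param sim a `gm11_simulation` from [gm11_simulate()].
#' @param divisor `"n_minus_1"` (default) or `"n"`.
#' @return The average relative error, a non-negative scalar.
#' @export
mean_relative_error <- function(sim, divisor = c("n_minus_1", "n")) {
  divisor <- match.arg(divisor)
  if (any(as.numeric(sim$series) <= 0))
    stop("relative errors undefined: series has non-positive values",
         call. = FALSE)
  rel <- sim$relative_errors
  n <- length(rel)
  if (divisor == "n_minus_1") mean(rel[-1L]) else sum(rel) / n
}

#' Grey absolute correlation degree
#'
#' Closeness measure in `(0, 1]` between an observed sequence and its
#' simulation, based on the (signed) areas each sequence sweeps relative to
#' its starting value. With
#' \deqn{|s| = \left|\sum_{k=2}^{n-1} (x(k) - x(1)) +
#'   \tfrac12 (x(n) - x(1))\right|}
#' for the observed series, \eqn{|\hat s|} likewise for the fitted series,
#' and \eqn{|\hat s - s|} the same statistic of the paired deviations, the
#' degree is
#' \deqn{\eta = \frac{1 + |s| + |\hat s|}{1 + |s| + |\hat s| + |\hat s - s|}.}
#' `eta = 1` exactly when the two sequences are geometrically identical up
#' to the zero-start shift (i.e. the swept-area statistics coincide).
#'
#' @param observed an [annual_series()] (or numeric vector).
#' @param fitted the simulated series, same length; by convention its first
#'   value equals the first observation.
#' @return The correlation degree, a scalar in `(0, 1]`.
#' @examples
#' grey_correlation(c(1, 2, 3, 4), c(1, 2.5, 3.5, 4.5))
#' @export
grey_correlation <- function(observed, fitted) {
  x <- as.numeric(observed); f <- as.numeric(fitted)
  if (length(x) != length(f))
    stop("observed and fitted lengths differ", call. = FALSE)
  s_obs <- swept_area(x)
  s_fit <- swept_area(f)
  s_diff <- swept_area(f - x)
  (1 + s_obs + s_fit) / (1 + s_obs + s_fit + s_diff)
}

# |s| statistic: absolute swept area of the zero-started sequence
swept_area <- function(x) {
  n <- length(x)
  d <- x - x[1L]
  abs(sum(d[2:(n - 1L)]) + 0.5 * d[n])
}

#' Accuracy grade thresholds
#'
#' The conventional four-level grading of grey-model adequacy. A model is
#' graded by the best (lowest) level whose threshold it meets: the average
#' relative error must fall at or below the level's `mre` bound, the
#' correlation degree at or above its `eta` bound.
#'
#' @return A data frame with columns `grade` (I-IV), `mre` and `eta`.
#' @export
grade_table <- function() {
  data.frame(grade = c("I", "II", "III", "IV"),
             mre = c(0.01, 0.05, 0.1, 0.2),
             eta = c(0.9, 0.8, 0.7, 0.6))
}

#' Grade a diagnostic value
#'
#' @param mre average relative error (graded against `<=` thresholds).
#' @param eta grey correlation degree (graded against `>=` thresholds).
#' @param table threshold table, by default [grade_table()].
#' @return Character grade `"I".."IV"`, or `"fail"` if no level is met.
#'   `accuracy_grade()` grades one statistic at a time; supply exactly one
#'   of `mre`, `eta`.
#' @export
accuracy_grade <- function(mre = NULL, eta = NULL, table = grade_table()) {
  if (is.null(mre) == is.null(eta))
    stop("supply exactly one of 'mre' or 'eta'", call. = FALSE)
  ok <- if (!is.null(mre)) mre <= table$mre else eta >= table$eta
  if (any(ok)) table$grade[which(ok)[1L]] else "fail"
}

#' Model-adequacy diagnostics for a GM(1,1) fit
#'
#' Runs the two standard adequacy tests on a fit (or a simulation): the
#' average relative error test and the grey absolute correlation degree
#' test, each graded I-IV against [grade_table()].
#'
#' @param object a `gm11_fit` or `gm11_simulation`.
#' @param divisor averaging convention for [mean_relative_error()].
#' @return A `gm11_diagnostics` list: `mean_relative_error`,
#'   `correlation_degree`, `grade_relative_error`, `grade_correlation`.
#' @examples
#' w4 <- annual_series(c(404.6, 399.7, 400.5, 388.9, 397.1, 393.8, 374.0),
#'                     2008, label = "W4", units = "10^4 tons")
#' gm11_diagnostics(gm11(w4))
#' @export
gm11_diagnostics <- function(object, divisor = c("n_minus_1", "n")) {
  sim <- if (inherits(object, "gm11_fit")) gm11_simulate(object) else object
  if (!inherits(sim, "gm11_simulation"))
    stop("need a gm11_fit or gm11_simulation", call. = FALSE)
  mre <- mean_relative_error(sim, divisor = divisor)
  eta <- grey_correlation(sim$series, sim$fitted)
  structure(list(mean_relative_error = mre,
                 correlation_degree = eta,
                 grade_relative_error = accuracy_grade(mre = mre),
                 grade_correlation = accuracy_grade(eta = eta)),
            class = "gm11_diagnostics")
}

#' @export
print.gm11_diagnostics <- function(x, ...) {
  cat("GM(1,1) adequacy diagnostics\n")
  cat(sprintf("  average relative error: %.4f (grade %s)\n",
              x$mean_relative_error, x$grade_relative_error))
  cat(sprintf("  grey correlation degree: %.4f (grade %s)\n",
              x$correlation_degree, x$grade_correlation))
  invisible(x)
}
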