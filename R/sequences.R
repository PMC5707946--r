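#' First-order accumulated generating operation (1-AGO)
#'
#' Transforms a raw series into its running partial sums,
#' `x1(k) = sum(x(1..k))`. Accumulation smooths the randomness of a short
#' series and exposes the quasi-exponential trend that the GM(1,1)
#' whitenized differential equation models.
#'
#' @param x an [annual_series()] (validated on entry).
#' @return An `accumulated_series` object: the cumulative sums, carrying the
#'   parent series as attribute `parent`.
#' @seealso [iago()] for the inverse (reduction), [mean_generation()]
#' @examples
#' w1 <- annual_series(c(5.58, 5.10, 4.00, 3.04, 2.69, 2.61, 2.12), 2008)
#' ago(w1)
#' @export
ago <- function(x) {
  x <- validate_series(x)
  structure(cumsum(as.numeric(x)), parent = x, class = "accumulated_series")
}

#' @export
print.accumulated_series <- function(x, ...) {
  cat("1-AGO accumulated series (parent: '",
      series_label(attr(x, "parent")), "')\n", sep = "")
  print(as.numeric(x), ...)
  invisible(x)
}

#' Inverse accumulated generating operation (reduction)
#'
#' First differencing with the first value preserved: the exact inverse of
#' [ago()]. Applied to a fitted accumulated trajectory it restores the
#' original-scale ("reduction") values.
#'
#' @param x an `accumulated_series`, or any numeric vector of partial sums.
#' @return If `x` carries a parent [annual_series()], an `annual_series`
#'   with the parent's metadata; otherwise a plain numeric vector.
#' @export
iago <- function(x) {
  v <- as.numeric(x)
  out <- if (length(v) > 1L) c(v[1L], diff(v)) else v
  parent <- attr(x, "parent")
  if (!is.null(parent)) series_like(parent, out) else out
}

#' Mean generation with consecutive neighbours
#'
#' Midpoints of adjacent accumulated values,
#' `z(k) = (x1(k) + x1(k-1)) / 2` for `k = 2..n`. This background sequence
#' is the regressor of the even GM(1,1) grey differential equation.
#'
#' @param x an `accumulated_series` from [ago()], or a numeric vector of
#'   partial sums with length `>= 2`.
#' @return Numeric vector of length `n - 1`, indexed `k = 2..n`.
#' @export
mean_generation <- function(x) {
  v <- as.numeric(x)
  if (length(v) < 2L)
    stop("mean_generation needs at least 2 accumulated values", call. = FALSE)
  (v[-1L] + v[-length(v)]) / 2
}

#' Grey strengthening buffer operator
#'
#' Sequence transformation that amplifies the trend of a monotone series,
#' used to correct observational data distorted by shocks (e.g. recorded
#' emissions lagging a true decline). For `k = 1..n-1`,
#' \deqn{x(k)d = (x(1) + \dots + x(k-1) + k\,x(k)) / (2k - 1),}
#' and the final value is left unchanged, `x(n)d = x(n)`. On a monotone
#' decreasing series the transform raises interior values toward the early
#' level; constants are fixed points. The operator is axiomatically a
#' *strengthening* operator only for monotone input, so non-monotone series
#' trigger a warning rather than an error (real records may break
#' monotonicity at a single point).
#'
#' @param x an [annual_series()].
#' @return An `annual_series` with `buffered = TRUE`, computed at full
#'   floating precision (use [round_display()] for printing conventions).
#' @examples
#' x <- annual_series(c(5.58, 4.86, 3.19, 1.91, 1.73, 1.90, 2.12), 2008,
#'                    label = "W1", units = "10^8 tons")
#' round_display(strengthen_buffer(x))
#' @export
strengthen_buffer <- function(x) {
  x <- validate_series(x)
  v <- as.numeric(x)
  n <- length(v)
  d <- diff(v)
  if (!(all(d >= 0) || all(d <= 0)))
    warning("series '", series_label(x), "' is not monotone; the ",
            "strengthening buffer operator is only guaranteed meaningful ",
            "for monotone sequences", call. = FALSE)
  k <- seq_len(n - 1L)
  # prefix sums x(1)+...+x(k-1); empty prefix at k = 1 gives x(1)d = x(1)
  prefix <- c(0, cumsum(v)[seq_len(n - 2L)])
  out <- c((prefix + k * v[k]) / (2 * k - 1), v[n])
  series_like(x, out, buffered = TRUE)
}
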