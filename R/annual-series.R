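#' Annual observation series
#'
#' Constructs the basic data object of the package: a short, year-indexed
#' sequence of non-negative observations, e.g. annual pollutant emission
#' volumes. Grey GM(1,1) modelling targets exactly this kind of series:
#' short (often fewer than ten points), positive, and too poorly understood
#' mechanistically for structural models.
#'
#' The internal index convention is `k = year - start_year + 1`, so the first
#' observation sits at `k = 1`.
#'
#' @param values numeric vector of observations, all `>= 0`, length `>= 4`.
#' @param start_year integer calendar year of the first observation.
#' @param label short text identifier for the series.
#' @param units free-text measurement units (e.g. `"10^8 tons"`).
#' @param buffered logical; has a buffer operator already been applied?
#'
#' @return An object of class `annual_series`: the numeric vector with
#'   `start_year`, `label`, `units` and `buffered` attributes.
#' @seealso [validate_series()], [strengthen_buffer()], [gm11()]
#' @examples
#' w1 <- annual_series(c(5.58, 5.10, 4.00, 3.04, 2.69, 2.61, 2.12),
#'                     start_year = 2008, label = "W1", units = "10^8 tons")
#' w1
#' @export
annual_series <- function(values, start_year, label = "series",
                          units = "", buffered = FALSE) {
  values <- as.numeric(values)
  stopifnot(length(start_year) == 1L, is.finite(start_year))
  x <- structure(values,
                 start_year = as.integer(start_year),
                 label = as.character(label)[1L],
                 units = as.character(units)[1L],
                 buffered = isTRUE(buffered),
                 class = "annual_series")
  validate_series(x)
}

#' Validate an annual series
#'
#' Checks the invariants every downstream operation relies on: all values
#' non-negative, at least four observations (the GM(1,1) regression needs
#' `n - 1 >= 3` points), and finite. Zero values are allowed but flagged
#' with a warning because relative-error diagnostics are undefined on them.
#'
#' @param x an [annual_series()] object (or a bare numeric vector, which is
#'   promoted with default metadata).
#' @return `x`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_series <- function(x) {
  if (!inherits(x, "annual_series")) {
    x <- annual_series(x, start_year = 1L)
    return(x)
  }
  v <- unclass(x)
  if (anyNA(v) || any(!is.finite(v)))
    stop("annual_series contains missing or non-finite values", call. = FALSE)
  if (any(v < 0))
    stop("annual_series must be non-negative; found value(s) < 0 at index ",
         paste(which(v < 0), collapse = ", "), call. = FALSE)
  if (length(v) < 4L)
    stop("annual_series too short: n = ", length(v),
         " but GM(1,1) needs at least 4 observations", call. = FALSE)
  if (any(v == 0))
    warning("annual_series contains zero value(s); relative-error ",
            "diagnostics will be undefined", call. = FALSE)
  x
}

#' @export
print.annual_series <- function(x, ...) {
  u <- series_units(x)
  cat("Annual series '", series_label(x), "'",
      if (nzchar(u)) paste0(" [", u, "]"),
      if (isTRUE(attr(x, "buffered"))) " (buffered)", "\n", sep = "")
  y <- stats::setNames(as.numeric(x), series_years(x))
  print(y, ...)
  invisible(x)
}

#' @export
as.data.frame.annual_series <- function(x, ...) {
  data.frame(year = series_years(x), value = as.numeric(x),
             series = series_label(x))
}

#' Series metadata accessors
#'
#' @param x an [annual_series()] object.
#' @return `series_years()` gives the integer calendar years;
#'   `series_label()` and `series_units()` the respective attributes;
#'   `start_year()` the first calendar year.
#' @export
series_years <- function(x) {
  start_year(x) + seq_along(x) - 1L
}

#' @rdname series_years
#' @export
start_year <- function(x) attr(x, "start_year")

#' @rdname series_years
#' @export
series_label <- function(x) attr(x, "label")

#' @rdname series_years
#' @export
series_units <- function(x) attr(x, "units")

# rebuild an annual_series with new values, keeping metadata
series_like <- function(template, values, buffered = attr(template, "buffered")) {
  structure(as.numeric(values),
            start_year = start_year(template),
            label = series_label(template),
            units = series_units(template),
            buffered = isTRUE(buffered),
            class = "annual_series")
}

#' Round values for display
#'
#' All model computation in the package runs at full floating precision;
#' this helper produces the conventionally rounded figures used in reports
#' (levels at 2 decimals, parameters at 3, diagnostics at 4).
#'
#' @param x numeric vector (or `annual_series`).
#' @param digits decimal places, default 2.
#' @return `x` rounded, preserving class and attributes.
#' @export
round_display <- function(x, digits = 2) {
  out <- round(as.numeric(x), digits)
  attributes(out) <- attributes(x)
  out
}
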