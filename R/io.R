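#' Read annual series from CSV
#'
#' Accepts either layout:
#' \itemize{
#'   \item wide — a `year` column plus one numeric column per series
#'     (column name becomes the label);
#'   \item long — columns `year`, `series` (or `label`) and `value`.
#' }
#' Years must be consecutive integers within each series.
#'
#' @param path CSV file with a header row.
#' @param columns optional character vector restricting which series to
#'   load (wide column names or long `series` values).
#' @param units units string attached to every loaded series.
#' @return A named list of [annual_series()]; a single `annual_series`
#'   when exactly one is selected.
#' @export
read_annual_series <- function(path, columns = NULL, units = "") {
  tab <- utils::read.csv(path, check.names = FALSE)
  names(tab) <- tolower_first(names(tab))
  if (!"year" %in% names(tab))
    stop("CSV must contain a 'year' column", call. = FALSE)
  long <- all(c("value") %in% names(tab)) &&
    any(c("series", "label") %in% names(tab))
  series_list <- if (long) {
    key <- intersect(c("series", "label"), names(tab))[1L]
    split_tab <- split(tab, tab[[key]])
    lapply(split_tab, function(d) {
      d <- d[order(d$year), ]
      check_years(d$year)
      annual_series(d$value, start_year = d$year[1L],
                    label = as.character(d[[key]][1L]), units = units)
    })
  } else {
    d <- tab[order(tab$year), ]
    check_years(d$year)
    value_cols <- setdiff(names(d), "year")
    out <- lapply(value_cols, function(nm)
      annual_series(d[[nm]], start_year = d$year[1L], label = nm,
                    units = units))
    stats::setNames(out, value_cols)
  }
  if (!is.null(columns)) {
    bad <- setdiff(columns, names(series_list))
    if (length(bad))
      stop("series not found in ", path, ": ", paste(bad, collapse = ", "),
           call. = FALSE)
    series_list <- series_list[columns]
  }
  if (length(series_list) == 1L) series_list[[1L]] else series_list
}

tolower_first <- function(x) {
  x[tolower(x) %in% c("year", "value", "series", "label")] <-
    tolower(x[tolower(x) %in% c("year", "value", "series", "label")])
  x
}

check_years <- function(years) {
  if (length(years) > 1L && any(diff(years) != 1L))
    stop("years must be consecutive integers", call. = FALSE)
  invisible(years)
}

#' Write annual series to CSV (wide layout)
#'
#' Inverse of [read_annual_series()]: writes one `year` column plus one
#' column per series. All series must share the same year range.
#'
#' @param series an [annual_series()] or a list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_annual_series <- function(series, path) {
  if (inherits(series, "annual_series")) series <- list(series)
  years <- series_years(series[[1L]])
  for (s in series)
    if (!identical(series_years(s), years))
      stop("all series must share the same years", call. = FALSE)
  df <- data.frame(year = years)
  for (s in series) df[[series_label(s)]] <- as.numeric(s)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Structured report for a GM(1,1) fit
#'
#' Bundles parameters, in-sample simulation, adequacy diagnostics and an
#' out-of-sample forecast into one list ready for JSON serialization.
#' Full-precision values are reported alongside display-rounded ones
#' (levels 2 decimals, parameters 3, diagnostics 4) so a report can be
#' compared at printed precision without losing auditability.
#'
#' @param fit a `gm11_fit`.
#' @param horizon forecast horizon in years; `0` omits the forecast block.
#' @param divisor averaging convention for [mean_relative_error()].
#' @return A `gm11_report` list.
#' @export
gm11_report <- function(fit, horizon = 6, divisor = c("n_minus_1", "n")) {
  sim <- gm11_simulate(fit)
  diag <- gm11_diagnostics(sim, divisor = divisor)
  rep <- list(
    label = series_label(fit$series),
    units = series_units(fit$series),
    buffered = isTRUE(attr(fit$series, "buffered")),
    years = series_years(fit$series),
    observed = as.numeric(fit$series),
    a = fit$a, b = fit$b,
    C = initial_condition(fit), init_variant = fit$init$variant,
    fitted = as.numeric(sim$fitted),
    residuals = sim$residuals,
    relative_errors = sim$relative_errors,
    diagnostics = list(
      mean_relative_error = diag$mean_relative_error,
      correlation_degree = diag$correlation_degree,
      grade_relative_error = diag$grade_relative_error,
      grade_correlation = diag$grade_correlation),
    display = list(a = round(fit$a, 3), b = round(fit$b, 3),
                   C = round(initial_condition(fit), 2),
                   fitted = round(as.numeric(sim$fitted), 2),
                   mean_relative_error = round(diag$mean_relative_error, 4),
                   correlation_degree = round(diag$correlation_degree, 4)))
  if (horizon >= 1) {
    fc <- predict(fit, h = horizon)
    rep$forecast <- list(years = fc$year, values = fc$value,
                         display = round(fc$value, 2))
  }
  structure(rep, class = c("gm11_report", "list"))
}

#' Run the full grey-forecasting pipeline over a CSV input
#'
#' End-to-end procedure: read the series, optionally apply the
#' strengthening buffer operator to selected series, fit GM(1,1), optimize
#' the initial condition, simulate, diagnose, forecast, and write one JSON
#' report plus one CSV of fitted and forecast levels per series. Output is
#' atomic: nothing is written until every series has been processed, so a
#' failing input leaves no partial files.
#'
#' @param input CSV path, read with [read_annual_series()].
#' @param output_dir directory for the report files (created if needed).
#' @param columns optional subset of series to process.
#' @param buffer character vector of series labels to pass through
#'   [strengthen_buffer()] before fitting.
#' @param init,objective_k1 passed to [gm11()].
#' @param divisor passed to [mean_relative_error()].
#' @param horizon forecast horizon (years); `0` skips forecasting.
#' @param units units string for the loaded series.
#' @return Invisibly, a named list of `gm11_report`s (also written to
#'   `<output_dir>/<label>.json` and `<label>_levels.csv`).
#' @export
run_pipeline <- function(input, output_dir, columns = NULL,
                         buffer = character(), init = "optimized",
                         objective_k1 = "ratio_to_first",
                         divisor = "n_minus_1", horizon = 6, units = "") {
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon < 0)
    stop("horizon must be a non-negative number", call. = FALSE)
  series_list <- read_annual_series(input, columns = columns, units = units)
  if (inherits(series_list, "annual_series"))
    series_list <- stats::setNames(list(series_list),
                                   series_label(series_list))
  bad <- setdiff(buffer, names(series_list))
  if (length(bad))
    stop("buffer requested for unknown series: ",
         paste(bad, collapse = ", "), call. = FALSE)
  reports <- lapply(series_list, function(s) {
    if (series_label(s) %in% buffer) s <- strengthen_buffer(s)
    gm11_report(gm11(s, init = init, objective_k1 = objective_k1),
                horizon = horizon, divisor = divisor)
  })
  # all computation done; now write (atomic-output contract)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  for (rep in reports) {
    base <- file.path(output_dir, rep$label)
    jsonlite::write_json(unclass(rep), paste0(base, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    df <- data.frame(year = rep$years, observed = rep$observed,
                     fitted = rep$fitted, kind = "simulated")
    if (!is.null(rep$forecast))
      df <- rbind(df, data.frame(year = rep$forecast$years, observed = NA,
                                 fitted = rep$forecast$values,
                                 kind = "forecast"))
    utils::write.csv(df, paste0(base, "_levels.csv"), row.names = FALSE)
  }
  invisible(reports)
}

#' Plot a GM(1,1) fit
#'
#' Base-graphics plot of the observed points, the restored in-sample
#' simulation, and (optionally) the out-of-sample forecast.
#'
#' @param x a `gm11_fit`.
#' @param h forecast horizon to draw; `0` draws none.
#' @param ... passed to [plot.default()].
#' @return `x`, invisibly.
#' @export
plot.gm11_fit <- function(x, h = 6, ...) {
  sim <- gm11_simulate(x)
  yrs <- series_years(x$series)
  obs <- as.numeric(x$series)
  fit <- as.numeric(sim$fitted)
  fc <- if (h >= 1) predict(x, h = h) else NULL
  ylim <- range(obs, fit, fc$value)
  xlim <- range(yrs, fc$year)
  u <- series_units(x$series)
  plot(yrs, obs, pch = 16, xlim = xlim, ylim = ylim,
       xlab = "year",
       ylab = paste0(series_label(x$series),
                     if (nzchar(u)) paste0(" (", u, ")")),
       main = paste("GM(1,1):", series_label(x$series)), ...)
  lines(yrs, fit, lty = 1)
  if (!is.null(fc)) lines(c(yrs[length(yrs)], fc$year),
                          c(fit[length(fit)], fc$value), lty = 2)
  legend("topright", bty = "n", pch = c(16, NA, NA), lty = c(NA, 1, 2),
         legend = c("observed", "simulated", "forecast"))
  invisible(x)
}
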