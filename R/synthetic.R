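#' Three Gorges Reservoir Area wastewater emission series, 2008-2014
#'
#' The packaged worked-example data: annual emissions of the four main
#' water pollutant streams in the Three Gorges Reservoir Area, from the
#' regional environmental and ecological monitoring bulletins.
#' \describe{
#'   \item{W1}{industrial wastewater, 10^8 tons. The raw record (`W1_raw`)
#'     is distorted by acquisition and collection artefacts, so the
#'     modelling column `W1` is the raw series stabilised by the grey
#'     strengthening buffer operator, stored at the conventional 2-decimal
#'     precision.}
#'   \item{W2}{domestic wastewater, 10^8 tons.}
#'   \item{W3}{oily wastewater from ships, 10^4 tons.}
#'   \item{W4}{domestic wastewater from ships, 10^4 tons.}
#' }
#'
#' @param which optional character vector of series to return (subset of
#'   `"W1"`, `"W1_raw"`, `"W2"`, `"W3"`, `"W4"`).
#' @return A named list of [annual_series()] objects; a single
#'   `annual_series` if `which` selects exactly one.
#' @examples
#' three_gorges_series("W1")
#' @export
three_gorges_series <- function(which = NULL) {
  path <- system.file("extdata", "three_gorges_wastewater.csv",
                      package = "greycast", mustWork = TRUE)
  tab <- utils::read.csv(path)
  units <- c(W1_raw = "10^8 tons", W1 = "10^8 tons", W2 = "10^8 tons",
             W3 = "10^4 tons", W4 = "10^4 tons")
  col <- c(W1_raw = "W1_X", W1 = "W1_XD", W2 = "W2", W3 = "W3", W4 = "W4")
  out <- lapply(names(col), function(nm)
    annual_series(tab[[col[[nm]]]], start_year = tab$year[1L], label = nm,
                  units = units[[nm]], buffered = (nm == "W1")))
  names(out) <- names(col)
  if (!is.null(which)) {
    bad <- setdiff(which, names(out))
    if (length(bad))
      stop("unknown series: ", paste(bad, collapse = ", "), call. = FALSE)
    out <- out[which]
    if (length(out) == 1L) return(out[[1L]])
  }
  out
}

#' Generate a series exactly following a GM(1,1) restored model
#'
#' Instantiates the restored-model equation as a data-generating process:
#' `x(1) = C` and `x(k) = (1 - e^a)(C - b/a) e^{-a(k-1)}` for `k >= 2`
#' (constant increments `b` in the `a -> 0` limit). Refitting such a series
#' recovers `a`, `b` and — through the initial-value optimizer — `C`, which
#' makes these generators the backbone of parameter-recovery and
#' self-consistency tests.
#'
#' With `noise_sd > 0` every value is multiplied by an independent
#' `1 + Normal(0, noise_sd)` factor (relative noise, matching the
#' relative-error objective of the method); draws that would produce a
#' non-positive value are rejected and resampled. Generation is
#' deterministic for a fixed `seed`.
#'
#' @param a development coefficient of the generating model.
#' @param b grey action quantity.
#' @param C initial condition; `x(1) = C` before noise.
#' @param n series length, `>= 4`.
#' @param noise_sd standard deviation of the multiplicative relative noise;
#'   `0` (default) gives the exact model series.
#' @param seed integer seed; required when `noise_sd > 0`.
#' @param start_year first calendar year of the generated series.
#' @param label series label.
#' @return An [annual_series()].
#' @examples
#' x <- gm11_generate(a = 0.181, b = 6.338, C = 5.58, n = 7)
#' coef(gm11(x))   # recovers a, b, C
#' @export
gm11_generate <- function(a, b, C, n, noise_sd = 0, seed = NULL,
                          start_year = 2008, label = "synthetic") {
  stopifnot(n >= 4, noise_sd >= 0)
  exact <- c(C, gm_restored(a, b, C, 2:n))
  if (any(exact <= 0))
    stop("generating model produces non-positive values; choose a, b, C ",
         "with positive restored levels", call. = FALSE)
  values <- exact
  if (noise_sd > 0) {
    if (is.null(seed))
      stop("a seed is required for noisy generation", call. = FALSE)
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    values <- exact * (1 + stats::rnorm(n, 0, noise_sd))
    # rejection-resample any non-positive draw, element-wise
    for (i in which(values <= 0)) {
      repeat {
        values[i] <- exact[i] * (1 + stats::rnorm(1, 0, noise_sd))
        if (values[i] > 0) break
      }
    }
  }
  annual_series(values, start_year = start_year, label = label)
}
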