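# shared fixtures and independent oracles for the test suite

# Three Gorges series built in code (same values as the packaged CSV),
# so sequence-level tests do not depend on the reader
tg <- list(
  W1_raw = c(5.58, 4.86, 3.19, 1.91, 1.73, 1.90, 2.12),
  W1 = c(5.58, 5.10, 4.00, 3.04, 2.69, 2.61, 2.12),
  W2 = c(5.93, 6.23, 6.15, 7.06, 7.31, 7.87, 7.94),
  W3 = c(41.20, 41.30, 48.13, 49.59, 51.02, 50.00, 43.90),
  W4 = c(404.6, 399.7, 400.5, 388.9, 397.1, 393.8, 374.0))

tg_series <- function(name) {
  annual_series(tg[[name]], start_year = 2008, label = name,
                buffered = (name == "W1"))
}

# independent least-squares oracle: closed-form grey normal equations,
# written out term by term (no matrix solver shared with the package)
normal_eq_fit <- function(x) {
  n <- length(x)
  x1 <- cumsum(x)
  z <- (x1[-1] + x1[-n]) / 2
  y <- x[-1]
  m <- n - 1
  den <- m * sum(z^2) - sum(z)^2
  a <- (sum(y) * sum(z) - m * sum(y * z)) / den
  b <- (sum(z^2) * sum(y) - sum(z) * sum(y * z)) / den
  c(a = a, b = b)
}

# brute-force initial-value oracle: golden-section search on the exported
# objective, independent of the closed-form minimizer
brute_force_C <- function(fit, ...) {
  x1 <- as.numeric(fit$series)[1]
  stats::optimize(function(C) gm11_objective(fit, C, ...),
                  interval = c(0.1 * x1, 10 * x1), tol = 1e-10)$minimum
}

series_like_test <- function(template, values) {
  annual_series(values, start_year(template), label = series_label(template))
}

# random positive series with a quasi-exponential trend plus relative noise
random_series <- function(n = 7, a = runif(1, -0.3, 0.3),
                          b = runif(1, 1, 50), noise = 0.05) {
  C <- b / max(abs(a), 0.05) * runif(1, 0.5, 1.5)
  base <- c(C, (1 - exp(a)) * (C - b / a) * exp(-a * (1:(n - 1))))
  if (any(base <= 0)) base <- abs(base) + 0.1
  vals <- base * (1 + rnorm(n, 0, noise))
  vals[vals <= 0] <- 0.01
  annual_series(vals, start_year = 2000)
}
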