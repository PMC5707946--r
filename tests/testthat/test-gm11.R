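test_that("least-squares fit matches the term-by-term normal-equation oracle", {
  set.seed(11)
  for (i in 1:20) {
    x <- random_series(n = sample(4:9, 1))
    fit <- gm11(x, init = "classic")
    oracle <- normal_eq_fit(as.numeric(x))
    expect_equal(fit$a, unname(oracle["a"]), tolerance = 1e-9)
    expect_equal(fit$b, unname(oracle["b"]), tolerance = 1e-9)
    # residual orthogonality of the normal equations
    z <- fit$z
    y <- as.numeric(x)[-1]
    r <- y - (-fit$a * z + fit$b)
    expect_lt(max(abs(c(sum(r * -z), sum(r)))), 1e-9 * max(1, sum(abs(y))))
  }
})

test_that("constant series fit exactly with a = 0, b = level", {
  fit <- gm11(annual_series(rep(2.5, 7), 2000), init = "classic")
  expect_equal(fit$a, 0, tolerance = 1e-12)
  expect_equal(fit$b, 2.5, tolerance = 1e-12)
  expect_equal(max(abs(gm11_simulate(fit)$residuals)), 0, tolerance = 1e-10)
})

test_that("exact geometric series give zero residuals and closed-form (a, b)", {
  for (cq in list(c(3, 0.8), c(1, 1.25), c(10, 0.5), c(0.2, 2),
                  c(5, 0.95))) {
    c0 <- cq[1]; q <- cq[2]
    x <- annual_series(c0 * q^(0:6), 2000)
    fit <- gm11(x, init = "classic")
    expect_equal(fit$a, -2 * (q - 1) / (q + 1), tolerance = 1e-10)
    expect_equal(fit$b, 2 * c0 / (q + 1), tolerance = 1e-10)
    r <- as.numeric(x)[-1] - (-fit$a * fit$z + fit$b)
    expect_lt(max(abs(r)), 1e-10 * c0)
  }
})

test_that("degenerate designs are rejected", {
  # all increments zero after the first value -> constant mean sequence
  suppressWarnings(
    expect_error(gm11(annual_series(c(5, 0, 0, 0), 2000)), "singular"))
})

test_that("time response equals C at the origin and matches the AGO of the simulation", {
  w1 <- tg_series("W1")
  fit <- gm11(w1)
  for (C in c(5.58, initial_condition(fit), 6.1)) {
    tr <- time_response(fit, C)
    expect_equal(tr(1), C)
    sim <- gm11_simulate(fit, C)
    acc <- cumsum(c(C, as.numeric(sim$fitted)[-1]))  # fitted[1] = C on AGO scale
    expect_equal(acc[-1], tr(2:7), tolerance = 1e-10)
  }
})

test_that("a -> 0 limit degrades gracefully to constant increments", {
  # constant-increment data: exact fit has a = 0 (numerically ~1e-16)
  x <- annual_series(c(4, 1.5, 1.5, 1.5, 1.5), 2000)
  fit <- gm11(x, init = "classic")
  expect_lt(abs(fit$a), 1e-12)
  expect_true(is.na(fit$b_over_a))
  expect_equal(time_response(fit)(1:5), 4 + 1.5 * (0:4), tolerance = 1e-10)
  expect_equal(as.numeric(predict(fit, h = 3)$value), rep(1.5, 3),
               tolerance = 1e-10)
})

test_that("restored simulation reproduces the published spot values", {
  sim1 <- gm11_simulate(gm11(tg_series("W1")))
  expect_equal(round(as.numeric(sim1$fitted)[2], 2), 4.87)  # 2009
  sim3 <- gm11_simulate(gm11(tg_series("W3")))
  expect_equal(round(as.numeric(sim3$fitted)[7], 2), 48.68) # 2014
  # zero first-year error convention
  expect_equal(as.numeric(sim1$fitted)[1], 5.58)
  expect_equal(sim1$residuals[1], 0)
  expect_true(all(sim1$relative_errors >= 0))
})

test_that("refitting a generated model series recovers its parameters closely", {
  # the generator uses the continuous rate a while the grey difference
  # equation identifies 2*tanh(a/2), so recovery is close, not exact
  for (ab in list(c(0.181, 6.338, 5.58), c(-0.0559, 5.637, 5.93),
                  c(0.01, 408.5, 404.6))) {
    x <- gm11_generate(a = ab[1], b = ab[2], C = ab[3], n = 7)
    fit <- gm11(x, init = "classic")
    expect_lt(abs(fit$a - ab[1]), 0.02)
    expect_lt(abs(fit$a - 2 * tanh(ab[1] / 2)), 1e-6)
    expect_lt(abs(fit$b - ab[2]) / ab[2], 0.005)
    sim <- gm11_simulate(fit, C = ab[3])
    expect_lt(mean(sim$relative_errors[-1]), 0.005)
  }
})

test_that("forecasts are log-linear with one-step ratio e^(-a)", {
  set.seed(3)
  for (i in 1:10) {
    fit <- gm11(random_series())
    fc <- predict(fit, h = 5)
    expect_equal(fc$value[-1] / fc$value[-5], rep(exp(-fit$a), 4),
                 tolerance = 1e-10)
    expect_equal(diff(log(fc$value)), rep(-fit$a, 4), tolerance = 1e-10)
  }
  # monotone direction follows the sign of a
  fcW1 <- predict(gm11(tg_series("W1")), h = 6)   # a > 0: decay
  expect_true(all(diff(fcW1$value) < 0))
  fcW2 <- predict(gm11(tg_series("W2")), h = 6)   # a < 0: growth
  expect_true(all(diff(fcW2$value) > 0))
})

test_that("forecast years map k = n+1.. onto the calendar", {
  fc <- predict(gm11(tg_series("W2")), h = 6)
  expect_identical(fc$year, 2015:2020)
  expect_error(predict(gm11(tg_series("W2")), h = 0), "positive")
  expect_error(predict(gm11(tg_series("W2")), h = -2), "positive")
})
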