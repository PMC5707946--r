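test_that("objective is zero at truth for perfectly generated series", {
  # evaluate the objective under the generator's own (a, b): the restored
  # model then passes through every point exactly at C = C_true
  x <- gm11_generate(a = 0.12, b = 9, C = 7.5, n = 8)
  fit <- structure(list(a = 0.12, b = 9, series = x), class = "gm11_fit")
  expect_equal(gm11_objective(fit, 7.5), 0, tolerance = 1e-12)
  expect_gt(gm11_objective(fit, 7.6), 0)
})

test_that("objective is a convex quadratic in C with a unique minimum", {
  fit <- gm11(tg_series("W1"), init = "classic")
  C_grid <- seq(4, 8, by = 0.01)
  obj <- gm11_objective(fit, C_grid)
  # second differences of a quadratic are a positive constant
  d2 <- diff(obj, differences = 2)
  expect_true(all(d2 > 0))
  expect_equal(max(d2) - min(d2), 0, tolerance = 1e-10)
  # the published optimum is bracketed
  expect_lt(gm11_objective(fit, 5.59), gm11_objective(fit, 5.00))
  expect_lt(gm11_objective(fit, 5.59), gm11_objective(fit, 6.20))
})

test_that("closed-form minimizer agrees with a golden-section oracle across random fits", {
  set.seed(101)
  for (i in 1:100) {
    fit <- gm11(random_series(n = sample(5:9, 1)), init = "classic")
    for (k1 in c("ratio_to_first", "restored_formula", "exclude")) {
      iv <- optimize_initial(fit, objective_k1 = k1)
      expect_equal(iv$C, brute_force_C(fit, objective_k1 = k1),
                   tolerance = 1e-6)
    }
  }
})

test_that("optimized C is stationary and never worse than the classic choice", {
  set.seed(55)
  for (i in 1:40) {
    fit <- gm11(random_series(), init = "classic")
    iv <- optimize_initial(fit)
    classic <- as.numeric(fit$series)[1]
    expect_lte(iv$objective_value, gm11_objective(fit, classic) + 1e-12)
    h <- 1e-5 * max(1, abs(iv$C))
    deriv <- (gm11_objective(fit, iv$C + h) -
                gm11_objective(fit, iv$C - h)) / (2 * h)
    curv <- (gm11_objective(fit, iv$C + h) - 2 * iv$objective_value +
               gm11_objective(fit, iv$C - h)) / h^2
    expect_lt(abs(deriv), 1e-6 * max(1, abs(curv)))
  }
})

test_that("optimizer recovers the true initial value of an exact model series", {
  for (ab in list(c(0.181, 6.338, 5.58), c(-0.05, 5.6, 5.9))) {
    x <- gm11_generate(a = ab[1], b = ab[2], C = ab[3], n = 7)
    fit <- structure(list(a = ab[1], b = ab[2], series = x),
                     class = "gm11_fit")
    # (the restored_formula variant scores k = 1 by the formula value,
    # which differs from x(1) = C even at truth, so it shifts the optimum)
    for (k1 in c("ratio_to_first", "exclude"))
      expect_equal(optimize_initial(fit, objective_k1 = k1)$C, ab[3],
                   tolerance = 1e-8)
  }
})

test_that("published optimized initial values are reproduced within tolerance", {
  expected <- c(W1 = 5.59, W2 = 5.93, W3 = 41.16, W4 = 404.64)
  for (nm in names(expected)) {
    fit <- gm11(tg_series(nm), init = "optimized")
    expect_equal(initial_condition(fit), unname(expected[nm]),
                 tolerance = 0.15 / unname(expected[nm]) + 1e-9)
    expect_identical(fit$init$variant, "optimized")
  }
})

test_that("fitted levels are insensitive to the initial-value convention", {
  # guards against over-reading the optimization: +/-0.1 perturbations of C
  # move fitted and forecast levels by well under a hundredth of a unit
  for (nm in c("W1", "W2", "W3", "W4")) {
    fit <- gm11(tg_series(nm), init = "optimized")
    C_opt <- initial_condition(fit)
    classic <- as.numeric(fit$series)[1]
    d_fit <- abs(as.numeric(gm11_simulate(fit, C_opt)$fitted) -
                 as.numeric(gm11_simulate(fit, classic)$fitted))
    expect_lt(max(d_fit), 0.01)
    d_fc <- abs(predict(fit, h = 6, C = C_opt + 0.1)$value -
                predict(fit, h = 6, C = C_opt)$value)
    expect_lt(max(d_fc), 0.02)
  }
})

test_that("objective refuses non-positive observations", {
  x <- suppressWarnings(annual_series(c(2, 0, 1, 1), 2000))
  fit0 <- structure(list(a = 0.1, b = 1, series = x), class = "gm11_fit")
  expect_error(gm11_objective(fit0, 2), "positive")
})
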