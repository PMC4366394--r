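test_that("a local linear fit reproduces noise-free lines exactly", {
  x <- 0:20
  for (alpha in c(0.4, 0.75, 1)) {
    fit <- lowess_fit(x, 2 * x + 1, loess_config(alpha = alpha,
                                                 iterations = 0))
    expect_lt(max(abs(fit$fitted - (2 * fit$age + 1))), 1e-9)
    # robustness iterations leave an exact fit untouched
    fit4 <- lowess_fit(x, 2 * x + 1, loess_config(alpha = alpha))
    expect_lt(max(abs(fit4$fitted - (2 * fit4$age + 1))), 1e-9)
  }
})

test_that("constant data give a constant fit", {
  fit <- lowess_fit(seq(0, 40, by = 2), rep(7, 21), loess_config())
  expect_equal(fit$fitted, rep(7, length(fit$age)))
})

test_that("robustness iterations suppress a gross outlier", {
  set.seed(21)
  x <- sort(runif(40, 0, 100))
  line <- 10 + 0.5 * x
  y <- line
  y[20] <- y[20] + 500
  plain <- lowess_fit(x, y, loess_config(iterations = 0))
  robust <- lowess_fit(x, y, loess_config(iterations = 4))
  err_plain <- max(abs(plain$fitted - (10 + 0.5 * plain$age)))
  err_robust <- max(abs(robust$fitted - (10 + 0.5 * robust$age)))
  expect_lt(err_robust, err_plain)
  expect_lt(err_robust, 5)
})

test_that("the fit agrees with Cleveland's lowess on noisy data", {
  set.seed(33)
  x <- sort(runif(80, 0, 120))
  y <- 40 + 0.6 * x + 15 * sin(x / 15) + rnorm(80, 0, 4)
  for (alpha in c(0.3, 0.75)) for (iter in c(0, 4)) {
    ours <- lowess_fit(x, y, loess_config(alpha = alpha, iterations = iter,
                                          grid = x))
    ref <- stats::lowess(x, y, f = alpha, iter = iter, delta = 0)
    expect_lt(max(abs(ours$fitted - ref$y)), 1e-6)
  }
})

test_that("fitted values stay essentially inside the data range for monotone data", {
  # local linear fits can overshoot a concave boundary by a sliver; anything
  # beyond 1% of the data range would indicate a real defect
  x <- 1:30
  y <- sqrt(x)
  slack <- 0.01 * diff(range(y))
  fit <- lowess_fit(x, y, loess_config(alpha = 0.5, iterations = 0))
  expect_true(all(fit$fitted >= min(y) - slack))
  expect_true(all(fit$fitted <= max(y) + slack))
})

test_that("degenerate inputs are refused with fit errors", {
  expect_error(lowess_fit(1:4, 1:4, loess_config()),
               class = "ccmorph_fit_error")
  expect_error(lowess_fit(rep(5, 10), rnorm(10), loess_config()),
               class = "ccmorph_fit_error")
  # neighbourhood of identical ages at small span
  ages <- c(rep(1, 6), 50, 60, 70, 80)
  expect_error(lowess_fit(ages, rnorm(10), loess_config(alpha = 0.5)),
               class = "ccmorph_fit_error")
})

test_that("the configuration is validated", {
  expect_error(loess_config(alpha = 0), class = "ccmorph_config_error")
  expect_error(loess_config(alpha = 1.5), class = "ccmorph_config_error")
  expect_error(loess_config(iterations = -1), class = "ccmorph_config_error")
  expect_error(loess_config(grid = c(3, 2)), class = "ccmorph_config_error")
  expect_error(loess_config(degree = 3), class = "ccmorph_config_error")
})
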