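test_that("fit_linear recovers exact lines and flags degenerate input", {
  x <- 1:10
  f <- fit_linear(x, 2 * x + 1)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_equal(f$r2, 1)
  flat <- fit_linear(x, rep(5, 10))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_error(fit_linear(1:2, 1:2), "at least 3")
  expect_error(fit_linear(rep(1, 5), 1:5), "zero variance")
})

test_that("SGR rises significantly with crude-protein ADC across the trial", {
  fx <- paper_fixture()
  f <- fit_linear(fx$adc["crude_protein", fx$growth$diet], fx$growth$sgr)
  expect_gt(f$slope, 0)
  expect_lt(f$p_slope, 0.05)
})

test_that("linear-plateau recovers noiseless two-segment data exactly", {
  x <- c(70, 73, 76, 78, 79, 80.5, 82, 84, 86, 90)
  y <- 2.46 - 0.25 * pmax(0, 80 - x)
  f <- fit_linear_plateau(x, y)
  expect_equal(f$breakpoint, 80, tolerance = 1e-6)
  expect_equal(f$slope, 0.25, tolerance = 1e-6)
  expect_equal(f$plateau, 2.46, tolerance = 1e-6)
  expect_lt(f$rss, 1e-12)
  expect_false(f$all_plateau)
})

test_that("constant response degenerates to a flagged flat fit", {
  x <- 1:8
  f <- fit_linear_plateau(x, rep(2.4, 8))
  expect_equal(f$slope, 0)
  expect_equal(f$plateau, 2.4)
  expect_equal(f$breakpoint, min(x))
  expect_true(f$all_plateau)
})

test_that("linear-plateau RSS never exceeds the best rising line (nesting)", {
  set.seed(11)
  for (i in 1:20) {
    x <- sort(runif(12, 0, 10))
    y <- 0.5 * x + rnorm(12, 0, 0.5)  # rising trend
    lp <- fit_linear_plateau(x, y)
    ln <- fit_linear(x, y)
    expect_lte(lp$rss, ln$rss + 1e-9)
  }
})

test_that("fits are invariant to shuffling point order", {
  set.seed(3)
  x <- runif(15, 70, 90)
  y <- 2.5 - 0.2 * pmax(0, 80 - x) + rnorm(15, 0, 0.05)
  f1 <- fit_linear_plateau(x, y)
  ord <- sample(15)
  f2 <- fit_linear_plateau(x[ord], y[ord])
  expect_equal(f1$breakpoint, f2$breakpoint, tolerance = 1e-10)
  expect_equal(f1$rss, f2$rss, tolerance = 1e-12)
})

test_that("breakpoint recovery: median error < 0.5 over 200 noisy replicates", {
  b_true <- 80; slope <- 0.25; plateau <- 2.46; sigma <- 0.03; n <- 30
  set.seed(20240325)
  est <- replicate(200, {
    x <- runif(n, 70, 90)
    y <- plateau - slope * pmax(0, b_true - x) + rnorm(n, 0, sigma)
    fit_linear_plateau(x, y)$breakpoint
  })
  expect_lt(median(abs(est - b_true)), 0.5)
})

test_that("prediction is continuous and piecewise linear", {
  x <- c(70, 74, 78, 79, 81, 83, 85, 88)
  y <- 2.46 - 0.25 * pmax(0, 80 - x)
  f <- fit_linear_plateau(x, y)
  expect_equal(predict(f, f$breakpoint), f$plateau, tolerance = 1e-9)
  expect_equal(predict(f, 1000), f$plateau)
  expect_equal(predict(f, 75), f$plateau - f$slope * (f$breakpoint - 75),
               tolerance = 1e-9)
  lf <- fit_linear(x, 2 * x + 1)
  expect_equal(predict(lf, c(0, 10)), c(1, 21), tolerance = 1e-9)
})

test_that("quadratic-plateau recovers its own noiseless data", {
  x <- seq(70, 90, length.out = 12)
  y <- 2.46 - 0.01 * pmax(0, 81 - x)^2
  f <- fit_quadratic_plateau(x, y)
  expect_equal(f$breakpoint, 81, tolerance = 1e-4)
  expect_equal(f$plateau, 2.46, tolerance = 1e-6)
  expect_equal(predict(f, 76), 2.46 - 0.01 * 25, tolerance = 1e-4)
})
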