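test_that("one-way ANOVA matches the two-group F = t^2 identity", {
  set.seed(5)
  x <- rnorm(3, 0, 1)
  y <- rnorm(3, 10, 1)
  av <- one_way_anova(c(x, y), rep(c("a", "b"), each = 3))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(av$f, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(av$p, tt$p.value, tolerance = 1e-10)
  expect_lt(av$p, 0.001)
})

test_that("identical constant groups are flagged degenerate, not an error", {
  av <- one_way_anova(rep(5, 9), rep(c("a", "b", "c"), each = 3))
  expect_true(av$degenerate)
  expect_true(is.na(av$f))
  d <- duncan_mrt(rep(5, 9), rep(c("a", "b", "c"), each = 3))
  expect_true(all(d$letters == "a"))
})

test_that("ANOVA p-values are uniform under the null", {
  set.seed(99)
  ps <- replicate(400, {
    one_way_anova(rnorm(30), rep(letters[1:10], each = 3))$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("groups with fewer than two observations are rejected", {
  expect_error(one_way_anova(c(1, 2, 3), c("a", "a", "b")), ">= 2")
  expect_error(one_way_anova(1:4, rep("a", 4)), "2 groups")
})

test_that("Duncan separates far-apart groups and merges tight ones", {
  set.seed(1)
  v <- c(rnorm(3, 0, 0.1), rnorm(3, 10, 0.1), rnorm(3, 20, 0.1))
  g <- rep(c("lo", "mid", "hi"), each = 3)
  d <- duncan_mrt(v, g)
  expect_equal(unname(d$letters[c("hi", "mid", "lo")]), c("a", "b", "c"))
  set.seed(2)
  v2 <- rnorm(9, 5, 0.05)
  d2 <- duncan_mrt(v2, g)
  expect_true(all(d2$letters == "a"))
})

test_that("with two groups Duncan is exactly the pooled t-test", {
  set.seed(123)
  for (i in 1:50) {
    delta <- runif(1, 0, 2)
    x <- rnorm(4, 0, 1)
    y <- rnorm(4, delta, 1)
    d <- duncan_mrt(c(x, y), rep(c("a", "b"), each = 4), alpha = 0.05)
    duncan_sig <- unname(d$letters[1] != d$letters[2])
    t_sig <- t.test(x, y, var.equal = TRUE)$p.value < 0.05
    expect_equal(duncan_sig, t_sig)
  }
})

test_that("Duncan letters are invariant to input order and location shifts", {
  set.seed(8)
  v <- c(rnorm(3, 0, 1), rnorm(3, 3, 1), rnorm(3, 6, 1), rnorm(3, 6.2, 1))
  g <- rep(c("a", "b", "c", "d"), each = 3)
  d1 <- duncan_mrt(v, g)
  ord <- sample(length(v))
  d2 <- duncan_mrt(v[ord], g[ord])
  expect_equal(d1$letters, d2$letters)
  d3 <- duncan_mrt(v + 100, g)
  expect_equal(d1$letters, d3$letters)
})

test_that("type-I family behaviour with 10 equal groups is recorded", {
  set.seed(77)
  frac <- mean(replicate(60, {
    d <- duncan_mrt(rnorm(30), rep(letters[1:10], each = 3))
    length(unique(d$letters)) > 1
  }))
  # documented characteristic of the step-down procedure, not a fixed value
  expect_gte(frac, 0)
  expect_lte(frac, 1)
})

test_that("Levene's median-centered test runs and detects heteroscedasticity", {
  set.seed(31)
  v <- c(rnorm(20, 0, 1), rnorm(20, 0, 6))
  g <- rep(c("a", "b"), each = 20)
  lt <- levene_test(v, g)
  expect_lt(lt$p, 0.05)
})

test_that("relative expression normalizes to references and the calibrator", {
  # target equals the single reference everywhere -> RQ 1
  rq <- relative_expression(c(20, 20), matrix(c(20, 20), ncol = 1),
                            c("cal", "trt"), calibrator = "cal")
  expect_equal(rq, c(1, 1))
  # one cycle lower than the calibrator at efficiency 2 -> one doubling
  rq2 <- relative_expression(c(24, 23), matrix(c(18, 18), ncol = 1),
                             c("cal", "trt"), calibrator = "cal")
  expect_equal(rq2, c(1, 2))
  # two references: hand-computed geometric-mean normalization
  ct_t <- c(24, 22.5)
  refs <- rbind(c(18, 20), c(17.5, 20.5))
  raw <- 2^(-ct_t) / sqrt(2^(-refs[, 1]) * 2^(-refs[, 2]))
  expected <- raw / raw[1]
  rq3 <- relative_expression(ct_t, refs, c("cal", "trt"), calibrator = "cal")
  expect_equal(rq3, expected, tolerance = 1e-12)
  expect_error(relative_expression(c(24), matrix(18, 1, 1), "a",
                                   efficiency = 2.5), "efficiency")
  expect_error(relative_expression(c(50), matrix(18, 1, 1), "a"), "Ct values")
})
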