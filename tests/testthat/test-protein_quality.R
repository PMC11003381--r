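fx <- paper_fixture()
req <- gibel_requirements()

test_that("EAAI reproduces the published index for recomputable diets", {
  expect_equal(round(eaai(fx$aa$Control, req)$value, 2), 95.83)
  expect_equal(round(eaai(fx$aa$A33, req)$value, 2), 97.07)
  expect_equal(round(eaai(fx$aa$C100, req)$value, 2), 97.26)
  # a diet exactly at the requirement pattern scores 100
  at_req <- aa_vector(req$requirements)
  expect_equal(eaai(at_req, req)$value, 100)
  expect_error(eaai(aa_vector(c(lysine = 2)), req), "missing EAA")
})

test_that("DEAAI reproduces the published index for recomputable diets", {
  d <- function(diet) deaai(fx$aa[[diet]], fx$adc[eaa_names(), diet], req)
  expect_equal(round(d("Control")$value, 2), 79.07)
  expect_equal(round(d("A33")$value, 2), 82.39)
  expect_equal(round(d("C100")$value, 2), 81.66)
  expect_error(deaai(fx$aa$Control, c(lysine = 84), req), "no ADC")
})

test_that("DEAAI reduces to EAAI when every ADC is 100", {
  full <- stats::setNames(rep(100, 9), eaa_names())
  for (diet in c("Control", "B67", "C33")) {
    expect_equal(deaai(fx$aa[[diet]], full, req)$value,
                 eaai(fx$aa[[diet]], req)$value, tolerance = 1e-12)
  }
})

test_that("EAAI is scale-invariant and DEAAI monotone in each ADC", {
  v <- fx$aa$Control
  for (c in c(0.5, 3, 10)) {
    scaled_req <- requirement_set(req$requirements * c)
    expect_equal(eaai(aa_vector(unclass(v) * c), scaled_req)$value,
                 eaai(v, req)$value, tolerance = 1e-10)
  }
  base_adc <- fx$adc[eaa_names(), "Control"]
  base <- deaai(v, base_adc, req)$value
  for (aa in eaa_names()) {
    up <- base_adc
    up[aa] <- up[aa] + 5
    expect_gt(deaai(v, up, req)$value, base)
  }
})

test_that("DEAAI never exceeds EAAI when all ADCs are at most 100", {
  set.seed(42)
  for (i in 1:20) {
    contents <- stats::setNames(runif(9, 0.3, 4), eaa_names())
    adcs <- stats::setNames(runif(9, 40, 100), eaa_names())
    e <- eaai(aa_vector(contents), req)$value
    d <- deaai(aa_vector(contents), adcs, req)$value
    expect_lte(d, e)
  }
})

test_that("log-space geometric mean agrees with the direct product form", {
  set.seed(7)
  for (i in 1:25) {
    contents <- stats::setNames(runif(9, 0.1, 5), eaa_names())
    direct <- 100 * prod(contents / req$requirements)^(1 / 9)
    expect_equal(eaai(aa_vector(contents), req)$value, direct,
                 tolerance = 1e-12)
  }
})

test_that("the DEAA ratio profile is consistent with the index and homogeneous", {
  adc_ctrl <- fx$adc[eaa_names(), "Control"]
  dig <- digestible_content(unclass(fx$aa$Control)[eaa_names()], adc_ctrl)
  # reference = digestible contents themselves -> all ratios 1
  self <- deaa_ratio_profile(fx$aa$Control, adc_ctrl, aa_vector(dig))
  expect_equal(unname(self), rep(1, 9), tolerance = 1e-12)
  # reference = requirements -> geometric mean recovers the DEAAI
  prof <- deaa_ratio_profile(fx$aa$Control, adc_ctrl,
                             aa_vector(req$requirements))
  expect_equal(100 * exp(mean(log(prof))),
               deaai(fx$aa$Control, adc_ctrl, req)$value, tolerance = 1e-10)
  # doubling the reference halves every ratio
  prof2 <- deaa_ratio_profile(fx$aa$Control, adc_ctrl,
                              aa_vector(req$requirements * 2))
  expect_equal(unname(prof2), unname(prof) / 2, tolerance = 1e-12)
})

test_that("the trial quality table reproduces at least 8 of 10 printed DEAAI cells", {
  q <- quality_index_table(fx$aa, fx$adc, req)
  printed <- fx$indices["DEAAI", q$diet]
  hits <- sum(abs(q$deaai - printed) <= 0.05)
  expect_gte(hits, 8)
})
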