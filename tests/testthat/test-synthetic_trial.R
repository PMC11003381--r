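noiseless_cfg <- function(...) {
  trial_config(sgr_sd = 0, assay_cv = 0, ct_sd = 0, ibw_sd = 0,
               survival_prob = 1, ...)
}

test_that("identical seeds give identical datasets; different seeds differ", {
  cfg <- trial_config()
  t1 <- generate_trial(cfg, seed = 42)
  t2 <- generate_trial(cfg, seed = 42)
  expect_identical(t1, t2)
  t3 <- generate_trial(cfg, seed = 43)
  expect_false(identical(t1$adc_assays$feces_conc, t3$adc_assays$feces_conc))
  expect_false(identical(
    vapply(t1$cage_records, function(r) r$fbw, numeric(1)),
    vapply(t3$cage_records, function(r) r$fbw, numeric(1))))
})

test_that("noiseless mass balance: pipeline ADCs equal the configured truth", {
  cfg <- noiseless_cfg()
  tr <- generate_trial(cfg, seed = 1)
  rec <- recover_adc(tr$adc_assays)
  rows <- intersect(rownames(rec), rownames(cfg$true_adc))
  expect_gt(length(rows), 10)
  expect_lt(max(abs(rec[rows, cfg$diets] - cfg$true_adc[rows, cfg$diets])),
            1e-9)
})

test_that("noiseless pipeline DEAAI equals the generator truth", {
  cfg <- noiseless_cfg()
  tr <- generate_trial(cfg, seed = 2)
  rec <- recover_adc(tr$adc_assays)
  q <- quality_index_table(tr$aa, rec, cfg$requirements)
  expect_lt(max(abs(q$deaai - unname(tr$truth$deaai[q$diet]))), 1e-9)
  expect_lt(max(abs(q$eaai - unname(tr$truth$eaai[q$diet]))), 1e-9)
})

test_that("noiseless cage SGR sits exactly on the configured growth curve", {
  cfg <- noiseless_cfg()
  tr <- generate_trial(cfg, seed = 3)
  sgr <- vapply(tr$cage_records, specific_growth_rate, numeric(1))
  diets <- vapply(tr$cage_records, function(r) r$diet, character(1))
  expect_equal(as.numeric(tapply(sgr, diets, mean)[cfg$diets]),
               unname(tr$truth$sgr_expected), tolerance = 1e-9)
})

test_that("target_deaai rescales ADCs so true DEAAI hits the target exactly", {
  targets <- stats::setNames(seq(76, 85, length.out = 10), trial_diet_names())
  cfg <- noiseless_cfg(target_deaai = targets)
  expect_equal(unname(cfg$true_deaai), unname(targets), tolerance = 1e-9)
})

test_that("end-to-end breakpoint recovery succeeds in >= 90% of 200 seeds", {
  targets <- stats::setNames(seq(76, 85, length.out = 10), trial_diet_names())
  cfg <- trial_config(target_deaai = targets, sgr_sd = 0.02,
                      assay_cv = 0, ct_sd = 0)
  hits <- vapply(1:200, function(s) {
    tr <- generate_trial(cfg, seed = s)
    sgr <- vapply(tr$cage_records, specific_growth_rate, numeric(1))
    diets <- vapply(tr$cage_records, function(r) r$diet, character(1))
    y <- tapply(sgr, diets, mean)[cfg$diets]
    f <- fit_linear_plateau(unname(cfg$true_deaai), unname(y))
    abs(f$breakpoint - cfg$breakpoint) <= 0.5
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("a breakpoint outside the generated DEAAI range is rejected", {
  expect_error(trial_config(breakpoint = 120), "outside")
})

test_that("the full analysis reproduces ground truth on a noiseless trial", {
  cfg <- noiseless_cfg()
  tr <- generate_trial(cfg, seed = 5)
  rep <- run_full_analysis(tr, requirements = cfg$requirements)
  expect_equal(rep$fits$sgr_vs_deaai$breakpoint, cfg$breakpoint,
               tolerance = 1e-4)
  expect_equal(rep$fits$sgr_vs_deaai$plateau, cfg$plateau_sgr,
               tolerance = 1e-6)
  expect_equal(rep$fits$sgr_vs_deaai$slope, cfg$rise_slope, tolerance = 1e-4)
})

test_that("the qPCR table recovers the configured expression shifts", {
  cfg <- noiseless_cfg()
  tr <- generate_trial(cfg, seed = 6)
  rq <- relative_expression(tr$ct$ct_target, tr$ct$ct_reference, tr$ct$diet,
                            calibrator = "Control", efficiency = 2)
  got <- as.numeric(tapply(rq, tr$ct$diet, mean)[cfg$diets])
  expected <- 2^(tr$truth$log2fc - tr$truth$log2fc["Control"])
  expect_equal(got, unname(expected), tolerance = 1e-9)
})
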