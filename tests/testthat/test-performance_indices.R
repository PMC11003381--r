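ctrl_cage <- function(...) {
  cage_record(diet = "Control", n_initial = 70, n_final = 70, ibw = 15.21,
              fbw = 59.05, feed_dm = 63, days = 56, basis = "fish", ...)
}

test_that("survival rate is the final/initial count ratio", {
  r <- cage_record("d", 70, 70, 10, 20, 50)
  expect_equal(survival_rate(r), 100)
  r2 <- cage_record("d", 70, 67, 10, 20, 50)
  expect_equal(round(survival_rate(r2), 2), 95.71)
  r3 <- cage_record("d", 70, 0, 10, 20, 50)
  expect_equal(survival_rate(r3), 0)
  expect_error(cage_record("d", 70, 71, 10, 20, 50), "n_final")
})

test_that("SGR matches printed control and B100 rows and the closed form", {
  expect_equal(round(specific_growth_rate(ctrl_cage()), 2), 2.42)
  b100 <- cage_record("B100", 70, 70, 15.15, 61.81, 60, days = 56)
  expect_equal(round(specific_growth_rate(b100), 2), 2.51)
  dbl <- cage_record("d", 10, 10, 10, 20, 5, days = 56)
  expect_equal(specific_growth_rate(dbl), 100 * log(2) / 56, tolerance = 1e-12)
  same <- cage_record("d", 10, 10, 15, 15, 5)
  expect_equal(specific_growth_rate(same), 0)
})

test_that("SGR is invariant to rescaling both weights", {
  base <- cage_record("d", 10, 10, 12.3, 45.6, 50, days = 42)
  for (c in c(0.1, 2, 70)) {
    scaled <- cage_record("d", 10, 10, 12.3 * c, 45.6 * c, 50, days = 42)
    expect_equal(specific_growth_rate(scaled), specific_growth_rate(base),
                 tolerance = 1e-12)
  }
})

test_that("feeding rate inverts the printed control value and is linear in feed", {
  expect_equal(round(feeding_rate(ctrl_cage()), 2), 3.03)
  zero <- cage_record("d", 10, 10, 10, 20, 0)
  expect_equal(feeding_rate(zero), 0)
  r1 <- cage_record("d", 10, 10, 10, 20, 30)
  r2 <- cage_record("d", 10, 10, 10, 20, 60)
  expect_equal(feeding_rate(r2), 2 * feeding_rate(r1))
})

test_that("feed efficiency credits dead-fish weight", {
  r <- cage_record("d", 10, 10, 50, 100, feed_dm = 100)
  expect_equal(feed_efficiency(r), 50)
  rd <- cage_record("d", 10, 9, 50, 100, feed_dm = 100, dead_weight = 10)
  expect_equal(feed_efficiency(rd), 60)
  flat <- cage_record("d", 10, 10, 50, 50, feed_dm = 100)
  expect_equal(feed_efficiency(flat), 0)
})

test_that("PER and PRE are gain and protein deposition over protein intake", {
  r <- cage_record("d", 10, 10, 10, 50, feed_dm = 100, protein_intake = 20,
                   body_protein_gain = 7)
  expect_equal(protein_efficiency_ratio(r), 2.0)
  expect_equal(protein_retention(r), 35.0)
  # spreadsheet oracle: protein intake from feed x diet CP, gain from
  # body-composition delta
  feed <- 120; cp <- 34.2
  ibw <- 15; fbw <- 60; bp_i <- 0.16; bp_f <- 0.17
  rec <- cage_record("d", 10, 10, ibw, fbw, feed,
                     protein_intake = feed * cp / 100,
                     body_protein_gain = fbw * bp_f - ibw * bp_i)
  expect_equal(protein_efficiency_ratio(rec), (60 - 15) / (120 * 0.342),
               tolerance = 1e-12)
  expect_equal(protein_retention(rec),
               100 * (60 * 0.17 - 15 * 0.16) / (120 * 0.342),
               tolerance = 1e-12)
})

test_that("FE and PER scale inversely with intake", {
  r1 <- cage_record("d", 10, 10, 10, 50, feed_dm = 100, protein_intake = 30)
  r2 <- cage_record("d", 10, 10, 10, 50, feed_dm = 200, protein_intake = 60)
  expect_equal(feed_efficiency(r2), feed_efficiency(r1) / 2)
  expect_equal(protein_efficiency_ratio(r2), protein_efficiency_ratio(r1) / 2)
})

test_that("morphometric indices follow their definitions", {
  m <- fish_morphometrics(100, 10, visceral_weight = 11.57,
                          liver_weight = 2.87)
  expect_equal(condition_factor(m), 10.0)
  expect_equal(viscerosomatic_index(m), 11.57)
  expect_equal(hepatosomatic_index(m), 2.87)
  expect_error(fish_morphometrics(100, 10, visceral_weight = 120),
               "visceral_weight")
  expect_error(fish_morphometrics(100, 10, visceral_weight = 12,
                                  liver_weight = 13), "liver_weight")
})

test_that("summarize_performance aggregates by diet with SE over cages", {
  recs <- list(
    cage_record("d1", 70, 70, 15, 60, 60, protein_intake = 20,
                body_protein_gain = 7),
    cage_record("d1", 70, 68, 15, 58, 61, protein_intake = 21,
                body_protein_gain = 7),
    cage_record("d2", 70, 70, 15, 50, 60, protein_intake = 20,
                body_protein_gain = 6)
  )
  s <- summarize_performance(recs)
  sgr <- s[s$index == "sgr" & s$diet == "d1", ]
  expect_equal(sgr$n, 2L)
  vals <- c(specific_growth_rate(recs[[1]]), specific_growth_rate(recs[[2]]))
  expect_equal(sgr$mean, mean(vals))
  expect_equal(sgr$se, stats::sd(vals) / sqrt(2))
})
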