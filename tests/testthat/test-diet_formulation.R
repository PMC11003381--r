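make_ing <- function(name, cp, aa = aa_vector(numeric(0))) {
  ingredient_profile(name, crude_protein = cp, aa = aa)
}

test_that("equivalence_factor is the CP ratio of fishmeal to the blend", {
  fm <- make_ing("fm", 65)
  ings <- list(a = make_ing("a", 65), b = make_ing("b", 65))
  bl <- blend_spec(c(a = 1, b = 3))
  expect_equal(equivalence_factor(fm, bl, ings), 1.0)
  ings2 <- list(a = make_ing("a", 50), b = make_ing("b", 80))
  expect_equal(equivalence_factor(fm, blend_spec(c(a = 1, b = 1)), ings2), 1.0)
  # blend-weighted CP 71.27 gives the back-derived factor of blend A
  ings3 <- list(a = make_ing("a", 71.27))
  expect_equal(equivalence_factor(fm, blend_spec(c(a = 1)), ings3),
               65 / 71.27, tolerance = 1e-12)
  expect_equal(round(65 / 71.27, 3), 0.912)
  expect_error(equivalence_factor(fm, blend_spec(c(zz = 1)), ings),
               "no ingredient profile")
})

test_that("blend_inclusions reproduces printed inclusion cells", {
  blends <- trial_blends()
  inc <- blend_inclusions(15, 1.0, blends$A, 0.912)
  expect_equal(unname(inc["cap"]), 9.12)
  expect_equal(unname(inc["t_molitor_meal"]), 1.14)
  expect_equal(unname(inc["fish_meal"]), 0)
  inc67 <- blend_inclusions(15, 2 / 3, blends$B, 0.96)
  expect_equal(unname(inc67["cap"]), 4.80)
  expect_equal(unname(inc67["fish_meal"]), 5.00)
  inc0 <- blend_inclusions(15, 0, blends$A, 0.912)
  expect_true(all(inc0[setdiff(names(inc0), "fish_meal")] == 0))
  expect_equal(unname(inc0["fish_meal"]), 15)
  expect_error(blend_inclusions(15, 1.5, blends$A, 0.912), "fraction")
})

test_that("blend mass is conserved and monotone in the replacement fraction", {
  bl <- trial_blends()$C
  for (f in c(0, 0.2, 1 / 3, 0.5, 2 / 3, 1)) {
    inc <- blend_inclusions(15, f, bl, 1.008)
    expect_equal(sum(inc[bl$ingredients]), 15 * f * 1.008, tolerance = 1e-12)
  }
  fracs <- seq(0, 1, by = 0.1)
  mat <- sapply(fracs, function(f)
    blend_inclusions(15, f, bl, 1.008)[bl$ingredients])
  expect_true(all(apply(mat, 1, function(r) all(diff(r) >= 0))))
})

test_that("the whole formulation table reproduces every printed blend cell", {
  fx <- paper_fixture()
  inc <- formulate_trial_diets()
  rows <- c("t_molitor_meal", "chlorella_meal", "cap", "cpc", "fish_meal")
  expect_equal(round(inc[rows, colnames(inc)], 2),
               fx$inclusions[rows, colnames(inc)])
})

test_that("diet_aa mixes profiles linearly", {
  a <- make_ing("a", 50, aa_vector(c(lysine = 2.0, proline = 1.0)))
  b <- make_ing("b", 50, aa_vector(c(lysine = 4.0)))
  ings <- list(a = a, b = b)
  one <- diet_aa(c(a = 100), ings)
  expect_equal(unname(one["lysine"]), 2.0)
  mix <- diet_aa(c(a = 50, b = 50), ings)
  expect_equal(unname(mix["lysine"]), 3.0)
  expect_equal(unname(mix["proline"]), 0.5)
  expect_error(diet_aa(c(a = 50, zz = 50), ings), "zz")
  # brute-force summation oracle on a synthetic 3-ingredient diet
  ings3 <- synthetic_ingredients()[c("fish_meal", "cap", "soybean_meal")]
  inc3 <- c(fish_meal = 10, cap = 5, soybean_meal = 25)
  got <- diet_aa(inc3, ings3)
  for (aa in aa_names()) {
    manual <- sum(vapply(names(inc3), function(i)
      inc3[[i]] / 100 * unclass(ings3[[i]]$aa)[aa], numeric(1)))
    expect_equal(unname(got[aa]), manual, tolerance = 1e-12)
  }
})

test_that("close_formulation sets the filler to balance to 100", {
  inc <- c(a = 60, b = 35.62)
  closed <- close_formulation(inc, "filler")
  expect_equal(unname(closed["filler"]), 4.38)
  expect_equal(sum(closed), 100)
  expect_equal(unname(close_formulation(c(a = 100), "f")["f"]), 0)
  expect_error(close_formulation(c(a = 101), "f"), "infeasible")
})
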