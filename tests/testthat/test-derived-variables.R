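test_that("dimensionless index is the VTI ratio with missing propagation", {
  expect_equal(dimensionless_index(20, 80), 0.25)
  expect_true(is.na(dimensionless_index(NA, 80)))
  expect_true(is.na(dimensionless_index(20, NA)))
  expect_equal(dimensionless_index(30, 30), 1)
  withr::with_seed(1, {
    x <- runif(50, 0.1, 50)
    expect_equal(dimensionless_index(x, x), rep(1, 50))
  })
})

test_that("any mitral calcification combines MAC and mitral stenosis", {
  expect_true(any_mitral_calcification("present", "none"))
  expect_false(any_mitral_calcification("none", "none"))
  expect_true(any_mitral_calcification("none", "mild"))
  expect_true(any_mitral_calcification("present", "severe"))
  expect_false(any_mitral_calcification(NA, "none"))
})

dd <- function(...) diastolic_function(tibble::tibble(...))$level

test_that("normal-EF arm counts the four guideline criteria", {
  # all four negative
  expect_equal(dd(lvef = 60, e_over_e_prime = 10, septal_e_prime = 8,
                  lateral_e_prime = 12, tr_vmax = 2.0, lavi = 30),
               "normal")
  # three of four positive
  expect_equal(dd(lvef = 60, e_over_e_prime = 16, septal_e_prime = 5,
                  lateral_e_prime = 12, tr_vmax = 3.2, lavi = 30),
               "dysfunction")
  # exactly half positive
  expect_equal(dd(lvef = 60, e_over_e_prime = 16, septal_e_prime = 5,
                  lateral_e_prime = 12, tr_vmax = 2.0, lavi = 30),
               "indeterminate")
  # fewer than two evaluable
  expect_equal(dd(lvef = 60, e_over_e_prime = 16, septal_e_prime = NA,
                  lateral_e_prime = NA, tr_vmax = NA, lavi = NA),
               "not assessable")
  expect_equal(dd(lvef = NA, e_over_e_prime = 16), "not assessable")
})

test_that("reduced-EF arm grades by mitral inflow with criterion back-up", {
  expect_equal(dd(lvef = 40, e_over_a = 0.6, mitral_e = 40), "grade I")
  expect_equal(dd(lvef = 40, e_over_a = 2.5, mitral_e = 120), "grade III")
  # intermediate band resolved by the three remaining criteria
  expect_equal(dd(lvef = 40, e_over_a = 1.2, mitral_e = 80,
                  e_over_e_prime = 16, tr_vmax = 3.0, lavi = 40),
               "grade II")
  expect_equal(dd(lvef = 40, e_over_a = 1.2, mitral_e = 80,
                  e_over_e_prime = 10, tr_vmax = 2.0, lavi = 30),
               "grade I")
  expect_equal(dd(lvef = 40, e_over_a = 1.2, mitral_e = 80,
                  e_over_e_prime = 16, tr_vmax = 2.0, lavi = NA),
               "indeterminate")
  expect_equal(dd(lvef = 40, e_over_a = NA), "not assessable")
})

test_that("flipping one criterion positive never moves towards normal", {
  rank <- c(normal = 1, indeterminate = 2, dysfunction = 3,
            "not assessable" = NA, "grade I" = NA, "grade II" = NA,
            "grade III" = NA)
  withr::with_seed(7, {
    for (i in 1:100) {
      base <- tibble::tibble(
        lvef = 60,
        e_over_e_prime = sample(c(10, 16, NA), 1),
        septal_e_prime = sample(c(8, 5, NA), 1),
        lateral_e_prime = sample(c(12, 8, NA), 1),
        tr_vmax = sample(c(2.0, 3.2, NA), 1),
        lavi = sample(c(30, 40, NA), 1))
      before <- diastolic_function(base)$level
      flip <- base
      # flip one currently-negative criterion to positive
      if (!is.na(flip$tr_vmax) && flip$tr_vmax <= 2.8) {
        flip$tr_vmax <- 3.5
      } else if (!is.na(flip$lavi) && flip$lavi <= 34) {
        flip$lavi <- 45
      } else if (!is.na(flip$e_over_e_prime) && flip$e_over_e_prime <= 14) {
        flip$e_over_e_prime <- 18
      } else next
      after <- diastolic_function(flip)$level
      if (!is.na(rank[before]) && !is.na(rank[after])) {
        expect_gte(rank[after], rank[before])
      }
    }
  })
})

test_that("introducing a missing input never flips normal and dysfunction", {
  withr::with_seed(13, {
    for (i in 1:100) {
      base <- tibble::tibble(
        lvef = 60,
        e_over_e_prime = sample(c(10, 16), 1),
        septal_e_prime = sample(c(8, 5), 1),
        lateral_e_prime = sample(c(12, 8), 1),
        tr_vmax = sample(c(2.0, 3.2), 1),
        lavi = sample(c(30, 40), 1))
      before <- diastolic_function(base)$level
      drop_field <- sample(c("e_over_e_prime", "tr_vmax", "lavi"), 1)
      gap <- base
      gap[[drop_field]] <- NA
      after <- diastolic_function(gap)$level
      if (before == "normal") expect_false(after == "dysfunction")
      if (before == "dysfunction") expect_false(after == "normal")
    }
  })
})
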