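test_that("heart-rate ranges are averaged and extremes excluded", {
  hr <- clean_heart_rate(c("120–180", "120-180", "120 to 180", "72",
                           "250", "fast", ""))
  expect_equal(hr$value, c(150, 150, 150, 72, NA, NA, NA))
  expect_equal(hr$provenance[1:4],
               c("range_mean", "range_mean", "range_mean", "direct"))
  expect_equal(hr$recode_reason[5], "out_of_range")
  expect_equal(hr$recode_reason[6], "unparseable")
  expect_true(is.na(hr$recode_reason[7]))
})

test_that("range mean equals the mean of the cleaned endpoints (property)", {
  withr::with_seed(42, {
    for (i in 1:200) {
      a <- round(runif(1, 0, 200))
      b <- round(runif(1, 0, 200))
      raw <- paste0(a, sample(c("-", "–", " to "), 1), b)
      got <- clean_heart_rate(raw)
      if (mean(c(a, b)) <= 200) {
        expect_equal(got$value, mean(c(a, b)))
      } else {
        expect_true(is.na(got$value))
        expect_equal(got$recode_reason, "out_of_range")
      }
    }
  })
})

test_that("heart-rate cleaning is idempotent on clean values", {
  once <- clean_heart_rate(c("150", "72"))
  twice <- clean_heart_rate(as.character(once$value))
  expect_equal(twice$value, once$value)
})

test_that("BMI handles units, transposition and plausibility bounds", {
  b <- compute_bmi(c("1.8", "80", "1.5", "180", ""),
                   c("80", "1.8", "180", "75", "70"))
  expect_equal(round(b$bmi[1], 2), 24.69)
  # transposed pair is swapped back and flagged
  expect_true(b$transposed[2])
  expect_equal(round(b$bmi[2], 2), 24.69)
  expect_equal(b$recode_reason[2], "transposed_corrected")
  # BMI 80 exceeds the upper plausibility bound
  expect_true(is.na(b$bmi[3]))
  expect_equal(b$recode_reason[3], "out_of_range")
  # height in centimetres
  expect_equal(round(b$bmi[4], 2), round(75 / 1.8^2, 2))
  expect_true(is.na(b$bmi[5]))
})

test_that("BMI bounds are closed at both thresholds", {
  # exactly 70 and exactly 14 are excluded, just inside is kept
  b70 <- compute_bmi("2", as.character(70 * 4))
  expect_true(is.na(b70$bmi))
  b14 <- compute_bmi("2", as.character(14 * 4))
  expect_true(is.na(b14$bmi))
  b_ok <- compute_bmi("2", as.character(69.9 * 4))
  expect_equal(b_ok$bmi, 69.9)
})

test_that("non-positive values are recoded with a reason", {
  expect_equal(clean_positive("-1.1", "ivsd")$recode_reason, "nonpositive")
  expect_equal(clean_positive("3.4", "aov_vmax")$value, 3.4)
  expect_equal(clean_positive("0", "lvpwd")$recode_reason, "nonpositive")
  expect_equal(clean_positive("??", "ivsd")$recode_reason, "unparseable")
  expect_true(is.na(clean_positive("", "ivsd")$recode_reason))
  expect_error(clean_positive("1", "not_a_field"), "not listed")
})

test_that("LVEF follows the method hierarchy", {
  expect_equal(select_lvef(c(lvef_teichholz = 55, lvef_biplane = 48))$value,
               48)
  expect_equal(select_lvef(c(lvef_mmode = 60))$value, 60)
  expect_true(is.na(select_lvef(list())$value))
  expect_error(select_lvef(c(simpson = 50)), "Unknown LVEF method")
  # invariant to inserting lower-priority methods
  base <- select_lvef(c(lvef_a4c = 52))$value
  more <- select_lvef(c(lvef_a4c = 52, lvef_teichholz = 61,
                        lvef_mmode = 64))$value
  expect_equal(more, base)
})

test_that("LVEF hierarchy works column-wise over a data frame", {
  df <- tibble::tibble(lvef_biplane = c(NA, 48, NA),
                       lvef_teichholz = c(55, 61, NA),
                       lvef_mmode = c(70, 70, NA))
  expect_equal(select_lvef(df)$value, c(55, 48, NA))
  expect_error(select_lvef(tibble::tibble(bogus = 1)), "Unknown")
})

test_that("RVSP prefers the numeric field and extracts the last mmHg number", {
  expect_equal(extract_rvsp("35", "RVSP 45 mmHg")$value, 35)
  r <- extract_rvsp("", "estimated RVSP of 42 mmHg plus RA pressure")
  expect_equal(r$value, 42)
  expect_equal(r$provenance, "text_extracted")
  expect_true(r$flagged)
  expect_true(is.na(extract_rvsp("", "RVSP could not be estimated")$value))
  # last anchored number wins when several are present
  expect_equal(extract_rvsp("", "RA 5 mmHg; RVSP estimated 40 mmHg")$value,
               40)
  expect_equal(extract_rvsp("", "gradient 38mmHg")$value, 38)
})
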