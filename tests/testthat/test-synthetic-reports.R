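test_that("invalid generator configurations are rejected by field name", {
  expect_error(generator_config(typo_rate = 1.2), "typo_rate")
  expect_error(generator_config(n_studies = 0), "n_studies")
  expect_error(generator_config(n_chunks = 0), "n_chunks")
  bank <- default_phrase_bank()
  bank$mac$present <- NULL
  expect_error(generator_config(phrase_bank = bank), "mac")
})

test_that("generation is deterministic given config and seed", {
  cfg <- generator_config(n_studies = 40, seed = 21)
  a <- simulate_echo_export(cfg)
  b <- simulate_echo_export(cfg)
  expect_identical(a$chunks, b$chunks)
  expect_identical(a$truth, b$truth)
  expect_identical(a$log, b$log)
  c2 <- simulate_echo_export(generator_config(n_studies = 40, seed = 22))
  expect_false(identical(a$chunks, c2$chunks))
})

test_that("chunks concatenate to n_studies rows and cycle alias profiles", {
  ex <- simulate_echo_export(quiet_config(n = 25, seed = 2, n_chunks = 3))
  expect_length(ex$chunks, 3)
  expect_equal(sum(vapply(ex$chunks, nrow, integer(1))), 25)
  expect_true("NHI" %in% names(ex$chunks[[1]]))       # profile v1
  expect_true("HR (bpm)" %in% names(ex$chunks[[2]]))  # profile v2
})

test_that("no-corruption exports classify back to ground truth exactly", {
  rt <- roundtrip(quiet_config(n = 60, seed = 10))
  expect_true(all(rt$val$results$agreement == 100))
  expect_true(all(rt$val$results$kappa == 1))
})

test_that("repeat studies get strictly later dates for the same patient", {
  ex <- simulate_echo_export(quiet_config(n = 80, seed = 4,
                                          repeat_study_rate = 0.3))
  by_pat <- split(ex$truth$study_date, ex$truth$nhi)
  reps <- by_pat[lengths(by_pat) > 1]
  expect_gt(length(reps), 0)
  for (d in reps) expect_true(all(diff(sort(d)) > 0))
  # distinct dates within patient make the study key unique
  expect_false(any(duplicated(ex$truth[c("nhi", "study_date")])))
})

test_that("ground truth records the realised transposition count", {
  cfg <- quiet_config(n = 400, seed = 6, transposition_rate = 0.05)
  ex <- simulate_echo_export(cfg)
  raw <- stitch_chunks(ex)$data
  h <- as.numeric(raw$height)
  w <- as.numeric(raw$weight)
  # with metre-unit heights, a stored height above the stored weight can
  # only arise from a swap
  expect_equal(sum(ex$truth$corrupt_transposed), sum(h > w))
  expect_equal(sum(ex$truth$corrupt_transposed),
               sum(ex$log$type == "transposed"))
  expect_gt(sum(ex$truth$corrupt_transposed), 0)
})

test_that("corruption accounting matches direct inspection of the chunks", {
  cfg <- quiet_config(n = 400, seed = 8, range_rate = 0.2,
                      extreme_value_rate = 0.05)
  ex <- simulate_echo_export(cfg)
  raw <- stitch_chunks(ex)$data
  # heart-rate ranges
  n_range <- sum(grepl("^\\d+(–|-)\\d+$", raw$heart_rate))
  expect_equal(n_range, sum(ex$log$type == "hr_range"))
  expect_equal(n_range, sum(ex$truth$corrupt_hr_range))
  # heart rates above 200
  hr_num <- suppressWarnings(as.numeric(raw$heart_rate))
  expect_equal(sum(hr_num > 200, na.rm = TRUE),
               sum(ex$truth$corrupt_hr_extreme))
  # non-positive injections, field by field
  np <- ex$log[ex$log$type == "nonpositive", ]
  expect_equal(nrow(np), sum(!is.na(ex$truth$corrupt_nonpositive_field)))
  for (f in unique(np$field)) {
    vals <- suppressWarnings(as.numeric(raw[[f]]))
    expect_equal(sum(vals <= 0, na.rm = TRUE), sum(np$field == f),
                 label = f)
  }
})

test_that("typos avoid rule keywords so recovery still succeeds", {
  rt <- roundtrip(quiet_config(n = 80, seed = 12, typo_rate = 0.3))
  expect_gt(sum(rt$export$log$type == "typo"), 0)
  expect_true(all(rt$val$results$agreement == 100))
  expect_true(all(rt$val$results$kappa == 1))
})

test_that("written chunks re-read and stitch to the same rows", {
  dir <- withr::local_tempdir()
  ex <- simulate_echo_export(quiet_config(n = 12, seed = 3, n_chunks = 3))
  paths <- write_export_chunks(ex, dir)
  expect_length(paths, 3)
  expect_true(all(file.exists(paths)))
  header2 <- readLines(paths[2], n = 1)
  expect_true(grepl("HR (bpm)", header2, fixed = TRUE))
  st <- stitch_chunks(paths)
  expect_equal(nrow(st$data), 12)
  st_mem <- stitch_chunks(ex)
  expect_equal(st$data$aov_text, st_mem$data$aov_text)
})

test_that("an empty chunk is written as a header-only file", {
  dir <- withr::local_tempdir()
  ex <- simulate_echo_export(quiet_config(n = 1, seed = 3, n_chunks = 2))
  paths <- write_export_chunks(ex, dir)
  lines <- readLines(paths[2])
  expect_length(lines, 1)   # header only
  expect_equal(nrow(stitch_chunks(paths)$data), 1)
})
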