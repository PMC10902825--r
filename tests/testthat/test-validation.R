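test_that("study sampling is exact, unique and seeded", {
  df <- tibble::tibble(id = 1:500)
  s <- sample_studies(df, 100, seed = 3)
  expect_equal(nrow(s), 100)
  expect_false(any(duplicated(s$id)))
  expect_identical(s, sample_studies(df, 100, seed = 3))
  whole <- sample_studies(df, 500, seed = 1)
  expect_setequal(whole$id, df$id)
  expect_error(sample_studies(df, 501), "Cannot sample")
})

test_that("kappa matches hand-computed confusion matrices", {
  expect_equal(as.numeric(cohen_kappa(rep(c("a", "b"), 5),
                                      rep(c("a", "b"), 5))), 1)
  # 2x2 counts (45, 5, 5, 45): p_o = 0.9, p_e = 0.5
  a <- rep(c("x", "x", "y", "y"), c(45, 5, 5, 45))
  b <- rep(c("x", "y", "x", "y"), c(45, 5, 5, 45))
  expect_equal(as.numeric(cohen_kappa(a, b)), 0.8)
  # complete disagreement with balanced marginals
  a2 <- rep(c("x", "y"), c(50, 50))
  b2 <- rep(c("y", "x"), c(50, 50))
  expect_equal(as.numeric(cohen_kappa(a2, b2)), -1)
  expect_error(cohen_kappa(c("a", "b"), "a"), "equal length")
})

test_that("missing pairs are dropped and degenerate cases defined", {
  k <- cohen_kappa(c("a", NA, "b", "a"), c("a", "b", NA, "a"))
  expect_equal(attr(k, "n_dropped"), 2)
  expect_equal(as.numeric(k), 1)
  # single shared label: p_e = 1, perfect agreement -> 1
  expect_equal(as.numeric(cohen_kappa(rep("a", 5), rep("a", 5))), 1)
  expect_true(is.na(cohen_kappa(NA_character_, NA_character_)))
  # missing-as-category mode keeps the pairs
  k2 <- cohen_kappa(c("a", NA, "b"), c("a", NA, "b"),
                    na_as_category = TRUE)
  expect_equal(as.numeric(k2), 1)
})

test_that("kappa equals the brute-force oracle on random labelings", {
  withr::with_seed(101, {
    for (i in 1:200) {
      len <- sample(2:200, 1)
      k <- sample(2:6, 1)
      a <- sample(letters[1:k], len, replace = TRUE)
      b <- if (runif(1) < 0.3) a else sample(letters[1:k], len,
                                             replace = TRUE)
      expect_equal(as.numeric(cohen_kappa(a, b)), kappa_oracle(a, b),
                   tolerance = 1e-12)
    }
  })
})

test_that("kappa agrees with an independent library implementation", {
  skip_if_not_installed("e1071")
  withr::with_seed(55, {
    for (i in 1:20) {
      a <- sample(letters[1:3], 80, replace = TRUE)
      b <- sample(letters[1:3], 80, replace = TRUE)
      tab <- table(factor(a, levels = letters[1:3]),
                   factor(b, levels = letters[1:3]))
      expect_equal(as.numeric(cohen_kappa(a, b)),
                   e1071::classAgreement(tab)$kappa, tolerance = 1e-10)
    }
  })
})

test_that("kappa never exceeds observed agreement and is permutation invariant", {
  withr::with_seed(77, {
    for (i in 1:50) {
      a <- sample(c("u", "v", "w"), 60, replace = TRUE)
      b <- sample(c("u", "v", "w"), 60, replace = TRUE)
      po <- mean(a == b)
      expect_lte(as.numeric(cohen_kappa(a, b)), po + 1e-12)
      perm <- sample(60)
      expect_equal(as.numeric(cohen_kappa(a[perm], b[perm])),
                   as.numeric(cohen_kappa(a, b)), tolerance = 1e-12)
    }
  })
})

test_that("weighted kappa reduces to unweighted for two categories", {
  withr::with_seed(5, {
    a <- sample(c("lo", "hi"), 100, replace = TRUE)
    b <- sample(c("lo", "hi"), 100, replace = TRUE)
    expect_equal(as.numeric(cohen_kappa(a, b, weights = "linear")),
                 as.numeric(cohen_kappa(a, b)), tolerance = 1e-12)
    expect_equal(as.numeric(cohen_kappa(a, b, weights = "quadratic")),
                 as.numeric(cohen_kappa(a, b)), tolerance = 1e-12)
  })
})

test_that("identity validation reports full agreement everywhere", {
  rt <- roundtrip(quiet_config(n = 40, seed = 14))
  self <- validate_extraction(rt$run$data, rt$run$data, n = 40, seed = 2)
  expect_true(all(self$results$agreement == 100))
  expect_true(all(self$results$kappa == 1))
  expect_equal(self$indications_mean_kappa, 1)
})

test_that("a known label-flip rate shows up as the expected disagreement", {
  rt <- roundtrip(quiet_config(n = 400, seed = 15))
  gold <- rt$export$truth
  withr::with_seed(99, {
    flip <- runif(nrow(gold)) < 0.05
    pool <- severity_levels()
    gold$aortic_regurgitation[flip] <- vapply(
      gold$aortic_regurgitation[flip],
      function(x) sample(setdiff(pool, x), 1), character(1))
  })
  val <- validate_extraction(rt$run$data, gold, n = 400, seed = 4,
                             lookup = rt$run$lookup)
  ar <- val$results[val$results$variable == "aortic_regurgitation", ]
  expect_equal(ar$agreement / 100, 1 - mean(flip), tolerance = 0.03)
  other <- val$results[val$results$variable == "mitral_regurgitation", ]
  expect_equal(other$agreement, 100)
})

test_that("validation demands the requested variables", {
  rt <- roundtrip(quiet_config(n = 10, seed = 16))
  expect_error(
    validate_extraction(rt$run$data, rt$export$truth,
                        variables = "nonexistent_thing",
                        n = 5, lookup = rt$run$lookup),
    "nonexistent_thing")
})

test_that("validation summaries and plot have the expected shape", {
  rt <- roundtrip(quiet_config(n = 30, seed = 18))
  val <- rt$val
  td <- tidy(val)
  expect_true(all(c("variable", "n_compared", "agreement", "kappa") %in%
                    names(td)))
  gl <- glance(val)
  expect_equal(gl$min_kappa, 1)
  expect_equal(gl$indications_mean_kappa, 1)
  p <- autoplot(val)
  expect_s3_class(p, "ggplot")
})
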