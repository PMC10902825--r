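rs <- default_rule_sets()

test_that("printed LV-function phrases classify to their printed grades", {
  phrases <- c(
    "Systolic function appears within normal limits" = "normal",
    "LV function appears mildly and globally impaired" = "mildly impaired",
    "Systolic function is difficult to assess but visually appears mild-to-moderately impaired" =
      "mild-to-moderately impaired",
    "Moderate decrease in systolic function" = "moderately impaired")
  got <- classify(names(phrases), rs$lv_function)$level
  expect_equal(got, unname(phrases))
})

test_that("aortic stenosis rules follow the replacement > severity > sclerosis order", {
  expect_equal(
    classify_aortic_stenosis("valve is thickened with no significant gradient"),
    "sclerosis")
  expect_equal(classify_aortic_stenosis("mechanical AVR in situ"), "AVR")
  expect_equal(classify_aortic_stenosis("AVR, no stenosis"), "AVR")
  # explicit severity outranks the thickening mention
  expect_equal(
    classify_aortic_stenosis("severely thickened leaflets, severe aortic stenosis"),
    "severe")
  expect_equal(classify_aortic_stenosis("No aortic stenosis"), "none")
  expect_equal(classify_aortic_stenosis(""), "none")
})

test_that("regurgitation direct rules beat catch-alls (worked counter-example)", {
  expect_equal(
    classify_regurgitation("mild regurgitation and moderate stenosis", "aortic"),
    "mild")
  expect_equal(
    classify_regurgitation("There is moderate eccentric regurgitation.", "aortic"),
    "moderate")
  expect_equal(classify_regurgitation("no regurgitation seen", "aortic"),
               "none")
})

test_that("every ordered severity pair grades regurgitation from its own severity", {
  sev <- c("mild", "mild-to-moderate", "moderate", "moderate-to-severe",
           "severe")
  for (s1 in sev) {
    for (s2 in setdiff(sev, s1)) {
      txt <- paste0(s1, " regurgitation and ", s2, " stenosis")
      for (valve in c("aortic", "mitral", "tricuspid", "pulmonary")) {
        expect_equal(classify_regurgitation(txt, valve), s1,
                     label = paste(valve, txt))
      }
    }
  }
})

test_that("aortic valve morphology handles bicuspid, unstated and rare forms", {
  expect_equal(classify_av_morphology("bicuspid aortic valve with raphe"),
               "bicuspid")
  expect_equal(classify_av_morphology(""), "tricuspid")
  expect_equal(classify_av_morphology("normal trileaflet valve"), "tricuspid")
  expect_equal(classify_av_morphology("quadricuspid valve"), "exclude")
  expect_equal(classify_av_morphology("unicuspid valve"), "exclude")
})

test_that("rhythm is prioritised and BBB extracted independently", {
  r <- classify_rhythm("AF with LBBB")
  expect_equal(r$rhythm, "atrial fibrillation")
  expect_equal(r$bbb, "left BBB")
  r <- classify_rhythm("sinus rhythm")
  expect_equal(r$rhythm, "sinus rhythm")
  expect_equal(r$bbb, "no BBB")
  # paced outranks the underlying rhythm
  expect_equal(classify_rhythm("paced rhythm, underlying atrial fibrillation")$rhythm,
               "artificially paced")
  expect_equal(classify_rhythm("right bundle branch block")$bbb, "right BBB")
  expect_equal(classify_rhythm("sinus with bundle branch block")$bbb,
               "BBB (unspecified)")
  expect_equal(classify_rhythm("")$rhythm, "uncertain")
})

test_that("LA size prefers free text and falls back to LAVi bins", {
  expect_equal(classify_la_size("moderately dilated left atrium", lavi = 30),
               "moderate")
  # guideline bins, inclusive upper bounds
  expect_equal(classify_la_size("", lavi = 30), "normal")
  expect_equal(classify_la_size("", lavi = 34), "normal")
  expect_equal(classify_la_size("", lavi = 35), "mild")
  expect_equal(classify_la_size("", lavi = 41), "mild")
  expect_equal(classify_la_size("", lavi = 42), "moderate")
  expect_equal(classify_la_size("", lavi = 48), "moderate")
  expect_equal(classify_la_size("", lavi = 49), "severe")
  expect_equal(classify_la_size("", lavi = NA), "not stated")
  expect_equal(classify_la_size(""), "not stated")
})

test_that("indication flags are independent binaries", {
  f <- flag_indications("murmur, query aortic stenosis")
  expect_true(f$ind_murmur)
  expect_true(f$ind_valve_assessment)
  expect_false(f$ind_heart_failure)
  f0 <- flag_indications("")
  expect_true(all(!unlist(f0)))
  f1 <- flag_indications("Palpitations for investigation")
  expect_equal(sum(unlist(f1)), 1)
  expect_true(f1$ind_arrhythmia)
})

test_that("empty text yields each variable's default level", {
  for (nm in names(rs)) {
    expect_equal(classify("", rs[[nm]])$level, rs[[nm]]$default, label = nm)
    expect_equal(classify(NA_character_, rs[[nm]])$level, rs[[nm]]$default,
                 label = nm)
  }
})

test_that("classification is invariant to input case", {
  bank <- default_phrase_bank()
  for (v in intersect(names(bank), names(rs))) {
    for (lv in names(bank[[v]])) {
      for (tpl in bank[[v]][[lv]]) {
        if (!nzchar(tpl)) next
        expect_equal(classify(toupper(tpl), rs[[v]])$level,
                     classify(tolower(tpl), rs[[v]])$level,
                     label = tpl)
      }
    }
  }
})

test_that("every shipped template classifies back to its own level", {
  bank <- default_phrase_bank()
  for (v in intersect(names(bank), names(rs))) {
    for (lv in names(bank[[v]])) {
      for (tpl in bank[[v]][[lv]]) {
        res <- classify(tpl, rs[[v]])
        expect_equal(res$level, lv, label = paste(v, "<-", tpl))
        if (res$matched_rule != "DEFAULT" && nzchar(tpl)) {
          expect_true(grepl(res$matched_span, tpl, ignore.case = TRUE,
                            fixed = FALSE) ||
                        grepl(res$matched_span, tpl, ignore.case = TRUE,
                              fixed = TRUE),
                      label = paste("span of", tpl))
        }
      }
    }
  }
})

test_that("inserting a lower-priority rule never changes earlier outcomes", {
  base <- rs$aortic_regurgitation
  texts <- c("mild regurgitation", "severe aortic regurgitation",
             "moderate eccentric regurgitation seen",
             "no regurgitation")
  before <- classify(texts, base)
  extra <- phrase_rule("late_rule", "regurg", "severe",
                       max(base$rules$priority) + 10L,
                       kind = "catch_all")
  grown <- rule_set(base$variable, base$levels, base$default,
                    dplyr::bind_rows(base$rules, extra))
  after <- classify(texts, grown)
  expect_equal(after$level, before$level)
})

test_that("rule-set invariants are enforced", {
  r1 <- phrase_rule("a", "foo", "none", 10)
  r2 <- phrase_rule("b", "bar", "mild", 10)
  expect_error(rule_set("x", severity_levels(), "none",
                        dplyr::bind_rows(r1, r2)),
               "priorities")
  expect_error(rule_set("x", severity_levels(), "nope",
                        dplyr::bind_rows(r1)), "Default")
  bad_lvl <- phrase_rule("c", "baz", "weird", 20)
  expect_error(rule_set("x", severity_levels(), "none",
                        dplyr::bind_rows(r1, bad_lvl)), "level set")
  ca <- phrase_rule("d", "tok", "mild", 5, kind = "catch_all")
  expect_error(rule_set("x", severity_levels(), "none",
                        dplyr::bind_rows(r1, ca)), "precede")
  expect_error(phrase_rule("e", "", "none", 1), "non-empty")
})

test_that("rule sets survive a YAML round trip", {
  path <- withr::local_tempfile(fileext = ".yml")
  write_rule_sets(rs[c("aortic_stenosis", "mac")], path)
  back <- read_rule_sets(path)
  expect_equal(names(back), c("aortic_stenosis", "mac"))
  texts <- c("severe aortic stenosis", "thickened valve", "AVR in situ", "")
  expect_equal(classify(texts, back$aortic_stenosis)$level,
               classify(texts, rs$aortic_stenosis)$level)
  expect_equal(back$mac$rules$pattern, rs$mac$rules$pattern)
})
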