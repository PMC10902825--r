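# Synthetic echocardiography report exports with hidden ground truth.
# Emulates a multi-chunk PACS data-mining export: column aliases across
# report versions, templated free-text sections built from a phrase bank,
# numeric fields with ranges / extremes / transpositions, per-field
# missingness — so every downstream cleaning stage is testable without
# clinical data.

#' Default phrase bank
#'
#' Template phrases per variable and level, used by the generator to
#' instantiate free-text report sections. Each template classifies back to
#' its own level under [default_rule_sets()] (a tested invariant), so with
#' all corruption rates at zero the cleaning pipeline recovers the ground
#' truth exactly.
#'
#' @return Named list: variable -> level -> character vector of templates.
#' @export
default_phrase_bank <- function() {
  list(
    aortic_stenosis = list(
      "none" = c("Normal aortic valve",
                 "The aortic valve opens well with no stenosis",
                 "No aortic stenosis"),
      "sclerosis" = c("The aortic valve is thickened with no significant gradient",
                      "Aortic sclerosis with preserved leaflet excursion",
                      "Mildly thickened aortic valve leaflets"),
      "mild" = c("Mild aortic stenosis", "Mild AS with preserved opening"),
      "mild-to-moderate" = c("Mild-to-moderate aortic stenosis"),
      "moderate" = c("Moderate aortic stenosis",
                     "Moderate calcific aortic stenosis"),
      "moderate-to-severe" = c("Moderate-to-severe aortic stenosis"),
      "severe" = c("Severe aortic stenosis",
                   "Severe calcific aortic valve stenosis"),
      "AVR" = c("Mechanical AVR in situ with stable gradients",
                "Bioprosthetic aortic valve replacement, well seated",
                "TAVI prosthesis in good position")
    ),
    aortic_regurgitation = list(
      "none" = c("No aortic regurgitation",
                 "Competent aortic valve with no regurgitation",
                 "Trivial aortic regurgitation only"),
      "mild" = c("Mild aortic regurgitation", "Mild AR"),
      "mild-to-moderate" = c("Mild-to-moderate aortic regurgitation"),
      "moderate" = c("Moderate aortic regurgitation",
                     "There is moderate eccentric regurgitation"),
      "moderate-to-severe" = c("Moderate-to-severe AR"),
      "severe" = c("Severe aortic regurgitation with diastolic flow reversal")
    ),
    av_morphology = list(
      "tricuspid" = c("Trileaflet aortic valve",
                      "Normal trileaflet valve structure"),
      "bicuspid" = c("Bicuspid aortic valve with fusion of right and left coronary cusps",
                     "The valve appears bicuspid")
    ),
    mitral_stenosis = list(
      "none" = c("No mitral stenosis", "Normal mitral valve inflow"),
      "mild" = c("Mild mitral stenosis"),
      "mild-to-moderate" = c("Mild-to-moderate mitral stenosis"),
      "moderate" = c("Moderate mitral stenosis"),
      "moderate-to-severe" = c("Moderate-to-severe mitral stenosis"),
      "severe" = c("Severe mitral stenosis with doming leaflets")
    ),
    mac = list(
      "none" = c("No mitral annular calcification"),
      "present" = c("Mitral annular calcification is present",
                    "Heavily calcified mitral annulus", "MAC noted")
    ),
    mitral_regurgitation = list(
      "none" = c("No mitral regurgitation",
                 "Competent mitral valve with no regurgitation",
                 "Trivial MR only"),
      "mild" = c("Mild mitral regurgitation", "Mild MR"),
      "mild-to-moderate" = c("Mild-to-moderate mitral regurgitation"),
      "moderate" = c("Moderate mitral regurgitation",
                     "Moderate central jet of regurgitation"),
      "moderate-to-severe" = c("Moderate-to-severe MR"),
      "severe" = c("Severe mitral regurgitation with flail leaflet")
    ),
    mitral_prolapse = list(
      "none" = c("No mitral valve prolapse"),
      "present" = c("Mitral valve prolapse of the posterior leaflet",
                    "Bileaflet prolapse noted")
    ),
    tricuspid_regurgitation = list(
      "none" = c("No tricuspid regurgitation", "Trivial TR only"),
      "mild" = c("Mild tricuspid regurgitation", "Mild TR"),
      "mild-to-moderate" = c("Mild-to-moderate TR"),
      "moderate" = c("Moderate tricuspid regurgitation"),
      "moderate-to-severe" = c("Moderate-to-severe tricuspid regurgitation"),
      "severe" = c("Severe TR with annular dilatation")
    ),
    pulmonary_stenosis = list(
      "none" = c("No pulmonary stenosis"),
      "mild" = c("Mild pulmonary stenosis"),
      "mild-to-moderate" = c("Mild-to-moderate pulmonary stenosis"),
      "moderate" = c("Moderate pulmonary stenosis"),
      "moderate-to-severe" = c("Moderate-to-severe pulmonary stenosis"),
      "severe" = c("Severe pulmonary valve stenosis")
    ),
    pulmonary_regurgitation = list(
      "none" = c("No pulmonary regurgitation", "Trivial PR only"),
      "mild" = c("Mild pulmonary regurgitation", "Mild PR"),
      "mild-to-moderate" = c("Mild-to-moderate PR"),
      "moderate" = c("Moderate pulmonary regurgitation"),
      "moderate-to-severe" = c("Moderate-to-severe PR"),
      "severe" = c("Severe pulmonary regurgitation")
    ),
    lv_size = list(
      "normal" = c("The left ventricle is normal in size",
                   "Normal LV cavity size"),
      "mild" = c("The left ventricle is mildly dilated",
                 "Mildly dilated left ventricle"),
      "moderate" = c("Moderately dilated left ventricle"),
      "severe" = c("Severely dilated left ventricle")
    ),
    lv_function = list(
      "normal" = c("Systolic function appears within normal limits",
                   "Normal LV systolic function"),
      "mildly impaired" = c("LV function appears mildly and globally impaired",
                            "Mildly impaired systolic function"),
      "mild-to-moderately impaired" = c(
        "Systolic function is difficult to assess but visually appears mild-to-moderately impaired",
        "Mild-to-moderately impaired LV systolic function"),
      "moderately impaired" = c("Moderate decrease in systolic function",
                                "Moderately impaired LV systolic function"),
      "moderate-to-severely impaired" = c(
        "Moderate-to-severely impaired systolic function"),
      "severely impaired" = c("Severely impaired LV systolic function",
                              "Severe reduction in systolic function")
    ),
    la_size = list(
      "normal" = c("The left atrium is normal in size",
                   "Normal left atrial size"),
      "mild" = c("Mildly dilated left atrium", "Mild left atrial dilatation"),
      "moderate" = c("Moderately dilated left atrium"),
      "severe" = c("Severely dilated left atrium")
    ),
    rv_size = list(
      "normal" = c("The right ventricle is normal in size", "Normal RV size"),
      "mild" = c("Mildly dilated right ventricle"),
      "moderate" = c("Moderately dilated right ventricle"),
      "severe" = c("Severely dilated right ventricle")
    ),
    rv_function = list(
      "normal" = c("Normal RV systolic function",
                   "RV function appears within normal limits"),
      "mildly impaired" = c("Mildly impaired RV function"),
      "mild-to-moderately impaired" = c("Mild-to-moderately impaired RV function"),
      "moderately impaired" = c("Moderately impaired RV systolic function"),
      "moderate-to-severely impaired" = c(
        "Moderate-to-severely impaired RV function"),
      "severely impaired" = c("Severely impaired RV systolic function")
    ),
    rhythm = list(
      "artificially paced" = c("Ventricularly paced rhythm",
                               "Paced rhythm throughout"),
      "supraventricular tachycardia" = c("Supraventricular tachycardia"),
      "atrial flutter" = c("Atrial flutter",
                           "Atrial flutter with 2:1 conduction"),
      "atrial fibrillation" = c("Atrial fibrillation",
                                "AF with controlled ventricular response"),
      "heart block" = c("Complete heart block", "Second degree AV block"),
      "sinus rhythm" = c("Sinus rhythm", "Normal sinus rhythm"),
      "other" = c("Junctional rhythm", "Frequent ventricular ectopic beats"),
      "uncertain" = c("Rhythm difficult to determine",
                      "Rhythm not clearly seen")
    ),
    bbb = list(
      "left BBB" = c("with LBBB", "with left bundle branch block"),
      "right BBB" = c("with RBBB", "with right bundle branch block"),
      "BBB (unspecified)" = c("with bundle branch block morphology"),
      "no BBB" = c("")
    ),
    indications = list(
      murmur = c("Systolic murmur on examination", "Ejection systolic murmur"),
      valve_assessment = c("Assessment of known aortic stenosis",
                           "Query valve disease",
                           "Reassessment of mitral regurgitation severity"),
      heart_failure = c("Heart failure with reduced exercise tolerance",
                        "Progressive dyspnoea and peripheral oedema"),
      arrhythmia = c("Palpitations for investigation",
                     "New atrial fibrillation"),
      preoperative = c("Pre-op assessment prior to non-cardiac surgery"),
      follow_up = c("Routine follow-up study", "Surveillance imaging")
    ),
    rvsp_text = list(
      "estimate" = c("Estimated RVSP of %d mmHg plus RA pressure",
                     "RVSP %d mmHg", "PASP estimated at %d mmHg"),
      "no_estimate" = c("RVSP could not be estimated",
                        "No adequate TR signal to estimate RVSP")
    )
  )
}

# True level prevalences: the study conditions the generator emulates
# (a general echocardiography laboratory population).
default_prevalence <- function() {
  sev6 <- function(p) setNames(p, severity_levels())
  list(
    aortic_stenosis = c(none = 0.50, sclerosis = 0.12, mild = 0.10,
                        `mild-to-moderate` = 0.04, moderate = 0.09,
                        `moderate-to-severe` = 0.03, severe = 0.07,
                        AVR = 0.05),
    aortic_regurgitation = sev6(c(0.45, 0.25, 0.06, 0.12, 0.04, 0.08)),
    av_morphology = c(tricuspid = 0.95, bicuspid = 0.05),
    mitral_stenosis = sev6(c(0.70, 0.12, 0.04, 0.07, 0.03, 0.04)),
    mac = c(none = 0.75, present = 0.25),
    mitral_regurgitation = sev6(c(0.45, 0.25, 0.06, 0.12, 0.04, 0.08)),
    mitral_prolapse = c(none = 0.85, present = 0.15),
    tricuspid_regurgitation = sev6(c(0.45, 0.25, 0.06, 0.12, 0.04, 0.08)),
    pulmonary_stenosis = sev6(c(0.70, 0.12, 0.04, 0.07, 0.03, 0.04)),
    pulmonary_regurgitation = sev6(c(0.55, 0.20, 0.05, 0.10, 0.04, 0.06)),
    lv_size = c(normal = 0.55, mild = 0.20, moderate = 0.15, severe = 0.10),
    lv_function = c("normal" = 0.55, "mildly impaired" = 0.15,
                    "mild-to-moderately impaired" = 0.05,
                    "moderately impaired" = 0.12,
                    "moderate-to-severely impaired" = 0.04,
                    "severely impaired" = 0.09),
    la_size = c(normal = 0.50, mild = 0.22, moderate = 0.17, severe = 0.11),
    rv_size = c(normal = 0.60, mild = 0.18, moderate = 0.13, severe = 0.09),
    rv_function = c("normal" = 0.60, "mildly impaired" = 0.14,
                    "mild-to-moderately impaired" = 0.04,
                    "moderately impaired" = 0.11,
                    "moderate-to-severely impaired" = 0.03,
                    "severely impaired" = 0.08),
    rhythm = c("artificially paced" = 0.07,
               "supraventricular tachycardia" = 0.02,
               "atrial flutter" = 0.04, "atrial fibrillation" = 0.18,
               "heart block" = 0.04, "sinus rhythm" = 0.60,
               "other" = 0.03, "uncertain" = 0.02),
    bbb = c("left BBB" = 0.09, "right BBB" = 0.08,
            "BBB (unspecified)" = 0.03, "no BBB" = 0.80),
    sex = c(Female = 0.52, Male = 0.48),
    indications = c(murmur = 0.20, valve_assessment = 0.30,
                    heart_failure = 0.20, arrhythmia = 0.15,
                    preoperative = 0.10, follow_up = 0.15)
  )
}

#' Generator configuration
#'
#' Defines the statistical structure of the synthetic export: cohort size,
#' repeat-study fraction, phrase bank, level prevalences, numeric sampling
#' ranges and corruption rates.
#'
#' @param n_studies Number of study rows to generate.
#' @param seed Integer seed; the export is a deterministic function of the
#'   configuration including the seed.
#' @param repeat_study_rate Fraction of studies that are repeat studies of
#'   an already-generated patient (strictly later date).
#' @param phrase_bank Variable -> level -> templates; see
#'   [default_phrase_bank()].
#' @param prevalence Variable -> named level probabilities.
#' @param typo_rate Per-token probability of a character swap/drop typo in
#'   free text. By default typos never touch tokens that appear in any
#'   classification pattern, so rule coverage (not luck) determines
#'   recovery.
#' @param adversarial If `TRUE`, typos target exactly those keyword tokens
#'   instead, at rate `adversarial_rate`, for robustness testing.
#' @param adversarial_rate Per-keyword-token corruption probability in
#'   adversarial mode.
#' @param missing_rate Per-field probability that an eligible numeric
#'   field is blank.
#' @param transposition_rate Per-study probability that height and weight
#'   are stored swapped.
#' @param range_rate Probability that heart rate is expressed as a range
#'   `"a-b"` (the mean of the endpoints equals the true rate).
#' @param extreme_value_rate Per-study probability, applied independently,
#'   of each injected extreme: a heart rate above 200 bpm, a weight
#'   implying BMI >= 70 kg/m^2, and a non-positive value in one
#'   physically-positive field.
#' @param cm_height_rate Probability that height is recorded in
#'   centimetres rather than metres.
#' @param n_chunks Number of export chunks (files) the rows are split into.
#' @param alias_profiles Column-name alias profiles cycled across chunks;
#'   see [default_alias_profiles()].
#' @param ranges Named list of numeric sampling ranges (physiologically
#'   plausible defaults).
#' @return List of class `echo_generator_config`.
#' @export
generator_config <- function(n_studies = 100, seed = 1L,
                             repeat_study_rate = 0.15,
                             phrase_bank = default_phrase_bank(),
                             prevalence = default_prevalence(),
                             typo_rate = 0.02,
                             adversarial = FALSE,
                             adversarial_rate = 0.05,
                             missing_rate = 0.05,
                             transposition_rate = 0.002,
                             range_rate = 0.15,
                             extreme_value_rate = 0.005,
                             cm_height_rate = 0.2,
                             n_chunks = 3,
                             alias_profiles = default_alias_profiles(),
                             ranges = list(
                               height = c(1.45, 2.00), bmi = c(17, 45),
                               heart_rate = c(45, 180), age = c(18, 95),
                               hr_extreme = c(205, 250))) {
  rates <- c(repeat_study_rate = repeat_study_rate, typo_rate = typo_rate,
             adversarial_rate = adversarial_rate,
             missing_rate = missing_rate,
             transposition_rate = transposition_rate,
             range_rate = range_rate,
             extreme_value_rate = extreme_value_rate,
             cm_height_rate = cm_height_rate)
  bad <- names(rates)[rates < 0 | rates > 1]
  if (length(bad)) {
    abort(paste0("Rate parameter(s) outside [0,1]: ",
                 paste(bad, collapse = ", ")))
  }
  if (n_studies < 1) abort("`n_studies` must be >= 1.")
  if (n_chunks < 1) abort("`n_chunks` must be >= 1.")
  for (v in names(prevalence)) {
    if (v %in% c("indications")) next
    if (v %in% names(phrase_bank)) {
      missing_lv <- setdiff(names(prevalence[[v]]), names(phrase_bank[[v]]))
      if (length(missing_lv)) {
        abort(paste0("phrase_bank lacks template(s) for '", v, "' level(s): ",
                     paste(missing_lv, collapse = ", ")))
      }
    }
  }
  structure(c(list(n_studies = as.integer(n_studies), seed = as.integer(seed),
                   phrase_bank = phrase_bank, prevalence = prevalence,
                   adversarial = adversarial, n_chunks = as.integer(n_chunks),
                   alias_profiles = alias_profiles, ranges = ranges),
              as.list(rates)),
            class = "echo_generator_config")
}

# Tokens that appear in any classification pattern; typos avoid these
# (or target them, in adversarial mode).
rule_keywords <- function() {
  pats <- unlist(lapply(default_rule_sets(), function(rs) rs$rules$pattern))
  pats <- c(pats, unlist(default_indication_categories()), "mmhg", "rvsp")
  pats <- gsub("\\\\[a-zA-Z]", " ", pats)       # strip \b \w \s escapes
  toks <- unlist(regmatches(pats, gregexpr("[A-Za-z]{2,}", pats)))
  unique(tolower(toks))
}

# Introduce one character swap or drop in a token.
typo_token <- function(tok) {
  n <- nchar(tok)
  if (n < 4) return(tok)
  if (runif(1) < 0.5) {
    i <- sample(seq_len(n - 1), 1)
    paste0(substr(tok, 1, i - 1), substr(tok, i + 1, i + 1),
           substr(tok, i, i), substr(tok, i + 2, n))
  } else {
    i <- sample(seq_len(n), 1)
    paste0(substr(tok, 1, i - 1), substr(tok, i + 1, n))
  }
}

# Apply typos to a text. Returns list(text=, n_typos=).
inject_typos <- function(text, rate, keywords, adversarial = FALSE) {
  if (rate == 0 || !nzchar(text)) return(list(text = text, n = 0L))
  toks <- strsplit(text, " ", fixed = TRUE)[[1]]
  # a token is protected if any of its alphabetic pieces is a pattern
  # token, or extends a pattern stem ("thickened" vs "thicken\\w*")
  stems <- keywords[nchar(keywords) >= 5]
  is_kw <- vapply(strsplit(gsub("[^a-z]", " ", tolower(toks)), " "),
                  function(p) {
                    p <- p[nzchar(p)]
                    any(p %in% keywords) ||
                      any(vapply(p, function(x) any(startsWith(x, stems)),
                                 logical(1)))
                  }, logical(1))
  has_digit <- grepl("[0-9]", toks)
  eligible <- nchar(toks) >= 4 & !has_digit &
    (if (adversarial) is_kw else !is_kw)
  do <- eligible & runif(length(toks)) < rate
  if (any(do)) toks[do] <- vapply(toks[do], typo_token, character(1))
  list(text = paste(toks, collapse = " "), n = sum(do))
}

sample_level <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

pick_template <- function(levels, bank_var) {
  vapply(levels, function(lv) {
    tpl <- bank_var[[lv]]
    tpl[sample.int(length(tpl), 1)]
  }, character(1), USE.NAMES = FALSE)
}

#' Generate a labelled synthetic echocardiography export
#'
#' Produces raw export chunks (all-character tibbles with version-specific
#' display headers), the hidden ground truth for every variable, and a
#' generation log recording each injected corruption. Deterministic given
#' the configuration (including its seed).
#'
#' @param config [generator_config()].
#' @return An object of class `echo_export`: list with `chunks` (list of
#'   tibbles), `truth` (tibble keyed by `study_id`, `nhi`, `study_date`),
#'   `log` (tibble: `study_id`, `type`, `field`, `detail`), and `config`.
#' @export
#' @examples
#' ex <- simulate_echo_export(generator_config(n_studies = 5, seed = 1))
#' names(ex$chunks)
simulate_echo_export <- function(config = generator_config()) {
  stopifnot(inherits(config, "echo_generator_config"))
  old_seed <- .Random.seed_exists()
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  n <- config$n_studies
  bank <- config$phrase_bank
  prev <- config$prevalence
  rg <- config$ranges
  keywords <- rule_keywords()

  # --- patients, repeats, dates -------------------------------------------
  n_repeat <- min(round(n * config$repeat_study_rate), n - 1)
  n_pat <- n - n_repeat
  letters_pool <- LETTERS
  nhi <- character(0)
  while (length(nhi) < n_pat) {
    cand <- paste0(
      apply(matrix(sample(letters_pool, 3 * (n_pat - length(nhi)),
                          replace = TRUE), ncol = 3), 1, paste,
            collapse = ""),
      sprintf("%04d", sample.int(9999, n_pat - length(nhi), replace = TRUE)))
    nhi <- unique(c(nhi, cand))
  }
  nhi <- nhi[seq_len(n_pat)]
  pat_idx <- c(seq_len(n_pat),
               if (n_repeat > 0) sample.int(n_pat, n_repeat, replace = TRUE))
  base_date <- as.Date("2010-01-01") +
    sample.int(as.integer(as.Date("2017-06-30") - as.Date("2010-01-01")),
               n_pat, replace = TRUE)
  study_date <- base_date[pat_idx]
  if (n_repeat > 0) {
    last_date <- base_date
    for (k in (n_pat + 1):n) {
      p <- pat_idx[k]
      study_date[k] <- last_date[p] + sample(30:400, 1)
      last_date[p] <- study_date[k]
    }
  }

  # --- categorical truths and section texts -------------------------------
  cat_vars <- categorical_schema()$variable
  truth <- tibble(study_id = seq_len(n), nhi = nhi[pat_idx],
                  study_date = study_date)
  truth$age <- sample(seq(rg$age[1], rg$age[2]), n, replace = TRUE)
  truth$sex <- sample_level(n, prev$sex)

  levels_by_var <- list()
  for (v in cat_vars) levels_by_var[[v]] <- sample_level(n, prev[[v]])
  # a replaced aortic valve has no native morphology to describe
  avr <- levels_by_var$aortic_stenosis == "AVR"
  levels_by_var$av_morphology[avr] <- "tricuspid"
  for (v in cat_vars) truth[[v]] <- levels_by_var[[v]]

  tpl <- lapply(cat_vars, function(v) pick_template(levels_by_var[[v]],
                                                    bank[[v]]))
  names(tpl) <- cat_vars
  tpl$av_morphology[avr] <- ""

  join_sentences <- function(...) {
    parts <- list(...)
    out <- vapply(seq_len(n), function(i) {
      s <- vapply(parts, `[[`, character(1), i)
      s <- s[nzchar(s)]
      if (length(s) == 0) "" else paste0(paste(s, collapse = ". "), ".")
    }, character(1))
    out
  }

  sections <- list(
    lv_text = join_sentences(tpl$lv_size, tpl$lv_function),
    la_text = join_sentences(tpl$la_size),
    rv_text = join_sentences(tpl$rv_size, tpl$rv_function),
    mitral_text = join_sentences(tpl$mitral_stenosis,
                                 tpl$mitral_regurgitation, tpl$mac,
                                 tpl$mitral_prolapse),
    aov_text = join_sentences(tpl$aortic_stenosis, tpl$aortic_regurgitation,
                              tpl$av_morphology),
    pulmonary_text = join_sentences(tpl$pulmonary_stenosis,
                                    tpl$pulmonary_regurgitation),
    tricuspid_text = join_sentences(tpl$tricuspid_regurgitation)
  )
  bbb_tpl <- pick_template(levels_by_var$bbb, bank$bbb)
  rhythm_tpl <- pick_template(levels_by_var$rhythm, bank$rhythm)
  sections$rhythm_text <- trimws(paste(rhythm_tpl, bbb_tpl))

  ind_cats <- names(prev$indications)
  ind <- vapply(ind_cats, function(cg) {
    runif(n) < prev$indications[[cg]]
  }, logical(n))
  ind <- matrix(ind, nrow = n,
                dimnames = list(NULL, ind_cats))
  sections$indication_text <- vapply(seq_len(n), function(i) {
    active <- ind_cats[ind[i, ]]
    if (length(active) == 0) return("")
    paste(vapply(active, function(cg) {
      t <- bank$indications[[cg]]
      t[sample.int(length(t), 1)]
    }, character(1)), collapse = ", ")
  }, character(1))
  for (cg in ind_cats) truth[[paste0("ind_", cg)]] <- ind[, cg]

  # --- numeric truths -----------------------------------------------------
  truth$height <- round(runif(n, rg$height[1], rg$height[2]), 2)
  truth$bmi <- round(runif(n, rg$bmi[1], rg$bmi[2]), 1)
  truth$weight <- round(truth$bmi * truth$height^2, 1)
  truth$heart_rate <- round(runif(n, rg$heart_rate[1], rg$heart_rate[2]))

  lvef_range <- list(
    "normal" = c(55, 70), "mildly impaired" = c(45, 54),
    "mild-to-moderately impaired" = c(40, 50),
    "moderately impaired" = c(35, 44),
    "moderate-to-severely impaired" = c(30, 38),
    "severely impaired" = c(12, 30))
  truth$lvef <- round(vapply(levels_by_var$lv_function, function(lv) {
    r <- lvef_range[[lv]]
    runif(1, r[1], r[2])
  }, numeric(1), USE.NAMES = FALSE))

  num <- tibble(
    ivsd = round(runif(n, 0.6, 1.6), 2),
    lvpwd = round(runif(n, 0.6, 1.5), 2),
    lvot_diam = round(runif(n, 1.8, 2.6), 2),
    mitral_e = round(runif(n, 40, 120)),
    mitral_a = round(runif(n, 30, 110)),
    septal_e_prime = round(runif(n, 4, 12), 1),
    lateral_e_prime = round(runif(n, 5, 15), 1),
    asc_aorta = round(runif(n, 2.5, 4.5), 2),
    aortic_root = round(runif(n, 2.5, 4.2), 2),
    aov_vmax = round(runif(n, 1.0, 4.5), 2),
    aov_mean_grad = round(runif(n, 3, 55)),
    lvot_vti = round(runif(n, 15, 25), 1),
    aov_area = round(runif(n, 0.6, 3.5), 2),
    tr_vmax = round(runif(n, 1.8, 4.2), 2),
    lavi = round(runif(n, 20, 60))
  )
  num$e_over_a <- round(num$mitral_e / num$mitral_a, 2)
  num$e_over_e_prime <- round(
    num$mitral_e / ((num$septal_e_prime + num$lateral_e_prime) / 2), 1)
  num$aov_vti <- round(num$lvot_vti / runif(n, 0.25, 0.7), 1)

  rvsp_mode <- sample(c("numeric", "text", "none"), n, replace = TRUE,
                      prob = c(0.5, 0.4, 0.1))
  rvsp_val <- as.integer(round(runif(n, 18, 70)))
  truth$rvsp <- ifelse(rvsp_mode == "none", NA_real_, rvsp_val)
  rvsp_numeric <- ifelse(rvsp_mode == "numeric", as.character(rvsp_val), "")
  rvsp_text <- vapply(seq_len(n), function(i) {
    if (rvsp_mode[i] == "text") {
      sprintf(bank$rvsp_text$estimate[
        sample.int(length(bank$rvsp_text$estimate), 1)], rvsp_val[i])
    } else if (rvsp_mode[i] == "none") {
      bank$rvsp_text$no_estimate[
        sample.int(length(bank$rvsp_text$no_estimate), 1)]
    } else ""
  }, character(1))

  # --- corruption injection ------------------------------------------------
  log <- list()
  add_log <- function(study_id, type, field, detail = "") {
    log[[length(log) + 1]] <<- tibble(study_id = as.integer(study_id),
                                      type = type, field = field,
                                      detail = as.character(detail))
  }

  height_s <- as.character(truth$height)
  weight_s <- as.character(truth$weight)
  cm_rows <- runif(n) < config$cm_height_rate
  height_s[cm_rows] <- as.character(round(truth$height[cm_rows] * 100))

  transposed <- runif(n) < config$transposition_rate & !cm_rows
  if (any(transposed)) {
    tmp <- height_s[transposed]
    height_s[transposed] <- weight_s[transposed]
    weight_s[transposed] <- tmp
    for (i in which(transposed)) add_log(i, "transposed", "height")
  }

  bmi_extreme <- runif(n) < config$extreme_value_rate & !transposed
  if (any(bmi_extreme)) {
    w_ext <- round(75 * truth$height[bmi_extreme]^2, 1)
    weight_s[bmi_extreme] <- as.character(w_ext)
    truth$bmi[bmi_extreme] <- NA_real_   # true BMI irrecoverable
    for (i in which(bmi_extreme)) add_log(i, "bmi_extreme", "weight")
  }

  hr_s <- as.character(truth$heart_rate)
  hr_extreme <- runif(n) < config$extreme_value_rate
  if (any(hr_extreme)) {
    hr_ext <- round(runif(sum(hr_extreme), rg$hr_extreme[1],
                          rg$hr_extreme[2]))
    hr_s[hr_extreme] <- as.character(hr_ext)
    truth$heart_rate[hr_extreme] <- NA_real_
    for (i in which(hr_extreme)) add_log(i, "hr_extreme", "heart_rate")
  }
  hr_range <- runif(n) < config$range_rate & !hr_extreme
  if (any(hr_range)) {
    delta <- sample(10:30, sum(hr_range), replace = TRUE)
    lo <- truth$heart_rate[hr_range] - delta
    hi <- truth$heart_rate[hr_range] + delta
    sep <- sample(c("–", "-"), sum(hr_range), replace = TRUE)
    hr_s[hr_range] <- paste0(lo, sep, hi)
    for (i in seq_along(which(hr_range))) {
      add_log(which(hr_range)[i], "hr_range", "heart_rate",
              hr_s[which(hr_range)[i]])
    }
  }

  nonpos_fields <- c("ivsd", "lvpwd", "lvot_diam", "mitral_e", "aov_vmax",
                     "tr_vmax")
  nonpos <- runif(n) < config$extreme_value_rate
  nonpos_field <- rep(NA_character_, n)
  if (any(nonpos)) {
    nonpos_field[nonpos] <- sample(nonpos_fields, sum(nonpos),
                                   replace = TRUE)
    for (i in which(nonpos)) {
      f <- nonpos_field[i]
      num[[f]][i] <- sample(c(0, -0.5, -1.1), 1)
      add_log(i, "nonpositive", f)
    }
  }

  truth$corrupt_transposed <- transposed
  truth$corrupt_bmi_extreme <- bmi_extreme
  truth$corrupt_hr_extreme <- hr_extreme
  truth$corrupt_hr_range <- hr_range
  truth$corrupt_nonpositive_field <- nonpos_field

  # --- LVEF method columns -------------------------------------------------
  pr_methods <- c("lvef_biplane", "lvef_a4c", "lvef_a2c", "lvef_teichholz",
                  "lvef_mmode_cube", "lvef_mmode")
  meth_p <- c(0.7, 0.3, 0.2, 0.3, 0.2, 0.3)
  meth <- matrix(runif(n * 6) < rep(meth_p, each = n), nrow = n,
                 dimnames = list(NULL, pr_methods))
  none_row <- rowSums(meth) == 0
  meth[none_row, "lvef_biplane"] <- TRUE
  lvef_cols <- lapply(pr_methods, function(m) {
    ifelse(meth[, m], as.character(truth$lvef), "")
  })
  names(lvef_cols) <- pr_methods

  # --- missingness ---------------------------------------------------------
  num_s <- lapply(num, as.character)
  miss_eligible <- setdiff(names(num), nonpos_fields)
  for (f in miss_eligible) {
    m <- runif(n) < config$missing_rate
    if (any(m)) {
      num_s[[f]][m] <- ""
      for (i in which(m)) add_log(i, "missing", f)
    }
  }

  # --- typos ---------------------------------------------------------------
  text_fields <- names(sections)
  rate <- if (config$adversarial) config$adversarial_rate else
    config$typo_rate
  if (rate > 0) {
    for (f in text_fields) {
      for (i in seq_len(n)) {
        r <- inject_typos(sections[[f]][i], rate, keywords,
                          adversarial = config$adversarial)
        if (r$n > 0) {
          sections[[f]][i] <- r$text
          add_log(i, if (config$adversarial) "adversarial_typo" else "typo",
                  f, r$n)
        }
      }
    }
  }

  # --- assemble raw canonical table ---------------------------------------
  raw <- tibble(
    nhi = truth$nhi,
    study_date = format(truth$study_date, "%Y-%m-%d"),
    age = as.character(truth$age),
    sex = truth$sex,
    height = height_s, weight = weight_s, heart_rate = hr_s,
    rhythm_text = sections$rhythm_text,
    indication_text = sections$indication_text,
    lv_text = sections$lv_text, la_text = sections$la_text,
    rv_text = sections$rv_text, mitral_text = sections$mitral_text,
    aov_text = sections$aov_text,
    pulmonary_text = sections$pulmonary_text,
    tricuspid_text = sections$tricuspid_text,
    rvsp_text = rvsp_text, rvsp = rvsp_numeric
  )
  for (f in names(num_s)) raw[[f]] <- num_s[[f]]
  for (f in pr_methods) raw[[f]] <- lvef_cols[[f]]
  raw$comments <- ""
  raw <- raw[, raw_schema()]

  # --- chunking with alias profiles ---------------------------------------
  profiles <- config$alias_profiles
  chunk_of <- sort(rep_len(seq_len(config$n_chunks), n))
  chunks <- lapply(seq_len(config$n_chunks), function(ci) {
    prof <- profiles[[((ci - 1) %% length(profiles)) + 1]]
    ch <- raw[chunk_of == ci, , drop = FALSE]
    if (prof$date_format != "%Y-%m-%d" && nrow(ch)) {
      ch$study_date <- format(as.Date(ch$study_date), prof$date_format)
    }
    names(ch) <- unname(prof$columns[names(ch)])
    ch
  })
  names(chunks) <- paste0("chunk_", seq_len(config$n_chunks))

  log <- if (length(log)) bind_rows(log) else {
    tibble(study_id = integer(), type = character(), field = character(),
           detail = character())
  }
  structure(list(chunks = chunks, truth = truth, log = log,
                 config = config),
            class = "echo_export")
}

#' @export
print.echo_export <- function(x, ...) {
  cat("<echo_export> ", nrow(x$truth), " studies in ", length(x$chunks),
      " chunk(s); ", nrow(x$log), " corruption/log events\n", sep = "")
  invisible(x)
}

#' Write export chunks (and ground truth) to disk
#'
#' One UTF-8 CSV per chunk with its alias-profile header, plus
#' `ground_truth.csv` and a line-oriented `generation_log.txt`.
#'
#' @param export An `echo_export` from [simulate_echo_export()].
#' @param dir Output directory (created if needed).
#' @return Character vector of the chunk file paths (ground-truth and log
#'   paths attached as attributes `truth_path`, `log_path`).
#' @export
write_export_chunks <- function(export, dir) {
  stopifnot(inherits(export, "echo_export"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(export$chunks), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(export$chunks[[nm]], p, na = "")
    p
  }, character(1))
  truth_path <- file.path(dir, "ground_truth.csv")
  readr::write_csv(export$truth, truth_path, na = "")
  log_path <- file.path(dir, "generation_log.txt")
  writeLines(sprintf("study=%d\ttype=%s\tfield=%s\tdetail=%s",
                     export$log$study_id, export$log$type,
                     export$log$field, export$log$detail),
             log_path)
  attr(paths, "truth_path") <- truth_path
  attr(paths, "log_path") <- log_path
  paths
}
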