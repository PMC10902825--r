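# Pipeline orchestration: load and stitch chunks, unify column names via
# alias profiles, drop all-missing columns, anonymise, run the cleaning
# stages in the documented order, de-duplicate to the earliest study per
# patient, and export — with every recode written to an audit log.

#' Pipeline configuration
#'
#' @param numeric [numeric_config()].
#' @param rules Named list of rule sets ([default_rule_sets()]).
#' @param indications Indication category map
#'   ([default_indication_categories()]).
#' @param diastolic [diastolic_criteria()].
#' @param la_thresholds LAVi bin bounds for [classify_la_size()].
#' @param alias_profiles [default_alias_profiles()].
#' @param dedupe_mode `"earliest_per_patient"` (one row per patient:
#'   earliest study) or `"keep_all"`.
#' @param seed Integer seed used for anonymous-ID generation.
#' @return List of class `echo_pipeline_config`.
#' @export
pipeline_config <- function(numeric = numeric_config(),
                            rules = default_rule_sets(),
                            indications = default_indication_categories(),
                            diastolic = diastolic_criteria(),
                            la_thresholds = c(normal = 34, mild = 41,
                                              moderate = 48),
                            alias_profiles = default_alias_profiles(),
                            dedupe_mode = c("earliest_per_patient",
                                            "keep_all"),
                            seed = 1L) {
  dedupe_mode <- match.arg(dedupe_mode)
  structure(list(numeric = numeric, rules = rules,
                 indications = indications, diastolic = diastolic,
                 la_thresholds = la_thresholds,
                 alias_profiles = alias_profiles,
                 dedupe_mode = dedupe_mode, seed = as.integer(seed)),
            class = "echo_pipeline_config")
}

# Match a chunk's headers against the alias profiles; returns the profile
# with the most matching display names.
match_profile <- function(headers, profiles) {
  scores <- vapply(profiles, function(p) {
    sum(headers %in% p$columns)
  }, numeric(1))
  if (max(scores) == 0) {
    abort("No alias profile matches the chunk headers.")
  }
  profiles[[which.max(scores)]]
}

#' Stitch export chunks into one raw table with canonical column names
#'
#' Each chunk (a data frame or a CSV path) is matched to the alias profile
#' whose display headers it uses, renamed to canonical names, and the
#' chunks are row-bound. Columns not named by any profile are preserved
#' untouched and reported. Study dates are normalised to ISO using the
#' matched profile's date format.
#'
#' @param chunks A list of data frames, an `echo_export`, or a character
#'   vector of CSV paths.
#' @param alias_profiles See [default_alias_profiles()].
#' @return List: `data` (tibble, all-character, canonical names, plus
#'   `.row_id`), `unmapped` (character vector of passthrough columns).
#' @export
stitch_chunks <- function(chunks, alias_profiles = default_alias_profiles()) {
  if (inherits(chunks, "echo_export")) chunks <- chunks$chunks
  if (is.character(chunks)) {
    chunks <- lapply(chunks, function(p) {
      readr::read_csv(p, col_types = readr::cols(.default = "c"),
                      na = character())
    })
  }
  unmapped <- character(0)
  std <- lapply(chunks, function(ch) {
    ch <- as_tibble(ch)
    prof <- match_profile(names(ch), alias_profiles)
    rev_map <- setNames(names(prof$columns), unname(prof$columns))
    known <- names(ch) %in% names(rev_map)
    unmapped <<- union(unmapped, names(ch)[!known])
    names(ch)[known] <- rev_map[names(ch)[known]]
    if ("study_date" %in% names(ch) && nrow(ch)) {
      d <- as.Date(ch$study_date, format = prof$date_format)
      ch$study_date <- ifelse(is.na(d), ch$study_date,
                              format(d, "%Y-%m-%d"))
    }
    ch
  })
  data <- bind_rows(std)
  data$.row_id <- seq_len(nrow(data))
  list(data = data, unmapped = unmapped)
}

#' Drop columns where every observation is missing
#'
#' @param data Data frame (character columns; empty string counts as
#'   missing).
#' @return List: `data` without the all-missing columns, `dropped` (their
#'   names).
#' @export
drop_unused <- function(data) {
  all_missing <- vapply(data, function(col) {
    all(is_blank(col))
  }, logical(1))
  list(data = data[, !all_missing, drop = FALSE],
       dropped = names(data)[all_missing])
}

#' De-duplicate to the earliest study per patient
#'
#' Sorts by patient and keeps the earliest study date for each patient;
#' ties on identical dates are broken by stable input order (first
#' occurrence kept). Rows with unparseable dates are excluded.
#'
#' @param data Data frame with `anonymous_id` and `study_date` (Date or
#'   ISO string).
#' @return List: `data` (deduplicated), `removed` (row count removed as
#'   later studies), `bad_dates` (rows dropped for unparseable dates),
#'   `ties` (number of same-day ties broken).
#' @export
dedupe_earliest <- function(data) {
  d <- suppressWarnings(as.Date(data$study_date))
  bad <- which(is.na(d))
  keep_idx <- setdiff(seq_len(nrow(data)), bad)
  dd <- d[keep_idx]
  id <- as.character(data$anonymous_id)[keep_idx]
  ord <- order(id, dd, keep_idx)          # stable: earliest, then input order
  sel <- ord[!duplicated(id[ord])]
  ties <- if (length(keep_idx)) {
    sum(tapply(dd, id, function(x) sum(x == min(x)) > 1))
  } else 0L
  out_idx <- sort(keep_idx[sel])
  list(data = data[out_idx, , drop = FALSE],
       removed = length(keep_idx) - length(sel),
       bad_dates = length(bad), ties = as.integer(ties))
}

#' Run the full cleaning pipeline
#'
#' Executes the cleaning sequence in order: load and stitch, rename via
#' alias maps, drop all-missing columns, anonymise; then demographics
#' (date, age, sex, height/weight/BMI), indications, rhythm and heart
#' rate, left-ventricular numerics, LV/LA free text, mitral valve, aortic
#' valve, pulmonary valve, tricuspid valve, RVSP, diastolic function,
#' right-ventricular free text; finally raw columns are dropped and (in
#' `earliest_per_patient` mode) the earliest study per patient is
#' selected. Deterministic given inputs, configuration and seed.
#'
#' @param chunks Input accepted by [stitch_chunks()].
#' @param config [pipeline_config()].
#' @param lookup Optional existing lookup table for [anonymize()].
#' @return Object of class `echo_clean_run`: list with `data` (the clean
#'   tibble), `audit` (recode/classification log), `lookup`,
#'   `dropped_columns`, `unmapped_columns`, `n_input`, `n_removed_dedupe`,
#'   `n_bad_dates`.
#' @export
#' @examples
#' ex <- simulate_echo_export(generator_config(n_studies = 8, seed = 42))
#' run <- clean_echo_reports(ex, pipeline_config())
#' names(run$data)[1:6]
clean_echo_reports <- function(chunks, config = pipeline_config(),
                               lookup = NULL) {
  stopifnot(inherits(config, "echo_pipeline_config"))
  audit <- list()
  note <- function(rows, stage, field, raw, action, reason = NA_character_) {
    if (length(rows)) {
      audit[[length(audit) + 1]] <<- audit_rows(rows, stage, field, raw,
                                                action, reason)
    }
  }

  # load, stitch, rename ----------------------------------------------------
  st <- stitch_chunks(chunks, config$alias_profiles)
  raw <- st$data
  mandatory <- c("nhi", "study_date")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols)) {
    abort(paste0("Mandatory column(s) missing after aliasing: ",
                 paste(missing_cols, collapse = ", ")))
  }

  # drop all-missing columns -------------------------------------------------
  du <- drop_unused(raw)
  raw <- du$data

  # anonymise ----------------------------------------------------------------
  an <- anonymize(raw, id_col = "nhi", lookup = lookup, seed = config$seed)
  raw <- an$data
  rid <- raw$.row_id

  col <- function(nm) {
    if (nm %in% names(raw)) as.character(raw[[nm]]) else {
      rep("", nrow(raw))
    }
  }
  out <- tibble(anonymous_id = raw$anonymous_id,
                study_date = as.Date(col("study_date")))

  # demographics -------------------------------------------------------------
  out$age <- parse_num(col("age"))
  sex_raw <- tolower(trimws(col("sex")))
  out$sex <- dplyr::case_when(
    sex_raw %in% c("f", "female") ~ "Female",
    sex_raw %in% c("m", "male") ~ "Male",
    .default = NA_character_
  )
  bm <- compute_bmi(col("height"), col("weight"), config$numeric)
  out$height <- bm$height
  out$weight <- bm$weight
  out$bmi <- bm$bmi
  note(rid[bm$transposed], "demographics", "bmi", col("height")[bm$transposed],
       "swapped", "transposed_corrected")
  bmi_oor <- !is.na(bm$recode_reason) & bm$recode_reason == "out_of_range"
  note(rid[bmi_oor], "demographics", "bmi", col("weight")[bmi_oor],
       "recoded_na", "out_of_range")

  # indications --------------------------------------------------------------
  ind <- flag_indications(col("indication_text"), config$indications)
  out <- dplyr::bind_cols(out, ind)

  # rhythm and heart rate ----------------------------------------------------
  ry <- classify_rhythm(col("rhythm_text"), config$rules)
  out$rhythm <- ry$rhythm
  out$bbb <- ry$bbb
  hr <- clean_heart_rate(col("heart_rate"), config$numeric)
  out$heart_rate <- hr$value
  hr_bad <- !is.na(hr$recode_reason)
  note(rid[hr_bad], "heart_rate", "heart_rate", col("heart_rate")[hr_bad],
       "recoded_na", hr$recode_reason[hr_bad])

  # helper for non-positive-excluded numeric fields --------------------------
  clean_pos_field <- function(field, stage) {
    cv <- clean_positive(col(field), field, config$numeric)
    bad <- !is.na(cv$recode_reason)
    note(rid[bad], stage, field, col(field)[bad], "recoded_na",
         cv$recode_reason[bad])
    cv$value
  }

  # left ventricle numerics --------------------------------------------------
  out$ivsd <- clean_pos_field("ivsd", "lv_numeric")
  out$lvpwd <- clean_pos_field("lvpwd", "lv_numeric")
  out$lvot_diam <- clean_pos_field("lvot_diam", "lv_numeric")
  lvef_cols <- intersect(config$numeric$lvef_method_priority, names(raw))
  lvef_clean <- lapply(lvef_cols, function(f) clean_pos_field(f, "lv_numeric"))
  names(lvef_clean) <- lvef_cols
  out$lvef <- if (length(lvef_clean)) {
    select_lvef(as_tibble(lvef_clean), config$numeric)$value
  } else NA_real_

  # left ventricle and atrium free text --------------------------------------
  out$lv_size <- classify(col("lv_text"), config$rules$lv_size)$level
  out$lv_function <- classify(col("lv_text"), config$rules$lv_function)$level
  out$lavi <- clean_pos_field("lavi", "la")
  out$la_size <- classify_la_size(col("la_text"), out$lavi,
                                  config$la_thresholds, config$rules$la_size)

  # mitral valve -------------------------------------------------------------
  for (f in c("mitral_e", "mitral_a", "e_over_a", "e_over_e_prime",
              "septal_e_prime", "lateral_e_prime")) {
    out[[f]] <- clean_pos_field(f, "mitral")
  }
  out$mitral_stenosis <- classify(col("mitral_text"),
                                  config$rules$mitral_stenosis)$level
  out$mitral_regurgitation <- classify(col("mitral_text"),
                                       config$rules$mitral_regurgitation)$level
  out$mac <- classify(col("mitral_text"), config$rules$mac)$level
  out$mitral_prolapse <- classify(col("mitral_text"),
                                  config$rules$mitral_prolapse)$level
  out$any_mitral_calcification <-
    any_mitral_calcification(out$mac, out$mitral_stenosis)

  # aortic valve -------------------------------------------------------------
  for (f in c("asc_aorta", "aortic_root", "aov_vmax", "aov_mean_grad",
              "aov_vti", "aov_area", "lvot_vti")) {
    out[[f]] <- clean_pos_field(f, "aov")
  }
  out$dimensionless_index <- dimensionless_index(out$lvot_vti, out$aov_vti)
  out$aortic_stenosis <- classify(col("aov_text"),
                                  config$rules$aortic_stenosis)$level
  out$aortic_regurgitation <- classify(col("aov_text"),
                                       config$rules$aortic_regurgitation)$level
  morph <- classify(col("aov_text"), config$rules$av_morphology)$level
  excl <- morph == "exclude"
  note(rid[excl], "aov", "av_morphology", col("aov_text")[excl],
       "excluded", "rare_morphology")
  morph[excl] <- NA_character_
  out$av_morphology <- morph

  # pulmonary valve ----------------------------------------------------------
  out$pulmonary_stenosis <- classify(col("pulmonary_text"),
                                     config$rules$pulmonary_stenosis)$level
  out$pulmonary_regurgitation <-
    classify(col("pulmonary_text"),
             config$rules$pulmonary_regurgitation)$level

  # tricuspid valve ----------------------------------------------------------
  out$tricuspid_regurgitation <-
    classify(col("tricuspid_text"),
             config$rules$tricuspid_regurgitation)$level
  out$tr_vmax <- clean_pos_field("tr_vmax", "tricuspid")

  # RVSP ---------------------------------------------------------------------
  rv <- extract_rvsp(col("rvsp"), col("rvsp_text"))
  out$rvsp <- rv$value
  note(rid[rv$flagged], "rvsp", "rvsp", col("rvsp_text")[rv$flagged],
       "text_extracted", NA_character_)

  # diastolic function -------------------------------------------------------
  out$diastolic_function <- diastolic_function(out, config$diastolic)$level

  # right ventricle ----------------------------------------------------------
  out$rv_size <- classify(col("rv_text"), config$rules$rv_size)$level
  out$rv_function <- classify(col("rv_text"), config$rules$rv_function)$level

  # export: drop raw/dummy variables, de-duplicate ---------------------------
  n_input <- nrow(out)
  removed <- 0L
  bad_dates <- 0L
  if (config$dedupe_mode == "earliest_per_patient") {
    dd <- dedupe_earliest(out)
    out <- dd$data
    removed <- dd$removed
    bad_dates <- dd$bad_dates
  }

  audit <- if (length(audit)) bind_rows(audit) else new_audit()
  structure(list(data = as_tibble(out), audit = audit, lookup = an$lookup,
                 dropped_columns = du$dropped,
                 unmapped_columns = st$unmapped,
                 n_input = n_input, n_removed_dedupe = removed,
                 n_bad_dates = bad_dates,
                 config = config),
            class = "echo_clean_run")
}

#' @export
print.echo_clean_run <- function(x, ...) {
  cat("<echo_clean_run> ", nrow(x$data), " clean studies (",
      x$n_input, " input rows, ", x$n_removed_dedupe,
      " removed as repeat studies)\n", sep = "")
  cat("  audit events: ", nrow(x$audit), "; lookup entries: ",
      nrow(x$lookup), "\n", sep = "")
  invisible(x)
}

#' Write the clean dataset (and lookup table) to disk
#'
#' @param run `echo_clean_run` from [clean_echo_reports()].
#' @param out Path for the clean CSV.
#' @param lookup_out Path for the lookup table; must differ from `out`
#'   (the lookup is stored separately from the de-identified data).
#' @param audit_out Optional path for the audit log (CSV).
#' @return `out`, invisibly.
#' @export
write_clean_export <- function(run, out, lookup_out = NULL,
                               audit_out = NULL) {
  stopifnot(inherits(run, "echo_clean_run"))
  readr::write_csv(run$data, out, na = "")
  if (!is.null(lookup_out)) write_lookup(run$lookup, lookup_out,
                                         data_path = out)
  if (!is.null(audit_out)) readr::write_csv(run$audit, audit_out, na = "")
  invisible(out)
}
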