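# Numeric recoding rules: plausibility exclusions, range averaging,
# hierarchy-based selection and unit-anchored extraction from free text.
# Every function returns a "clean value" tibble (value, provenance,
# recode_reason) so each recode is auditable.

#' Numeric cleaning configuration
#'
#' @param bmi_upper,bmi_lower BMI plausibility bounds (kg/m^2). Values
#'   `>= bmi_upper` or `<= bmi_lower` are recoded to missing (closed at
#'   both thresholds).
#' @param hr_max Maximum plausible heart rate (bpm); values strictly above
#'   are recoded to missing.
#' @param nonpositive_excluded_fields Fields where a value `<= 0` is
#'   physically impossible and is recoded to missing.
#' @param lvef_method_priority Ordered LVEF method hierarchy, most
#'   trusted first.
#' @return A list of class `echo_numeric_config`.
#' @export
#' @examples
#' numeric_config()$hr_max
numeric_config <- function(bmi_upper = 70, bmi_lower = 14, hr_max = 200,
                           nonpositive_excluded_fields = c(
                             "ivsd", "lvpwd", "lvot_diam",
                             "lvef_biplane", "lvef_a4c", "lvef_a2c",
                             "lvef_teichholz", "lvef_mmode_cube",
                             "lvef_mmode",
                             "mitral_e", "mitral_a", "septal_e_prime",
                             "lateral_e_prime", "e_over_a",
                             "e_over_e_prime", "asc_aorta", "aortic_root",
                             "aov_vmax", "aov_mean_grad", "aov_vti",
                             "aov_area", "lvot_vti", "tr_vmax", "lavi"),
                           lvef_method_priority = c(
                             "lvef_biplane", "lvef_a4c", "lvef_a2c",
                             "lvef_teichholz", "lvef_mmode_cube",
                             "lvef_mmode")) {
  if (!(bmi_lower < bmi_upper)) abort("`bmi_lower` must be < `bmi_upper`.")
  if (hr_max <= 0) abort("`hr_max` must be positive.")
  if (length(lvef_method_priority) == 0 ||
      anyDuplicated(lvef_method_priority)) {
    abort("`lvef_method_priority` must be non-empty without duplicates.")
  }
  structure(list(bmi_upper = bmi_upper, bmi_lower = bmi_lower,
                 hr_max = hr_max,
                 nonpositive_excluded_fields = nonpositive_excluded_fields,
                 lvef_method_priority = lvef_method_priority),
            class = "echo_numeric_config")
}

clean_value <- function(value, provenance, reason = NA_character_) {
  tibble(value = as.numeric(value), provenance = provenance,
         recode_reason = reason)
}

#' Clean a heart-rate field, averaging ranges
#'
#' A single number passes through; a range `"a-b"` (hyphen, en-dash, em-dash
#' or `"to"`) is recoded to the arithmetic mean of its endpoints, so
#' `"120-180"` becomes 150 bpm. Results strictly above `hr_max` are recoded
#' to missing (`out_of_range`); unparseable non-empty strings to missing
#' (`unparseable`).
#'
#' @param raw Character vector of raw heart-rate strings.
#' @param config [numeric_config()].
#' @return Tibble: `value` (bpm), `provenance` (`direct` / `range_mean`),
#'   `recode_reason`.
#' @export
#' @examples
#' clean_heart_rate("120–180")$value  # 150
clean_heart_rate <- function(raw, config = numeric_config()) {
  raw <- as.character(raw)
  n <- length(raw)
  value <- rep(NA_real_, n)
  prov <- rep("direct", n)
  reason <- rep(NA_character_, n)

  blank <- is_blank(raw)
  num <- parse_num(raw)
  direct <- !blank & !is.na(num)
  value[direct] <- num[direct]

  range_pat <- "^\\s*(\\d+(?:\\.\\d+)?)\\s*(?:–|—|-|to)\\s*(\\d+(?:\\.\\d+)?)\\s*$"
  m <- regmatches(raw, regexec(range_pat, raw, perl = TRUE))
  is_range <- !blank & !direct & lengths(m) == 3L
  if (any(is_range)) {
    ends <- t(vapply(m[is_range], function(g) as.numeric(g[2:3]),
                     numeric(2)))
    value[is_range] <- rowMeans(ends)
    prov[is_range] <- "range_mean"
  }

  unpar <- !blank & !direct & !is_range
  reason[unpar] <- "unparseable"
  high <- !is.na(value) & value > config$hr_max
  value[high] <- NA_real_
  reason[high] <- "out_of_range"
  clean_value(value, prov, reason)
}

#' Compute body mass index with unit and transposition handling
#'
#' BMI is weight (kg) divided by height (m) squared. A height above 3 is
#' interpreted as centimetres and divided by 100. Raw pairs that look
#' transposed (raw height in plausible weight range 20-250 and raw weight
#' in plausible height range 1.2-2.2 m) are swapped and flagged,
#' automating what would otherwise be a manual correction. BMI values
#' `>= bmi_upper` or `<= bmi_lower` are recoded to missing.
#'
#' @param height_raw,weight_raw Character vectors of raw values.
#' @param config [numeric_config()].
#' @return Tibble: `height` (m), `weight` (kg), `bmi`, `provenance`,
#'   `recode_reason`, `transposed` (logical flag for review).
#' @export
#' @examples
#' compute_bmi("80", "1.8")$transposed  # TRUE: swapped then BMI 24.7
compute_bmi <- function(height_raw, weight_raw, config = numeric_config()) {
  h <- parse_num(height_raw)
  w <- parse_num(weight_raw)
  swapped <- !is.na(h) & !is.na(w) &
    h >= 20 & h <= 250 & w >= 1.2 & w <= 2.2
  tmp <- h[swapped]
  h[swapped] <- w[swapped]
  w[swapped] <- tmp

  cm <- !is.na(h) & h > 3
  h[cm] <- h[cm] / 100

  bmi <- w / h^2
  reason <- rep(NA_character_, length(bmi))
  out <- !is.na(bmi) &
    (bmi >= config$bmi_upper | bmi <= config$bmi_lower)
  bmi[out] <- NA_real_
  reason[out] <- "out_of_range"
  reason[swapped & !out] <- "transposed_corrected"
  tibble(height = h, weight = w, bmi = bmi,
         provenance = ifelse(swapped | cm, "computed", "computed"),
         recode_reason = reason, transposed = swapped)
}

#' Recode impossible (non-positive) values to missing
#'
#' For measurements that cannot physically be zero or negative (wall
#' thicknesses, velocities, diameters, ...), a parseable value `<= 0` is
#' recoded to missing with reason `nonpositive`.
#'
#' @param raw Character vector of raw values.
#' @param field Field name; must be listed in
#'   `config$nonpositive_excluded_fields`.
#' @param config [numeric_config()].
#' @return Clean-value tibble.
#' @export
#' @examples
#' clean_positive("-1.1", "ivsd")$recode_reason  # "nonpositive"
clean_positive <- function(raw, field, config = numeric_config()) {
  if (!field %in% config$nonpositive_excluded_fields) {
    abort(paste0("Field '", field,
                 "' is not listed in `nonpositive_excluded_fields`."))
  }
  raw <- as.character(raw)
  blank <- is_blank(raw)
  num <- parse_num(raw)
  value <- num
  reason <- rep(NA_character_, length(raw))
  nonpos <- !is.na(num) & num <= 0
  value[nonpos] <- NA_real_
  reason[nonpos] <- "nonpositive"
  unpar <- !blank & is.na(num)
  reason[unpar] <- "unparseable"
  clean_value(value, "direct", reason)
}

#' Select LVEF by method hierarchy
#'
#' Several techniques can measure left ventricular ejection fraction; when
#' more than one was recorded the most trusted available method is used,
#' in the order: modified biplane, modified apical four chamber, modified
#' apical two chamber, Teichholz 2D, M-mode cube, M-mode.
#'
#' @param measurements A named list / named numeric vector of method ->
#'   value (already cleaned; `NA` allowed), or a data frame whose columns
#'   are method names (one row per study).
#' @param config [numeric_config()]; `lvef_method_priority` defines both
#'   the admissible method names and their order.
#' @return Clean-value tibble (provenance `hierarchy_selected`), one row
#'   per study.
#' @export
#' @examples
#' select_lvef(c(lvef_teichholz = 55, lvef_biplane = 48))$value  # 48
select_lvef <- function(measurements, config = numeric_config()) {
  pr <- config$lvef_method_priority
  if (is.data.frame(measurements)) {
    unknown <- setdiff(names(measurements), pr)
    if (length(unknown)) {
      abort(paste0("Unknown LVEF method(s): ",
                   paste(unknown, collapse = ", ")))
    }
    present <- intersect(pr, names(measurements))
    if (length(present) == 0) {
      return(clean_value(rep(NA_real_, nrow(measurements)),
                         "hierarchy_selected"))
    }
    cols <- lapply(present, function(p) as.numeric(measurements[[p]]))
    value <- Reduce(function(a, b) ifelse(is.na(a), b, a), cols)
    return(clean_value(value, "hierarchy_selected"))
  }
  measurements <- unlist(measurements)
  unknown <- setdiff(names(measurements), pr)
  if (length(unknown)) {
    abort(paste0("Unknown LVEF method(s): ",
                 paste(unknown, collapse = ", ")))
  }
  for (p in pr) {
    if (p %in% names(measurements) && !is.na(measurements[[p]])) {
      return(clean_value(measurements[[p]], "hierarchy_selected"))
    }
  }
  clean_value(NA_real_, "hierarchy_selected")
}

#' Extract right ventricular systolic pressure
#'
#' The direct numeric RVSP field is prioritised as the final result; when
#' it is empty, the free text is scanned and the last number immediately
#' preceding "mmHg" (any case, optional whitespace) is extracted. Values
#' recovered from text are flagged for audit review.
#'
#' @param numeric_field Character vector of the raw numeric RVSP field.
#' @param free_text Character vector of the RVSP free-text section.
#' @return Tibble: `value` (mmHg), `provenance`
#'   (`direct` / `text_extracted`), `recode_reason`, `flagged` (logical:
#'   text-extracted values for review).
#' @export
#' @examples
#' extract_rvsp("", "estimated RVSP of 42 mmHg plus RA pressure")$value
extract_rvsp <- function(numeric_field, free_text) {
  numeric_field <- as.character(numeric_field)
  free_text <- as.character(free_text)
  n <- max(length(numeric_field), length(free_text))
  numeric_field <- rep_len(numeric_field, n)
  free_text <- rep_len(free_text, n)

  num <- parse_num(numeric_field)
  value <- num
  prov <- rep("direct", n)
  flagged <- rep(FALSE, n)

  need <- is.na(num) & !is_blank(free_text)
  if (any(need)) {
    pat <- "(\\d+(?:\\.\\d+)?)\\s*mmhg"
    mm <- gregexpr(pat, free_text[need], ignore.case = TRUE, perl = TRUE)
    txt <- regmatches(free_text[need], mm)
    got <- vapply(txt, function(v) {
      if (length(v) == 0) NA_real_ else {
        parse_num(sub("(?i)\\s*mmhg", "", tail(v, 1), perl = TRUE))
      }
    }, numeric(1))
    idx <- which(need)
    value[idx] <- got
    ok <- idx[!is.na(got)]
    prov[ok] <- "text_extracted"
    flagged[ok] <- TRUE
  }
  tibble(value = value, provenance = prov,
         recode_reason = NA_character_, flagged = flagged)
}
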