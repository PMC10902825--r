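# Declarative phrase-rule engine: ordered, case-insensitive rules mapping
# free-text report sections to categorical levels. Rules are data, not code,
# so a laboratory can re-tune phrase banks without editing the package.

#' Create a single phrase rule
#'
#' A phrase rule maps a text pattern to a category level. Rules are
#' evaluated in priority order (lower first) and the first match wins.
#' `direct` rules are precise patterns (typically severity adjacent to the
#' lesion word); `catch_all` rules are looser co-occurrence searches and are
#' always evaluated after every direct rule, so that e.g. a text containing
#' "mild regurgitation" is graded mild before a moderate catch-all can see
#' the word "moderate" elsewhere in the sentence.
#'
#' @param id Short identifier used in audit output.
#' @param pattern For `whole_text` scope, a case-insensitive Perl regular
#'   expression. For `sentence` scope, one or more regular expressions
#'   separated by `" & "`; all must match within a single sentence
#'   (sentences are delimited by `.`, `;` or newline).
#' @param level Target category level.
#' @param priority Integer; lower values are evaluated first.
#' @param scope `"whole_text"` or `"sentence"`.
#' @param kind `"direct"` or `"catch_all"`.
#' @return A one-row tibble.
#' @export
#' @examples
#' phrase_rule("mr_mod", "moderate & regurgitation", "moderate", 40,
#'             scope = "sentence", kind = "catch_all")
phrase_rule <- function(id, pattern, level, priority,
                        scope = c("whole_text", "sentence"),
                        kind = c("direct", "catch_all")) {
  scope <- match.arg(scope)
  kind <- match.arg(kind)
  if (!nzchar(pattern)) abort("`pattern` must be non-empty.")
  tibble::tibble(id = id, pattern = pattern, level = level,
                 priority = as.integer(priority), scope = scope, kind = kind)
}

#' Assemble an ordered rule set for one categorical variable
#'
#' @param variable Variable name (used in audit output).
#' @param levels Character vector of admissible levels. May include the
#'   sentinel `"exclude"` for records that are dropped from analyses of
#'   this variable (e.g. very rare aortic valve morphologies).
#' @param default Level assigned when no rule fires (including empty text).
#' @param rules A tibble of rules, e.g. built with [phrase_rule()] and
#'   `dplyr::bind_rows()`.
#' @return An object of class `echo_ruleset`.
#' @details Invariants enforced: priorities unique; every rule level is in
#'   `levels`; all `direct` rules precede all `catch_all` rules once sorted
#'   by priority.
#' @export
rule_set <- function(variable, levels, default, rules) {
  rules <- dplyr::arrange(as_tibble(rules), .data$priority)
  if (anyDuplicated(rules$priority)) {
    abort(paste0("Duplicate rule priorities in rule set '", variable, "'."))
  }
  if (!default %in% levels) {
    abort(paste0("Default level '", default, "' not in declared levels for '",
                 variable, "'."))
  }
  bad <- setdiff(unique(rules$level), levels)
  if (length(bad)) {
    abort(paste0("Rule levels not in declared level set for '", variable,
                 "': ", paste(bad, collapse = ", ")))
  }
  kinds <- rules$kind
  if (any(kinds == "catch_all")) {
    first_catch <- match("catch_all", kinds)
    if (any(kinds[seq_len(nrow(rules)) >= first_catch] == "direct")) {
      abort(paste0("Direct rules must all precede catch-all rules in '",
                   variable, "'."))
    }
  }
  structure(list(variable = variable, levels = levels, default = default,
                 rules = rules),
            class = "echo_ruleset")
}

#' @export
print.echo_ruleset <- function(x, ...) {
  cat("<echo_ruleset> ", x$variable, "\n", sep = "")
  cat("  levels:  ", paste(x$levels, collapse = " < "), "\n", sep = "")
  cat("  default: ", x$default, "\n", sep = "")
  print(x$rules, n = Inf)
  invisible(x)
}

#' Classify free text against a rule set
#'
#' Evaluates the rules of `ruleset` in priority order against each element
#' of `text`; the first matching rule assigns the level. Sentence-scope
#' rules split the text on `.`, `;` and newlines and require all of the
#' rule's `&`-separated patterns to match within one sentence. Texts that
#' match no rule (including empty or `NA` text) receive the default level.
#' Matching is case-insensitive; classification is a pure function of
#' `(text, ruleset)`.
#'
#' @param text Character vector of report-section texts.
#' @param ruleset An [rule_set()] object.
#' @return A tibble with one row per text: `level`, `matched_rule` (rule id
#'   or `"DEFAULT"`), `matched_span` (the matched fragment, `NA` for
#'   default).
#' @export
#' @examples
#' rs <- default_rule_sets()$lv_function
#' classify("Systolic function appears within normal limits", rs)$level
classify <- function(text, ruleset) {
  stopifnot(inherits(ruleset, "echo_ruleset"))
  text <- as.character(text)
  text[is.na(text)] <- ""
  n <- length(text)
  level <- rep(NA_character_, n)
  rule_id <- rep(NA_character_, n)
  span <- rep(NA_character_, n)
  undecided <- rep(TRUE, n)

  sent <- NULL     # lazily built flat sentence table
  sent_idx <- NULL

  rules <- ruleset$rules
  for (i in seq_len(nrow(rules))) {
    if (!any(undecided)) break
    pat <- rules$pattern[i]
    if (rules$scope[i] == "whole_text") {
      hit <- undecided & re_detect(text, pat)
      if (any(hit)) span[hit] <- re_extract(text[hit], pat)
    } else {
      if (is.null(sent)) {
        pieces <- split_sentences(text)
        sent <- unlist(pieces, use.names = FALSE)
        sent_idx <- rep(seq_len(n), lengths(pieces))
      }
      toks <- strsplit(pat, "\\s*&\\s*")[[1]]
      ok <- rep(TRUE, length(sent))
      for (tk in toks) ok <- ok & re_detect(sent, tk)
      hit_idx <- unique(sent_idx[ok])
      hit <- rep(FALSE, n)
      hit[hit_idx] <- TRUE
      hit <- hit & undecided
      if (any(hit)) {
        # extract span from the first matching sentence of each hit text
        for (j in which(hit)) {
          s <- sent[sent_idx == j & ok][1]
          span[j] <- re_extract(s, toks[1])
        }
      }
    }
    level[hit] <- rules$level[i]
    rule_id[hit] <- rules$id[i]
    undecided[hit] <- FALSE
  }
  level[undecided] <- ruleset$default
  rule_id[undecided] <- "DEFAULT"
  tibble(level = level, matched_rule = rule_id, matched_span = span)
}

# ---------------------------------------------------------------------------
# Rule-set builders. Severity patterns are shared across valve lesions; the
# compound grades (mild-to-moderate, moderate-to-severe) always precede the
# simple grades because the simple adjective is a substring of the compound.

sev_order <- function() {
  c("moderate-to-severe", "mild-to-moderate", "severe", "moderate", "mild")
}

# Regex core for a severity adjective (word-bounded; compounds allow "-"
# or space around "to").
sev_adj <- function(s) {
  switch(s,
    "mild-to-moderate" = "\\bmild[- ]to[- ]moderate\\b",
    "moderate-to-severe" = "\\bmoderate[- ]to[- ]severe\\b",
    paste0("\\b", s, "\\b"))
}

# Adverbial form used for function grading ("moderately impaired").
sev_adv <- function(s) {
  switch(s,
    "mild-to-moderate" = "\\bmild[- ]to[- ]moderately\\b",
    "moderate-to-severe" = "\\bmoderate[- ]to[- ]severely\\b",
    "mild" = "\\bmildly\\b", "moderate" = "\\bmoderately\\b",
    "severe" = "\\bseverely\\b")
}

# Severity grading of a regurgitant lesion. Direct rules demand the
# severity within two words of a regurgitation term; the catch-alls only
# require co-occurrence in a sentence.
regurg_rule_set <- function(variable, abbrev) {
  lesion <- paste0("(?:regurgitation|\\b", abbrev, "\\b)")
  near <- "\\s+(?:\\w+\\s+){0,2}"
  rules <- list(phrase_rule(
    paste0(variable, "_none"),
    paste0("(?:\\bno\\b|\\btrivial\\b|\\btrace\\b)", near, lesion),
    "none", 10
  ))
  p <- 20L
  for (s in sev_order()) {
    rules <- c(rules, list(phrase_rule(
      paste0(variable, "_", s),
      paste0(sev_adj(s), near, lesion), s, p)))
    p <- p + 10L
  }
  for (s in sev_order()) {
    rules <- c(rules, list(phrase_rule(
      paste0(variable, "_", s, "_ca"),
      paste0(sev_adj(s), " & ", lesion), s, p,
      scope = "sentence", kind = "catch_all")))
    p <- p + 10L
  }
  rule_set(variable, severity_levels(), "none", dplyr::bind_rows(rules))
}

# Severity grading of a stenotic lesion (no sclerosis/replacement layer).
stenosis_rule_set <- function(variable, abbrev = NULL) {
  lesion <- "(?:stenosis)"
  if (!is.null(abbrev)) {
    lesion <- paste0("(?:stenosis|\\b", abbrev, "\\b)")
  }
  near <- "\\s+(?:\\w+\\s+){0,2}"
  rules <- list(phrase_rule(
    paste0(variable, "_none"),
    paste0("\\bno\\b", near, lesion), "none", 10))
  p <- 20L
  for (s in sev_order()) {
    rules <- c(rules, list(phrase_rule(
      paste0(variable, "_", s),
      paste0(sev_adj(s), near, lesion), s, p)))
    p <- p + 10L
  }
  for (s in sev_order()) {
    rules <- c(rules, list(phrase_rule(
      paste0(variable, "_", s, "_ca"),
      paste0(sev_adj(s), " & ", lesion), s, p,
      scope = "sentence", kind = "catch_all")))
    p <- p + 10L
  }
  rule_set(variable, severity_levels(), "none", dplyr::bind_rows(rules))
}

# Calcific aortic valve disease: replacement terms first (so "AVR, no
# stenosis" codes AVR), then explicit severity, then thickening/sclerosis,
# then default none. The sclerosis layer sits after the severity
# catch-alls so "severe stenosis of a thickened valve" grades severe.
aortic_stenosis_rule_set <- function() {
  near <- "\\s+(?:\\w+\\s+){0,2}"
  lesion <- "(?:stenosis|\\bAS\\b)"
  rules <- list(
    phrase_rule("as_avr",
                paste0("\\bAVR\\b|\\bTAVI\\b|\\bSAVR\\b|prosthe\\w*|",
                       "valve replacement"),
                "AVR", 5),
    phrase_rule("as_none", paste0("\\bno\\b", near, lesion), "none", 10)
  )
  p <- 20L
  for (s in sev_order()) {
    rules <- c(rules, list(phrase_rule(
      paste0("as_", s), paste0(sev_adj(s), near, lesion), s, p)))
    p <- p + 10L
  }
  for (s in sev_order()) {
    rules <- c(rules, list(phrase_rule(
      paste0("as_", s, "_ca"), paste0(sev_adj(s), " & ", lesion), s, p,
      scope = "sentence", kind = "catch_all")))
    p <- p + 10L
  }
  rules <- c(rules, list(phrase_rule(
    "as_sclerosis", "thicken\\w*|sclero\\w*", "sclerosis", p,
    kind = "catch_all")))
  rule_set("aortic_stenosis", stenosis_av_levels(), "none",
           dplyr::bind_rows(rules))
}

# Ventricular systolic function ("mildly and globally impaired",
# "moderate decrease in systolic function", ...).
function_rule_set <- function(variable) {
  level_of <- function(s) paste0(
    sub("mild-to-moderate", "mild-to-moderately",
        sub("moderate-to-severe", "moderate-to-severely",
            sub("^(mild|moderate|severe)$", "\\1ly", s))), " impaired")
  impair_adj <- "(?:decrease|reduction|impairment)"
  rules <- list()
  p <- 10L
  for (s in sev_order()) {
    pat <- paste0(
      sev_adv(s), "\\s+(?:and\\s+\\w+\\s+)?(?:impaired|reduced)",
      "|", sev_adj(s), "\\s+", impair_adj)
    rules <- c(rules, list(phrase_rule(
      paste0(variable, "_", s), pat, level_of(s), p)))
    p <- p + 10L
  }
  rules <- c(rules, list(phrase_rule(
    paste0(variable, "_normal"),
    paste0("within normal limits|normal\\s+(?:\\w+\\s+){0,2}function",
           "|function\\s+is\\s+normal|preserved"),
    "normal", p)))
  p <- p + 10L
  # redundant co-occurrence routes: classification survives a typo in any
  # single supporting word (only the grade word itself is irreplaceable)
  for (s in sev_order()) {
    rules <- c(rules, list(phrase_rule(
      paste0(variable, "_", s, "_ca"),
      paste0("(?:", sev_adv(s), "|", sev_adj(s), ")",
             " & ",
             "impair\\w*|reduc\\w*|decreas\\w*|dysfunc\\w*|function|systolic"),
      level_of(s), p, scope = "sentence", kind = "catch_all")))
    p <- p + 10L
  }
  rules <- c(rules, list(phrase_rule(
    paste0(variable, "_normal_ca"),
    "\\bnormal\\b & function|systolic|limits",
    "normal", p, scope = "sentence", kind = "catch_all")))
  rule_set(variable, function_levels(), "not stated", dplyr::bind_rows(rules))
}

# Chamber size ("mildly dilated", "normal in size").
chamber_size_rule_set <- function(variable) {
  rules <- list()
  p <- 10L
  for (s in sev_order()) {
    pat <- paste0(sev_adv(s), "\\s+(?:dilated|enlarged)",
                  "|", sev_adj(s), "\\s+(?:dilatation|dilation|enlargement)")
    # compound adverbs are rare for size but harmless to accept
    rules <- c(rules, list(phrase_rule(
      paste0(variable, "_", s), pat, s, p)))
    p <- p + 10L
  }
  rules <- c(rules, list(phrase_rule(
    paste0(variable, "_normal"),
    paste0("normal\\s+(?:in\\s+)?size|not\\s+dilated",
           "|normal\\s+(?:\\w+\\s+){0,2}(?:size|dimensions|cavity)"),
    "normal", p)))
  p <- p + 10L
  # chamber words as redundant co-occurrence anchors (see function sets)
  anchors <- "dilat\\w*|enlarg\\w*|cavity|size|ventricle|atrium|atrial"
  for (s in sev_order()) {
    rules <- c(rules, list(phrase_rule(
      paste0(variable, "_", s, "_ca"),
      paste0("(?:", sev_adv(s), "|", sev_adj(s), ")", " & ", anchors),
      s, p, scope = "sentence", kind = "catch_all")))
    p <- p + 10L
  }
  rules <- c(rules, list(phrase_rule(
    paste0(variable, "_normal_ca"),
    paste0("\\bnormal\\b & ", anchors, "|\\bRV\\b|\\bLV\\b|\\bLA\\b"),
    "normal", p, scope = "sentence", kind = "catch_all")))
  lv <- union(size_levels(), sev_order())
  rule_set(variable, lv, "not stated", dplyr::bind_rows(rules))
}

mac_rule_set <- function() {
  rule_set("mac", binary_levels(), "none", dplyr::bind_rows(
    phrase_rule("mac_none",
                "\\bno\\b\\s+(?:\\w+\\s+){0,2}calcification|no MAC",
                "none", 10),
    phrase_rule("mac_present",
                paste0("annular calcification|\\bMAC\\b|",
                       "calcified\\s+(?:\\w+\\s+){0,2}annulus|",
                       "annulus\\s+is\\s+calcified"),
                "present", 20)
  ))
}

prolapse_rule_set <- function() {
  rule_set("mitral_prolapse", binary_levels(), "none", dplyr::bind_rows(
    phrase_rule("prolapse_none", "\\bno\\b\\s+(?:\\w+\\s+){0,2}prolapse",
                "none", 10),
    phrase_rule("prolapse_present", "prolaps\\w*", "present", 20)
  ))
}

# Aortic valve morphology: a reported bicuspid valve always wins; very rare
# morphologies are excluded; anything else (normal or unstated structure)
# is taken as tricuspid, because a bicuspid valve is a clinically
# significant finding that would not go unreported.
av_morphology_rule_set <- function() {
  rule_set("av_morphology", morphology_levels(), "tricuspid",
    dplyr::bind_rows(
      phrase_rule("morph_bicuspid", "bicuspid", "bicuspid", 10),
      phrase_rule("morph_rare", "unicuspid|quadricuspid", "exclude", 20),
      phrase_rule("morph_tricuspid", "tricuspid|trileaflet|three[- ]leaflet",
                  "tricuspid", 30)
    ))
}

# Prioritised cardiac rhythm: first match in clinical priority order.
rhythm_rule_set <- function() {
  rule_set("rhythm", rhythm_levels(), "uncertain", dplyr::bind_rows(
    phrase_rule("rhythm_paced",
                "paced|pacemaker|pacing|\\bventricularly\\b",
                "artificially paced", 10),
    phrase_rule("rhythm_svt",
                "supraventricular|\\bSVT\\b|\\btachycardia\\b",
                "supraventricular tachycardia", 20),
    phrase_rule("rhythm_flutter", "flutter", "atrial flutter", 30),
    phrase_rule("rhythm_af",
                "fibrillation|\\bAF\\b|\\ba[- ]?fib\\b",
                "atrial fibrillation", 40),
    phrase_rule("rhythm_block",
                "heart block|\\bAV block\\b|degree\\s+\\bAV\\b|\\bCHB\\b",
                "heart block", 50),
    phrase_rule("rhythm_sinus", "sinus", "sinus rhythm", 60),
    phrase_rule("rhythm_other", "junctional|nodal|ectopic|idioventricular",
                "other", 70)
  ))
}

# Bundle branch block, extracted independently of rhythm. Left/right
# patterns precede the unspecified pattern because "LBBB" contains "BBB".
bbb_rule_set <- function() {
  rule_set("bbb", bbb_levels(), "no BBB", dplyr::bind_rows(
    phrase_rule("bbb_left", "\\bLBBB\\b|left bundle", "left BBB", 10),
    phrase_rule("bbb_right", "\\bRBBB\\b|right bundle", "right BBB", 20),
    phrase_rule("bbb_unspec", "\\bBBB\\b|bundle branch block",
                "BBB (unspecified)", 30)
  ))
}

la_size_rule_set <- function() {
  rs <- chamber_size_rule_set("la_size")
  rs$variable <- "la_size"
  rs
}

#' Default rule sets for every free-text variable
#'
#' One [rule_set()] per categorical variable in the cleaning schema. These
#' encode the laboratory phrase conventions that the package ships with;
#' they are data, and are expected to be re-tuned against a local phrase
#' inventory via the iterate-and-revalidate workflow (classify, inspect
#' disagreements with [validate_extraction()], edit rules, repeat).
#'
#' @return Named list of `echo_ruleset` objects.
#' @export
#' @examples
#' names(default_rule_sets())
default_rule_sets <- function() {
  list(
    aortic_stenosis = aortic_stenosis_rule_set(),
    aortic_regurgitation = regurg_rule_set("aortic_regurgitation", "AR"),
    av_morphology = av_morphology_rule_set(),
    mitral_stenosis = stenosis_rule_set("mitral_stenosis", "MS"),
    mac = mac_rule_set(),
    mitral_regurgitation = regurg_rule_set("mitral_regurgitation", "MR"),
    mitral_prolapse = prolapse_rule_set(),
    tricuspid_regurgitation = regurg_rule_set("tricuspid_regurgitation", "TR"),
    pulmonary_stenosis = stenosis_rule_set("pulmonary_stenosis", "PS"),
    pulmonary_regurgitation = regurg_rule_set("pulmonary_regurgitation", "PR"),
    lv_size = chamber_size_rule_set("lv_size"),
    lv_function = function_rule_set("lv_function"),
    la_size = la_size_rule_set(),
    rv_size = chamber_size_rule_set("rv_size"),
    rv_function = function_rule_set("rv_function"),
    rhythm = rhythm_rule_set(),
    bbb = bbb_rule_set()
  )
}

# ---------------------------------------------------------------------------
# Convenience wrappers for the variables with bespoke contracts.

#' Grade calcific aortic valve disease from the aortic-valve text
#'
#' Replacement terms (AVR, prosthesis, valve replacement) are checked
#' first, so "AVR, no stenosis" codes AVR; explicit severities come next
#' (so "severe stenosis of a thickened valve" grades severe); any mention
#' of thickening or sclerosis then codes sclerosis; otherwise none.
#'
#' @param text Character vector (aortic-valve section).
#' @param ruleset Rule set; defaults to the shipped one.
#' @return Character vector of levels.
#' @export
#' @examples
#' classify_aortic_stenosis("valve is thickened with no significant gradient")
classify_aortic_stenosis <- function(text,
                                     ruleset = default_rule_sets()$aortic_stenosis) {
  classify(text, ruleset)$level
}

#' Grade valve regurgitation from free text
#'
#' Direct adjacency patterns ("moderate regurgitation", "mild MR") are
#' evaluated before sentence-scope catch-alls, so "mild regurgitation and
#' moderate stenosis" grades mild.
#'
#' @param text Character vector (valve section).
#' @param valve One of `"aortic"`, `"mitral"`, `"tricuspid"`, `"pulmonary"`.
#' @param rules Optional list of rule sets (as [default_rule_sets()]).
#' @return Character vector of severity levels.
#' @export
classify_regurgitation <- function(text,
                                   valve = c("aortic", "mitral",
                                             "tricuspid", "pulmonary"),
                                   rules = default_rule_sets()) {
  valve <- match.arg(valve)
  classify(text, rules[[paste0(valve, "_regurgitation")]])$level
}

#' Classify aortic valve morphology
#'
#' @inheritParams classify_aortic_stenosis
#' @return Character vector over `"bicuspid"`, `"tricuspid"`, `"exclude"`
#'   (rare morphologies: the study is excluded from morphology analyses).
#' @export
classify_av_morphology <- function(text,
                                   ruleset = default_rule_sets()$av_morphology) {
  classify(text, ruleset)$level
}

#' Classify cardiac rhythm and bundle branch block
#'
#' The prioritised rhythm takes the highest-priority match in the order:
#' artificially paced, supraventricular tachycardia, atrial flutter,
#' atrial fibrillation, heart block, sinus rhythm, other, uncertain.
#' Bundle branch block is extracted independently.
#'
#' @param text Character vector (rhythm field).
#' @param rules Optional list of rule sets.
#' @return Tibble with columns `rhythm`, `bbb`.
#' @export
#' @examples
#' classify_rhythm("AF with LBBB")
classify_rhythm <- function(text, rules = default_rule_sets()) {
  tibble(rhythm = classify(text, rules$rhythm)$level,
         bbb = classify(text, rules$bbb)$level)
}

#' Grade left atrial size, preferring free text over the indexed volume
#'
#' The free-text interpretation is the clinically used value and is
#' preferred; when the text yields no level, the left atrial volume index
#' (LAVi) is binned per configured guideline thresholds.
#'
#' @param text Character vector (left-atrium section).
#' @param lavi Optional numeric LAVi (mL/m^2), recycled to length of text.
#' @param thresholds Named numeric vector `c(normal=, mild=, moderate=)`:
#'   upper inclusive bounds of the normal, mild and moderate bins; values
#'   above the moderate bound grade severe.
#' @param ruleset Rule set for the text pass.
#' @return Character vector of levels (`"not stated"` when neither source
#'   is informative).
#' @export
#' @examples
#' classify_la_size("", lavi = 45)
classify_la_size <- function(text, lavi = NULL,
                             thresholds = c(normal = 34, mild = 41,
                                            moderate = 48),
                             ruleset = default_rule_sets()$la_size) {
  res <- classify(text, ruleset)$level
  if (is.null(lavi)) return(res)
  lavi <- rep_len(as.numeric(lavi), length(res))
  fallback <- res == "not stated" & !is.na(lavi)
  binned <- cut(lavi,
                breaks = c(-Inf, thresholds[["normal"]], thresholds[["mild"]],
                           thresholds[["moderate"]], Inf),
                labels = c("normal", "mild", "moderate", "severe"),
                right = TRUE)
  res[fallback] <- as.character(binned[fallback])
  res
}

#' Flag study indications
#'
#' One binary flag per indication category; a study can carry several.
#'
#' @param text Character vector (indication section).
#' @param categories Named list: category -> character vector of
#'   case-insensitive regular expressions.
#' @return Tibble of logicals, one column per category (prefixed `ind_`).
#' @export
#' @examples
#' flag_indications("murmur, query aortic stenosis")
flag_indications <- function(text, categories = default_indication_categories()) {
  text <- as.character(text)
  text[is.na(text)] <- ""
  out <- lapply(categories, function(pats) {
    hit <- rep(FALSE, length(text))
    for (p in pats) hit <- hit | re_detect(text, p)
    hit
  })
  names(out) <- paste0("ind_", names(categories))
  as_tibble(out)
}

#' Default indication categories
#'
#' A compact category map in the spirit of laboratory indication lists;
#' extensible configuration, not a canonical inventory.
#'
#' @return Named list: category -> patterns.
#' @export
default_indication_categories <- function() {
  list(
    murmur = c("murmur"),
    valve_assessment = c("valve", "stenosis", "regurgitation",
                         "\\bAS\\b", "\\bAR\\b", "\\bMR\\b"),
    heart_failure = c("heart failure", "\\bCHF\\b", "dyspnoea",
                      "shortness of breath", "\\bSOB\\b", "oedema"),
    arrhythmia = c("atrial fibrillation", "palpitation", "arrhythmia",
                   "tachycardia", "\\bAF\\b"),
    preoperative = c("pre[- ]?op\\b", "preoperative", "prior to surgery"),
    follow_up = c("follow[- ]?up", "surveillance", "serial stud")
  )
}

# ---------------------------------------------------------------------------
# Rule sets as editable configuration files (one YAML document per list).

#' Write / read rule sets as a YAML configuration file
#'
#' The on-disk form is human-editable: one entry per variable with its
#' level set, default level and ordered rules.
#'
#' @param rules Named list of [rule_set()] objects.
#' @param path File path.
#' @return `write_rule_sets()` returns `path` invisibly;
#'   `read_rule_sets()` returns the named list of rule sets.
#' @export
write_rule_sets <- function(rules, path) {
  doc <- lapply(rules, function(rs) {
    list(variable = rs$variable, levels = rs$levels, default = rs$default,
         rules = lapply(seq_len(nrow(rs$rules)), function(i) {
           as.list(rs$rules[i, , drop = FALSE])
         }))
  })
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_rule_sets
#' @export
read_rule_sets <- function(path) {
  doc <- yaml::read_yaml(path)
  out <- lapply(doc, function(d) {
    rules <- dplyr::bind_rows(lapply(d$rules, as_tibble))
    rule_set(d$variable, unlist(d$levels), d$default, rules)
  })
  names(out) <- vapply(out, function(rs) rs$variable, character(1))
  out
}
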