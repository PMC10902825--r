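# Internal helpers shared across modules.

# Parse a raw string field to numeric. Returns NA for empty / unparseable.
parse_num <- function(x) {
  x <- trimws(as.character(x))
  x[x == ""] <- NA_character_
  suppressWarnings(as.numeric(x))
}

is_blank <- function(x) is.na(x) | trimws(as.character(x)) == ""

# Empty audit-log skeleton: one row per recode / classification event.
new_audit <- function() {
  tibble::tibble(
    row_id = integer(), stage = character(), field = character(),
    raw = character(), action = character(), reason = character()
  )
}

audit_rows <- function(row_id, stage, field, raw, action, reason = NA_character_) {
  if (length(row_id) == 0) return(new_audit())
  tibble::tibble(
    row_id = as.integer(row_id), stage = stage, field = field,
    raw = as.character(raw), action = action, reason = reason
  )
}

# Vectorised case-insensitive PCRE detection.
re_detect <- function(x, pattern) {
  out <- grepl(pattern, x, ignore.case = TRUE, perl = TRUE)
  out[is.na(x)] <- FALSE
  out
}

# First match of `pattern` in each element of x (NA where no match).
re_extract <- function(x, pattern) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  m <- regexpr(pattern, x, ignore.case = TRUE, perl = TRUE)
  out <- rep(NA_character_, length(x))
  out[m > 0L] <- regmatches(x, m)
  out
}

# Split free text into sentences on full stop, semicolon, or newline.
split_sentences <- function(x) {
  x[is.na(x)] <- ""
  strsplit(x, "[.;\n]+")
}
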