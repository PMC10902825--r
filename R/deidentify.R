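# Pseudonymisation: every unique patient identifier (e.g. an NHI number)
# is replaced by a random 10-character anonymous ID; the mapping lives in
# a lookup table stored separately from the de-identified data.

# Uppercase letters + digits minus visually ambiguous O/0 and I/1.
anon_alphabet <- function() {
  setdiff(c(LETTERS, as.character(0:9)), c("O", "0", "I", "1"))
}

draw_anon_ids <- function(n, taken = character()) {
  alpha <- anon_alphabet()
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    cand <- vapply(seq_len(need), function(i) {
      paste(sample(alpha, 10, replace = TRUE), collapse = "")
    }, character(1))
    cand <- setdiff(unique(cand), c(taken, out))  # collisions: redraw
    out <- c(out, cand)
  }
  out
}

#' Replace true patient identifiers with anonymous 10-character IDs
#'
#' Generates a random 10-character identifier for each unique value of the
#' identifier column, replaces the column with the anonymous ID, and
#' returns the lookup table linking the two. The lookup is a bijection;
#' identifiers already present in `lookup` keep their existing anonymous
#' ID, so the mapping is stable across runs.
#'
#' @param data Data frame with an identifier column.
#' @param id_col Name of the identifier column (default `"nhi"`).
#' @param lookup Optional existing lookup table (tibble with columns
#'   `true_id`, `anonymous_id`) from a previous run.
#' @param seed Integer seed for the random draw (the draw is local: the
#'   caller's RNG state is restored afterwards).
#' @return List with `data` (identifier column replaced by
#'   `anonymous_id`) and `lookup` (the updated table).
#' @export
#' @examples
#' out <- anonymize(data.frame(nhi = c("ABC1234", "ABC1234", "XYZ9876")),
#'                  seed = 1)
#' nrow(out$lookup)  # 2 unique patients
anonymize <- function(data, id_col = "nhi", lookup = NULL, seed = 1L) {
  if (!id_col %in% names(data)) {
    abort(paste0("Column '", id_col, "' not found."))
  }
  ids <- as.character(data[[id_col]])
  missing_rows <- which(is_blank(ids))
  if (length(missing_rows)) {
    abort(paste0("Missing identifier in row(s): ",
                 paste(head(missing_rows, 20), collapse = ", ")))
  }
  if (is.null(lookup)) {
    lookup <- tibble(true_id = character(), anonymous_id = character())
  }
  validate_lookup(lookup)
  new_ids <- setdiff(unique(ids), lookup$true_id)
  if (length(new_ids)) {
    old <- .Random.seed_exists()
    set.seed(seed)
    drawn <- draw_anon_ids(length(new_ids), taken = lookup$anonymous_id)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    lookup <- bind_rows(lookup,
                        tibble(true_id = new_ids, anonymous_id = drawn))
  }
  anon <- lookup$anonymous_id[match(ids, lookup$true_id)]
  data <- as_tibble(data)
  data[[id_col]] <- NULL
  data <- dplyr::bind_cols(tibble(anonymous_id = anon), data)
  list(data = data, lookup = lookup)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

validate_lookup <- function(lookup) {
  if (!all(c("true_id", "anonymous_id") %in% names(lookup))) {
    abort("Lookup table needs columns `true_id` and `anonymous_id`.")
  }
  if (anyDuplicated(lookup$true_id) || anyDuplicated(lookup$anonymous_id)) {
    abort("Lookup table must be a bijection (no duplicate ids).")
  }
  if (nrow(lookup) && any(nchar(lookup$anonymous_id) != 10L)) {
    abort("All anonymous IDs must have length 10.")
  }
  invisible(lookup)
}

#' Save / load the identifier lookup table
#'
#' The lookup table is written as two-column delimited text and must be
#' stored separately from the de-identified dataset: writing it to the
#' same path as a dataset export is refused.
#'
#' @param lookup Lookup tibble (`true_id`, `anonymous_id`).
#' @param path Destination file.
#' @param data_path Optional path of the de-identified dataset; if equal
#'   to `path` the write is refused.
#' @return `write_lookup()` returns `path` invisibly; `read_lookup()`
#'   returns the lookup tibble.
#' @export
write_lookup <- function(lookup, path, data_path = NULL) {
  validate_lookup(lookup)
  if (!is.null(data_path) &&
      normalizePath(path, mustWork = FALSE) ==
      normalizePath(data_path, mustWork = FALSE)) {
    abort("Refusing to write the lookup table to the dataset path; store it separately.")
  }
  readr::write_csv(lookup, path)
  invisible(path)
}

#' @rdname write_lookup
#' @export
read_lookup <- function(path) {
  lookup <- readr::read_csv(path, col_types = readr::cols(
    true_id = readr::col_character(),
    anonymous_id = readr::col_character()))
  validate_lookup(as_tibble(lookup))
}
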