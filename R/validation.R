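# Validation protocol: seeded random sampling of studies, per-variable
# percent agreement and Cohen's kappa against a gold standard, and the
# mean kappa across indication flags.

#' Simple random sample of studies
#'
#' @param data Data frame.
#' @param n Sample size (without replacement); must not exceed the row
#'   count.
#' @param seed Integer seed; the draw is deterministic and local.
#' @return Tibble of `n` rows.
#' @export
sample_studies <- function(data, n, seed = 1L) {
  if (n > nrow(data)) {
    abort(paste0("Cannot sample ", n, " studies from ", nrow(data),
                 " rows."))
  }
  old <- .Random.seed_exists()
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()), add = TRUE)
  set.seed(seed)
  as_tibble(data[sample.int(nrow(data), n), , drop = FALSE])
}

#' Cohen's kappa between two categorical labelings
#'
#' Chance-corrected agreement: `kappa = (p_o - p_e) / (1 - p_e)` with
#' `p_o` the observed agreement and `p_e` the chance agreement computed
#' from the marginal label frequencies. Pairs with a missing label on
#' either side are dropped (their count is reported as an attribute).
#' When both sequences use one identical label (`p_e = 1`), kappa is
#' defined as 1; an empty comparison gives `NA`.
#'
#' @param a,b Equal-length label vectors.
#' @param weights `"none"` (default, unweighted), `"linear"` or
#'   `"quadratic"`; weighted variants order categories by the sorted union
#'   of observed labels unless `a`/`b` are factors.
#' @param na_as_category If `TRUE`, missing labels are treated as a
#'   category of their own instead of being dropped.
#' @return Kappa in `[-1, 1]`, with attribute `n_dropped`.
#' @export
#' @examples
#' cohen_kappa(rep(c("x", "y"), c(50, 50)),
#'             c(rep("x", 45), rep("y", 5), rep("x", 5), rep("y", 45)))
cohen_kappa <- function(a, b, weights = c("none", "linear", "quadratic"),
                        na_as_category = FALSE) {
  weights <- match.arg(weights)
  if (length(a) != length(b)) {
    abort("`a` and `b` must have equal length.")
  }
  if (is.factor(a) || is.factor(b)) {
    lv <- union(levels(as.factor(a)), levels(as.factor(b)))
  } else lv <- NULL
  a <- as.character(a)
  b <- as.character(b)
  if (na_as_category) {
    a[is.na(a)] <- "<missing>"
    b[is.na(b)] <- "<missing>"
    drop_n <- 0L
  } else {
    keep <- !is.na(a) & !is.na(b)
    drop_n <- sum(!keep)
    a <- a[keep]
    b <- b[keep]
  }
  if (length(a) == 0) {
    return(structure(NA_real_, n_dropped = drop_n))
  }
  if (is.null(lv)) lv <- sort(union(a, b))
  pa <- vapply(lv, function(l) mean(a == l), numeric(1))
  pb <- vapply(lv, function(l) mean(b == l), numeric(1))
  if (weights == "none") {
    po <- mean(a == b)
    pe <- sum(pa * pb)
  } else {
    k <- length(lv)
    d <- abs(outer(seq_len(k), seq_len(k), "-"))
    w <- if (weights == "linear") 1 - d / max(1, k - 1) else {
      1 - (d / max(1, k - 1))^2
    }
    ia <- match(a, lv)
    ib <- match(b, lv)
    po <- mean(w[cbind(ia, ib)])
    pe <- sum(w * outer(pa, pb))
  }
  kap <- if (1 - pe < .Machine$double.eps) {
    if (po >= 1 - 1e-12) 1 else NA_real_
  } else (po - pe) / (1 - pe)
  structure(kap, n_dropped = drop_n)
}

#' Validate the cleaned dataset against a gold standard
#'
#' Implements the validation protocol: draw a seeded random sample of
#' studies, compare each variable to the gold standard, and report
#' percent agreement and Cohen's kappa per variable — the shape of a
#' final validation table. Indication flags are compared per category and
#' summarised by their mean kappa.
#'
#' @param clean Clean data frame keyed by `anonymous_id` + `study_date`
#'   (e.g. `clean_echo_reports(...)$data`).
#' @param gold Gold-standard data frame keyed either the same way or by
#'   `nhi` + `study_date` (supply `lookup` to translate).
#' @param variables Variables to compare; defaults to the standard
#'   validation list. Variables prefixed `ind_` are treated as indication
#'   flags.
#' @param n Number of studies to sample (default 100); capped at the
#'   number of comparable studies.
#' @param seed Sampling seed.
#' @param lookup Optional lookup table used to map the gold standard's
#'   `nhi` to `anonymous_id`.
#' @return Object of class `echo_validation`: list with `results`
#'   (tibble: variable, n_compared, agreement, kappa),
#'   `indication_results`, `indications_mean_kappa`, `sample_size`,
#'   `seed`.
#' @export
validate_extraction <- function(clean, gold,
                                variables = default_validation_variables(),
                                n = 100, seed = 1L, lookup = NULL) {
  gold <- as_tibble(gold)
  clean <- as_tibble(clean)
  if (!"anonymous_id" %in% names(gold)) {
    if (is.null(lookup) || !"nhi" %in% names(gold)) {
      abort("`gold` needs `anonymous_id`, or `nhi` plus a `lookup` table.")
    }
    gold$anonymous_id <- lookup$anonymous_id[match(gold$nhi,
                                                   lookup$true_id)]
  }
  gold$study_date <- as.Date(gold$study_date)
  clean$study_date <- as.Date(clean$study_date)

  ind_vars <- grep("^ind_", variables, value = TRUE)
  plain_vars <- setdiff(variables, ind_vars)
  for (v in c(plain_vars, ind_vars)) {
    for (tb in c("clean", "gold")) {
      if (!v %in% names(get(tb))) {
        abort(paste0("Variable '", v, "' absent from `", tb, "`."))
      }
    }
  }

  joined <- inner_join(clean, gold, by = c("anonymous_id", "study_date"),
                       suffix = c("..clean", "..gold"))
  if (nrow(joined) == 0) abort("No studies shared between clean and gold.")
  n_use <- min(n, nrow(joined))
  smp <- sample_studies(joined, n_use, seed = seed)

  compare_var <- function(v) {
    a <- smp[[paste0(v, "..clean")]] %||% smp[[v]]
    b <- smp[[paste0(v, "..gold")]] %||% smp[[v]]
    a <- as.character(a)
    b <- as.character(b)
    keep <- !is.na(a) & !is.na(b)
    kap <- cohen_kappa(a, b)
    tibble(variable = v, n_compared = sum(keep),
           agreement = if (any(keep)) 100 * mean(a[keep] == b[keep]) else
             NA_real_,
           kappa = as.numeric(kap))
  }
  results <- bind_rows(lapply(plain_vars, compare_var))
  ind_results <- if (length(ind_vars)) {
    bind_rows(lapply(ind_vars, compare_var))
  } else NULL
  mean_kappa <- if (!is.null(ind_results)) {
    mean(ind_results$kappa, na.rm = TRUE)
  } else NA_real_
  if (!is.null(ind_results)) {
    results <- bind_rows(results, tibble(
      variable = "indications",
      n_compared = as.integer(round(mean(ind_results$n_compared))),
      agreement = mean(ind_results$agreement, na.rm = TRUE),
      kappa = mean_kappa))
  }
  structure(list(results = results, indication_results = ind_results,
                 indications_mean_kappa = mean_kappa,
                 sample_size = n_use, seed = seed),
            class = "echo_validation")
}

#' Default validation variable list
#'
#' The per-variable comparison set: valve severities and structure,
#' chamber size/function, demographics, rhythm, plus one `ind_` flag per
#' shipped indication category (summarised as their mean kappa).
#'
#' @return Character vector.
#' @export
default_validation_variables <- function() {
  c("aortic_stenosis", "aortic_regurgitation", "av_morphology",
    "mitral_stenosis", "mac", "mitral_regurgitation",
    "tricuspid_regurgitation", "pulmonary_stenosis",
    "pulmonary_regurgitation", "lv_size", "lv_function", "la_size",
    "rv_size", "rv_function", "sex", "age", "rhythm", "bbb",
    paste0("ind_", names(default_indication_categories())))
}

#' @export
print.echo_validation <- function(x, ...) {
  cat("<echo_validation> n = ", x$sample_size, " sampled studies (seed ",
      x$seed, ")\n\n", sep = "")
  r <- x$results
  r$agreement <- sprintf("%.0f", r$agreement)
  r$kappa <- sprintf("%.2f", r$kappa)
  print(as.data.frame(r), row.names = FALSE)
  invisible(x)
}

#' @rdname validate_extraction
#' @param x An `echo_validation` object.
#' @param ... Unused.
#' @export
tidy.echo_validation <- function(x, ...) {
  x$results
}

#' @rdname validate_extraction
#' @export
glance.echo_validation <- function(x, ...) {
  tibble(n_variables = nrow(x$results),
         sample_size = x$sample_size,
         min_kappa = min(x$results$kappa, na.rm = TRUE),
         mean_kappa = mean(x$results$kappa, na.rm = TRUE),
         min_agreement = min(x$results$agreement, na.rm = TRUE),
         indications_mean_kappa = x$indications_mean_kappa)
}

#' @rdname validate_extraction
#' @param object An `echo_validation` object.
#' @export
autoplot.echo_validation <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::mutate(object$results, agreement = .data$agreement / 100),
    cols = c("agreement", "kappa"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$value,
    y = stats::reorder(.data$variable, .data$value),
    colour = .data$metric)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_continuous(limits = c(min(0.5, min(df$value,
                                                        na.rm = TRUE)), 1)) +
    ggplot2::labs(x = "Agreement (proportion) / Cohen's kappa",
                  y = NULL, colour = NULL,
                  title = "Validation against gold standard") +
    ggplot2::theme_minimal()
}

#' Summaries of a cleaning run
#'
#' `tidy()` returns the audit log; `glance()` a one-row run summary.
#'
#' @param x An `echo_clean_run`.
#' @param ... Unused.
#' @export
tidy.echo_clean_run <- function(x, ...) {
  x$audit
}

#' @rdname tidy.echo_clean_run
#' @export
glance.echo_clean_run <- function(x, ...) {
  tibble(n_input = x$n_input, n_clean = nrow(x$data),
         n_removed_dedupe = x$n_removed_dedupe,
         n_bad_dates = x$n_bad_dates,
         n_audit_events = nrow(x$audit),
         n_patients = nrow(x$lookup))
}
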