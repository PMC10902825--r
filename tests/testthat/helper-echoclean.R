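# Shared fixtures, built in code.

# Generator configuration with every corruption switched off.
quiet_config <- function(n = 50, seed = 1L, ...) {
  args <- list(typo_rate = 0, missing_rate = 0, transposition_rate = 0,
               range_rate = 0, extreme_value_rate = 0,
               repeat_study_rate = 0, cm_height_rate = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(generator_config,
          c(list(n_studies = n, seed = seed), args))
}

# Generate, clean (keeping all studies), and validate against ground truth.
roundtrip <- function(config, n_validate = config$n_studies,
                      val_seed = 1L) {
  ex <- simulate_echo_export(config)
  run <- clean_echo_reports(ex, pipeline_config(dedupe_mode = "keep_all"))
  val <- validate_extraction(run$data, ex$truth, n = n_validate,
                             seed = val_seed, lookup = run$lookup)
  list(export = ex, run = run, val = val)
}

# Independent Cohen's-kappa oracle: builds the full confusion matrix and
# applies the closed form through matrix marginals (distinct route from the
# implementation, which works over label frequencies without a matrix).
kappa_oracle <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  a <- factor(a[keep])
  b <- factor(b[keep], levels = union(levels(a), unique(b[keep])))
  a <- factor(a, levels = levels(b))
  tab <- table(a, b)
  n <- sum(tab)
  if (n == 0) return(NA_real_)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < .Machine$double.eps) {
    return(if (po >= 1 - 1e-12) 1 else NA_real_)
  }
  (po - pe) / (1 - pe)
}
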