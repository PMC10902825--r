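# Variables computed from other cleaned variables: the aortic valve
# dimensionless index, the "any mitral calcification" flag, and the
# guideline two-arm diastolic-function decision tree.

#' Aortic valve dimensionless index
#'
#' LVOT velocity-time integral divided by aortic-valve velocity-time
#' integral; a flow-independent marker of aortic stenosis. Missing inputs
#' propagate.
#'
#' @param lvot_vti,aov_vti Numeric vectors (cleaned, positive or `NA`).
#' @return Numeric vector.
#' @export
#' @examples
#' dimensionless_index(20, 80)  # 0.25
dimensionless_index <- function(lvot_vti, aov_vti) {
  as.numeric(lvot_vti) / as.numeric(aov_vti)
}

#' Any mitral calcification
#'
#' `TRUE` when mitral annular calcification is present or mitral stenosis
#' is graded above none.
#'
#' @param mac Character vector over `"none"` / `"present"`.
#' @param mitral_stenosis Character vector of stenosis severity levels.
#' @return Logical vector.
#' @export
#' @examples
#' any_mitral_calcification("none", "mild")  # TRUE
any_mitral_calcification <- function(mac, mitral_stenosis) {
  mac_pos <- !is.na(mac) & mac == "present"
  ms_pos <- !is.na(mitral_stenosis) &
    !mitral_stenosis %in% c("none", "not stated")
  mac_pos | ms_pos
}

#' Diastolic-function criteria configuration
#'
#' Thresholds of the guideline decision tree. The tree splits on LVEF:
#' studies with LVEF above `lvef_normal_cutoff` are assessed with four
#' criteria (average E/e' above `e_over_e_prime_cutoff`; septal e' below
#' `septal_e_prime_cutoff` cm/s or lateral e' below
#' `lateral_e_prime_cutoff` cm/s; TR Vmax above `tr_vmax_cutoff` m/s; LAVi
#' above `lavi_cutoff` mL/m^2). Studies at or below the cutoff are graded
#' from the mitral inflow pattern (`ea_low`, `ea_high`, `e_low` cm/s) with
#' the remaining criteria resolving the intermediate band.
#'
#' @param lvef_normal_cutoff LVEF (%) above which the normal-EF arm is
#'   used. Default 50.
#' @param e_over_e_prime_cutoff,septal_e_prime_cutoff,lateral_e_prime_cutoff
#'   Tissue-Doppler thresholds.
#' @param tr_vmax_cutoff TR velocity threshold (m/s).
#' @param lavi_cutoff LA volume index threshold (mL/m^2).
#' @param ea_low,ea_high E/A boundaries of the reduced-EF arm.
#' @param e_low Mitral E threshold (cm/s) separating grade I from the
#'   intermediate band when E/A is at or below `ea_low`.
#' @return List of class `echo_diastolic_criteria`.
#' @export
diastolic_criteria <- function(lvef_normal_cutoff = 50,
                               e_over_e_prime_cutoff = 14,
                               septal_e_prime_cutoff = 7,
                               lateral_e_prime_cutoff = 10,
                               tr_vmax_cutoff = 2.8,
                               lavi_cutoff = 34,
                               ea_low = 0.8, ea_high = 2, e_low = 50) {
  vals <- c(lvef_normal_cutoff, e_over_e_prime_cutoff,
            septal_e_prime_cutoff, lateral_e_prime_cutoff, tr_vmax_cutoff,
            lavi_cutoff, ea_low, ea_high, e_low)
  if (any(vals <= 0)) abort("All diastolic criteria must be positive.")
  if (lvef_normal_cutoff >= 100) {
    abort("`lvef_normal_cutoff` must be below 100.")
  }
  structure(list(lvef_normal_cutoff = lvef_normal_cutoff,
                 e_over_e_prime_cutoff = e_over_e_prime_cutoff,
                 septal_e_prime_cutoff = septal_e_prime_cutoff,
                 lateral_e_prime_cutoff = lateral_e_prime_cutoff,
                 tr_vmax_cutoff = tr_vmax_cutoff,
                 lavi_cutoff = lavi_cutoff,
                 ea_low = ea_low, ea_high = ea_high, e_low = e_low),
            class = "echo_diastolic_criteria")
}

#' Assess diastolic function with the two-arm guideline decision tree
#'
#' Takes a data frame of cleaned per-study measurements and returns the
#' diastolic-function level per study.
#'
#' Normal-EF arm (LVEF above the cutoff): the four criteria are counted
#' over those that are evaluable; more than half positive gives
#' `dysfunction`, fewer than half `normal`, exactly half `indeterminate`,
#' and fewer than two evaluable `not assessable`. Reduced-EF arm: E/A at
#' or below `ea_low` with E at or below `e_low` gives `grade I`; E/A at or
#' above `ea_high` gives `grade III`; the intermediate band is resolved by
#' counting the three remaining criteria (majority positive `grade II`,
#' majority negative `grade I`, tie or fewer than two evaluable
#' `indeterminate`). A missing LVEF (or, in the reduced arm, missing E/A)
#' is `not assessable`.
#'
#' @param data Data frame with (any subset of) columns `lvef`,
#'   `e_over_e_prime`, `septal_e_prime`, `lateral_e_prime`, `tr_vmax`,
#'   `lavi`, `e_over_a`, `mitral_e`.
#' @param criteria [diastolic_criteria()].
#' @return Tibble: `level`, `arm` (`normal_ef` / `reduced_ef` / `NA`),
#'   `n_evaluable`, `n_positive`.
#' @export
#' @examples
#' diastolic_function(data.frame(lvef = 60, e_over_e_prime = 10,
#'                               septal_e_prime = 8, tr_vmax = 2.0,
#'                               lavi = 30))$level  # "normal"
diastolic_function <- function(data, criteria = diastolic_criteria()) {
  get_col <- function(nm) {
    if (nm %in% names(data)) as.numeric(data[[nm]]) else {
      rep(NA_real_, nrow(data))
    }
  }
  lvef <- get_col("lvef")
  ee <- get_col("e_over_e_prime")
  se <- get_col("septal_e_prime")
  le <- get_col("lateral_e_prime")
  tr <- get_col("tr_vmax")
  lavi <- get_col("lavi")
  ea <- get_col("e_over_a")
  e <- get_col("mitral_e")

  c1 <- ee > criteria$e_over_e_prime_cutoff
  # e' criterion positive if either wall is below threshold; evaluable if
  # either wall was measured
  c2 <- dplyr::case_when(
    !is.na(se) & se < criteria$septal_e_prime_cutoff ~ TRUE,
    !is.na(le) & le < criteria$lateral_e_prime_cutoff ~ TRUE,
    is.na(se) & is.na(le) ~ NA,
    .default = FALSE
  )
  c3 <- tr > criteria$tr_vmax_cutoff
  c4 <- lavi > criteria$lavi_cutoff

  crit <- cbind(c1, c2, c3, c4)
  n_eval <- rowSums(!is.na(crit))
  n_pos <- rowSums(crit, na.rm = TRUE)

  # support criteria for the intermediate band of the reduced arm (E/e',
  # TR, LAVi)
  crit3 <- cbind(c1, c3, c4)
  n_eval3 <- rowSums(!is.na(crit3))
  n_pos3 <- rowSums(crit3, na.rm = TRUE)

  n <- nrow(data)
  level <- rep("not assessable", n)
  arm <- rep(NA_character_, n)

  normal_arm <- !is.na(lvef) & lvef > criteria$lvef_normal_cutoff
  arm[normal_arm] <- "normal_ef"
  idx <- which(normal_arm)
  lvl <- dplyr::case_when(
    n_eval[idx] < 2 ~ "not assessable",
    n_pos[idx] > n_eval[idx] / 2 ~ "dysfunction",
    n_pos[idx] < n_eval[idx] / 2 ~ "normal",
    .default = "indeterminate"
  )
  level[idx] <- lvl

  reduced <- !is.na(lvef) & lvef <= criteria$lvef_normal_cutoff
  arm[reduced] <- "reduced_ef"
  idx <- which(reduced)
  if (length(idx)) {
    ea_i <- ea[idx]
    e_i <- e[idx]
    inter <- dplyr::case_when(
      n_eval3[idx] < 2 ~ "indeterminate",
      n_pos3[idx] > n_eval3[idx] / 2 ~ "grade II",
      n_pos3[idx] < n_eval3[idx] / 2 ~ "grade I",
      .default = "indeterminate"
    )
    lvl <- dplyr::case_when(
      is.na(ea_i) ~ "not assessable",
      ea_i <= criteria$ea_low & !is.na(e_i) & e_i <= criteria$e_low ~
        "grade I",
      ea_i >= criteria$ea_high ~ "grade III",
      .default = inter
    )
    level[idx] <- lvl
  }

  tibble(level = level, arm = arm,
         n_evaluable = as.integer(n_eval),
         n_positive = as.integer(n_pos))
}
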