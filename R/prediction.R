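#' The 19-segment table
#'
#' Segment counting assumes 19 equal-volume bronchopulmonary segments: 10 on
#' the right (3 upper, 2 middle, 5 lower) and 9 on the left (5 upper, 4
#' lower), each contributing 1/19 = 5.26% of function.
#'
#' @return A tibble with columns `lobe` and `segments`.
#' @examples
#' lung_segment_table()
#' @export
lung_segment_table <- function() {
  tibble(
    lobe = c("RUL", "RML", "RLL", "LUL", "LLL"),
    segments = c(3L, 2L, 5L, 5L, 4L)
  )
}

#' Segments resected with a set of lobes
#'
#' @param resected Character vector of lobe names.
#' @return Total segment count.
#' @examples
#' segments_for("RUL") # 3
#' segments_for(c("LUL", "LLL")) # 9 (the whole left lung)
#' @export
segments_for <- function(resected) {
  tab <- lung_segment_table()
  unknown <- setdiff(resected, tab$lobe)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown lobe(s): %s.", paste(unknown, collapse = ", ")),
      class = "lungflv_spec_error"
    )
  }
  sum(tab$segments[tab$lobe %in% resected])
}

#' Fixed regression coefficients for postoperative spirometry
#'
#' The default coefficients of the linear equations
#' `postFVC  = 0.8   x preFVC  - 0.784 x ΔFLV/FLV + 0.283` (R^2 0.677,
#' residual SD 0.338 L) and
#' `postFEV1 = 0.766 x preFEV1 - 0.694 x ΔFLV/FLV + 0.22` (R^2 0.743,
#' residual SD 0.265 L). Refitted coefficients (e.g. from [ols_fit()]) can
#' be supplied anywhere these defaults are accepted.
#'
#' @param fvc,fev1 Lists with `pre` (slope on the preoperative value),
#'   `delta` (slope on ΔFLV/FLV), `intercept`, `r2`, `rsd`.
#' @return A list of class `flv_reg_coefs`.
#' @export
regression_coefficients <- function(fvc = list(pre = 0.8, delta = -0.784,
                                           intercept = 0.283,
                                           r2 = 0.677, rsd = 0.338),
                                fev1 = list(pre = 0.766, delta = -0.694,
                                            intercept = 0.22,
                                            r2 = 0.743, rsd = 0.265)) {
  for (cf in list(fvc, fev1)) {
    if (cf$rsd < 0 || cf$r2 < 0 || cf$r2 > 1) {
      abort("Residual SD must be >= 0 and R^2 within [0, 1].",
        class = "lungflv_spec_error"
      )
    }
  }
  structure(list(fvc = fvc, fev1 = fev1), class = "flv_reg_coefs")
}

#' Predicted postoperative spirometry by the FLV method
#'
#' Scales the preoperative values by the fraction of functional lung volume
#' remaining: `pre x (1 - resected FLV / total FLV)`.
#'
#' @param pre_fvc,pre_fev1 Preoperative FVC and FEV1 in litres (vectors).
#' @param resected_flv_ml,total_flv_ml Resected and total FLV in mL.
#' @return A tibble with `ppo_fvc_flv`, `ppo_fev1_flv`.
#' @examples
#' ppo_flv(3.0, 2.0, resected_flv_ml = 500, total_flv_ml = 4000)
#' @export
ppo_flv <- function(pre_fvc, pre_fev1, resected_flv_ml, total_flv_ml) {
  check_positive_spiro(pre_fvc, pre_fev1)
  if (any(total_flv_ml <= 0, na.rm = TRUE)) {
    abort("Total FLV must be > 0.", class = "lungflv_spec_error")
  }
  if (any(resected_flv_ml < 0 | resected_flv_ml > total_flv_ml, na.rm = TRUE)) {
    abort("Resected FLV must lie within [0, total FLV].", class = "lungflv_spec_error")
  }
  remaining <- 1 - resected_flv_ml / total_flv_ml
  tibble(ppo_fvc_flv = pre_fvc * remaining, ppo_fev1_flv = pre_fev1 * remaining)
}

#' Predicted postoperative spirometry by segment counting
#'
#' Scales the preoperative values by the fraction of the 19 segments
#' remaining: `pre x (1 - n/19)`. Segment counting does not apply to
#' non-anatomic (wedge) resections; pass `NA` to propagate a missing
#' prediction.
#'
#' @inheritParams ppo_flv
#' @param resected_segments Integer count(s) in 0..19, or `NA`.
#' @return A tibble with `ppo_fvc_sc`, `ppo_fev1_sc`.
#' @examples
#' ppo_sc(3.0, 1.9, resected_segments = segments_for("RUL"))
#' @export
ppo_sc <- function(pre_fvc, pre_fev1, resected_segments) {
  check_positive_spiro(pre_fvc, pre_fev1)
  bad <- !is.na(resected_segments) &
    (resected_segments < 0 | resected_segments > 19)
  if (any(bad)) {
    abort("Resected segment counts must lie in 0..19.", class = "lungflv_spec_error")
  }
  remaining <- 1 - resected_segments / 19
  tibble(ppo_fvc_sc = pre_fvc * remaining, ppo_fev1_sc = pre_fev1 * remaining)
}

#' Predicted postoperative spirometry by the regression equations
#'
#' Evaluates the fixed-coefficient linear forms (no noise is added):
#' `post = pre_slope x pre + delta_slope x ΔFLV/FLV + intercept`.
#'
#' @inheritParams ppo_flv
#' @param delta_flv_ratio Loss ratio(s) in `[0, 1)`.
#' @param coefficients A [regression_coefficients()] object.
#' @return A tibble with `reg_post_fvc`, `reg_post_fev1`.
#' @examples
#' regression_predict(3.0, 2.5, delta_flv_ratio = 0.2)
#' @export
regression_predict <- function(pre_fvc, pre_fev1, delta_flv_ratio,
                               coefficients = regression_coefficients()) {
  stopifnot(inherits(coefficients, "flv_reg_coefs"))
  check_positive_spiro(pre_fvc, pre_fev1)
  if (any(delta_flv_ratio < 0 | delta_flv_ratio >= 1, na.rm = TRUE)) {
    abort("ΔFLV/FLV must lie in [0, 1).", class = "lungflv_spec_error")
  }
  cf <- coefficients
  tibble(
    reg_post_fvc = cf$fvc$pre * pre_fvc + cf$fvc$delta * delta_flv_ratio +
      cf$fvc$intercept,
    reg_post_fev1 = cf$fev1$pre * pre_fev1 + cf$fev1$delta * delta_flv_ratio +
      cf$fev1$intercept
  )
}

check_positive_spiro <- function(pre_fvc, pre_fev1) {
  if (any(pre_fvc <= 0, na.rm = TRUE) || any(pre_fev1 <= 0, na.rm = TRUE)) {
    abort("Preoperative spirometry must be > 0 L.", class = "lungflv_spec_error")
  }
  invisible(TRUE)
}

#' Add all prediction columns to a cohort table
#'
#' Applies the FLV method (where `resected_flv_ml` and `total_flv_ml` are
#' present), segment counting (where `resected_segment_count` is present)
#' and the regression equations (where `delta_flv_ratio` is present),
#' returning the cohort with the prediction columns appended.
#'
#' @param cohort A cohort tibble (see [read_cohort()]).
#' @param methods Subset of `c("flv", "sc", "regression")`.
#' @param coefficients A [regression_coefficients()] object.
#' @return The cohort tibble with prediction columns.
#' @examples
#' cohort <- simulate_cohort(cohort_sim_params(n = 5, seed = 3))
#' predict_cohort(cohort)[, c("id", "ppo_fvc_flv", "ppo_fvc_sc", "reg_post_fvc")]
#' @export
predict_cohort <- function(cohort,
                           methods = c("flv", "sc", "regression"),
                           coefficients = regression_coefficients()) {
  cohort <- validate_cohort(cohort)
  methods <- match.arg(methods, several.ok = TRUE)
  out <- cohort
  if ("flv" %in% methods && all(c("resected_flv_ml", "total_flv_ml") %in% names(cohort))) {
    out <- dplyr::bind_cols(out, ppo_flv(
      cohort$pre_fvc, cohort$pre_fev1,
      cohort$resected_flv_ml, cohort$total_flv_ml
    ))
  }
  if ("sc" %in% methods && "resected_segment_count" %in% names(cohort)) {
    out <- dplyr::bind_cols(out, ppo_sc(
      cohort$pre_fvc, cohort$pre_fev1, cohort$resected_segment_count
    ))
  }
  if ("regression" %in% methods && "delta_flv_ratio" %in% names(cohort)) {
    out <- dplyr::bind_cols(out, regression_predict(
      cohort$pre_fvc, cohort$pre_fev1, cohort$delta_flv_ratio,
      coefficients = coefficients
    ))
  }
  out
}
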