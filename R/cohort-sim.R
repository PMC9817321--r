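#' Parameters of the simulated surgical cohort
#'
#' The simulator reproduces the statistical structure the regression
#' machinery is validated against: preoperative spirometry drawn from
#' truncated Normals (FVC 2.92 +/- 0.59 L, FEV1 2.41 +/- 0.56 L, truncated
#' above 0.5 L), a resected lobe drawn per patient, a functional-volume loss
#' ratio (ΔFLV/FLV) derived from per-lobe FLV shares of total FLV (RUL
#' 20.39%, RML 9.74%, RLL 23.91%, LUL 24.08%, LLL 21.88%), and postoperative
#' spirometry generated by the fixed linear equations
#' `postFVC = 0.8 pre - 0.784 Δ + 0.283` (residual SD 0.338 L) and
#' `postFEV1 = 0.766 pre - 0.694 Δ + 0.22` (residual SD 0.265 L).
#'
#' @param n Number of patients.
#' @param group_mix Named probabilities over `lobectomy`, `segmentectomy`,
#'   `wedge`.
#' @param lobe_mix Named weights over the five lobes for the resected lobe.
#' @param pre_fvc,pre_fev1 `c(mean, sd)` in litres of the preoperative draws.
#' @param spiro_floor Lower truncation (L) of the spirometry draws.
#' @param lobe_flv_pct Named per-lobe FLV share of total FLV, percent.
#' @param delta_noise_sd SD of the Gaussian noise added to the loss ratio.
#' @param delta_dist `"lobar"` (share of the resected lobe plus noise,
#'   scaled per group) or `"uniform"` (ΔFLV/FLV ~ U(`delta_range`),
#'   convenient for regression-recovery studies).
#' @param delta_range Range of the uniform ΔFLV/FLV draw.
#' @param coefficients A [regression_coefficients()] object (or compatible list)
#'   supplying slopes, intercepts and residual SDs of the generative model.
#' @param total_flv `c(mean, sd)` in mL of total preoperative FLV.
#' @param seed Integer seed.
#'
#' @return A list of class `cohort_sim_params`.
#' @seealso [simulate_cohort()]
#' @export
cohort_sim_params <- function(n = 113L,
                              group_mix = c(lobectomy = 0.5,
                                            segmentectomy = 0.25,
                                            wedge = 0.25),
                              lobe_mix = c(RUL = 27, RML = 8, RLL = 14,
                                           LUL = 33, LLL = 15),
                              pre_fvc = c(2.92, 0.59),
                              pre_fev1 = c(2.41, 0.56),
                              spiro_floor = 0.5,
                              lobe_flv_pct = c(RUL = 20.39, RML = 9.74,
                                               RLL = 23.91, LUL = 24.08,
                                               LLL = 21.88),
                              delta_noise_sd = 0.03,
                              delta_dist = c("lobar", "uniform"),
                              delta_range = c(0.08, 0.30),
                              coefficients = regression_coefficients(),
                              total_flv = c(4136, 580),
                              seed = 1L) {
  delta_dist <- match.arg(delta_dist)
  params <- list(
    n = as.integer(n), group_mix = group_mix, lobe_mix = lobe_mix,
    pre_fvc = pre_fvc, pre_fev1 = pre_fev1, spiro_floor = spiro_floor,
    lobe_flv_pct = lobe_flv_pct, delta_noise_sd = delta_noise_sd,
    delta_dist = delta_dist, delta_range = delta_range,
    coefficients = coefficients, total_flv = total_flv,
    seed = as.integer(seed)
  )
  if (params$n < 1L) abort("`n` must be >= 1.", class = "lungflv_spec_error")
  if (any(lobe_flv_pct <= 0)) {
    abort("Lobar FLV proportions must be positive.", class = "lungflv_spec_error")
  }
  if (delta_noise_sd < 0) {
    abort("`delta_noise_sd` must be >= 0.", class = "lungflv_spec_error")
  }
  rsds <- c(coefficients$fvc$rsd, coefficients$fev1$rsd)
  if (any(rsds < 0)) {
    abort("Residual SDs must be >= 0.", class = "lungflv_spec_error")
  }
  structure(params, class = "cohort_sim_params")
}

#' Simulate a surgical cohort
#'
#' Draws a per-patient table from the generative model described in
#' [cohort_sim_params()]. The loss ratio of a lobectomy is the resected
#' lobe's FLV share; a segmentectomy loses that share divided by the lobe's
#' segment count, and a wedge loses 30% of the share. Gaussian noise
#' (`delta_noise_sd`) is added and the ratio clipped to `[0.01, 0.6]`.
#' Wedge rows carry `resected_segment_count = NA`: segment counting does not
#' apply to non-anatomic resections. With residual SDs and delta noise set
#' to 0 the postoperative values equal the linear forms exactly.
#'
#' @param params A [cohort_sim_params()].
#' @return A cohort tibble (see [read_cohort()] for the column contract).
#' @examples
#' cohort <- simulate_cohort(cohort_sim_params(n = 20, seed = 7))
#' dplyr::count(cohort, group)
#' @export
simulate_cohort <- function(params = cohort_sim_params()) {
  stopifnot(inherits(params, "cohort_sim_params"))
  n <- params$n
  seg_tab <- lung_segment_table()
  segments <- structure(seg_tab$segments, names = seg_tab$lobe)

  with_substream(params$seed, "cohort", {
    group <- sample(names(params$group_mix), n,
      replace = TRUE, prob = params$group_mix
    )
    lobe <- sample(names(params$lobe_mix), n,
      replace = TRUE, prob = params$lobe_mix
    )
    pre_fvc <- rnorm_trunc(n, params$pre_fvc[1], params$pre_fvc[2], params$spiro_floor)
    pre_fev1 <- rnorm_trunc(n, params$pre_fev1[1], params$pre_fev1[2], params$spiro_floor)

    if (params$delta_dist == "uniform") {
      delta <- runif(n, params$delta_range[1], params$delta_range[2])
    } else {
      share <- params$lobe_flv_pct[lobe] / 100
      scale <- dplyr::case_when(
        group == "lobectomy" ~ 1,
        group == "segmentectomy" ~ 1 / segments[lobe],
        TRUE ~ 0.3
      )
      delta <- share * scale + rnorm(n, 0, params$delta_noise_sd)
      delta <- pmin(pmax(delta, 0.01), 0.6)
    }
    delta <- unname(delta)

    total_flv <- rnorm_trunc(n, params$total_flv[1], params$total_flv[2], 1500)
    cf <- params$coefficients
    post_fvc <- cf$fvc$pre * pre_fvc + cf$fvc$delta * delta +
      cf$fvc$intercept + rnorm(n, 0, cf$fvc$rsd)
    post_fev1 <- cf$fev1$pre * pre_fev1 + cf$fev1$delta * delta +
      cf$fev1$intercept + rnorm(n, 0, cf$fev1$rsd)
  })

  seg_count <- dplyr::case_when(
    group == "lobectomy" ~ as.numeric(segments[lobe]),
    group == "segmentectomy" ~ 1,
    TRUE ~ NA_real_
  )
  resected_lobes <- ifelse(group == "wedge", paste0("wedge:", lobe), lobe)

  tibble(
    id = sprintf("P%04d", seq_len(n)),
    group = group,
    resected_lobes = resected_lobes,
    resected_segment_count = seg_count,
    pre_fvc = pre_fvc,
    pre_fev1 = pre_fev1,
    post_fvc = post_fvc,
    post_fev1 = post_fev1,
    delta_flv_ratio = unname(delta),
    total_flv_ml = total_flv,
    resected_flv_ml = unname(delta) * total_flv
  )
}
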