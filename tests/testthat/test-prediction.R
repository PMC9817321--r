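test_that("the FLV method scales by remaining functional fraction", {
  expect_equal(
    ppo_flv(3.1, 2.4, resected_flv_ml = 0, total_flv_ml = 4000),
    tibble::tibble(ppo_fvc_flv = 3.1, ppo_fev1_flv = 2.4)
  )
  out <- ppo_flv(3.0, 2.0, resected_flv_ml = 500, total_flv_ml = 4000)
  expect_equal(out$ppo_fev1_flv, 2.0 * 0.875)
  full <- ppo_flv(3.0, 2.0, resected_flv_ml = 4000, total_flv_ml = 4000)
  expect_equal(full$ppo_fvc_flv, 0)
  expect_error(ppo_flv(3, 2, 500, 0), class = "lungflv_spec_error")
  expect_error(ppo_flv(3, 2, 5000, 4000), class = "lungflv_spec_error")
})

test_that("segment counting scales by remaining segment fraction", {
  expect_equal(
    ppo_sc(2.5, 2.0, resected_segments = 0),
    tibble::tibble(ppo_fvc_sc = 2.5, ppo_fev1_sc = 2.0)
  )
  expect_equal(ppo_sc(2.5, 2.0, 19)$ppo_fvc_sc, 0)
  expect_equal(
    ppo_sc(2.5, 1.9, segments_for("RUL"))$ppo_fev1_sc,
    1.9 * 16 / 19
  )
  expect_true(is.na(ppo_sc(2.5, 2.0, NA)$ppo_fvc_sc))
  expect_error(ppo_sc(2.5, 2.0, 20), class = "lungflv_spec_error")
})

test_that("segment lookup matches the 3/2/5/5/4 table over every lobe subset", {
  expect_identical(segments_for("RUL"), 3L)
  expect_identical(segments_for(c("LUL", "LLL")), 9L) # whole left lung
  expect_identical(segments_for(character()), 0L)
  expect_identical(segments_for(c("RUL", "RML", "RLL")), 10L)
  expect_error(segments_for("RIL"), class = "lungflv_spec_error")

  lobes <- c("RUL", "RML", "RLL", "LUL", "LLL")
  per <- c(RUL = 3L, RML = 2L, RLL = 5L, LUL = 5L, LLL = 4L)
  for (k in 1:5) {
    combos <- utils::combn(lobes, k, simplify = FALSE)
    for (cmb in combos) {
      expect_identical(segments_for(cmb), sum(per[cmb]))
    }
  }
})

test_that("the regression equations evaluate the fixed linear forms", {
  out <- regression_predict(3.0, 2.5, delta_flv_ratio = 0.2)
  expect_equal(out$reg_post_fvc, 0.8 * 3.0 - 0.784 * 0.2 + 0.283)
  out2 <- regression_predict(3.0, 2.5, delta_flv_ratio = 0.25)
  expect_equal(out2$reg_post_fev1, 0.766 * 2.5 - 0.694 * 0.25 + 0.22)
  expect_error(regression_predict(3, 2.5, 1.2), class = "lungflv_spec_error")
  # intercept-only limit: slopes evaluated at tiny pre and zero delta
  cf <- regression_coefficients()
  tiny <- regression_predict(1e-9, 1e-9, 0)
  expect_equal(tiny$reg_post_fvc, cf$fvc$intercept, tolerance = 1e-6)
  expect_equal(tiny$reg_post_fev1, cf$fev1$intercept, tolerance = 1e-6)
})

test_that("predictions are monotone decreasing in the resected quantity", {
  res <- seq(0, 4000, by = 500)
  flv <- ppo_flv(rep(3, length(res)), rep(2, length(res)), res, 4000)
  expect_true(all(diff(flv$ppo_fvc_flv) < 0))
  sc <- ppo_sc(rep(3, 20), rep(2, 20), 0:19)
  expect_true(all(diff(sc$ppo_fev1_sc) < 0))
})

test_that("FLV and SC methods diverge as the lobar share predicts", {
  # RUL holds 20.4% of FLV but only 3/19 = 15.8% of segments, so the FLV
  # method predicts a larger loss than segment counting for RUL resection
  frac <- 844.91 / 4135.98
  flv <- ppo_flv(3.0, 2.4, frac * 4135.98, 4135.98)
  sc <- ppo_sc(3.0, 2.4, segments_for("RUL"))
  expect_lt(flv$ppo_fvc_flv, sc$ppo_fvc_sc)
  # RML: 9.6% of FLV vs 2/19 = 10.5% of segments, direction reverses
  frac_rml <- 396.12 / 4135.98
  flv2 <- ppo_flv(3.0, 2.4, frac_rml * 4135.98, 4135.98)
  sc2 <- ppo_sc(3.0, 2.4, segments_for("RML"))
  expect_gt(flv2$ppo_fvc_flv, sc2$ppo_fvc_sc)
})

test_that("predict_cohort appends method columns and respects missing inputs", {
  cohort <- simulate_cohort(cohort_sim_params(n = 60, seed = 17))
  pred <- predict_cohort(cohort)
  expect_true(all(c(
    "ppo_fvc_flv", "ppo_fev1_flv", "ppo_fvc_sc", "ppo_fev1_sc",
    "reg_post_fvc", "reg_post_fev1"
  ) %in% names(pred)))
  expect_true(all(pred$ppo_fvc_flv <= pred$pre_fvc))
  expect_true(all(is.na(pred$ppo_fvc_sc[pred$group == "wedge"])))
  expect_true(all(!is.na(pred$ppo_fvc_sc[pred$group != "wedge"])))
  # custom coefficients flow through
  cf <- regression_coefficients(
    fvc = list(pre = 1, delta = 0, intercept = 0, r2 = 1, rsd = 0),
    fev1 = list(pre = 1, delta = 0, intercept = 0, r2 = 1, rsd = 0)
  )
  ident <- predict_cohort(cohort, coefficients = cf)
  expect_equal(ident$reg_post_fvc, cohort$pre_fvc)
})
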