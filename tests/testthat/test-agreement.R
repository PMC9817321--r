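test_that("Pearson correlation matches the direct product-moment formula", {
  x <- c(1, 2, 3, 4)
  y <- c(1, 3, 2, 4)
  got <- pearson_cor(x, y)
  # brute-force covariance formula, computed independently
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$r, r_direct, tolerance = 1e-10)
  tstat <- r_direct * sqrt((4 - 2) / (1 - r_direct^2))
  expect_equal(got$p, 2 * pt(-abs(tstat), df = 2), tolerance = 1e-10)

  perfect <- pearson_cor(1:10, 2 * (1:10) + 1)
  expect_equal(perfect$r, 1)
  expect_lt(perfect$p, 1e-12)
  expect_error(pearson_cor(rep(1, 5), 1:5), class = "lungflv_degenerate_error")
  expect_error(pearson_cor(1:2, 1:2), class = "lungflv_spec_error")
})

test_that("Bland-Altman reproduces hand-computed limits", {
  same <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$mean_diff, 0)
  expect_equal(same$loa_low, 0)
  expect_equal(same$loa_high, 0)

  ba <- bland_altman(c(0, 2, 4), c(1, 2, 3)) # differences -1, 0, 1
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, 1)
  expect_equal(ba$loa_low, -1.96)
  expect_equal(ba$loa_high, 1.96)
  expect_error(bland_altman(1:3, 1:4), class = "lungflv_spec_error")
})

test_that("the 1.96 SD limits cover about 95% of Normal differences", {
  set.seed(1)
  meas <- rnorm(10000, 2.5, 0.5)
  pred <- meas + rnorm(10000, -0.1, 0.3)
  ba <- bland_altman(pred, meas)
  inside <- mean(ba$diffs >= ba$loa_low & ba$diffs <= ba$loa_high)
  expect_gte(inside, 0.94)
  expect_lte(inside, 0.96)
})

test_that("Bland-Altman limits are scale-equivariant", {
  set.seed(3)
  pred <- rnorm(50, 2, 0.4)
  meas <- pred + rnorm(50, 0, 0.2)
  a <- bland_altman(pred, meas)
  b <- bland_altman(3 * pred, 3 * meas)
  expect_equal(b$mean_diff, 3 * a$mean_diff)
  expect_equal(b$loa_low, 3 * a$loa_low)
  expect_equal(b$loa_high, 3 * a$loa_high)
})

test_that("ICC(A,1) matches an independent two-way ANOVA decomposition", {
  x <- c(9, 6, 8, 7, 10)
  y <- c(9.5, 5.5, 9, 8, 9)
  got <- icc_agreement(x, y)
  # oracle: mean squares from aov on the long layout
  long <- data.frame(
    value = c(x, y),
    subject = factor(rep(1:5, 2)),
    rater = factor(rep(c("a", "b"), each = 5))
  )
  ms <- summary(stats::aov(value ~ subject + rater, data = long))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  icc_oracle <- (msr - mse) / (msr + mse + 2 / 5 * (msc - mse))
  expect_equal(got$icc, icc_oracle, tolerance = 1e-10)

  expect_equal(icc_agreement(1:10, 1:10)$icc, 1)
  # absolute agreement penalises a constant offset that r ignores
  shifted <- icc_agreement(1:10, 1:10 + 10)
  expect_lt(shifted$icc, pearson_cor(1:10, 1:10 + 10)$r - 0.5)
  expect_error(icc_agreement(rep(1, 5), rep(1, 5)),
    class = "lungflv_degenerate_error"
  )
})

test_that("OLS matches the normal-equations solution on a fixture", {
  set.seed(9)
  d <- data.frame(x1 = rnorm(40), x2 = rnorm(40))
  d$y <- 1.5 + 2 * d$x1 - 0.7 * d$x2 + rnorm(40, 0, 0.3)
  fit <- ols_fit(d, "y", c("x1", "x2"))
  X <- cbind(1, d$x1, d$x2)
  beta <- solve(t(X) %*% X, t(X) %*% d$y)
  expect_equal(tidy(fit)$estimate, as.numeric(beta), tolerance = 1e-10)
  resid <- d$y - X %*% beta
  rsd <- sqrt(sum(resid^2) / (40 - 3))
  expect_equal(glance(fit)$residual_sd, rsd, tolerance = 1e-10)
  se <- sqrt(diag(solve(t(X) %*% X)) * rsd^2)
  expect_equal(tidy(fit)$std_error, as.numeric(se), tolerance = 1e-10)
  ci_low <- as.numeric(beta) + qt(0.025, 37) * se
  expect_equal(tidy(fit)$conf_low, as.numeric(ci_low), tolerance = 1e-10)

  exact <- suppressWarnings(
    ols_fit(data.frame(y = 2 * (1:6) + 3, x = 1:6), "y", "x")
  )
  expect_equal(glance(exact)$r_squared, 1)
  expect_equal(glance(exact)$residual_sd, 0, tolerance = 1e-12)

  d$dup <- d$x1
  expect_error(ols_fit(d, "y", c("x1", "dup")), class = "lungflv_degenerate_error")
})

test_that("single-predictor OLS is consistent with Pearson", {
  set.seed(13)
  x <- rnorm(60)
  y <- -1.2 * x + rnorm(60, 0, 0.8)
  fit <- ols_fit(data.frame(x = x, y = y), "y", "x")
  r <- pearson_cor(x, y)$r
  slope <- tidy(fit)$estimate[tidy(fit)$term == "x"]
  expect_equal(sign(slope), sign(r))
  expect_equal(glance(fit)$r_squared, r^2, tolerance = 1e-10)
})

test_that("stepwise limits behave as specified at the threshold extremes", {
  set.seed(21)
  d <- data.frame(a = rnorm(100), b = rnorm(100), c = rnorm(100))
  d$y <- 2 * d$a + rnorm(100)
  none <- stepwise_select(d, "y", c("a", "b", "c"), p_enter = 0, p_remove = 0)
  expect_identical(none$selected, character())
  expect_identical(none$fit$terms$term, "(Intercept)")
  all_in <- stepwise_select(d, "y", c("a", "b", "c"), p_enter = 1, p_remove = 1)
  expect_setequal(all_in$selected, c("a", "b", "c"))
  expect_equal(
    sort(tidy(all_in$fit)$estimate),
    sort(tidy(ols_fit(d, "y", c("a", "b", "c")))$estimate)
  )
})

test_that("stepwise keeps the signal and admits noise at about the entry rate", {
  set.seed(77)
  n_rep <- 100
  kept_signal <- logical(n_rep)
  noise_in <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    d <- data.frame(x = rnorm(400), z = rnorm(400))
    d$y <- 0.5 * d$x + rnorm(400)
    sel <- stepwise_select(d, "y", c("x", "z"))$selected
    kept_signal[i] <- "x" %in% sel
    noise_in[i] <- "z" %in% sel
  }
  expect_true(all(kept_signal))
  # null predictor enters at roughly p_enter = 0.05 (binomial slack)
  expect_lte(mean(noise_in), 0.12)
})

test_that("stepwise on the cohort structure retains the physiologic drivers", {
  set.seed(55)
  cohort <- simulate_cohort(cohort_sim_params(
    n = 2000, seed = 55, delta_dist = "uniform"
  ))
  d <- data.frame(
    post_fvc = cohort$post_fvc,
    pre_fvc = cohort$pre_fvc,
    delta = cohort$delta_flv_ratio,
    sex = rbinom(2000, 1, 0.4),
    age = rnorm(2000, 61, 8),
    height = rnorm(2000, 165, 8),
    weight = rnorm(2000, 63, 10),
    rl_vol = rnorm(2000, 840, 280),
    inl_vol = rnorm(2000, 1300, 300),
    cnl_vol = rnorm(2000, 1900, 500)
  )
  sel <- stepwise_select(
    d, "post_fvc",
    c("sex", "age", "height", "weight", "rl_vol", "inl_vol", "cnl_vol",
      "delta", "pre_fvc")
  )
  expect_true(all(c("pre_fvc", "delta") %in% sel$selected))
  fit <- tidy(sel$fit)
  expect_lt(abs(fit$estimate[fit$term == "pre_fvc"] - 0.8), 0.1)
})

test_that("compare_methods is exact when predictions equal measurements", {
  post_fvc <- c(2.1, 2.6, 3.0, 2.4, 2.9)
  post_fev1 <- c(1.7, 2.1, 2.5, 1.9, 2.3)
  df <- tibble::tibble(
    group = c("lobectomy", "wedge", "lobectomy", "wedge", "lobectomy"),
    post_fvc = post_fvc, post_fev1 = post_fev1,
    ppo_fvc_flv = post_fvc, ppo_fev1_flv = post_fev1,
    ppo_fvc_sc = post_fvc, ppo_fev1_sc = post_fev1
  )
  rep <- compare_methods(df)
  expect_true(all(rep$pairs$r == 1))
  expect_true(all(rep$pairs$icc == 1))
  expect_true(all(rep$pairs$ba_loa_low == 0 & rep$pairs$ba_loa_high == 0))
  expect_true(all(rep$anova$f_p == 1))
})

test_that("agreement reports round-trip through JSON", {
  cohort <- predict_cohort(simulate_cohort(cohort_sim_params(n = 50, seed = 41)))
  rep <- compare_methods(cohort)
  path <- withr::local_tempfile(fileext = ".json")
  write_agreement(rep, path)
  back <- read_agreement(path)
  expect_equal(as.data.frame(back$pairs), as.data.frame(rep$pairs),
    tolerance = 1e-12
  )
  expect_equal(back$n, rep$n)
})

test_that("the agreement battery behaves sensibly on a simulated cohort", {
  cohort <- predict_cohort(simulate_cohort(cohort_sim_params(n = 400, seed = 19)))
  rep <- compare_methods(cohort)
  expect_setequal(unique(rep$pairs$method), c("flv", "sc", "regression"))
  # the generative post values follow the regression model, so the regression
  # predictions must agree best
  reg_r <- rep$pairs$r[rep$pairs$method == "regression" & rep$pairs$outcome == "fvc"]
  expect_gt(reg_r, 0.7)
  expect_true(all(abs(rep$pairs$ba_mean_diff[rep$pairs$method == "regression"]) < 0.05))
})
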