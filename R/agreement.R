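#' Pearson correlation between predicted and measured values
#'
#' Product-moment correlation with the p-value from the t transform on
#' n - 2 degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors, n >= 3, neither constant.
#' @return A list of class `flv_cor` with `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  check_pairs(x, y, min_n = 3)
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation is undefined for a constant series.",
      class = "lungflv_degenerate_error"
    )
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(
    list(r = unname(ct$estimate), p = ct$p.value, n = length(x)),
    class = "flv_cor"
  )
}

#' Bland-Altman agreement analysis
#'
#' Differences are taken as predicted minus measured, so a negative mean
#' difference means the prediction underestimates. Limits of agreement use
#' the exact 1.96 multiplier on the n-1 SD of the differences.
#'
#' @param pred,meas Equal-length numeric vectors, n >= 2.
#' @return A list of class `flv_bland_altman` with `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n`, and the per-pair `means`/`diffs` used for
#'   plotting. [tidy()] returns the summary row; [autoplot()] draws the
#'   standard Bland-Altman plot.
#' @examples
#' ba <- bland_altman(c(1, 2, 3), c(2, 2, 2))
#' tidy(ba)
#' @export
bland_altman <- function(pred, meas) {
  check_pairs(pred, meas, min_n = 2)
  diffs <- pred - meas
  m <- mean(diffs)
  s <- sd(diffs)
  structure(
    list(
      mean_diff = m, sd_diff = s,
      loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
      n = length(diffs),
      means = (pred + meas) / 2, diffs = diffs
    ),
    class = "flv_bland_altman"
  )
}

#' Intraclass correlation, two-way absolute agreement, single measure
#'
#' ICC(A,1): a two-way model with absolute agreement, so a constant offset
#' between the two series lowers the coefficient (unlike Pearson r).
#' Computed from the mean squares of the two-way decomposition:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))` with k = 2 raters.
#'
#' @param x,y Paired numeric vectors, n >= 3.
#' @return A list of class `flv_icc` with `icc`, `model`, `n`.
#' @export
icc_agreement <- function(x, y) {
  check_pairs(x, y, min_n = 3)
  n <- length(x)
  k <- 2
  dat <- cbind(x, y)
  grand <- mean(dat)
  row_means <- rowMeans(dat)
  col_means <- colMeans(dat)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sse <- sum((dat - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  if (denom <= 0) {
    abort("ICC is undefined: no variance in the paired measurements.",
      class = "lungflv_degenerate_error"
    )
  }
  structure(
    list(
      icc = (msr - mse) / denom,
      model = "two-way, absolute agreement, single measure (A,1)",
      n = n
    ),
    class = "flv_icc"
  )
}

#' Ordinary least squares with the reporting shape of the agreement battery
#'
#' Fits `response ~ predictors` by least squares and reports, per term, the
#' coefficient, 95% confidence interval and two-sided p-value, plus R^2,
#' the residual SD `sqrt(SSE / (n - p - 1))` and n. The fit itself is
#' delegated to [stats::lm()].
#'
#' @param data A data frame.
#' @param response Name of the response column.
#' @param predictors Character vector of predictor column names.
#' @return An object of class `flv_ols`; [tidy()] gives the per-term table,
#'   [glance()] the fit summary.
#' @examples
#' d <- data.frame(y = c(1, 2, 3, 5), x = c(1, 2, 3, 4))
#' glance(ols_fit(d, "y", "x"))
#' @export
ols_fit <- function(data, response, predictors) {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(c(response, predictors), names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("Missing column(s): %s.", paste(missing_cols, collapse = ", ")),
      class = "lungflv_spec_error"
    )
  }
  data <- data[stats::complete.cases(data[, c(response, predictors), drop = FALSE]), ]
  n <- nrow(data)
  if (n <= length(predictors) + 1) {
    abort("Not enough complete cases for the requested model.",
      class = "lungflv_spec_error"
    )
  }
  fml <- stats::reformulate(predictors, response = response)
  fit <- lm(fml, data = data)
  if (fit$rank < length(predictors) + 1) {
    abort("Design matrix is rank deficient.", class = "lungflv_degenerate_error")
  }
  sm <- summary(fit)
  ci <- confint(fit, level = 0.95)
  terms_tbl <- tibble(
    term = rownames(sm$coefficients),
    estimate = unname(sm$coefficients[, 1]),
    std_error = unname(sm$coefficients[, 2]),
    conf_low = unname(ci[, 1]),
    conf_high = unname(ci[, 2]),
    p_value = unname(sm$coefficients[, 4])
  )
  structure(
    list(
      terms = terms_tbl,
      r_squared = sm$r.squared,
      residual_sd = sm$sigma,
      n = n,
      response = response,
      predictors = predictors,
      fit = fit
    ),
    class = "flv_ols"
  )
}

#' Stepwise predictor selection by p-values
#'
#' Forward selection with a backward check, the convention of classic
#' statistical packages: at each step the candidate with the smallest
#' partial p-value enters if it is below `p_enter`; after every entry, any
#' included predictor whose p-value has risen above `p_remove` is dropped
#' (largest p first). Ties break on the smaller p, then lexically on the
#' name, so the procedure is deterministic given the data. With
#' `p_enter = 0` the result is intercept-only; with
#' `p_enter = p_remove = 1` the full model.
#'
#' @inheritParams ols_fit
#' @param candidates Character vector of candidate predictor names.
#' @param p_enter,p_remove Entry / removal thresholds on the partial t-test
#'   p-value.
#' @return A list of class `flv_stepwise` with `selected` (character),
#'   `fit` (an [ols_fit()] result, or intercept-only summary when nothing
#'   enters) and `trace` (a tibble of the add/drop history).
#' @export
stepwise_select <- function(data, response, candidates,
                            p_enter = 0.05, p_remove = 0.10) {
  stopifnot(is.data.frame(data))
  data <- data[stats::complete.cases(data[, c(response, candidates), drop = FALSE]), ]
  selected <- character()
  trace <- list()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > 4L * length(candidates) + 10L) break # cycling guard
    pool <- setdiff(candidates, selected)
    if (length(pool) == 0) break
    entry <- purrr::map_dfr(pool, function(cand) {
      fit <- ols_fit(data, response, c(selected, cand))
      tibble(term = cand, p = fit$terms$p_value[fit$terms$term == cand])
    })
    entry <- entry[order(entry$p, entry$term), ]
    if (entry$p[1] >= p_enter || is.na(entry$p[1])) break
    selected <- c(selected, entry$term[1])
    trace[[length(trace) + 1]] <- tibble(
      action = "add", term = entry$term[1], p = entry$p[1]
    )
    # backward check: drop anything whose partial p rose above p_remove
    repeat {
      fit <- ols_fit(data, response, selected)
      ps <- fit$terms[fit$terms$term != "(Intercept)", ]
      ps <- ps[order(-ps$p_value, ps$term), ]
      if (nrow(ps) == 0 || ps$p_value[1] <= p_remove) break
      drop_term <- ps$term[1]
      selected <- setdiff(selected, drop_term)
      trace[[length(trace) + 1]] <- tibble(
        action = "drop", term = drop_term, p = ps$p_value[1]
      )
      if (length(selected) == 0) break
    }
  }
  fit <- if (length(selected) > 0) {
    ols_fit(data, response, selected)
  } else {
    intercept_only_fit(data, response)
  }
  structure(
    list(
      selected = selected, fit = fit,
      trace = if (length(trace)) dplyr::bind_rows(trace) else {
        tibble(action = character(), term = character(), p = numeric())
      },
      p_enter = p_enter, p_remove = p_remove
    ),
    class = "flv_stepwise"
  )
}

intercept_only_fit <- function(data, response) {
  y <- data[[response]]
  y <- y[!is.na(y)]
  n <- length(y)
  structure(
    list(
      terms = tibble(
        term = "(Intercept)", estimate = mean(y),
        std_error = sd(y) / sqrt(n),
        conf_low = mean(y) + stats::qt(0.025, n - 1) * sd(y) / sqrt(n),
        conf_high = mean(y) + stats::qt(0.975, n - 1) * sd(y) / sqrt(n),
        p_value = stats::t.test(y)$p.value
      ),
      r_squared = 0, residual_sd = sd(y), n = n,
      response = response, predictors = character(), fit = NULL
    ),
    class = "flv_ols"
  )
}

check_pairs <- function(x, y, min_n) {
  if (length(x) != length(y)) {
    abort("Series lengths differ.", class = "lungflv_spec_error")
  }
  if (anyNA(x) || anyNA(y)) {
    abort("Paired series must be complete (no NA).", class = "lungflv_spec_error")
  }
  if (length(x) < min_n) {
    abort(sprintf("At least %d pairs are required.", min_n),
      class = "lungflv_spec_error"
    )
  }
  invisible(TRUE)
}

#' Agreement battery between predictions and measured outcomes
#'
#' For each prediction method present in the table (FLV, segment counting,
#' regression) and each outcome (FVC, FEV1), computes Pearson correlation,
#' ICC(A,1) and Bland-Altman limits against the measured postoperative
#' value, a one-way ANOVA across the measured values and the two
#' anatomical-method predictions, and (when `group` has two or more levels)
#' Welch two-sample t-tests of the measured outcomes between the first two
#' groups. The ANOVA treats the three series as independent groups, matching
#' common surgical-series reporting; strictly they are repeated measures on
#' the same patients.
#'
#' @param predictions A cohort tibble with measured `post_fvc`/`post_fev1`
#'   and prediction columns as produced by [predict_cohort()].
#' @return A list of class `flv_agreement`: `pairs` (one row per
#'   outcome x method), `anova`, `t_tests`, `n`. [tidy()] returns the
#'   `pairs` tibble; [write_agreement()]/[read_agreement()] round-trip the
#'   report through JSON.
#' @examples
#' cohort <- predict_cohort(simulate_cohort(cohort_sim_params(n = 40, seed = 2)))
#' tidy(compare_methods(cohort))
#' @export
compare_methods <- function(predictions) {
  stopifnot(is.data.frame(predictions))
  outcome_cols <- c(fvc = "post_fvc", fev1 = "post_fev1")
  method_cols <- list(
    flv = c(fvc = "ppo_fvc_flv", fev1 = "ppo_fev1_flv"),
    sc = c(fvc = "ppo_fvc_sc", fev1 = "ppo_fev1_sc"),
    regression = c(fvc = "reg_post_fvc", fev1 = "reg_post_fev1")
  )
  pairs <- list()
  for (outcome in names(outcome_cols)) {
    meas_col <- outcome_cols[[outcome]]
    if (!meas_col %in% names(predictions)) next
    for (method in names(method_cols)) {
      pred_col <- method_cols[[method]][[outcome]]
      if (!pred_col %in% names(predictions)) next
      ok <- stats::complete.cases(predictions[, c(meas_col, pred_col)])
      if (sum(ok) < 3) {
        abort(sprintf("Fewer than 3 complete cases for %s/%s.", method, outcome),
          class = "lungflv_spec_error"
        )
      }
      pred <- predictions[[pred_col]][ok]
      meas <- predictions[[meas_col]][ok]
      cor_res <- pearson_cor(pred, meas)
      icc_res <- icc_agreement(pred, meas)
      ba <- bland_altman(pred, meas)
      pairs[[length(pairs) + 1]] <- tibble(
        outcome = outcome, method = method, n = sum(ok),
        r = cor_res$r, r_p = cor_res$p, icc = icc_res$icc,
        ba_mean_diff = ba$mean_diff, ba_sd_diff = ba$sd_diff,
        ba_loa_low = ba$loa_low, ba_loa_high = ba$loa_high
      )
    }
  }
  if (length(pairs) == 0) {
    abort("No prediction/measurement pairings found.", class = "lungflv_spec_error")
  }
  pairs <- dplyr::bind_rows(pairs)

  anova_tbl <- purrr::map_dfr(names(outcome_cols), function(outcome) {
    meas_col <- outcome_cols[[outcome]]
    series <- list(measured = predictions[[meas_col]])
    for (method in c("flv", "sc")) {
      col <- method_cols[[method]][[outcome]]
      if (col %in% names(predictions)) series[[method]] <- predictions[[col]]
    }
    if (is.null(series$measured) || length(series) < 2) {
      return(tibble())
    }
    long <- tidyr::drop_na(tibble(
      value = unlist(series, use.names = FALSE),
      grp = rep(names(series), lengths(series))
    ))
    fit <- stats::aov(value ~ grp, data = long)
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tibble(outcome = outcome, groups = paste(names(series), collapse = ","),
           f_p = if (is.nan(p)) 1 else p)
  })

  t_tbl <- tibble()
  if ("group" %in% names(predictions) &&
      length(unique(predictions$group)) >= 2) {
    lv <- sort(unique(predictions$group))[1:2]
    t_tbl <- purrr::map_dfr(names(outcome_cols), function(outcome) {
      col <- outcome_cols[[outcome]]
      if (!col %in% names(predictions)) return(tibble())
      a <- predictions[[col]][predictions$group == lv[1]]
      b <- predictions[[col]][predictions$group == lv[2]]
      a <- a[!is.na(a)]
      b <- b[!is.na(b)]
      if (length(a) < 2 || length(b) < 2) return(tibble())
      tt <- stats::t.test(a, b)
      tibble(
        outcome = outcome, contrast = paste(lv, collapse = " vs "),
        estimate = unname(diff(rev(tt$estimate))), p = tt$p.value
      )
    })
  }

  structure(
    list(
      pairs = pairs, anova = anova_tbl, t_tests = t_tbl,
      icc_model = "two-way, absolute agreement, single measure (A,1)",
      n = nrow(predictions)
    ),
    class = "flv_agreement"
  )
}

#' Serialise / restore an agreement report as JSON
#'
#' @param report An `flv_agreement` object.
#' @param path JSON path.
#' @return `write_agreement()` returns `path` invisibly; `read_agreement()`
#'   the restored report.
#' @export
write_agreement <- function(report, path) {
  stopifnot(inherits(report, "flv_agreement"))
  jsonlite::write_json(
    list(
      pairs = report$pairs, anova = report$anova, t_tests = report$t_tests,
      icc_model = report$icc_model, n = report$n
    ),
    path,
    dataframe = "columns", auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_agreement
#' @export
read_agreement <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      pairs = as_tibble(raw$pairs),
      anova = as_tibble(raw$anova),
      t_tests = as_tibble(raw$t_tests),
      icc_model = raw$icc_model,
      n = raw$n
    ),
    class = "flv_agreement"
  )
}

#' @export
print.flv_agreement <- function(x, ...) {
  cat(sprintf("<flv_agreement> %d patients; ICC model: %s\n", x$n, x$icc_model))
  print(x$pairs)
  invisible(x)
}
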