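#' @exportS3Method generics::tidy
tidy.flv_ols <- function(x, ...) x$terms

#' @exportS3Method generics::glance
glance.flv_ols <- function(x, ...) {
  tibble(r_squared = x$r_squared, residual_sd = x$residual_sd, n = x$n)
}

#' @export
print.flv_ols <- function(x, ...) {
  cat(sprintf(
    "<flv_ols> %s ~ %s  (n = %d, R^2 = %.3f, residual SD = %.3f)\n",
    x$response,
    if (length(x$predictors)) paste(x$predictors, collapse = " + ") else "1",
    x$n, x$r_squared, x$residual_sd
  ))
  print(x$terms)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.flv_bland_altman <- function(x, ...) {
  tibble(
    mean_diff = x$mean_diff, sd_diff = x$sd_diff,
    loa_low = x$loa_low, loa_high = x$loa_high, n = x$n
  )
}

#' @export
print.flv_bland_altman <- function(x, ...) {
  cat(sprintf(
    "<flv_bland_altman> n = %d, mean difference %.3f, limits of agreement [%.3f, %.3f]\n",
    x$n, x$mean_diff, x$loa_low, x$loa_high
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.flv_cor <- function(x, ...) tibble(r = x$r, p = x$p, n = x$n)

#' @export
print.flv_cor <- function(x, ...) {
  cat(sprintf("<flv_cor> r = %.3f, p = %.3g, n = %d\n", x$r, x$p, x$n))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.flv_icc <- function(x, ...) tibble(icc = x$icc, model = x$model, n = x$n)

#' @export
print.flv_icc <- function(x, ...) {
  cat(sprintf("<flv_icc> ICC = %.3f (%s), n = %d\n", x$icc, x$model, x$n))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.flv_stepwise <- function(x, ...) tidy(x$fit)

#' @exportS3Method generics::glance
glance.flv_stepwise <- function(x, ...) glance(x$fit)

#' @export
print.flv_stepwise <- function(x, ...) {
  cat(sprintf(
    "<flv_stepwise> selected: %s (p_enter = %g, p_remove = %g)\n",
    if (length(x$selected)) paste(x$selected, collapse = ", ") else "<none>",
    x$p_enter, x$p_remove
  ))
  print(x$fit)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.flv_agreement <- function(x, ...) x$pairs

#' Bland-Altman plot
#'
#' Scatter of per-pair differences against per-pair means with the mean
#' difference (solid) and the 1.96 SD limits of agreement (dashed).
#'
#' @param object An `flv_bland_altman` result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.flv_bland_altman <- function(object, ...) {
  df <- tibble(mean = object$means, diff = object$diffs)
  ggplot2::ggplot(df, ggplot2::aes(x = mean, y = diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$mean_diff, linewidth = 0.8) +
    ggplot2::geom_hline(
      yintercept = c(object$loa_low, object$loa_high),
      linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "Mean of predicted and measured (L)",
      y = "Predicted - measured (L)",
      title = sprintf(
        "Bland-Altman: mean %.2f, limits [%.2f, %.2f]",
        object$mean_diff, object$loa_low, object$loa_high
      )
    )
}

#' Predicted-versus-measured scatter per method
#'
#' One panel per outcome/method pairing with the identity line; the panel
#' label carries Pearson r and the ICC.
#'
#' @param predictions A prediction tibble from [predict_cohort()] with
#'   measured outcomes.
#' @return A ggplot.
#' @export
plot_prediction_agreement <- function(predictions) {
  report <- compare_methods(predictions)
  cols <- list(
    c("fvc", "flv", "ppo_fvc_flv", "post_fvc"),
    c("fvc", "sc", "ppo_fvc_sc", "post_fvc"),
    c("fvc", "regression", "reg_post_fvc", "post_fvc"),
    c("fev1", "flv", "ppo_fev1_flv", "post_fev1"),
    c("fev1", "sc", "ppo_fev1_sc", "post_fev1"),
    c("fev1", "regression", "reg_post_fev1", "post_fev1")
  )
  df <- purrr::map_dfr(cols, function(cc) {
    if (!all(cc[3:4] %in% names(predictions))) {
      return(tibble())
    }
    stats_row <- report$pairs[
      report$pairs$outcome == cc[1] & report$pairs$method == cc[2],
    ]
    tibble(
      panel = sprintf(
        "%s / %s (r = %.2f, ICC = %.2f)",
        toupper(cc[1]), cc[2], stats_row$r, stats_row$icc
      ),
      predicted = predictions[[cc[3]]],
      measured = predictions[[cc[4]]]
    )
  })
  df <- tidyr::drop_na(df)
  ggplot2::ggplot(df, ggplot2::aes(x = measured, y = predicted)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = "Measured postoperative (L)", y = "Predicted (L)")
}
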