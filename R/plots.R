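#' Plot closed-form bias measures over an effect-size grid
#'
#' Box-plots of one bias measure against the exposure effect `beta_YX`,
#' faceted by the auxiliary-on-missingness effect `beta_RZ`; the spread in
#' each box is the variation over the remaining missingness effects
#' (`beta_RY`, and `beta_RX` for S3).
#'
#' @param object An [run_grid_closed_form()] result.
#' @param measure One of `"max_bias"`, `"max_additional_bias"`,
#'   `"max_total_bias"`, `"max_relative_additional_bias"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.auxbias_grid <- function(object,
                                  measure = c("max_additional_bias",
                                              "max_bias", "max_total_bias",
                                              "max_relative_additional_bias"),
                                  ...) {
  measure <- rlang::arg_match(measure)
  df <- dplyr::filter(object, !is.na(.data[[measure]]))
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = factor(.data$beta_YX),
      y = .data[[measure]],
      group = factor(.data$beta_YX)
    )
  ) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(
      ggplot2::vars(.data$beta_RZ),
      labeller = ggplot2::label_both
    ) +
    ggplot2::labs(
      x = expression(beta[YX]),
      y = measure,
      title = sprintf("%s, scenario %s", measure, attr(object, "scenario")),
      subtitle = "box spread: variation over the remaining missingness effects"
    ) +
    ggplot2::theme_bw()
}

#' Plot convergence of the MI estimator to its limiting value
#'
#' Mean MI estimates (with and without the auxiliary variable) against the
#' observed proportion, with the closed-form limits as horizontal lines and
#' 4-SE Monte-Carlo error bars. The x axis is reversed so that reading left
#' to right follows the missing fraction growing towards one.
#'
#' @param object A [limiting_case_check()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.auxbias_limits <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("est_no_aux", "est_with_aux"),
    names_to = "model", values_to = "estimate"
  )
  long$mc_se <- ifelse(long$model == "est_no_aux",
                       long$mc_se_no_aux, long$mc_se_with_aux)
  long$model <- ifelse(long$model == "est_no_aux",
                       "imputation without Z", "imputation with Z")
  limits <- tibble::tibble(
    model = c("imputation without Z", "imputation with Z"),
    limit = c(object$limit_no_aux[1], object$limit_with_aux[1])
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$pi_obs, y = .data$estimate, colour = .data$model)
  ) +
    ggplot2::geom_hline(
      data = limits,
      ggplot2::aes(yintercept = .data$limit, colour = .data$model),
      linetype = 2
    ) +
    ggplot2::geom_hline(yintercept = object$beta_true[1], colour = "grey40") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$estimate - 4 * .data$mc_se,
                   ymax = .data$estimate + 4 * .data$mc_se)
    ) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(
      x = "observed proportion π₁ (decreasing → all missing)",
      y = "mean MI estimate of the exposure coefficient",
      colour = NULL
    ) +
    ggplot2::theme_bw()
}
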