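#' MR scatter plot of per-variant effects with fitted lines
#'
#' Each point is one instrument (exposure effect on x, outcome effect on y,
#' error bars of one standard error); each line is one estimator's fit —
#' IVW and weighted-median through the origin, Egger with its estimated
#' intercept.
#'
#' @param fit An [mr_fit] object.
#' @return A ggplot object.
#' @export
plot_mr_scatter <- function(fit) {
  stopifnot(inherits(fit, "mr_fit"))
  sd <- mr_scatter_data(fit$instruments, generics::tidy(fit))
  ggplot2::ggplot(sd$points, ggplot2::aes(x = .data$beta_exp, y = .data$beta_out)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$beta_out - .data$se_out,
                                        ymax = .data$beta_out + .data$se_out),
                           linewidth = 0.3, alpha = 0.6) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$beta_exp - .data$se_exp,
                                         xmax = .data$beta_exp + .data$se_exp),
                            linewidth = 0.3, alpha = 0.6) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(data = sd$lines,
                         ggplot2::aes(slope = .data$slope,
                                      intercept = .data$intercept,
                                      colour = .data$method)) +
    ggplot2::labs(x = "Effect on exposure", y = "Effect on outcome",
                  colour = "Method") +
    ggplot2::theme_minimal()
}

#' @rdname plot_mr_scatter
#' @param object,... For the `autoplot` method.
#' @export
autoplot.mr_fit <- function(object, ...) plot_mr_scatter(object)

#' Leave-one-out plot
#'
#' IVW estimate after dropping each instrument in turn, with the full-set
#' estimate as a reference line.
#'
#' @param fit An [mr_fit] object (needs >= 3 instruments).
#' @return A ggplot object.
#' @export
plot_leave_one_out <- function(fit) {
  stopifnot(inherits(fit, "mr_fit"), !is.null(fit$loo))
  loo <- fit$loo
  ggplot2::ggplot(loo, ggplot2::aes(x = .data$estimate,
                                    y = stats::reorder(.data$rsid_left_out,
                                                       .data$estimate))) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = attr(loo, "estimate_full"),
                        colour = "red", linetype = 2) +
    ggplot2::labs(x = "IVW estimate without this variant", y = NULL) +
    ggplot2::theme_minimal()
}

#' Forest plot of significant screen results
#'
#' One row per exposure-outcome pair with the IVW estimate and its 95%
#' confidence interval (`beta +/- 1.96 se`).
#'
#' @param results Screen results tibble (from [run_screen()]), typically
#'   filtered to `status == "significant"`.
#' @return A ggplot object.
#' @export
plot_forest <- function(results) {
  df <- forest_data(results)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate,
                                   y = stats::reorder(.data$label, .data$estimate))) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Causal estimate (IVW, 95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_forest
#' @return `forest_data()`: tibble `label`, `estimate`, `ci_low`, `ci_high`.
#' @export
forest_data <- function(results) {
  results |>
    dplyr::transmute(
      label = paste(.data$exposure, "→", .data$outcome),
      estimate = .data$beta_ivw,
      ci_low = .data$beta_ivw - 1.96 * .data$se_ivw,
      ci_high = .data$beta_ivw + 1.96 * .data$se_ivw
    )
}

#' Power-curve plot
#'
#' @param curve A tibble from [power_curve()].
#' @return A ggplot object.
#' @export
plot_power_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$beta_c, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.8, linetype = 2, colour = "grey50") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Causal effect size", y = "Post-hoc power") +
    ggplot2::theme_minimal()
}
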