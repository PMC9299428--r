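# ggplot2 displays for the main result types.

#' Plot a joint genetic-by-lifestyle risk grid
#'
#' Point-range display of the cell odds ratios (and hazard ratios when
#' present) against the low-genetic-risk / favorable-lifestyle
#' reference.
#'
#' @param object A `joint_grid` from [joint_analysis()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot joint_grid
#' @export
autoplot.joint_grid <- function(object, ...) {
  base <- object[c("genetic_risk", "lifestyle_category")]
  long <- dplyr::bind_cols(base, tibble::tibble(
    scale = "OR", estimate = object$or,
    conf.low = object$or.conf.low, conf.high = object$or.conf.high
  ))
  if ("hr" %in% names(object)) {
    long <- dplyr::bind_rows(long, dplyr::bind_cols(base, tibble::tibble(
      scale = "HR", estimate = object$hr,
      conf.low = object$hr.conf.low, conf.high = object$hr.conf.high
    )))
  }
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$lifestyle_category, y = .data$estimate,
    colour = .data$genetic_risk, group = .data$genetic_risk
  )) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
      position = ggplot2::position_dodge(width = 0.4)
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~scale) +
    ggplot2::labs(
      x = "lifestyle category", y = "estimate vs low genetic / favorable",
      colour = "genetic risk"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a restricted-cubic-spline risk curve
#'
#' @param object A `prsj_rcs` from [rcs_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot prsj_rcs
#' @export
autoplot.prsj_rcs <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$estimate)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
      fill = "grey80"
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "score", y = "odds ratio vs reference") +
    ggplot2::theme_minimal()
}

#' Score distributions by case status
#'
#' Density overlay of the standardized score in cases and controls.
#'
#' @param scores Tibble with `iid` and `z` (e.g. [prs_standardize()]).
#' @param cohort Data frame with `iid` and `status`.
#' @return A ggplot.
#' @export
plot_prs_distribution <- function(scores, cohort) {
  d <- dplyr::inner_join(scores, cohort[c("iid", "status")], by = "iid") |>
    dplyr::mutate(group = ifelse(.data$status == 1, "case", "control"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$z, fill = .data$group)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::labs(x = "standardized PRS", y = "density", fill = NULL) +
    ggplot2::theme_minimal()
}
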