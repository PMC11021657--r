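#' Forest plot of per-method odds ratios
#'
#' @param estimates A per-method estimates tibble (from [run_all_methods()],
#'   `tidy()` on an `mr_direction`, or the `estimates.tsv` report table).
#' @return A ggplot object: odds ratios with 95% confidence intervals, one
#'   row per method (and per run when a `run` column is present).
#' @export
plot_forest <- function(estimates) {
  estimates <- as_tibble(estimates)
  estimates$label <- if ("run" %in% names(estimates)) {
    paste(estimates$run, estimates$method, sep = ": ")
  } else {
    estimates$method
  }
  ggplot2::ggplot(estimates,
                  ggplot2::aes(x = .data$or, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$or_low,
                                         xmax = .data$or_high),
                            height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of SNP effects with per-method fit lines
#'
#' Per-SNP exposure effects against outcome effects with error bars, overlaid
#' with each method's fitted line (slope through the origin except MR-Egger,
#' which carries its intercept).
#'
#' @param h A harmonized tibble.
#' @param estimates Optional per-method estimates tibble to draw fit lines.
#' @return A ggplot object.
#' @export
plot_scatter <- function(h, estimates = NULL) {
  h <- as_tibble(h)
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$beta_x, y = .data$beta_y)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$beta_y - .data$se_y,
                                        ymax = .data$beta_y + .data$se_y),
                           colour = "grey70", width = 0) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$beta_x - .data$se_x,
                                         xmax = .data$beta_x + .data$se_x),
                            colour = "grey70", height = 0) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "SNP effect on exposure",
                  y = "SNP effect on outcome") +
    ggplot2::theme_minimal()
  if (!is.null(estimates) && nrow(estimates)) {
    est <- as_tibble(estimates)
    est$intercept <- if ("egger_intercept" %in% names(est)) {
      ifelse(est$method == "egger" & !is.na(est$egger_intercept),
             est$egger_intercept, 0)
    } else {
      0
    }
    p <- p + ggplot2::geom_abline(
      data = est,
      ggplot2::aes(slope = .data$beta, intercept = .data$intercept,
                   colour = .data$method)) +
      ggplot2::labs(colour = "Method")
  }
  p
}

#' Leave-one-out plot
#'
#' @param loo A leave-one-out table from [leave_one_out()].
#' @return A ggplot object: the IVW estimate (with 95% CI) after omitting
#'   each SNP, with the all-SNP estimate as a reference line.
#' @export
plot_leave_one_out <- function(loo) {
  loo <- as_tibble(loo)
  full <- loo$beta[loo$excluded_snp == "none"][1]
  ggplot2::ggplot(loo, ggplot2::aes(x = .data$beta,
                                    y = .data$excluded_snp)) +
    ggplot2::geom_vline(xintercept = full, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$beta - 1.96 * .data$se,
                                         xmax = .data$beta + 1.96 * .data$se),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "IVW estimate omitting each SNP", y = "Excluded SNP") +
    ggplot2::theme_minimal()
}

#' @method autoplot mr_direction
#' @export
autoplot.mr_direction <- function(object, ...) {
  plot_scatter(object$harmonized, object$estimates)
}

#' @method autoplot mr_panel
#' @export
autoplot.mr_panel <- function(object, ...) {
  est <- tidy(object)
  plot_forest(dplyr::mutate(est, run = paste(.data$exposure, .data$direction,
                                             sep = " ")))
}
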