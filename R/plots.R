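#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point
#'   geom_pointrange geom_hline labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot a high-resolution threshold scan
#'
#' Incremental R-squared (in percent) across the p-value threshold grid, with
#' the best-fitting threshold highlighted.
#'
#' @param object A `prs_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.prs_scan <- function(object, ...) {
  scan <- object$scan
  best <- object$best
  ggplot(scan, aes(x = .data$threshold, y = 100 * .data$delta_r2)) +
    geom_line(colour = "grey40") +
    geom_point(
      data = tibble::tibble(threshold = best$best_threshold,
                            delta_r2 = best$delta_r2),
      aes(y = 100 * .data$delta_r2), colour = "red", size = 2
    ) +
    labs(
      x = expression(p[T] ~ "(inclusion threshold)"),
      y = expression(Delta * R^2 ~ "(%)"),
      title = sprintf("%s: best p_T = %.3f", object$phenotype,
                      best$best_threshold)
    ) +
    theme_minimal()
}

#' Plot a quantile-effect curve
#'
#' Per-quantile effect estimates (beta, or odds ratio for logistic fits) with
#' confidence intervals, relative to the reference quantile.
#'
#' @param object A `quantile_effects` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.quantile_effects <- function(object, ...) {
  fam <- attr(object, "family")
  dat <- tidy.quantile_effects(object)
  if (fam == "logistic") {
    dat$y <- ifelse(dat$reference, 1, dat$or)
    dat$lo <- dat$or_low; dat$hi <- dat$or_high
    ref_y <- 1; ylab <- "Odds ratio vs reference quantile"
  } else {
    dat$y <- dat$estimate
    dat$lo <- dat$conf_low; dat$hi <- dat$conf_high
    ref_y <- 0; ylab <- "Effect vs reference quantile"
  }
  ggplot(dat, aes(x = .data$quantile, y = .data$y)) +
    geom_hline(yintercept = ref_y, linetype = "dashed", colour = "grey60") +
    geom_pointrange(aes(ymin = .data$lo, ymax = .data$hi)) +
    labs(x = "PRS quantile", y = ylab, title = object$phenotype[1]) +
    theme_minimal()
}
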