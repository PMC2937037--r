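#' Plot binned learning curves
#'
#' Gain per bin (top) and, when available, error in the estimated prior mean
#' per bin (bottom), the standard presentation of prior-learning curves.
#'
#' @param object A [bin_series()] result (or any tibble with `bin`, `r` and
#'   optionally `mu_p_error`, `se_r`, `se_mu_p_error`).
#' @param r_true Optional reference gain drawn as a dashed line.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot binned_estimates
#' @export
autoplot.binned_estimates <- function(object, r_true = NULL, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object, "bin", dplyr::any_of(c("r", "mu_p_error"))),
    -"bin", names_to = "quantity", values_to = "value"
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$bin, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 0.8, colour = "steelblue") +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "bin (10 trials)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(r_true)) {
    p <- p + ggplot2::geom_hline(
      data = data.frame(quantity = "r", yint = r_true),
      ggplot2::aes(yintercept = .data$yint), linetype = "dashed"
    )
  }
  p
}

#' @rdname autoplot.binned_estimates
#' @param binned A [bin_series()] result.
#' @export
plot_learning_curves <- function(binned, r_true = NULL) {
  autoplot.binned_estimates(binned, r_true = r_true)
}

#' Plot a switch-aligned mean-estimate curve
#'
#' Mean estimate (with standard-error ribbon) by trials since a switch in the
#' prior's mean.
#'
#' @param object An [align_to_switches()] result.
#' @param means Optional two candidate means drawn as dashed reference lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot switch_aligned_curve
#' @export
autoplot.switch_aligned_curve <- function(object, means = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$mean_estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_estimate - .data$se,
                                      ymax = .data$mean_estimate + .data$se),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "trials since switch", y = "estimated prior mean") +
    ggplot2::theme_minimal()
  if (!is.null(means)) {
    p <- p + ggplot2::geom_hline(yintercept = means, linetype = "dashed")
  }
  p
}

#' @rdname autoplot.switch_aligned_curve
#' @param curve An [align_to_switches()] result.
#' @export
plot_switch_curve <- function(curve, means = c(-0.05, 0.05)) {
  autoplot.switch_aligned_curve(curve, means = means)
}

#' Plot the reconstructed prior's evolution
#'
#' Per-bin reconstructed prior spread band (mean +/- sd) over the session;
#' flat-prior bins are omitted from the band.
#'
#' @param trajectory A [prior_trajectory()] result.
#' @return A ggplot object.
#' @export
plot_prior_trajectory <- function(trajectory) {
  finite <- dplyr::filter(trajectory, !.data$flat)
  ggplot2::ggplot(finite, ggplot2::aes(x = .data$bin, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25, fill = "darkorange") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "bin (10 trials)", y = "position (screen units)",
                  title = "Reconstructed prior (mean +/- sd)") +
    ggplot2::theme_minimal()
}
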