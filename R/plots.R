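# ggplot2 views of the package's result types.

#' Plot an MI degradation curve
#'
#' Mean MI (ribbon: +/- one per-level std) against noise width on a log
#' axis, with the zero-noise threshold band (zero-noise MI +/- its
#' data-fraction uncertainty) shaded.
#'
#' @param object A [noise_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.noise_curve <- function(object, ...) {
  nz <- object[object$r_c_ms > 0, ]
  mi0 <- attr(object, "zero_noise_mi")
  s0 <- attr(object, "zero_noise_std")
  ggplot2::ggplot(nz, ggplot2::aes(x = .data$r_c_ms, y = .data$mi_mean)) +
    ggplot2::annotate("rect", xmin = min(nz$r_c_ms), xmax = max(nz$r_c_ms),
                      ymin = mi0 - s0, ymax = mi0 + s0,
                      fill = "purple", alpha = 0.2) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mi_mean - .data$mi_std,
                                      ymax = .data$mi_mean + .data$mi_std),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "noise width r_c (ms)", y = "MI (bits)")
}

#' Plot a discrete MI curve
#'
#' Raw and shuffle-corrected MI against bin size on a log axis.
#'
#' @param object A [discrete_mi_curve()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.discrete_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[, c("r_d_ms", "I_d", "I_dsh")],
    c("I_d", "I_dsh"), names_to = "estimate", values_to = "mi")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$r_d_ms, y = .data$mi,
                                     linetype = .data$estimate)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "bin size r_d (ms)", y = "MI (bits)",
                  linetype = NULL)
}

#' Plot a validation report
#'
#' Estimated against ground-truth precision per method (mean +/- std over
#' repeats), with the unit line of perfect recovery.
#'
#' @param object A [run_validation()] report.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.validation_report <- function(object, ...) {
  s <- glance(object)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$truth_ms, y = .data$mean_ms,
                                  colour = .data$method,
                                  shape = .data$generator)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_ms - .data$std_ms,
                                          ymax = .data$mean_ms + .data$std_ms),
                             position = ggplot2::position_dodge(width = 0.15)) +
    ggplot2::labs(x = "ground-truth precision (ms)",
                  y = "estimated precision (ms)")
}

#' Plot k-NN distance diagnostics
#'
#' Median k-th-neighbour distance shift (ms) against noise width per
#' spike-count class.
#'
#' @param object A [knn_distance_diagnostics()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.knn_diagnostics <- function(object, ...) {
  nz <- object[object$r_c_ms > 0, ]
  ggplot2::ggplot(nz, ggplot2::aes(x = .data$r_c_ms, y = .data$delta_ms,
                                   colour = factor(.data$count))) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "noise width r_c (ms)",
                  y = "shift in median k-NN distance (ms)",
                  colour = "spikes/trial")
}
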