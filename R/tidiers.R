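## broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a probe result
#'
#' @param x An `mcg_probe_result`.
#' @param ... Unused.
#' @return Long tibble: `fold`, `metric`, `value`.
#' @export
tidy.mcg_probe_result <- function(x, ...) {
  tidyr::pivot_longer(x$fold_metrics, -"fold", names_to = "metric",
                      values_to = "value")
}

#' One-row summary of a probe result
#'
#' @param x An `mcg_probe_result`.
#' @param ... Unused.
#' @return Tibble with task, mode, fold count, AUC mean and 95% CI.
#' @export
glance.mcg_probe_result <- function(x, ...) {
  a <- x$summary[x$summary$metric == "auc", ]
  tibble::tibble(task = x$task,
                 mode = if (x$pretrained) "ssl_probe" else "supervised",
                 n_folds = nrow(x$fold_metrics), auc = a$mean,
                 auc_ci_lo = a$ci_lo, auc_ci_hi = a$ci_hi)
}

#' Tidy an SNR report
#'
#' @param x An `mcg_snr_report`.
#' @param ... Unused.
#' @return Tibble `channel`, `snr_db`, `valid`.
#' @export
tidy.mcg_snr_report <- function(x, ...) {
  tibble::tibble(channel = seq_along(x$channel_snr), snr_db = x$channel_snr,
                 valid = is.finite(x$channel_snr))
}

#' ROC curves for a probe result
#'
#' Pooled patient-level ROC with per-fold curves underneath.
#'
#' @param object An `mcg_probe_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mcg_probe_result <- function(object, ...) {
  ps <- object$patient_scores
  per_fold <- dplyr::group_modify(dplyr::group_by(ps, .data$fold),
                                  ~ roc_points(.x$score, .x$label))
  pooled <- roc_points(ps$score, ps$label)
  ggplot2::ggplot() +
    ggplot2::geom_path(data = per_fold,
                       ggplot2::aes(.data$fpr, .data$tpr,
                                    group = .data$fold),
                       colour = "grey70", linewidth = 0.4) +
    ggplot2::geom_path(data = pooled,
                       ggplot2::aes(.data$fpr, .data$tpr),
                       colour = "#00558C", linewidth = 1) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate",
                  title = sprintf("%s: patient-level ROC", object$task)) +
    ggplot2::theme_minimal()
}

#' Beat-aligned importance profile plot
#'
#' @param object An `mcg_beat_profile`.
#' @param ... Unused.
#' @return A ggplot (time relative to the R-peak in ms).
#' @export
autoplot.mcg_beat_profile <- function(object, ...) {
  t_ms <- (seq_along(object$profile) - object$pre - 1) / object$fs * 1000
  ggplot2::ggplot(tibble::tibble(t_ms = t_ms, importance = object$profile),
                  ggplot2::aes(.data$t_ms, .data$importance)) +
    ggplot2::geom_area(fill = "#B2182B", alpha = 0.4) +
    ggplot2::geom_line(colour = "#B2182B") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "Time from R-peak (ms)",
                  y = "Normalised importance",
                  title = sprintf("Beat-aligned importance (%d beats)",
                                  object$n_beats)) +
    ggplot2::theme_minimal()
}

#' Sensor-array importance map
#'
#' @param importance Per-channel importance vector (length 64) or the tibble
#'   from [spatial_importance()].
#' @param sensor_array An `mcg_sensor_array`.
#' @return A ggplot of the array viewed from above, point size and colour
#'   encoding importance.
#' @export
plot_sensor_importance <- function(importance,
                                   sensor_array = default_sensor_array()) {
  d <- if (is.data.frame(importance)) {
    importance
  } else {
    tibble::tibble(x = sensor_array$x, y = sensor_array$y,
                   importance = importance)
  }
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y,
                                  size = .data$importance,
                                  colour = .data$importance)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_viridis_c(option = "inferno") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", colour = "importance",
                  size = "importance",
                  title = "Channel importance on the sensor array") +
    ggplot2::theme_minimal()
}

#' Quick look at a recording
#'
#' @param object An `mcg_recording`.
#' @param channels Channels to draw.
#' @param seconds Time span from the start (s).
#' @param ... Unused.
#' @return A ggplot of stacked channel traces.
#' @export
autoplot.mcg_recording <- function(object, channels = c(1, 9, 17, 33, 49),
                                   seconds = 5, ...) {
  n <- min(ncol(object$signal), round(seconds * object$fs))
  d <- purrr::map_dfr(channels, function(c) {
    tibble::tibble(channel = factor(c), t = (seq_len(n) - 1) / object$fs,
                   bz = object$signal[c, seq_len(n)])
  })
  ggplot2::ggplot(d, ggplot2::aes(.data$t, .data$bz)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = "Bz (pT)",
                  title = sprintf("%s (%s)", object$patient_id,
                                  object$class_label)) +
    ggplot2::theme_minimal()
}
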