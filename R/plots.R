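# ggplot2 displays for the main result types.

#' Plot a projection with detected signals
#'
#' Raster of a corrected projection with optional detected-signal
#' overlay.
#'
#' @param corrected Numeric matrix.
#' @param signals Optional tibble with `centroid_row`/`centroid_col` (from
#'   [segment_signals()]) or `row`/`col` (from [detect_maxima()]).
#' @return A ggplot object.
#' @export
plot_projection <- function(corrected, signals = NULL) {
  df <- tidyr::expand_grid(row = seq_len(nrow(corrected)),
                           col = seq_len(ncol(corrected)))
  df$intensity <- corrected[cbind(df$row, df$col)]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column (px)", y = "row (px)", fill = "intensity")
  if (!is.null(signals) && nrow(signals)) {
    pts <- if (all(c("centroid_row", "centroid_col") %in% names(signals))) {
      tibble::tibble(row = signals$centroid_row, col = signals$centroid_col)
    } else {
      tibble::tibble(row = signals$row, col = signals$col)
    }
    p <- p + ggplot2::geom_point(data = pts,
                                 ggplot2::aes(x = .data$col, y = .data$row),
                                 inherit.aes = FALSE,
                                 shape = 1, color = "red", size = 2)
  }
  p
}

#' Plot a Monte Carlo null distribution
#'
#' Histogram of the replicate frequencies with the mean marked; an
#' observed frequency can be overlaid for comparison.
#'
#' @param object An `rcp_mc_null`.
#' @param observed Optional observed same-color frequency to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rcp_mc_null <- function(object, observed = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency)) +
    ggplot2::geom_histogram(bins = max(5, ceiling(sqrt(nrow(df)))),
                            fill = "grey70", color = "grey30") +
    ggplot2::geom_vline(xintercept = object$mean_frequency,
                        linetype = "dashed") +
    ggplot2::labs(x = "same-color neighbor frequency (null)", y = "replicates")
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_vline(xintercept = observed, color = "red")
  }
  p
}

#' Plot an integrity test report
#'
#' Observed frequency per experiment replicate against the matched null
#' mean with a plus/minus two-SD ribbon.
#'
#' @param object An `rcp_integrity_test`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rcp_integrity_test <- function(object, ...) {
  df <- object$results
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$replicate))) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$null_mean - 2 * .data$null_sd,
                                        ymax = .data$null_mean + 2 * .data$null_sd),
                           width = 0.2, color = "grey50") +
    ggplot2::geom_point(ggplot2::aes(y = .data$null_mean), color = "grey40",
                        shape = 15, size = 2) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), color = "red", size = 2) +
    ggplot2::labs(x = "experiment replicate",
                  y = "same-color neighbor frequency",
                  subtitle = "red: observed; grey: null mean ± 2 SD")
}

#' Plot SNR measurement distributions for two conditions
#'
#' @param a,b Tibbles from [measure_snr_all()].
#' @param labels Condition names (length 2).
#' @return A ggplot object (boxplot of `snr_db` by condition).
#' @export
plot_snr_comparison <- function(a, b, labels = c("compact", "dispersed")) {
  df <- dplyr::bind_rows(
    dplyr::mutate(a, condition = labels[1]),
    dplyr::mutate(b, condition = labels[2])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$snr_db)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey85") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = NULL, y = "SNR (dB)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
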