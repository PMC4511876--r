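# Disk-based signal-to-noise measurement: per-signal peak intensity in an
# inner disk against the SD of the surrounding annulus, converted to
# decibels as SNR = 20 * log10(r).

#' Inner/outer disk geometry for SNR measurement
#'
#' @param inner_radius_px Radius of the signal disk, pixels (default 3).
#' @param outer_radius_px Radius of the surrounding background disk,
#'   pixels (default 7). The alternative geometry used for the robustness
#'   check is (5, 12).
#' @return Object of class `disk_geometry`.
#' @export
disk_geometry <- function(inner_radius_px = 3, outer_radius_px = 7) {
  abort_if(!(inner_radius_px > 0), "inner_radius_px must be > 0")
  abort_if(!(outer_radius_px > inner_radius_px),
           "outer_radius_px must exceed inner_radius_px")
  structure(list(inner_radius_px = inner_radius_px,
                 outer_radius_px = outer_radius_px),
            class = "disk_geometry")
}

#' @export
print.disk_geometry <- function(x, ...) {
  cat(sprintf("<disk_geometry> inner %g px, outer %g px\n",
              x$inner_radius_px, x$outer_radius_px))
  invisible(x)
}

#' Retain only signals with an unexclusive measurement neighborhood
#'
#' A signal's SNR measurement is valid only if its background annulus
#' samples pure local background. A signal is retained iff (a) its outer
#' disk lies fully inside the image, (b) no other candidate center lies
#' closer than twice the outer radius (so no two annuli overlap; both
#' members of a too-close pair are dropped), and (c) no pixel of any other
#' segmented object falls inside its outer disk.
#'
#' @param signals Tibble of candidate signals (from [filter_clusters()]),
#'   with `label`, `peak_row`, `peak_col` and a `pixels` list-column.
#' @param geometry A [disk_geometry()].
#' @param image_shape `c(height, width)` of the image.
#' @param all_objects Tibble of every segmented object (default
#'   `signals`); pre-filter objects still disqualify neighborhoods they
#'   intrude on.
#' @return Integer vector of retained `label` values.
#' @export
exclude_overlapping <- function(signals, geometry, image_shape,
                                all_objects = signals) {
  abort_if(!inherits(geometry, "disk_geometry"), "geometry must be a disk_geometry")
  if (nrow(signals) == 0L) return(integer())
  R <- geometry$outer_radius_px
  h <- image_shape[1]; w <- image_shape[2]
  cr <- signals$peak_row; cc <- signals$peak_col

  inside <- cr - R >= 1 & cr + R <= h & cc - R >= 1 & cc + R <= w

  d <- as.matrix(stats::dist(cbind(cr, cc)))
  diag(d) <- Inf
  isolated <- apply(d, 1, min) >= 2 * R
  if (nrow(signals) == 1L) isolated <- TRUE

  no_intrusion <- vapply(seq_len(nrow(signals)), function(i) {
    others <- all_objects[all_objects$label != signals$label[i], , drop = FALSE]
    if (nrow(others) == 0L) return(TRUE)
    px <- do.call(rbind, others$pixels)
    all(sqrt((px[, 1] - cr[i])^2 + (px[, 2] - cc[i])^2) > R)
  }, TRUE)

  signals$label[inside & isolated & no_intrusion]
}

#' Measure the SNR of one signal
#'
#' The ratio `r` is the maximum intensity within the inner disk around the
#' signal center divided by the sample standard deviation of all pixels in
#' the surrounding annulus (distance in `(inner, outer]`); the decibel
#' value is `20 * log10(r)`. Disk membership is Euclidean distance from
#' the pixel's integer coordinate to the center, `<=` the radius.
#'
#' @param corrected Numeric matrix.
#' @param center `c(row, col)` signal center; anchored on the brightest
#'   pixel of the object by [measure_snr_all()].
#' @param geometry A [disk_geometry()].
#' @return One-row tibble: `peak_intensity`, `local_sd`, `ratio_r`,
#'   `snr_db`.
#' @export
measure_snr <- function(corrected, center, geometry) {
  abort_if(!inherits(geometry, "disk_geometry"), "geometry must be a disk_geometry")
  R <- geometry$outer_radius_px
  h <- nrow(corrected); w <- ncol(corrected)
  abort_if(center[1] - R < 1 || center[1] + R > h ||
             center[2] - R < 1 || center[2] + R > w,
           "outer disk extends beyond the image")
  inner <- disk_offsets(geometry$inner_radius_px)
  ann <- annulus_offsets(geometry$inner_radius_px, geometry$outer_radius_px)
  ctr <- round(center)
  peak <- max(corrected[cbind(ctr[1] + inner[, 1], ctr[2] + inner[, 2])])
  local_sd <- sd(corrected[cbind(ctr[1] + ann[, 1], ctr[2] + ann[, 2])])
  abort_if(!is.finite(local_sd) || local_sd == 0,
           "degenerate background: local SD is zero")
  r <- peak / local_sd
  tibble::tibble(peak_intensity = peak, local_sd = local_sd,
                 ratio_r = r, snr_db = snr_db(r))
}

#' Convert an intensity ratio to decibels
#'
#' `snr_db(r) = 20 * log10(r)`.
#'
#' @param ratio_r Positive ratio of peak intensity to local background SD.
#' @return SNR in decibels.
#' @export
snr_db <- function(ratio_r) {
  20 * log10(ratio_r)
}

#' Measure SNR for all retained signals of an image
#'
#' Applies neighborhood exclusion ([exclude_overlapping()]) and measures
#' each retained signal with [measure_snr()], anchored on its brightest
#' pixel. Signals whose annulus has zero SD are dropped and counted.
#'
#' @inheritParams exclude_overlapping
#' @param corrected Numeric matrix the signals were segmented from.
#' @return Tibble with one row per measured signal (`signal_id`, `row`,
#'   `col`, `peak_intensity`, `local_sd`, `ratio_r`, `snr_db`), with
#'   attributes `n_candidates`, `n_retained`, `n_degenerate`.
#' @export
measure_snr_all <- function(corrected, signals, geometry = disk_geometry(),
                            all_objects = signals) {
  keep <- exclude_overlapping(signals, geometry, dim(corrected), all_objects)
  retained <- signals[signals$label %in% keep, , drop = FALSE]
  n_degenerate <- 0L
  rows <- purrr::map(seq_len(nrow(retained)), function(i) {
    m <- tryCatch(
      measure_snr(corrected,
                  c(retained$peak_row[i], retained$peak_col[i]), geometry),
      error = function(e) NULL)
    if (is.null(m)) return(NULL)
    dplyr::bind_cols(tibble::tibble(signal_id = retained$label[i],
                                    row = retained$peak_row[i],
                                    col = retained$peak_col[i]), m)
  })
  n_degenerate <- sum(vapply(rows, is.null, TRUE))
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(signal_id = integer(), row = numeric(),
                          col = numeric(), peak_intensity = numeric(),
                          local_sd = numeric(), ratio_r = numeric(),
                          snr_db = numeric())
  }
  attr(out, "n_candidates") <- nrow(signals)
  attr(out, "n_retained") <- nrow(retained)
  attr(out, "n_degenerate") <- n_degenerate
  out
}

#' Summarize signal intensities and SNR
#'
#' Arithmetic mean, sample SD (n-1 denominator) and SEM (`SD / sqrt(n)`)
#' per variable. With a single value the SD and SEM are `NA`.
#'
#' @param measurements Tibble from [measure_snr_all()] (needs
#'   `peak_intensity` and `snr_db` columns).
#' @return Tibble with columns `variable`, `mean`, `sd`, `sem`, `n`.
#' @export
summarize_intensity <- function(measurements) {
  abort_if(nrow(measurements) == 0L, "no measurements to summarize")
  measurements |>
    dplyr::select("peak_intensity", "snr_db") |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "variable") |>
    dplyr::group_by(.data$variable) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = sd(.data$value),
                     n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(sem = .data$sd / sqrt(.data$n)) |>
    dplyr::select("variable", "mean", "sd", "sem", "n")
}

#' Compare two groups of measurements
#'
#' Checks each group for normality with a one-sample Kolmogorov-Smirnov
#' test against a normal with the group's estimated mean and SD (alpha =
#' 0.05). If both groups pass, a two-tailed Welch t-test is used;
#' otherwise a two-sided Mann-Whitney U (Wilcoxon rank-sum) test. A group
#' with zero variance is treated as non-normal.
#'
#' @param a,b Numeric vectors, each of length >= 3.
#' @return Object of class `rcp_group_test` with the chosen test's name,
#'   statistic and two-sided p-value plus the per-group normality
#'   p-values; supports [tidy()].
#' @export
compare_groups <- function(a, b) {
  abort_if(length(a) < 3 || length(b) < 3, "each group needs n >= 3")
  norm_p <- vapply(list(a, b), function(x) {
    if (sd(x) == 0) return(0)
    suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x))$p.value)
  }, numeric(1))
  both_normal <- all(norm_p > 0.05)
  degenerate <- sd(a) == 0 && sd(b) == 0 && a[1] == b[1]
  if (both_normal) {
    ht <- t.test(a, b)
    test <- "Welch two-sample t-test"
  } else {
    ht <- suppressWarnings(wilcox.test(a, b, exact = FALSE))
    test <- "Mann-Whitney U test"
  }
  structure(list(test = test,
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 normality_p = norm_p,
                 both_normal = both_normal,
                 degenerate = degenerate,
                 n = c(length(a), length(b)),
                 means = c(mean(a), mean(b))),
            class = "rcp_group_test")
}

#' @export
print.rcp_group_test <- function(x, ...) {
  cat(sprintf("<rcp_group_test> %s\n", x$test))
  cat(sprintf("  group means: %.4g vs %.4g (n = %d, %d)\n",
              x$means[1], x$means[2], x$n[1], x$n[2]))
  cat(sprintf("  statistic = %.4g, two-sided p = %.4g\n", x$statistic, x$p_value))
  if (x$degenerate) cat("  note: both groups constant and equal\n")
  invisible(x)
}
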