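# broom-style tidiers for the package's result objects.

#' Tidy a Monte Carlo null
#'
#' @param x An `rcp_mc_null`.
#' @param ... Unused.
#' @return Tibble with one row per replicate: `replicate`, `frequency`.
#' @export
tidy.rcp_mc_null <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$frequencies),
                 frequency = x$frequencies)
}

#' Glance at a Monte Carlo null
#'
#' @param x An `rcp_mc_null`.
#' @param ... Unused.
#' @return One-row tibble: `mean_frequency`, `sd_frequency`,
#'   `n_replicates`, `n1`, `n2`.
#' @export
glance.rcp_mc_null <- function(x, ...) {
  tibble::tibble(mean_frequency = x$mean_frequency,
                 sd_frequency = x$sd_frequency,
                 n_replicates = x$n_replicates,
                 n1 = x$color_counts[1],
                 n2 = x$color_counts[2])
}

#' Tidy an integrity test report
#'
#' @param x An `rcp_integrity_test`.
#' @param ... Unused.
#' @return Per-replicate tibble of observed vs null comparisons.
#' @export
tidy.rcp_integrity_test <- function(x, ...) {
  x$results
}

#' Glance at an integrity test report
#'
#' @param x An `rcp_integrity_test`.
#' @param ... Unused.
#' @return One-row tibble with mean observed and null frequencies, the
#'   mean relative difference and the smallest per-replicate p-value.
#' @export
glance.rcp_integrity_test <- function(x, ...) {
  r <- x$results
  tibble::tibble(mean_observed = mean(r$observed),
                 mean_null = mean(r$null_mean),
                 mean_relative_diff = mean(r$relative_diff),
                 min_p_value = min(r$p_value),
                 n_replicates = nrow(r))
}

#' Tidy a two-group comparison
#'
#' @param x An `rcp_group_test`.
#' @param ... Unused.
#' @return One-row tibble: test name, statistic, p-value, group means and
#'   sizes, per-group normality p-values.
#' @export
tidy.rcp_group_test <- function(x, ...) {
  tibble::tibble(test = x$test,
                 statistic = x$statistic,
                 p_value = x$p_value,
                 mean_a = x$means[1], mean_b = x$means[2],
                 n_a = x$n[1], n_b = x$n[2],
                 normality_p_a = x$normality_p[1],
                 normality_p_b = x$normality_p[2])
}

#' Tidy a dose-response report
#'
#' @param x An `rcp_dose_response`.
#' @param ... Unused.
#' @return The pairwise LSD comparison tibble.
#' @export
tidy.rcp_dose_response <- function(x, ...) {
  x$pairwise
}

#' Glance at a dose-response report
#'
#' @param x An `rcp_dose_response`.
#' @param ... Unused.
#' @return The one-row ANOVA tibble.
#' @export
glance.rcp_dose_response <- function(x, ...) {
  x$anova
}
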