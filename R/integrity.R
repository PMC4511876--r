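# Signal integrity: frequency of same-color nearest neighbors, Monte
# Carlo random-placement null with fixed per-color counts, closed-form
# null, and the per-replicate comparison test.
#
# If one RCP disintegrates into several foci, those foci sit close
# together and share a color, so the fraction of signals whose nearest
# neighbor has the same color rises above what random placement of the
# same color counts would give.

#' Same-color nearest-neighbor frequency
#'
#' For every point, finds its nearest other point by Euclidean distance
#' (over both colors; exact ties resolve toward the candidate with the
#' smallest (row, col)) and reports the fraction of points whose nearest
#' neighbor carries the same color. The relation is directed, so the
#' number of pairs equals the number of points.
#'
#' @param points Tibble/data frame with columns `row`, `col`, `color`.
#' @return One-row tibble: `n_pairs_total`, `n_same_color`, `frequency`.
#' @export
same_color_frequency <- function(points) {
  abort_if(!all(c("row", "col", "color") %in% names(points)),
           "points needs columns row, col, color")
  abort_if(nrow(points) < 2L, "need at least two points")
  nn <- nn_nearest_index(as.numeric(points$row), as.numeric(points$col))
  same <- points$color[nn] == points$color
  tibble::tibble(n_pairs_total = length(same),
                 n_same_color = sum(same),
                 frequency = mean(same))
}

#' Monte Carlo null for the same-color neighbor frequency
#'
#' Simulates the frequency expected if signals of two colors were placed
#' uniformly at random over the image rectangle with fixed per-color
#' counts: each replicate draws a fresh point set with
#' [generate_point_set()] and computes [same_color_frequency()].
#'
#' @param color_counts `c(n1, n2)` per-color signal counts.
#' @param image_shape `c(height, width)` of the placement rectangle.
#' @param n_replicates Number of Monte Carlo replicates (default 10).
#' @param seed Optional master seed; replicate seeds derive from it.
#' @return Object of class `rcp_mc_null`: per-replicate `frequencies`,
#'   `mean_frequency`, `sd_frequency`, and the inputs. Supports [tidy()]
#'   and [glance()].
#' @export
monte_carlo_null <- function(color_counts, image_shape = c(1040, 1388),
                             n_replicates = 10, seed = NULL) {
  abort_if(length(color_counts) != 2L ||
             !all(vapply(color_counts, is_count, TRUE)) ||
             sum(color_counts) < 2,
           "color_counts must be two non-negative integers summing to >= 2")
  abort_if(!is_count(n_replicates) || n_replicates < 1,
           "n_replicates must be a positive integer")
  seeds <- if (is.null(seed)) rep(list(NULL), n_replicates)
           else as.list(derive_seeds(seed, n_replicates))
  freqs <- vapply(seeds, function(s) {
    pts <- generate_point_set(color_counts, image_shape, seed = s)
    same_color_frequency(pts)$frequency
  }, numeric(1))
  structure(list(frequencies = freqs,
                 mean_frequency = mean(freqs),
                 sd_frequency = sd(freqs),
                 n_replicates = as.integer(n_replicates),
                 color_counts = as.integer(color_counts),
                 image_shape = image_shape,
                 seed = seed),
            class = "rcp_mc_null")
}

#' @export
print.rcp_mc_null <- function(x, ...) {
  cat(sprintf(
    "<rcp_mc_null> counts (%d, %d), %d replicates: mean %.4f, sd %.4f\n",
    x$color_counts[1], x$color_counts[2], x$n_replicates,
    x$mean_frequency, x$sd_frequency))
  invisible(x)
}

#' Closed-form null same-color probability
#'
#' If the nearest neighbor were an exchangeable draw among the other
#' points, the probability that it shares the focal point's color is
#' `(n1 (n1 - 1) + n2 (n2 - 1)) / ((n1 + n2)(n1 + n2 - 1))`. Serves as an
#' independent check on [monte_carlo_null()].
#'
#' @param color_counts `c(n1, n2)`.
#' @return Same-color probability in `[0, 1]`.
#' @export
analytic_null <- function(color_counts) {
  abort_if(length(color_counts) != 2L || sum(color_counts) < 2,
           "color_counts must be two counts summing to >= 2")
  n1 <- color_counts[1]; n2 <- color_counts[2]; n <- n1 + n2
  (n1 * (n1 - 1) + n2 * (n2 - 1)) / (n * (n - 1))
}

#' Test observed neighbor frequencies against their Monte Carlo nulls
#'
#' For each experiment replicate, runs a two-tailed one-sample t-test of
#' the null's per-replicate frequencies against the observed frequency.
#' If the null frequencies are constant (SD 0), an exact comparison is
#' reported instead of a t-statistic. The report also flags whether the
#' observed value falls within the null mean plus/minus two null SDs, and
#' gives the relative difference `(observed - null mean) / null mean`.
#'
#' @param observed Numeric vector of observed same-color frequencies, one
#'   per experiment replicate (or a tibble with a `frequency` column).
#' @param nulls A single `rcp_mc_null` (recycled) or a list of them, one
#'   per experiment replicate.
#' @return Object of class `rcp_integrity_test` wrapping a per-replicate
#'   tibble: `replicate`, `observed`, `null_mean`, `null_sd`, `p_value`,
#'   `within_2sd`, `relative_diff`, `method`. Supports [tidy()] and
#'   [glance()].
#' @export
integrity_test <- function(observed, nulls) {
  if (is.data.frame(observed)) observed <- observed$frequency
  abort_if(length(observed) < 1, "need at least one observed replicate")
  if (inherits(nulls, "rcp_mc_null")) nulls <- rep(list(nulls), length(observed))
  abort_if(length(nulls) != length(observed),
           "need one null per observed replicate")
  rows <- purrr::map(seq_along(observed), function(i) {
    nl <- nulls[[i]]
    abort_if(!inherits(nl, "rcp_mc_null"), "nulls must be rcp_mc_null objects")
    obs <- observed[i]
    if (nl$sd_frequency == 0 || is.na(nl$sd_frequency)) {
      p <- if (isTRUE(all.equal(obs, nl$mean_frequency))) 1 else 0
      method <- "exact comparison (degenerate null SD)"
    } else {
      p <- t.test(nl$frequencies, mu = obs)$p.value
      method <- "one-sample two-tailed t-test"
    }
    tibble::tibble(
      replicate = i,
      observed = obs,
      null_mean = nl$mean_frequency,
      null_sd = nl$sd_frequency,
      p_value = p,
      within_2sd = abs(obs - nl$mean_frequency) <= 2 * nl$sd_frequency,
      relative_diff = (obs - nl$mean_frequency) / nl$mean_frequency,
      method = method
    )
  })
  structure(list(results = dplyr::bind_rows(rows)),
            class = "rcp_integrity_test")
}

#' @export
print.rcp_integrity_test <- function(x, ...) {
  cat("<rcp_integrity_test>\n")
  print(x$results)
  invisible(x)
}

#' Pool same-color neighbor statistics over images
#'
#' Frequencies from several images of one experiment replicate are pooled
#' by total counts: summed same-color pairs over summed pairs.
#'
#' @param stats_list List of [same_color_frequency()] results.
#' @return One-row tibble like [same_color_frequency()].
#' @export
pool_neighbor_stats <- function(stats_list) {
  all <- dplyr::bind_rows(stats_list)
  abort_if(nrow(all) == 0, "nothing to pool")
  tibble::tibble(n_pairs_total = sum(all$n_pairs_total),
                 n_same_color = sum(all$n_same_color),
                 frequency = sum(all$n_same_color) / sum(all$n_pairs_total))
}

#' Label-permutation variant of the null
#'
#' Instead of re-placing points uniformly, keeps the observed positions
#' and permutes the color labels. This conditions on the observed spatial
#' geometry (including any clustering), so it tests label exchangeability
#' rather than complete spatial randomness; the random-placement null of
#' [monte_carlo_null()] is the primary null.
#'
#' @param points Tibble with `row`, `col`, `color`.
#' @param n_replicates Number of permutations (default 10).
#' @param seed Optional master seed.
#' @return An `rcp_mc_null` object.
#' @export
permutation_null <- function(points, n_replicates = 10, seed = NULL) {
  abort_if(nrow(points) < 2, "need at least two points")
  seeds <- if (is.null(seed)) rep(list(NULL), n_replicates)
           else as.list(derive_seeds(seed, n_replicates))
  freqs <- vapply(seeds, function(s) {
    perm <- points
    perm$color <- with_seed_maybe(s, sample(points$color))
    same_color_frequency(perm)$frequency
  }, numeric(1))
  counts <- c(sum(points$color == 1), sum(points$color == 2))
  structure(list(frequencies = freqs,
                 mean_frequency = mean(freqs),
                 sd_frequency = sd(freqs),
                 n_replicates = as.integer(n_replicates),
                 color_counts = as.integer(counts),
                 image_shape = NULL,
                 seed = seed),
            class = "rcp_mc_null")
}
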