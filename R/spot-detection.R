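# Two detection paths: threshold + connected components (for SNR
# measurement) and Gaussian smoothing + median subtraction + local maxima
# (for the proximity/integrity statistic).

#' Segment candidate signals by thresholding
#'
#' Binarizes the corrected image at `>= threshold`, labels 8-connected
#' components, and measures each object. Circularity is the form factor
#' `4 * pi * area / perimeter^2` (1 for a perfect disk). The perimeter is
#' the Crofton-style estimate `pi / 4` times the count of 4-adjacent
#' foreground/background pixel edges: the raw edge count measures
#' city-block boundary length, which overestimates the Euclidean
#' perimeter of a digitized disk by `4 / pi` and would push round spots
#' below the 0.5 circularity cut. Circularity is capped at 1 to absorb
#' discretization overshoot for tiny objects.
#'
#' @param corrected Numeric matrix (background-corrected projection).
#' @param threshold Positive intensity threshold.
#' @return Tibble with one row per object: `label`, `area_px`,
#'   `perimeter_px`, `circularity`, `centroid_row`, `centroid_col`,
#'   `peak_row`, `peak_col`, `peak_intensity`, and a list-column `pixels`
#'   (two-column matrix of row, col).
#' @export
segment_signals <- function(corrected, threshold) {
  abort_if(!is.matrix(corrected) || !is.numeric(corrected),
           "corrected must be a numeric matrix")
  abort_if(!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0,
           "threshold must be a single positive number")
  mask <- corrected >= threshold
  labels <- label_components(mask, connectivity = 8)
  n_obj <- max(labels)
  empty <- tibble::tibble(label = integer(), area_px = integer(),
                          perimeter_px = numeric(), circularity = numeric(),
                          centroid_row = numeric(), centroid_col = numeric(),
                          peak_row = integer(), peak_col = integer(),
                          peak_intensity = numeric(), pixels = list())
  if (n_obj == 0L) return(empty)
  h <- nrow(corrected)
  idx <- which(labels > 0L)
  lab <- labels[idx]
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  vals <- corrected[idx]
  by_obj <- split(seq_along(idx), lab)
  out <- purrr::map(by_obj, function(sel) {
    r <- rows[sel]; c <- cols[sel]; v <- vals[sel]
    obj_mask <- matrix(FALSE, max(r) - min(r) + 1L, max(c) - min(c) + 1L)
    obj_mask[cbind(r - min(r) + 1L, c - min(c) + 1L)] <- TRUE
    per <- (pi / 4) * boundary_edge_perimeter(obj_mask)
    peak <- which.max(v)
    tibble::tibble(
      area_px = length(sel),
      perimeter_px = per,
      circularity = min(1, 4 * pi * length(sel) / per^2),
      centroid_row = mean(r),
      centroid_col = mean(c),
      peak_row = r[peak],
      peak_col = c[peak],
      peak_intensity = v[peak],
      pixels = list(cbind(row = r, col = c))
    )
  })
  dplyr::bind_rows(out, .id = "label") |>
    dplyr::mutate(label = as.integer(.data$label))
}

#' Exclude clustered signals by size and shape
#'
#' Clustered (coalesced) RCPs segment as large or irregular objects;
#' removing objects larger than `max_area` pixels or with circularity
#' below `min_circularity` keeps only well-formed single signals. The
#' boundary values themselves are kept: an object of exactly `max_area`
#' pixels or exactly `min_circularity` passes.
#'
#' @param signals Tibble from [segment_signals()].
#' @param max_area Maximum object area in pixels (default 40).
#' @param min_circularity Minimum circularity (default 0.5).
#' @return The retained rows of `signals`, order preserved.
#' @export
filter_clusters <- function(signals, max_area = 40, min_circularity = 0.5) {
  abort_if(max_area <= 0, "max_area must be positive")
  abort_if(min_circularity <= 0, "min_circularity must be positive")
  dplyr::filter(signals,
                .data$area_px <= max_area,
                .data$circularity >= min_circularity)
}

#' Detect signals as local intensity maxima
#'
#' Smooths the image with a Gaussian kernel (standard deviation one pixel
#' by default, the length scale of a diffraction-limited spot), removes
#' background by subtracting the median of the smoothed image (floored at
#' 0), and reports strict local maxima over the 8-neighborhood with
#' positive remaining value. A flat plateau of equal maximal values yields
#' a single point at the plateau centroid.
#'
#' @param image Numeric matrix.
#' @param smoothing_sigma_px Gaussian sigma in pixels (default 1).
#' @param min_prominence Minimum median-subtracted value a maximum must
#'   exceed (default 0, i.e. any positive value qualifies).
#' @return Tibble with columns `row`, `col` (plateau centroids, real
#'   valued) and `value` (smoothed, median-subtracted intensity).
#' @export
detect_maxima <- function(image, smoothing_sigma_px = 1, min_prominence = 0) {
  abort_if(!is.matrix(image) || length(image) == 0,
           "image must be a nonempty numeric matrix")
  sm <- gaussian_smooth(image, smoothing_sigma_px)
  sm <- sm - median(sm)
  sm[sm < 0] <- 0
  h <- nrow(sm); w <- ncol(sm)
  padded <- matrix(-Inf, h + 2L, w + 2L)
  padded[2:(h + 1L), 2:(w + 1L)] <- sm
  nb_max <- matrix(-Inf, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb_max <- pmax(nb_max, padded[(2:(h + 1L)) + dr, (2:(w + 1L)) + dc])
  }
  cand <- sm > min_prominence & sm > 0 & sm >= nb_max
  if (!any(cand)) return(tibble::tibble(row = numeric(), col = numeric(),
                                        value = numeric()))
  # Adjacent candidates necessarily share one value (otherwise the smaller
  # would have a greater neighbor), so candidate components are plateaus.
  plateau <- label_components(cand, connectivity = 8)
  out <- purrr::map(seq_len(max(plateau)), function(lb) {
    idx <- which(plateau == lb)
    r <- ((idx - 1L) %% h) + 1L
    c <- ((idx - 1L) %/% h) + 1L
    val <- sm[idx[1]]
    # Strictness: every neighbor outside the plateau must be lower.
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      rr <- r + dr; cc <- c + dc
      inside <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
      nb <- cbind(rr[inside], cc[inside])
      if (length(nb)) {
        on_plateau <- plateau[nb] == lb
        if (any(sm[nb[!on_plateau, , drop = FALSE]] >= val)) return(NULL)
      }
    }
    tibble::tibble(row = mean(r), col = mean(c), value = val)
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    return(tibble::tibble(row = numeric(), col = numeric(), value = numeric()))
  }
  res
}

#' Combine per-channel maxima into a two-color point set
#'
#' @param points1,points2 Tibbles from [detect_maxima()] for the two
#'   channels.
#' @return Tibble with columns `row`, `col`, `color`.
#' @export
as_colored_points <- function(points1, points2) {
  dplyr::bind_rows(
    dplyr::mutate(points1[, c("row", "col")], color = 1L),
    dplyr::mutate(points2[, c("row", "col")], color = 2L)
  )
}
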