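# Projection and automatic thresholding of z-stacks.

#' Project a z-stack to background-corrected 2-D
#'
#' Computes the pixelwise maximum and minimum intensity projections over z
#' and their difference (the background-corrected image, floored at 0).
#' Subtracting the minimum projection removes structure that is present at
#' every focal plane — the slide/tissue background — while in-focus spots
#' survive in the maximum projection.
#'
#' @param stack Numeric array `[row, col, z]`, or a matrix (treated as one
#'   z-level).
#' @return A list of class `projection_pair`: `max_projection`,
#'   `min_projection`, `corrected` (all matrices of one shape) and `n_z`.
#' @export
project_stack <- function(stack) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1L))
  abort_if(!is.array(stack) || length(dim(stack)) != 3L,
           "stack must be a [row, col, z] array or a matrix")
  nz <- dim(stack)[3]
  abort_if(nz < 1L, "stack must contain at least one z-level")
  planes <- lapply(seq_len(nz), function(z) stack[, , z])
  max_proj <- Reduce(pmax, planes)
  min_proj <- Reduce(pmin, planes)
  corrected <- max_proj - min_proj
  corrected[corrected < 0] <- 0
  structure(list(max_projection = max_proj,
                 min_projection = min_proj,
                 corrected = corrected,
                 n_z = nz),
            class = "projection_pair")
}

#' @export
print.projection_pair <- function(x, ...) {
  cat(sprintf("<projection_pair> %d x %d px from %d z-level(s)\n",
              nrow(x$corrected), ncol(x$corrected), x$n_z))
  invisible(x)
}

#' Automatic background-mode intensity threshold
#'
#' Estimates the background intensity as the mode of the pixel histogram
#' and sets the detection threshold at twice that value, the "background"
#' style of automatic thresholding used for sparse spot images where the
#' vast majority of pixels are background. Only pixels between the 2% and
#' 98% percentiles of the intensity distribution enter the histogram,
#' making the mode robust to dead and hot pixels.
#'
#' @param image Numeric matrix.
#' @param n_bins Number of equal-width histogram bins over the clipped
#'   range (default 256). The mode is the center of the fullest bin; ties
#'   break toward the lower-intensity bin (a conservative threshold).
#' @param clip_quantiles Lower/upper percentile clip (default `c(0.02, 0.98)`).
#' @return A list of class `threshold_result`: `mode_value`, `threshold`
#'   (`= 2 * mode_value`), `clip_range`, `n_bins`.
#' @export
mode_threshold <- function(image, n_bins = 256L, clip_quantiles = c(0.02, 0.98)) {
  abort_if(!is.numeric(image) || length(image) == 0, "image must be nonempty numeric")
  abort_if(!is_count(n_bins) || n_bins < 1, "n_bins must be a positive integer")
  vals <- as.numeric(image)
  clip <- unname(quantile(vals, clip_quantiles, names = FALSE))
  if (clip[1] == clip[2]) {
    mode_value <- clip[1]
  } else {
    keep <- vals[vals >= clip[1] & vals <= clip[2]]
    abort_if(length(keep) == 0, "no pixels remain inside the clip range")
    counts <- histogram_counts(keep, clip[1], clip[2], n_bins)
    best <- which.max(counts)  # which.max takes the first (lowest) maximal bin
    width <- (clip[2] - clip[1]) / n_bins
    mode_value <- clip[1] + (best - 0.5) * width
  }
  structure(list(mode_value = mode_value,
                 threshold = 2 * mode_value,
                 clip_range = clip,
                 n_bins = as.integer(n_bins)),
            class = "threshold_result")
}

histogram_counts <- function(x, lo, hi, n_bins) {
  bin <- floor((x - lo) / (hi - lo) * n_bins) + 1L
  bin[bin > n_bins] <- n_bins  # x == hi lands in the last bin
  tabulate(bin, nbins = n_bins)
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> mode %.4g, threshold %.4g (clip %.4g..%.4g)\n",
              x$mode_value, x$threshold, x$clip_range[1], x$clip_range[2]))
  invisible(x)
}
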