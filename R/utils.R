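# Shared low-level helpers: argument checks, disk/annulus pixel offsets,
# Gaussian smoothing, connected-component labeling, seed derivation.
#
# Coordinate convention used throughout the package: 1-based (row, col),
# pixel centers at integer coordinates, images stored as R matrices
# [row, col] and z-stacks as arrays [row, col, z].

abort_if <- function(cond, msg) {
  if (cond) stop(msg, call. = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

#' Pixel offsets of a Euclidean disk
#'
#' Integer (row, col) offsets whose Euclidean distance from the origin is
#' at most `radius`. A pixel belongs to a disk iff the distance from its
#' integer coordinate to the disk center is `<= radius`.
#'
#' @param radius Disk radius in pixels (may be non-integer).
#' @return Integer matrix with columns `dr`, `dc`.
#' @keywords internal
#' @noRd
disk_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  keep <- sqrt(g$dr^2 + g$dc^2) <= radius
  as.matrix(g[keep, , drop = FALSE])
}

# Annulus: strictly greater than inner, at most outer.
annulus_offsets <- function(inner_radius, outer_radius) {
  r <- ceiling(outer_radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  d <- sqrt(g$dr^2 + g$dc^2)
  keep <- d > inner_radius & d <= outer_radius
  as.matrix(g[keep, , drop = FALSE])
}

#' Gaussian smoothing of a 2-D image
#'
#' Convolves with an isotropic Gaussian kernel (replicate boundary).
#' `sigma = 0` returns the image unchanged.
#'
#' @param image Numeric matrix.
#' @param sigma Kernel standard deviation in pixels.
#' @return Numeric matrix of the same shape.
#' @export
gaussian_smooth <- function(image, sigma) {
  abort_if(!is.matrix(image) || !is.numeric(image), "image must be a numeric matrix")
  abort_if(!is.numeric(sigma) || length(sigma) != 1L || sigma < 0,
           "sigma must be a single non-negative number")
  if (sigma == 0) return(image)
  size <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  brush <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma)
  out <- EBImage::filter2(image, brush, boundary = "replicate")
  matrix(as.numeric(out), nrow = nrow(image))
}

#' Label connected components of a binary mask
#'
#' Breadth-first labeling of foreground (`TRUE`/nonzero) pixels.
#'
#' @param mask Logical or numeric matrix; nonzero is foreground.
#' @param connectivity 4 or 8 (default 8: diagonal neighbors connect).
#' @return Integer matrix; 0 is background, components numbered from 1 in
#'   order of their first pixel in column-major scan order.
#' @export
label_components <- function(mask, connectivity = 8) {
  abort_if(!is.matrix(mask), "mask must be a matrix")
  abort_if(!connectivity %in% c(4, 8), "connectivity must be 4 or 8")
  h <- nrow(mask); w <- ncol(mask)
  fg <- which(mask != 0)
  labels <- matrix(0L, h, w)
  if (length(fg) == 0L) return(labels)
  if (connectivity == 8) {
    dr <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
    dc <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L)
    dc <- c(0L, 0L, -1L, 1L)
  }
  fg_mask <- matrix(FALSE, h, w)
  fg_mask[fg] <- TRUE
  lab <- 0L
  for (start in fg) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    while (length(queue)) {
      idx <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r0 <- ((idx - 1L) %% h) + 1L
      c0 <- ((idx - 1L) %/% h) + 1L
      rr <- r0 + dr
      cc <- c0 + dc
      ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
      nb <- (cc[ok] - 1L) * h + rr[ok]
      nb <- nb[fg_mask[nb] & labels[nb] == 0L]
      if (length(nb)) {
        labels[nb] <- lab
        queue <- c(queue, nb)
      }
    }
  }
  labels
}

# Perimeter of one labeled object as the count of 4-adjacent foreground/
# background (or image border) pixel edges.
boundary_edge_perimeter <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  padded <- matrix(FALSE, h + 2L, w + 2L)
  padded[2:(h + 1L), 2:(w + 1L)] <- mask
  core <- padded[2:(h + 1L), 2:(w + 1L), drop = FALSE]
  sum(core & !padded[1:h, 2:(w + 1L), drop = FALSE]) +
    sum(core & !padded[3:(h + 2L), 2:(w + 1L), drop = FALSE]) +
    sum(core & !padded[2:(h + 1L), 1:w, drop = FALSE]) +
    sum(core & !padded[2:(h + 1L), 3:(w + 2L), drop = FALSE])
}

# Deterministic per-replicate seeds derived from one master seed. Keeps
# every derived seed a valid 32-bit R integer.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max, n))
}

# Run `expr` under `seed` if non-NULL, otherwise with the ambient RNG.
with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}
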