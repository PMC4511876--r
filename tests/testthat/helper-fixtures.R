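# Shared fixture builders. Everything is generated in code; tests that
# need images build small ones here.

# A quiet, small compact-scene config for fast end-to-end tests.
small_scene_config <- function(...) {
  scene_config(image_shape = c(160L, 160L), n_z = 8L,
               n_spots_per_color = c(12L, 12L),
               border_margin_px = 10, min_center_separation_px = 14, ...)
}

# Deterministic blob image: Gaussian spots on a flat background, no noise.
blob_image <- function(shape, centers, amplitude = 100, sigma = 1.5,
                       background = 0) {
  img <- matrix(background, shape[1], shape[2])
  for (i in seq_len(nrow(centers))) {
    r0 <- centers[i, 1]; c0 <- centers[i, 2]
    rr <- seq_len(shape[1]); cc <- seq_len(shape[2])
    img <- img + amplitude *
      exp(-outer((rr - r0)^2, (cc - c0)^2, "+") / (2 * sigma^2))
  }
  img
}

# O(n^2) oracle for the same-color nearest-neighbor frequency, with the
# same tie-break (smaller row, then col).
brute_force_same_color <- function(points) {
  n <- nrow(points)
  same <- 0L
  for (i in seq_len(n)) {
    d <- sqrt((points$row - points$row[i])^2 + (points$col - points$col[i])^2)
    d[i] <- Inf
    best <- which(d == min(d))
    if (length(best) > 1) {
      ord <- order(points$row[best], points$col[best], best)
      best <- best[ord[1]]
    }
    same <- same + (points$color[best] == points$color[i])
  }
  same / n
}

# Naive recursive flood fill (8-connected) returning a label matrix;
# independent of label_components' BFS.
flood_fill_labels <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  lab <- 0L
  fill <- function(r, c, lab) {
    stack <- list(c(r, c))
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      r0 <- p[1]; c0 <- p[2]
      if (r0 < 1 || r0 > h || c0 < 1 || c0 > w) next
      if (!mask[r0, c0] || labels[r0, c0] != 0L) next
      labels[r0, c0] <<- lab
      for (dr in -1:1) for (dc in -1:1) {
        if (dr || dc) stack[[length(stack) + 1L]] <- c(r0 + dr, c0 + dc)
      }
    }
  }
  for (c in seq_len(w)) for (r in seq_len(h)) {
    if (mask[r, c] && labels[r, c] == 0L) {
      lab <- lab + 1L
      fill(r, c, lab)
    }
  }
  labels
}

# Brute-force perimeter: count 4-neighbor fg/bg (or border) edges.
brute_force_perimeter <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  per <- 0L
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (!mask[r, c]) next
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr < 1 || rr > h || cc < 1 || cc > w || !mask[rr, cc]) per <- per + 1L
    }
  }
  per
}
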