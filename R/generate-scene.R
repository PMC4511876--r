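# Synthetic scene rendering: parent-center placement with minimum
# separation, sub-focus sampling, 3-D Gaussian blob rendering, background
# and noise.

#' Generate a synthetic two-channel RCP scene with ground truth
#'
#' Renders each RCP as one (compact mode) or several (dispersed mode) 3-D
#' Gaussian blobs in the channel matching its color: lateral sigma
#' `psf_sigma_px`, axial sigma `axial_sigma_z` z-levels. Parent centers are
#' placed by rejection sampling, uniform over the field minus the border
#' margin, with pairwise distance at least `min_center_separation_px`.
#' Background (constant level plus a smooth linear ramp) and noise (Poisson
#' on signal plus background, then additive Gaussian, floored at 0) are
#' added per channel. The same configuration and seed reproduce the scene
#' exactly.
#'
#' @param config A [scene_config()].
#' @param seed RNG seed; defaults to `config$seed`. `NULL` uses the ambient
#'   RNG state.
#' @return A list with elements
#'   * `channel1`, `channel2`: numeric arrays `[row, col, z]`;
#'   * `truth`: tibble with one row per sub-focus — `rcp_id`, `color`,
#'     `parent_row`, `parent_col`, `parent_z`, `subfocus_index`, `row`,
#'     `col`, `z`, `amplitude`;
#'   * `config`: the configuration used.
#' @export
generate_scene <- function(config, seed = config$seed) {
  abort_if(!inherits(config, "scene_config"), "config must be a scene_config")
  with_seed_maybe(seed, generate_scene_impl(config))
}

generate_scene_impl <- function(config) {
  h <- config$image_shape[1]; w <- config$image_shape[2]; nz <- config$n_z
  n1 <- config$n_spots_per_color[1]; n2 <- config$n_spots_per_color[2]
  n <- n1 + n2

  centers <- place_centers(n, h, w,
                           margin = config$border_margin_px,
                           min_sep = config$min_center_separation_px)
  colors <- rep(1:2, times = c(n1, n2))

  # Parent axial centers: integer z-levels away from the stack faces where
  # possible, so each blob spans >= 3 levels.
  zlo <- min(nz, 2L); zhi <- max(1L, nz - 1L)
  parent_z <- if (zlo < zhi) {
    sample(zlo:zhi, n, replace = TRUE)
  } else {
    rep(max(zlo, 1L), n)
  }
  parent_z <- pmin(parent_z, nz)

  amp_factor <- if (config$amplitude_cv > 0) {
    exp(rnorm(n, mean = -config$amplitude_cv^2 / 2, sd = config$amplitude_cv))
  } else rep(1, n)
  parent_amp <- config$spot_amplitude * amp_factor

  truth_rows <- vector("list", n)
  for (i in seq_len(n)) {
    k <- subfocus_count(config)
    if (k == 1L) {
      sub <- tibble::tibble(subfocus_index = 1L,
                            row = centers[i, 1], col = centers[i, 2],
                            z = parent_z[i], amplitude = parent_amp[i])
    } else {
      disp <- truncated_gaussian_disp(k, config$subfoci_spread_px)
      rows <- pmin(pmax(centers[i, 1] + disp[, 1], 1), h)
      cols <- pmin(pmax(centers[i, 2] + disp[, 2], 1), w)
      dz <- sample(c(-1L, 0L, 1L), k, replace = TRUE, prob = c(0.25, 0.5, 0.25))
      zz <- pmin(pmax(parent_z[i] + dz, 1L), nz)
      wts <- rgamma(k, shape = 1)
      wts <- wts / sum(wts)
      sub <- tibble::tibble(subfocus_index = seq_len(k),
                            row = rows, col = cols, z = zz,
                            amplitude = parent_amp[i] * wts)
    }
    sub$rcp_id <- i
    sub$color <- colors[i]
    sub$parent_row <- centers[i, 1]
    sub$parent_col <- centers[i, 2]
    sub$parent_z <- parent_z[i]
    truth_rows[[i]] <- sub
  }
  truth_cols <- c("rcp_id", "color", "parent_row", "parent_col", "parent_z",
                  "subfocus_index", "row", "col", "z", "amplitude")
  truth <- if (n == 0L) {
    tibble::tibble(rcp_id = integer(), color = integer(),
                   parent_row = numeric(), parent_col = numeric(),
                   parent_z = integer(), subfocus_index = integer(),
                   row = numeric(), col = numeric(), z = integer(),
                   amplitude = numeric())
  } else {
    dplyr::bind_rows(truth_rows)[, truth_cols]
  }

  ch <- lapply(1:2, function(col_id) {
    sig <- array(0, dim = c(h, w, nz))
    sub <- truth[truth$color == col_id, , drop = FALSE]
    for (j in seq_len(nrow(sub))) {
      sig <- add_blob(sig, sub$row[j], sub$col[j], sub$z[j], sub$amplitude[j],
                      config$psf_sigma_px, config$axial_sigma_z)
    }
    add_background_noise(sig, config)
  })

  list(channel1 = ch[[1]], channel2 = ch[[2]], truth = truth, config = config)
}

# Rejection sampling of parent centers; errors naming the first spot that
# cannot be placed within the attempt budget.
place_centers <- function(n, h, w, margin, min_sep, max_attempts = 2000L) {
  centers <- matrix(numeric(0), ncol = 2)
  if (n == 0L) return(centers)
  rlo <- 1 + margin; rhi <- h - margin
  clo <- 1 + margin; chi <- w - margin
  abort_if(rlo > rhi || clo > chi,
           "border margin leaves no room to place spots")
  centers <- matrix(NA_real_, nrow = n, ncol = 2)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (attempt in seq_len(max_attempts)) {
      cand <- c(runif(1, rlo, rhi), runif(1, clo, chi))
      if (i == 1L || all(sqrt((centers[seq_len(i - 1), 1] - cand[1])^2 +
                              (centers[seq_len(i - 1), 2] - cand[2])^2) >= min_sep)) {
        centers[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    abort_if(!placed, sprintf(
      "could not place spot %d of %d with separation >= %g after %d attempts",
      i, n, min_sep, max_attempts))
  }
  centers
}

subfocus_count <- function(config) {
  if (config$mode == "compact") return(1L)
  if (!is.null(config$subfoci_fixed)) return(config$subfoci_fixed)
  min(1L + rpois(1, config$subfoci_lambda), config$subfoci_kmax)
}

# Isotropic in-plane Gaussian displacements truncated at radius 3*sd.
truncated_gaussian_disp <- function(k, sd) {
  out <- matrix(rnorm(2 * k, sd = sd), ncol = 2)
  r <- sqrt(rowSums(out^2))
  bad <- which(r > 3 * sd)
  while (length(bad)) {
    out[bad, ] <- rnorm(2 * length(bad), sd = sd)
    r <- sqrt(rowSums(out[bad, , drop = FALSE]^2))
    bad <- bad[r > 3 * sd]
  }
  out
}

# Add one 3-D Gaussian blob (peak value = amplitude at the continuous
# center) to a stack, evaluated over a +-4 sigma window.
add_blob <- function(stack, r0, c0, z0, amplitude, sigma, sigma_z) {
  h <- dim(stack)[1]; w <- dim(stack)[2]; nz <- dim(stack)[3]
  wr <- ceiling(4 * sigma)
  rr <- max(1, floor(r0 - wr)):min(h, ceiling(r0 + wr))
  cc <- max(1, floor(c0 - wr)):min(w, ceiling(c0 + wr))
  wz <- ceiling(4 * sigma_z)
  zz <- max(1, floor(z0 - wz)):min(nz, ceiling(z0 + wz))
  lat <- exp(-(outer((rr - r0)^2, (cc - c0)^2, "+")) / (2 * sigma^2))
  ax <- exp(-((zz - z0)^2) / (2 * sigma_z^2))
  for (iz in seq_along(zz)) {
    stack[rr, cc, zz[iz]] <- stack[rr, cc, zz[iz]] + amplitude * ax[iz] * lat
  }
  stack
}

add_background_noise <- function(sig, config) {
  h <- dim(sig)[1]; w <- dim(sig)[2]; nz <- dim(sig)[3]
  bg <- config$background_level
  if (config$background_gradient > 0) {
    ramp_r <- if (h > 1) (seq_len(h) - 1) / (h - 1) else rep(0, h)
    ramp_c <- if (w > 1) (seq_len(w) - 1) / (w - 1) else rep(0, w)
    bg <- bg + config$background_gradient * outer(ramp_r, ramp_c, function(a, b) (a + b) / 2)
  }
  bg_field <- if (length(bg) == 1L) matrix(bg, h, w) else bg
  # Axial haze profile: mid-stack planes carry more out-of-focus
  # background than the stack ends (cosine bump, min 0 at the ends).
  zprof <- if (nz > 1) {
    0.5 * (1 + cos(2 * pi * (seq_len(nz) - (nz + 1) / 2) / nz))
  } else rep(1, nz)
  out <- sig
  for (iz in seq_len(nz)) {
    out[, , iz] <- out[, , iz] +
      bg_field * (1 + config$background_z_amplitude * zprof[iz])
  }
  if (config$poisson_noise) {
    g <- config$photons_per_unit
    out <- array(rpois(length(out), lambda = pmax(out, 0) * g) / g,
                 dim = dim(out))
  }
  if (config$gaussian_noise_sd > 0) {
    out <- out + array(rnorm(length(out), sd = config$gaussian_noise_sd),
                       dim = dim(out))
  }
  out[out < 0] <- 0
  out
}

#' Generate a random two-color point set
#'
#' Places exactly `n_per_color[1]` points of color 1 and `n_per_color[2]`
#' of color 2 independently and uniformly over the image rectangle. This is
#' the point-level random-placement model behind [monte_carlo_null()]:
#' spatially random signals with fixed per-color occurrence counts.
#'
#' @param n_per_color Integer vector `c(n1, n2)`.
#' @param image_shape `c(height, width)` of the rectangle, pixels.
#' @param seed Optional RNG seed.
#' @return Tibble with columns `row`, `col`, `color`.
#' @export
generate_point_set <- function(n_per_color, image_shape, seed = NULL) {
  abort_if(length(n_per_color) != 2L || !all(vapply(n_per_color, is_count, TRUE)),
           "n_per_color must be two non-negative integers")
  abort_if(length(image_shape) != 2L || any(image_shape <= 0),
           "image_shape must be two positive numbers")
  n <- sum(n_per_color)
  with_seed_maybe(seed, tibble::tibble(
    row = runif(n, 0, image_shape[1]),
    col = runif(n, 0, image_shape[2]),
    color = rep(1:2, times = n_per_color)
  ))
}
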