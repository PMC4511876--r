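#' Configuration for a synthetic two-channel RCP scene
#'
#' Describes a simulated microscopy field of rolling circle amplification
#' products (RCPs) rendered as diffraction-limited Gaussian spots in two
#' color channels over a z-stack. `mode = "compact"` renders every RCP as
#' a single tight spot; `mode = "dispersed"` splits each RCP into several
#' nearby sub-foci, modeling disintegration of the amplification product
#' into a cluster of same-color signals. Total fluorophore content is
#' conserved between the two modes: in dispersed mode the parent spot
#' amplitude is shared across sub-foci by symmetric Dirichlet weights, so
#' compact-versus-dispersed comparisons of brightness are like-for-like.
#'
#' Defaults emulate the acquisition the statistics were designed for:
#' 14-bit-scale intensities, ~0.5 um pixels (a diffraction-limited spot
#' has `psf_sigma_px` near 1), 12 z-levels, and sparse spots over a
#' smooth uneven background.
#'
#' @param image_shape Integer vector `c(height, width)` in pixels.
#' @param n_z Number of z-levels (>= 1).
#' @param n_spots_per_color Integer vector `c(n1, n2)`: RCP counts for the
#'   two channels.
#' @param mode `"compact"` or `"dispersed"`.
#' @param subfoci_lambda In dispersed mode the sub-focus count per RCP is
#'   `1 + Poisson(subfoci_lambda)` truncated to `[1, subfoci_kmax]`.
#' @param subfoci_kmax Maximum sub-foci per RCP.
#' @param subfoci_fixed Optional fixed sub-focus count (overrides the
#'   Poisson law; used mainly for controlled experiments).
#' @param subfoci_spread_px In-plane standard deviation (pixels) of the
#'   isotropic Gaussian displacement of sub-foci from the parent center;
#'   displacements are truncated at 3x this value. Axial displacement is
#'   at most one z-level.
#' @param psf_sigma_px Lateral Gaussian width of one spot, in pixels.
#' @param axial_sigma_z Axial Gaussian width, in z-levels (each spot spans
#'   at least 3 z-levels).
#' @param spot_amplitude Mean peak amplitude of one RCP, intensity units.
#' @param amplitude_cv Log-normal sdlog of the per-RCP multiplicative
#'   amplitude variation.
#' @param background_level Constant background, intensity units.
#' @param background_gradient Peak-to-peak amplitude of a smooth linear
#'   background ramp across the field.
#' @param background_z_amplitude Fractional axial variation of the
#'   background: out-of-focus haze makes mid-stack planes brighter than
#'   the stack ends by up to this fraction of the local background
#'   (smooth cosine profile over z). This is what leaves a nonzero
#'   background pedestal in the max-minus-min corrected projection, as in
#'   real stacks.
#' @param poisson_noise If `TRUE`, pixel values (signal + background) are
#'   shot-noise resampled: the photon count `photons_per_unit * value` is
#'   Poisson-distributed and converted back to intensity units.
#' @param photons_per_unit Detector conversion factor (detected photons
#'   per intensity unit); sets the shot-noise scale, SD
#'   `sqrt(value / photons_per_unit)` intensity units.
#' @param gaussian_noise_sd SD of additive Gaussian read noise.
#' @param min_center_separation_px Minimum pairwise distance between
#'   parent RCP centers (across both colors).
#' @param border_margin_px Minimum distance of parent centers from the
#'   image border; keep at least the outer SNR disk radius so measurement
#'   neighborhoods fit inside the field.
#' @param seed Optional RNG seed stored with the config; `generate_scene()`
#'   uses it unless given an explicit seed.
#' @return An object of class `scene_config`.
#' @seealso [generate_scene()], [generate_point_set()]
#' @export
scene_config <- function(image_shape = c(512L, 512L),
                         n_z = 12L,
                         n_spots_per_color = c(120L, 120L),
                         mode = c("compact", "dispersed"),
                         subfoci_lambda = 1.5,
                         subfoci_kmax = 6L,
                         subfoci_fixed = NULL,
                         subfoci_spread_px = 4,
                         psf_sigma_px = 1.2,
                         axial_sigma_z = 1.0,
                         spot_amplitude = 3000,
                         amplitude_cv = 0.25,
                         background_level = 400,
                         background_gradient = 120,
                         background_z_amplitude = 0.3,
                         poisson_noise = TRUE,
                         photons_per_unit = 4,
                         gaussian_noise_sd = 10,
                         min_center_separation_px = 8,
                         border_margin_px = 12,
                         seed = NULL) {
  mode <- match.arg(mode)
  abort_if(length(image_shape) != 2L || !all(vapply(image_shape, is_count, TRUE)) ||
             any(image_shape < 1), "image_shape must be two positive integers")
  abort_if(!is_count(n_z) || n_z < 1, "n_z must be a positive integer")
  abort_if(length(n_spots_per_color) != 2L ||
             !all(vapply(n_spots_per_color, is_count, TRUE)),
           "n_spots_per_color must be two non-negative integers")
  abort_if(!is_count(subfoci_kmax) || subfoci_kmax < 1,
           "subfoci_kmax must be a positive integer")
  abort_if(!is.null(subfoci_fixed) &&
             (!is_count(subfoci_fixed) || subfoci_fixed < 1),
           "subfoci_fixed must be NULL or a positive integer")
  abort_if(subfoci_lambda < 0, "subfoci_lambda must be >= 0")
  abort_if(subfoci_spread_px <= 0, "subfoci_spread_px must be > 0")
  abort_if(psf_sigma_px <= 0, "psf_sigma_px must be > 0")
  abort_if(axial_sigma_z <= 0, "axial_sigma_z must be > 0")
  abort_if(spot_amplitude <= 0, "spot_amplitude must be > 0")
  abort_if(amplitude_cv < 0, "amplitude_cv must be >= 0")
  abort_if(background_level < 0, "background_level must be >= 0")
  abort_if(background_gradient < 0, "background_gradient must be >= 0")
  abort_if(background_z_amplitude < 0, "background_z_amplitude must be >= 0")
  abort_if(photons_per_unit <= 0, "photons_per_unit must be > 0")
  abort_if(gaussian_noise_sd < 0, "gaussian_noise_sd must be >= 0")
  abort_if(min_center_separation_px < 0, "min_center_separation_px must be >= 0")
  abort_if(border_margin_px < 0, "border_margin_px must be >= 0")

  structure(list(
    image_shape = as.integer(image_shape),
    n_z = as.integer(n_z),
    n_spots_per_color = as.integer(n_spots_per_color),
    mode = mode,
    subfoci_lambda = subfoci_lambda,
    subfoci_kmax = as.integer(subfoci_kmax),
    subfoci_fixed = if (is.null(subfoci_fixed)) NULL else as.integer(subfoci_fixed),
    subfoci_spread_px = subfoci_spread_px,
    psf_sigma_px = psf_sigma_px,
    axial_sigma_z = axial_sigma_z,
    spot_amplitude = spot_amplitude,
    amplitude_cv = amplitude_cv,
    background_level = background_level,
    background_gradient = background_gradient,
    background_z_amplitude = background_z_amplitude,
    poisson_noise = poisson_noise,
    photons_per_unit = photons_per_unit,
    gaussian_noise_sd = gaussian_noise_sd,
    min_center_separation_px = min_center_separation_px,
    border_margin_px = border_margin_px,
    seed = seed
  ), class = "scene_config")
}

#' @export
print.scene_config <- function(x, ...) {
  cat("<scene_config>\n")
  cat(sprintf("  field: %d x %d px, %d z-levels\n",
              x$image_shape[1], x$image_shape[2], x$n_z))
  cat(sprintf("  spots: %d + %d, mode: %s\n",
              x$n_spots_per_color[1], x$n_spots_per_color[2], x$mode))
  cat(sprintf("  psf sigma: %.2f px, amplitude: %.0f, background: %.0f (+%.0f ramp)\n",
              x$psf_sigma_px, x$spot_amplitude, x$background_level,
              x$background_gradient))
  cat(sprintf("  noise: %s, gaussian sd %.1f\n",
              if (x$poisson_noise) "poisson" else "none", x$gaussian_noise_sd))
  invisible(x)
}
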