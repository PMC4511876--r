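# Synthetic scene generator: ground-truth contracts, determinism,
# photometric mass conservation, and the geometry of the two colors.

test_that("a zero-spot config yields background-only stacks and empty truth", {
  cfg <- scene_config(image_shape = c(40L, 40L), n_z = 4L,
                      n_spots_per_color = c(0L, 0L), seed = 1)
  sc <- generate_scene(cfg)
  expect_identical(dim(sc$channel1), c(40L, 40L, 4L))
  expect_identical(dim(sc$channel2), dim(sc$channel1))
  expect_identical(nrow(sc$truth), 0L)
  # background + noise only: everything near the background level
  expect_lt(max(sc$channel1), 2 * (cfg$background_level + cfg$background_gradient))
})

test_that("a single noiseless compact spot peaks at its amplitude at the true center", {
  cfg <- scene_config(image_shape = c(64L, 64L), n_z = 7L,
                      n_spots_per_color = c(1L, 0L),
                      spot_amplitude = 1000, amplitude_cv = 0,
                      background_level = 0, background_gradient = 0,
                      poisson_noise = FALSE, gaussian_noise_sd = 0,
                      seed = 11)
  sc <- generate_scene(cfg)
  tr <- sc$truth
  expect_identical(nrow(tr), 1L)
  peak <- max(sc$channel1)
  # grid sampling of the continuous center can only lose amplitude
  expect_lte(peak, 1000 + 1e-9)
  expect_gte(peak, 1000 * exp(-0.5 / cfg$psf_sigma_px^2))
  idx <- which(sc$channel1 == peak, arr.ind = TRUE)[1, ]
  expect_lt(abs(idx[1] - tr$row), 1)
  expect_lt(abs(idx[2] - tr$col), 1)
  expect_identical(max(sc$channel2), 0)
  # the blob spans at least 3 z-levels
  z_extent <- sum(apply(sc$channel1, 3, max) > 0.01 * peak)
  expect_gte(z_extent, 3)
})

test_that("dispersed mode with a fixed sub-focus count honors its truth-table contract", {
  cfg <- scene_config(image_shape = c(128L, 128L), n_z = 8L,
                      n_spots_per_color = c(6L, 5L), mode = "dispersed",
                      subfoci_fixed = 3L, seed = 5)
  sc <- generate_scene(cfg)
  tr <- sc$truth
  counts <- table(tr$rcp_id)
  expect_true(all(counts == 3))
  expect_identical(length(unique(tr$rcp_id[tr$color == 1])), 6L)
  expect_identical(length(unique(tr$rcp_id[tr$color == 2])), 5L)
  d <- sqrt((tr$row - tr$parent_row)^2 + (tr$col - tr$parent_col)^2)
  expect_true(all(d <= 3 * cfg$subfoci_spread_px + 1e-9))
  expect_true(all(abs(tr$z - tr$parent_z) <= 1))
  # per-parent amplitude shares sum to the parent amplitude distribution
  tot <- tapply(tr$amplitude, tr$rcp_id, sum)
  expect_true(all(tot > 0))
})

test_that("compact mode has one sub-focus per RCP at the parent center", {
  sc <- generate_scene(small_scene_config(seed = 3))
  tr <- sc$truth
  expect_true(all(table(tr$rcp_id) == 1))
  expect_identical(tr$row, tr$parent_row)
  expect_identical(tr$col, tr$parent_col)
  expect_identical(sum(tr$color == 1), 12L)
  expect_identical(sum(tr$color == 2), 12L)
})

test_that("parent centers respect the separation and border-margin invariants", {
  cfg <- small_scene_config(seed = 9)
  sc <- generate_scene(cfg)
  tr <- sc$truth
  ctr <- unique(tr[, c("parent_row", "parent_col")])
  d <- as.matrix(dist(ctr))
  diag(d) <- Inf
  expect_gte(min(d), cfg$min_center_separation_px)
  expect_gte(min(ctr$parent_row), 1 + cfg$border_margin_px)
  expect_lte(max(ctr$parent_row), cfg$image_shape[1] - cfg$border_margin_px)
  expect_gte(min(ctr$parent_col), 1 + cfg$border_margin_px)
  expect_lte(max(ctr$parent_col), cfg$image_shape[2] - cfg$border_margin_px)
})

test_that("an impossible placement fails with an error naming the spot", {
  cfg <- scene_config(image_shape = c(60L, 60L), n_z = 2L,
                      n_spots_per_color = c(30L, 30L),
                      min_center_separation_px = 30,
                      border_margin_px = 5, seed = 2)
  expect_error(generate_scene(cfg), "could not place spot")
})

test_that("the same config and seed reproduce a scene exactly, on disk too", {
  cfg <- small_scene_config(seed = 21)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$channel1, b$channel1)
  expect_identical(a$channel2, b$channel2)
  expect_identical(a$truth, b$truth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_scene(a, d1); write_scene(b, d2)
  for (f in c("channel1.tif", "channel2.tif", "truth.csv")) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))))
  }
})

test_that("with no background or noise, stack mass equals summed blob mass", {
  # brute-force oracle: full-grid discrete Gaussian sums per sub-focus
  cfg <- scene_config(image_shape = c(96L, 96L), n_z = 10L,
                      n_spots_per_color = c(4L, 3L), mode = "dispersed",
                      subfoci_fixed = 2L, subfoci_spread_px = 2,
                      background_level = 0, background_gradient = 0,
                      poisson_noise = FALSE, gaussian_noise_sd = 0,
                      border_margin_px = 15, seed = 31)
  sc <- generate_scene(cfg)
  expected <- function(truth, shape, nz, sigma, sigma_z) {
    tot <- 0
    for (i in seq_len(nrow(truth))) {
      lat <- sum(exp(-outer((seq_len(shape[1]) - truth$row[i])^2,
                            (seq_len(shape[2]) - truth$col[i])^2, "+") /
                       (2 * sigma^2)))
      ax <- sum(exp(-((seq_len(nz) - truth$z[i])^2) / (2 * sigma_z^2)))
      tot <- tot + truth$amplitude[i] * lat * ax
    }
    tot
  }
  for (ch in 1:2) {
    tr <- sc$truth[sc$truth$color == ch, ]
    mass <- expected(tr, cfg$image_shape, cfg$n_z, cfg$psf_sigma_px,
                     cfg$axial_sigma_z)
    got <- sum(if (ch == 1) sc$channel1 else sc$channel2)
    expect_lt(abs(got - mass) / mass, 0.01)
  }
})

test_that("point sets have exact per-color counts and are reproducible", {
  pts <- generate_point_set(c(0L, 5L), c(100, 100), seed = 4)
  expect_identical(nrow(pts), 5L)
  expect_true(all(pts$color == 2L))
  expect_identical(generate_point_set(c(7L, 3L), c(50, 80), seed = 8),
                   generate_point_set(c(7L, 3L), c(50, 80), seed = 8))
  big <- generate_point_set(c(10000L, 10000L), c(1000, 1000), seed = 2)
  expect_identical(mean(big$color == 1L), 0.5)
  expect_true(all(big$row >= 0 & big$row <= 1000))
})

test_that("center geometry is color-blind: both colors share one spatial law", {
  # two-sample KS on each coordinate, both colors, across seeds
  reject <- 0L
  n_seeds <- 60L
  for (s in seq_len(n_seeds)) {
    pts <- generate_point_set(c(2000L, 2000L), c(1040, 1388), seed = 1000 + s)
    p1 <- pts[pts$color == 1, ]; p2 <- pts[pts$color == 2, ]
    p_row <- suppressWarnings(ks.test(p1$row, p2$row)$p.value)
    p_col <- suppressWarnings(ks.test(p1$col, p2$col)$p.value)
    if (min(p_row, p_col) < 0.01) reject <- reject + 1L
  }
  expect_lte(reject / n_seeds, 0.10)
})
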