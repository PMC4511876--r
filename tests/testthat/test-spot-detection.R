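# Segmentation, cluster filtering and local-maxima detection.

test_that("an all-background image segments to an empty table", {
  sig <- segment_signals(matrix(1, 10, 10), threshold = 5)
  expect_identical(nrow(sig), 0L)
})

test_that("a solid square segments as one object with the right geometry", {
  img <- matrix(0, 12, 12)
  img[5:7, 6:8] <- 10
  sig <- segment_signals(img, threshold = 5)
  expect_identical(nrow(sig), 1L)
  expect_identical(sig$area_px, 9L)
  expect_equal(sig$perimeter_px, 12 * pi / 4)
  expect_equal(sig$circularity, min(1, 4 * pi * 9 / (12 * pi / 4)^2))
  expect_equal(sig$centroid_row, 6)
  expect_equal(sig$centroid_col, 7)
  expect_identical(sig$peak_intensity, 10)
})

test_that("segmentation recovers well-separated compact spots at truth positions", {
  cfg <- small_scene_config(seed = 17, gaussian_noise_sd = 0,
                            poisson_noise = FALSE)
  sc <- generate_scene(cfg)
  pp <- project_stack(sc$channel1)
  th <- mode_threshold(pp$corrected)
  sig <- segment_signals(pp$corrected, th$threshold)
  tr <- sc$truth[sc$truth$color == 1, ]
  expect_identical(nrow(sig), nrow(tr))
  d <- sqrt(outer(sig$centroid_row, tr$row, "-")^2 +
              outer(sig$centroid_col, tr$col, "-")^2)
  expect_lt(max(apply(d, 2, min)), 1)
})

test_that("object areas and circularities match a naive flood-fill oracle", {
  withr::local_seed(23)
  for (rep in 1:20) {
    mask <- matrix(runif(144) < 0.35, 12, 12)
    img <- matrix(0, 12, 12); img[mask] <- 10
    sig <- segment_signals(img, threshold = 5)
    oracle <- flood_fill_labels(mask)
    expect_identical(nrow(sig), max(oracle))
    # match oracle objects by their pixel sets
    for (lb in seq_len(max(oracle))) {
      px <- which(oracle == lb, arr.ind = TRUE)
      hit <- which(vapply(sig$pixels, function(p) {
        nrow(p) == nrow(px) &&
          all(p[order(p[, 1], p[, 2]), ] == px[order(px[, 1], px[, 2]), ])
      }, TRUE))
      expect_length(hit, 1L)
      obj_mask <- matrix(FALSE, 12, 12); obj_mask[px] <- TRUE
      per <- (pi / 4) * brute_force_perimeter(obj_mask)
      expect_equal(sig$perimeter_px[hit], per)
      expect_equal(sig$circularity[hit], min(1, 4 * pi * nrow(px) / per^2))
    }
  }
})

test_that("cluster filtering applies the size and circularity rules at their boundaries", {
  mk <- function(area, circ) tibble::tibble(label = 1L, area_px = area,
                                            circularity = circ)
  expect_identical(nrow(filter_clusters(mk(41L, 0.9))), 0L)
  expect_identical(nrow(filter_clusters(mk(40L, 0.9))), 1L)
  expect_identical(nrow(filter_clusters(mk(10L, 0.49))), 0L)
  expect_identical(nrow(filter_clusters(mk(10L, 0.5))), 1L)
})

test_that("a digitized disk of radius 3 survives the cluster filter", {
  img <- matrix(0, 15, 15)
  for (r in 1:15) for (c in 1:15) {
    if (sqrt((r - 8)^2 + (c - 8)^2) <= 3) img[r, c] <- 10
  }
  sig <- segment_signals(img, threshold = 5)
  expect_identical(sig$area_px, 29L)
  expect_equal(sig$perimeter_px,
               (pi / 4) * brute_force_perimeter(img > 5))
  expect_gte(sig$circularity, 0.5)
  expect_identical(nrow(filter_clusters(sig)), 1L)
})

test_that("filtering is idempotent and returns a subset", {
  withr::local_seed(2)
  img <- blob_image(c(60, 60), cbind(runif(6, 10, 50), runif(6, 10, 50)),
                    amplitude = 50, sigma = 2)
  sig <- segment_signals(img, threshold = 10)
  f1 <- filter_clusters(sig)
  expect_identical(filter_clusters(f1), f1)
  expect_true(all(f1$label %in% sig$label))
})

test_that("maxima detection handles constant, single-blob and two-blob images", {
  expect_identical(nrow(detect_maxima(matrix(7, 20, 20))), 0L)
  one <- blob_image(c(31, 31), cbind(16, 16), amplitude = 100, sigma = 1.5)
  mx <- detect_maxima(one)
  expect_identical(nrow(mx), 1L)
  expect_equal(mx$row, 16); expect_equal(mx$col, 16)
  two <- blob_image(c(41, 41), rbind(c(15, 20), c(25, 20)),
                    amplitude = 100, sigma = 1.5)
  mx2 <- detect_maxima(two)
  expect_identical(nrow(mx2), 2L)
  expect_equal(sort(mx2$row), c(15, 25))
  # brute-force scan of the smoothed array confirms those are the only
  # strict 8-neighborhood maxima with positive median-subtracted value
  sm <- gaussian_smooth(two, 1); sm <- sm - median(sm); sm[sm < 0] <- 0
  hits <- 0L
  for (r in 2:40) for (c in 2:40) {
    nb <- sm[(r - 1):(r + 1), (c - 1):(c + 1)]
    if (sm[r, c] > 0 && sm[r, c] == max(nb) && sum(nb == max(nb)) == 1) hits <- hits + 1L
  }
  expect_identical(nrow(mx2), hits)
})

test_that("a flat plateau yields one maximum at its centroid", {
  img <- matrix(0, 21, 21)
  img[10:11, 10:12] <- 50
  mx <- detect_maxima(img, smoothing_sigma_px = 0)
  expect_identical(nrow(mx), 1L)
  expect_equal(mx$row, 10.5)
  expect_equal(mx$col, 11)
})

test_that("the minimum-prominence knob suppresses shallow maxima", {
  img <- blob_image(c(41, 41), rbind(c(12, 12), c(30, 30)),
                    amplitude = 100, sigma = 1.5)
  img <- img + blob_image(c(41, 41), cbind(21, 21), amplitude = 5, sigma = 1.5)
  all_mx <- detect_maxima(img)
  strong <- detect_maxima(img, min_prominence = 20)
  expect_gte(nrow(all_mx), 3L)
  expect_identical(nrow(strong), 2L)
})

test_that("dispersed scenes yield at least as many maxima as matched compact scenes", {
  for (s in 1:4) {
    base <- list(image_shape = c(160L, 160L), n_z = 8L,
                 n_spots_per_color = c(10L, 10L), seed = 600 + s,
                 border_margin_px = 12, min_center_separation_px = 16)
    count_maxima <- function(mode) {
      sc <- generate_scene(do.call(scene_config, c(base, list(mode = mode))))
      pp <- project_stack(sc$channel1)
      th <- mode_threshold(pp$corrected)
      nrow(detect_maxima(pp$corrected, min_prominence = th$threshold))
    }
    expect_gte(count_maxima("dispersed"), count_maxima("compact"))
  }
})

test_that("compact-scene recall is high with few false detections", {
  recall <- fp <- numeric(0)
  for (s in 1:20) {
    sc <- generate_scene(scene_config(image_shape = c(256L, 256L), n_z = 8L,
                                      n_spots_per_color = c(30L, 0L),
                                      seed = 700 + s))
    pp <- project_stack(sc$channel1)
    th <- mode_threshold(pp$corrected)
    sig <- filter_clusters(segment_signals(pp$corrected, th$threshold))
    tr <- sc$truth[sc$truth$color == 1, ]
    d <- sqrt(outer(sig$centroid_row, tr$row, "-")^2 +
                outer(sig$centroid_col, tr$col, "-")^2)
    recall <- c(recall, mean(apply(d, 2, min) <= 1.5))
    fp <- c(fp, sum(apply(d, 1, min) > 4) / nrow(tr))
  }
  expect_gte(mean(recall), 0.95)
  expect_lte(mean(fp), 0.02)
})
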