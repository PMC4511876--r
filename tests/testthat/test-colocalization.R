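# Pixel-level intersection-over-union and solution-phase dual-color
# classification.

test_that("identical and disjoint masks bound the overlap fraction", {
  a <- matrix(0, 8, 8); a[2:3, 2:3] <- 10
  same <- pixel_overlap(a, a, binarization_threshold = 5,
                        smoothing_sigma_px = 0)
  expect_identical(same$overlap_fraction, 1)
  b <- matrix(0, 8, 8); b[6:7, 6:7] <- 10
  disj <- pixel_overlap(a, b, binarization_threshold = 5,
                        smoothing_sigma_px = 0)
  expect_identical(disj$overlap_fraction, 0)
  expect_identical(disj$n_union_px, 8L)
  none <- pixel_overlap(matrix(0, 8, 8), matrix(0, 8, 8),
                        binarization_threshold = 5, smoothing_sigma_px = 0)
  expect_identical(none$overlap_fraction, 0)
  expect_true(none$degenerate)
  expect_error(pixel_overlap(a, matrix(0, 4, 4), binarization_threshold = 5),
               "shape")
})

test_that("a toy mask pair reproduces the set-arithmetic value 2/6", {
  m1 <- matrix(0, 4, 4); m1[1, 1:2] <- 10; m1[3, 3] <- 10; m1[4, 4] <- 10
  m2 <- matrix(0, 4, 4); m2[1, 1:2] <- 10; m2[2, 4] <- 10; m2[4, 1] <- 10
  ov <- pixel_overlap(m1, m2, binarization_threshold = 5,
                      smoothing_sigma_px = 0)
  expect_identical(ov$n_intersection_px, 2L)
  expect_identical(ov$n_union_px, 6L)
  expect_equal(ov$overlap_fraction, 1 / 3)
})

test_that("overlap matches brute-force set arithmetic on random masks", {
  withr::local_seed(61)
  for (rep in 1:100) {
    h <- sample(4:16, 1); w <- sample(4:16, 1)
    m1 <- matrix(runif(h * w, 0, 10), h, w)
    m2 <- matrix(runif(h * w, 0, 10), h, w)
    ov <- pixel_overlap(m1, m2, binarization_threshold = 6,
                        smoothing_sigma_px = 0)
    s1 <- which(m1 >= 6); s2 <- which(m2 >= 6)
    n_int <- length(intersect(s1, s2)); n_uni <- length(union(s1, s2))
    expect_identical(ov$n_intersection_px, n_int)
    expect_identical(ov$n_union_px, n_uni)
    expect_identical(ov$overlap_fraction,
                     if (n_uni == 0) 0 else n_int / n_uni)
  }
})

test_that("overlap is symmetric and the union shrinks as the threshold rises", {
  withr::local_seed(67)
  m1 <- blob_image(c(40, 40), cbind(runif(5, 8, 32), runif(5, 8, 32)),
                   amplitude = 80, sigma = 2)
  m2 <- blob_image(c(40, 40), cbind(runif(5, 8, 32), runif(5, 8, 32)),
                   amplitude = 80, sigma = 2)
  o12 <- pixel_overlap(m1, m2, binarization_threshold = 20)
  o21 <- pixel_overlap(m2, m1, binarization_threshold = 20)
  expect_identical(o12$overlap_fraction, o21$overlap_fraction)
  unions <- vapply(c(10, 20, 40, 60), function(th)
    pixel_overlap(m1, m2, binarization_threshold = th)$n_union_px, integer(1))
  expect_true(all(diff(unions) <= 0))
})

test_that("independent-channel overlap falls toward zero as density drops", {
  mean_overlap <- function(n) {
    ov <- vapply(1:3, function(s) {
      sc <- generate_scene(scene_config(image_shape = c(200L, 200L), n_z = 6L,
                                        n_spots_per_color = c(n, n),
                                        min_center_separation_px = 4,
                                        seed = 1200 + 10 * n + s))
      p1 <- project_stack(sc$channel1)$corrected
      p2 <- project_stack(sc$channel2)$corrected
      pixel_overlap(p1, p2,
                    binarization_threshold = mode_threshold(p1)$threshold)$overlap_fraction
    }, numeric(1))
    mean(ov)
  }
  dens <- vapply(c(60L, 25L, 6L), mean_overlap, numeric(1))
  expect_true(all(diff(dens) <= 0))
  expect_lt(dens[3], 0.01)
})

test_that("solution-phase size and intensity rules are applied at their boundaries", {
  put <- function(img, px, val) { img[px] <- val; img }
  blank <- matrix(0, 20, 20)
  # 1-pixel object rejected; 2-pixel accepted
  one <- classify_solution_rcps(put(blank, 50, 40), blank)
  expect_identical(nrow(one$objects), 0L)
  two <- classify_solution_rcps(put(blank, c(50, 51), 40), blank)
  expect_identical(two$objects$area_px, 2L)
  expect_identical(two$objects$class, "ch1_only")
  # 30-pixel kept, 31-pixel rejected
  keep30 <- classify_solution_rcps(put(blank, 1:30, 40), blank)
  expect_identical(keep30$objects$area_px, 30L)
  drop31 <- classify_solution_rcps(put(blank, 1:31, 40), blank)
  expect_identical(nrow(drop31$objects), 0L)
  # PMT 34 is background, 35 is signal
  expect_identical(nrow(classify_solution_rcps(put(blank, c(50, 51), 34),
                                               blank)$objects), 0L)
  at35 <- classify_solution_rcps(put(blank, c(50, 51), 35), blank)
  expect_identical(nrow(at35$objects), 1L)
})

test_that("engineered dual objects give the expected dual fraction", {
  withr::local_seed(71)
  h <- 220; w <- 220
  ch1 <- matrix(0, h, w); ch2 <- matrix(0, h, w)
  # 50 ch1-only, 50 ch2-only, 10 dual 2x2 squares on a coarse grid
  anchors <- as.matrix(expand.grid(row = seq(3, h - 3, by = 10),
                                   col = seq(3, w - 3, by = 10)))
  anchors <- anchors[sample(nrow(anchors), 110), ]
  stamp <- function(img, a) { img[a[1]:(a[1] + 1), a[2]:(a[2] + 1)] <- 50; img }
  for (i in 1:50) ch1 <- stamp(ch1, anchors[i, ])
  for (i in 51:100) ch2 <- stamp(ch2, anchors[i, ])
  for (i in 101:110) { ch1 <- stamp(ch1, anchors[i, ]); ch2 <- stamp(ch2, anchors[i, ]) }
  res <- classify_solution_rcps(ch1, ch2)
  expect_identical(sum(res$counts), 110L)
  expect_identical(res$counts[["dual"]], 10L)
  expect_equal(res$dual_fraction, 10 / 110, tolerance = 1e-12)
})

test_that("cross-channel entities merge when their pixels intersect", {
  ch1 <- matrix(0, 10, 10); ch2 <- matrix(0, 10, 10)
  ch1[4, 4:6] <- 40      # three pixels in channel 1
  ch2[4, 6:8] <- 40      # overlaps at (4,6)
  res <- classify_solution_rcps(ch1, ch2)
  expect_identical(nrow(res$objects), 1L)
  expect_identical(res$objects$class, "dual")
  expect_identical(res$objects$area_px, 5L)
})

test_that("the ANOVA/LSD wrapper behaves on degenerate and separated designs", {
  withr::local_seed(81)
  same <- tibble::tibble(value = rnorm(30), group = rep(c("a", "b", "c"), 10))
  same$value <- same$value - ave(same$value, same$group)  # identical means
  r0 <- dose_response_test(same)
  expect_gt(r0$anova$p_value, 0.99)
  sep <- tibble::tibble(value = c(rnorm(10, 0), rnorm(10, 0), rnorm(10, 5)),
                        group = rep(c("a", "b", "c"), each = 10))
  r1 <- dose_response_test(sep)
  expect_lt(r1$anova$p_value, 0.001)
  pw <- tidy(r1)
  expect_identical(nrow(pw), 3L)
  ab <- pw[pw$group1 == "a" & pw$group2 == "b", ]
  expect_gt(ab$p_value, 0.05)
  expect_lt(max(pw$p_value[pw$group2 == "c" | pw$group1 == "c"]), 0.001)
  # two groups: ANOVA p equals the pooled-variance t-test p
  two <- tibble::tibble(value = c(rnorm(8, 0), rnorm(8, 1)),
                        group = rep(c("a", "b"), each = 8))
  r2 <- dose_response_test(two)
  tt <- t.test(value ~ group, data = two, var.equal = TRUE)
  expect_equal(r2$anova$p_value, tt$p.value)
  expect_equal(tidy(r2)$p_value, tt$p.value)
  # zero-variance n = 2 group excluded from the post hoc with a warning
  degen <- tibble::tibble(value = c(1, 1, rnorm(6)),
                          group = rep(c("z", "a", "b"), c(2, 3, 3)))
  expect_warning(r3 <- dose_response_test(degen), "zero-variance")
  expect_false("z" %in% c(tidy(r3)$group1, tidy(r3)$group2))
})
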