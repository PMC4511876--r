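# Two-channel co-localization: pixel-level intersection-over-union for
# slide images, and object-level dual-color classification for
# solution-phase line-scan images.

#' Pixel-level overlap (intersection over union) of two channels
#'
#' Both channels are Gaussian smoothed and binarized at the same fixed
#' threshold; the overlap fraction is the number of foreground pixels
#' shared by the two channels divided by the number of foreground pixels
#' in either. An empty union gives overlap 0 with `degenerate = TRUE`.
#'
#' @param img1,img2 Numeric matrices of one shape.
#' @param binarization_threshold Intensity threshold applied (`>=`) to
#'   both smoothed channels. A reproducible default is the
#'   [mode_threshold()] of channel 1.
#' @param smoothing_sigma_px Gaussian sigma in pixels (default 1; 0 skips
#'   smoothing).
#' @return One-row tibble: `n_intersection_px`, `n_union_px`,
#'   `overlap_fraction`, `threshold`, `degenerate`.
#' @export
pixel_overlap <- function(img1, img2,
                          binarization_threshold = mode_threshold(img1)$threshold,
                          smoothing_sigma_px = 1) {
  abort_if(!identical(dim(img1), dim(img2)), "images must share one shape")
  abort_if(!is.numeric(binarization_threshold) || binarization_threshold <= 0,
           "binarization_threshold must be positive")
  m1 <- gaussian_smooth(img1, smoothing_sigma_px) >= binarization_threshold
  m2 <- gaussian_smooth(img2, smoothing_sigma_px) >= binarization_threshold
  n_int <- sum(m1 & m2)
  n_uni <- sum(m1 | m2)
  tibble::tibble(
    n_intersection_px = n_int,
    n_union_px = n_uni,
    overlap_fraction = if (n_uni == 0) 0 else n_int / n_uni,
    threshold = binarization_threshold,
    degenerate = n_uni == 0
  )
}

#' Classify solution-phase RCPs by dual-color positivity
#'
#' Detects objects independently in each channel at `>= pmt_threshold`
#' (photomultiplier-tube units), keeps objects whose area lies within
#' `size_range` (endpoints inclusive), and merges detections across
#' channels into single RCP entities wherever their pixel sets intersect.
#' Each entity is classified by which channels exceed the threshold
#' within its footprint: with `positivity = "any"` (default) a channel is
#' positive if any entity pixel reaches the threshold in that channel;
#' `"mean"` requires the entity's mean channel intensity to reach it.
#'
#' @param ch1,ch2 Numeric matrices of one shape (the two detector
#'   channels of a line-scan image).
#' @param pmt_threshold Intensity threshold (default 35).
#' @param size_range `c(min, max)` object area in pixels (default
#'   `c(2, 30)`, inclusive).
#' @param positivity `"any"` or `"mean"`.
#' @return A list of class `solution_rcps`: `objects` (tibble with
#'   `object_id`, `area_px`, `max_ch1`, `max_ch2`, `mean_ch1`, `mean_ch2`,
#'   `class`), `dual_fraction`, and per-class `counts`.
#' @export
classify_solution_rcps <- function(ch1, ch2, pmt_threshold = 35,
                                   size_range = c(2, 30),
                                   positivity = c("any", "mean")) {
  positivity <- match.arg(positivity)
  abort_if(!identical(dim(ch1), dim(ch2)), "channels must share one shape")
  abort_if(length(size_range) != 2L || size_range[1] > size_range[2],
           "size_range must be c(min, max)")

  chan_pixels <- function(img) {
    labels <- label_components(img >= pmt_threshold, connectivity = 8)
    if (max(labels) == 0L) return(list())
    h <- nrow(img)
    idx <- which(labels > 0L)
    by_obj <- split(idx, labels[idx])
    keep <- vapply(by_obj, function(v)
      length(v) >= size_range[1] && length(v) <= size_range[2], TRUE)
    unname(by_obj[keep])
  }
  objs <- c(chan_pixels(ch1), chan_pixels(ch2))
  empty <- tibble::tibble(object_id = integer(), area_px = integer(),
                          max_ch1 = numeric(), max_ch2 = numeric(),
                          mean_ch1 = numeric(), mean_ch2 = numeric(),
                          class = character())
  if (length(objs) == 0L) {
    return(structure(list(objects = empty, dual_fraction = NA_real_,
                          counts = c(ch1_only = 0L, ch2_only = 0L, dual = 0L)),
                     class = "solution_rcps"))
  }

  # Merge channel detections into entities via shared pixels (union-find).
  parent <- seq_along(objs)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  pixel_owner <- new.env(hash = TRUE)
  for (i in seq_along(objs)) {
    for (px in objs[[i]]) {
      key <- as.character(px)
      j <- pixel_owner[[key]]
      if (is.null(j)) {
        pixel_owner[[key]] <- i
      } else {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_along(objs), find, integer(1))
  entities <- split(seq_along(objs), roots)

  rows <- purrr::imap(unname(entities), function(members, eid) {
    px <- sort(unique(unlist(objs[members])))
    v1 <- ch1[px]; v2 <- ch2[px]
    pos1 <- if (positivity == "any") any(v1 >= pmt_threshold) else mean(v1) >= pmt_threshold
    pos2 <- if (positivity == "any") any(v2 >= pmt_threshold) else mean(v2) >= pmt_threshold
    cls <- if (pos1 && pos2) "dual" else if (pos1) "ch1_only" else "ch2_only"
    tibble::tibble(object_id = as.integer(eid), area_px = length(px),
                   max_ch1 = max(v1), max_ch2 = max(v2),
                   mean_ch1 = mean(v1), mean_ch2 = mean(v2), class = cls)
  })
  objects <- dplyr::bind_rows(rows)
  counts <- c(ch1_only = sum(objects$class == "ch1_only"),
              ch2_only = sum(objects$class == "ch2_only"),
              dual = sum(objects$class == "dual"))
  structure(list(objects = objects,
                 dual_fraction = counts[["dual"]] / nrow(objects),
                 counts = counts),
            class = "solution_rcps")
}

#' @export
print.solution_rcps <- function(x, ...) {
  cat(sprintf("<solution_rcps> %d entities: %d ch1-only, %d ch2-only, %d dual (dual fraction %.4f)\n",
              sum(x$counts), x$counts[["ch1_only"]], x$counts[["ch2_only"]],
              x$counts[["dual"]],
              if (is.na(x$dual_fraction)) NA else x$dual_fraction))
  invisible(x)
}

#' One-way ANOVA with Fisher's LSD post hoc on dual fractions
#'
#' Tests whether dual-color fractions differ across conditions (for
#' example compaction-oligonucleotide concentrations): one-way ANOVA
#' followed by Fisher's least-significant-difference post hoc, i.e.
#' pairwise t-tests using the pooled within-group mean square error with
#' unadjusted two-sided p-values. A group with zero variance and n <= 2
#' is excluded from the post hoc with a warning.
#'
#' @param data Data frame with the response and grouping columns.
#' @param value,group Column names (strings) of the response and the
#'   condition factor.
#' @return Object of class `rcp_dose_response`: `anova` (one-row tibble
#'   with `f_statistic`, `p_value`, `df_between`, `df_within`) and
#'   `pairwise` (tibble with `group1`, `group2`, `mean_diff`,
#'   `t_statistic`, `p_value`). Supports [tidy()] and [glance()].
#' @export
dose_response_test <- function(data, value = "value", group = "group") {
  abort_if(!all(c(value, group) %in% names(data)),
           "data must contain the value and group columns")
  y <- data[[value]]
  g <- factor(data[[group]])
  abort_if(nlevels(g) < 2, "need at least two groups")
  sizes <- table(g)
  abort_if(any(sizes < 2), "each group needs n >= 2")

  fit <- aov(y ~ g)
  an <- summary(fit)[[1]]
  mse <- an["Residuals", "Mean Sq"]
  df_within <- an["Residuals", "Df"]
  anova_tbl <- tibble::tibble(f_statistic = an[1, "F value"],
                              p_value = an[1, "Pr(>F)"],
                              df_between = an[1, "Df"],
                              df_within = df_within)

  grp_var <- tapply(y, g, stats::var)
  usable <- levels(g)
  bad <- names(grp_var)[grp_var == 0 & sizes <= 2]
  if (length(bad)) {
    warning("excluding zero-variance group(s) with n <= 2 from post hoc: ",
            paste(bad, collapse = ", "))
    usable <- setdiff(usable, bad)
  }
  means <- tapply(y, g, mean)
  pairs <- if (length(usable) >= 2) utils::combn(usable, 2, simplify = FALSE) else list()
  pairwise <- purrr::map(pairs, function(p) {
    n1 <- sizes[[p[1]]]; n2 <- sizes[[p[2]]]
    se <- sqrt(mse * (1 / n1 + 1 / n2))
    tstat <- (means[[p[1]]] - means[[p[2]]]) / se
    tibble::tibble(group1 = p[1], group2 = p[2],
                   mean_diff = means[[p[1]]] - means[[p[2]]],
                   t_statistic = tstat,
                   p_value = 2 * pt(-abs(tstat), df_within))
  }) |> dplyr::bind_rows()
  if (nrow(pairwise) == 0L) {
    pairwise <- tibble::tibble(group1 = character(), group2 = character(),
                               mean_diff = numeric(), t_statistic = numeric(),
                               p_value = numeric())
  }
  structure(list(anova = anova_tbl, pairwise = pairwise),
            class = "rcp_dose_response")
}

#' @export
print.rcp_dose_response <- function(x, ...) {
  cat(sprintf("<rcp_dose_response> ANOVA F = %.4g (df %d, %d), p = %.4g\n",
              x$anova$f_statistic, x$anova$df_between, x$anova$df_within,
              x$anova$p_value))
  if (nrow(x$pairwise)) {
    cat("  LSD post hoc (unadjusted):\n")
    print(x$pairwise)
  }
  invisible(x)
}
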