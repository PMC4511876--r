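# End-to-end orchestration: simulate (or load) a two-channel experiment,
# project and threshold, detect signals both ways, then run the SNR,
# integrity and co-localization analyses, writing every intermediate
# table plus a run manifest.

#' Configuration for an end-to-end pipeline run
#'
#' Exactly one input source must be given: a [scene_config()] to
#' simulate, or a directory holding `channel1.tif` and `channel2.tif`.
#'
#' @param scene A [scene_config()] to simulate from, or `NULL`.
#' @param input_dir Directory with existing channel TIFF stacks, or
#'   `NULL`.
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "prep", "detect", "snr", "integrity", "coloc")` (the
#'   `prep`..`coloc` stages require their predecessors).
#' @param geometry A [disk_geometry()] for the SNR stage.
#' @param max_area,min_circularity Cluster-filter parameters (defaults 40
#'   px, 0.5).
#' @param smoothing_sigma_px Gaussian sigma for maxima detection and
#'   co-localization (default 1).
#' @param threshold_override Optional fixed intensity threshold replacing
#'   the automatic [mode_threshold()] in every stage.
#' @param maxima_prominence Minimum prominence for [detect_maxima()];
#'   `NULL` (default) uses each channel's automatic intensity threshold,
#'   so the maxima path and the segmentation path share one notion of
#'   "above background".
#' @param mc_replicates Monte Carlo replicates for the integrity null
#'   (default 10).
#' @param seed Master seed; all stage randomness derives from it.
#' @param out_dir Output directory.
#' @return Object of class `run_config`.
#' @export
run_config <- function(scene = NULL, input_dir = NULL,
                       stages = c("simulate", "prep", "detect", "snr",
                                  "integrity", "coloc"),
                       geometry = disk_geometry(),
                       max_area = 40, min_circularity = 0.5,
                       smoothing_sigma_px = 1,
                       threshold_override = NULL,
                       maxima_prominence = NULL,
                       mc_replicates = 10,
                       seed = 1,
                       out_dir = tempfile("rcpquant-run-")) {
  abort_if(is.null(scene) == is.null(input_dir),
           "give exactly one input source: scene or input_dir")
  abort_if(!is.null(scene) && !inherits(scene, "scene_config"),
           "scene must be a scene_config")
  known <- c("simulate", "prep", "detect", "snr", "integrity", "coloc")
  abort_if(length(stages) > 0 && !all(stages %in% known),
           paste("stages must be among:", paste(known, collapse = ", ")))
  structure(list(scene = scene, input_dir = input_dir, stages = stages,
                 geometry = geometry, max_area = max_area,
                 min_circularity = min_circularity,
                 smoothing_sigma_px = smoothing_sigma_px,
                 threshold_override = threshold_override,
                 maxima_prominence = maxima_prominence,
                 mc_replicates = mc_replicates,
                 seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' Run the analysis pipeline
#'
#' Executes the selected stages in order, writes each intermediate table
#' (CSV) and report (JSON) under `config$out_dir`, and returns a run
#' manifest: the echoed configuration, per-stage record counts, the seed
#' chain and wall time per stage. Re-running with the same configuration
#' and seed reproduces every numeric output exactly. A stage failure
#' leaves partial outputs plus a `FAILED` marker naming the stage.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of class `run_manifest` (also written as
#'   `manifest.json`), with a `results` attribute holding the in-memory
#'   stage outputs.
#' @export
run_pipeline <- function(config) {
  abort_if(!inherits(config, "run_config"), "config must be a run_config")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  abort_if(file.access(out, 2) != 0, paste("output dir not writable:", out))

  stage_seeds <- derive_seeds(config$seed, 2L)
  names(stage_seeds) <- c("simulate", "integrity")
  manifest <- list(
    package_version = as.character(utils::packageVersion("rcpquant")),
    seed = config$seed,
    seed_chain = as.list(stage_seeds),
    stages_run = character(),
    counts = list(),
    wall_time_s = list(),
    config = echo_config(config)
  )
  results <- list()
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    ok <- tryCatch({ fun(); TRUE }, error = function(e) {
      writeLines(paste0("stage ", name, ": ", conditionMessage(e)),
                 file.path(out, "FAILED"))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    manifest$stages_run <<- c(manifest$stages_run, name)
    manifest$wall_time_s[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    invisible(ok)
  }

  run_stage("simulate", function() {
    scene <- generate_scene(config$scene, seed = stage_seeds[["simulate"]])
    write_scene(scene, file.path(out, "scene"))
    state$stacks <- list(scene$channel1, scene$channel2)
    state$truth <- scene$truth
    manifest$counts$simulated_rcps <<- length(unique(scene$truth$rcp_id))
    results$scene <<- scene
  })
  if (!is.null(config$input_dir) &&
      any(c("prep", "detect", "snr", "integrity", "coloc") %in% config$stages)) {
    state$stacks <- list(read_stack(file.path(config$input_dir, "channel1.tif")),
                         read_stack(file.path(config$input_dir, "channel2.tif")))
  }

  run_stage("prep", function() {
    abort_if(is.null(state$stacks), "prep needs stacks (simulate stage or input_dir)")
    state$proj <- lapply(state$stacks, project_stack)
    state$thr <- lapply(state$proj, function(p) {
      if (!is.null(config$threshold_override)) {
        list(threshold = config$threshold_override, mode_value = NA,
             clip_range = c(NA, NA))
      } else {
        unclass(mode_threshold(p$corrected))
      }
    })
    for (ch in 1:2) {
      write_stack(state$proj[[ch]]$corrected,
                  file.path(out, sprintf("corrected_ch%d.tif", ch)))
    }
    jsonlite::write_json(state$thr, file.path(out, "thresholds.json"),
                         auto_unbox = TRUE, digits = NA)
    results$projections <<- state$proj
    results$thresholds <<- state$thr
  })

  run_stage("detect", function() {
    abort_if(is.null(state$proj), "detect needs the prep stage")
    state$signals <- state$filtered <- state$maxima <- vector("list", 2)
    for (ch in 1:2) {
      corrected <- state$proj[[ch]]$corrected
      sig <- segment_signals(corrected, state$thr[[ch]]$threshold)
      filt <- filter_clusters(sig, config$max_area, config$min_circularity)
      prom <- if (is.null(config$maxima_prominence)) state$thr[[ch]]$threshold
              else config$maxima_prominence
      mx <- detect_maxima(corrected, config$smoothing_sigma_px,
                          min_prominence = prom)
      state$signals[[ch]] <- sig
      state$filtered[[ch]] <- filt
      state$maxima[[ch]] <- mx
      write_table_csv(sig, file.path(out, sprintf("signals_ch%d.csv", ch)))
      write_table_csv(filt, file.path(out, sprintf("signals_filtered_ch%d.csv", ch)))
      write_table_csv(mx, file.path(out, sprintf("maxima_ch%d.csv", ch)))
      manifest$counts[[sprintf("detected_ch%d", ch)]] <<- nrow(sig)
      manifest$counts[[sprintf("filtered_ch%d", ch)]] <<- nrow(filt)
      manifest$counts[[sprintf("maxima_ch%d", ch)]] <<- nrow(mx)
    }
    results$signals <<- state$signals
    results$filtered <<- state$filtered
    results$maxima <<- state$maxima
  })

  run_stage("snr", function() {
    abort_if(is.null(state$filtered), "snr needs the detect stage")
    state$snr <- vector("list", 2)
    for (ch in 1:2) {
      m <- measure_snr_all(state$proj[[ch]]$corrected, state$filtered[[ch]],
                           config$geometry, all_objects = state$signals[[ch]])
      state$snr[[ch]] <- m
      write_table_csv(m, file.path(out, sprintf("snr_ch%d.csv", ch)))
      manifest$counts[[sprintf("snr_retained_ch%d", ch)]] <<- attr(m, "n_retained")
      if (nrow(m)) {
        jsonlite::write_json(summarize_intensity(m),
                             file.path(out, sprintf("snr_summary_ch%d.json", ch)),
                             auto_unbox = TRUE, digits = NA, dataframe = "rows")
      }
    }
    results$snr <<- state$snr
  })

  run_stage("integrity", function() {
    abort_if(is.null(state$maxima), "integrity needs the detect stage")
    pts <- as_colored_points(state$maxima[[1]], state$maxima[[2]])
    abort_if(nrow(pts) < 2, "fewer than two detected maxima")
    obs <- same_color_frequency(pts)
    counts <- c(nrow(state$maxima[[1]]), nrow(state$maxima[[2]]))
    shape <- dim(state$proj[[1]]$corrected)
    null <- monte_carlo_null(counts, shape,
                             n_replicates = config$mc_replicates,
                             seed = stage_seeds[["integrity"]])
    test <- integrity_test(obs$frequency, null)
    report <- list(observed = as.list(obs),
                   null = as.list(glance(null)),
                   test = as.list(test$results[1, ]))
    jsonlite::write_json(report, file.path(out, "integrity.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$counts$integrity_points <<- nrow(pts)
    results$integrity <<- list(points = pts, observed = obs, null = null,
                               test = test)
  })

  run_stage("coloc", function() {
    abort_if(is.null(state$proj), "coloc needs the prep stage")
    ov <- pixel_overlap(state$proj[[1]]$corrected, state$proj[[2]]$corrected,
                        binarization_threshold = state$thr[[1]]$threshold,
                        smoothing_sigma_px = config$smoothing_sigma_px)
    jsonlite::write_json(as.list(ov), file.path(out, "colocalization.json"),
                         auto_unbox = TRUE, digits = NA)
    results$colocalization <<- ov
  })

  class(manifest) <- "run_manifest"
  jsonlite::write_json(unclass(manifest), file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  attr(manifest, "results") <- results
  invisible(manifest)
}

# Configuration echoed into the manifest as plain lists so it round-trips
# through JSON.
echo_config <- function(config) {
  list(
    scene = if (is.null(config$scene)) NULL else unclass(config$scene),
    input_dir = config$input_dir,
    stages = config$stages,
    geometry = unclass(config$geometry),
    max_area = config$max_area,
    min_circularity = config$min_circularity,
    smoothing_sigma_px = config$smoothing_sigma_px,
    threshold_override = config$threshold_override,
    maxima_prominence = config$maxima_prominence,
    mc_replicates = config$mc_replicates,
    seed = config$seed,
    out_dir = config$out_dir
  )
}

#' Rebuild a run configuration from a manifest
#'
#' Re-parses the configuration echoed into a pipeline manifest (or
#' `manifest.json`) into an equivalent [run_config()].
#'
#' @param manifest A `run_manifest` or path to a `manifest.json`.
#' @return A [run_config()].
#' @export
config_from_manifest <- function(manifest) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest,
                                                              simplifyVector = TRUE)
  cfg <- manifest$config
  scene <- if (is.null(cfg$scene)) NULL else {
    vals <- cfg$scene[names(cfg$scene) %in% names(formals(scene_config))]
    do.call(scene_config, vals)
  }
  run_config(scene = scene,
             input_dir = cfg$input_dir,
             stages = unlist(cfg$stages),
             geometry = disk_geometry(cfg$geometry$inner_radius_px,
                                      cfg$geometry$outer_radius_px),
             max_area = cfg$max_area,
             min_circularity = cfg$min_circularity,
             smoothing_sigma_px = cfg$smoothing_sigma_px,
             threshold_override = cfg$threshold_override,
             maxima_prominence = cfg$maxima_prominence,
             mc_replicates = cfg$mc_replicates,
             seed = cfg$seed,
             out_dir = cfg$out_dir)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>\n")
  cat("  stages:", paste(x$stages_run, collapse = ", "), "\n")
  if (length(x$counts)) {
    cat("  counts:\n")
    for (nm in names(x$counts)) cat(sprintf("    %s: %s\n", nm, x$counts[[nm]]))
  }
  invisible(x)
}
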