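#' Pipeline configuration
#'
#' Builds and validates the configuration of a full quantification run:
#' input source (existing stacks or the synthetic generator), preprocessing,
#' classifier, detection thresholds and statistics design. Every
#' field has a default matching the standard analysis chain; detection
#' thresholds are validated here, before any computation (`final <= core`).
#'
#' @param input `list(mode = "simulate")` or `list(mode = "files",
#'   paths = <TIFF paths>, group = <per-file group>, donor = <per-file id>)`.
#' @param geometry Parameters passed to [acquisition_geometry()]:
#'   `list(fov_um, grid_px, z_step_um, frame_period_s)`.
#' @param n_z Number of z planes (simulate mode).
#' @param simulate `list(groups = list(list(name, preset, n_donors,
#'   treatment)), timestamps_min, donor_variability, tissue_class)`; `preset`
#'   is `"ms"`, `"nonms"` or a [scene_preset()].
#' @param preprocess `list(register, targets_min, median_radius_px, clahe =
#'   list(tile_px, clip_limit, nbins))`; `targets_min = NULL` analyses all
#'   timepoints.
#' @param classify `list(scales_px, num_trees, n_annotations_per_class)`.
#' @param detect `list(core, final, min_diameter_um, max_diameter_um,
#'   sphericity_threshold)`.
#' @param stats `list(baseline_level, condition_levels)`;
#'   `condition_levels` labels the analysed timepoints (e.g. sodium mM).
#' @param seed Master seed; all stage seeds derive from it.
#' @param output_dir Optional directory for CSV/JSON artifacts.
#' @return A validated list of class `thg_config`.
#' @export
pipeline_config <- function(input = list(mode = "simulate"),
                            geometry = list(fov_um = 100, grid_px = 250,
                                            z_step_um = 0.4,
                                            frame_period_s = 1.8),
                            n_z = 50,
                            simulate = list(),
                            preprocess = list(),
                            classify = list(),
                            detect = list(),
                            stats = list(),
                            seed = 1,
                            output_dir = NULL) {
  simulate <- utils::modifyList(list(
    groups = list(list(name = "MS", preset = "ms", n_donors = 5,
                       treatment = "none"),
                  list(name = "non-MS", preset = "nonms", n_donors = 6,
                       treatment = "none")),
    timestamps_min = 0, donor_variability = FALSE, tissue_class = "WM"),
    simulate)
  preprocess <- utils::modifyList(list(
    register = TRUE, targets_min = NULL, median_radius_px = 2,
    clahe = list(tile_px = 64, clip_limit = 0.01, nbins = 256)), preprocess)
  classify <- utils::modifyList(list(
    scales_px = c(0.7, 1.0, 1.6, 3.5, 5.0), num_trees = 100,
    n_annotations_per_class = 2000), classify)
  detect <- utils::modifyList(list(
    core = 0.85, final = 0.5, min_diameter_um = 2.0, max_diameter_um = 8.0,
    sphericity_threshold = 0.75), detect)
  stats <- utils::modifyList(list(baseline_level = NULL,
                                  condition_levels = NULL), stats)
  if (!(detect$final > 0 && detect$final <= detect$core &&
        detect$core <= 1))
    stop("invalid detection thresholds: need 0 < final <= core <= 1")
  if (detect$min_diameter_um > detect$max_diameter_um)
    stop("invalid size filter bounds")
  if (is.null(seed)) stop("a seed is mandatory")
  structure(list(input = input, geometry = geometry, n_z = n_z,
                 simulate = simulate, preprocess = preprocess,
                 classify = classify, detect = detect, stats = stats,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "thg_config")
}

#' @rdname pipeline_config
#' @param path YAML file with the fields of [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y[intersect(names(y), names(formals(
    pipeline_config)))])
}

resolve_preset <- function(p) {
  if (inherits(p, "thg_preset")) return(p)
  switch(as.character(p),
         ms = preset_ms(), nonms = preset_nonms(),
         stop("unknown preset: ", p))
}

#' Preprocess one volume for detection
#'
#' The pre-detection chain on a single `(y, x, z)` unit-scale volume:
#' inversion (non-myelin bright), disk median filtering and per-slice CLAHE.
#' Registration and timepoint selection happen at the stack level before
#' this.
#'
#' @param volume Unit-scale `(y, x, z)` array.
#' @param median_radius_px Disk median radius.
#' @param clahe_params `list(tile_px, clip_limit, nbins)`.
#' @return The processed volume.
#' @export
preprocess_volume <- function(volume, median_radius_px = 2,
                              clahe_params = list(tile_px = 64,
                                                  clip_limit = 0.01,
                                                  nbins = 256)) {
  v <- invert_intensity(volume, scale = "unit")
  v <- median_filter_2px(v, median_radius_px)
  clahe(v, tile_px = clahe_params$tile_px,
        clip_limit = clahe_params$clip_limit, nbins = clahe_params$nbins,
        range = c(0, 1))
}

#' Detect swellings on a probability map
#'
#' Hysteresis thresholding, 26-connected labeling, size filtering and
#' roundness classification in one step.
#'
#' @param prob A [probability_map()].
#' @param core,final Hysteresis thresholds.
#' @param min_diameter_um,max_diameter_um Size-filter bounds.
#' @param sphericity_threshold Roundness acceptance threshold.
#' @param timepoint Timepoint index recorded with the objects.
#' @return A `thg_swelling_set`.
#' @export
detect_from_probability <- function(prob, core = 0.85, final = 0.5,
                                    min_diameter_um = 1.0,
                                    max_diameter_um = 15.0,
                                    sphericity_threshold = 0.6,
                                    timepoint = 1L) {
  mask <- hysteresis_threshold(prob, core, final)
  obj <- label_objects(mask, prob$geometry, timepoint = timepoint)
  obj <- size_filter(obj, min_diameter_um, max_diameter_um)
  classify_objects(obj, sphericity_threshold)
}

# Full image chain for one simulated donor; returns per-timepoint densities
# and the object tables.
quantify_donor_stack <- function(stack, truth, cfg, donor_seed) {
  n_t <- n_timepoints(stack)
  if (cfg$preprocess$register && n_t > 1) {
    stack <- register_timelapse(stack)$registered
  }
  sel <- if (!is.null(cfg$preprocess$targets_min) && n_t > 1)
    select_timepoints(stack$timestamps_min, cfg$preprocess$targets_min)
  else seq_len(n_t)
  geometry <- stack$geometry
  dens <- numeric(0)
  objects <- NULL
  model <- NULL
  for (ti in seq_along(sel)) {
    t_idx <- sel[ti]
    vol <- preprocess_volume(stack_volume(stack, t_idx),
                             cfg$preprocess$median_radius_px,
                             cfg$preprocess$clahe)
    feats <- compute_features(vol, cfg$classify$scales_px)
    if (is.null(model)) {
      ann <- if (!is.null(truth)) {
        sample_sparse_labels(truth$labels[[t_idx]],
                             cfg$classify$n_annotations_per_class,
                             seed = donor_seed + 7L)
      } else if (!is.null(cfg$classify$labels_csv)) {
        read_sparse_labels_csv(cfg$classify$labels_csv)
      } else {
        stop("file-based runs need classify$labels_csv annotations")
      }
      model <- train_pixel_classifier(feats, ann, seed = donor_seed + 11L,
                                      num_trees = cfg$classify$num_trees)
    }
    prob <- predict_probability(model, feats, geometry)
    set <- detect_from_probability(
      prob, cfg$detect$core, cfg$detect$final, cfg$detect$min_diameter_um,
      cfg$detect$max_diameter_um, cfg$detect$sphericity_threshold,
      timepoint = t_idx)
    dens <- c(dens, set$density_per_mm3)
    objects <- rbind(objects, set$objects)
    rm(feats, prob)
  }
  list(density_per_mm3 = dens, timepoint = sel, objects = objects)
}

#' Run the full quantification pipeline
#'
#' Executes the stages in acquisition-processing order -- simulate (or load),
#' register, select timepoints, invert, median filter, CLAHE, probability
#' mapping, hysteresis detection, size and roundness classification,
#' densities, group statistics -- from a single validated configuration, and
#' returns (and optionally writes) every artifact plus a run manifest
#' sufficient to reproduce the run (full parameter echo, seeds, package
#' version). Reruns with the same configuration are identical.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `thg_run`: `densities` (data.frame donor, group,
#'   treatment, level, timepoint, density), `objects` (all object tables),
#'   `truth` (per-donor ground truth, simulate mode), `report` (a
#'   [group_report()] when the design has >= 2 groups), `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "thg_config"))
  cfg <- config
  geometry <- do.call(acquisition_geometry, cfg$geometry)
  densities <- NULL
  objects <- NULL
  truths <- list()
  if (identical(cfg$input$mode, "simulate")) {
    donor_idx <- 0L
    for (grp in cfg$simulate$groups) {
      preset <- resolve_preset(grp$preset)
      dens_donor <- if (isTRUE(cfg$simulate$donor_variability))
        simulate_donor_densities(preset, grp$n_donors,
                                 seed = cfg$seed + 1000L * donor_idx)
      else rep(preset$swelling_density_per_mm3, grp$n_donors)
      for (di in seq_len(grp$n_donors)) {
        donor_idx <- donor_idx + 1L
        donor_seed <- cfg$seed + 100L * donor_idx
        p_i <- preset
        p_i$swelling_density_per_mm3 <- dens_donor[di]
        sim <- simulate_timelapse(p_i, geometry, cfg$n_z,
                                  cfg$simulate$timestamps_min,
                                  seed = donor_seed,
                                  tissue_class = cfg$simulate$tissue_class)
        q <- quantify_donor_stack(sim$stack, sim$truth, cfg, donor_seed)
        lvl <- if (!is.null(cfg$stats$condition_levels))
          cfg$stats$condition_levels[seq_along(q$timepoint)] else q$timepoint
        id <- sprintf("%s_donor%02d", grp$name, di)
        densities <- rbind(densities, data.frame(
          donor = id, group = grp$name,
          treatment = if (is.null(grp$treatment)) "none" else grp$treatment,
          level = lvl, timepoint = q$timepoint,
          density = q$density_per_mm3,
          true_density = sim$truth$true_density_per_mm3[q$timepoint]))
        if (!is.null(q$objects) && nrow(q$objects)) {
          q$objects$donor <- id
          objects <- rbind(objects, q$objects)
        }
        truths[[id]] <- sim$truth
        thg_log("donor %s: true %.3g, detected %.3g per mm^3", id,
                sim$truth$true_density_per_mm3[1], q$density_per_mm3[1])
      }
    }
  } else if (identical(cfg$input$mode, "files")) {
    for (i in seq_along(cfg$input$paths)) {
      stack <- read_tiff_stack(cfg$input$paths[i], geometry = geometry)
      q <- quantify_donor_stack(stack, NULL, cfg,
                                donor_seed = cfg$seed + 100L * i)
      id <- if (!is.null(cfg$input$donor)) cfg$input$donor[i] else
        basename(cfg$input$paths[i])
      densities <- rbind(densities, data.frame(
        donor = id,
        group = if (!is.null(cfg$input$group)) cfg$input$group[i] else "all",
        treatment = "none", level = q$timepoint, timepoint = q$timepoint,
        density = q$density_per_mm3, true_density = NA_real_))
    }
  } else stop("unknown input mode: ", cfg$input$mode)

  report <- if (length(unique(densities$group)) >= 2 ||
                any(densities$treatment != "none"))
    tryCatch(group_report(densities,
                          baseline_level = cfg$stats$baseline_level),
             error = function(e) NULL)
  else NULL

  manifest <- list(package = "thgmyelin",
                   version = as.character(packageVersion("thgmyelin")),
                   seed = cfg$seed,
                   config = unclass(cfg[c("input", "geometry", "n_z",
                                          "preprocess", "classify",
                                          "detect", "stats")]),
                   n_donors = length(unique(densities$donor)),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(densities, file.path(cfg$output_dir, "densities.csv"),
              row.names = FALSE)
    if (!is.null(objects))
      write.csv(objects, file.path(cfg$output_dir, "objects.csv"),
                row.names = FALSE)
    jsonlite::write_json(manifest,
                         file.path(cfg$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest$paths <- file.path(cfg$output_dir,
                                c("densities.csv", "objects.csv",
                                  "manifest.json"))
  }
  structure(list(densities = densities, objects = objects, truth = truths,
                 report = report, manifest = manifest),
            class = "thg_run")
}

#' @export
print.thg_run <- function(x, ...) {
  cat(sprintf("<thg_run> %d donor(s), %d density measurement(s)\n",
              length(unique(x$densities$donor)), nrow(x$densities)))
  agg <- aggregate(density ~ group, x$densities, mean)
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %s: mean detected density %.4g per mm^3\n",
                agg$group[i], agg$density[i]))
  invisible(x)
}
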