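#' Default pipeline configuration
#'
#' Parameters mirror the published processing chain: 3D median filter
#' (radius 10 for real PTA data; the phantom preset uses radius 3, which
#' matches the milder noise of the synthetic volumes), snake segmentation
#' with gradient threshold 30 and 50 iterations, K-means with k = 3,
#' cube3 erosion with one iteration, 26-connectivity, and the 27-voxel
#' minimum blob size.
#'
#' @param input path to a TIFF stack, or `NULL` when a phantom is used.
#' @param phantom `NULL`, `TRUE` (phantom preset with default spec), or a
#'   list of [phantom_spec()] arguments.
#' @param median_radius median filter radius (scalar or 3 values).
#' @param snake list of [snake_params()] arguments.
#' @param kmeans list of [kmeans_params()] arguments.
#' @param blobs list of [blob_params()] arguments.
#' @param mask_dilation_voxels outward padding of the segmentation mask,
#'   voxels.  The median filter suppresses the thin bright border of the
#'   element, so the snake converges to the border's inner edge; padding
#'   by one voxel puts the border inside the mask (as in the published
#'   segmentation, where the light border had to be removed by erosion)
#'   while keeping the bright sheet thin enough for one cube erosion to
#'   delete it.
#' @param zonation_window half-width of the zonation step detector,
#'   slices.  The pipeline default of 25 makes the epiphysis-diaphysis
#'   density step (a factor of two) stand clear of the Poisson noise of
#'   the per-slice cell counts at realistic densities.
#' @param polarity list: `plane`, `elongation_min`, `superficial_um`.
#' @param init list: `method`, optional `seed_point` (y, x), optional
#'   `init_slice` (0-based; default middle slice).
#' @param out_dir output directory for artifacts.
#' @param write_artifacts write intermediate volumes/tables to `out_dir`.
#' @param seed seed for the phantom (and any seeded sub-step).
#' @return A validated list of class `cq_config`.
#' @export
pipeline_config <- function(input = NULL, phantom = NULL,
                            median_radius = NULL,
                            snake = list(), kmeans = list(), blobs = list(),
                            mask_dilation_voxels = 1L,
                            zonation_window = 25L,
                            polarity = list(plane = "xy",
                                            elongation_min = 1.2,
                                            superficial_um = 15),
                            init = list(method = "auto"),
                            out_dir = tempfile("chondroquant_run_"),
                            write_artifacts = TRUE,
                            seed = 42L) {
  use_phantom <- !is.null(phantom) && !isFALSE(phantom)
  if (is.null(median_radius)) median_radius <- if (use_phantom) 3L else 10L
  cfg <- list(input = input, phantom = phantom,
              median_radius = as.integer(rep(median_radius, length.out = 3L)),
              snake = snake, kmeans = kmeans, blobs = blobs,
              mask_dilation_voxels = as.integer(mask_dilation_voxels),
              zonation_window = as.integer(zonation_window),
              polarity = modifyList(list(plane = "xy", elongation_min = 1.2,
                                         superficial_um = 15),
                                    polarity),
              init = modifyList(list(method = "auto", seed_point = NULL,
                                     init_slice = NULL), init),
              out_dir = out_dir, write_artifacts = isTRUE(write_artifacts),
              seed = as.integer(seed))
  class(cfg) <- "cq_config"
  validate_config(cfg)
}

#' Validate (and normalise) a pipeline configuration
#'
#' Accepts a `cq_config`, a plain list, or a path to a JSON config file.
#' Unknown keys and out-of-range values raise an itemised error; defaults
#' are filled in and sub-parameter constructors are run so every
#' cross-field check happens before any I/O.
#'
#' @param config configuration object, list, or JSON file path.
#' @return A normalised `cq_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (inherits(config, "cq_config")) {
    cfg <- unclass(config)
  } else {
    known <- c("input", "phantom", "median_radius", "snake", "kmeans",
               "blobs", "mask_dilation_voxels", "zonation_window",
               "polarity", "init", "out_dir", "write_artifacts", "seed")
    unknown <- setdiff(names(config), known)
    if (length(unknown))
      stop("validation error: unknown config keys: ",
           paste(unknown, collapse = ", "))
    args <- config
    if (!is.null(args$phantom) && isTRUE(args$phantom)) args$phantom <- TRUE
    return(do.call(pipeline_config, args))
  }
  problems <- character(0)
  if (is.null(cfg$input) && (is.null(cfg$phantom) || isFALSE(cfg$phantom)))
    problems <- c(problems, "either input or phantom must be given")
  if (any(cfg$median_radius < 0))
    problems <- c(problems, "median_radius: must be >= 0")
  sp <- try(do.call(snake_params, cfg$snake), silent = TRUE)
  if (inherits(sp, "try-error"))
    problems <- c(problems, paste0("snake: ", attr(sp, "condition")$message))
  kp <- try(do.call(kmeans_params, cfg$kmeans), silent = TRUE)
  if (inherits(kp, "try-error"))
    problems <- c(problems, paste0("kmeans: ", attr(kp, "condition")$message))
  bp <- try(do.call(blob_params, cfg$blobs), silent = TRUE)
  if (inherits(bp, "try-error"))
    problems <- c(problems, paste0("blobs: ", attr(bp, "condition")$message))
  if (cfg$zonation_window < 1L)
    problems <- c(problems, "zonation_window: must be >= 1")
  if (cfg$mask_dilation_voxels < 0L)
    problems <- c(problems, "mask_dilation_voxels: must be >= 0")
  if (length(problems))
    stop("validation error:\n  ", paste(problems, collapse = "\n  "))
  if (!inherits(kp, "try-error") && kp$k != 3L)
    warning("k = ", kp$k, " classes; the standard pipeline uses 3 ",
            "(background, ECM, nuclei)")
  cfg$snake_params <- sp
  cfg$kmeans_params <- kp
  cfg$blob_params <- bp
  class(cfg) <- "cq_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Stages, in the published order: load or generate the volume; 3D median
#' filter; snake segmentation on the filtered volume with slice
#' propagation; transparent-zero masking of the original volume; K-means
#' classification into background/ECM/nuclei; erosion-based blob
#' splitting and labeling; blob metrics and the 27-voxel size filter;
#' per-slice profile, zonation and element summary; polarity mapping.
#' Intermediate artifacts (filtered, mask, masked, classmap, labels,
#' blobs.csv, profile.csv, summary.json, polarity.csv) are written to
#' `config$out_dir` when `write_artifacts` is set, along with
#' `report.json`.
#'
#' @param config a [pipeline_config()] (or anything [validate_config()]
#'   accepts).
#' @param keep_volumes also return the in-memory intermediate objects.
#' @return The run report (list of class `cq_report`): parameters, stage
#'   timings, counts, densities, zone boundaries, parabola vertex and
#'   polarity aggregates.
#' @export
run_pipeline <- function(config, keep_volumes = FALSE) {
  cfg <- validate_config(config)
  t_all <- proc.time()[["elapsed"]]
  timings <- list()
  tic <- function() proc.time()[["elapsed"]]
  stage_log <- function(name, t0)
    timings[[name]] <<- round(tic() - t0, 3)

  if (cfg$write_artifacts && !dir.exists(cfg$out_dir))
    dir.create(cfg$out_dir, recursive = TRUE)
  art <- function(f) file.path(cfg$out_dir, f)

  # --- input -------------------------------------------------------------
  t0 <- tic()
  truth <- NULL
  if (!is.null(cfg$phantom) && !isFALSE(cfg$phantom)) {
    spec_args <- if (is.list(cfg$phantom)) cfg$phantom else list()
    if (is.null(spec_args$seed)) spec_args$seed <- cfg$seed
    spec <- do.call(phantom_spec, spec_args)
    message("stage: generate phantom (seed ", spec$seed, ")")
    ph <- generate_phantom(spec)
    volume <- ph$volume
    truth <- ph$truth
    if (cfg$write_artifacts) truth_report(truth, art("truth.json"))
  } else {
    message("stage: read ", cfg$input)
    volume <- read_tiff_stack(cfg$input)
  }
  stage_log("input", t0)

  # --- median filter ------------------------------------------------------
  t0 <- tic()
  message("stage: median3d radius ", paste(cfg$median_radius, collapse = ","))
  filtered <- median3d(volume, cfg$median_radius)
  if (cfg$write_artifacts) write_tiff_stack(filtered, art("filtered.tif"))
  stage_log("median", t0)

  # --- segmentation -------------------------------------------------------
  t0 <- tic()
  d <- dim(volume$data)
  z_init <- if (!is.null(cfg$init$init_slice)) as.integer(cfg$init$init_slice)
            else (d[1L] - 1L) %/% 2L
  seed_pt <- cfg$init$seed_point
  if (is.null(seed_pt) && identical(cfg$init$method, "auto"))
    seed_pt <- c((d[2L] - 1) / 2, (d[3L] - 1) / 2)
  message("stage: snake segmentation from slice ", z_init)
  init <- init_contour(filtered$data[z_init + 1L, , ],
                       method = cfg$init$method, seed_point = seed_pt,
                       slice_index = z_init,
                       resample_spacing = cfg$snake_params$resample_spacing)
  mask <- segment_element(volume, filtered, cfg$snake_params, init)
  if (cfg$mask_dilation_voxels > 0L) {
    contours <- attr(mask, "contours")
    mask <- dilate_mask(mask, cfg$mask_dilation_voxels)
    attr(mask, "contours") <- contours
  }
  if (cfg$write_artifacts) {
    write_mask_tiff(mask, art("mask.tif"))
    write_table(contours_table(mask), art("contours.csv"))
  }
  stage_log("segment", t0)

  # --- masking + K-means --------------------------------------------------
  t0 <- tic()
  message("stage: transparent-zero mask + K-means (k = ",
          cfg$kmeans_params$k, ")")
  masked <- apply_mask(volume, mask)
  if (cfg$write_artifacts) write_tiff_stack(masked, art("masked.tif"))
  classmap <- kmeans_classify(masked, cfg$kmeans_params)
  if (cfg$write_artifacts)
    write_tiff_stack(new_volume(classmap$data, volume$voxel_size_um, 8L),
                     art("classmap.tif"))
  stage_log("kmeans", t0)

  # --- blobs --------------------------------------------------------------
  t0 <- tic()
  message("stage: erosion-based splitting + blob analysis")
  nuclei <- class_binary(classmap, classmap$k - 1L)
  labels <- split_blobs(nuclei, cfg$blob_params)
  blobs_all <- blob_metrics(labels)
  blobs <- filter_blobs(blobs_all, cfg$blob_params$min_voxels)
  if (cfg$write_artifacts) {
    write_labels_tiff(labels, art("labels.tif"))
    write_table(blobs, art("blobs.csv"))
  }
  stage_log("blobs", t0)

  # --- zonal statistics ---------------------------------------------------
  t0 <- tic()
  message("stage: zonal profile + summary")
  profile <- per_slice_profile(classmap, labels, blobs,
                               cartilage_mask = mask)
  zones <- detect_zones(profile$cell_density_per_mm3,
                        window = cfg$zonation_window,
                        area = profile$cartilage_area_um2,
                        z_offset = min(profile$z))
  parabola <- tryCatch(fit_parabola(profile), error = function(e) NULL)
  summary <- summarize_element(mask, blobs, zones)
  if (cfg$write_artifacts) write_table(profile, art("profile.csv"))
  stage_log("zones", t0)

  # --- polarity -----------------------------------------------------------
  t0 <- tic()
  message("stage: polarity mapping (plane ", cfg$polarity$plane, ")")
  pol <- polarity_map(blobs, mask, plane = cfg$polarity$plane,
                      elongation_min = cfg$polarity$elongation_min,
                      superficial_max_um = cfg$polarity$superficial_um,
                      zones = zones)
  if (cfg$write_artifacts) write_table(pol$records, art("polarity.csv"))
  stage_log("polarity", t0)

  report <- structure(list(
    parameters = list(
      median_radius = cfg$median_radius,
      snake = unclass(cfg$snake_params),
      kmeans = unclass(cfg$kmeans_params),
      blobs = unclass(cfg$blob_params),
      zonation_window = cfg$zonation_window,
      polarity = cfg$polarity,
      seed = cfg$seed),
    cell_number = summary$cell_number,
    element_volume_mm3 = summary$element_volume_mm3,
    density_cells_per_mm3 = summary$density_cells_per_mm3,
    average_cell_size_um3 = summary$average_cell_size_um3,
    zones = summary$zones,
    zonation_detected = summary$zonation_detected,
    zone_boundaries = if (zones$detected) c(z1 = zones$z1, z2 = zones$z2)
                      else NULL,
    parabola = if (!is.null(parabola)) unclass(parabola) else NULL,
    kmeans_centroids = classmap$centroids,
    polarity = pol$aggregates[setdiff(names(pol$aggregates), "per_slice")],
    truth = if (!is.null(truth)) list(
      n_cells = nrow(truth$centers_um),
      element_volume_mm3 = truth$element_volume_mm3,
      zone_densities = as.list(truth$zone_densities),
      zone_boundaries_slice = as.list(truth$zone_boundaries_slice)) else NULL,
    timings = timings,
    total_seconds = round(tic() - t_all, 3)),
    class = "cq_report")
  if (cfg$write_artifacts) {
    jrep <- report
    jrep$timings <- NULL; jrep$total_seconds <- NULL
    jsonlite::write_json(jrep, art("report.json"), auto_unbox = TRUE,
                         digits = NA, force = TRUE)
    summ <- list(cell_number = summary$cell_number,
                 element_volume_mm3 = summary$element_volume_mm3,
                 density_cells_per_mm3 = summary$density_cells_per_mm3,
                 average_cell_size_um3 = summary$average_cell_size_um3,
                 zones = summary$zones,
                 zonation_detected = summary$zonation_detected)
    jsonlite::write_json(summ, art("summary.json"), auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  }
  if (keep_volumes) {
    attr(report, "objects") <- list(volume = volume, filtered = filtered,
                                    mask = mask, masked = masked,
                                    classmap = classmap, labels = labels,
                                    blobs_all = blobs_all, blobs = blobs,
                                    profile = profile, zones = zones,
                                    parabola = parabola, summary = summary,
                                    polarity = pol, truth = truth)
  }
  report
}

#' @export
print.cq_report <- function(x, ...) {
  cat("<cq_report>\n")
  cat(sprintf("  cells: %d, element volume: %.5f mm^3, density: %.0f /mm^3\n",
              x$cell_number, x$element_volume_mm3, x$density_cells_per_mm3))
  if (!is.null(x$zone_boundaries))
    cat(sprintf("  zone boundaries: z1 = %d, z2 = %d\n",
                x$zone_boundaries[["z1"]], x$zone_boundaries[["z2"]]))
  if (!is.null(x$parabola) && is.finite(x$parabola$vertex_z))
    cat(sprintf("  ratio parabola vertex at slice %.1f\n",
                x$parabola$vertex_z))
  cat(sprintf("  total %.1f s\n", x$total_seconds))
  invisible(x)
}
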