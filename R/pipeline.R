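#' Default run configuration
#'
#' All tunable parameters of the pipeline in one (YAML round-trippable)
#' list:
#' \describe{
#'   \item{calibration}{Named map objective -> um/px. The shipped values are
#'     placeholders on a plausible scale for a 2448 x 1920 camera; replace
#'     them with your microscope's calibration.}
#'   \item{default_calibration}{Used when an image names no objective.}
#'   \item{median_radius}{Median smoothing radius (px).}
#'   \item{edge_threshold}{`"otsu"` or an absolute Sobel magnitude.}
#'   \item{closing_radius, edge_compensation}{Segmentation morphology (px).}
#'   \item{filters}{Per image kind (`spore`, `pellet`), a list of
#'     `list(kind=, threshold=)` rules. Spore images remove non-circular
#'     debris (angular mineral grains rasterize well below circularity
#'     0.75 while spores sit above 0.85); pellet images remove too-small
#'     objects. Objects touching the frame border are always excluded,
#'     since partial objects corrupt size statistics.}
#'   \item{class_threshold}{Two-class area threshold, um^2 (1e4 by
#'     default; 1e5 suits slow non-agglomerative pellet formation).}
#'   \item{alpha}{Significance level of the t confidence bands.}
#'   \item{n_dirs}{Chord directions for the mean diameter.}
#'   \item{seed}{Seed for every source of randomness in a run.}
#'   \item{filename_pattern}{Regex with three groups (condition, time in
#'     hours, index) parsed from image file names.}
#' }
#'
#' @return A named list of class `myco_config`.
#' @export
default_config <- function() {
  structure(list(
    calibration = list("4x" = 1.6, "10x" = 0.64, "20x" = 0.32,
                       "40x" = 0.16, "100x" = 0.064),
    default_calibration = 1.0,
    median_radius = 1,
    edge_threshold = "otsu",
    closing_radius = 2,
    edge_compensation = 1,
    filters = list(
      spore = list(list(kind = "min_circularity", threshold = 0.75),
                   list(kind = "border_exclusion", threshold = 1)),
      pellet = list(list(kind = "min_area", threshold = 200),
                    list(kind = "border_exclusion", threshold = 1))
    ),
    class_threshold = 1e4,
    alpha = 0.05,
    n_dirs = 180,
    seed = 1,
    filename_pattern = "^([A-Za-z]+)_([0-9.]+)h_([0-9]+)$"
  ), class = "myco_config")
}

#' Read / write a run configuration
#'
#' Configurations round-trip losslessly through YAML.
#'
#' @param path File path.
#' @param config A config list (see [default_config()]).
#' @return `read_config()` returns the config; `write_config()` the path,
#'   invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: '%s'", path))
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  for (nm in names(cfg)) base[[nm]] <- cfg[[nm]]
  validate_config(base)
  base
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  validate_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

validate_config <- function(config) {
  num_pos <- c("default_calibration", "median_radius", "closing_radius",
               "class_threshold", "alpha")
  for (nm in num_pos) {
    if (!is.numeric(config[[nm]]) || config[[nm]] < 0) {
      abort(sprintf("Config field `%s` must be a non-negative number.", nm))
    }
  }
  if (config$class_threshold <= 0) abort("`class_threshold` must be positive.")
  for (kind in names(config$filters)) {
    for (r in config$filters[[kind]]) {
      filter_rule(r$kind, r$threshold)  # validates
    }
  }
  invisible(config)
}

rules_from_config <- function(config, image_kind = "spore") {
  specs <- config$filters[[image_kind]]
  if (is.null(specs)) {
    abort(sprintf("No filter set named '%s' in the config (have: %s).",
                  image_kind, paste(names(config$filters), collapse = ", ")))
  }
  purrr::map(specs, function(r) filter_rule(r$kind, r$threshold))
}

#' Analyze one micrograph end to end
#'
#' Runs the full chain on a single image: green-plane extraction, median
#' smoothing, Sobel edge enhancement, edge-based segmentation, descriptor
#' measurement, then AOI restriction and debris filtering. The returned
#' object table contains one row per surviving object; the removal report
#' and the segmented scene are attached as attributes `removals` and
#' `scene`.
#'
#' @param img A [calibrated_image] (RGB or grayscale).
#' @param config A config list (see [default_config()]).
#' @param image_kind Which filter set to apply (`"spore"` or `"pellet"`),
#'   or `"none"` for no filtering.
#' @param aoi Optional AOI polygon (n x 2, 0-based pixel coordinates) or
#'   list of polygons.
#' @param image_id Identifier for the `image` column.
#' @return A tibble of per-object descriptors (see [measure_objects()]).
#' @export
analyze_image <- function(img, config = default_config(),
                          image_kind = "spore", aoi = NULL,
                          image_id = NA_character_) {
  stopifnot(inherits(img, "calibrated_image"))
  gray <- extract_green_plane(img)
  if (config$median_radius >= 1) {
    gray <- median_smooth(gray, config$median_radius)
  }
  edges <- sobel_edge_magnitude(gray)
  scene <- segment_from_edges(edges, edge_threshold = config$edge_threshold,
                              closing_radius = config$closing_radius,
                              edge_compensation = config$edge_compensation)
  if (!is.null(aoi)) {
    if (is.list(aoi) && !is.matrix(aoi) && !is.data.frame(aoi)) {
      for (p in aoi) scene <- apply_aoi(scene, p)
    } else {
      scene <- apply_aoi(scene, aoi)
    }
  }
  morpho <- measure_objects(scene, image = image_id,
                            time_hr = img$time_hr %||% NA_real_,
                            condition = img$condition %||% NA_character_,
                            n_dirs = config$n_dirs)
  removals <- tibble::tibble(object_id = integer(0), rule = character(0))
  if (!identical(image_kind, "none")) {
    rules <- rules_from_config(config, image_kind)
    scene <- apply_filters(scene, rules, morpho = morpho)
    removals <- attr(scene, "removals")
    morpho <- morpho[!morpho$object_id %in% removals$object_id, , drop = FALSE]
    morpho$object_id <- seq_len(nrow(morpho))
  }
  attr(morpho, "removals") <- removals
  attr(morpho, "scene") <- scene
  morpho
}

parse_image_name <- function(name, pattern) {
  base <- tools::file_path_sans_ext(basename(name))
  m <- regmatches(base, regexec(pattern, base))[[1]]
  if (length(m) < 4) return(NULL)
  list(condition = m[2], time_hr = as.numeric(m[3]), index = as.integer(m[4]))
}

#' Analyze a directory of micrographs
#'
#' Loads every TIFF/PNG in `input_dir`, parses `<condition>_<time>h_<index>`
#' metadata from the file names, analyzes each image and writes one object
#' CSV per image plus a combined table and a plain-text run log (config
#' hash, per-image status, filter removals). Unreadable or unparseable
#' images are logged and skipped.
#'
#' @param input_dir Directory of images.
#' @param output_dir Output directory (created if needed).
#' @param config Config list.
#' @param image_kind Filter set to apply to every image.
#' @param calibration um/px applied to all images (default:
#'   `config$default_calibration`).
#' @return The combined object tibble, invisibly, with attributes `n_failed`
#'   and `log` (character vector of log lines).
#' @export
run_analyze <- function(input_dir, output_dir, config = default_config(),
                        image_kind = "spore", calibration = NULL) {
  if (!dir.exists(input_dir)) abort(sprintf("Input directory not found: '%s'", input_dir))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(calibration)) calibration <- config$default_calibration
  files <- sort(list.files(input_dir, pattern = "\\.(tif|tiff|png)$",
                           ignore.case = TRUE, full.names = TRUE))
  log_lines <- c(sprintf("run_analyze: %d image file(s) in %s", length(files), input_dir),
                 sprintf("config hash: %s", rlang::hash(config)))
  if (length(files) == 0) {
    warn(sprintf("No images found in '%s'; writing an empty table.", input_dir))
    log_lines <- c(log_lines, "warning: empty input directory")
  }
  n_failed <- 0L
  all_records <- list()
  for (f in files) {
    meta <- parse_image_name(f, config$filename_pattern)
    rec <- tryCatch({
      img <- load_image(f, calibration,
                        time_hr = if (is.null(meta)) NULL else meta$time_hr,
                        condition = if (is.null(meta)) NULL else meta$condition)
      analyze_image(img, config, image_kind = image_kind,
                    image_id = basename(f))
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      n_failed <- n_failed + 1L
      log_lines <- c(log_lines, sprintf("SKIPPED %s: %s", basename(f),
                                        conditionMessage(rec)))
      next
    }
    removals <- attr(rec, "removals")
    log_lines <- c(log_lines,
                   sprintf("%s: %d object(s), %d removed by filters",
                           basename(f), nrow(rec), nrow(removals)))
    per_image <- file.path(output_dir, paste0(
      tools::file_path_sans_ext(basename(f)), "_objects.csv"))
    utils::write.csv(strip_attrs(rec), per_image, row.names = FALSE)
    all_records[[basename(f)]] <- strip_attrs(rec)
  }
  combined <- dplyr::bind_rows(all_records)
  utils::write.csv(combined, file.path(output_dir, "objects_combined.csv"),
                   row.names = FALSE)
  log_lines <- c(log_lines, sprintf("total: %d object(s), %d image(s) failed",
                                    nrow(combined), n_failed))
  writeLines(log_lines, file.path(output_dir, "run_analyze.log"))
  attr(combined, "n_failed") <- n_failed
  attr(combined, "log") <- log_lines
  invisible(combined)
}

strip_attrs <- function(x) {
  attr(x, "removals") <- NULL
  attr(x, "scene") <- NULL
  attr(x, "mo_form") <- NULL
  x
}

#' Summarize an object table
#'
#' Partitions the objects at the configured two-class area threshold and
#' writes per time x condition x class x parameter statistics with t
#' confidence bands.
#'
#' @param records Object table (tibble or path to a CSV written by
#'   [run_analyze()]).
#' @param config Config list (`class_threshold`, `alpha`).
#' @param output Optional path for the summary CSV.
#' @return The summary tibble (see [summarize_morphology()]).
#' @export
run_summarize <- function(records, config = default_config(), output = NULL) {
  if (is.character(records)) {
    if (!file.exists(records)) abort(sprintf("Object table not found: '%s'", records))
    records <- tibble::as_tibble(utils::read.csv(records))
  }
  required <- c("A_um2", "D_um", "Dmax_um", "E", "R", "Mo")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    abort(sprintf("Object table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  part <- partition_by_area(records, config$class_threshold)
  summ <- summarize_morphology(part, alpha = config$alpha)
  if (!is.null(output)) {
    utils::write.csv(summ, output, row.names = FALSE)
  }
  summ
}

#' Simulate and write a synthetic timecourse
#'
#' Runs [simulate_timecourse()] and writes, per time point, the rendered
#' scene as an 8-bit TIFF, the true label grid as a 16-bit TIFF and the
#' ground-truth descriptor CSV, plus a manifest listing every file with the
#' seed and a content hash.
#'
#' @param profile Profile name or schedule (see [simulate_timecourse()]).
#' @param output_dir Output directory.
#' @param config Config list (seed, class threshold).
#' @param width,height Scene size (px).
#' @param condition Cultivation arm label.
#' @param times Optional subset of the profile's scheduled times.
#' @return The timecourse tibble, invisibly, with attribute `manifest`.
#' @export
run_simulate <- function(profile, output_dir, config = default_config(),
                         width = 2448, height = 1920,
                         condition = "standard", times = NULL) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  tc <- simulate_timecourse(profile, seed = config$seed, width = width,
                            height = height, condition = condition,
                            times = times)
  manifest <- purrr::pmap(tc, function(time_hr, stage, condition, scene) {
    stem <- sprintf("%s_%gh", condition, time_hr)
    img <- render_scene(scene)
    scene_path <- file.path(output_dir, paste0(stem, ".tif"))
    tiff::writeTIFF(img$pixels / 255, scene_path, bits.per.sample = 8)
    labs <- scene_labels(scene)
    labels_path <- file.path(output_dir, paste0(stem, "_labels.tif"))
    tiff::writeTIFF(labs$labels / 65535, labels_path, bits.per.sample = 16)
    truth <- scene_truth(scene, class_threshold = config$class_threshold)
    truth_path <- file.path(output_dir, paste0(stem, "_truth.csv"))
    utils::write.csv(truth, truth_path, row.names = FALSE)
    tibble::tibble(
      time_hr = time_hr, stage = stage, condition = condition,
      seed = scene$seed,
      scene_file = basename(scene_path), labels_file = basename(labels_path),
      truth_file = basename(truth_path),
      scene_hash = rlang::hash(img$pixels)
    )
  })
  manifest <- dplyr::bind_rows(manifest)
  utils::write.csv(manifest, file.path(output_dir, "manifest.csv"),
                   row.names = FALSE)
  attr(tc, "manifest") <- manifest
  invisible(tc)
}
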