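#' Partition objects into two size classes
#'
#' In the first day of a submerged cultivation, mycelial objects often split
#' into two coexisting populations (e.g. residual small agglomerates next to
#' growing large ones). Objects are assigned to the `small` class when their
#' projected area is strictly below the threshold and to `large` otherwise
#' (an area exactly equal to the threshold counts as `large`). The default
#' threshold is 1e4 um^2; slower, non-agglomerative species can need 1e5
#' um^2.
#'
#' @param records A tibble of per-object descriptors (from
#'   [measure_objects()]), needing at least columns `A_um2` and `object_id`.
#' @param threshold Class threshold in um^2 (> 0).
#' @return The records with a `class` factor column (`small`/`large`) added,
#'   of class `myco_partition`, with attribute `threshold`.
#' @export
partition_by_area <- function(records, threshold = 1e4) {
  stopifnot(is.data.frame(records), threshold > 0)
  if (!"A_um2" %in% names(records)) abort("`records` must have an `A_um2` column.")
  out <- dplyr::mutate(
    tibble::as_tibble(records),
    class = factor(ifelse(.data$A_um2 < threshold, "small", "large"),
                   levels = c("small", "large"))
  )
  class(out) <- c("myco_partition", class(out))
  attr(out, "threshold") <- threshold
  out
}

#' @export
tidy.myco_partition <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$class, .drop = FALSE),
    n = dplyr::n(),
    mean_A_um2 = mean(.data$A_um2),
    sd_A_um2 = stats::sd(.data$A_um2),
    .groups = "drop"
  )
}

#' @export
glance.myco_partition <- function(x, ...) {
  tibble::tibble(
    threshold_um2 = attr(x, "threshold"),
    n = nrow(x),
    n_small = sum(x$class == "small"),
    n_large = sum(x$class == "large")
  )
}

#' Per-timepoint descriptor statistics with t confidence bands
#'
#' For each time point, cultivation arm, size class and descriptor, computes
#' the arithmetic mean, the sample standard deviation (n - 1 denominator)
#' and the half-width of the Student-t confidence band,
#' `t(1 - alpha/2, n - 1) * sd / sqrt(n)`. Each class is summarized
#' separately and together (`class = "all"`). Groups of a single object
#' report the mean with `sd`/`ci_half_width` set to `NA` and flagged
#' undefined.
#'
#' @param records Per-object descriptor tibble; if it carries a `class`
#'   column (see [partition_by_area()]) per-class rows are produced.
#' @param parameters Descriptor columns to summarize.
#' @param alpha Significance level of the confidence band (default 0.05).
#' @return A tibble of class `myco_summary` with columns `time_hr`,
#'   `condition`, `class`, `parameter`, `n`, `mean`, `sd`, `ci_half_width`,
#'   `undefined`.
#' @export
summarize_morphology <- function(records,
                                 parameters = c("A_um2", "D_um", "Dmax_um",
                                                "E", "R", "Mo"),
                                 alpha = 0.05) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) abort("`records` is empty: nothing to summarize.")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie in (0, 1).")
  }
  missing_cols <- setdiff(parameters, names(records))
  if (length(missing_cols)) {
    abort(sprintf("Missing descriptor column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  recs <- tibble::as_tibble(records)
  if (!"time_hr" %in% names(recs)) recs$time_hr <- NA_real_
  if (!"condition" %in% names(recs)) recs$condition <- NA_character_
  with_class <- "class" %in% names(recs)
  all_recs <- dplyr::mutate(recs, class = "all")
  pooled <- if (with_class) {
    dplyr::bind_rows(dplyr::mutate(recs, class = as.character(.data$class)),
                     all_recs)
  } else {
    all_recs
  }
  long <- tidyr::pivot_longer(
    dplyr::select(pooled, "time_hr", "condition", "class",
                  dplyr::all_of(parameters)),
    cols = dplyr::all_of(parameters),
    names_to = "parameter", values_to = "value"
  )
  long <- dplyr::filter(long, is.finite(.data$value))
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$time_hr, .data$condition, .data$class,
                    .data$parameter),
    n = dplyr::n(),
    mean = mean(.data$value),
    sd = ifelse(dplyr::n() > 1, stats::sd(.data$value), NA_real_),
    .groups = "drop"
  )
  out <- dplyr::mutate(out,
    ci_half_width = ifelse(.data$n > 1,
                           stats::qt(1 - alpha / 2,
                                     df = pmax(.data$n - 1, 1)) *
                             .data$sd / sqrt(.data$n),
                           NA_real_),
    undefined = .data$n == 1
  )
  class(out) <- c("myco_summary", class(out))
  attr(out, "alpha") <- alpha
  out
}

#' @export
glance.myco_summary <- function(x, ...) {
  tibble::tibble(
    alpha = attr(x, "alpha"),
    n_groups = nrow(x),
    n_timepoints = length(unique(x$time_hr)),
    parameters = paste(sort(unique(x$parameter)), collapse = ",")
  )
}

#' Manual core and filament measures of a pellet
#'
#' Hairy and core-shell pellets are characterized by the diameter of their
#' dense core(s) and the length of the filaments protruding from it,
#' expressed relative to the pellet's mean diameter. Core masks come from
#' generator ground truth or a manual annotation; filament lengths are
#' supplied directly.
#'
#' @param pellet_mask Logical matrix of the whole pellet.
#' @param core_masks List of logical matrices (same frame as `pellet_mask`),
#'   each a subset of the pellet; may be empty.
#' @param filament_lengths Numeric vector of filament lengths in um; may be
#'   empty.
#' @param calibration Micrometers per pixel.
#' @return A one-row tibble with `core_diameter_um`, `pellet_diameter_um`,
#'   `core_ratio`, `mean_filament_length_um`, `filament_ratio`, `n_cores`.
#' @export
core_measures <- function(pellet_mask, core_masks = list(),
                          filament_lengths = numeric(0), calibration = 1) {
  check_mask(pellet_mask)
  stopifnot(is.list(core_masks), calibration > 0)
  for (cm in core_masks) {
    check_mask(cm)
    if (!identical(dim(cm), dim(pellet_mask))) {
      abort("Core masks must live in the same pixel frame as the pellet mask.")
    }
    if (any(cm & !pellet_mask)) {
      abort("A core mask has pixels outside the pellet mask.")
    }
  }
  pellet_d <- as.numeric(mean_diameter(pellet_mask, calibration))
  core_d <- NA_real_
  if (length(core_masks) > 0) {
    sizes <- vapply(core_masks, sum, numeric(1))
    core_d <- as.numeric(mean_diameter(core_masks[[which.max(sizes)]], calibration))
  }
  mean_fil <- if (length(filament_lengths) > 0) mean(filament_lengths) else NA_real_
  tibble::tibble(
    core_diameter_um = core_d,
    pellet_diameter_um = pellet_d,
    core_ratio = core_d / pellet_d,
    mean_filament_length_um = mean_fil,
    filament_ratio = mean_fil / pellet_d,
    n_cores = length(core_masks)
  )
}
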