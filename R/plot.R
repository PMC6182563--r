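#' Plot descriptor trajectories
#'
#' Mean trajectories over time with the Student-t confidence band as a
#' ribbon, one facet per descriptor, colored by size class.
#'
#' @param object A `myco_summary` tibble (from [summarize_morphology()]).
#' @param parameters Descriptors to show (default: all present).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.myco_summary <- function(object, parameters = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(parameters)) {
    df <- dplyr::filter(df, .data$parameter %in% parameters)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_hr, y = .data$mean,
                                   color = .data$class, fill = .data$class)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$ci_half_width,
                                      ymax = .data$mean + .data$ci_half_width),
                         alpha = 0.2, color = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "time since inoculation (hr)", y = "mean ± t-CI",
                  color = "class", fill = "class") +
    ggplot2::theme_minimal()
}

#' Plot a two-class partition
#'
#' Morphology number against projected area (log scale) with the class
#' threshold marked.
#'
#' @param object A `myco_partition` (from [partition_by_area()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.myco_partition <- function(object, ...) {
  thr <- attr(object, "threshold")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$A_um2, y = .data$Mo,
                               color = .data$class)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression("projected area A (" * mu * m^2 * ")"),
                  y = "morphology number Mo", color = "class") +
    ggplot2::theme_minimal()
}

#' Plot a synthetic scene
#'
#' Renders the scene and shows its green plane; optionally outlines the
#' ground-truth masks.
#'
#' @param object A `myco_scene`.
#' @param truth_outline Overlay boundary pixels of the true masks.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.myco_scene <- function(object, truth_outline = FALSE, ...) {
  img <- extract_green_plane(render_scene(object))
  m <- img$pixels
  df <- tibble::tibble(
    x = rep(seq_len(ncol(m)), each = nrow(m)) - 1L,
    y = rep(seq_len(nrow(m)), times = ncol(m)) - 1L,
    intensity = as.vector(m)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                        fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::guides(fill = "none")
  if (truth_outline) {
    h <- object$height
    bnd <- purrr::imap(object$objects, function(ob, i) {
      cm <- crop_mask(h, ob$idx)
      b <- which(boundary_mask(cm$mask), arr.ind = TRUE)
      tibble::tibble(x = b[, 2] - 1L + cm$x0, y = b[, 1] - 1L + cm$y0)
    })
    p <- p + ggplot2::geom_point(
      data = dplyr::bind_rows(bnd),
      ggplot2::aes(.data$x, .data$y), inherit.aes = FALSE,
      color = "red", size = 0.1)
  }
  p
}
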