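#' Plot a penetration-depth profile
#'
#' Depth band (min-max) and mean per residue, with the phosphate-plane
#' sigma band marked; residues above the band line are candidate
#' hotspots.
#'
#' @param object A `depth_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.depth_profile <- function(object, ...) {
  sigma <- attr(object, "plane_sigma")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$residue_id)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$min_dz,
                                      ymax = .data$max_dz),
                         fill = "pink", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_dz), color = "deeppink") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_hline(yintercept = sigma, linetype = 3) +
    ggplot2::labs(x = "residue", y = "penetration depth dz (A)",
                  title = "Membrane penetration depth",
                  subtitle = "dotted line: phosphate-plane sigma (burial threshold)") +
    ggplot2::theme_minimal()
}

#' Plot a radial distribution function
#'
#' @param object An `rdf_result`.
#' @param ... Unused.
#' @return A ggplot object with g(r) and the cumulative count.
#' @export
autoplot.rdf_result <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$g), color = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative_n), linetype = 2) +
    ggplot2::labs(x = "r (A)", y = "g(r) / cumulative n(r)",
                  title = "Radial distribution function") +
    ggplot2::theme_minimal()
  if ("g_smooth" %in% names(object)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$g_smooth),
                                color = "deeppink")
  }
  p
}

#' Plot a free-energy profile
#'
#' @param object A `free_energy_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.free_energy_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$xi, y = .data$F)) +
    ggplot2::geom_line(color = "deeppink") +
    ggplot2::labs(x = "collective variable (A)", y = "F (kcal/mol)",
                  title = "WHAM free-energy profile") +
    ggplot2::theme_minimal()
}

#' Plot a band-optimized path over its surface
#'
#' For 2-D surfaces: filled contours of the energy with the image chain
#' overlaid. For 1-D: energy along the path coordinate.
#'
#' @param object A `neb_path`.
#' @param surface The surface the path was optimized on (2-D plot only).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.neb_path <- function(object, surface = NULL, ...) {
  td <- tidy(object)
  if (ncol(object$images) == 2 && !is.null(surface)) {
    dom <- surface$domain
    gx <- seq(dom[1, 1], dom[1, 2], length.out = 120)
    gy <- seq(dom[2, 1], dom[2, 2], length.out = 120)
    grid <- expand.grid(x = gx, y = gy)
    grid$energy <- surface$energy(as.matrix(grid))
    ggplot2::ggplot(grid, ggplot2::aes(.data$x, .data$y)) +
      ggplot2::geom_contour_filled(ggplot2::aes(z = .data$energy),
                                   bins = 18, show.legend = FALSE) +
      ggplot2::geom_path(data = td, color = "white") +
      ggplot2::geom_point(data = td, color = "white", size = 1.5) +
      ggplot2::labs(title = "CI-NEB minimum-energy path") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(td, ggplot2::aes(.data$image, .data$energy)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "image", y = "energy",
                    title = "Band energy profile") +
      ggplot2::theme_minimal()
  }
}

#' Plot per-residue barrier contributions
#'
#' @param object A `residue_contributions` tibble (from
#'   [residue_deletion_scan()]), optionally with an `axis` column added
#'   by the caller via [axis_projection()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.residue_contributions <- function(object, ...) {
  if ("axis" %in% names(object)) {
    ggplot2::ggplot(object, ggplot2::aes(.data$axis, .data$ddEa,
                                         color = .data$class)) +
      ggplot2::geom_point() +
      ggplot2::geom_hline(yintercept = 0, linetype = 2) +
      ggplot2::labs(x = "acid/base axis coordinate (A)",
                    y = "ddEa (kcal/mol)",
                    title = "Residue-deletion barrier contributions") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object, ggplot2::aes(stats::reorder(.data$label,
                                                        .data$ddEa),
                                         .data$ddEa, fill = .data$class)) +
      ggplot2::geom_col() +
      ggplot2::coord_flip() +
      ggplot2::labs(x = NULL, y = "ddEa (kcal/mol)",
                    title = "Residue-deletion barrier contributions") +
      ggplot2::theme_minimal()
  }
}

#' Plot a 2-D density map
#'
#' @param object A `density_map`.
#' @param smoothed Plot the smoothed surface when available.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.density_map <- function(object, smoothed = TRUE, ...) {
  if (smoothed && !is.null(object$smoothed)) {
    m <- object$smoothed
    df <- expand.grid(x = attr(m, "x"), y = attr(m, "y"))
    df$density <- as.numeric(m)
  } else {
    df <- expand.grid(x = object$x, y = object$y)
    df$density <- as.numeric(object$counts)
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (A)", y = "y (A)", title = "In-plane density") +
    ggplot2::theme_minimal()
}
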