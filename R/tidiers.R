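#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a free-energy profile
#'
#' @param x A `free_energy_profile`.
#' @param ... Unused.
#' @return Tibble with `xi` and `F` (plain tibble, attributes dropped).
#' @export
tidy.free_energy_profile <- function(x, ...) {
  tibble::tibble(xi = x$xi, F = x$F)
}

#' @rdname tidy.free_energy_profile
#' @export
glance.free_energy_profile <- function(x, ...) {
  tibble::tibble(
    n_windows = attr(x, "n_windows"),
    iterations = attr(x, "iterations"),
    residual = attr(x, "residual"),
    temperature = attr(x, "temperature"),
    bin_width = attr(x, "bin_width"),
    xi_min = min(x$xi), xi_max = max(x$xi),
    f_max = max(x$F, na.rm = TRUE)
  )
}

#' Tidy a nudged-elastic-band path
#'
#' @param x A `neb_path`.
#' @param ... Unused.
#' @return Tibble with `image`, coordinate columns and `energy`.
#' @export
tidy.neb_path <- function(x, ...) {
  d <- ncol(x$images)
  out <- tibble::as_tibble(x$images, .name_repair = "minimal")
  names(out) <- c("x", "y", "z")[seq_len(d)]
  dplyr::bind_cols(tibble::tibble(image = seq_len(nrow(x$images))), out,
                   tibble::tibble(energy = x$energies))
}

#' @rdname tidy.neb_path
#' @export
glance.neb_path <- function(x, ...) {
  tibble::tibble(
    n_images = nrow(x$images),
    converged = x$converged,
    max_perp_force = x$max_perp_force,
    climbing_index = x$climbing_index,
    climbing_energy = if (is.na(x$climbing_index)) max(x$energies) else
      x$energies[x$climbing_index],
    steps = x$steps
  )
}

#' Tidy a pathway comparison
#'
#' @param x A `pathway_comparison`.
#' @param ... Unused.
#' @return `tidy`: the two pathway rows. `glance`: one row with the
#'   ratio, ddG and its decomposition.
#' @export
tidy.pathway_comparison <- function(x, ...) {
  x$paths
}

#' @rdname tidy.pathway_comparison
#' @export
glance.pathway_comparison <- function(x, ...) {
  tibble::tibble(
    fast = x$fast, slow = x$slow, ratio = x$ratio,
    ratio_1sf = x$ratio_1sf, ddg = x$ddg,
    population_term = x$population_term, barrier_term = x$barrier_term,
    temperature = x$temperature
  )
}

#' Tidy a cluster result
#'
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @return The per-cluster table.
#' @export
tidy.cluster_result <- function(x, ...) {
  x$clusters
}
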