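#' Radial distribution function
#'
#' g(r) of a population selection around a reference that is either a
#' single atom or the midpoint of two atoms, recomputed every frame.
#' Distances use the minimum-image convention; the reference density is
#' the mean population count divided by the box volume. The cumulative
#' coordination number `n(r)` (mean count within r) is reported alongside.
#'
#' @param traj A trajectory.
#' @param population_selection Selection name or atom ids counted in g(r).
#' @param reference A single atom id, or a length-2 vector for the
#'   midpoint of two atoms, or a selection name resolving to 1 or 2 atoms.
#' @param r_max Histogram range, A (at most half the smallest box edge).
#' @param bin_width Bin width, A.
#' @param smooth_sigma Optional Gaussian smoothing width for g, in bins.
#' @return An `rdf_result` tibble with `r` (bin centers), `g`,
#'   `cumulative_n` and optionally `g_smooth`; reference density in
#'   attribute `rho_ref`.
#' @export
rdf <- function(traj, population_selection, reference, r_max,
                bin_width = 0.1, smooth_sigma = NULL) {
  box <- traj_box(traj)
  if (r_max > min(box) / 2) {
    stop("validation error: r_max exceeds half the smallest box edge",
         call. = FALSE)
  }
  pop_ids <- setdiff(resolve_ids(traj, population_selection),
                     resolve_ids(traj, reference))
  ref_ids <- resolve_ids(traj, reference)
  stopifnot(length(ref_ids) %in% c(1L, 2L))
  edges <- seq(0, r_max, by = bin_width)
  nb <- length(edges) - 1L
  d <- ref_distances(traj, pop_ids, ref_ids, box)
  n_frames <- nrow(d)
  counts <- tabulate(findInterval(d[d < r_max], edges), nbins = nb)
  vol <- prod(box)
  rho <- length(pop_ids) / vol
  shell_vol <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  g <- counts / n_frames / (rho * shell_vol)
  cum_n <- cumsum(counts) / n_frames
  out <- tibble::tibble(r = edges[-length(edges)] + bin_width / 2,
                        g = g, cumulative_n = cum_n)
  if (!is.null(smooth_sigma)) {
    out$g_smooth <- smooth_profile(g, smooth_sigma)
  }
  structure(out, rho_ref = rho, bin_width = bin_width,
            n_frames = n_frames,
            class = c("rdf_result", class(tibble::tibble())))
}

# frames x atoms matrix of minimum-image distances from the per-frame
# reference point (atom or two-atom midpoint) to each population atom
ref_distances <- function(traj, pop_ids, ref_ids, box) {
  cfp <- coord_frames(traj, pop_ids)
  cfr <- coord_frames(traj, ref_ids)
  refx <- rowMeans(cfr$x); refy <- rowMeans(cfr$y); refz <- rowMeans(cfr$z)
  dx <- cfp$x - refx
  dy <- cfp$y - refy
  dz <- cfp$z - refz
  dx <- dx - box[1] * round(dx / box[1])
  dy <- dy - box[2] * round(dy / box[2])
  dz <- dz - box[3] * round(dz / box[3])
  sqrt(dx * dx + dy * dy + dz * dz)
}

# 1-D Gaussian smoothing with edge renormalization (sigma in bins)
smooth_profile <- function(y, sigma_bins) {
  half <- max(1L, ceiling(4 * sigma_bins))
  k <- stats::dnorm(seq(-half, half), sd = sigma_bins)
  k <- k / sum(k)
  n <- length(y)
  padded <- c(rep(0, half), y, rep(0, half))
  mask <- c(rep(0, half), rep(1, n), rep(0, half))
  num <- conv_same(padded, k)[(half + 1):(half + n)]
  den <- conv_same(mask, k)[(half + 1):(half + n)]
  num / den
}

#' Mean shell occupancy
#'
#' Average per-frame count of population atoms with distance in
#' `[r_lo, r_hi)` from the reference. Accepts either a trajectory (exact
#' per-frame counting) or an `rdf_result` (quadrature of
#' `rho_ref g(r) 4 pi r^2`).
#'
#' @param x A trajectory or an `rdf_result`.
#' @param r_lo,r_hi Shell bounds, A (`0 <= r_lo < r_hi`).
#' @param ... For the trajectory method: `population_selection` and
#'   `reference` as in [rdf()].
#' @return Mean occupancy (dimensionless).
#' @export
shell_statistics <- function(x, r_lo, r_hi, ...) {
  if (r_lo < 0 || r_hi <= r_lo) {
    stop("validation error: need 0 <= r_lo < r_hi", call. = FALSE)
  }
  UseMethod("shell_statistics")
}

#' @export
shell_statistics.rdf_result <- function(x, r_lo, r_hi, ...) {
  bw <- attr(x, "bin_width")
  rho <- attr(x, "rho_ref")
  lo_e <- x$r - bw / 2
  hi_e <- x$r + bw / 2
  frac <- pmax(0, pmin(hi_e, r_hi) - pmax(lo_e, r_lo)) / bw
  shell_vol <- 4 / 3 * pi * (hi_e^3 - lo_e^3)
  sum(rho * x$g * shell_vol * frac)
}

#' @export
shell_statistics.spla2_trajectory <- function(x, r_lo, r_hi,
                                              population_selection,
                                              reference, ...) {
  box <- traj_box(x)
  pop_ids <- setdiff(resolve_ids(x, population_selection),
                     resolve_ids(x, reference))
  ref_ids <- resolve_ids(x, reference)
  d <- ref_distances(x, pop_ids, ref_ids, box)
  sum(d >= r_lo & d < r_hi) / nrow(d)
}

#' Mean coordination number
#'
#' Average per-frame count of ligand atoms within `r_cut` of the center
#' atom(s). With several center atoms the count is summed over centers and
#' then averaged over frames.
#'
#' @param traj A trajectory.
#' @param center_selection,ligand_selection Selection names or atom ids.
#' @param r_cut Cutoff radius, A.
#' @return Mean count (dimensionless).
#' @export
coordination_number <- function(traj, center_selection, ligand_selection,
                                r_cut) {
  stopifnot(r_cut > 0)
  c_ids <- resolve_ids(traj, center_selection)
  if (length(c_ids) == 0) stop("selection error: empty center selection",
                               call. = FALSE)
  l_ids <- setdiff(resolve_ids(traj, ligand_selection), c_ids)
  box <- traj_box(traj)
  frames <- sort(unique(traj$frame))
  counts <- vapply(frames, function(f) {
    ctr <- frame_coords(traj, f, c_ids)
    lig <- frame_coords(traj, f, l_ids)
    sum(cross_min_image(ctr, lig, box) < r_cut)
  }, numeric(1))
  mean(counts)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Samples `n_points` quasi-uniform directions (golden-spiral lattice) on
#' each target atom's solvent-expanded sphere of radius `r_vdw + probe`;
#' a point is buried if it falls inside any other atom's expanded sphere.
#' The per-atom area is `4 pi (r_vdw + probe)^2` times the accessible
#' fraction.
#'
#' @param traj A trajectory (one frame is analysed at a time).
#' @param target_atoms Atom ids whose area is wanted.
#' @param frame Frame number (default: first).
#' @param probe Probe radius, A.
#' @param n_points Sphere sample points per atom.
#' @param radii Named vector of van der Waals radii keyed by element
#'   (defaults to the Bondi set).
#' @return A `sasa_result` tibble with `atom_id`, `element`, `radius`,
#'   `area` (A^2).
#' @export
sasa <- function(traj, target_atoms, frame = NULL, probe = 1.4,
                 n_points = 960, radii = bondi_radii) {
  if (is.null(frame)) frame <- min(traj$frame)
  sub <- traj[traj$frame == frame, ]
  elements <- sub$element
  lookup <- radii[normalize_element(elements)]
  if (any(is.na(lookup))) {
    stop("lookup error: no van der Waals radius for element(s): ",
         paste(unique(elements[is.na(lookup)]), collapse = ", "),
         call. = FALSE)
  }
  coords <- cbind(sub$x, sub$y, sub$z)
  rr <- as.numeric(lookup) + probe
  dirs <- golden_spiral(n_points)
  rows <- purrr::map(target_atoms, function(id) {
    i <- which(sub$atom_id == id)
    if (length(i) != 1) stop("selection error: atom ", id, " not found",
                             call. = FALSE)
    pts <- sweep(dirs * rr[i], 2, coords[i, ], "+")
    buried <- rep(FALSE, n_points)
    for (j in seq_len(nrow(coords))) {
      if (j == i) next
      dj2 <- sum((coords[j, ] - coords[i, ])^2)
      if (dj2 > (rr[i] + rr[j])^2) next
      dd <- (pts[, 1] - coords[j, 1])^2 + (pts[, 2] - coords[j, 2])^2 +
        (pts[, 3] - coords[j, 3])^2
      buried <- buried | dd < rr[j]^2
    }
    tibble::tibble(atom_id = id, element = elements[i],
                   radius = as.numeric(lookup[i]),
                   area = 4 * pi * rr[i]^2 * mean(!buried))
  })
  out <- dplyr::bind_rows(rows)
  structure(out, probe = probe, n_points = n_points,
            class = c("sasa_result", class(tibble::tibble())))
}

normalize_element <- function(el) {
  paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, 2)))
}

golden_spiral <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
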