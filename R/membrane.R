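#' Phosphate reference plane of the upper leaflet
#'
#' Per-frame mean and standard deviation (population convention) of the z
#' coordinate of the selected phosphorus atoms. The pooled statistics over
#' all frame-atom observations are attached as attributes `pooled_mean`
#' and `pooled_sigma`.
#'
#' @param traj A trajectory.
#' @param selection Name of a stored atom selection, or an integer vector
#'   of atom ids.
#' @return Tibble with `frame`, `mean_z`, `sigma_z`.
#' @export
reference_plane <- function(traj, selection = "upper_leaflet_P") {
  ids <- resolve_ids(traj, selection)
  if (length(ids) == 0) stop("selection error: empty selection",
                             call. = FALSE)
  cf <- coord_frames(traj, ids)
  mean_z <- rowMeans(cf$z)
  sigma_z <- sqrt(rowMeans(cf$z^2) - mean_z^2)
  out <- tibble::tibble(frame = cf$frames, mean_z = mean_z,
                        sigma_z = sigma_z)
  attr(out, "pooled_mean") <- mean(cf$z)
  attr(out, "pooled_sigma") <- stats::sd(as.numeric(cf$z)) *
    sqrt((length(cf$z) - 1) / length(cf$z))
  out
}

resolve_ids <- function(traj, selection) {
  if (is.character(selection)) traj_select(traj, selection)
  else as.integer(selection)
}

#' Assign phosphate atoms to leaflets
#'
#' Phosphorus atoms whose time-averaged z lies above the box midplane form
#' the upper leaflet. Assignment is static per trajectory (no flip-flop at
#' these timescales). Adds `upper_leaflet_P` / `lower_leaflet_P`
#' selections.
#'
#' @param traj A trajectory.
#' @param p_ids Phosphorus atom ids (default: all atoms named `"P"`).
#' @return The trajectory with leaflet selections attached.
#' @export
assign_leaflets <- function(traj, p_ids = NULL) {
  if (is.null(p_ids)) p_ids <- atom_ids(traj, atom_name = "P")
  if (length(p_ids) == 0) stop("selection error: no P atoms", call. = FALSE)
  cf <- coord_frames(traj, p_ids)
  mid <- mean(cf$z)
  zbar <- colMeans(cf$z)
  traj <- traj_select_add(traj, "upper_leaflet_P", p_ids[zbar > mid])
  traj_select_add(traj, "lower_leaflet_P", p_ids[zbar <= mid])
}

#' Membrane penetration depth per residue
#'
#' For each residue and frame, `dz = mean_z(upper-leaflet P) - z(residue
#' cog)` with the center of geometry unweighted. Positive `dz` means the
#' residue sits below the phosphate plane (buried toward the membrane
#' interior). The profile aggregates the per-frame depths into mean,
#' minimum and maximum per residue.
#'
#' @param traj A trajectory.
#' @param residues Residue ids to profile (default: every residue in the
#'   `residue_cog`-eligible protein selection, i.e. all residues not named
#'   like lipids/water/ions).
#' @param plane_selection Selection naming the upper-leaflet P atoms.
#' @return A `depth_profile` tibble with `residue_id`, `residue_name`,
#'   `mean_dz`, `min_dz`, `max_dz`; plane statistics are attached as
#'   attributes `plane_mean`, `plane_sigma` (pooled).
#' @export
penetration_depth <- function(traj, residues = NULL,
                              plane_selection = "upper_leaflet_P") {
  plane <- reference_plane(traj, plane_selection)
  prot <- traj[!(traj$residue_name %in%
                   c("POPC", "POPS", "WAT", "HOH", "SOL", "TIP", "ION",
                     "CA2", "NA+", "CL-")), ]
  plane_ids <- resolve_ids(traj, plane_selection)
  prot <- prot[!(prot$atom_id %in% plane_ids), ]
  if (!is.null(residues)) prot <- prot[prot$residue_id %in% residues, ]
  if (nrow(prot) == 0) stop("selection error: no residue atoms",
                            call. = FALSE)
  cog <- dplyr::summarise(
    dplyr::group_by(prot, .data$frame, .data$residue_id,
                    .data$residue_name),
    cog_z = mean(.data$z), .groups = "drop")
  cog <- dplyr::left_join(cog, plane, by = "frame")
  cog$dz <- cog$mean_z - cog$cog_z
  prof <- dplyr::summarise(
    dplyr::group_by(cog, .data$residue_id, .data$residue_name),
    mean_dz = mean(.data$dz), min_dz = min(.data$dz),
    max_dz = max(.data$dz), .groups = "drop")
  prof <- dplyr::arrange(prof, .data$residue_id)
  structure(prof,
            plane_mean = attr(plane, "pooled_mean"),
            plane_sigma = attr(plane, "pooled_sigma"),
            per_frame = cog,
            class = c("depth_profile", class(tibble::tibble())))
}

#' Buried-residue hotspots
#'
#' A residue is flagged as buried when its deepest excursion passes the
#' pooled (mean - sigma) level of the phosphate plane toward the membrane
#' interior; in depth coordinates that is `max_dz > sigma_z`. Flagged
#' residues adjacent in sequence numbering merge into one hotspot.
#'
#' @param profile A `depth_profile`.
#' @param sigma Override for the plane sigma (defaults to the profile's
#'   pooled value).
#' @return Tibble with one row per hotspot: `hotspot`, `first_residue`,
#'   `last_residue`, `n_residues`, `peak_depth`.
#' @export
find_buried_hotspots <- function(profile, sigma = NULL) {
  if (is.null(sigma)) sigma <- attr(profile, "plane_sigma")
  if (is.null(sigma)) stop("profile carries no plane sigma; pass `sigma`",
                           call. = FALSE)
  flagged <- profile$residue_id[profile$max_dz > sigma]
  if (length(flagged) == 0) {
    return(tibble::tibble(hotspot = integer(0), first_residue = integer(0),
                          last_residue = integer(0), n_residues = integer(0),
                          peak_depth = numeric(0)))
  }
  flagged <- sort(flagged)
  run_id <- cumsum(c(1L, as.integer(diff(flagged) > 1)))
  purrr::map_dfr(split(flagged, run_id), function(ids) {
    tibble::tibble(first_residue = min(ids), last_residue = max(ids),
                   n_residues = length(ids),
                   peak_depth = max(profile$max_dz[profile$residue_id %in%
                                                     ids]))
  }) |>
    dplyr::mutate(hotspot = dplyr::row_number(), .before = 1)
}

#' In-plane (xy) density map
#'
#' Histograms the selected atoms over all frames on an xy grid
#' perpendicular to the membrane normal, optionally smoothing with an
#' isotropic Gaussian of width `smooth_sigma` (in A, converted to bins).
#' Smoothing pads the grid so total mass is conserved.
#'
#' @param traj A trajectory.
#' @param selection Selection name or atom ids.
#' @param bin_width Grid spacing, A.
#' @param smooth_sigma Optional Gaussian width, A.
#' @return Object of class `density_map`: list with `x`, `y` (bin
#'   centers), `counts` (matrix), `smoothed` (matrix or NULL),
#'   `bin_width`.
#' @export
density_map <- function(traj, selection, bin_width = 1,
                        smooth_sigma = NULL) {
  stopifnot(bin_width > 0)
  ids <- resolve_ids(traj, selection)
  sub <- traj[traj$atom_id %in% ids, ]
  box <- traj_box(traj)
  xr <- range(sub$x); yr <- range(sub$y)
  xe <- seq(floor(xr[1] / bin_width) * bin_width, xr[2] + bin_width,
            by = bin_width)
  ye <- seq(floor(yr[1] / bin_width) * bin_width, yr[2] + bin_width,
            by = bin_width)
  ix <- findInterval(sub$x, xe, rightmost.closed = TRUE)
  iy <- findInterval(sub$y, ye, rightmost.closed = TRUE)
  counts <- matrix(0, length(xe) - 1, length(ye) - 1)
  tab <- table(factor(ix, levels = seq_len(nrow(counts))),
               factor(iy, levels = seq_len(ncol(counts))))
  counts[] <- as.numeric(tab)
  xc <- xe[-length(xe)] + bin_width / 2
  yc <- ye[-length(ye)] + bin_width / 2
  smoothed <- NULL
  if (!is.null(smooth_sigma)) {
    sm <- blur_padded(counts, smooth_sigma / bin_width)
    smoothed <- sm$m
    xc_s <- seq(xc[1] - sm$pad * bin_width, by = bin_width,
                length.out = nrow(smoothed))
    yc_s <- seq(yc[1] - sm$pad * bin_width, by = bin_width,
                length.out = ncol(smoothed))
    attr(smoothed, "x") <- xc_s
    attr(smoothed, "y") <- yc_s
  }
  structure(list(x = xc, y = yc, counts = counts, smoothed = smoothed,
                 bin_width = bin_width, box = box),
            class = "density_map")
}

# separable zero-padded Gaussian blur; kernel renormalized so discrete
# convolution conserves mass exactly
blur_padded <- function(m, sigma_bins) {
  if (sigma_bins <= 0) return(list(m = m, pad = 0L))
  half <- max(1L, ceiling(4 * sigma_bins))
  k <- stats::dnorm(seq(-half, half), sd = sigma_bins)
  k <- k / sum(k)
  pad <- half
  big <- matrix(0, nrow(m) + 2 * pad, ncol(m) + 2 * pad)
  big[pad + seq_len(nrow(m)), pad + seq_len(ncol(m))] <- m
  big <- apply(big, 2, function(col) conv_same(col, k))
  big <- t(apply(big, 1, function(row) conv_same(row, k)))
  list(m = big, pad = pad)
}

conv_same <- function(v, k) {
  half <- (length(k) - 1L) / 2L
  full <- stats::convolve(v, rev(k), type = "open")
  full[(half + 1L):(half + length(v))]
}

#' Minimum residue-substrate distances
#'
#' For each residue and frame, the minimum over all atom pairs between the
#' residue and the target selection (minimum-image convention), averaged
#' over frames. Residues whose average minimum distance is strictly below
#' `shell_cutoff` are flagged `in_shell`.
#'
#' @param traj A trajectory.
#' @param residues Residue ids (default: all non-lipid/water residues).
#' @param target_selection Selection name or atom ids of the substrate.
#' @param shell_cutoff Shell cutoff, A (default 5).
#' @return Tibble with `residue_id`, `mean_min_distance`, `in_shell`.
#' @export
residue_min_distance <- function(traj, residues = NULL, target_selection,
                                 shell_cutoff = 5.0) {
  tgt_ids <- resolve_ids(traj, target_selection)
  if (length(tgt_ids) == 0) stop("selection error: empty target selection",
                                 call. = FALSE)
  box <- traj_box(traj)
  prot <- traj[!(traj$atom_id %in% tgt_ids), ]
  if (!is.null(residues)) prot <- prot[prot$residue_id %in% residues, ]
  frames <- sort(unique(traj$frame))
  res_ids <- sort(unique(prot$residue_id))
  acc <- matrix(0, length(res_ids), length(frames),
                dimnames = list(res_ids, NULL))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    tgt <- frame_coords(traj, f, tgt_ids)
    pf <- prot[prot$frame == f, ]
    d <- cross_min_image(cbind(pf$x, pf$y, pf$z), tgt, box)
    mins <- tapply(apply(d, 1, min), pf$residue_id, min)
    acc[names(mins), fi] <- mins
  }
  mmd <- unname(rowMeans(acc))
  tibble::tibble(
    residue_id = res_ids,
    mean_min_distance = mmd,
    in_shell = mmd < shell_cutoff
  )
}
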