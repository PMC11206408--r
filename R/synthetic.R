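#' Synthetic membrane-interface trajectory
#'
#' Generates a minimal bilayer/protein fixture with the statistical
#' structure the membrane analyses assume: upper/lower-leaflet phosphorus
#' atoms with Gaussian z-spread about `+/- plane_z`, and one
#' center-of-geometry marker atom per protein residue at
#' `z = plane_z - depth_mean + noise` (so positive depth means buried
#' below the upper phosphate plane). xy positions are uniform in the box.
#'
#' @param n_frames Number of frames.
#' @param n_lipids_per_leaflet P atoms per leaflet.
#' @param plane_z Upper-leaflet phosphate plane position, A.
#' @param plane_sigma Gaussian z-spread of P atoms, A (>= 0).
#' @param residue_depths Tibble with `residue_id`, `depth_mean`,
#'   `depth_sd` (A). Defaults to [default_residue_depths()].
#' @param box Box lengths, A.
#' @return A spec list of class `membrane_fixture_spec`.
#' @export
membrane_fixture_spec <- function(n_frames = 500, n_lipids_per_leaflet = 40,
                                  plane_z = 20, plane_sigma = 1.5,
                                  residue_depths = default_residue_depths(),
                                  box = c(93.21, 88.40, 103.30)) {
  stopifnot(n_frames >= 1, n_lipids_per_leaflet >= 1, plane_sigma >= 0,
            all(residue_depths$depth_sd >= 0))
  structure(list(n_frames = as.integer(n_frames),
                 n_lipids_per_leaflet = as.integer(n_lipids_per_leaflet),
                 plane_z = plane_z, plane_sigma = plane_sigma,
                 residue_depths = tibble::as_tibble(residue_depths),
                 box = box),
            class = "membrane_fixture_spec")
}

#' @rdname membrane_fixture_spec
#'
#' @details `default_residue_depths()` emulates a 124-residue interfacial
#' enzyme in which five contiguous runs of residues dip below the
#' phosphate plane (the shape reported for membrane-bound secreted
#' phospholipases) while the rest of the protein floats above it.
#' @export
default_residue_depths <- function() {
  depths <- tibble::tibble(residue_id = 1:124,
                           depth_mean = -2.0, depth_sd = 0.4)
  buried <- list(`1` = 1:6, `2` = 16:20, `3` = 30, `4` = 62:65,
                 `5` = 111:116)
  depth_of <- c(3.0, 2.5, 3.5, 2.8, 3.2)
  for (k in seq_along(buried)) {
    sel <- depths$residue_id %in% buried[[k]]
    depths$depth_mean[sel] <- depth_of[k]
    depths$depth_sd[sel] <- 0.5
  }
  depths
}

#' @rdname membrane_fixture_spec
#' @param spec A `membrane_fixture_spec`.
#' @param seed Integer seed; output is a pure function of (spec, seed).
#' @return `gen_membrane_trajectory`: a trajectory with selections
#'   `upper_leaflet_P`, `lower_leaflet_P`, `residue_cog`.
#' @export
gen_membrane_trajectory <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "membrane_fixture_spec"))
  withr::with_seed(seed, {
    nl <- spec$n_lipids_per_leaflet
    nf <- spec$n_frames
    nr <- nrow(spec$residue_depths)
    n_atoms <- 2L * nl + nr
    per_frame <- function(f) {
      zu <- stats::rnorm(nl, spec$plane_z, spec$plane_sigma)
      zl <- stats::rnorm(nl, -spec$plane_z, spec$plane_sigma)
      zr <- spec$plane_z - spec$residue_depths$depth_mean +
        stats::rnorm(nr, 0, spec$residue_depths$depth_sd)
      tibble::tibble(
        frame = f,
        atom_id = seq_len(n_atoms),
        atom_name = c(rep("P", 2L * nl), rep("CG", nr)),
        element = c(rep("P", 2L * nl), rep("C", nr)),
        residue_name = c(rep("POPC", 2L * nl), rep("RES", nr)),
        residue_id = c(1000L + seq_len(2L * nl),
                       spec$residue_depths$residue_id),
        x = stats::runif(n_atoms, 0, spec$box[1]),
        y = stats::runif(n_atoms, 0, spec$box[2]),
        z = c(zu, zl, zr))
    }
    tbl <- dplyr::bind_rows(lapply(seq_len(nf), per_frame))
    tbl$time <- as.numeric(tbl$frame - 1)
    as_trajectory(tbl, box = spec$box, selections = list(
      upper_leaflet_P = seq_len(nl),
      lower_leaflet_P = nl + seq_len(nl),
      residue_cog = 2L * nl + seq_len(nr)))
  })
}

#' Synthetic active-site ensemble
#'
#' Builds frames of an esterase-like active site - His N-delta, substrate
#' ester carbon and carbonyl oxygen, a Ca2+ cofactor and water molecules -
#' in which each frame is drawn from one of three conformational states
#' (single-water, assisting-water, non-productive) and the atoms are
#' placed so the drawn catalytic distances are realized to better than
#' 0.01 A. The whole site is uniformly rotated per frame and re-centered
#' in the box; bulk waters fill the box outside a 6 A exclusion zone
#' around the site.
#'
#' State-specific distance laws are truncated Gaussians; the headline
#' water-Ca2+ distance is drawn first and the nuisance distances are
#' redrawn until the triangle-inequality construction is feasible, so the
#' headline marginal stays intact.
#'
#' @param n_frames Number of frames.
#' @param state_probabilities Named or ordered probabilities for
#'   `single_water`, `assisting_water`, `nonproductive`; must sum to 1.
#' @param single_water,assisting_water,nonproductive Per-state distance
#'   laws: named lists of `c(mean, sd)` entries (A) for `d_nd_h`, `d_c_o`,
#'   `d_bridge`, `d_nd_c`, `d_ca_o_popc`, `d_ca_o_wat` (subsets override
#'   the defaults).
#' @param n_bulk_waters Bulk waters per frame.
#' @param box Box lengths, A.
#' @return A spec list of class `active_site_fixture_spec`.
#' @export
active_site_fixture_spec <- function(n_frames = 5000,
                                     state_probabilities = c(
                                       single_water = 0.75,
                                       assisting_water = 0.04,
                                       nonproductive = 0.21),
                                     single_water = list(),
                                     assisting_water = list(),
                                     nonproductive = list(),
                                     n_bulk_waters = 8,
                                     box = c(30, 30, 30)) {
  p <- as.numeric(state_probabilities)
  if (length(p) != 3 || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("state_probabilities must be 3 non-negative values summing to 1",
         call. = FALSE)
  }
  laws <- list(
    single_water = utils::modifyList(list(
      d_nd_h = c(1.9, 0.15), d_c_o = c(3.2, 0.25), d_bridge = c(0.96, 0.005),
      d_nd_c = c(4.2, 0.25), d_ca_o_popc = c(2.4, 0.25),
      d_ca_o_wat = c(3.6, 1.5)), single_water),
    assisting_water = utils::modifyList(list(
      d_nd_h = c(1.9, 0.15), d_c_o = c(3.2, 0.25), d_bridge = c(1.8, 0.15),
      d_nd_c = c(4.6, 0.25), d_ca_o_popc = c(2.4, 0.15),
      d_ca_o_wat = c(4.8, 0.2)), assisting_water),
    nonproductive = utils::modifyList(list(
      d_nd_h = c(3.4, 0.3), d_c_o = c(5.5, 0.4), d_bridge = c(0.96, 0.005),
      d_nd_c = c(5.0, 0.4), d_ca_o_popc = c(4.0, 0.8),
      d_ca_o_wat = c(NA, NA)), nonproductive)
  )
  for (st in names(laws)) {
    sds <- vapply(laws[[st]], `[`, numeric(1), 2)
    if (any(!is.na(sds) & sds < 0)) {
      stop("distance sds must be >= 0 (state ", st, ")", call. = FALSE)
    }
  }
  structure(list(n_frames = as.integer(n_frames),
                 state_probabilities = stats::setNames(
                   p, c("single_water", "assisting_water", "nonproductive")),
                 laws = laws,
                 n_bulk_waters = as.integer(n_bulk_waters),
                 box = box),
            class = "active_site_fixture_spec")
}

#' @rdname active_site_fixture_spec
#' @param spec An `active_site_fixture_spec`.
#' @param seed Integer seed.
#' @return `gen_active_site_trajectory`: a trajectory whose attribute
#'   `"truth"` holds the per-frame generating state and drawn distances.
#'   Selections: `nd_his`, `c_popc`, `o_popc`, `ca_ion`, `water_o`,
#'   `water_h`.
#' @export
gen_active_site_trajectory <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "active_site_fixture_spec"))
  withr::with_seed(seed, {
    states <- sample(names(spec$state_probabilities), spec$n_frames,
                     replace = TRUE, prob = spec$state_probabilities)
    frames <- vector("list", spec$n_frames)
    truth <- vector("list", spec$n_frames)
    for (f in seq_len(spec$n_frames)) {
      site <- build_site_frame(states[f], spec$laws[[states[f]]])
      frames[[f]] <- assemble_site_atoms(site, spec, frame = f)
      truth[[f]] <- tibble::tibble(frame = f, state = states[f],
                                   !!!site$drawn)
    }
    tbl <- dplyr::bind_rows(frames)
    tbl$time <- as.numeric(tbl$frame - 1)
    n_site <- 4L
    wat_o <- n_site + c(1L, 4L) # OW of the two tracked waters
    n_bulk <- spec$n_bulk_waters
    all_o <- c(wat_o, if (n_bulk > 0) n_site + 6L + 3L * (seq_len(n_bulk) - 1L) + 1L)
    all_h <- setdiff((n_site + 1L):(n_site + 6L + 3L * n_bulk), all_o)
    out <- as_trajectory(tbl, box = spec$box, selections = list(
      nd_his = 1L, c_popc = 2L, o_popc = 3L, ca_ion = 4L,
      water_o = all_o, water_h = all_h))
    attr(out, "truth") <- dplyr::bind_rows(truth)
    out
  })
}

draw_gauss <- function(law, lower = 0.05, upper = Inf, max_try = 400) {
  if (is.na(law[1])) return(NA_real_)
  if (law[2] == 0) return(law[1])
  for (i in seq_len(max_try)) {
    v <- stats::rnorm(1, law[1], law[2])
    if (v > lower && v < upper) return(v)
  }
  stop("construction error: distance law (", law[1], ", ", law[2],
       ") cannot produce a value in (", lower, ", ", upper, ")",
       call. = FALSE)
}

# intersection circle of two spheres; returns center, radius, orthonormal
# in-plane basis, or NULL when the spheres do not intersect
sphere_circle <- function(p1, r1, p2, r2) {
  d <- sqrt(sum((p2 - p1)^2))
  if (d < 1e-9 || d > r1 + r2 || d < abs(r1 - r2)) return(NULL)
  a <- (d^2 + r1^2 - r2^2) / (2 * d)
  rho2 <- r1^2 - a^2
  if (rho2 < 0) return(NULL)
  axis <- (p2 - p1) / d
  center <- p1 + a * axis
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * axis) * axis
  u <- u / sqrt(sum(u^2))
  v <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  list(center = center, radius = sqrt(rho2), u = u, v = v)
}

circle_point <- function(circ, angle) {
  circ$center + circ$radius * (cos(angle) * circ$u + sin(angle) * circ$v)
}

# internal O-H bond length of the rigid water model used in fixtures
OH_BOND <- 0.96
HOH_ANGLE <- 104.5 * pi / 180

# place the two hydrogens of a water given its oxygen and the direction of
# the first O-H bond; the H-O-H plane is spanned with `helper`
water_from_oh <- function(o, h1) {
  b <- (h1 - o) / sqrt(sum((h1 - o)^2))
  ref <- if (abs(b[1]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
  p <- ref - sum(ref * b) * b
  p <- p / sqrt(sum(p^2))
  h2 <- o + OH_BOND * (cos(HOH_ANGLE) * b + sin(HOH_ANGLE) * p)
  rbind(h1, h2)
}

build_site_frame <- function(state, laws, max_try = 200) {
  nd <- c(0, 0, 0)
  if (state == "single_water") {
    # headline draw first; truncated only at the hard geometric reach of
    # the construction (the carbonyl direction and H-bond bend are free)
    d_ca_o_wat <- draw_gauss(laws$d_ca_o_wat, lower = 0.1, upper = 7.6)
    for (try in seq_len(max(max_try, 1000))) {
      d_nd_h <- draw_gauss(laws$d_nd_h, lower = 0.3)
      d_c_o <- draw_gauss(laws$d_c_o, lower = 1.2)
      d_nd_c <- draw_gauss(laws$d_nd_c, lower = 1.5)
      d_ca_o_popc <- draw_gauss(laws$d_ca_o_popc, lower = 1.0)
      d_oh <- draw_gauss(laws$d_bridge, lower = 0.2)
      cpop <- c(d_nd_c, 0, 0)
      geom <- place_substrate_site(nd, cpop, d_nd_h, d_c_o, d_ca_o_popc,
                                   d_ca_o_wat)
      if (is.null(geom)) next
      w1 <- rbind(geom$ow, water_from_oh(geom$ow, geom$h1))
      return(list(
        nd = nd, cpop = cpop, opop = geom$opop, ca = geom$ca,
        w1 = w1, w2 = NULL,
        drawn = list(d_nd_h = d_nd_h, d_c_o = d_c_o, d_o_h = d_oh,
                     d_nd_c = d_nd_c, d_ca_o_popc = d_ca_o_popc,
                     d_ca_o_wat = d_ca_o_wat)))
    }
    stop("construction error: single-water frame infeasible for the ",
         "(d_nd_h, d_c_o, d_ca_o_popc, d_ca_o_wat) triple (",
         signif(d_ca_o_wat, 3), " A water-Ca)", call. = FALSE)
  }
  if (state == "assisting_water") {
    d_ca_o_wat <- draw_gauss(laws$d_ca_o_wat, lower = 0.1)
    for (try in seq_len(max_try)) {
      d_nd_h <- draw_gauss(laws$d_nd_h, lower = 0.3)
      d_c_o <- draw_gauss(laws$d_c_o, lower = 1.2)
      d_bridge <- draw_gauss(laws$d_bridge, lower = 0.5)
      d_nd_c <- draw_gauss(laws$d_nd_c, lower = 1.5)
      d_ca_o_popc <- draw_gauss(laws$d_ca_o_popc, lower = 1.0)
      if (d_nd_h + d_bridge < 3.15) next # W1 must stay out of His reach
      cpop <- c(d_nd_c, 0, 0)
      # W1 oxygen: attack distance to C, and an Nd distance inside the
      # proton-relay window [3.1, d_nd_h + d_bridge)
      t_no <- min(3.3, d_nd_h + d_bridge - 0.08)
      w1_circ <- sphere_circle(nd, t_no, cpop, d_c_o)
      if (is.null(w1_circ)) next
      ow1 <- circle_point(w1_circ, pi / 2)
      geom <- place_carbonyl_and_ca(cpop, ow1, d_c_o, d_ca_o_popc,
                                    d_ca_o_wat)
      if (is.null(geom)) next
      # bridging hydrogen of W2: d(Nd,H) = d_nd_h and d(O_W1,H) = d_bridge
      hb_circ <- sphere_circle(nd, d_nd_h, ow1, d_bridge)
      if (is.null(hb_circ)) next
      ang <- seq(0, 2 * pi, length.out = 121)[-121]
      hpts <- sapply(ang, function(a) circle_point(hb_circ, a))
      d_ch <- sqrt(colSums((hpts - cpop)^2))
      if (max(d_ch) < 3.3) next # W2 oxygen must stay > 4 A from C
      hb <- hpts[, which.max(d_ch)]
      ow2 <- hb + OH_BOND * (hb - cpop) / sqrt(sum((hb - cpop)^2))
      w2 <- rbind(ow2, water_from_oh(ow2, hb))
      # W1 hydrogens point away from His
      a1 <- (ow1 - nd) / sqrt(sum((ow1 - nd)^2))
      h1w1 <- ow1 + OH_BOND * a1
      w1 <- rbind(ow1, water_from_oh(ow1, h1w1))
      return(list(
        nd = nd, cpop = cpop, opop = geom$opop, ca = geom$ca,
        w1 = w1, w2 = w2,
        drawn = list(d_nd_h = d_nd_h, d_c_o = d_c_o, d_o_h = d_bridge,
                     d_nd_c = d_nd_c, d_ca_o_popc = d_ca_o_popc,
                     d_ca_o_wat = d_ca_o_wat)))
    }
    stop("construction error: assisting-water frame infeasible for ",
         "(d_nd_h, d_bridge, d_ca_o_wat) draw", call. = FALSE)
  }
  # nonproductive: one distant water, Ca loosely attached
  for (try in seq_len(max_try)) {
    d_nd_h <- draw_gauss(laws$d_nd_h, lower = 2.8)
    d_c_o <- draw_gauss(laws$d_c_o, lower = 4.3)
    d_nd_c <- draw_gauss(laws$d_nd_c, lower = 1.5)
    d_ca_o_popc <- draw_gauss(laws$d_ca_o_popc, lower = 1.5)
    cpop <- c(d_nd_c, 0, 0)
    opop <- cpop + c(0, 1.23, 0)
    ca <- opop + d_ca_o_popc * c(0, 1, 0)
    circ <- sphere_circle(nd, d_nd_h + 0.93, cpop, d_c_o)
    if (is.null(circ)) next
    ow <- circle_point(circ, pi / 2)
    h_circ <- sphere_circle(nd, d_nd_h, ow, OH_BOND)
    if (is.null(h_circ)) next
    h1 <- circle_point(h_circ, 0)
    w1 <- rbind(ow, water_from_oh(ow, h1))
    return(list(
      nd = nd, cpop = cpop, opop = opop, ca = ca, w1 = w1, w2 = NULL,
      drawn = list(d_nd_h = d_nd_h, d_c_o = d_c_o, d_o_h = OH_BOND,
                   d_nd_c = d_nd_c, d_ca_o_popc = d_ca_o_popc,
                   d_ca_o_wat = sqrt(sum((ca - ow)^2)))))
  }
  stop("construction error: nonproductive frame infeasible", call. = FALSE)
}

# single-water active-site core: water oxygen on the (His, C) circle with
# a near-linear N...H-O bond bent only when the reach requires it, then
# the carbonyl direction and Ca position solved from the remaining
# distance constraints
place_substrate_site <- function(nd, cpop, d_nd_h, d_c_o, d_ca_o_popc,
                                 d_ca_o_wat) {
  r_no_cands <- unique(pmax(pmin(
    d_nd_h + c(0.93, 0.955, 0.85, 0.7, 0.5, 0.3, 0.1, -0.1, -0.3, -0.5),
    d_nd_h + OH_BOND - 0.005), abs(d_nd_h - OH_BOND) + 0.005))
  for (r_no in r_no_cands) {
    circ <- sphere_circle(nd, r_no, cpop, d_c_o)
    if (is.null(circ)) next
    ow <- circle_point(circ, pi / 2)
    geom <- place_carbonyl_and_ca(cpop, ow, d_c_o, d_ca_o_popc,
                                  d_ca_o_wat)
    if (is.null(geom)) next
    h_circ <- sphere_circle(nd, d_nd_h, ow, OH_BOND)
    if (is.null(h_circ)) next
    return(list(ow = ow, h1 = circle_point(h_circ, 0),
                opop = geom$opop, ca = geom$ca))
  }
  NULL
}

# the carbonyl oxygen sits 1.23 A from the ester carbon in a free
# direction; choose it so the Ca trilateration (carbonyl sphere + water
# sphere) is feasible, aiming at the middle of the feasible band
place_carbonyl_and_ca <- function(cpop, ow, d_c_o, d_ca_o_popc,
                                  d_ca_o_wat) {
  lo <- max(abs(d_ca_o_wat - d_ca_o_popc) + 0.005, d_c_o - 1.23 + 0.005)
  hi <- min(d_ca_o_wat + d_ca_o_popc - 0.005, d_c_o + 1.23 - 0.005)
  if (lo >= hi) return(NULL)
  d_op <- (lo + hi) / 2
  op_circ <- sphere_circle(cpop, 1.23, ow, d_op)
  if (is.null(op_circ)) return(NULL)
  opop <- circle_point(op_circ, 0)
  ca_circ <- sphere_circle(opop, d_ca_o_popc, ow, d_ca_o_wat)
  if (is.null(ca_circ)) return(NULL)
  list(opop = opop, ca = circle_point(ca_circ, 0))
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

assemble_site_atoms <- function(site, spec, frame) {
  box <- spec$box
  center <- box / 2
  rot <- random_rotation()
  place <- function(p) as.numeric(rot %*% p + center)
  # parked position for the second tracked water when the state has none:
  # a bulk-like slot far from the site
  parked <- function() {
    repeat {
      p <- stats::runif(3, 0, 1) * box
      if (min(sqrt(sum((p - center)^2))) > 9) return(p)
    }
  }
  if (is.null(site$w2)) {
    o2 <- parked()
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    w2 <- rbind(o2, water_from_oh(o2, o2 + OH_BOND * dir))
  } else {
    w2 <- t(apply(site$w2, 1, place))
  }
  core <- rbind(place(site$nd), place(site$cpop), place(site$opop),
                place(site$ca))
  w1 <- t(apply(site$w1, 1, place))
  bulk <- matrix(0, 0, 3)
  if (spec$n_bulk_waters > 0) {
    guard <- rbind(core, w1[1, , drop = FALSE], w2[1, , drop = FALSE])
    bulk_o <- matrix(0, spec$n_bulk_waters, 3)
    k <- 0L
    while (k < spec$n_bulk_waters) {
      p <- stats::runif(3, 0, 1) * box
      if (min(sqrt(rowSums(sweep(guard, 2, p)^2))) > 6) {
        k <- k + 1L
        bulk_o[k, ] <- p
        guard <- rbind(guard, p)
      }
    }
    bulk <- do.call(rbind, lapply(seq_len(spec$n_bulk_waters), function(i) {
      dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
      rbind(bulk_o[i, ], water_from_oh(bulk_o[i, ],
                                       bulk_o[i, ] + OH_BOND * dir))
    }))
  }
  coords <- rbind(core, w1, w2, bulk)
  n_bulk <- spec$n_bulk_waters
  wat_names <- rep(c("OW", "HW1", "HW2"), times = 2 + n_bulk)
  wat_elems <- rep(c("O", "H", "H"), times = 2 + n_bulk)
  wat_res <- rep(400L + seq_len(2 + n_bulk), each = 3)
  tibble::tibble(
    frame = frame,
    atom_id = seq_len(nrow(coords)),
    atom_name = c("ND1", "C21", "O22", "CA", wat_names),
    element = c("N", "C", "O", "Ca", wat_elems),
    residue_name = c("HIS", "POPC", "POPC", "ION",
                     rep("WAT", length(wat_res))),
    residue_id = c(47L, 201L, 201L, 301L, wat_res),
    x = coords[, 1], y = coords[, 2], z = coords[, 3])
}

#' Synthetic charge fixture for residue-deletion analysis
#'
#' Reproducible reactant/transition-state QM point-charge sets plus MM
#' residue charge groups, for exercising the per-residue barrier
#' decomposition on layouts whose Coulomb sums are computable in closed
#' form.
#'
#' @param n_qm QM charges per state.
#' @param n_residues MM residue groups.
#' @param charges_per_residue Point charges per MM group.
#' @param seed Integer seed.
#' @return A [state_charge_system()] whose TS charges are identical to R
#'   but whose TS geometry is shifted 0.5 A toward the MM region's first
#'   group (so contributions are nonzero and sign-interpretable).
#' @export
gen_charge_states <- function(n_qm = 4, n_residues = 6,
                              charges_per_residue = 3, seed = 1) {
  withr::with_seed(seed, {
    qm_pos <- matrix(stats::rnorm(n_qm * 3, sd = 1.0), ncol = 3)
    qm_q <- stats::runif(n_qm, -0.8, 0.8)
    qm_q <- qm_q - mean(qm_q) - 1 / n_qm # net charge -1 (oxyanion-like)
    res_names <- rep(c("ASP", "LYS", "SER", "ALA"),
                     length.out = n_residues)
    mm <- purrr::map_dfr(seq_len(n_residues), function(i) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      base <- u * stats::runif(1, 6, 12)
      pos <- sweep(matrix(stats::rnorm(charges_per_residue * 3, sd = 0.5),
                          ncol = 3), 2, base, "+")
      q <- stats::runif(charges_per_residue, -0.5, 0.5)
      tibble::tibble(label = sprintf("%s%d", res_names[i], i),
                     residue_name = res_names[i],
                     q = q, x = pos[, 1], y = pos[, 2], z = pos[, 3])
    })
    shift <- mm[mm$label == mm$label[1], c("x", "y", "z")]
    dir <- colMeans(as.matrix(shift))
    dir <- dir / sqrt(sum(dir^2))
    qm_r <- tibble::tibble(q = qm_q, x = qm_pos[, 1], y = qm_pos[, 2],
                           z = qm_pos[, 3])
    qm_ts <- qm_r
    qm_ts[, c("x", "y", "z")] <- qm_ts[, c("x", "y", "z")] +
      matrix(0.5 * dir, n_qm, 3, byrow = TRUE)
    state_charge_system(qm_r, qm_ts, mm)
  })
}
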