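#' Geometric criteria for catalytic-water classification
#'
#' Thresholds (strict `<`) for the three defining distances: the
#' His-to-water hydrogen bond d(Nd-H), the nucleophilic attack distance
#' d(C-O) and the water-water proton-relay bridge d(O-H).
#'
#' @param d_his_h_max His Nd to water H threshold, A.
#' @param d_c_o_max Ester C to water O threshold, A.
#' @param d_bridge_max Water O to relay-water H threshold, A.
#' @return List of class `classification_criteria`.
#' @export
classification_criteria <- function(d_his_h_max = 2.5, d_c_o_max = 4.0,
                                    d_bridge_max = 2.5) {
  stopifnot(d_his_h_max > 0, d_c_o_max > 0, d_bridge_max > 0)
  structure(list(d_his_h_max = d_his_h_max, d_c_o_max = d_c_o_max,
                 d_bridge_max = d_bridge_max),
            class = "classification_criteria")
}

#' Default active-site atom map
#'
#' Resolves the atoms the catalytic-distance calculation needs from a
#' trajectory's selections (as produced by
#' [gen_active_site_trajectory()]), or from explicit atom ids.
#'
#' @param traj A trajectory.
#' @param nd_his,c_popc,o_popc,ca_ion Single atom ids (defaults: the
#'   selections of the same name).
#' @param water_o,water_h Water oxygen / hydrogen atom ids.
#' @return List of class `active_site_map`; water hydrogens are paired
#'   with their oxygen by residue.
#' @export
active_site_map <- function(traj, nd_his = NULL, c_popc = NULL,
                            o_popc = NULL, ca_ion = NULL, water_o = NULL,
                            water_h = NULL) {
  pick <- function(given, name) {
    if (!is.null(given)) return(as.integer(given))
    sel <- traj_selections(traj)[[name]]
    if (is.null(sel)) stop("selection error: cannot resolve '", name, "'",
                           call. = FALSE)
    as.integer(sel)
  }
  nd <- pick(nd_his, "nd_his"); cc <- pick(c_popc, "c_popc")
  op <- pick(o_popc, "o_popc"); ca <- pick(ca_ion, "ca_ion")
  wo <- pick(water_o, "water_o"); wh <- pick(water_h, "water_h")
  stopifnot(length(nd) == 1, length(cc) == 1, length(op) == 1,
            length(ca) == 1)
  one <- traj[traj$frame == traj$frame[1], ]
  res_of <- stats::setNames(one$residue_id, one$atom_id)
  waters <- purrr::map_dfr(wo, function(o) {
    hs <- wh[res_of[as.character(wh)] == res_of[as.character(o)]]
    if (length(hs) != 2) {
      stop("selection error: water oxygen ", o, " has ", length(hs),
           " hydrogens in its residue", call. = FALSE)
    }
    tibble::tibble(o = o, h1 = hs[1], h2 = hs[2])
  })
  structure(list(nd_his = nd, c_popc = cc, o_popc = op, ca_ion = ca,
                 waters = waters),
            class = "active_site_map")
}

#' Per-frame catalytic distances
#'
#' Computes, for every frame, the minimum-image distances defining the
#' catalytic geometry. Candidate waters are those with oxygen within
#' `candidate_cutoff` of the substrate carbon (a performance guard). The
#' per-frame record reports d(Nd-H) minimized over all candidate waters
#' and hydrogens (`d_nd_h_min`), the nucleophile assignment (water with
#' the smallest d(C-O)), and the always-defined d(Nd-C) and d(Ca-O_POPC);
#' the full per-water candidate table used by [classify_conformations()]
#' rides along in attribute `"candidates"`.
#'
#' @param traj A trajectory.
#' @param map An [active_site_map()] (default: resolved from `traj`).
#' @param candidate_cutoff Water-oxygen to substrate-carbon cutoff, A.
#' @return Tibble of `conformation_records` with one row per frame:
#'   `frame`, `d_nd_h_min`, `d_nd_h`, `d_c_o`, `d_o_h`, `d_nd_c`,
#'   `d_ca_o_popc`, `d_ca_o_wat` (assignment columns refer to the
#'   nucleophile water until labels are attached).
#' @export
catalytic_distances <- function(traj, map = NULL, candidate_cutoff = 8) {
  if (is.null(map)) map <- active_site_map(traj)
  box <- traj_box(traj)
  frames <- sort(unique(traj$frame))
  n_wat <- nrow(map$waters)
  cand_list <- vector("list", length(frames))
  rec_list <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    core <- frame_coords(traj, f,
                         c(map$nd_his, map$c_popc, map$o_popc, map$ca_ion))
    nd <- core[1, ]; cc <- core[2, ]; op <- core[3, ]; ca <- core[4, ]
    ow <- frame_coords(traj, f, map$waters$o)
    h1 <- frame_coords(traj, f, map$waters$h1)
    h2 <- frame_coords(traj, f, map$waters$h2)
    d_c_ow <- min_image_distance(ow, matrix(cc, n_wat, 3, byrow = TRUE), box)
    keep <- which(d_c_ow < candidate_cutoff)
    if (length(keep) == 0) keep <- which.min(d_c_ow)
    d_nd_h <- pmin(
      min_image_distance(h1[keep, , drop = FALSE],
                         matrix(nd, length(keep), 3, byrow = TRUE), box),
      min_image_distance(h2[keep, , drop = FALSE],
                         matrix(nd, length(keep), 3, byrow = TRUE), box))
    d_ca_ow <- min_image_distance(ow[keep, , drop = FALSE],
                                  matrix(ca, length(keep), 3, byrow = TRUE),
                                  box)
    cand_list[[fi]] <- tibble::tibble(
      frame = f, water = map$waters$o[keep],
      d_c_o = d_c_ow[keep], d_nd_h = d_nd_h, d_ca_o_wat = d_ca_ow)
    # bridge distances between candidate pairs (donor hydrogens vs oxygens)
    nk <- length(keep)
    if (nk > 1) {
      hk1 <- h1[keep, , drop = FALSE]; hk2 <- h2[keep, , drop = FALSE]
      owk <- ow[keep, , drop = FALSE]
      bridge <- pmin(cross_min_image(owk, hk1, box),
                     cross_min_image(owk, hk2, box))
      diag(bridge) <- Inf # a water cannot bridge to itself
      attr(cand_list[[fi]], "bridge") <- bridge
    }
    nuc <- which.min(d_c_ow[keep])
    rec_list[[fi]] <- tibble::tibble(
      frame = f,
      d_nd_h_min = min(d_nd_h),
      d_nd_h = d_nd_h[nuc],
      d_c_o = d_c_ow[keep][nuc],
      d_o_h = NA_real_,
      d_nd_c = min_image_distance(nd, cc, box),
      d_ca_o_popc = min_image_distance(ca, op, box),
      d_ca_o_wat = d_ca_ow[nuc])
  }
  out <- dplyr::bind_rows(rec_list)
  structure(out, candidates = cand_list,
            class = c("conformation_records", class(tibble::tibble())))
}

#' Classify catalytic microstates
#'
#' A frame is `single_water` when one water alone satisfies
#' `d(Nd-H) < d_his_h_max` and `d(C-O) < d_c_o_max`; otherwise it is
#' `assisting_water` when a nucleophile/donor pair (W1, W2) exists with
#' `d(C-O_W1) < d_c_o_max`, `d(Nd-H_W2) < d_his_h_max` and
#' `d(O_W1-H_W2) < d_bridge_max`; otherwise `nonproductive`. All
#' inequalities are strict, so boundary geometries fall into
#' `nonproductive`. After labelling, the record's assignment distances are
#' those of the defining water(s).
#'
#' @param records Output of [catalytic_distances()].
#' @param criteria A [classification_criteria()].
#' @return The records with a `label` column; the label fractions are in
#'   attribute `"populations"`.
#' @export
classify_conformations <- function(records,
                                   criteria = classification_criteria()) {
  cands <- attr(records, "candidates")
  labels <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    cand <- cands[[i]]
    single <- cand$d_nd_h < criteria$d_his_h_max &
      cand$d_c_o < criteria$d_c_o_max
    if (any(single)) {
      labels[i] <- "single_water"
      w <- which(single)[which.min(cand$d_c_o[single])]
      records$d_nd_h[i] <- cand$d_nd_h[w]
      records$d_c_o[i] <- cand$d_c_o[w]
      records$d_ca_o_wat[i] <- cand$d_ca_o_wat[w]
      next
    }
    bridge <- attr(cand, "bridge")
    found <- FALSE
    if (!is.null(bridge)) {
      nucs <- which(cand$d_c_o < criteria$d_c_o_max)
      donors <- which(cand$d_nd_h < criteria$d_his_h_max)
      for (w1 in nucs) {
        for (w2 in setdiff(donors, w1)) {
          if (bridge[w1, w2] < criteria$d_bridge_max) {
            labels[i] <- "assisting_water"
            records$d_c_o[i] <- cand$d_c_o[w1]
            records$d_nd_h[i] <- cand$d_nd_h[w2]
            records$d_o_h[i] <- bridge[w1, w2]
            records$d_ca_o_wat[i] <- cand$d_ca_o_wat[w1]
            found <- TRUE
            break
          }
        }
        if (found) break
      }
    }
    if (!found) labels[i] <- "nonproductive"
  }
  records$label <- factor(labels, levels = c("single_water",
                                             "assisting_water",
                                             "nonproductive"))
  pops <- table(records$label) / nrow(records)
  attr(records, "populations") <- tibble::tibble(
    label = names(pops), fraction = as.numeric(pops))
  records
}

#' His-water hydrogen-bond occupancy
#'
#' Fraction of frames in which any water hydrogen sits within `cutoff` of
#' the His N-delta.
#'
#' @param records Output of [catalytic_distances()].
#' @param cutoff Distance cutoff, A.
#' @return Occupancy fraction in `[0, 1]`.
#' @export
hbond_occupancy <- function(records, cutoff = 2.5) {
  mean(records$d_nd_h_min < cutoff)
}

#' Density-based clustering in the catalytic-distance plane
#'
#' Kernel-density estimate (isotropic Gaussian, width `kde_sigma`) on two
#' chosen distance columns; grid cells with density at or above the
#' `density_quantile` level of the positive grid densities form
#' 8-connected components, and each record is assigned to the component
#' holding its cell (records in cells below the level are noise).
#'
#' @param records A records tibble.
#' @param fields Two column names spanning the plane.
#' @param kde_sigma Gaussian kernel width, A.
#' @param density_quantile Density threshold quantile in `(0, 1)`.
#' @return List of class `cluster_result`: `assignments` (integer per
#'   record, `NA` = noise), `clusters` (tibble with `cluster`, `n`,
#'   `fraction`, centroid columns), and the grid (`x`, `y`, `density`).
#' @export
cluster_microstates <- function(records,
                                fields = c("d_nd_c", "d_ca_o_popc"),
                                kde_sigma = 1.0, density_quantile = 0.5) {
  stopifnot(length(fields) == 2)
  if (nrow(records) < 50) {
    stop("clustering error: need >= 50 records", call. = FALSE)
  }
  px <- records[[fields[1]]]
  py <- records[[fields[2]]]
  if (stats::var(px) < 1e-12 && stats::var(py) < 1e-12) {
    stop("clustering error: zero variance in both fields", call. = FALSE)
  }
  bw <- kde_sigma / 3
  xe <- seq(min(px) - bw, max(px) + bw, by = bw)
  ye <- seq(min(py) - bw, max(py) + bw, by = bw)
  ix <- findInterval(px, xe, rightmost.closed = TRUE)
  iy <- findInterval(py, ye, rightmost.closed = TRUE)
  counts <- matrix(0, length(xe) - 1, length(ye) - 1)
  tab <- table(factor(ix, levels = seq_len(nrow(counts))),
               factor(iy, levels = seq_len(ncol(counts))))
  counts[] <- as.numeric(tab)
  sm <- blur_padded(counts, kde_sigma / bw)
  dens <- sm$m
  ix_p <- ix + sm$pad
  iy_p <- iy + sm$pad
  # level-set threshold over the cells the kernel actually reaches: the
  # quantile runs over strictly positive grid densities, so raising
  # density_quantile peels fringe cells (and their records) off as noise
  thr <- stats::quantile(dens[dens > 0], density_quantile)
  above <- dens >= thr & dens > 0
  comp <- label_components_8(above)
  assignments <- comp[cbind(ix_p, iy_p)]
  assignments[assignments == 0] <- NA_integer_
  keep <- sort(unique(stats::na.omit(assignments)))
  remap <- stats::setNames(seq_along(keep), keep)
  assignments <- as.integer(remap[as.character(assignments)])
  clusters <- purrr::map_dfr(seq_along(keep), function(k) {
    sel <- which(assignments == k)
    tibble::tibble(cluster = k, n = length(sel),
                   fraction = length(sel) / nrow(records),
                   centroid_x = mean(px[sel]), centroid_y = mean(py[sel]))
  })
  clusters <- dplyr::arrange(clusters, dplyr::desc(.data$n))
  remap2 <- stats::setNames(seq_len(nrow(clusters)), clusters$cluster)
  assignments <- as.integer(remap2[as.character(assignments)])
  clusters$cluster <- seq_len(nrow(clusters))
  structure(list(assignments = assignments, clusters = clusters,
                 fields = fields,
                 grid = list(x = xe, y = ye, density = dens,
                             threshold = thr)),
            class = "cluster_result")
}

# 8-connected component labelling of a logical matrix via igraph
label_components_8 <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (nrow(idx) == 0) return(lab)
  cell_id <- stats::setNames(seq_len(nrow(idx)),
                             paste(idx[, 1], idx[, 2]))
  edges <- integer(0)
  shifts <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  for (s in seq_len(nrow(shifts))) {
    nb <- cbind(idx[, 1] + shifts[s, 1], idx[, 2] + shifts[s, 2])
    key <- paste(nb[, 1], nb[, 2])
    hit <- !is.na(cell_id[key])
    if (any(hit)) {
      edges <- c(edges, rbind(seq_len(nrow(idx))[hit],
                              unname(cell_id[key[hit]])))
    }
  }
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[idx] <- comp
  lab
}

#' Per-state distance summaries
#'
#' Mean and standard deviation (population convention, so a single record
#' gives sd 0) of each distance column, per classification label.
#'
#' @param records Labelled records from [classify_conformations()].
#' @return Tibble with `label`, `distance`, `mean`, `sd`, `n`.
#' @export
state_distance_summary <- function(records) {
  stopifnot("label" %in% names(records))
  cols <- intersect(c("d_nd_h", "d_c_o", "d_o_h", "d_nd_c", "d_ca_o_popc",
                      "d_ca_o_wat"), names(records))
  long <- tidyr::pivot_longer(
    records[, c("label", cols)], dplyr::all_of(cols),
    names_to = "distance", values_to = "value")
  dplyr::summarise(
    dplyr::group_by(long, .data$label, .data$distance),
    mean = mean(.data$value, na.rm = TRUE),
    sd = pop_sd(.data$value),
    n = sum(!is.na(.data$value)),
    .groups = "drop")
}

pop_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}
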