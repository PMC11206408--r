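#' Tidy trajectory tables
#'
#' A trajectory is a tibble with one row per (frame, atom) observation and
#' columns `frame`, `time`, `atom_id`, `atom_name`, `element`,
#' `residue_name`, `residue_id`, `chain`, `x`, `y`, `z`. Two attributes ride
#' along: `box`, the orthorhombic box lengths (A), and `selections`, a named
#' list of atom-id vectors (e.g. `"upper_leaflet_P"`). Atom order and
#' identity are identical across frames.
#'
#' @param tbl A data frame with the columns above (`time`, `element`,
#'   `chain` may be omitted and are filled with defaults).
#' @param box Numeric length-3 box vector in A, all components > 0.
#' @param selections Named list of integer atom-id vectors.
#' @return A `spla2_trajectory` tibble.
#' @examples
#' tr <- as_trajectory(
#'   tibble::tibble(frame = 1, atom_id = 1:2, atom_name = c("OW", "P"),
#'                  residue_name = c("WAT", "POPC"), residue_id = c(1L, 2L),
#'                  x = c(0, 3), y = 0, z = 0),
#'   box = c(30, 30, 30))
#' n_frames(tr)
#' @export
as_trajectory <- function(tbl, box, selections = list()) {
  tbl <- tibble::as_tibble(tbl)
  required <- c("frame", "atom_id", "atom_name", "residue_name",
                "residue_id", "x", "y", "z")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    stop("trajectory table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"time" %in% names(tbl)) tbl$time <- as.numeric(tbl$frame)
  if (!"element" %in% names(tbl)) tbl$element <- guess_element(tbl$atom_name)
  if (!"chain" %in% names(tbl)) tbl$chain <- "A"
  if (!is.numeric(box) || length(box) != 3 || any(!is.finite(box)) ||
      any(box <= 0)) {
    stop("`box` must be a finite positive length-3 vector (A)", call. = FALSE)
  }
  if (any(!is.finite(tbl$x)) || any(!is.finite(tbl$y)) ||
      any(!is.finite(tbl$z))) {
    stop("non-finite coordinates in trajectory", call. = FALSE)
  }
  if (any(tbl$residue_id < 1)) {
    stop("residue_id must be >= 1", call. = FALSE)
  }
  tbl <- dplyr::arrange(tbl, .data$frame, .data$atom_id)
  ids_by_frame <- split(tbl$atom_id, tbl$frame)
  ref <- ids_by_frame[[1]]
  same <- vapply(ids_by_frame, function(v) identical(v, ref), logical(1))
  if (!all(same)) {
    stop("atom set differs across frames (structure error)", call. = FALSE)
  }
  bad_sel <- names(selections)[!vapply(selections, function(s)
    all(s %in% ref), logical(1))]
  if (length(bad_sel) > 0) {
    stop("selection(s) reference unknown atom ids: ",
         paste(bad_sel, collapse = ", "), call. = FALSE)
  }
  tbl <- dplyr::select(tbl, "frame", "time", "atom_id", "atom_name",
                       "element", "residue_name", "residue_id", "chain",
                       "x", "y", "z")
  structure(tbl, box = as.numeric(box), selections = selections,
            class = c("spla2_trajectory", class(tibble::tibble())))
}

#' @rdname as_trajectory
#' @param traj A trajectory.
#' @export
traj_box <- function(traj) attr(traj, "box")

#' @rdname as_trajectory
#' @export
traj_selections <- function(traj) attr(traj, "selections")

#' @rdname as_trajectory
#' @export
n_frames <- function(traj) length(unique(traj$frame))

#' Look up or store a named atom selection
#'
#' @param traj A trajectory.
#' @param name Selection name.
#' @param ids Integer atom ids (for `traj_select_add`).
#' @return `traj_select`: integer atom ids. `traj_select_add`: the modified
#'   trajectory.
#' @export
traj_select <- function(traj, name) {
  sel <- traj_selections(traj)
  if (is.null(sel[[name]])) {
    stop("selection not found: ", name, call. = FALSE)
  }
  sel[[name]]
}

#' @rdname traj_select
#' @export
traj_select_add <- function(traj, name, ids) {
  sel <- traj_selections(traj)
  sel[[name]] <- as.integer(ids)
  attr(traj, "selections") <- sel
  traj
}

#' Resolve atoms by residue/atom identity
#'
#' @param traj A trajectory.
#' @param atom_name,residue_id,residue_name,chain Optional filters.
#' @return Integer atom ids (unique atoms, not per-frame rows).
#' @examples
#' # atoms named ND1 in residue 47 resolve the His47 N-delta
#' @export
atom_ids <- function(traj, atom_name = NULL, residue_id = NULL,
                     residue_name = NULL, chain = NULL) {
  one <- traj[traj$frame == traj$frame[1], ]
  keep <- rep(TRUE, nrow(one))
  if (!is.null(atom_name)) keep <- keep & one$atom_name %in% atom_name
  if (!is.null(residue_id)) keep <- keep & one$residue_id %in% residue_id
  if (!is.null(residue_name)) keep <- keep & one$residue_name %in% residue_name
  if (!is.null(chain)) keep <- keep & one$chain %in% chain
  one$atom_id[keep]
}

# coordinates of a set of atoms as an (n_frames x n_atoms) matrix per axis
coord_frames <- function(traj, ids) {
  sub <- traj[traj$atom_id %in% ids, ]
  sub <- dplyr::arrange(sub, .data$frame, .data$atom_id)
  nf <- length(unique(sub$frame))
  na <- length(ids)
  list(
    x = matrix(sub$x, nrow = nf, ncol = na, byrow = TRUE),
    y = matrix(sub$y, nrow = nf, ncol = na, byrow = TRUE),
    z = matrix(sub$z, nrow = nf, ncol = na, byrow = TRUE),
    frames = sort(unique(sub$frame))
  )
}

# one frame's coordinates for given atom ids, as an n x 3 matrix in id order
frame_coords <- function(traj, frame, ids) {
  sub <- traj[traj$frame == frame & traj$atom_id %in% ids, ]
  sub <- sub[match(ids, sub$atom_id), ]
  cbind(sub$x, sub$y, sub$z)
}

#' Minimum-image distance under an orthorhombic box
#'
#' @param a,b Coordinate matrices (n x 3) or length-3 vectors.
#' @param box Length-3 box vector in A.
#' @return Numeric distances.
#' @examples
#' min_image_distance(c(1, 0, 0), c(92, 0, 0), box = c(93.21, 88.4, 103.3))
#' @export
min_image_distance <- function(a, b, box) {
  a <- rbind_coords(a)
  b <- rbind_coords(b)
  d <- a - b
  for (k in 1:3) {
    d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  }
  sqrt(rowSums(d * d))
}

rbind_coords <- function(m) {
  if (is.null(dim(m))) matrix(m, ncol = 3) else as.matrix(m)
}

# all minimum-image pairwise distances between rows of a (n x 3) and b (m x 3)
cross_min_image <- function(a, b, box) {
  n <- nrow(a); m <- nrow(b)
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  dz <- outer(a[, 3], b[, 3], "-")
  dx <- dx - box[1] * round(dx / box[1])
  dy <- dy - box[2] * round(dy / box[2])
  dz <- dz - box[3] * round(dz / box[3])
  sqrt(dx * dx + dy * dy + dz * dz)
}

guess_element <- function(atom_name) {
  nm <- toupper(trimws(atom_name))
  two <- substr(nm, 1, 2)
  el <- ifelse(two %in% c("CL", "BR", "NA", "MG", "ZN"),
               two, substr(gsub("^[0-9]+", "", nm), 1, 1))
  # calcium ions are conventionally named CA with a non-protein residue;
  # protein CA (alpha carbon) cannot be told apart by name alone, so only
  # map two-letter symbols we are sure about
  el <- gsub("^(.)(.)$", "\\1\\L\\2", el, perl = TRUE)
  el
}
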