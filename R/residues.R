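#' Point-charge Coulomb interaction energy
#'
#' Vacuum electrostatic interaction between two charge sets,
#' `E = 332.0637 sum_ij q_i q_j / r_ij` (kcal mol^-1 with charges in e and
#' distances in A), no cutoff.
#'
#' @param group Tibble with columns `q`, `x`, `y`, `z` (the MM charge
#'   group).
#' @param qm_charges Tibble with the same columns (the QM region).
#' @return Interaction energy, kcal mol^-1 (0 if either set is empty).
#' @examples
#' a <- tibble::tibble(q = 1, x = 0, y = 0, z = 0)
#' b <- tibble::tibble(q = -1, x = 3.320637, y = 0, z = 0)
#' coulomb_interaction(a, b)   # -100
#' @export
coulomb_interaction <- function(group, qm_charges) {
  if (nrow(group) == 0 || nrow(qm_charges) == 0) return(0)
  a <- as.matrix(group[, c("x", "y", "z")])
  b <- as.matrix(qm_charges[, c("x", "y", "z")])
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  dz <- outer(a[, 3], b[, 3], "-")
  r <- sqrt(dx^2 + dy^2 + dz^2)
  if (any(r < 0.1)) {
    idx <- which(r < 0.1, arr.ind = TRUE)[1, ]
    stop("singularity error: charges ", idx[1], " (group) and ", idx[2],
         " (QM) are ", signif(r[idx[1], idx[2]], 3), " A apart",
         call. = FALSE)
  }
  spla2_constants$coulomb_kcal * sum(outer(group$q, qm_charges$q) / r)
}

#' Two-state charge system for residue-deletion analysis
#'
#' Holds the QM-region point charges of the reactant (R) and transition
#' state (TS) plus the MM residue charge groups of each state. Group labels
#' must match across states; positions may differ.
#'
#' @param qm_r,qm_ts QM charges per state: tibbles with `q`, `x`, `y`, `z`.
#' @param mm_r,mm_ts MM groups per state: tibbles with `label`, `q`, `x`,
#'   `y`, `z` (and optionally `residue_name` for classification).
#' @return Object of class `state_charge_system`.
#' @export
state_charge_system <- function(qm_r, qm_ts, mm_r, mm_ts = mm_r) {
  lab_r <- sort(unique(mm_r$label))
  lab_ts <- sort(unique(mm_ts$label))
  if (!identical(lab_r, lab_ts)) {
    stop("consistency error: MM group labels differ between states: ",
         paste(c(setdiff(lab_r, lab_ts), setdiff(lab_ts, lab_r)),
               collapse = ", "), call. = FALSE)
  }
  structure(list(qm_r = tibble::as_tibble(qm_r),
                 qm_ts = tibble::as_tibble(qm_ts),
                 mm_r = tibble::as_tibble(mm_r),
                 mm_ts = tibble::as_tibble(mm_ts)),
            class = "state_charge_system")
}

#' Per-residue contribution to the activation energy
#'
#' For every MM charge group the scan computes
#' `ddE_a = E_int(group, TS) - E_int(group, R)`: the amount the barrier
#' drops when the group's charges are deleted, with the sign convention
#' that negative values mark residues that stabilize the transition state.
#' Each state's interaction energy uses that state's own geometry.
#'
#' @param system A [state_charge_system()].
#' @return Tibble with `label`, `ddEa` (kcal mol^-1), `e_r`, `e_ts` and,
#'   when residue names are present, `class` (negative / positive / polar /
#'   apolar).
#' @export
residue_deletion_scan <- function(system) {
  stopifnot(inherits(system, "state_charge_system"))
  labels <- sort(unique(system$mm_r$label))
  rows <- purrr::map(labels, function(lab) {
    gr_r <- system$mm_r[system$mm_r$label == lab, ]
    gr_ts <- system$mm_ts[system$mm_ts$label == lab, ]
    e_r <- coulomb_interaction(gr_r, system$qm_r)
    e_ts <- coulomb_interaction(gr_ts, system$qm_ts)
    tibble::tibble(label = lab, e_r = e_r, e_ts = e_ts,
                   ddEa = e_ts - e_r,
                   class = residue_class(first_or_na(gr_r[["residue_name"]])))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("residue_contributions", class(out))
  out
}

first_or_na <- function(x) {
  if (is.null(x) || length(x) == 0) NA_character_ else x[1]
}

# four-way amino acid classification used for coloring contribution plots
residue_class <- function(residue_name) {
  if (is.na(residue_name)) return(NA_character_)
  rn <- toupper(substr(residue_name, 1, 3))
  if (rn %in% c("ASP", "GLU")) return("negative")
  if (rn %in% c("LYS", "ARG", "HIS")) return("positive")
  if (rn %in% c("SER", "THR", "ASN", "GLN", "TYR", "CYS", "TRP"))
    return("polar")
  "apolar"
}

#' Geometric axis coordinate for a charge group
#'
#' Projects a residue onto the acid/base dividing axis used to display
#' per-residue barrier contributions: the difference between the distance
#' from the group's center of geometry to the proton-receiving base
#' reference and to the proton-donating acid reference. Groups equidistant
#' from both references sit at zero (on the dividing plane).
#'
#' @param group Tibble with `x`, `y`, `z` (one charge group).
#' @param base_ref,acid_ref Length-3 reference coordinates.
#' @return Signed axis coordinate, A.
#' @export
axis_projection <- function(group, base_ref, acid_ref) {
  cog <- colMeans(as.matrix(group[, c("x", "y", "z")]))
  sqrt(sum((cog - base_ref)^2)) - sqrt(sum((cog - acid_ref)^2))
}

#' Read a whitespace-delimited charge table
#'
#' Columns `label q x y z` (QM tables may omit `label`); `#` comments are
#' skipped.
#'
#' @param path File path.
#' @param labelled Whether the first column is a group label.
#' @return Tibble with `label` (if present), `q`, `x`, `y`, `z`.
#' @export
read_charge_table <- function(path, labelled = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "\\s+")
  need <- if (labelled) 5L else 4L
  if (any(lengths(toks) < need)) {
    stop("parse error: expected ", need, " columns in ", path, call. = FALSE)
  }
  num <- function(j) suppressWarnings(
    as.numeric(vapply(toks, `[[`, character(1), j)))
  if (labelled) {
    out <- tibble::tibble(label = vapply(toks, `[[`, character(1), 1),
                          q = num(2), x = num(3), y = num(4), z = num(5))
  } else {
    out <- tibble::tibble(q = num(1), x = num(2), y = num(3), z = num(4))
  }
  if (any(is.na(out$q))) stop("parse error: non-numeric charge in ", path,
                              call. = FALSE)
  out
}
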