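# small programmatic fixtures shared across test files

# bare trajectory from coordinate rows: coords is an n x 3 matrix (one
# frame) or a list of such matrices (frames)
make_traj <- function(coords, box = c(20, 20, 20), atom_name = NULL,
                      residue_id = NULL, residue_name = "UNK",
                      element = NULL, selections = list()) {
  if (!is.list(coords)) coords <- list(coords)
  na <- nrow(coords[[1]])
  if (is.null(atom_name)) atom_name <- rep("C", na)
  if (is.null(residue_id)) residue_id <- seq_len(na)
  if (is.null(element)) element <- rep("C", na)
  tbl <- dplyr::bind_rows(lapply(seq_along(coords), function(f) {
    tibble::tibble(frame = f, atom_id = seq_len(na), atom_name = atom_name,
                   element = element, residue_name = residue_name,
                   residue_id = as.integer(residue_id),
                   x = coords[[f]][, 1], y = coords[[f]][, 2],
                   z = coords[[f]][, 3])
  }))
  as_trajectory(tbl, box = box, selections = selections)
}

# uniform ideal-gas trajectory with one tagged reference atom (atom 1)
make_uniform_gas <- function(n_frames, n_atoms, box = c(20, 20, 20),
                             seed = 1) {
  withr::with_seed(seed, {
    n <- n_frames * (n_atoms + 1)
    tbl <- tibble::tibble(
      frame = rep(seq_len(n_frames), each = n_atoms + 1),
      atom_id = rep(seq_len(n_atoms + 1), n_frames),
      atom_name = rep(c("REF", rep("OW", n_atoms)), n_frames),
      element = rep(c("C", rep("O", n_atoms)), n_frames),
      residue_name = "WAT",
      residue_id = rep(seq_len(n_atoms + 1), n_frames),
      x = stats::runif(n, 0, box[1]),
      y = stats::runif(n, 0, box[2]),
      z = stats::runif(n, 0, box[3]))
    as_trajectory(tbl, box = box,
                  selections = list(ref = 1L, pop = 2:(n_atoms + 1)))
  })
}

# flat 1-D surface (F = 0 everywhere)
flat_surface_1d <- function() {
  structure(list(dim = 1L,
                 energy = function(x) rep(0, length(x)),
                 gradient = function(x) matrix(0, length(x), 1),
                 domain = cbind(lower = -5, upper = 5),
                 family = "flat", params = list()),
            class = "spla2_surface")
}

expect_tibble <- function(x) expect_s3_class(x, "tbl_df")

# wrap hand-built per-frame candidate tables into a conformation_records
# object (one row per frame, nucleophile pre-assigned as min d_c_o)
fake_records <- function(cand_list) {
  rows <- lapply(cand_list, function(cand) {
    nuc <- which.min(cand$d_c_o)
    tibble::tibble(frame = cand$frame[1],
                   d_nd_h_min = min(cand$d_nd_h),
                   d_nd_h = cand$d_nd_h[nuc],
                   d_c_o = cand$d_c_o[nuc],
                   d_o_h = NA_real_,
                   d_nd_c = 4.2, d_ca_o_popc = 2.4,
                   d_ca_o_wat = cand$d_ca_o_wat[nuc])
  })
  out <- dplyr::bind_rows(rows)
  structure(out, candidates = cand_list,
            class = c("conformation_records", class(tibble::tibble())))
}
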