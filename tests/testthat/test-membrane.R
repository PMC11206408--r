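test_that("reference plane uses population statistics per frame", {
  coords <- cbind(0, 0, c(19, 19, 21, 21))
  tr <- make_traj(coords, atom_name = rep("P", 4), element = rep("P", 4),
                  selections = list(upper_leaflet_P = 1:4))
  rp <- reference_plane(tr)
  expect_equal(rp$mean_z, 20)
  expect_equal(rp$sigma_z, 1) # population convention
  tr2 <- make_traj(cbind(0, 0, rep(20, 4)), atom_name = rep("P", 4),
                   selections = list(upper_leaflet_P = 1:4))
  expect_equal(reference_plane(tr2)$sigma_z, 0)
  expect_error(reference_plane(tr, integer(0)), "selection error")
})

test_that("penetration depth recovers planted depths and is translation
           invariant", {
  depths <- tibble::tibble(residue_id = 1:4,
                           depth_mean = c(3, -1, 0.5, 2),
                           depth_sd = c(0.5, 0.3, 0.2, 0.4))
  spec <- membrane_fixture_spec(n_frames = 2000,
                                n_lipids_per_leaflet = 30,
                                residue_depths = depths)
  tr <- gen_membrane_trajectory(spec, seed = 21)
  dp <- penetration_depth(tr)
  expect_equal(dp$mean_dz, depths$depth_mean, tolerance = 0.05)
  expect_true(all(dp$min_dz <= dp$mean_dz & dp$mean_dz <= dp$max_dz))
  # rigid translation in z leaves the profile unchanged
  tr_shift <- tr
  tr_shift$z <- tr_shift$z + 5
  dp2 <- penetration_depth(tr_shift)
  expect_equal(dp2$mean_dz, dp$mean_dz, tolerance = 1e-12)
  expect_equal(dp2$max_dz, dp$max_dz, tolerance = 1e-12)
})

test_that("pooled plane sigma recovers the planted spread", {
  spec <- membrane_fixture_spec(n_frames = 1000, n_lipids_per_leaflet = 20,
                                plane_sigma = 1.5,
                                residue_depths = tibble::tibble(
                                  residue_id = 1L, depth_mean = 2,
                                  depth_sd = 0.1))
  tr <- gen_membrane_trajectory(spec, seed = 13)
  dp <- penetration_depth(tr)
  expect_lt(abs(attr(dp, "plane_sigma") - 1.5), 0.1)
})

test_that("hotspot detection merges contiguous flagged residues", {
  prof <- tibble::tibble(
    residue_id = 1:10, residue_name = "RES",
    mean_dz = 0, min_dz = -1,
    max_dz = c(3, 3, 3, 0, 0, 0, 0, 0, 3, 3))
  hs <- find_buried_hotspots(prof, sigma = 1.5)
  expect_equal(nrow(hs), 2)
  expect_equal(hs$n_residues, c(3, 2))
  expect_equal(hs$first_residue, c(1, 9))
  none <- find_buried_hotspots(
    dplyr::mutate(prof, max_dz = 0), sigma = 1.5)
  expect_equal(nrow(none), 0)
})

test_that("hotspot detection is monotone under deepening", {
  spec <- membrane_fixture_spec(n_frames = 200)
  tr <- gen_membrane_trajectory(spec, seed = 3)
  dp <- penetration_depth(tr)
  base <- find_buried_hotspots(dp)
  deeper <- dp
  deeper$max_dz[deeper$residue_id == 80] <- deeper$max_dz[80] + 10
  more <- find_buried_hotspots(deeper, sigma = attr(dp, "plane_sigma"))
  base_res <- unlist(purrr::map2(base$first_residue, base$last_residue, `:`))
  more_res <- unlist(purrr::map2(more$first_residue, more$last_residue, `:`))
  expect_true(all(base_res %in% more_res))
})

test_that("five planted buried runs are recovered as five hotspots", {
  spec <- membrane_fixture_spec(n_frames = 400)
  tr <- gen_membrane_trajectory(spec, seed = 17)
  hs <- find_buried_hotspots(penetration_depth(tr))
  expect_equal(nrow(hs), 5)
  expect_equal(hs$first_residue, c(1, 16, 30, 62, 111))
  expect_equal(hs$last_residue, c(6, 20, 30, 65, 116))
})

test_that("density map counts every observation and smoothing conserves
           mass", {
  tr <- make_traj(replicate(100, cbind(10, 10, 5), simplify = FALSE),
                  selections = list(a = 1L))
  dm <- density_map(tr, "a", bin_width = 1)
  expect_equal(sum(dm$counts), 100)
  expect_equal(max(dm$counts), 100) # one bin holds everything
  spec <- membrane_fixture_spec(n_frames = 50)
  trm <- gen_membrane_trajectory(spec, seed = 2)
  dm2 <- density_map(trm, "upper_leaflet_P", bin_width = 2,
                     smooth_sigma = 3)
  expect_equal(sum(dm2$counts), 50 * 40)
  expect_lt(abs(sum(dm2$smoothed) - sum(dm2$counts)) / sum(dm2$counts),
            1e-6)
})

test_that("uniform xy points keep bin counts within the Poisson band", {
  spec <- membrane_fixture_spec(n_frames = 400, n_lipids_per_leaflet = 50,
                                residue_depths = tibble::tibble(
                                  residue_id = 1L, depth_mean = 0,
                                  depth_sd = 0.1))
  tr <- gen_membrane_trajectory(spec, seed = 29)
  dm <- density_map(tr, "upper_leaflet_P", bin_width = 10)
  inner <- dm$counts[2:(nrow(dm$counts) - 1), 2:(ncol(dm$counts) - 1)]
  lambda <- mean(inner)
  expect_true(all(abs(inner - lambda) < 4 * sqrt(lambda)))
})

test_that("minimum residue-substrate distances respect the boundary rule
           and PBC", {
  box <- c(93.21, 88.40, 103.30)
  coords <- rbind(c(1, 10, 10),    # residue atom
                  c(92, 10, 10),   # target: 2.21 A away through the wall
                  c(50, 10, 13))   # second residue, 3 A from nothing
  tr <- make_traj(coords, box = box, residue_id = c(1L, 900L, 2L),
                  selections = list(target = 2L))
  rmd <- residue_min_distance(tr, target_selection = "target")
  r1 <- rmd[rmd$residue_id == 1, ]
  expect_equal(r1$mean_min_distance, 93.21 - 91, tolerance = 1e-9)
  expect_true(r1$in_shell)
  # exactly at the cutoff is outside the shell (strict less-than)
  coords2 <- rbind(c(10, 10, 10), c(15, 10, 10))
  tr2 <- make_traj(coords2, residue_id = c(1L, 900L),
                   selections = list(target = 2L))
  rmd2 <- residue_min_distance(tr2, target_selection = "target")
  expect_equal(rmd2$mean_min_distance, 5)
  expect_false(rmd2$in_shell)
})
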