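test_that("membrane generator honors the zero-noise limit and the seed", {
  depths <- tibble::tibble(residue_id = 1:3, depth_mean = c(2, 2, 2),
                           depth_sd = 0)
  spec <- membrane_fixture_spec(n_frames = 3, n_lipids_per_leaflet = 5,
                                plane_z = 20, plane_sigma = 0,
                                residue_depths = depths)
  tr <- gen_membrane_trajectory(spec, seed = 4)
  p_up <- tr[tr$atom_id %in% traj_select(tr, "upper_leaflet_P"), ]
  expect_true(all(p_up$z == 20))
  res <- tr[tr$atom_id %in% traj_select(tr, "residue_cog"), ]
  expect_true(all(res$z == 18))
  # determinism
  tr2 <- gen_membrane_trajectory(spec, seed = 4)
  expect_identical(tr, tr2)
  tr3 <- gen_membrane_trajectory(spec, seed = 5)
  expect_false(identical(tr$x, tr3$x))
})

test_that("membrane generator P-atom spread matches the planted sigma", {
  spec <- membrane_fixture_spec(n_frames = 2000, n_lipids_per_leaflet = 10,
                                plane_sigma = 1,
                                residue_depths = tibble::tibble(
                                  residue_id = 1L, depth_mean = 0,
                                  depth_sd = 0))
  tr <- gen_membrane_trajectory(spec, seed = 11)
  z <- tr$z[tr$atom_id %in% traj_select(tr, "upper_leaflet_P")]
  expect_lt(abs(sd(z) - 1), 0.05)
})

test_that("active-site generator realizes drawn distances and is seeded", {
  spec <- active_site_fixture_spec(n_frames = 40)
  tr <- gen_active_site_trajectory(spec, seed = 2)
  expect_identical(tr, gen_active_site_trajectory(spec, seed = 2))
  truth <- attr(tr, "truth")
  rec <- catalytic_distances(tr)
  m <- dplyr::inner_join(truth, tibble::as_tibble(rec), by = "frame",
                         suffix = c("_drawn", "_meas"))
  sw <- m[m$state == "single_water", ]
  expect_gt(nrow(sw), 5)
  expect_lt(max(abs(sw$d_nd_c_drawn - sw$d_nd_c_meas)), 0.01)
  expect_lt(max(abs(sw$d_ca_o_popc_drawn - sw$d_ca_o_popc_meas)), 0.01)
  expect_lt(max(abs(sw$d_c_o_drawn - sw$d_c_o_meas)), 0.01)
  expect_lt(max(abs(sw$d_ca_o_wat_drawn - sw$d_ca_o_wat_meas)), 0.01)
  expect_lt(max(abs(sw$d_nd_h_drawn - sw$d_nd_h_meas)), 0.01)
})

test_that("degenerate mixture produces only single-water frames", {
  spec <- active_site_fixture_spec(
    n_frames = 60, state_probabilities = c(1, 0, 0),
    single_water = list(d_nd_h = c(1.9, 0), d_c_o = c(3.2, 0),
                        d_nd_c = c(4.2, 0), d_ca_o_popc = c(2.4, 0),
                        d_ca_o_wat = c(3.6, 0)))
  tr <- gen_active_site_trajectory(spec, seed = 1)
  rec <- classify_conformations(catalytic_distances(tr))
  expect_true(all(rec$label == "single_water"))
})

test_that("contradictory distance demands raise a construction error", {
  spec <- active_site_fixture_spec(
    n_frames = 2, state_probabilities = c(1, 0, 0),
    single_water = list(d_nd_h = c(1.0, 0), d_c_o = c(12, 0)))
  expect_error(gen_active_site_trajectory(spec, seed = 1),
               "construction error")
})

test_that("mixture fractions converge to the state probabilities", {
  spec <- active_site_fixture_spec(n_frames = 4000,
                                   state_probabilities = c(0.75, 0.04, 0.21),
                                   n_bulk_waters = 2)
  tr <- gen_active_site_trajectory(spec, seed = 7)
  frac <- table(attr(tr, "truth")$state) / 4000
  expect_lt(abs(frac[["single_water"]] - 0.75), 0.02)
  expect_lt(abs(frac[["assisting_water"]] - 0.04), 0.02)
  expect_lt(abs(frac[["nonproductive"]] - 0.21), 0.02)
})

test_that("biased sampler matches the harmonic stationary law on a flat
           surface", {
  meta <- window_metadata(1.5, 100)
  ws <- sample_biased_windows(flat_surface_1d(), meta, n_steps = 25000,
                              seed = 3)
  v <- ws[[1]]$values
  expect_lt(abs(mean(v) - 1.5), 0.01)
  expect_lt(abs(var(v) - rt_kcal() / 100), 0.0006) # RT/k = 0.61633/100
  # determinism
  ws2 <- sample_biased_windows(flat_surface_1d(), meta, n_steps = 25000,
                               seed = 3)
  expect_identical(ws[[1]]$values, ws2[[1]]$values)
  expect_error(sample_biased_windows(flat_surface_1d(), meta,
                                     step_size = -1), "step_size")
})

test_that("flat-surface samples pass a KS test against the analytic
           Gaussian", {
  meta <- window_metadata(0, 100)
  ws <- sample_biased_windows(flat_surface_1d(), meta, n_steps = 13000,
                              seed = 5)
  v <- ws[[1]]$values
  # thin to roughly independent draws before the KS test
  v <- v[seq(1, length(v), by = 5)]
  ks <- suppressWarnings(stats::ks.test(v, "pnorm", 0,
                                        sqrt(rt_kcal() / 100)))
  expect_gt(ks$p.value, 0.01)
})

test_that("neighboring windows overlap on a double-well surface", {
  s <- double_well_1d(8, 3)
  meta <- window_metadata(seq(-1.8, 1.8, length.out = 12), 100)
  ws <- sample_biased_windows(s, meta, n_steps = 3000, seed = 2)
  ranges <- t(vapply(ws, function(w) range(w$values), numeric(2)))
  ord <- order(meta$bias_center)
  overlaps <- vapply(seq_len(11), function(i) {
    a <- ranges[ord[i], ]; b <- ranges[ord[i + 1], ]
    min(a[2], b[2]) - max(a[1], b[1])
  }, numeric(1))
  expect_true(all(overlaps > 0))
})

test_that("analytic surface gradients agree with finite differences", {
  surfaces <- list(double_well_1d(17, 3, -7.9), default_test_surface())
  for (s in surfaces) {
    withr::with_seed(8, {
      for (i in 1:25) {
        p <- stats::runif(s$dim, s$domain[, 1], s$domain[, 2])
        ev <- eval_surface(s, p)
        num <- vapply(seq_len(s$dim), function(k) {
          h <- 1e-6
          pp <- p; pp[k] <- pp[k] + h
          pm <- p; pm[k] <- pm[k] - h
          (eval_surface(s, pp)$energy - eval_surface(s, pm)$energy) / (2 * h)
        }, numeric(1))
        denom <- max(1, sqrt(sum(ev$gradient^2)))
        expect_lt(max(abs(ev$gradient - num)) / denom, 1e-5)
      }
    })
  }
})

test_that("surface special points evaluate as designed", {
  s <- double_well_1d(barrier = 6, separation = 4)
  at0 <- eval_surface(s, 0)
  expect_equal(at0$energy, 6)
  expect_equal(at0$gradient, 0)
  expect_equal(eval_surface(s, -2)$energy, 0)
  g <- gaussian_sum_2d(c(-5, 3), rbind(c(0, 0), c(4, 0)), c(0.5, 0.5))
  expect_equal(eval_surface(g, c(4, 0))$energy, 3, tolerance = 1e-10)
})

test_that("charge fixture supports identity and linearity checks", {
  sys <- gen_charge_states(seed = 6)
  scan <- residue_deletion_scan(sys)
  expect_equal(nrow(scan), 6)
  # identity: same geometry in both states zeroes every contribution
  sys0 <- state_charge_system(sys$qm_r, sys$qm_r, sys$mm_r, sys$mm_r)
  expect_equal(residue_deletion_scan(sys0)$ddEa, rep(0, 6))
  # linearity: doubling one group's charges doubles its contribution
  mm2 <- sys$mm_r
  target <- scan$label[1]
  mm2$q[mm2$label == target] <- 2 * mm2$q[mm2$label == target]
  sys2 <- state_charge_system(sys$qm_r, sys$qm_ts, mm2, {
    mt <- sys$mm_ts
    mt$q[mt$label == target] <- 2 * mt$q[mt$label == target]
    mt
  })
  scan2 <- residue_deletion_scan(sys2)
  expect_equal(scan2$ddEa[scan2$label == target],
               2 * scan$ddEa[scan$label == target])
  expect_equal(scan2$ddEa[scan2$label != target],
               scan$ddEa[scan$label != target])
})
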