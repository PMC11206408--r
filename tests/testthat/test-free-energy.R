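test_that("umbrella window container validates its inputs", {
  expect_error(umbrella_window(1:5, 0, -1), "force_constant")
  expect_error(umbrella_window(1:5, 0, 100, discard_fraction = 1),
               "discard_fraction")
  w <- umbrella_window(c(1, 2, 3, 4), 0, 100, discard_fraction = 0.5)
  expect_equal(spla2kit:::retained_values(w), c(3, 4))
})

test_that("time-block analysis flags drifting windows", {
  withr::with_seed(71, {
    stationary <- umbrella_window(rnorm(2000, 1.5, 0.1), 1.5, 100)
    drift <- umbrella_window(rnorm(2000, 1.5, 0.1) +
                               seq(0, 0.5, length.out = 2000), 1.5, 100)
  })
  ok <- time_block_check(stationary)
  expect_true(ok$equilibrated)
  expect_true(all(ok$block_overlap >= 0.9))
  bad <- time_block_check(drift)
  expect_false(bad$equilibrated)
  # identical blocks give coefficients of exactly one
  flat <- time_block_check(umbrella_window(rep(c(1, 2), 200), 0, 100))
  expect_equal(flat$block_overlap, rep(1, 4), tolerance = 1e-12)
  expect_error(time_block_check(umbrella_window(1:20, 0, 100)),
               "too short")
})

test_that("WHAM inverts a Gaussian to its quadratic free energy", {
  withr::with_seed(72, v <- rnorm(2e5, 0, 0.5))
  prof <- suppressWarnings(wham_solve(umbrella_window(v, 0, 0), bin_width = 0.05))
  td <- tidy(prof)
  sel <- abs(td$xi) <= 0.5 & is.finite(td$F)
  pred <- rt_kcal() * td$xi^2 / (2 * 0.25)
  pred <- pred - min(pred[sel])
  expect_lt(max(abs(td$F[sel] - pred[sel])), 0.05)
})

test_that("a flat landscape reconstructs flat within 0.1 kcal/mol", {
  meta <- window_metadata(seq(0, 1.65, by = 0.15), 100)
  ws <- sample_biased_windows(flat_surface_1d(), meta, n_steps = 20000,
                              seed = 73)
  prof <- suppressWarnings(wham_solve(ws, bin_width = 0.05))
  # judge flatness over the spanned range (between the window centers);
  # the barely-visited tail bins outside it are statistical noise
  fe <- prof$F[is.finite(prof$F) & prof$xi >= 0 & prof$xi <= 1.65]
  expect_lt(diff(range(fe)), 0.1)
})

test_that("WHAM is invariant to window order and reports convergence", {
  s <- double_well_1d(5, 2)
  meta <- window_metadata(seq(-1.3, 1.3, length.out = 10), 100)
  ws <- sample_biased_windows(s, meta, n_steps = 4000, seed = 74)
  p1 <- wham_solve(ws, bin_width = 0.05)
  p2 <- wham_solve(rev(ws), bin_width = 0.05)
  expect_equal(p2$F, p1$F, tolerance = 1e-5)
  expect_lt(attr(p1, "residual"), 1e-7)
  expect_equal(min(p1$F, na.rm = TRUE), 0)
  g <- glance(p1)
  expect_equal(g$n_windows, 10)
})

test_that("disconnected window chains are rejected", {
  withr::with_seed(75, {
    w1 <- umbrella_window(rnorm(500, 0, 0.05), 0, 100)
    w2 <- umbrella_window(rnorm(500, 5, 0.05), 5, 100)
  })
  expect_error(wham_solve(list(w1, w2)), "disconnected")
})

test_that("doubling samples shrinks the reconstruction error", {
  s <- double_well_1d(6, 2.4)
  meta <- window_metadata(seq(-1.5, 1.5, length.out = 14), 100)
  rms <- vapply(c(2500, 5000, 10000, 20000), function(n) {
    ws <- sample_biased_windows(s, meta, n_steps = n, seed = 76)
    prof <- suppressWarnings(wham_solve(ws, bin_width = 0.05))
    sel <- is.finite(prof$F) & abs(prof$xi) < 1.4
    truth <- s$energy(matrix(prof$xi[sel], ncol = 1))
    resid <- prof$F[sel] - truth
    sqrt(mean((resid - mean(resid))^2))
  }, numeric(1))
  # Monte-Carlo convergence: 8x the samples should clearly shrink the
  # error (about 1/sqrt(8) ~ 0.35, allow slack for correlation noise)
  expect_lt(rms[4], rms[1] * 0.75)
})

test_that("profile features find minima, barrier and reaction energy", {
  xi <- seq(-2, 2, by = 0.02)
  sym <- tibble::tibble(xi = xi, F = 5 * (xi^2 - 1)^2 / 1)
  ft <- profile_features(sym, c(-1.5, -0.5), c(0.5, 1.5))
  expect_equal(ft$delta_g, 0, tolerance = 1e-9)
  expect_equal(ft$xi_ts, 0, tolerance = 0.02)
  expect_equal(ft$barrier, 5, tolerance = 1e-6)
  mono <- tibble::tibble(xi = xi, F = xi + 2)
  expect_error(profile_features(mono, c(-2, -1), c(1, 2)),
               "feature error")
})

test_that("a planted exergonic double well yields its offset", {
  s <- double_well_1d(10, 3, -7.9)
  meta <- window_metadata(seq(-1.8, 1.8, length.out = 20), 100)
  ws <- sample_biased_windows(s, meta, n_steps = 6000, seed = 77)
  prof <- suppressWarnings(wham_solve(ws, bin_width = 0.05))
  ft <- profile_features(prof, c(-2, -1), c(1, 2))
  expect_lt(abs(ft$delta_g + 7.9), 0.3)
})

test_that("discarding the burn-in of a stationary series barely moves the
           profile", {
  withr::with_seed(78, v <- rnorm(5e4, 1, 0.3))
  p_all <- suppressWarnings(wham_solve(umbrella_window(v, 1, 0), bin_width = 0.1))
  p_cut <- suppressWarnings(
    wham_solve(umbrella_window(v, 1, 0, discard_fraction = 0.2),
               bin_width = 0.1))
  joint <- dplyr::inner_join(tidy(p_all), tidy(p_cut), by = "xi")
  joint <- joint[is.finite(joint$F.x) & is.finite(joint$F.y) &
                   abs(joint$xi - 1) < 0.6, ]
  expect_lt(max(abs(joint$F.x - joint$F.y)), 0.1)
})
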