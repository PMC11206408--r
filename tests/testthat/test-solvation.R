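test_that("ideal-gas g(r) is flat at unity", {
  tr <- make_uniform_gas(n_frames = 1000, n_atoms = 500, seed = 2)
  r <- rdf(tr, "pop", "ref", r_max = 9, bin_width = 0.5)
  sel <- r$r >= 2
  expect_lt(max(abs(r$g[sel] - 1)), 0.05)
  expect_true(all(r$g >= 0))
  expect_true(all(diff(r$cumulative_n) >= 0))
  expect_error(rdf(tr, "pop", "ref", r_max = 15), "r_max")
})

test_that("cumulative count equals the g(r) quadrature", {
  tr <- make_uniform_gas(n_frames = 100, n_atoms = 200, seed = 5)
  r <- rdf(tr, "pop", "ref", r_max = 8, bin_width = 0.2)
  rho <- attr(r, "rho_ref")
  lo <- r$r - 0.1; hi <- r$r + 0.1
  quad <- cumsum(rho * r$g * 4 / 3 * pi * (hi^3 - lo^3))
  sel <- seq_along(r$r) >= 2
  expect_lt(max(abs(r$cumulative_n[sel] - quad[sel]) /
                  pmax(quad[sel], 1e-9)), 0.01)
})

test_that("rdf is invariant under rigid rotation of every frame", {
  tr <- make_uniform_gas(n_frames = 30, n_atoms = 100, seed = 3)
  r1 <- rdf(tr, "pop", "ref", r_max = 6, bin_width = 0.3)
  # rotate all coordinates about the box center (z axis, 90 degrees)
  rot <- tr
  cx <- traj_box(tr)[1] / 2; cy <- traj_box(tr)[2] / 2
  x <- rot$x - cx; y <- rot$y - cy
  rot$x <- -y + cx; rot$y <- x + cy
  r2 <- rdf(rot, "pop", "ref", r_max = 6, bin_width = 0.3)
  expect_equal(r2$g, r1$g, tolerance = 1e-9)
})

test_that("a frozen water at 3 A registers in the cumulative count", {
  coords <- rbind(c(10, 10, 10), c(13, 10, 10))
  tr <- make_traj(coords, atom_name = c("REF", "OW"),
                  element = c("C", "O"),
                  selections = list(ref = 1L, pop = 2L))
  r <- rdf(tr, "pop", "ref", r_max = 5, bin_width = 0.1)
  expect_equal(r$cumulative_n[r$r > 3.15][1], 1)
  expect_equal(shell_statistics(tr, 2.5, 3.2, population_selection = "pop",
                                reference = "ref"), 1)
  expect_equal(shell_statistics(tr, 0, 2.5, population_selection = "pop",
                                reference = "ref"), 0)
  expect_error(shell_statistics(tr, 3, 2), "validation error")
})

test_that("midpoint references are recomputed per frame", {
  # two fixed anchors with one population atom at the midpoint + 2 A
  coords <- list(rbind(c(8, 10, 10), c(12, 10, 10), c(10, 12, 10)),
                 rbind(c(6, 10, 10), c(14, 10, 10), c(10, 12, 10)))
  tr <- make_traj(coords, atom_name = c("A", "B", "OW"),
                  selections = list(anchors = 1:2, pop = 3L))
  occ <- shell_statistics(tr, 1.9, 2.1, population_selection = "pop",
                          reference = "anchors")
  expect_equal(occ, 1) # midpoint is (10,10,10) in both frames
})

test_that("planted shell occupancy is recovered", {
  # 0.7 waters on average placed in [2.5, 3.2) around a fixed reference
  withr::with_seed(31, {
    nf <- 4000
    coords <- lapply(seq_len(nf), function(f) {
      base <- c(10, 10, 10)
      if (stats::runif(1) < 0.7) {
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        w <- base + stats::runif(1, 2.5, 3.199) * u
      } else {
        w <- c(2, 2, 2)
      }
      rbind(base, w)
    })
  })
  tr <- make_traj(coords, atom_name = c("REF", "OW"),
                  selections = list(ref = 1L, pop = 2L))
  occ <- shell_statistics(tr, 2.5, 3.2, population_selection = "pop",
                          reference = "ref")
  expect_lt(abs(occ - 0.7), 0.05)
})

test_that("coordination numbers count ligands inside the cutoff", {
  oct <- rbind(c(2.4, 0, 0), c(-2.4, 0, 0), c(0, 2.4, 0), c(0, -2.4, 0),
               c(0, 0, 2.4), c(0, 0, -2.4))
  coords <- rbind(c(10, 10, 10), sweep(oct, 2, c(10, 10, 10), "+"))
  tr <- make_traj(coords, atom_name = c("CA", rep("OW", 6)),
                  element = c("Ca", rep("O", 6)),
                  selections = list(ca = 1L, lig = 2:7))
  expect_equal(coordination_number(tr, "ca", "lig", 3.4), 6)
  expect_equal(coordination_number(tr, "ca", "lig", 2.0), 0)
  expect_error(coordination_number(tr, integer(0), "lig", 3.4),
               "selection error")
})

test_that("a planted mean coordination number is recovered", {
  withr::with_seed(41, {
    nf <- 5000
    coords <- lapply(seq_len(nf), function(f) {
      n_in <- stats::rpois(1, 8.4)
      pts <- matrix(c(2, 2, 2), max(n_in, 1), 3, byrow = TRUE)
      if (n_in > 0) {
        u <- matrix(stats::rnorm(n_in * 3), ncol = 3)
        u <- u / sqrt(rowSums(u^2))
        pts[seq_len(n_in), ] <- sweep(u * stats::runif(n_in, 2.0, 3.35),
                                      2, c(10, 10, 10), "+")
      }
      # pad to a fixed atom count with far-away ligands
      pad <- matrix(c(2, 2, 2), 30 - n_in, 3, byrow = TRUE)
      rbind(c(10, 10, 10), pts[seq_len(n_in), , drop = FALSE], pad)
    })
  })
  tr <- make_traj(coords, atom_name = c("CA", rep("OW", 30)),
                  selections = list(ca = 1L, lig = 2:31))
  cn <- coordination_number(tr, "ca", "lig", 3.4)
  expect_lt(abs(cn - 8.4), 0.1)
})

test_that("Shrake-Rupley matches the analytic isolated sphere", {
  tr <- make_traj(cbind(10, 10, 10), element = "C")
  s <- sasa(tr, 1L, probe = 1.4, n_points = 960)
  expect_lt(abs(s$area - 4 * pi * 3.1^2) / (4 * pi * 3.1^2), 0.01)
})

test_that("a fully enclosed atom has zero accessible area", {
  dirs <- spla2kit:::golden_spiral(60)
  coords <- rbind(c(10, 10, 10), sweep(dirs * 1.6, 2, c(10, 10, 10), "+"))
  tr <- make_traj(coords, element = rep("C", 61))
  s <- sasa(tr, 1L)
  expect_equal(s$area, 0)
})

test_that("distant atoms are independent and approach is monotone", {
  iso <- sasa(make_traj(cbind(10, 10, 10), element = "C"), 1L)$area
  pairf <- function(d) {
    tr <- make_traj(rbind(c(5, 10, 10), c(5 + d, 10, 10)),
                    element = c("C", "C"), box = c(40, 40, 40))
    sasa(tr, 1L)$area
  }
  expect_equal(pairf(12), iso)
  areas <- vapply(c(6.5, 5, 4, 3, 2.5), pairf, numeric(1))
  expect_true(all(diff(areas) <= 1e-9))
  expect_error(sasa(make_traj(cbind(1, 1, 1), element = "Xx"), 1L),
               "lookup error")
})
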