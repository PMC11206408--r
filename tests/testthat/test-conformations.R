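# brute-force oracle: evaluates the classification logic by exhaustive
# enumeration over all waters and water pairs in a frame
brute_force_label <- function(cand, bridge, crit) {
  single <- cand$d_nd_h < crit$d_his_h_max & cand$d_c_o < crit$d_c_o_max
  if (any(single)) return("single_water")
  if (!is.null(bridge)) {
    for (w1 in seq_len(nrow(cand))) {
      for (w2 in seq_len(nrow(cand))) {
        if (w1 == w2) next
        if (cand$d_c_o[w1] < crit$d_c_o_max &&
            cand$d_nd_h[w2] < crit$d_his_h_max &&
            bridge[w1, w2] < crit$d_bridge_max) return("assisting_water")
      }
    }
  }
  "nonproductive"
}

test_that("catalytic distances match the generator construction and are
           rotation invariant", {
  spec <- active_site_fixture_spec(n_frames = 30)
  tr <- gen_active_site_trajectory(spec, seed = 12)
  rec <- catalytic_distances(tr)
  truth <- attr(tr, "truth")
  sw <- which(truth$state == "single_water")
  expect_lt(max(abs(rec$d_nd_c[sw] - truth$d_nd_c[sw])), 0.01)
  expect_lt(max(abs(rec$d_c_o[sw] - truth$d_c_o[sw])), 0.01)
  # rigid rotation of every frame about the box center leaves them fixed
  rot <- tr
  ctr <- traj_box(tr) / 2
  x <- rot$x - ctr[1]; y <- rot$y - ctr[2]
  rot$x <- -y + ctr[1]; rot$y <- x + ctr[2]
  rec2 <- catalytic_distances(rot)
  expect_equal(rec2$d_nd_c, rec$d_nd_c, tolerance = 1e-9)
  expect_equal(rec2$d_nd_h_min, rec$d_nd_h_min, tolerance = 1e-9)
})

test_that("classification follows the geometric criteria on hand-built
           frames", {
  crit <- classification_criteria()
  # single water: d(Nd-H) = 1.8, d(C-O) = 3.0
  rec1 <- fake_records(list(tibble::tibble(
    frame = 1L, water = 10L, d_c_o = 3.0, d_nd_h = 1.8,
    d_ca_o_wat = 3.5)))
  out1 <- classify_conformations(rec1, crit)
  expect_equal(as.character(out1$label), "single_water")
  # assisting: W1 attacks (3.5) but cannot reach His (4.0); W2 donates
  cand2 <- tibble::tibble(frame = 1L, water = c(10L, 11L),
                          d_c_o = c(3.5, 6.0), d_nd_h = c(4.0, 2.0),
                          d_ca_o_wat = c(4.8, 7.0))
  attr(cand2, "bridge") <- matrix(c(Inf, 5, 1.9, Inf), 2, 2)
  out2 <- classify_conformations(fake_records(list(cand2)), crit)
  expect_equal(as.character(out2$label), "assisting_water")
  expect_equal(out2$d_o_h, 1.9)
  expect_equal(out2$d_c_o, 3.5)
  expect_equal(out2$d_nd_h, 2.0)
  # exactly-at-threshold geometries are nonproductive (strict <)
  rec3 <- fake_records(list(tibble::tibble(
    frame = 1L, water = 10L, d_c_o = 4.0, d_nd_h = 2.5,
    d_ca_o_wat = 3.5)))
  expect_equal(as.character(classify_conformations(rec3, crit)$label),
               "nonproductive")
})

test_that("classifier agrees with the brute-force oracle frame by frame", {
  spec <- active_site_fixture_spec(n_frames = 300, n_bulk_waters = 4)
  tr <- gen_active_site_trajectory(spec, seed = 23)
  rec <- catalytic_distances(tr)
  crit <- classification_criteria()
  got <- classify_conformations(rec, crit)
  cands <- attr(rec, "candidates")
  want <- vapply(cands, function(cand)
    brute_force_label(cand, attr(cand, "bridge"), crit), character(1))
  expect_equal(as.character(got$label), want)
  # fractions sum to one exactly
  expect_equal(sum(attr(got, "populations")$fraction), 1)
})

test_that("classification is monotone in the thresholds", {
  spec <- active_site_fixture_spec(n_frames = 400)
  tr <- gen_active_site_trajectory(spec, seed = 8)
  rec <- catalytic_distances(tr)
  tight <- classify_conformations(rec, classification_criteria(2.0, 3.5, 2.0))
  loose <- classify_conformations(rec, classification_criteria(2.8, 4.5, 2.8))
  productive <- function(r) sum(r$label != "nonproductive")
  expect_gte(productive(loose), productive(tight))
})

test_that("hydrogen-bond occupancy recovers a planted fraction", {
  withr::with_seed(51, {
    n <- 5000
    d <- ifelse(stats::runif(n) < 0.42, stats::runif(n, 1.6, 2.45),
                stats::runif(n, 2.6, 6))
  })
  rec <- tibble::tibble(frame = seq_along(d), d_nd_h_min = d)
  expect_lt(abs(hbond_occupancy(rec) - 0.42), 0.02)
  expect_equal(hbond_occupancy(tibble::tibble(d_nd_h_min = rep(1, 5))), 1)
  expect_equal(hbond_occupancy(tibble::tibble(d_nd_h_min = rep(9, 5))), 0)
})

test_that("density clustering separates planted blobs", {
  withr::with_seed(61, {
    blob <- function(n, cx, cy) tibble::tibble(
      d_nd_c = stats::rnorm(n, cx, 0.2),
      d_ca_o_popc = stats::rnorm(n, cy, 0.2))
    two <- dplyr::bind_rows(blob(500, 0, 0), blob(500, 10, 0))
  })
  cl <- cluster_microstates(two, kde_sigma = 0.2, density_quantile = 0.5)
  expect_equal(nrow(cl$clusters), 2)
  expect_lt(max(abs(cl$clusters$fraction - 0.5)), 0.05)
  # single blob: one cluster holding at least 1 - quantile of records
  withr::with_seed(62, one <- tibble::tibble(
    d_nd_c = stats::rnorm(600, 4, 0.3),
    d_ca_o_popc = stats::rnorm(600, 2.4, 0.3)))
  cl1 <- cluster_microstates(one, kde_sigma = 0.3, density_quantile = 0.5)
  expect_equal(nrow(cl1$clusters), 1)
  expect_gte(cl1$clusters$fraction[1], 0.5)
  expect_error(cluster_microstates(one[1:10, ]), "clustering error")
  expect_error(cluster_microstates(
    tibble::tibble(d_nd_c = rep(1, 100), d_ca_o_popc = rep(2, 100))),
    "clustering error")
})

test_that("a minority cluster at the 6% level is resolved", {
  withr::with_seed(63, {
    blob <- function(n, cx, cy, s = 0.25) tibble::tibble(
      d_nd_c = stats::rnorm(n, cx, s),
      d_ca_o_popc = stats::rnorm(n, cy, s))
    recs <- dplyr::bind_rows(blob(120, 4.2, 2.4), blob(940, 5.5, 6.5),
                             blob(940, 8.5, 3.5))
  })
  cl <- cluster_microstates(recs, kde_sigma = 0.25, density_quantile = 0.4)
  expect_equal(nrow(cl$clusters), 3)
  expect_lt(abs(min(cl$clusters$fraction) - 0.06), 0.02)
})

test_that("state summaries use the population sd convention", {
  rec <- tibble::tibble(
    label = factor(c("single_water", "assisting_water")),
    d_nd_h = c(1.8, 2.0), d_c_o = c(3.0, 3.5), d_o_h = c(NA, 1.9),
    d_nd_c = c(4.2, 4.6), d_ca_o_popc = c(2.4, 2.4),
    d_ca_o_wat = c(3.6, 4.8))
  s <- state_distance_summary(rec)
  one <- s[s$label == "single_water" & s$distance == "d_ca_o_wat", ]
  expect_equal(one$mean, 3.6)
  expect_equal(one$sd, 0)
})

test_that("planted distance laws are recovered through the full pipeline", {
  spec <- active_site_fixture_spec(n_frames = 2500)
  tr <- gen_active_site_trajectory(spec, seed = 33)
  rec <- classify_conformations(catalytic_distances(tr))
  s <- state_distance_summary(rec)
  sw <- s[s$label == "single_water" & s$distance == "d_ca_o_wat", ]
  aw <- s[s$label == "assisting_water" & s$distance == "d_ca_o_wat", ]
  expect_lt(abs(sw$mean - 3.6), 0.1)
  expect_lt(abs(sw$sd - 1.5), 0.1)
  expect_lt(abs(aw$mean - 4.8), 0.1)
  expect_lt(abs(aw$sd - 0.2), 0.1)
})
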