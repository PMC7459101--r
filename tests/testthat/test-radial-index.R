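test_that("radial_ratio handles center, surface and interior spots", {
  nuc <- nucleus_model("n1", semi_axes = c(5, 5, 5))
  spots <- dplyr::bind_rows(
    make_spot(0, 0, 0, "center"),
    make_spot(5, 0, 0, "surface"),
    make_spot(3, 0, 0, "interior"))
  out <- radial_ratio(spots, nuc)
  expect_equal(out$radial_ratio, c(0, 1, 0.6))
})

test_that("radial_ratio is frame-aware for rotated ellipsoids", {
  set.seed(3)
  R <- rand_rotation()
  nuc <- nucleus_model("n1", semi_axes = c(6, 4, 2), center = c(1, -2, 3),
                       orientation = R)
  # a point at half the principal x semi-axis, expressed in the lab frame
  p <- c(1, -2, 3) + R %*% c(3, 0, 0)
  out <- radial_ratio(make_spot(p[1], p[2], p[3]), nuc)
  expect_equal(out$radial_ratio, 0.5, tolerance = 1e-12)
})

test_that("out-of-boundary spots are clamped within tolerance, rejected beyond", {
  nuc <- nucleus_model("n1", semi_axes = c(5, 5, 5))
  expect_warning(out <- radial_ratio(make_spot(5.1, 0, 0, "sA"), nuc),
                 "clamped")
  expect_equal(out$radial_ratio, 1)
  expect_error(radial_ratio(make_spot(5.5, 0, 0, "sB"), nuc), "sB")
  expect_error(radial_ratio(make_spot(1, 1, 1, nucleus_id = "ghost"), nuc),
               "ghost")
})

test_that("distance index maps rho through the isovolumetric construction", {
  out <- normalized_distance_index(c(0, 0.5^(1 / 3), 1))
  expect_equal(out$distance_index, c(0, 0.5, 1))
  expect_equal(out$shell, c(1L, 5000L, 10000L))
  lin <- normalized_distance_index(0.5, mode = "linear")
  expect_equal(lin$distance_index, 0.5)
  expect_error(normalized_distance_index(1.2), "\\[0, 1\\]")
  expect_error(normalized_distance_index(-0.1), "\\[0, 1\\]")
})

test_that("volume-mode index is the cube of the linear-mode index", {
  rho <- runif(200)
  vol <- normalized_distance_index(rho, mode = "volume")$distance_index
  lin <- normalized_distance_index(rho, mode = "linear")$distance_index
  expect_equal(vol, lin^3, tolerance = 1e-15)
})

test_that("uniform-in-volume spots give a flat volume-mode index", {
  set.seed(19)
  nuc <- rand_nucleus("u1", center = c(0, 0, 0))
  n <- 1e5
  # rejection-sample points uniform in the ellipsoid volume (independent
  # of the simulate_spots construction)
  R <- matrix(c(nuc$r11, nuc$r21, nuc$r31, nuc$r12, nuc$r22, nuc$r32,
                nuc$r13, nuc$r23, nuc$r33), 3, 3)
  ax <- c(nuc$a_um, nuc$b_um, nuc$c_um)
  pts <- matrix(numeric(0), ncol = 3)
  while (nrow(pts) < n) {
    cand <- cbind(runif(n, -ax[1], ax[1]), runif(n, -ax[2], ax[2]),
                  runif(n, -ax[3], ax[3]))
    keep <- rowSums(sweep(cand, 2, ax, "/")^2) <= 1
    pts <- rbind(pts, cand[keep, , drop = FALSE])
  }
  pts <- pts[seq_len(n), ] %*% t(R)
  spots <- tibble::tibble(spot_id = as.character(seq_len(n)),
                          nucleus_id = "u1", probe_id = "P",
                          x_um = pts[, 1], y_um = pts[, 2], z_um = pts[, 3])
  idx <- spots |>
    radial_ratio(nuc) |>
    normalized_distance_index()
  ks <- suppressWarnings(ks.test(idx$distance_index, "punif"))
  expect_lt(unname(ks$statistic), 0.01)
  # shell occupancy: aggregate the 10000 shells into 100 groups and check
  # each against a 4-sigma Poisson band
  grp <- (idx$shell - 1) %/% 100
  counts <- tabulate(grp + 1, nbins = 100)
  expected <- n / 100
  expect_true(all(abs(counts - expected) < 4 * sqrt(expected)))
})

test_that("radial_distribution_summary bins correctly", {
  s <- radial_distribution_summary(rep(0.5, 7), n_bins = 10)
  expect_equal(sum(s$fraction), 1)
  expect_equal(s$fraction[5], 1)
  g <- glance(s)
  expect_equal(g$mean, 0.5)
  expect_equal(g$n, 7)
  set.seed(5)
  u <- radial_distribution_summary(runif(1e4), n_bins = 10)
  expect_true(all(abs(u$fraction - 0.1) < 0.01))
  expect_error(radial_distribution_summary(numeric(0)), "non-empty")
})

test_that("zone classification splits [0,1] at the breakpoints", {
  expect_equal(as.character(zone_classification(c(0.1, 0.5, 0.9))),
               c("centre", "middle", "periphery"))
  expect_equal(as.character(zone_classification(c(1 / 3, 2 / 3))),
               c("middle", "periphery"))
  expect_error(zone_classification(0.5, breakpoints = c(0.7, 0.3)),
               "low < high")
  # uniform-in-volume population: equal-volume zones get 1/3 each
  set.seed(23)
  n <- 1e4
  zones <- zone_classification(runif(n))
  frac <- as.numeric(table(zones)) / n
  se3 <- 3 * sqrt(1 / 3 * 2 / 3 / n)
  expect_true(all(abs(frac - 1 / 3) < se3))
})
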