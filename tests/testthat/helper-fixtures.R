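# Shared generators for geometric fixtures. Everything is built in code at
# test time; no binary fixtures.

# voxelized sphere mask centered in its grid
make_sphere_mask <- function(radius = 5, spacing = c(0.13, 0.13, 0.2)) {
  n <- nucleus_model("sph", semi_axes = rep(radius, 3))
  voxelize(n, spacing = spacing)
}

# random proper rotation matrix
rand_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

# random ellipsoid nucleus with semi-axes in [2, 8] um
rand_nucleus <- function(id = "n1", center = runif(3, -2, 2)) {
  ax <- sort(runif(3, 2, 8), decreasing = TRUE)
  nucleus_model(id, semi_axes = ax, center = center,
                orientation = rand_rotation())
}

# one-row spot tibble
make_spot <- function(x, y, z, spot_id = "s1", nucleus_id = "n1",
                      probe_id = "P") {
  tibble::tibble(spot_id = spot_id, nucleus_id = nucleus_id,
                 probe_id = probe_id, x_um = x, y_um = y, z_um = z)
}

# independent brute-force boundary radius: bisection on rho such that the
# point center + rho * t * dir leaves the ellipsoid
ray_march_radius <- function(nucleus, direction, tol = 1e-9) {
  inside <- function(t) {
    p <- c(nucleus$center_x_um, nucleus$center_y_um, nucleus$center_z_um) +
      t * direction
    R <- matrix(c(nucleus$r11, nucleus$r21, nucleus$r31,
                  nucleus$r12, nucleus$r22, nucleus$r32,
                  nucleus$r13, nucleus$r23, nucleus$r33), 3, 3)
    v <- drop(crossprod(R, p - c(nucleus$center_x_um, nucleus$center_y_um,
                                 nucleus$center_z_um)))
    sum((v / c(nucleus$a_um, nucleus$b_um, nucleus$c_um))^2) <= 1
  }
  lo <- 0
  hi <- 2 * nucleus$a_um
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (inside(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# independent step-up FDR adjustment written from the definition
stepup_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
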