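#' Radial ratio of FISH spots inside their nuclei
#'
#' For each spot, the ratio \eqn{\rho} of its distance from the nucleus
#' center to the boundary radius along the ray through the spot: 0 at the
#' center, 1 on the nuclear border. In the principal frame with spot vector
#' `v` and semi-axes `a`, this is \eqn{\rho = \sqrt{\sum_i (v_i/a_i)^2}}.
#' Spots falling slightly outside the fitted boundary
#' (\eqn{1 < \rho \le 1 +} `tol`) are clamped to 1 with a warning — fitted
#' ellipsoids do not perfectly contain every segmented signal; spots beyond
#' the tolerance raise an error naming them (a segmentation/fit mismatch
#' that should not be silently absorbed).
#'
#' @param spots Spot table: `spot_id`, `nucleus_id`, `probe_id`,
#'   `x_um`, `y_um`, `z_um` (µm, lab frame).
#' @param nuclei Nucleus table as produced by [nucleus_model()],
#'   [simulate_nuclei()] or [read_nucleus_table()].
#' @param tol Out-of-boundary clamping tolerance on `rho` (default 0.05).
#' @return The spot table with a `radial_ratio` column appended.
#' @export
radial_ratio <- function(spots, nuclei, tol = 0.05) {
  required <- c("spot_id", "nucleus_id", "x_um", "y_um", "z_um")
  missing <- setdiff(required, names(spots))
  if (length(missing) > 0) {
    stop("spot table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  assert_nucleus_tbl(nuclei)
  unknown <- setdiff(unique(spots$nucleus_id), nuclei$nucleus_id)
  if (length(unknown) > 0) {
    stop("spots reference unknown nucleus id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  j <- dplyr::left_join(
    spots,
    dplyr::select(nuclei, "nucleus_id", "center_x_um", "center_y_um",
                  "center_z_um", "a_um", "b_um", "c_um",
                  dplyr::all_of(paste0("r", outer(1:3, 1:3, paste0)))),
    by = "nucleus_id"
  )
  dx <- j$x_um - j$center_x_um
  dy <- j$y_um - j$center_y_um
  dz <- j$z_um - j$center_z_um
  # principal-frame components: v = R^T (p - c)
  v1 <- j$r11 * dx + j$r21 * dy + j$r31 * dz
  v2 <- j$r12 * dx + j$r22 * dy + j$r32 * dz
  v3 <- j$r13 * dx + j$r23 * dy + j$r33 * dz
  rho <- sqrt((v1 / j$a_um)^2 + (v2 / j$b_um)^2 + (v3 / j$c_um)^2)
  out_of_nucleus <- rho > 1 + tol
  if (any(out_of_nucleus)) {
    stop("spot(s) outside the nucleus boundary beyond tolerance (rho > ",
         1 + tol, "): ",
         paste(utils::head(spots$spot_id[out_of_nucleus], 5), collapse = ", "),
         call. = FALSE)
  }
  clamped <- rho > 1
  if (any(clamped)) {
    warning(sum(clamped), " spot(s) slightly outside the fitted boundary ",
            "(rho <= ", 1 + tol, ") were clamped to rho = 1", call. = FALSE)
    rho[clamped] <- 1
  }
  dplyr::mutate(spots, radial_ratio = rho)
}

#' Normalized distance index from radial ratios
#'
#' Converts radial ratios into the 0-to-1 normalized distance index by the
#' isovolumetric-shell construction: the nuclear volume is divided into
#' `n_shells` concentric shells of equal volume and a spot is assigned to
#' the shell its radial ratio falls in. In the default `"volume"` mode the
#' continuous index is \eqn{\rho^3} (shell k is the smallest k with
#' \eqn{\rho^3 \le k/N}), so a population of spots distributed uniformly in
#' nuclear volume has a flat index distribution. `"linear"` mode reports
#' \eqn{\rho} itself with equal-width shells in \eqn{\rho}.
#'
#' @param rho Numeric vector of radial ratios in `[0, 1]`, or a data frame
#'   carrying a `radial_ratio` column (e.g. output of [radial_ratio()]).
#' @param n_shells Number of isovolumetric shells (default 10000).
#' @param mode `"volume"` (default) or `"linear"`.
#' @return For numeric input, a tibble with `radial_ratio`, `shell`,
#'   `distance_index`, `n_shells`, `index_mode`; for data frame input the
#'   same columns appended to it.
#' @examples
#' normalized_distance_index(c(0, 0.5^(1 / 3), 1))
#' @export
normalized_distance_index <- function(rho, n_shells = 10000,
                                      mode = c("volume", "linear")) {
  mode <- match.arg(mode)
  if (is.data.frame(rho)) {
    if (!"radial_ratio" %in% names(rho)) {
      stop("data frame input must have a `radial_ratio` column ",
           "(run radial_ratio() first)", call. = FALSE)
    }
    idx <- distance_index_vec(rho$radial_ratio, n_shells, mode)
    return(dplyr::mutate(rho,
                         shell = idx$shell,
                         distance_index = idx$distance_index,
                         n_shells = n_shells, index_mode = mode))
  }
  idx <- distance_index_vec(rho, n_shells, mode)
  tibble::tibble(radial_ratio = as.numeric(rho), shell = idx$shell,
                 distance_index = idx$distance_index,
                 n_shells = n_shells, index_mode = mode)
}

distance_index_vec <- function(rho, n_shells, mode) {
  if (any(!is.finite(rho)) || any(rho < 0) || any(rho > 1)) {
    stop("radial ratio must lie in [0, 1]", call. = FALSE)
  }
  if (n_shells < 1) stop("`n_shells` must be >= 1", call. = FALSE)
  index <- if (mode == "volume") rho^3 else rho
  # smallest k with index <= k/N; the epsilon absorbs cube-root round-trip
  # noise at exact shell boundaries
  shell <- pmin(pmax(ceiling(index * n_shells - 1e-9), 1L), n_shells)
  list(shell = as.integer(shell), distance_index = index)
}

#' Feret (maximum caliper) diameter of a nucleus
#'
#' For a parametric/fitted ellipsoid model the Feret diameter is twice the
#' largest semi-axis. For a voxel mask it is the maximum pairwise extent of
#' surface voxel centers; since the exact 3D convex hull is not needed at
#' voxel resolution, the implementation takes the extreme surface voxel
#' along each of a fixed fan of directions and maximizes pairwise distance
#' over those extremes (exact for convex shapes up to voxel resolution).
#'
#' @param x One-or-more-row nucleus tibble, or a [voxel_mask()].
#' @param ... Passed to methods.
#' @return Feret diameter(s) in µm.
#' @export
feret_diameter <- function(x, ...) UseMethod("feret_diameter")

#' @rdname feret_diameter
#' @export
feret_diameter.data.frame <- function(x, ...) {
  assert_nucleus_tbl(x)
  2 * x$a_um
}

#' @rdname feret_diameter
#' @param n_directions Number of probe directions for the mask method.
#' @export
feret_diameter.voxel_mask <- function(x, n_directions = 512, ...) {
  pts <- mask_voxel_centers(x)
  if (nrow(pts) == 0) stop("mask is empty; no Feret diameter", call. = FALSE)
  dirs <- fibonacci_sphere(n_directions)
  proj <- pts %*% t(dirs)
  extremes <- unique(c(apply(proj, 2, which.max), apply(proj, 2, which.min)))
  ext <- pts[extremes, , drop = FALSE]
  d2 <- as.matrix(stats::dist(ext))
  max(d2)
}

# deterministic, roughly uniform directions on the unit sphere
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}
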