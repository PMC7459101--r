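#' Euclidean distance between two spots of the same nucleus
#'
#' @param spot_a,spot_b One-row spot tibbles (columns `nucleus_id`,
#'   `x_um`, `y_um`, `z_um`).
#' @return Distance in µm.
#' @export
spot_pair_distance <- function(spot_a, spot_b) {
  stopifnot(nrow(spot_a) == 1, nrow(spot_b) == 1)
  if (!identical(as.character(spot_a$nucleus_id),
                 as.character(spot_b$nucleus_id))) {
    stop("cannot pair spots from different nuclei ('",
         spot_a$nucleus_id, "' vs '", spot_b$nucleus_id, "')", call. = FALSE)
  }
  sqrt((spot_a$x_um - spot_b$x_um)^2 +
         (spot_a$y_um - spot_b$y_um)^2 +
         (spot_a$z_um - spot_b$z_um)^2)
}

#' Normalize an intranuclear distance by the nucleus Feret diameter
#'
#' Dividing by the per-nucleus Feret (maximum caliper) diameter removes
#' overall nuclear size from locus-locus distances, so that Mb/Mt size
#' differences cannot masquerade as locus repositioning.
#'
#' @param distance Distance(s) in µm.
#' @param feret Feret diameter(s) in µm (> 0), recycled as usual.
#' @return Dimensionless normalized distance(s).
#' @export
normalize_by_feret <- function(distance, feret) {
  if (any(!is.finite(feret)) || any(feret <= 0)) {
    stop("`feret` must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(distance)) || any(distance < 0)) {
    stop("`distance` must be finite and >= 0", call. = FALSE)
  }
  distance / feret
}

#' Pairwise gene-centromere distances within nuclei
#'
#' Pairs each gene-probe signal with a centromere-probe signal of the same
#' nucleus and reports raw (µm) and Feret-normalized distances. With
#' `pairing = "nearest"` (default) each gene spot is matched to its nearest
#' centromere spot — the usual convention when homolog pairing is unknown;
#' `pairing = "all"` emits every gene x centromere combination.
#'
#' @param spots Spot table (`spot_id`, `nucleus_id`, `probe_id`,
#'   `x_um`, `y_um`, `z_um`).
#' @param nuclei Nucleus table (for the per-nucleus Feret diameter).
#' @param gene_probe,centromere_probe `probe_id` values selecting the two
#'   signal classes.
#' @param pairing `"nearest"` or `"all"`.
#' @return Tibble: `nucleus_id`, `gene_spot_id`, `centromere_spot_id`,
#'   `raw_distance_um`, `feret_um`, `feret_normalized_distance`.
#' @export
locus_centromere_distances <- function(spots, nuclei, gene_probe,
                                       centromere_probe,
                                       pairing = c("nearest", "all")) {
  pairing <- match.arg(pairing)
  assert_nucleus_tbl(nuclei)
  g <- dplyr::filter(spots, .data$probe_id == gene_probe)
  cen <- dplyr::filter(spots, .data$probe_id == centromere_probe)
  pairs <- dplyr::inner_join(
    dplyr::select(g, gene_spot_id = "spot_id", "nucleus_id",
                  gx = "x_um", gy = "y_um", gz = "z_um"),
    dplyr::select(cen, centromere_spot_id = "spot_id", "nucleus_id",
                  cx = "x_um", cy = "y_um", cz = "z_um"),
    by = "nucleus_id", relationship = "many-to-many"
  )
  pairs <- dplyr::mutate(
    pairs,
    raw_distance_um = sqrt((.data$gx - .data$cx)^2 + (.data$gy - .data$cy)^2 +
                             (.data$gz - .data$cz)^2)
  )
  if (pairing == "nearest") {
    pairs <- pairs |>
      dplyr::group_by(.data$gene_spot_id) |>
      dplyr::slice_min(.data$raw_distance_um, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
  }
  feret_lookup <- if ("feret_um" %in% names(nuclei)) {
    dplyr::select(nuclei, "nucleus_id", "feret_um")
  } else {
    dplyr::transmute(nuclei, .data$nucleus_id, feret_um = 2 * .data$a_um)
  }
  pairs |>
    dplyr::left_join(feret_lookup, by = "nucleus_id") |>
    dplyr::mutate(feret_normalized_distance =
                    normalize_by_feret(.data$raw_distance_um, .data$feret_um)) |>
    dplyr::select("nucleus_id", "gene_spot_id", "centromere_spot_id",
                  "raw_distance_um", "feret_um", "feret_normalized_distance")
}

#' Compare two groups of observations
#'
#' The package's two workhorse tests: the Mann-Whitney U test for nuclear
#' observations (radial indices, normalized distances) and Welch's t-test
#' for other quantities. The Mann-Whitney p-value uses the exact
#' permutation null (full enumeration over group assignments, valid under
#' ties) when `min(n_a, n_b) <= 8`, and the normal approximation with tie
#' correction and continuity correction otherwise.
#'
#' @param values_a,values_b Numeric vectors (non-empty; the t-test needs
#'   at least 2 values per group).
#' @param test `"mann_whitney"` (default) or `"t_test"`.
#' @param exact_max Largest `min(n_a, n_b)` for which the exact
#'   Mann-Whitney null is enumerated.
#' @return An object of class `rf_comparison`: a list with `test_name`,
#'   `statistic` (U or t), `p_value`, `n_a`, `n_b`, `mean_a`, `sd_a`,
#'   `mean_b`, `sd_b`, `method`. Use [generics::tidy()] for a one-row
#'   tibble.
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6))
#' @export
compare_groups <- function(values_a, values_b,
                           test = c("mann_whitney", "t_test"),
                           exact_max = 8) {
  test <- match.arg(test)
  values_a <- as.numeric(values_a)
  values_b <- as.numeric(values_b)
  if (length(values_a) == 0 || length(values_b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (any(!is.finite(c(values_a, values_b)))) {
    stop("group values must be finite", call. = FALSE)
  }
  n_a <- length(values_a)
  n_b <- length(values_b)
  if (test == "t_test") {
    if (min(n_a, n_b) < 2) {
      stop("t-test requires at least 2 observations per group", call. = FALSE)
    }
    ht <- stats::t.test(values_a, values_b)
    statistic <- unname(ht$statistic)
    p <- ht$p.value
    method <- "welch_t"
  } else {
    mw <- mann_whitney_u(values_a, values_b, exact_max = exact_max)
    statistic <- mw$u
    p <- mw$p
    method <- mw$method
  }
  structure(list(test_name = test, statistic = statistic,
                 p_value = p, n_a = n_a, n_b = n_b,
                 mean_a = mean(values_a), sd_a = stats::sd(values_a),
                 mean_b = mean(values_b), sd_b = stats::sd(values_b),
                 method = method),
            class = "rf_comparison")
}

#' @export
print.rf_comparison <- function(x, ...) {
  cat(sprintf("%s comparison (%s): statistic = %.4g, p = %.4g\n",
              x$test_name, x$method, x$statistic, x$p_value))
  cat(sprintf("  group a: n = %d, mean = %.4g +/- %.4g\n", x$n_a, x$mean_a, x$sd_a))
  cat(sprintf("  group b: n = %d, mean = %.4g +/- %.4g\n", x$n_b, x$mean_b, x$sd_b))
  invisible(x)
}

# Mann-Whitney U with exact enumeration for small samples (tie-safe)
mann_whitney_u <- function(a, b, exact_max = 8) {
  n_a <- length(a)
  n_b <- length(b)
  ranks <- rank(c(a, b))
  u_obs <- sum(ranks[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  mu <- n_a * n_b / 2
  if (min(n_a, n_b) <= exact_max && choose(n_a + n_b, n_a) <= 5e5) {
    combos <- utils::combn(n_a + n_b, n_a)
    rank_sums <- colSums(matrix(ranks[combos], nrow = n_a))
    u_all <- rank_sums - n_a * (n_a + 1) / 2
    # two-sided: as-or-more-extreme distance of U from its null mean
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    list(u = u_obs, p = p, method = "exact_enumeration")
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    )
    list(u = u_obs, p = wt$p.value, method = "normal_approximation")
  }
}

#' Summarize a radial index distribution
#'
#' Bins normalized distance indices into equal-width bins on `[0, 1]` and
#' reports bin occupancy fractions plus the sample mean and SD.
#'
#' @param indices Numeric vector of distance indices, or a data frame with
#'   a `distance_index` column (e.g. from [normalized_distance_index()]).
#' @param n_bins Number of equal-width bins over `[0, 1]`.
#' @return A tibble of class `rf_radial_summary` with columns `bin`,
#'   `lower`, `upper`, `count`, `fraction`; the mean, SD and n of the
#'   indices are attached as attributes and available via
#'   [generics::glance()].
#' @export
radial_distribution_summary <- function(indices, n_bins = 10) {
  if (is.data.frame(indices)) {
    if (!"distance_index" %in% names(indices)) {
      stop("data frame input must have a `distance_index` column", call. = FALSE)
    }
    indices <- indices$distance_index
  }
  indices <- as.numeric(indices)
  if (length(indices) == 0) stop("`indices` must be non-empty", call. = FALSE)
  if (any(!is.finite(indices)) || any(indices < 0) || any(indices > 1)) {
    stop("indices must lie in [0, 1]", call. = FALSE)
  }
  if (n_bins < 1) stop("`n_bins` must be >= 1", call. = FALSE)
  breaks <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(pmax(ceiling(indices * n_bins), 1L), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  out <- tibble::tibble(bin = seq_len(n_bins),
                        lower = breaks[-(n_bins + 1)], upper = breaks[-1],
                        count = counts, fraction = counts / length(indices))
  attr(out, "mean") <- mean(indices)
  attr(out, "sd") <- stats::sd(indices)
  attr(out, "n") <- length(indices)
  class(out) <- c("rf_radial_summary", class(out))
  out
}

#' Classify a distance index into nuclear zones
#'
#' Operationalizes "centre / middle zone / periphery" as three intervals of
#' the normalized distance index. With the volume-mode index and the
#' default breakpoints (1/3, 2/3) the three zones have equal nuclear
#' volume.
#'
#' @param index Distance index values in `[0, 1]`.
#' @param breakpoints Two increasing values in (0, 1).
#' @return Factor with levels `centre`, `middle`, `periphery`.
#' @export
zone_classification <- function(index, breakpoints = c(1 / 3, 2 / 3)) {
  if (length(breakpoints) != 2 || any(!is.finite(breakpoints)) ||
      breakpoints[1] <= 0 || breakpoints[2] >= 1 ||
      breakpoints[1] >= breakpoints[2]) {
    stop("`breakpoints` must satisfy 0 < low < high < 1", call. = FALSE)
  }
  if (any(!is.finite(index)) || any(index < 0) || any(index > 1)) {
    stop("index values must lie in [0, 1]", call. = FALSE)
  }
  cut(index, breaks = c(-Inf, breakpoints, Inf),
      labels = c("centre", "middle", "periphery"), right = FALSE) |>
    factor(levels = c("centre", "middle", "periphery"))
}

#' Mobility-threshold analysis of per-locus positional changes
#'
#' Joins each locus's Mb-vs-Mt positional comparison (p-value) with its
#' intra-chromosomal gene-centromere distance and tabulates the 2x2
#' contingency of (distance above threshold) x (change significant). The
#' motivating observation is that loci closer than ~50 Mbp to their
#' centromere do not show significant distance-index changes.
#'
#' @param per_locus Tibble with one row per locus: `gene_symbol`,
#'   `distance_mbp` (intra-chromosomal gene-centromere distance) and
#'   `p_value` (positional Mb-vs-Mt comparison).
#' @param threshold_mbp Mobility threshold in Mbp (default 50).
#' @param alpha Significance level for the positional change (default 0.05).
#' @return The input with logical columns `above_threshold` and
#'   `significant` appended; the 2x2 contingency table (rows: above
#'   threshold TRUE/FALSE, columns: significant TRUE/FALSE) is attached as
#'   attribute `"contingency"`.
#' @export
mobility_threshold_analysis <- function(per_locus, threshold_mbp = 50,
                                        alpha = 0.05) {
  needed <- c("gene_symbol", "distance_mbp", "p_value")
  missing <- setdiff(needed, names(per_locus))
  if (length(missing) > 0) {
    stop("per-locus table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  incomplete <- per_locus$gene_symbol[!is.finite(per_locus$distance_mbp)]
  if (length(incomplete) > 0) {
    stop("missing intra-chromosomal distance for locus/loci: ",
         paste(incomplete, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::mutate(per_locus,
                       above_threshold = .data$distance_mbp > threshold_mbp,
                       significant = .data$p_value < alpha)
  tab <- table(factor(out$above_threshold, levels = c(TRUE, FALSE)),
               factor(out$significant, levels = c(TRUE, FALSE)),
               dnn = c("above_threshold", "significant"))
  attr(out, "contingency") <- tab
  attr(out, "threshold_mbp") <- threshold_mbp
  attr(out, "alpha") <- alpha
  class(out) <- c("rf_mobility", class(out))
  out
}

#' Fusion index
#'
#' Fraction of nuclei residing in multinucleated (fused) cells — the
#' standard readout of myogenic differentiation efficiency.
#'
#' @param n_nuclei_in_multinucleated Number of nuclei counted inside
#'   multinucleated cells.
#' @param n_total_nuclei Total number of counted nuclei (>= 1).
#' @return Fusion index in `[0, 1]`.
#' @examples
#' fusion_index(77, 100)
#' @export
fusion_index <- function(n_nuclei_in_multinucleated, n_total_nuclei) {
  if (any(n_total_nuclei < 1)) stop("`n_total_nuclei` must be >= 1", call. = FALSE)
  if (any(n_nuclei_in_multinucleated < 0) ||
      any(n_nuclei_in_multinucleated > n_total_nuclei)) {
    stop("fused nuclei count must lie in [0, n_total_nuclei]", call. = FALSE)
  }
  n_nuclei_in_multinucleated / n_total_nuclei
}
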