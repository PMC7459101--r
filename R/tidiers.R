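#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a group comparison
#'
#' @param x An `rf_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return One-row tibble: `test_name`, `statistic`, `p_value`, `n_a`,
#'   `n_b`, `mean_a`, `sd_a`, `mean_b`, `sd_b`, `method`.
#' @method tidy rf_comparison
#' @export
tidy.rf_comparison <- function(x, ...) {
  tibble::tibble(test_name = x$test_name, statistic = x$statistic,
                 p_value = x$p_value, n_a = x$n_a, n_b = x$n_b,
                 mean_a = x$mean_a, sd_a = x$sd_a,
                 mean_b = x$mean_b, sd_b = x$sd_b, method = x$method)
}

#' @rdname tidy.rf_comparison
#' @method glance rf_comparison
#' @export
glance.rf_comparison <- function(x, ...) tidy(x, ...)

#' Tidy a K_GOI/K_mean correlation
#'
#' @param x An `rf_correlation` from [correlate_kgoi_kmean()].
#' @param ... Unused.
#' @return One-row tibble: `rho`, `ci_low`, `ci_high`, `p_value`, `n`,
#'   `conf_level`, `method`.
#' @method tidy rf_correlation
#' @export
tidy.rf_correlation <- function(x, ...) {
  tibble::tibble(rho = x$rho, ci_low = x$ci_low, ci_high = x$ci_high,
                 p_value = x$p_value, n = x$n, conf_level = x$conf_level,
                 method = x$method)
}

#' @rdname tidy.rf_correlation
#' @method glance rf_correlation
#' @export
glance.rf_correlation <- function(x, ...) tidy(x, ...)

#' Glance at a radial index distribution summary
#'
#' @param x An `rf_radial_summary` from [radial_distribution_summary()].
#' @param ... Unused.
#' @return One-row tibble: `mean`, `sd`, `n`.
#' @method glance rf_radial_summary
#' @export
glance.rf_radial_summary <- function(x, ...) {
  tibble::tibble(mean = attr(x, "mean"), sd = attr(x, "sd"),
                 n = attr(x, "n"))
}

#' Glance at a mobility-threshold analysis
#'
#' @param x An `rf_mobility` from [mobility_threshold_analysis()].
#' @param ... Unused.
#' @return One-row tibble with the 2x2 contingency counts
#'   (`above_sig`, `above_ns`, `below_sig`, `below_ns`), the threshold and
#'   alpha.
#' @method glance rf_mobility
#' @export
glance.rf_mobility <- function(x, ...) {
  tab <- attr(x, "contingency")
  tibble::tibble(above_sig = tab["TRUE", "TRUE"],
                 above_ns = tab["TRUE", "FALSE"],
                 below_sig = tab["FALSE", "TRUE"],
                 below_ns = tab["FALSE", "FALSE"],
                 threshold_mbp = attr(x, "threshold_mbp"),
                 alpha = attr(x, "alpha"))
}
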