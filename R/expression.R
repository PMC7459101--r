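#' Linear fold change from group mean log2 intensities
#'
#' Direction convention: Mt over Mb, so `fold_change > 1` means
#' upregulated in myotubes.
#'
#' @param mean_log2_mb,mean_log2_mt Group mean log2 intensities (vectorized).
#' @return Linear fold-change ratio(s), `2^(mt - mb)`.
#' @examples
#' fold_change(5, 6) # twofold up in Mt
#' @export
fold_change <- function(mean_log2_mb, mean_log2_mt) {
  if (any(!is.finite(mean_log2_mb)) || any(!is.finite(mean_log2_mt))) {
    stop("log2 means must be finite", call. = FALSE)
  }
  2^(mean_log2_mt - mean_log2_mb)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, preserving input order.
#' Delegates to [stats::p.adjust()].
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in `[0, 1]`, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Twofold + adjusted-p differential expression filter
#'
#' A record is called up if `fold_change >= fc_threshold` and
#' `p_adj < alpha`; down if `fold_change <= 1/fc_threshold` and
#' `p_adj < alpha`. Fold-change bounds are inclusive, the alpha bound
#' exclusive.
#'
#' @param records Expression table with columns `fold_change` and `p_adj`
#'   (see [read_expression_table()]; `fold_change` is computed from the
#'   log2 means if absent).
#' @param fc_threshold Linear fold-change threshold (default 2).
#' @param alpha Adjusted-p threshold (default 0.01).
#' @return The differentially expressed records with a `direction` column
#'   (`"up"` or `"down"`).
#' @export
differential_filter <- function(records, fc_threshold = 2, alpha = 0.01) {
  if (!"fold_change" %in% names(records)) {
    if (all(c("mean_log2_mb", "mean_log2_mt") %in% names(records))) {
      records <- dplyr::mutate(
        records,
        fold_change = fold_change(.data$mean_log2_mb, .data$mean_log2_mt))
    } else {
      stop("records need a `fold_change` column or both log2 mean columns",
           call. = FALSE)
    }
  }
  if (!"p_adj" %in% names(records)) {
    stop("records lack `p_adj`; adjust p-values (bh_adjust) before filtering",
         call. = FALSE)
  }
  if (fc_threshold < 1) stop("`fc_threshold` must be >= 1", call. = FALSE)
  records |>
    dplyr::mutate(direction = dplyr::case_when(
      .data$fold_change >= fc_threshold & .data$p_adj < alpha ~ "up",
      .data$fold_change <= 1 / fc_threshold & .data$p_adj < alpha ~ "down",
      TRUE ~ NA_character_
    )) |>
    dplyr::filter(!is.na(.data$direction))
}

#' Per-chromosome change coefficient
#'
#' `C_co = n_down / n_up`: the ratio of downregulated to upregulated
#' transcript counts on a chromosome. `n_up = 0` with `n_down > 0` yields
#' `Inf` (the chromosome cannot be classified by ratio); `0/0` yields
#' `NaN`.
#'
#' @param n_down,n_up Non-negative transcript counts (vectorized).
#' @return The change coefficient(s).
#' @export
change_coefficient <- function(n_down, n_up) {
  if (any(n_down < 0) || any(n_up < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  ifelse(n_up == 0, ifelse(n_down == 0, NaN, Inf), n_down / n_up)
}

#' Classify a chromosome by its change coefficient
#'
#' Chromosomes with `0.5 < C_co < 1.5` carry a balanced mix of up- and
#' downregulation ("intermediate"); `C_co <= 0.5` is up-dominant and
#' `C_co >= 1.5` down-dominant (the open interval defines intermediate, so
#' the boundaries fall to the dominant groups). Non-finite coefficients
#' (no upregulated transcripts) are `"undefined"`.
#'
#' @param c_co Change coefficient(s) from [change_coefficient()].
#' @param low,high Interval bounds (defaults 0.5 and 1.5).
#' @return Factor with levels `up_dominant`, `intermediate`,
#'   `down_dominant`, `undefined`.
#' @export
classify_chromosome <- function(c_co, low = 0.5, high = 1.5) {
  if (low <= 0 || high <= low) stop("need 0 < low < high", call. = FALSE)
  out <- dplyr::case_when(
    !is.finite(c_co) ~ "undefined",
    c_co <= low ~ "up_dominant",
    c_co >= high ~ "down_dominant",
    TRUE ~ "intermediate"
  )
  factor(out, levels = c("up_dominant", "intermediate", "down_dominant",
                         "undefined"))
}

#' Per-chromosome activity table from differential calls
#'
#' Counts up- and downregulated transcripts per chromosome, computes the
#' change coefficient and assigns the activity group. Only chromosomes
#' with at least one differential transcript appear.
#'
#' @param de_records Output of [differential_filter()] (needs `chromosome`
#'   and `direction` columns).
#' @param low,high Grouping bounds passed to [classify_chromosome()].
#' @return Tibble: `chromosome`, `n_up`, `n_down`, `c_co`, `group`.
#' @export
chromosome_activity <- function(de_records, low = 0.5, high = 1.5) {
  needed <- c("chromosome", "direction")
  missing <- setdiff(needed, names(de_records))
  if (length(missing) > 0) {
    stop("differential table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  counts <- de_records |>
    dplyr::count(.data$chromosome, .data$direction) |>
    tidyr::pivot_wider(names_from = "direction", values_from = "n",
                       values_fill = 0L)
  if (!"up" %in% names(counts)) counts$up <- 0L
  if (!"down" %in% names(counts)) counts$down <- 0L
  counts |>
    dplyr::transmute(.data$chromosome, n_up = .data$up, n_down = .data$down,
                     c_co = change_coefficient(.data$down, .data$up),
                     group = classify_chromosome(.data$c_co, low, high)) |>
    dplyr::arrange(.data$chromosome)
}

#' Symmetric expression-change magnitude (K factor)
#'
#' `K = log2(fc)` for upregulation (`fc > 1`) and `K = log2(1/fc)` for
#' downregulation (`fc <= 1`), i.e. `K = |log2(fc)|` in bits, so up- and
#' downregulation contribute equally to neighbourhood averages.
#'
#' @param f_c Linear fold change(s), > 0.
#' @return K factor(s) in bits, >= 0.
#' @examples
#' k_factor(c(2, 0.5, 1)) # 1, 1, 0
#' @export
k_factor <- function(f_c) {
  if (any(!is.finite(f_c)) || any(f_c <= 0)) {
    stop("`f_c` must be finite and > 0", call. = FALSE)
  }
  ifelse(f_c > 1, log2(f_c), log2(1 / f_c))
}

#' Mean K factor in the genomic neighbourhood of genes of interest
#'
#' For each gene of interest (GOI), averages the K factors of all genes on
#' the same chromosome whose midpoint lies within `window_mbp / 2` of the
#' GOI midpoint (a centered window of total width `window_mbp`). The GOI
#' itself is excluded by default so its own change cannot inflate the
#' neighbourhood signal.
#'
#' @param records Expression table with `gene_symbol`, `chromosome`,
#'   `start_bp`, `end_bp` and either `fold_change` or both log2 mean
#'   columns.
#' @param goi Character vector of gene symbols present in `records`.
#' @param window_mbp Window width(s) in Mbp (default 1.0), recycled over
#'   `goi` — per-gene windows (e.g. 0.95 vs 1.5 Mbp) are supplied here.
#' @param include_goi Include the GOI's own K factor in the mean?
#' @param membership `"midpoint"` (default) or `"overlap"`: whether a
#'   neighbour qualifies by its midpoint falling in the window or by any
#'   overlap of its gene body with the window.
#' @return Tibble: `gene_symbol`, `k_goi`, `k_mean`, `window_mbp`,
#'   `n_neighbors`. An empty neighbourhood gives `k_mean = NA` with a
#'   warning.
#' @export
neighborhood_k_mean <- function(records, goi, window_mbp = 1,
                                include_goi = FALSE,
                                membership = c("midpoint", "overlap")) {
  membership <- match.arg(membership)
  needed <- c("gene_symbol", "chromosome", "start_bp", "end_bp")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    stop("expression table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"fold_change" %in% names(records)) {
    records <- dplyr::mutate(
      records,
      fold_change = fold_change(.data$mean_log2_mb, .data$mean_log2_mt))
  }
  if (any(window_mbp <= 0)) stop("`window_mbp` must be > 0", call. = FALSE)
  window_mbp <- rep_len(window_mbp, length(goi))
  records <- dplyr::mutate(records,
                           .k = k_factor(.data$fold_change),
                           .mid = (.data$start_bp + .data$end_bp) / 2)
  out <- purrr::map2(goi, window_mbp, function(g, w) {
    row <- dplyr::filter(records, .data$gene_symbol == g)
    if (nrow(row) == 0) {
      stop("gene of interest '", g, "' not found in expression table",
           call. = FALSE)
    }
    row <- row[1, ]
    half <- w * 1e6 / 2
    nb <- dplyr::filter(records, .data$chromosome == row$chromosome)
    nb <- if (membership == "midpoint") {
      dplyr::filter(nb, abs(.data$.mid - row$.mid) <= half)
    } else {
      dplyr::filter(nb, .data$end_bp >= row$.mid - half,
                    .data$start_bp <= row$.mid + half)
    }
    if (!include_goi) nb <- dplyr::filter(nb, .data$gene_symbol != g)
    tibble::tibble(gene_symbol = g, k_goi = row$.k,
                   k_mean = if (nrow(nb) == 0) NA_real_ else mean(nb$.k),
                   window_mbp = w, n_neighbors = nrow(nb))
  })
  out <- dplyr::bind_rows(out)
  if (anyNA(out$k_mean)) {
    warning("empty neighbourhood for: ",
            paste(out$gene_symbol[is.na(out$k_mean)], collapse = ", "),
            "; k_mean is NA", call. = FALSE)
  }
  out
}

#' Spearman correlation of GOI expression change with its neighbourhood
#'
#' Spearman rank correlation between per-gene `k_goi` and `k_mean`, with a
#' 95% confidence interval from the Fisher z-transform
#' (`atanh(rho) +/- 1.96 / sqrt(n - 3)`, back-transformed) and a two-sided
#' p-value from the t-approximation `t = rho * sqrt((n-2)/(1-rho^2))`.
#'
#' @param pairs Tibble with columns `k_goi` and `k_mean` (e.g. from
#'   [neighborhood_k_mean()]); rows with missing values are dropped.
#' @param conf_level Confidence level for the Fisher-z interval.
#' @return An object of class `rf_correlation` (list with `rho`, `ci_low`,
#'   `ci_high`, `p_value`, `n`, `method`); [generics::tidy()] gives a
#'   one-row tibble.
#' @export
correlate_kgoi_kmean <- function(pairs, conf_level = 0.95) {
  needed <- c("k_goi", "k_mean")
  missing <- setdiff(needed, names(pairs))
  if (length(missing) > 0) {
    stop("pairs table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ok <- stats::complete.cases(pairs[, needed])
  x <- pairs$k_goi[ok]
  y <- pairs$k_mean[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete (k_goi, k_mean) pairs", call. = FALSE)
  rho <- stats::cor(x, y, method = "spearman")
  z_crit <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (abs(rho) >= 1) {
    ci <- c(rho, rho)
    p <- 0
  } else {
    z <- atanh(rho)
    ci <- tanh(z + c(-1, 1) * z_crit / sqrt(n - 3))
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(rho = rho, ci_low = ci[1], ci_high = ci[2], p_value = p,
                 n = n, conf_level = conf_level,
                 method = "spearman_fisher_z"),
            class = "rf_correlation")
}

#' @export
print.rf_correlation <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f, %d%% CI (%.3f, %.3f), p = %.4g, n = %d\n",
              x$rho, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$p_value, x$n))
  invisible(x)
}

#' Intra-chromosomal gene-centromere distance
#'
#' Linear genomic separation in Mbp between a gene (its midpoint) and its
#' chromosome's centromere.
#'
#' @param annotation Locus table with `chromosome`, `gene_start_bp`,
#'   `gene_end_bp` and, unless `genome` is supplied, a
#'   `centromere_position_bp` column.
#' @param genome Optional genome definition (see [genome_definition()])
#'   with `chromosome` and `centromere_bp`; its centromere positions are
#'   joined by chromosome. Loci on chromosomes absent from the genome
#'   definition raise an error.
#' @return The annotation with a `distance_mbp` column appended.
#' @export
intrachromosomal_distance <- function(annotation, genome = NULL) {
  needed <- c("chromosome", "gene_start_bp", "gene_end_bp")
  missing <- setdiff(needed, names(annotation))
  if (length(missing) > 0) {
    stop("annotation is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!is.null(genome)) {
    unknown <- setdiff(unique(annotation$chromosome), genome$chromosome)
    if (length(unknown) > 0) {
      stop("chromosome(s) not in genome definition: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    annotation <- annotation |>
      dplyr::select(-dplyr::any_of("centromere_position_bp")) |>
      dplyr::left_join(
        dplyr::select(genome, "chromosome",
                      centromere_position_bp = "centromere_bp"),
        by = "chromosome")
  }
  if (!"centromere_position_bp" %in% names(annotation)) {
    stop("annotation needs `centromere_position_bp` or a `genome` definition",
         call. = FALSE)
  }
  if (any(annotation$gene_start_bp >= annotation$gene_end_bp)) {
    stop("gene_start_bp must be < gene_end_bp", call. = FALSE)
  }
  dplyr::mutate(
    annotation,
    distance_mbp = abs((.data$gene_start_bp + .data$gene_end_bp) / 2 -
                         .data$centromere_position_bp) / 1e6)
}
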