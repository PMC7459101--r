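#' Pipeline run configuration
#'
#' Collects every analysis choice in one serializable object so a report
#' records exactly how it was produced.
#'
#' @param index_mode `"volume"` (default) or `"linear"` distance index.
#' @param n_shells Number of isovolumetric shells.
#' @param window_mbp Default neighbourhood width (Mbp) when the annotation
#'   carries no per-gene `window_mbp`.
#' @param fc_threshold,alpha_de Differential expression thresholds.
#' @param alpha_spatial Significance level for positional comparisons.
#' @param mobility_threshold_mbp Intra-chromosomal mobility threshold.
#' @param pairing Gene-centromere pairing rule (`"nearest"` or `"all"`).
#' @param include_goi Include each GOI in its own neighbourhood K mean?
#' @param out_of_nucleus_tol Radial-ratio clamping tolerance.
#' @param seed Integer seed recorded in (and used by) simulation-backed
#'   runs.
#' @return A list of class `rf_config`.
#' @export
run_config <- function(index_mode = c("volume", "linear"), n_shells = 10000,
                       window_mbp = 1, fc_threshold = 2, alpha_de = 0.01,
                       alpha_spatial = 0.05, mobility_threshold_mbp = 50,
                       pairing = c("nearest", "all"), include_goi = FALSE,
                       out_of_nucleus_tol = 0.05, seed = 1) {
  index_mode <- match.arg(index_mode)
  pairing <- match.arg(pairing)
  if (n_shells < 1 || window_mbp <= 0 || fc_threshold < 1 ||
      alpha_de <= 0 || alpha_de >= 1 || alpha_spatial <= 0 ||
      alpha_spatial >= 1 || mobility_threshold_mbp < 0 ||
      out_of_nucleus_tol < 0) {
    stop("invalid run configuration", call. = FALSE)
  }
  structure(list(index_mode = index_mode, n_shells = n_shells,
                 window_mbp = window_mbp, fc_threshold = fc_threshold,
                 alpha_de = alpha_de, alpha_spatial = alpha_spatial,
                 mobility_threshold_mbp = mobility_threshold_mbp,
                 pairing = pairing, include_goi = include_goi,
                 out_of_nucleus_tol = out_of_nucleus_tol, seed = seed),
            class = "rf_config")
}

#' Run the full positional + expression analysis
#'
#' Reproduces the study's analysis order on one set of input tables:
#' per-group nuclear morphology; differential expression with
#' per-chromosome activity; K factor/K mean neighbourhood correlation for
#' the annotated loci; per-probe radial distance-index distributions and
#' Mb-vs-Mt comparisons; Feret-normalized locus-centromere distances; and
#' the intra-chromosomal mobility-threshold table.
#'
#' Probes are linked to loci via the annotation's `probe_id`; a probe's
#' positional comparison is skipped (with a message) when either group
#' lacks spots. Centromere probes are expected to be named
#' `CEN<chromosome>` (e.g. `CENchr2`); the locus-centromere analysis is
#' only run for loci whose centromere probe is present in the spot table.
#'
#' @param study List with `nuclei`, `spots`, `expression`, `annotation`,
#'   `genome` ([simulate_study()] or [read_study()] output).
#' @param config A [run_config()].
#' @return List of class `rf_report`: `morphology`, `de_table`,
#'   `chromosome_activity`, `k_table`, `k_correlation`, `radial_indices`,
#'   `positional_tests`, `distance_pairs`, `distance_tests`, `mobility`,
#'   `config`.
#' @export
run_pipeline <- function(study, config = run_config()) {
  stopifnot(inherits(config, "rf_config"))
  needed <- c("nuclei", "spots", "expression", "annotation", "genome")
  missing <- setdiff(needed, names(study))
  if (length(missing) > 0) {
    stop("study is missing component(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }

  morphology <- stage("morphology", {
    study$nuclei |>
      dplyr::mutate(flattening = flattening(.data$volume_um3,
                                            .data$feret_um)) |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(n = dplyr::n(),
                       volume_mean = mean(.data$volume_um3),
                       volume_sd = stats::sd(.data$volume_um3),
                       flattening_mean = mean(.data$flattening),
                       flattening_sd = stats::sd(.data$flattening),
                       .groups = "drop")
  })

  de_table <- stage("differential_expression",
                    differential_filter(study$expression,
                                        fc_threshold = config$fc_threshold,
                                        alpha = config$alpha_de))
  chrom_activity <- stage("chromosome_activity", chromosome_activity(de_table))

  k_table <- stage("k_factor", {
    ann <- dplyr::filter(study$annotation,
                         .data$gene_symbol %in% study$expression$gene_symbol)
    if (nrow(ann) == 0) {
      tibble::tibble(gene_symbol = character(0), k_goi = numeric(0),
                     k_mean = numeric(0), window_mbp = numeric(0),
                     n_neighbors = integer(0))
    } else {
      w <- if ("window_mbp" %in% names(ann)) ann$window_mbp else config$window_mbp
      neighborhood_k_mean(study$expression, ann$gene_symbol, window_mbp = w,
                          include_goi = config$include_goi)
    }
  })
  k_correlation <- if (sum(stats::complete.cases(
    k_table[, c("k_goi", "k_mean")])) >= 4) {
    stage("k_correlation", correlate_kgoi_kmean(k_table))
  } else {
    NULL
  }

  radial <- stage("radial_index", {
    study$spots |>
      radial_ratio(study$nuclei, tol = config$out_of_nucleus_tol) |>
      normalized_distance_index(n_shells = config$n_shells,
                                mode = config$index_mode) |>
      dplyr::left_join(dplyr::select(study$nuclei, "nucleus_id", "group"),
                       by = "nucleus_id")
  })

  groups <- sort(unique(study$nuclei$group))
  positional_tests <- stage("positional_tests", {
    if (length(groups) != 2) {
      tibble::tibble()
    } else {
      radial |>
        dplyr::group_by(.data$probe_id) |>
        dplyr::group_modify(function(d, key) {
          a <- d$distance_index[d$group == groups[1]]
          b <- d$distance_index[d$group == groups[2]]
          if (length(a) == 0 || length(b) == 0) {
            message("probe ", key$probe_id,
                    ": spots missing in one group; comparison skipped")
            return(tibble::tibble())
          }
          generics::tidy(compare_groups(a, b, "mann_whitney"))
        }) |>
        dplyr::ungroup()
    }
  })

  cen_probes <- unique(grep("^CEN", study$spots$probe_id, value = TRUE))
  distance_pairs <- stage("locus_centromere_distances", {
    ann <- study$annotation
    probe_col <- if ("probe_id" %in% names(ann)) ann$probe_id else ann$gene_symbol
    purrr::map2(probe_col, ann$chromosome, function(p, chr) {
      cen <- paste0("CEN", chr)
      if (!p %in% study$spots$probe_id || !cen %in% cen_probes) {
        return(NULL)
      }
      locus_centromere_distances(study$spots, study$nuclei, p, cen,
                                 pairing = config$pairing) |>
        dplyr::mutate(probe_id = p, centromere_probe = cen)
    }) |> dplyr::bind_rows()
  })

  distance_tests <- stage("distance_tests", {
    if (nrow(distance_pairs) == 0 || length(groups) != 2) {
      tibble::tibble()
    } else {
      distance_pairs |>
        dplyr::left_join(dplyr::select(study$nuclei, "nucleus_id", "group"),
                         by = "nucleus_id") |>
        dplyr::group_by(.data$probe_id) |>
        dplyr::group_modify(function(d, key) {
          a <- d$feret_normalized_distance[d$group == groups[1]]
          b <- d$feret_normalized_distance[d$group == groups[2]]
          if (length(a) == 0 || length(b) == 0) return(tibble::tibble())
          generics::tidy(compare_groups(a, b, "mann_whitney"))
        }) |>
        dplyr::ungroup()
    }
  })

  mobility <- stage("mobility_threshold", {
    src <- if (nrow(distance_tests) > 0) distance_tests else positional_tests
    if (nrow(src) == 0) {
      NULL
    } else {
      ann <- intrachromosomal_distance(study$annotation,
                                       genome = study$genome)
      probe_col <- if ("probe_id" %in% names(ann)) "probe_id" else "gene_symbol"
      per_locus <- ann |>
        dplyr::select("gene_symbol", dplyr::all_of(probe_col),
                      "distance_mbp") |>
        dplyr::inner_join(dplyr::select(src, "probe_id", "p_value"),
                          by = stats::setNames("probe_id", probe_col))
      if (nrow(per_locus) == 0) {
        NULL
      } else {
        mobility_threshold_analysis(
          per_locus, threshold_mbp = config$mobility_threshold_mbp,
          alpha = config$alpha_spatial)
      }
    }
  })

  structure(list(morphology = morphology, de_table = de_table,
                 chromosome_activity = chrom_activity, k_table = k_table,
                 k_correlation = k_correlation, radial_indices = radial,
                 positional_tests = positional_tests,
                 distance_pairs = distance_pairs,
                 distance_tests = distance_tests, mobility = mobility,
                 config = config),
            class = "rf_report")
}

#' @export
print.rf_report <- function(x, ...) {
  cat("<rf_report>\n")
  cat(sprintf("  morphology groups: %s\n",
              paste(x$morphology$group, collapse = ", ")))
  cat(sprintf("  differential transcripts: %d (%d up, %d down)\n",
              nrow(x$de_table), sum(x$de_table$direction == "up"),
              sum(x$de_table$direction == "down")))
  if (!is.null(x$k_correlation)) {
    cat(sprintf("  K_GOI vs K_mean: rho = %.3f (p = %.3g, n = %d)\n",
                x$k_correlation$rho, x$k_correlation$p_value,
                x$k_correlation$n))
  }
  cat(sprintf("  probes with positional tests: %d\n",
              nrow(x$positional_tests)))
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' One tidy TSV per analysis table plus a JSON summary (headline numbers
#' and the configuration). Deterministic: identical reports produce
#' identical bytes.
#'
#' @param report An `rf_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "rf_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(tbl, name) {
    if (!is.null(tbl) && nrow(tbl) > 0) {
      readr::write_tsv(tbl, file.path(dir, name))
    }
  }
  w(report$morphology, "morphology.tsv")
  w(report$de_table, "differential_expression.tsv")
  w(report$chromosome_activity, "chromosome_activity.tsv")
  w(report$k_table, "k_factors.tsv")
  w(report$radial_indices, "radial_indices.tsv")
  w(report$positional_tests, "positional_tests.tsv")
  w(report$distance_pairs, "distance_pairs.tsv")
  w(report$distance_tests, "distance_tests.tsv")
  if (!is.null(report$mobility)) {
    w(tibble::as_tibble(report$mobility), "mobility_threshold.tsv")
  }
  summary <- list(
    config = unclass(report$config),
    n_de = nrow(report$de_table),
    n_up = sum(report$de_table$direction == "up"),
    n_down = sum(report$de_table$direction == "down"),
    k_correlation = if (!is.null(report$k_correlation))
      unclass(report$k_correlation),
    mobility_contingency = if (!is.null(report$mobility))
      as.vector(attr(report$mobility, "contingency"))
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
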