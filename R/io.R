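# Readers and writers for the package's table schemas. Headers are matched
# case-insensitively; all positions are µm (spots, nuclei) or bp
# (annotation, expression). Parse failures name the file, column and rows.

read_table_checked <- function(path, required, delim, optional = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  names(tbl) <- tolower(names(tbl))
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    stop(basename(path), ": missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tbl
}

check_numeric_cols <- function(tbl, cols, path) {
  for (col in cols) {
    v <- suppressWarnings(as.numeric(tbl[[col]]))
    bad <- which(is.na(v) & !is.na(tbl[[col]]))
    if (length(bad) > 0) {
      stop(basename(path), ": non-numeric value in `", col, "` at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    if (anyNA(v)) {
      stop(basename(path), ": missing value in `", col, "` at row(s) ",
           paste(utils::head(which(is.na(v)), 5), collapse = ", "),
           call. = FALSE)
    }
    tbl[[col]] <- v
  }
  tbl
}

#' Read a spot table (CSV)
#'
#' Schema: `spot_id`, `nucleus_id`, `probe_id`, `x_um`, `y_um`, `z_um`,
#' optional `volume_um3`. Coordinates are µm in the lab frame.
#'
#' @param path CSV file path.
#' @return Spot tibble.
#' @export
read_spot_table <- function(path) {
  tbl <- read_table_checked(path, c("spot_id", "nucleus_id", "probe_id",
                                    "x_um", "y_um", "z_um"), ",")
  tbl <- check_numeric_cols(tbl, c("x_um", "y_um", "z_um"), path)
  dplyr::mutate(tbl, spot_id = as.character(.data$spot_id),
                nucleus_id = as.character(.data$nucleus_id),
                probe_id = as.character(.data$probe_id))
}

#' Read a nucleus table (CSV)
#'
#' Schema: `nucleus_id`, `group`, `center_x_um`, `center_y_um`,
#' `center_z_um`, `a_um`, `b_um`, `c_um`, `r11`..`r33` (row-major
#' principal-to-lab rotation), optional `volume_um3` and `feret_um`
#' overrides (defaults: exact ellipsoid volume and `2a`).
#'
#' @param path CSV file path.
#' @return Nucleus tibble (validated like [nucleus_model()] output).
#' @export
read_nucleus_table <- function(path) {
  rot_cols <- paste0("r", outer(1:3, 1:3, paste0))
  tbl <- read_table_checked(path, c("nucleus_id", "group", "center_x_um",
                                    "center_y_um", "center_z_um",
                                    "a_um", "b_um", "c_um", rot_cols), ",")
  tbl <- check_numeric_cols(tbl, c("center_x_um", "center_y_um",
                                   "center_z_um", "a_um", "b_um", "c_um",
                                   rot_cols,
                                   intersect(c("volume_um3", "feret_um"),
                                             names(tbl))), path)
  bad <- which(tbl$a_um < tbl$b_um | tbl$b_um < tbl$c_um | tbl$c_um <= 0)
  if (length(bad) > 0) {
    stop(basename(path), ": semi-axes not positive/descending at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (!"volume_um3" %in% names(tbl)) {
    tbl$volume_um3 <- 4 / 3 * pi * tbl$a_um * tbl$b_um * tbl$c_um
  }
  if (!"feret_um" %in% names(tbl)) tbl$feret_um <- 2 * tbl$a_um
  if (!"source" %in% names(tbl)) tbl$source <- "parametric"
  dplyr::mutate(tbl, nucleus_id = as.character(.data$nucleus_id),
                group = as.character(.data$group))
}

#' Read a normalized expression table (TSV)
#'
#' Schema: `probe_id`, `gene_symbol`, `chromosome`, `start_bp`, `end_bp`,
#' `mean_log2_mb`, `mean_log2_mt`, `p_raw`; `p_adj` and `fold_change` are
#' computed when absent (Benjamini-Hochberg, Mt/Mb direction).
#'
#' @param path TSV file path.
#' @param genome Optional genome definition; if given, chromosomes are
#'   validated against it.
#' @return Expression tibble.
#' @export
read_expression_table <- function(path, genome = NULL) {
  tbl <- read_table_checked(path, c("probe_id", "gene_symbol", "chromosome",
                                    "start_bp", "end_bp", "mean_log2_mb",
                                    "mean_log2_mt", "p_raw"), "\t")
  tbl <- check_numeric_cols(tbl, c("start_bp", "end_bp", "mean_log2_mb",
                                   "mean_log2_mt", "p_raw",
                                   intersect("p_adj", names(tbl))), path)
  bad <- which(tbl$start_bp >= tbl$end_bp)
  if (length(bad) > 0) {
    stop(basename(path), ": start_bp >= end_bp at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (!is.null(genome)) {
    unknown <- setdiff(unique(tbl$chromosome), genome$chromosome)
    if (length(unknown) > 0) {
      stop(basename(path), ": unknown chromosome(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  if (!"p_adj" %in% names(tbl)) tbl$p_adj <- bh_adjust(tbl$p_raw)
  if (!"fold_change" %in% names(tbl)) {
    tbl$fold_change <- fold_change(tbl$mean_log2_mb, tbl$mean_log2_mt)
  }
  tbl
}

#' Read a BED-like locus annotation (TSV)
#'
#' Columns `chromosome`, `start`, `end`, `gene_symbol` with 0-based
#' half-open coordinates (BED convention); converted once here to the
#' 1-based inclusive `gene_start_bp`/`gene_end_bp` used in reports.
#' Optional columns `probe_id` and `window_mbp` are carried through.
#'
#' @param path TSV file path.
#' @param genome Optional genome definition for chromosome validation.
#' @return Annotation tibble: `gene_symbol`, `chromosome`,
#'   `gene_start_bp`, `gene_end_bp` (+ optional carried columns).
#' @export
read_annotation <- function(path, genome = NULL) {
  tbl <- read_table_checked(path, c("chromosome", "start", "end",
                                    "gene_symbol"), "\t")
  tbl <- check_numeric_cols(tbl, c("start", "end"), path)
  bad <- which(tbl$start >= tbl$end | tbl$start < 0)
  if (length(bad) > 0) {
    stop(basename(path), ": invalid interval (start >= end or negative) ",
         "at row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(genome)) {
    unknown <- setdiff(unique(tbl$chromosome), genome$chromosome)
    if (length(unknown) > 0) {
      stop(basename(path), ": unknown chromosome(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  dplyr::transmute(tbl, .data$gene_symbol, .data$chromosome,
                   gene_start_bp = .data$start + 1, gene_end_bp = .data$end,
                   dplyr::across(dplyr::any_of(c("probe_id", "window_mbp"))))
}

#' Read a genome definition table (TSV)
#'
#' Columns `chromosome`, `length_bp`, `centromere_bp`.
#'
#' @param path TSV file path.
#' @return Genome tibble.
#' @export
read_genome <- function(path) {
  tbl <- read_table_checked(path, c("chromosome", "length_bp",
                                    "centromere_bp"), "\t")
  check_numeric_cols(tbl, c("length_bp", "centromere_bp"), path)
}

#' Write the tables of a (simulated or real) study to a fixture directory
#'
#' Emits the exact schemas the readers consume: `nuclei.csv`, `spots.csv`,
#' `expression.tsv`, `annotation.bed` (TSV, 0-based half-open),
#' `genome.tsv` and `manifest.json`.
#'
#' @param study List with `nuclei`, `spots`, `expression`, `annotation`,
#'   `genome` and optionally `manifest` (see [simulate_study()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(study$nuclei, file.path(dir, "nuclei.csv"))
  readr::write_csv(study$spots, file.path(dir, "spots.csv"))
  readr::write_tsv(study$expression, file.path(dir, "expression.tsv"))
  bed <- dplyr::transmute(study$annotation, .data$chromosome,
                          start = .data$gene_start_bp - 1,
                          end = .data$gene_end_bp, .data$gene_symbol,
                          dplyr::across(dplyr::any_of(c("probe_id",
                                                        "window_mbp"))))
  readr::write_tsv(bed, file.path(dir, "annotation.bed"))
  readr::write_tsv(study$genome, file.path(dir, "genome.tsv"))
  if (!is.null(study$manifest)) {
    jsonlite::write_json(study$manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' Read a study fixture directory back into memory
#'
#' @param dir Directory written by [write_study()] (or assembled by hand
#'   with the same file names).
#' @return List with `nuclei`, `spots`, `expression`, `annotation`,
#'   `genome`.
#' @export
read_study <- function(dir) {
  genome <- read_genome(file.path(dir, "genome.tsv"))
  list(
    nuclei = read_nucleus_table(file.path(dir, "nuclei.csv")),
    spots = read_spot_table(file.path(dir, "spots.csv")),
    expression = read_expression_table(file.path(dir, "expression.tsv"),
                                       genome = genome),
    annotation = read_annotation(file.path(dir, "annotation.bed"),
                                 genome = genome),
    genome = genome
  )
}
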