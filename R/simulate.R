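#' Morphology presets for simulated nuclear populations
#'
#' Packaged mean +/- SD of nuclear volume (µm³) and flattening for the two
#' study populations: proliferating myoblasts (`"Mb"`: 970.9 +/- 341.3 µm³,
#' flattening -0.771 +/- 0.286) and differentiated myotubes (`"Mt"`:
#' 811.1 +/- 231.1 µm³, -0.935 +/- 0.308). `"custom"` presets take all
#' four parameters explicitly.
#'
#' @param name `"Mb"`, `"Mt"` or `"custom"`.
#' @param volume_mean,volume_sd Volume distribution parameters (µm³).
#' @param flattening_mean,flattening_sd Flattening distribution parameters.
#' @return One-row tibble: `name`, `volume_mean`, `volume_sd`,
#'   `flattening_mean`, `flattening_sd`.
#' @examples
#' morphology_preset("Mt")
#' @export
morphology_preset <- function(name = c("Mb", "Mt", "custom"),
                              volume_mean = NULL, volume_sd = NULL,
                              flattening_mean = NULL, flattening_sd = NULL) {
  name <- match.arg(name)
  params <- switch(name,
    Mb = list(v = 970.9, vs = 341.3, f = -0.771, fs = 0.286),
    Mt = list(v = 811.1, vs = 231.1, f = -0.935, fs = 0.308),
    custom = list(v = volume_mean, vs = volume_sd,
                  f = flattening_mean, fs = flattening_sd)
  )
  if (any(vapply(params, is.null, logical(1)))) {
    stop("custom presets need all four parameters", call. = FALSE)
  }
  if (params$v <= 0 || params$vs < 0 || params$fs < 0 ||
      params$f <= -1 || params$f >= 1) {
    stop("invalid preset: need volume_mean > 0, SDs >= 0, ",
         "flattening_mean in (-1, 1)", call. = FALSE)
  }
  tibble::tibble(name = name, volume_mean = params$v, volume_sd = params$vs,
                 flattening_mean = params$f, flattening_sd = params$fs)
}

# truncated-normal sampler by inverse CDF (robust even when the kept mass
# is a far tail of the untruncated normal)
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  pa <- stats::pnorm(lower, mean, sd)
  pb <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, pa, pb), mean, sd)
}

# mean of a normal(mu, sd) truncated to (lower, upper)
truncnorm_mean <- function(mu, sd, lower, upper) {
  a <- (lower - mu) / sd
  b <- (upper - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# location parameter such that the truncated normal's mean equals `target`.
# Needed because the flattening presets sit close to the physical bound at
# -1: naive truncation would bias the population mean away from the preset.
truncnorm_location <- function(target, sd, lower, upper) {
  if (sd == 0) return(target)
  f <- function(mu) truncnorm_mean(mu, sd, lower, upper) - target
  lo <- target
  hi <- target
  for (i in 1:60) {
    if (is.finite(f(lo)) && f(lo) < 0) break
    lo <- lo - sd / 2
  }
  for (i in 1:60) {
    if (is.finite(f(hi)) && f(hi) > 0) break
    hi <- hi + sd / 2
  }
  if (!(is.finite(f(lo)) && is.finite(f(hi)) && f(lo) < 0 && f(hi) > 0)) {
    stop("cannot match the preset mean under the truncation bounds",
         call. = FALSE)
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

# uniform random rotation matrices (via QR of a Gaussian matrix)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

#' Simulate a population of nuclei from a morphology preset
#'
#' Draws volume and flattening from truncated normals (volume > 50 µm³,
#' flattening in (-0.99, 0.5)). The underlying location parameter is
#' solved so the *truncated* distribution's mean equals the preset mean —
#' the flattening presets lie close to the physical lower bound at -1, so
#' naive truncation would otherwise shift the population mean visibly.
#' Each nucleus is realized as an oblate
#' spheroid with equal equatorial axes `a = b` and polar axis
#' `c = a (1 + f)`, so the two preset quantities fully determine the
#' shape: `a = (3 V / (4 pi (1 + f)))^(1/3)`. Orientations are uniform
#' over rotations; centers are at the origin (positions are only ever used
#' relative to the nucleus). Output is deterministic for a fixed seed.
#'
#' @param n Number of nuclei (>= 1).
#' @param preset A [morphology_preset()] row (or preset name).
#' @param seed Optional integer seed.
#' @param id_prefix Prefix for generated nucleus ids.
#' @return Nucleus tibble (see [nucleus_model()]) with `n` rows and a
#'   `group` column set to the preset name.
#' @export
simulate_nuclei <- function(n, preset = morphology_preset("Mb"), seed = NULL,
                            id_prefix = NULL) {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (is.character(preset)) preset <- morphology_preset(preset)
  if (!is.null(seed)) set.seed(seed)
  mu_v <- truncnorm_location(preset$volume_mean, preset$volume_sd,
                             lower = 50, upper = Inf)
  mu_f <- truncnorm_location(preset$flattening_mean, preset$flattening_sd,
                             lower = -0.99, upper = 0.5)
  v <- rtruncnorm(n, mu_v, preset$volume_sd, lower = 50)
  f <- rtruncnorm(n, mu_f, preset$flattening_sd, lower = -0.99, upper = 0.5)
  a <- (3 * v / (4 * pi * (1 + f)))^(1 / 3)
  c_ax <- a * (1 + f)
  if (is.null(id_prefix)) id_prefix <- preset$name
  rows <- purrr::map(seq_len(n), function(i) {
    R <- random_rotation()
    ax <- c(a[i], a[i], c_ax[i])
    if (c_ax[i] > a[i]) { # prolate draw (f > 0): reorder axes descending
      ax <- c(c_ax[i], a[i], a[i])
      R <- R[, c(3, 1, 2)] # cyclic permutation keeps det = +1
    }
    nucleus_model(sprintf("%s_%04d", id_prefix, i), semi_axes = ax,
                  orientation = R, group = preset$name,
                  volume = 4 / 3 * pi * prod(ax), feret = 2 * ax[1])
  })
  dplyr::bind_rows(rows)
}

#' Simulate FISH spots with a controlled radial law
#'
#' Draws each spot's volume-mode distance index from a Beta distribution
#' (the "radial law"), converts it to a radial ratio `rho = v^(1/3)`,
#' picks a direction uniformly on the sphere in the nucleus principal
#' frame and places the spot at `rho` times the boundary radius along that
#' direction. By construction every spot satisfies `rho <= 1`, and
#' `Beta(1, 1)` yields spots uniform in nuclear volume.
#'
#' @param nuclei Nucleus tibble (e.g. from [simulate_nuclei()]).
#' @param probe_id Probe label written to every generated spot.
#' @param alpha,beta Beta shape parameters of the radial law (> 0).
#' @param spots_per_nucleus Signals per nucleus (2 for a diploid locus).
#' @param seed Optional integer seed.
#' @return Spot tibble: `spot_id`, `nucleus_id`, `probe_id`, `x_um`,
#'   `y_um`, `z_um`.
#' @export
simulate_spots <- function(nuclei, probe_id, alpha = 1, beta = 1,
                           spots_per_nucleus = 2, seed = NULL) {
  assert_nucleus_tbl(nuclei)
  if (nrow(nuclei) == 0) stop("`nuclei` must be non-empty", call. = FALSE)
  if (alpha <= 0 || beta <= 0) {
    stop("Beta shape parameters must be > 0", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n_total <- nrow(nuclei) * spots_per_nucleus
  v <- stats::rbeta(n_total, alpha, beta)
  rho <- v^(1 / 3)
  u <- matrix(stats::rnorm(3 * n_total), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  k <- 0
  rows <- purrr::map(seq_len(nrow(nuclei)), function(i) {
    row <- nuclei[i, ]
    R <- nucleus_rotation(row)
    ax <- nucleus_axes(row)
    ctr <- nucleus_center(row)
    idx <- (i - 1) * spots_per_nucleus + seq_len(spots_per_nucleus)
    ui <- u[idx, , drop = FALSE]
    # boundary radius along each direction in the principal frame
    rb <- 1 / sqrt(rowSums(sweep(ui, 2, ax, "/")^2))
    pts_principal <- ui * (rho[idx] * rb)
    pts <- sweep(pts_principal %*% t(R), 2, ctr, "+")
    tibble::tibble(
      spot_id = sprintf("%s_%s_s%d", row$nucleus_id, probe_id,
                        seq_len(spots_per_nucleus)),
      nucleus_id = row$nucleus_id, probe_id = probe_id,
      x_um = pts[, 1], y_um = pts[, 2], z_um = pts[, 3])
  })
  dplyr::bind_rows(rows)
}

#' Simulate a block-correlated expression table
#'
#' Emulates the ~1 Mbp ("TAD-like") correlation structure of expression
#' change: genes are placed uniformly along chromosomes and partitioned
#' into consecutive blocks of `block_size_mbp`; a subset of blocks is
#' designated differentially expressed (DE) until about `fraction_de` of
#' genes is covered. Each DE block receives a shared latent log2 effect
#' `b ~ Normal(0, block_effect_sd)` conditioned on
#' `|b| >= min_block_effect`, so that "designated DE" genuinely means a
#' detectable (at least ~2.8-fold by default) shared change; every gene
#' adds independent `Normal(0, gene_noise_sd)` noise to its true log2 fold
#' change. Group means and raw p-values are then generated consistently
#' from a two-sample model: `replicates` array replicates per group with
#' residual SD `replicate_sd`, Welch t-test per gene.
#'
#' @param n_genes Number of genes. The default (20000) gives a realistic
#'   protein-coding gene density (~6.5 genes/Mbp) over the packaged
#'   genome, so ~1 Mbp neighbourhoods hold a handful of genes as they do
#'   in real annotation.
#' @param genome Genome definition for gene placement (default
#'   [genome_definition()]).
#' @param block_size_mbp Block ("TAD") size in Mbp, default 1.0.
#' @param block_effect_sd SD (bits) of the latent DE block effect; 0 means
#'   no block effects at all.
#' @param gene_noise_sd Per-gene log2 noise SD (bits).
#' @param fraction_de Target fraction of genes in DE blocks.
#' @param min_block_effect Detectability floor (bits) for a DE block's
#'   latent effect (ignored when `block_effect_sd = 0`).
#' @param replicates Array replicates per group for p-value generation.
#' @param replicate_sd Residual log2 SD across replicates.
#' @param baseline_mean,baseline_sd Baseline log2 intensity distribution.
#' @param seed Optional integer seed.
#' @return Expression tibble: `probe_id`, `gene_symbol`, `chromosome`,
#'   `start_bp`, `end_bp`, `mean_log2_mb`, `mean_log2_mt`, `fold_change`,
#'   `p_raw`, `p_adj`, plus generator truth columns `block_id`,
#'   `de_block`, `true_log2fc`.
#' @export
simulate_expression <- function(n_genes = 20000, genome = genome_definition(),
                                block_size_mbp = 1, block_effect_sd = 2,
                                gene_noise_sd = 0.2, fraction_de = 0.1,
                                min_block_effect = 1.5, replicates = 3,
                                replicate_sd = 0.1, baseline_mean = 8,
                                baseline_sd = 2, seed = NULL) {
  if (n_genes < 1 || block_size_mbp <= 0 || gene_noise_sd < 0 ||
      block_effect_sd < 0 || fraction_de < 0 || fraction_de > 1 ||
      replicates < 2 || replicate_sd < 0) {
    stop("invalid expression simulation configuration", call. = FALSE)
  }
  if (any(block_size_mbp * 1e6 > genome$length_bp)) {
    stop("`block_size_mbp` exceeds the shortest chromosome", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  chromosome <- sample(genome$chromosome, n_genes, replace = TRUE,
                       prob = genome$length_bp)
  len <- genome$length_bp[match(chromosome, genome$chromosome)]
  gene_width <- 2e4
  start_bp <- floor(stats::runif(n_genes, 0, len - gene_width))
  end_bp <- start_bp + gene_width
  mid <- (start_bp + end_bp) / 2
  block_id <- paste0(chromosome, "_b", floor(mid / (block_size_mbp * 1e6)))

  # designate whole blocks DE until ~fraction_de of genes is covered
  blocks <- sample(unique(block_id))
  block_sizes <- table(block_id)[blocks]
  target <- round(fraction_de * n_genes)
  n_covered <- cumsum(as.integer(block_sizes))
  n_de_blocks <- if (target == 0) 0 else which.min(abs(n_covered - target))
  de_blocks <- if (n_de_blocks == 0) character(0) else blocks[seq_len(n_de_blocks)]
  de_block <- block_id %in% de_blocks

  effect_of <- function(k) {
    if (block_effect_sd == 0 || k == 0) return(numeric(k))
    out <- numeric(0)
    while (length(out) < k) {
      x <- stats::rnorm(2 * k + 10, 0, block_effect_sd)
      out <- c(out, x[abs(x) >= min_block_effect])
    }
    out[seq_len(k)]
  }
  block_effects <- stats::setNames(effect_of(length(de_blocks)), de_blocks)
  true_log2fc <- ifelse(de_block, block_effects[block_id], 0) +
    stats::rnorm(n_genes, 0, gene_noise_sd)

  baseline <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
  if (replicate_sd == 0) {
    # noiseless replicates: means are exact, no sampling evidence either way
    mean_mb <- baseline
    mean_mt <- baseline + true_log2fc
    p_raw <- ifelse(true_log2fc == 0, 1, 0)
  } else {
    mb_reps <- matrix(stats::rnorm(n_genes * replicates, baseline,
                                   replicate_sd),
                      n_genes, replicates)
    mt_reps <- matrix(stats::rnorm(n_genes * replicates,
                                   baseline + true_log2fc, replicate_sd),
                      n_genes, replicates)
    mean_mb <- rowMeans(mb_reps)
    mean_mt <- rowMeans(mt_reps)
    p_raw <- row_welch_p(mt_reps, mb_reps)
  }

  tibble::tibble(
    probe_id = sprintf("probe_%05d", seq_len(n_genes)),
    gene_symbol = sprintf("GENE%05d", seq_len(n_genes)),
    chromosome = chromosome, start_bp = start_bp, end_bp = end_bp,
    mean_log2_mb = mean_mb, mean_log2_mt = mean_mt,
    fold_change = fold_change(mean_mb, mean_mt),
    p_raw = p_raw, p_adj = bh_adjust(p_raw),
    block_id = block_id, de_block = de_block,
    true_log2fc = true_log2fc
  )
}

# vectorized two-sided Welch t-test p-values across rows
row_welch_p <- function(x, y) {
  nx <- ncol(x)
  ny <- ncol(y)
  mx <- rowMeans(x)
  my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  tstat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * stats::pt(-abs(tstat), df)
}

#' Sample genes of interest from a simulated expression table
#'
#' Mirrors the study's locus panel: a mix of genes from differentially
#' expressed blocks and genes from stable blocks, each drawn from a
#' distinct block that holds at least one other gene (so the
#' neighbourhood K mean is defined). Requires the generator truth column
#' `de_block`, i.e. a [simulate_expression()] output.
#'
#' @param records Simulated expression tibble.
#' @param n_goi Panel size (default 11).
#' @param de_fraction Fraction of the panel drawn from DE blocks
#'   (default 8/11, the changed:stable ratio of the study's panel).
#' @return Character vector of `gene_symbol`s.
#' @export
sample_goi <- function(records, n_goi = 11, de_fraction = 8 / 11) {
  if (!"de_block" %in% names(records)) {
    stop("`records` must be a simulate_expression() output (needs `de_block`)",
         call. = FALSE)
  }
  block_n <- table(records$block_id)
  eligible <- records[block_n[records$block_id] >= 2, ]
  pick <- function(pool, k) {
    pool <- pool[sample.int(nrow(pool)), ]
    pool <- pool[!duplicated(pool$block_id), ]
    if (nrow(pool) < k) {
      stop("not enough distinct blocks to sample genes of interest",
           call. = FALSE)
    }
    pool$gene_symbol[seq_len(k)]
  }
  n_de <- round(n_goi * de_fraction)
  de_pool <- eligible[eligible$de_block, ]
  stable_pool <- eligible[!eligible$de_block, ]
  if (nrow(de_pool) == 0) n_de <- 0 # no DE blocks simulated
  c(if (n_de > 0) pick(de_pool, n_de),
    pick(stable_pool, n_goi - n_de))
}

#' Rasterize a nucleus model into a voxel mask
#'
#' Sets every voxel whose center lies inside the model ellipsoid, using
#' the default confocal acquisition geometry (0.13 µm in-plane, 0.2 µm
#' z-steps). The grid is sized to the rotated ellipsoid's bounding box
#' plus one voxel of padding; the mask records its µm origin so fitted
#' centers remain comparable.
#'
#' @param nucleus One-row nucleus tibble.
#' @param spacing Voxel spacing `(dx, dy, dz)` in µm.
#' @param min_voxels Minimum voxels for a usable mask (else a resolution
#'   error).
#' @return A [voxel_mask()].
#' @export
voxelize <- function(nucleus, spacing = c(0.13, 0.13, 0.2), min_voxels = 30) {
  assert_nucleus_tbl(nucleus)
  stopifnot(nrow(nucleus) == 1)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0)) {
    stop("`spacing` must be three positive values", call. = FALSE)
  }
  R <- nucleus_rotation(nucleus)
  ax <- nucleus_axes(nucleus)
  ctr <- nucleus_center(nucleus)
  # half-extent of the rotated ellipsoid along lab axis e_j:
  # max over surface of |x . e_j| = |diag(a) R^T e_j|
  half <- sqrt(colSums((ax * t(R))^2))
  lo <- ctr - half - spacing
  n_vox <- ceiling((2 * half + 2 * spacing) / spacing) + 1
  xs <- lo[1] + (seq_len(n_vox[1]) - 1) * spacing[1]
  ys <- lo[2] + (seq_len(n_vox[2]) - 1) * spacing[2]
  zs <- lo[3] + (seq_len(n_vox[3]) - 1) * spacing[3]
  arr <- array(FALSE, dim = c(length(zs), length(ys), length(xs)))
  inv_ax <- 1 / ax
  for (iz in seq_along(zs)) {
    # principal-frame coordinates of all voxel centers in this z-slice
    g <- expand.grid(y = ys, x = xs)
    d <- cbind(g$x - ctr[1], g$y - ctr[2], zs[iz] - ctr[3])
    v <- d %*% R
    s <- (v[, 1] * inv_ax[1])^2 + (v[, 2] * inv_ax[2])^2 +
      (v[, 3] * inv_ax[3])^2
    arr[iz, , ] <- matrix(s <= 1, length(ys), length(xs))
  }
  if (sum(arr) < min_voxels) {
    stop(sprintf("voxelizing nucleus '%s' at spacing (%g, %g, %g) sets %d voxels (< %d): resolution too coarse",
                 nucleus$nucleus_id, spacing[1], spacing[2], spacing[3],
                 sum(arr), min_voxels), call. = FALSE)
  }
  voxel_mask(arr, spacing = spacing, origin = lo)
}

#' Simulate a complete Mb/Mt FISH + expression study
#'
#' Convenience generator producing every table the pipeline consumes:
#' Mb and Mt nucleus populations from the packaged morphology presets,
#' per-probe FISH spots with condition-specific radial laws, a
#' block-correlated expression table, the locus annotation and the genome
#' definition. All randomness derives from `seed` (split per stage).
#'
#' @param n_nuclei Nuclei per group (default 80, the study's per-group
#'   imaging scale).
#' @param probes Tibble with columns `probe_id`, `alpha_mb`, `beta_mb`,
#'   `alpha_mt`, `beta_mt` (per-condition radial laws). The default ships
#'   one repositioning probe and one stable control.
#' @param spots_per_nucleus Signals per nucleus and probe.
#' @param seed Integer seed.
#' @param expression_args List of overrides passed to
#'   [simulate_expression()].
#' @return List: `nuclei`, `spots`, `expression`, `annotation`, `genome`,
#'   `manifest` (config echo).
#' @export
simulate_study <- function(n_nuclei = 80,
                           probes = default_probe_laws(),
                           spots_per_nucleus = 2, seed = 1,
                           expression_args = list()) {
  stopifnot(all(c("probe_id", "alpha_mb", "beta_mb", "alpha_mt", "beta_mt")
                %in% names(probes)))
  nuc_mb <- simulate_nuclei(n_nuclei, morphology_preset("Mb"), seed = seed)
  nuc_mt <- simulate_nuclei(n_nuclei, morphology_preset("Mt"), seed = seed + 1)
  nuclei <- dplyr::bind_rows(nuc_mb, nuc_mt)
  spots <- purrr::pmap(probes, function(probe_id, alpha_mb, beta_mb,
                                        alpha_mt, beta_mt, ...) {
    probe_seed <- seed + 100 + match(probe_id, probes$probe_id)
    dplyr::bind_rows(
      simulate_spots(nuc_mb, probe_id, alpha_mb, beta_mb,
                     spots_per_nucleus, seed = probe_seed),
      simulate_spots(nuc_mt, probe_id, alpha_mt, beta_mt,
                     spots_per_nucleus, seed = probe_seed + 1000)
    )
  }) |> dplyr::bind_rows()
  expression <- do.call(
    simulate_expression,
    utils::modifyList(list(seed = seed + 5000), expression_args))
  list(nuclei = nuclei, spots = spots, expression = expression,
       annotation = goi_annotation(), genome = genome_definition(),
       manifest = list(n_nuclei = n_nuclei, spots_per_nucleus =
                         spots_per_nucleus, seed = seed,
                       probes = probes, expression_args = expression_args,
                       package_version = as.character(
                         utils::packageVersion("radfish"))))
}

#' Default per-probe radial laws for simulated studies
#'
#' One probe that repositions outward on differentiation (central in Mb,
#' peripheral in Mt) and one stable mid-nuclear control.
#'
#' @return Tibble usable as the `probes` argument of [simulate_study()].
#' @export
default_probe_laws <- function() {
  tibble::tibble(
    probe_id = c("SHIFTED", "STABLE"),
    alpha_mb = c(2, 2), beta_mb = c(5, 2),
    alpha_mt = c(5, 2), beta_mt = c(2, 2)
  )
}
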