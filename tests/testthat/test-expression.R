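test_that("fold change follows the Mt-over-Mb convention", {
  expect_equal(fold_change(5, 5), 1)
  expect_equal(fold_change(5, 6), 2)
  expect_equal(fold_change(5, 3), 0.25)
  expect_error(fold_change(NA, 5), "finite")
})

test_that("bh_adjust reproduces the step-up adjustment", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(61)
  for (i in 1:100) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), stepup_bh(p), tolerance = 1e-15)
  }
})

test_that("differential filter applies twofold + alpha rules", {
  toy <- tibble::tibble(
    gene_symbol = paste0("g", 1:5), chromosome = "chr1",
    start_bp = 1:5, end_bp = 2:6,
    fold_change = c(2.5, 1.8, 0.4, 3.0, 0.5),
    p_adj = c(0.005, 0.001, 0.005, 0.02, 0.009))
  de <- differential_filter(toy)
  expect_equal(sum(de$direction == "up"), 1)
  expect_equal(sum(de$direction == "down"), 2)
  expect_setequal(de$gene_symbol, c("g1", "g3", "g5"))
  expect_equal(nrow(differential_filter(toy[0, ])), 0)
  expect_equal(nrow(differential_filter(
    dplyr::mutate(toy, fold_change = 1))), 0)
  expect_error(differential_filter(dplyr::select(toy, -p_adj)), "p_adj")
})

test_that("differential filter matches a row-by-row oracle on random tables", {
  set.seed(67)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    tbl <- tibble::tibble(fold_change = 2^rnorm(n, 0, 1.5),
                          p_adj = runif(n)^2)
    de <- differential_filter(tbl)
    manual <- sum(vapply(seq_len(n), function(j) {
      fc <- tbl$fold_change[j]
      p <- tbl$p_adj[j]
      (fc >= 2 && p < 0.01) || (fc <= 0.5 && p < 0.01)
    }, logical(1)))
    expect_equal(nrow(de), manual)
  }
})

test_that("change coefficient and chromosome grouping follow the C_co rules", {
  expect_equal(change_coefficient(10, 5), 2)
  expect_equal(change_coefficient(0, 5), 0)
  expect_equal(change_coefficient(3, 0), Inf)
  expect_true(is.nan(change_coefficient(0, 0)))
  expect_error(change_coefficient(-1, 2), "non-negative")
  expect_equal(as.character(classify_chromosome(c(0.4, 1.0, 2.0, Inf))),
               c("up_dominant", "intermediate", "down_dominant", "undefined"))
  # boundaries fall to the dominant groups
  expect_equal(as.character(classify_chromosome(c(0.5, 1.5))),
               c("up_dominant", "down_dominant"))
})

test_that("chromosome_activity covers every chromosome with a DE transcript", {
  de <- tibble::tibble(
    chromosome = c("chr1", "chr1", "chr1", "chr2", "chr3", "chr3"),
    direction = c("up", "up", "down", "down", "up", "down"))
  act <- chromosome_activity(de)
  expect_equal(nrow(act), 3)
  expect_equal(act$c_co[act$chromosome == "chr1"], 0.5)
  expect_equal(act$c_co[act$chromosome == "chr2"], Inf)
  expect_equal(as.character(act$group[act$chromosome == "chr2"]),
               "undefined")
  expect_equal(sum(act$n_up + act$n_down), nrow(de))
})

test_that("K factor is the symmetric log2 change magnitude", {
  expect_equal(k_factor(2), 1)
  expect_equal(k_factor(0.5), 1)
  expect_equal(k_factor(1), 0)
  expect_error(k_factor(0), "> 0")
  set.seed(71)
  f <- 10^runif(1e4, -3, 3)
  expect_equal(k_factor(f), k_factor(1 / f), tolerance = 1e-12)
  expect_true(all(k_factor(f) >= 0))
})

test_that("neighbourhood K mean averages the window, excluding the GOI", {
  rec <- tibble::tibble(
    gene_symbol = c("GOI", paste0("n", 1:4)),
    chromosome = "chr1",
    start_bp = c(5e6, 5.1e6, 5.2e6, 4.8e6, 4.9e6),
    end_bp = c(5e6, 5.1e6, 5.2e6, 4.8e6, 4.9e6) + 1e4,
    fold_change = c(8, 2, 0.5, 1, 4))
  out <- neighborhood_k_mean(rec, "GOI", window_mbp = 1)
  expect_equal(out$k_goi, 3)
  expect_equal(out$k_mean, (1 + 1 + 0 + 2) / 4)
  expect_equal(out$n_neighbors, 4)
  with_goi <- neighborhood_k_mean(rec, "GOI", window_mbp = 1,
                                  include_goi = TRUE)
  expect_equal(with_goi$k_mean, (3 + 1 + 1 + 0 + 2) / 5)
  # narrow window: empty neighbourhood is NA and flagged
  expect_warning(empty <- neighborhood_k_mean(rec, "GOI", window_mbp = 1e-4),
                 "empty neighbourhood")
  expect_true(is.na(empty$k_mean))
  expect_equal(empty$n_neighbors, 0)
  expect_error(neighborhood_k_mean(rec, "missing_gene"), "not found")
})

test_that("simple K means: {1,2,3} -> 2", {
  rec <- tibble::tibble(
    gene_symbol = c("G", "a", "b", "c"), chromosome = "chrQ",
    start_bp = c(1e6, 1.1e6, 1.2e6, 1.3e6),
    end_bp = c(1e6, 1.1e6, 1.2e6, 1.3e6) + 1e3,
    fold_change = c(1, 2, 4, 8))
  out <- neighborhood_k_mean(rec, "G", window_mbp = 1)
  expect_equal(out$k_mean, 2)
})

test_that("Spearman correlation with Fisher-z CI matches the closed form", {
  inc <- tibble::tibble(k_goi = 1:10, k_mean = (1:10)^2)
  expect_equal(correlate_kgoi_kmean(inc)$rho, 1)
  dec <- tibble::tibble(k_goi = 1:10, k_mean = -(1:10))
  expect_equal(correlate_kgoi_kmean(dec)$rho, -1)
  # rho = 0.83 at n = 11 gives the Fisher-z interval ~ (0.46, 0.96)
  z <- atanh(0.83) + c(-1, 1) * qnorm(0.975) / sqrt(11 - 3)
  expect_equal(tanh(z), c(0.4583, 0.9546), tolerance = 1e-3)
  pairs <- tibble::tibble(
    k_goi = c(0.1, 0.4, 0.9, 1.4, 1.8, 2.2, 2.7, 3.1, 3.6, 4.0, 4.4),
    k_mean = c(0.3, 0.2, 1.1, 1.0, 2.1, 1.7, 2.9, 2.6, 3.8, 3.5, 4.6))
  res <- correlate_kgoi_kmean(pairs)
  expect_equal(res$ci_low, tanh(atanh(res$rho) - qnorm(0.975) / sqrt(8)))
  expect_equal(res$ci_high, tanh(atanh(res$rho) + qnorm(0.975) / sqrt(8)))
  expect_error(correlate_kgoi_kmean(inc[1:3, ]), "at least 4")
  td <- tidy(correlate_kgoi_kmean(inc))
  expect_named(td, c("rho", "ci_low", "ci_high", "p_value", "n",
                     "conf_level", "method"))
})

test_that("intrachromosomal distance uses the gene midpoint in Mbp", {
  ann <- tibble::tibble(gene_symbol = "G", chromosome = "chr2",
                        gene_start_bp = 161e6, gene_end_bp = 163e6,
                        centromere_position_bp = 93e6)
  expect_equal(intrachromosomal_distance(ann)$distance_mbp, 69)
  at_cen <- dplyr::mutate(ann, gene_start_bp = 92.5e6, gene_end_bp = 93.5e6)
  expect_equal(intrachromosomal_distance(at_cen)$distance_mbp, 0)
  genome <- tibble::tibble(chromosome = "chr2", length_bp = 242e6,
                           centromere_bp = 93e6)
  expect_equal(intrachromosomal_distance(ann, genome)$distance_mbp, 69)
  bad <- dplyr::mutate(ann, chromosome = "chr99")
  expect_error(intrachromosomal_distance(bad, genome), "chr99")
})
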