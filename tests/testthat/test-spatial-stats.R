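test_that("spot_pair_distance is Euclidean and nucleus-safe", {
  a <- make_spot(0, 0, 0, "a")
  expect_equal(spot_pair_distance(a, make_spot(3, 4, 0, "b")), 5)
  expect_equal(spot_pair_distance(a, a), 0)
  expect_equal(spot_pair_distance(make_spot(1, 1, 1, "a"),
                                  make_spot(2, 2, 2, "b")), sqrt(3))
  other <- make_spot(1, 1, 1, "c", nucleus_id = "n2")
  expect_error(spot_pair_distance(a, other), "different nuclei")
})

test_that("Feret normalization is a plain ratio with guards", {
  expect_equal(normalize_by_feret(3, 12), 0.25)
  expect_equal(normalize_by_feret(12, 12), 1)
  expect_error(normalize_by_feret(3, 0), "> 0")
})

test_that("Feret-normalized distances are invariant to nucleus scaling", {
  set.seed(31)
  for (i in 1:10) {
    nuc <- rand_nucleus("n1", center = c(0, 0, 0))
    s <- runif(1, 0.2, 5)
    p1 <- runif(3, -1, 1)
    p2 <- runif(3, -1, 1)
    d1 <- sqrt(sum((p1 - p2)^2)) / nuc$feret_um
    scaled <- nucleus_model("n1s", semi_axes = c(nuc$a_um, nuc$b_um,
                                                 nuc$c_um) * s)
    d2 <- sqrt(sum((s * p1 - s * p2)^2)) / scaled$feret_um
    expect_equal(d2, d1, tolerance = 1e-9)
  }
})

test_that("locus_centromere_distances pairs within nuclei", {
  nuc <- nucleus_model("n1", semi_axes = c(6, 5, 4))
  spots <- dplyr::bind_rows(
    make_spot(0, 0, 0, "g1", probe_id = "GENE"),
    make_spot(3, 0, 0, "c1", probe_id = "CEN"),
    make_spot(0, 4, 0, "c2", probe_id = "CEN"))
  nearest <- locus_centromere_distances(spots, nuc, "GENE", "CEN")
  expect_equal(nrow(nearest), 1)
  expect_equal(nearest$centromere_spot_id, "c1")
  expect_equal(nearest$raw_distance_um, 3)
  expect_equal(nearest$feret_normalized_distance, 3 / 12)
  all_pairs <- locus_centromere_distances(spots, nuc, "GENE", "CEN",
                                          pairing = "all")
  expect_equal(nrow(all_pairs), 2)
})

test_that("Mann-Whitney comparison matches its printed small-sample cases", {
  same <- compare_groups(1:5, 1:5)
  expect_equal(same$statistic, 12.5)
  expect_gte(same$p_value, 0.99)
  sep <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$statistic, 0)
  expect_equal(sep$p_value, 0.1)
  expect_identical(sep$method, "exact_enumeration")
  expect_error(compare_groups(numeric(0), 1:3), "non-empty")
})

test_that("exact Mann-Whitney p agrees with wilcox.test on 50 tie-free cases", {
  set.seed(47)
  for (i in 1:50) {
    n1 <- sample(2:8, 1)
    n2 <- sample(2:8, 1)
    a <- rnorm(n1)
    b <- rnorm(n2, mean = runif(1, -1, 1))
    ours <- compare_groups(a, b)
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$statistic, unname(ref$statistic))
  }
})

test_that("large-sample comparisons detect a known shift", {
  set.seed(53)
  a <- rnorm(300)
  b <- rnorm(300, mean = 0.5)
  expect_lt(compare_groups(a, b)$p_value, 0.001)
  expect_identical(compare_groups(a, b)$method, "normal_approximation")
  tt <- compare_groups(a, b, test = "t_test")
  expect_lt(tt$p_value, 0.001)
  expect_error(compare_groups(1, c(1, 2), test = "t_test"), "at least 2")
})

test_that("tidy/glance produce one-row summaries of comparisons", {
  cmp <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  td <- tidy(cmp)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_named(td, c("test_name", "statistic", "p_value", "n_a", "n_b",
                     "mean_a", "sd_a", "mean_b", "sd_b", "method"))
  expect_equal(glance(cmp), td)
})

test_that("mobility threshold analysis tabulates the 2x2 contingency", {
  toy <- tibble::tibble(
    gene_symbol = c("A", "B", "C", "D"),
    distance_mbp = c(60, 70, 10, 20),
    p_value = c(0.001, 0.001, 0.4, 0.4))
  res <- mobility_threshold_analysis(toy)
  tab <- attr(res, "contingency")
  expect_equal(as.vector(tab), c(2, 0, 0, 2))
  expect_equal(sum(tab), nrow(toy))
  g <- glance(res)
  expect_equal(g$above_sig, 2)
  expect_equal(g$below_ns, 2)

  below <- mobility_threshold_analysis(
    dplyr::mutate(toy, distance_mbp = c(10, 20, 30, 40)))
  expect_equal(sum(attr(below, "contingency")["TRUE", ]), 0)
  zero <- mobility_threshold_analysis(toy, threshold_mbp = 0)
  expect_true(all(zero$above_threshold))
  expect_error(
    mobility_threshold_analysis(
      dplyr::mutate(toy, distance_mbp = c(60, NA, 10, 20))), "B")
})

test_that("fusion index is a guarded ratio", {
  expect_equal(fusion_index(77, 100), 0.77)
  expect_equal(fusion_index(0, 100), 0)
  expect_error(fusion_index(101, 100), "\\[0, n_total_nuclei\\]")
  expect_error(fusion_index(1, 0), ">= 1")
})
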