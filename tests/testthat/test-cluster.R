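mk_stat <- function(v, valid = NULL, n = 50, labels = NULL) {
  V <- nrow(v)
  labels <- labels %||% sprintf("R%03d", seq_len(V))
  if (is.null(valid)) {
    valid <- matrix(TRUE, V, V); diag(valid) <- FALSE
  }
  structure(list(values = v, valid = valid, statistic_kind = "partial_r",
                 covariate_names = character(0), n_subjects = n,
                 region_labels = labels), class = "fr_edge_stat")
}

test_that("suprathreshold selection is strict and mask-aware", {
  v <- matrix(0, 5, 5)
  cfg <- cluster_config(0.3, "positive", 10, seed = 1)
  expect_equal(nrow(suprathreshold_edges(mk_stat(v), cfg)), 0)

  v[2, 4] <- v[4, 2] <- 0.5
  got <- suprathreshold_edges(mk_stat(v), cluster_config(0.32, "positive", 10))
  expect_equal(got$i, 2L); expect_equal(got$j, 4L)

  # exactly at the threshold is excluded (strict inequality)
  v[2, 4] <- v[4, 2] <- 0.32
  expect_equal(nrow(suprathreshold_edges(mk_stat(v), cluster_config(0.32, "positive", 10))), 0)

  # masked pairs can never enter, whatever value they store
  v[2, 4] <- v[4, 2] <- 0.9
  valid <- matrix(TRUE, 5, 5); diag(valid) <- FALSE
  valid[2, 4] <- valid[4, 2] <- FALSE
  expect_equal(nrow(suprathreshold_edges(mk_stat(v, valid),
                                         cluster_config(0.32, "positive", 10))), 0)

  # negative direction mirrors with strictly-smaller
  v2 <- matrix(0, 5, 5); v2[1, 3] <- v2[3, 1] <- -0.45
  got <- suprathreshold_edges(mk_stat(v2), cluster_config(-0.3, "negative", 10))
  expect_equal(nrow(got), 1)
  expect_error(cluster_config(-0.2, "positive", 10), "positive")
  expect_error(cluster_config(0.2, "negative", 10), "negative")
  expect_error(cluster_config(0.3, "positive", 0), "n_permutations")
})

test_that("clustering by shared nodes matches a union-find oracle", {
  cl <- clusters(tibble::tibble(i = c(1L, 2L, 7L), j = c(2L, 3L, 8L)))
  expect_equal(unname(sort(vapply(cl, nrow, integer(1)), decreasing = TRUE)), c(2L, 1L))
  expect_equal(clusters(tibble::tibble(i = integer(0), j = integer(0))), list())

  withr::local_seed(55)
  for (rep in 1:25) {
    V <- 30
    m <- sample(0:25, 1)
    pairs <- which(upper.tri(matrix(0, V, V)), arr.ind = TRUE)
    pick <- pairs[sample.int(nrow(pairs), m), , drop = FALSE]
    es <- tibble::tibble(i = as.integer(pick[, 1]), j = as.integer(pick[, 2]))
    got <- sort(vapply(clusters(es), nrow, integer(1)), decreasing = TRUE)
    expect_equal(as.integer(got), uf_cluster_sizes(es$i, es$j))
  }
})

test_that("max_cluster picks the largest cluster with a deterministic tie rule", {
  es <- tibble::tibble(i = c(1L, 2L, 7L), j = c(2L, 3L, 8L), r = c(.5, .6, .7))
  mc <- max_cluster(es)
  expect_equal(mc$size, 2L)
  expect_setequal(mc$edges$i, c(1L, 2L))

  empty <- max_cluster(es[0, ])
  expect_equal(empty$size, 0L)
  expect_equal(nrow(empty$edges), 0)

  # two clusters of equal size: the one holding the smallest pair wins
  es2 <- tibble::tibble(i = c(5L, 6L, 1L, 2L), j = c(6L, 7L, 2L, 3L))
  mc2 <- max_cluster(es2)
  expect_equal(min(mc2$edges$i), 1L)
})

test_that("p-value interval follows the parametric closed form", {
  expect_equal(pvalue_interval(0.5, 100), c(low = 0.402, high = 0.598),
               tolerance = 1e-3)
  iv <- pvalue_interval(0.026, 5000)
  expect_equal(unname(iv[2] - iv[1]) / 2, 1.96 * sqrt(0.026 * 0.974 / 5000),
               tolerance = 1e-12)
  expect_equal(unname(pvalue_interval(1, 5000)), c(1, 1))
  expect_error(pvalue_interval(0, 10), "0, 1")
})

test_that("permutation null is seed-deterministic and never yields p = 0", {
  ch <- tiny_cohort(n = 12, V = 12, beta = 1.2, seed = 3)
  flows <- cohort_flows(ch)
  cfg <- cluster_config(0.4, "positive", 60, seed = 77)
  n1 <- permutation_null(ch, flows, cfg)
  n2 <- permutation_null(ch, flows, cfg)
  expect_identical(n1, n2)
  expect_length(n1, 60)
  res <- cluster_size_test(ch, flows, cfg)
  expect_identical(res$null_sizes, n1)
  expect_gt(res$p_value, 0)
  expect_lte(res$p_value, 1)
  expect_true(res$p_value >= res$p_interval[["low"]] &&
              res$p_value <= res$p_interval[["high"]])
})

test_that("cluster test handles an observed size of zero", {
  ch <- tiny_cohort(n = 12, V = 10, beta = 0, seed = 5)
  flows <- cohort_flows(ch)
  # absurd threshold: nothing survives
  cfg <- cluster_config(0.999, "positive", 30, seed = 1)
  res <- cluster_size_test(ch, flows, cfg)
  expect_equal(res$observed_size, 0L)
  expect_equal(res$p_value, 1)
  expect_equal(nrow(res$edges), 0)
  expect_false(res$significant)
})

test_that("returned subnetworks are connected under shared-node adjacency", {
  ch <- tiny_cohort(n = 25, V = 15, beta = 1.5, seed = 11)
  flows <- cohort_flows(ch)
  res <- cluster_size_test(ch, flows, cluster_config(0.3, "positive", 50, seed = 2))
  expect_gt(res$observed_size, 0)
  sizes <- uf_cluster_sizes(res$edges$i, res$edges$j)
  expect_length(sizes, 1)  # one connected component
  expect_equal(sizes[1], res$observed_size)
})

test_that("tiny cohorts have an enumerable permutation null", {
  ch <- tiny_cohort(n = 6, V = 10, beta = 0.5, seed = 19)
  ch$covariates <- ch$covariates[1:5, ]
  ch$connectomes <- ch$connectomes[1:5]
  flows <- cohort_flows(ch)
  cfg <- cluster_config(0.5, "positive", 80, seed = 3, covariates = character(0))

  # every sampled null size must come from the exhaustive set over all 5! orderings
  edu <- ch$covariates$education_years
  exhaustive <- vapply(all_permutations(seq_len(5)), function(p) {
    st <- education_flow_correlation(set_education(ch, edu[p]), flows,
                                     covariates = character(0))
    max_cluster(suprathreshold_edges(st, cfg))$size
  }, integer(1))
  sampled <- permutation_null(ch, flows, cfg)
  expect_true(all(sampled %in% exhaustive))

  # cohorts of fewer subjects than covariates + 3 are rejected
  ch2 <- ch
  ch2$covariates <- ch$covariates[1:4, ]
  ch2$connectomes <- ch$connectomes[1:4]
  expect_error(
    cluster_size_test(ch2, flows[1:4],
                      cluster_config(0.5, "positive", 10, seed = 1,
                                     covariates = c("age", "sex"))),
    "n > k")
})

test_that("threshold sweep is monotone in observed size and reports overlap", {
  ch <- tiny_cohort(n = 20, V = 15, beta = 1.2, seed = 13)
  flows <- cohort_flows(ch)
  sw <- threshold_sweep(ch, flows, thresholds = c(0.2, 0.3, 0.4, 0.5),
                        direction = "positive", n_permutations = 40, seed = 5)
  expect_equal(nrow(sw), 4)
  expect_true(all(diff(sw$observed_size) <= 0))
  expect_true(is.na(sw$jaccard_prev[1]))
  single <- threshold_sweep(ch, flows, thresholds = 0.3, direction = "positive",
                            n_permutations = 40, seed = 5)
  direct <- cluster_size_test(ch, flows,
                              cluster_config(0.3, "positive", 40, seed = 6))
  expect_equal(single$observed_size, direct$observed_size)
  expect_equal(single$p_value, direct$p_value)
  expect_error(threshold_sweep(ch, flows, numeric(0), "positive"), "non-empty")
})

test_that("subsampling with fraction 1 reproduces the full subnetwork", {
  ch <- tiny_cohort(n = 16, V = 12, beta = 1.5, seed = 21)
  flows <- cohort_flows(ch)
  cfg <- cluster_config(0.3, "positive", 40, seed = 9)
  rep1 <- subsample_reproducibility(ch, flows, cfg, fraction = 1,
                                    n_subsamples = 3)
  expect_true(all(rep1$table$overlap == 1))
  expect_true(all(rep1$table$observed_size == rep1$full$observed_size))
  expect_error(
    subsample_reproducibility(ch, flows, cfg, fraction = 0),
    "fraction")
})
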