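two_cohorts <- function(nA = 12, nB = 12, V = 10, seedA = 1, seedB = 2,
                        betaA = 0.5, betaB = 0.5) {
  a <- generate_cohort(sim_config(n_subjects = nA, V = V, n_planted_pairs = 2,
                                  n_relays_per_pair = 2, effect_beta = betaA,
                                  group = "NC", seed = seedA))
  b <- generate_cohort(sim_config(n_subjects = nB, V = V, n_planted_pairs = 2,
                                  n_relays_per_pair = 2, effect_beta = betaB,
                                  group = "AD", seed = seedB))
  list(a = a, b = b, fa = cohort_flows(a), fb = cohort_flows(b))
}

test_that("edgewise ANCOVA with no covariates reduces to the two-sample t-test", {
  tc <- two_cohorts()
  got <- edgewise_ancova(tc$a, tc$fa, tc$b, tc$fb, covariates = character(0))
  ut <- which(upper.tri(got$values) & got$valid, arr.ind = TRUE)
  for (k in sample(nrow(ut), 10)) {
    i <- ut[k, 1]; j <- ut[k, 2]
    ya <- vapply(tc$fa, function(f) as.numeric(f$values[i, j]), numeric(1))
    yb <- vapply(tc$fb, function(f) as.numeric(f$values[i, j]), numeric(1))
    expect_equal(got$values[i, j], t.test(ya, yb, var.equal = TRUE)$p.value,
                 tolerance = 1e-8)
  }
})

test_that("edgewise ANCOVA masks constant pairs and is label-symmetric", {
  tc <- two_cohorts()
  got <- edgewise_ancova(tc$a, tc$fa, tc$b, tc$fb)
  expect_identical(got$valid, t(got$valid))
  expect_equal(got$values, t(got$values), tolerance = 1e-12)
  # a pair with identical flow everywhere carries no test
  fa2 <- lapply(tc$fa, function(f) { f$values[1, 2] <- f$values[2, 1] <- 5L; f })
  fb2 <- lapply(tc$fb, function(f) { f$values[1, 2] <- f$values[2, 1] <- 5L; f })
  got2 <- edgewise_ancova(tc$a, fa2, tc$b, fb2)
  expect_false(got2$valid[1, 2])
  # two-sided: swapping the group labels leaves p unchanged
  swapped <- edgewise_ancova(tc$b, tc$fb, tc$a, tc$fa)
  expect_equal(got$values, swapped$values, tolerance = 1e-10)
})

test_that("exchangeable groups give roughly uniform ANCOVA p-values", {
  full <- generate_cohort(sim_config(n_subjects = 40, V = 12, n_planted_pairs = 2,
                                     n_relays_per_pair = 2, seed = 31))
  flows <- cohort_flows(full)
  withr::local_seed(31)
  half <- sample(40, 20)
  a <- full; a$covariates <- full$covariates[half, ]; a$connectomes <- full$connectomes[half]
  b <- full; b$covariates <- full$covariates[-half, ]; b$connectomes <- full$connectomes[-half]
  fa <- flows[half]; fb <- flows[-half]
  got <- edgewise_ancova(a, fa, b, fb)
  corr <- bonferroni(got)
  expect_equal(nrow(corr$significant), 0)
  ps <- got$values[upper.tri(got$values) & got$valid]
  expect_gt(mean(ps), 0.3)  # no systematic group difference
})

test_that("Bonferroni correction uses valid-pair count and strict threshold", {
  V <- 5
  p <- matrix(1, V, V)
  valid <- matrix(TRUE, V, V); diag(valid) <- FALSE
  m <- sum(upper.tri(p))
  p[1, 2] <- p[2, 1] <- 0.05 / m      # lands exactly on alpha after correction
  p[1, 3] <- p[3, 1] <- 0.04 / m
  stat <- structure(list(values = p, valid = valid, statistic_kind = "p_value",
                         covariate_names = character(0), n_subjects = 40,
                         region_labels = sprintf("R%03d", 1:V)),
                    class = "fr_edge_stat")
  out <- bonferroni(stat, alpha = 0.05)
  expect_equal(out$m, m)
  expect_equal(out$corrected$values[1, 2], 0.05)
  expect_equal(nrow(out$significant), 1)  # boundary pair excluded under strict <
  expect_equal(out$significant$i, 1L)
  expect_equal(out$significant$j, 3L)
  expect_true(all(out$corrected$values >= p))

  allone <- stat; allone$values[] <- 1; diag(allone$values) <- 1
  expect_equal(nrow(bonferroni(allone)$significant), 0)
})

test_that("mean-flow group comparison recovers a constant shift exactly", {
  tc <- two_cohorts(nA = 10, nB = 10, V = 10)
  # group B = group A with every flow shifted by +2, same covariates
  b <- tc$a
  b$covariates$subject_id <- paste0("B", seq_len(10))
  fb <- lapply(tc$fa, function(f) { f$values <- f$values + 2L; diag(f$values) <- 0L; f })
  got <- mean_flow_comparison(tc$a, tc$fa, b, fb,
                              covariates = c("age", "sex", "education_years"))
  expect_equal(got$estimate, 2, tolerance = 1e-8)
  single <- tc$a
  single$covariates <- single$covariates[1, ]
  single$connectomes <- single$connectomes[1]
  expect_error(mean_flow_comparison(single, tc$fa[1], b, fb), "two subjects")
})

test_that("cross-applied subnetworks average the other cohort's correlations", {
  ch <- generate_cohort(sim_config(n_subjects = 30, V = 15, n_planted_pairs = 2,
                                   n_relays_per_pair = 2, effect_beta = 1.2,
                                   seed = 41))
  flows <- cohort_flows(ch)
  res <- cluster_size_test(ch, flows, cluster_config(0.3, "positive", 40, seed = 1))
  expect_gt(res$observed_size, 0)
  # applying a subnetwork back to its own cohort reproduces its matrix values
  st <- education_flow_correlation(ch, flows)
  cross <- cross_apply_subnetwork(res, ch, flows)
  expect_equal(cross$mean_r,
               mean(st$values[cbind(res$edges$i, res$edges$j)]),
               tolerance = 1e-12)
  # single-edge subnetwork: mean equals that edge's r
  one <- res
  one$edges <- res$edges[1, ]
  cross1 <- cross_apply_subnetwork(one, ch, flows)
  expect_equal(cross1$mean_r, cross1$edges$r[1])
  none <- res; none$edges <- res$edges[0, ]
  expect_error(cross_apply_subnetwork(none, ch, flows), "no edges")
})

test_that("summary measures count edges, streamlines, FA and flow once per pair", {
  k4 <- connectome(adjacency = k_graph(4), fiber_count = k_graph(4) * 5L,
                   fa = k_graph(4) * 0.5)
  fl <- pairwise_flow(k4)
  sm <- summary_measures(k4, fl)
  expect_equal(sm$total_edges, 6L)
  expect_equal(sm$flow_sum, 18L)       # 6 pairs x flow 3
  expect_equal(sm$total_streamlines, 30L)
  expect_equal(sm$fa_sum, 3)
  empty <- connectome(adjacency = matrix(0L, 4, 4))
  sm0 <- summary_measures(empty, pairwise_flow(empty))
  expect_equal(sm0$total_edges, 0L)
  expect_equal(sm0$flow_sum, 0L)
  expect_true(is.na(sm0$fa_sum))
})

test_that("summary measures are invariant to node relabeling", {
  withr::local_seed(61)
  a <- rand_graph(8, 0.4)
  cn <- connectome(adjacency = a)
  perm <- sample(8)
  cn2 <- connectome(adjacency = a[perm, perm])
  expect_equal(summary_measures(cn, pairwise_flow(cn))[c("total_edges", "flow_sum")],
               summary_measures(cn2, pairwise_flow(cn2))[c("total_edges", "flow_sum")])
})

test_that("summary regression recovers noiseless coefficients and flags collinearity", {
  ch <- tiny_cohort(n = 20, V = 8, seed = 51)
  flows <- cohort_flows(ch)
  tbl <- cohort_summary_measures(ch, flows)
  tbl$synthetic_outcome <- 2 * tbl$education_years + 0.5 * tbl$age
  fit <- suppressWarnings(summary_regression(tbl, "synthetic_outcome"))
  expect_equal(fit$estimate[fit$term == "education_years"], 2,
               tolerance = 1e-10, ignore_attr = TRUE)
  tbl$age2 <- tbl$age
  expect_error(summary_regression(tbl, "synthetic_outcome",
                                  covariates = c("age", "age2")),
               "rank deficient")
  expect_error(summary_regression(tbl[1:4, ], "synthetic_outcome"), "4 subjects")
})
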