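#' Configuration for the suprathreshold cluster-size permutation test
#'
#' @param r_threshold correlation threshold; must be positive for
#'   `direction = "positive"` (edges with r strictly greater are kept) and
#'   negative for `direction = "negative"` (edges with r strictly smaller).
#' @param direction `"positive"` or `"negative"`.
#' @param n_permutations number of education permutations M (default 5000;
#'   with this M a permutation p-value near 0.026 carries a parametric 95%
#'   interval of about +/- 0.004).
#' @param seed RNG seed for the permutations.
#' @param covariates covariate names for the partial correlation; `NULL`
#'   picks the cohort's default (see [education_flow_correlation()]).
#' @param alpha significance level reported with results (default 0.05).
#' @return A validated `fr_cluster_config` list.
#' @export
cluster_config <- function(r_threshold, direction = c("positive", "negative"),
                           n_permutations = 5000, seed = 1, covariates = NULL,
                           alpha = 0.05) {
  direction <- match.arg(direction)
  if (n_permutations < 1) abort("`n_permutations` must be >= 1")
  if (direction == "positive" && r_threshold <= 0) {
    abort("positive direction requires a positive `r_threshold`")
  }
  if (direction == "negative" && r_threshold >= 0) {
    abort("negative direction requires a negative `r_threshold`")
  }
  structure(list(r_threshold = r_threshold, direction = direction,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), covariates = covariates,
                 alpha = alpha),
            class = "fr_cluster_config")
}

#' Node pairs exceeding the correlation threshold
#'
#' Collects the valid node pairs whose correlation is strictly greater than
#' the threshold (positive direction) or strictly smaller (negative
#' direction). Masked (undefined) pairs are never selected, whatever value
#' they store.
#'
#' @param corr an `fr_edge_stat` of kind `"partial_r"`.
#' @param config an [cluster_config()].
#' @return Tibble of suprathreshold pairs with columns `i`, `j`
#'   (`i < j`) and `r`.
#' @export
suprathreshold_edges <- function(corr, config) {
  stopifnot(inherits(corr, "fr_edge_stat"), inherits(config, "fr_cluster_config"))
  if (corr$statistic_kind != "partial_r") {
    abort("suprathreshold selection needs a partial_r edge statistic")
  }
  idx <- which(upper.tri(corr$values), arr.ind = TRUE)
  r <- corr$values[idx]
  keep <- corr$valid[idx] &
    (if (config$direction == "positive") r > config$r_threshold
     else r < config$r_threshold)
  tibble(i = as.integer(idx[keep, 1]), j = as.integer(idx[keep, 2]), r = r[keep])
}

# connected components of an edge set under shared-node adjacency;
# returns per-edge component id (edges sharing a node share a component)
pair_components <- function(i, j) {
  if (length(i) == 0) return(integer(0))
  g <- igraph::graph_from_edgelist(cbind(i, j), directed = FALSE)
  memb <- igraph::components(g)$membership
  memb[i]
}

#' Cluster an edge set by shared nodes
#'
#' Two node pairs are adjacent when they share a node; each connected
#' component of that relation is one cluster. The size of a cluster is its
#' number of edges.
#'
#' @param edges tibble or matrix with columns `i`, `j` (any extra columns
#'   are carried along).
#' @return List of clusters, each a tibble of edges, ordered by decreasing
#'   size.
#' @export
clusters <- function(edges) {
  edges <- as_tibble(as.data.frame(edges))
  if (nrow(edges) == 0) return(list())
  memb <- pair_components(edges$i, edges$j)
  out <- lapply(split(seq_len(nrow(edges)), memb), function(ix) edges[ix, ])
  out[order(-vapply(out, nrow, integer(1)))]
}

#' Largest cluster of an edge set
#'
#' @inheritParams clusters
#' @return List with `edges` (tibble, possibly empty) and `size` (edge
#'   count). Ties between equally large clusters are broken deterministically
#'   in favour of the cluster containing the lexicographically smallest node
#'   pair.
#' @export
max_cluster <- function(edges) {
  cl <- clusters(edges)
  if (length(cl) == 0) {
    return(list(edges = tibble(i = integer(0), j = integer(0), r = numeric(0)),
                size = 0L))
  }
  sizes <- vapply(cl, nrow, integer(1))
  top <- which(sizes == max(sizes))
  if (length(top) > 1) {
    key <- vapply(cl[top], function(e) {
      o <- order(e$i, e$j)
      c(e$i[o][1], e$j[o][1])
    }, numeric(2))
    top <- top[order(key[1, ], key[2, ])[1]]
  }
  list(edges = cl[[top]], size = max(sizes))
}

max_cluster_size <- function(i, j) {
  if (length(i) == 0) return(0L)
  memb <- pair_components(i, j)
  max(tabulate(memb))
}

# observed/null machinery shared by cluster_size_test, permutation_null and
# threshold_sweep: everything education-independent is precomputed once
supra_from_r <- function(r_vec, threshold, direction) {
  if (direction == "positive") which(!is.na(r_vec) & r_vec > threshold)
  else which(!is.na(r_vec) & r_vec < threshold)
}

null_sizes_impl <- function(prep, config, pair_i, pair_j) {
  M <- config$n_permutations
  n <- prep$n
  withr::with_seed(config$seed, {
    sizes <- integer(M)
    done <- 0L
    while (done < M) {
      block <- min(500L, M - done)
      E <- vapply(seq_len(block), function(b) prep$education[sample.int(n)],
                  numeric(n))
      R <- edu_flow_r(prep, E)  # block x pairs
      for (b in seq_len(block)) {
        keep <- supra_from_r(R[b, ], config$r_threshold, config$direction)
        sizes[done + b] <- max_cluster_size(pair_i[keep], pair_j[keep])
      }
      done <- done + block
    }
    sizes
  })
}

#' Permutation null distribution of the maximum cluster size
#'
#' Randomly permutes the education vector across subjects (covariates and
#' flow matrices stay bound to their subjects), recomputes the full
#' covariate-adjusted correlation matrix for each permutation, and records
#' the maximum suprathreshold cluster size. The resulting sizes form the
#' null distribution used for familywise-error-corrected inference.
#'
#' @inheritParams cluster_size_test
#' @return Integer vector of `n_permutations` maximum cluster sizes;
#'   identical seed gives identical output.
#' @export
permutation_null <- function(cohort, flows, config) {
  stopifnot(inherits(config, "fr_cluster_config"))
  covariates <- config$covariates %||% default_covariates(cohort)
  prep <- prepare_association(cohort, flows, covariates)
  idx <- which(upper.tri(matrix(0, length(prep$labels), length(prep$labels))),
               arr.ind = TRUE)
  null_sizes_impl(prep, config, idx[, 1], idx[, 2])
}

subnetwork_result <- function(edges, labels, p, interval, null_sizes, config,
                              covariates, n_subjects) {
  edges <- dplyr::arrange(edges, .data$i, .data$j)
  edges$region_i <- labels[edges$i]
  edges$region_j <- labels[edges$j]
  nodes <- sort(unique(c(edges$i, edges$j)))
  structure(list(
    edges = dplyr::relocate(edges, "region_i", "region_j"),
    nodes = nodes, observed_size = nrow(edges), p_value = p,
    p_interval = interval, null_sizes = null_sizes, config = config,
    covariate_names = covariates, n_subjects = n_subjects,
    region_labels = labels,
    significant = nrow(edges) > 0 && p < config$alpha
  ), class = "fr_subnetwork")
}

#' Suprathreshold cluster-size permutation test
#'
#' Identifies the education-associated subnetwork of a cohort: thresholds
#' the covariate-adjusted education-flow correlation matrix, takes the
#' largest connected cluster of surviving node pairs as the candidate
#' subnetwork, and assigns it a familywise-error-corrected p-value by
#' comparing its size with the null distribution of maximum cluster sizes
#' under education permutation. The p-value uses the add-one convention
#' `p = (1 + #\{null >= observed\}) / (M + 1)`, which can never return 0, and
#' is reported with the parametric 95% interval of [pvalue_interval()].
#'
#' @param cohort an [cohort()].
#' @param flows aligned list of `fr_flow` (see [cohort_flows()]).
#' @param config an [cluster_config()].
#' @return An `fr_subnetwork`: the maximum cluster's edges (with their
#'   correlations), its node set, observed size, `p_value`, `p_interval`,
#'   the M null sizes, and the configuration. An observed size of 0 yields
#'   an empty edge set with p = 1. The edge set is the significant
#'   subnetwork when `p_value < config$alpha` (`$significant`).
#' @export
cluster_size_test <- function(cohort, flows, config) {
  stopifnot(inherits(config, "fr_cluster_config"))
  covariates <- config$covariates %||% default_covariates(cohort)
  prep <- prepare_association(cohort, flows, covariates)
  V <- length(prep$labels)
  idx <- which(upper.tri(matrix(0, V, V)), arr.ind = TRUE)

  r_obs <- drop(edu_flow_r(prep, prep$education))
  keep <- supra_from_r(r_obs, config$r_threshold, config$direction)
  obs <- max_cluster(tibble(i = idx[keep, 1], j = idx[keep, 2], r = r_obs[keep]))

  null_sizes <- null_sizes_impl(prep, config, idx[, 1], idx[, 2])
  M <- config$n_permutations
  p <- (1 + sum(null_sizes >= obs$size)) / (M + 1)
  if (obs$size == 0) {
    p <- 1
    obs$edges <- obs$edges[0, ]
  }
  subnetwork_result(obs$edges, prep$labels, p, pvalue_interval(p, M),
                    null_sizes, config, covariates, prep$n)
}

#' Parametric 95% interval for a permutation p-value
#'
#' `p +/- 1.96 sqrt(p (1 - p) / M)`, clipped to `[0, 1]` — the normal
#' approximation to the Monte-Carlo uncertainty of a permutation p-value
#' estimated from M permutations.
#'
#' @param p estimated p-value in (0, 1].
#' @param M number of permutations.
#' @return Named numeric vector `c(low, high)`.
#' @export
pvalue_interval <- function(p, M) {
  if (p <= 0 || p > 1) abort("`p` must lie in (0, 1]")
  if (M < 1) abort("`M` must be >= 1")
  hw <- 1.96 * sqrt(p * (1 - p) / M)
  c(low = max(0, p - hw), high = min(1, p + hw))
}

#' @export
print.fr_subnetwork <- function(x, ...) {
  cat(sprintf(
    "<fr_subnetwork> %s direction, r threshold %g: %d edges over %d nodes\n  p = %.4g (95%% interval %.4g-%.4g, M = %d)%s\n",
    x$config$direction, x$config$r_threshold, x$observed_size,
    length(x$nodes), x$p_value, x$p_interval[["low"]], x$p_interval[["high"]],
    x$config$n_permutations,
    if (x$significant) sprintf("; significant at alpha = %g", x$config$alpha) else ""))
  invisible(x)
}

#' @describeIn cluster_size_test Edge-per-row tibble of the subnetwork.
#' @param x an `fr_subnetwork`.
#' @param ... unused.
#' @export
tidy.fr_subnetwork <- function(x, ...) as_tibble(x$edges)

#' @describeIn cluster_size_test One-row summary (size, node count, p-value
#'   and interval, threshold, direction, significance).
#' @export
glance.fr_subnetwork <- function(x, ...) {
  tibble(observed_size = x$observed_size, n_nodes = length(x$nodes),
         p_value = x$p_value, p_low = x$p_interval[["low"]],
         p_high = x$p_interval[["high"]],
         r_threshold = x$config$r_threshold, direction = x$config$direction,
         n_permutations = x$config$n_permutations,
         alpha = x$config$alpha, significant = x$significant)
}

#' @export
autoplot.fr_subnetwork <- function(object, ...) {
  df <- tibble(size = object$null_sizes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_size, colour = "red",
                        linetype = 2) +
    ggplot2::labs(x = "maximum cluster size under permutation",
                  y = "permutations",
                  title = sprintf("Observed size %d, p = %.3g",
                                  object$observed_size, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Cluster test across a range of correlation thresholds
#'
#' Runs [cluster_size_test()] at each threshold (each with a sub-seed
#' `seed + index` so rows are independently reproducible) and reports, for
#' consecutive thresholds, the Jaccard overlap of the identified edge sets —
#' the consistency evidence used to pick a working threshold.
#'
#' @inheritParams cluster_size_test
#' @param thresholds numeric vector, all positive (positive direction) or
#'   all negative.
#' @param direction,n_permutations,seed,covariates,alpha as in
#'   [cluster_config()].
#' @return Tibble with one row per threshold: `r_threshold`,
#'   `observed_size`, `p_value`, `p_low`, `p_high`, `significant`,
#'   `jaccard_prev` (`NA` for the first row), plus the subnetworks in the
#'   `result` list-column.
#' @export
threshold_sweep <- function(cohort, flows, thresholds,
                            direction = c("positive", "negative"),
                            n_permutations = 1000, seed = 1, covariates = NULL,
                            alpha = 0.05) {
  direction <- match.arg(direction)
  if (length(thresholds) == 0) abort("`thresholds` must be non-empty")
  results <- purrr::imap(thresholds, function(th, k) {
    cfg <- cluster_config(th, direction, n_permutations, seed = seed + k,
                          covariates = covariates, alpha = alpha)
    cluster_size_test(cohort, flows, cfg)
  })
  edge_key <- function(res) paste(res$edges$i, res$edges$j)
  jac <- c(NA_real_, purrr::map2_dbl(results[-length(results)], results[-1],
    function(a, b) {
      u <- union(edge_key(a), edge_key(b))
      if (length(u) == 0) return(NA_real_)
      length(intersect(edge_key(a), edge_key(b))) / length(u)
    }))
  out <- purrr::map_dfr(results, glance)
  out$jaccard_prev <- jac
  out$result <- results
  dplyr::relocate(out, "r_threshold")
}

subset_cohort <- function(x, idx) {
  out <- cohort(x$covariates[idx, ], x$connectomes[idx], name = x$name)
  out
}

safe_cor_p <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(1)
  stats::cor.test(x, y)$p.value
}

#' Subsample reproducibility of an identified subnetwork
#'
#' Repeats the cluster test on random subsamples of the cohort (90% of
#' subjects by default). Each subsample is redrawn (bounded retries) until
#' education shows no significant Pearson association (p > 0.05) with each
#' balance-check covariate, mimicking matched subgroup construction; the
#' test is then run per subsample and its identified edges are compared with
#' the full-cohort subnetwork.
#'
#' @inheritParams cluster_size_test
#' @param fraction fraction of subjects kept per subsample (default 0.9).
#' @param n_subsamples number of subsamples (default 20).
#' @param balance_checks covariates that must stay unassociated with
#'   education (default age and sex; add `"cdr_sob"` for severity-matched
#'   groups).
#' @param max_retries redraw bound per subsample.
#' @return List with `full` (the full-cohort `fr_subnetwork`) and `table`, a
#'   tibble with one row per subsample: `significant`, `observed_size`,
#'   `p_value` and `overlap` = |edges intersecting the full subnetwork| /
#'   |full subnetwork edges|.
#' @export
subsample_reproducibility <- function(cohort, flows, config, fraction = 0.9,
                                      n_subsamples = 20,
                                      balance_checks = c("age", "sex"),
                                      max_retries = 200) {
  stopifnot(inherits(config, "fr_cluster_config"))
  if (fraction <= 0 || fraction > 1) abort("`fraction` must lie in (0, 1]")
  full <- cluster_size_test(cohort, flows, config)
  full_key <- paste(full$edges$i, full$edges$j)
  n <- nrow(cohort$covariates)
  m <- max(2L, round(fraction * n))
  rows <- purrr::map_dfr(seq_len(n_subsamples), function(s) {
    sub_seed <- config$seed + s
    idx <- withr::with_seed(sub_seed, {
      tries <- 0L
      repeat {
        cand <- sort(sample.int(n, m))
        edu <- cohort$covariates$education_years[cand]
        ok <- all(vapply(balance_checks, function(cv)
          safe_cor_p(edu, cohort$covariates[[cv]][cand]) > 0.05, logical(1)))
        if (ok) break
        tries <- tries + 1L
        if (tries >= max_retries) {
          abort("could not draw an education-balanced subsample; enlarge the cohort or relax balance_checks")
        }
      }
      cand
    })
    cfg <- config
    cfg$seed <- sub_seed
    res <- cluster_size_test(subset_cohort(cohort, idx), flows[idx], cfg)
    key <- paste(res$edges$i, res$edges$j)
    tibble(subsample = s, n_subjects = m, significant = res$significant,
           observed_size = res$observed_size, p_value = res$p_value,
           overlap = if (length(full_key) == 0) NA_real_
                     else length(intersect(key, full_key)) / length(full_key))
  })
  list(full = full, table = rows)
}
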