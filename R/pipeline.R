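#' Configuration for the end-to-end two-group analysis
#'
#' Describes the canonical workflow: a control-like group tested for a
#' positively education-associated subnetwork, and (optionally) a
#' patient-like group tested in the negative direction with dementia
#' severity as an extra covariate.
#'
#' @param nc the control-like cohort: an [cohort()], or a list
#'   `list(covariates = <csv path>, matrix_dir = <dir>, matrix_kind = ...)`
#'   passed to [read_cohort()].
#' @param ad optional patient-like cohort, same forms; when `NULL`, group
#'   comparisons are skipped.
#' @param fiber_threshold streamline threshold for binarization (default 3);
#'   applied when fiber-count matrices are available.
#' @param r_threshold_positive,r_threshold_negative correlation thresholds
#'   for the two directions (defaults 0.32 and -0.3).
#' @param n_permutations permutations M per cluster test.
#' @param seed master seed; every stage derives its sub-seed from it.
#' @param alpha significance level.
#' @param covariates_nc,covariates_ad adjusted covariates per group.
#' @param out_dir optional output directory; when given, all tables and a
#'   manifest are written there.
#' @return A validated `fr_pipeline_config` list.
#' @export
pipeline_config <- function(nc, ad = NULL, fiber_threshold = 3,
                            r_threshold_positive = 0.32,
                            r_threshold_negative = -0.3,
                            n_permutations = 1000, seed = 1, alpha = 0.05,
                            covariates_nc = c("age", "sex"),
                            covariates_ad = c("age", "sex", "cdr_sob"),
                            out_dir = NULL) {
  stopifnot(fiber_threshold >= 1, n_permutations >= 1)
  structure(list(nc = nc, ad = ad, fiber_threshold = fiber_threshold,
                 r_threshold_positive = r_threshold_positive,
                 r_threshold_negative = r_threshold_negative,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), alpha = alpha,
                 covariates_nc = covariates_nc, covariates_ad = covariates_ad,
                 out_dir = out_dir),
            class = "fr_pipeline_config")
}

load_cohort_arg <- function(x, fiber_threshold) {
  if (inherits(x, "fr_cohort")) {
    return(apply_fiber_threshold(x, fiber_threshold, required = FALSE))
  }
  if (is.list(x) && !is.null(x$covariates) && !is.null(x$matrix_dir)) {
    return(read_cohort(x$covariates, x$matrix_dir,
                       matrix_kind = x$matrix_kind %||% "fiber_count",
                       fiber_threshold = fiber_threshold))
  }
  abort("cohort argument must be an fr_cohort or list(covariates=, matrix_dir=, matrix_kind=)")
}

#' Re-binarize a cohort's connectomes at a new fiber threshold
#'
#' @param cohort an [cohort()] whose connectomes carry fiber counts.
#' @param threshold new streamline threshold.
#' @param required error when fiber counts are absent (`TRUE`) or return the
#'   cohort unchanged (`FALSE`).
#' @return The cohort with adjacencies recomputed as
#'   `fiber_count >= threshold`.
#' @export
apply_fiber_threshold <- function(cohort, threshold, required = TRUE) {
  has_fc <- !vapply(cohort$connectomes, function(cn) is.null(cn$fiber_count), logical(1))
  if (!all(has_fc)) {
    if (required) abort("cohort has no fiber-count matrices; cannot re-binarize")
    return(cohort)
  }
  out <- cohort
  out$connectomes <- purrr::map(cohort$connectomes, function(cn) {
    connectome(fiber_count = cn$fiber_count, fa = cn$fa,
               region_labels = cn$region_labels, fiber_threshold = threshold)
  })
  out
}

run_group <- function(coh, flows, r_threshold, direction, covariates, config,
                      seed_offset) {
  cfg <- cluster_config(r_threshold, direction, config$n_permutations,
                        seed = config$seed + seed_offset,
                        covariates = covariates, alpha = config$alpha)
  corr <- education_flow_correlation(coh, flows, covariates)
  subnet <- cluster_size_test(coh, flows, cfg)
  hubs <- if (subnet$observed_size > 0) hub_report(subnet) else NULL
  meas <- cohort_summary_measures(coh, flows)
  outcomes <- c("total_edges", "flow_sum",
                if (!anyNA(meas$total_streamlines)) "total_streamlines",
                if (!anyNA(meas$fa_sum)) "fa_sum")
  reg <- purrr::map_dfr(outcomes, function(o) {
    tbl <- summary_regression(meas, o)
    dplyr::mutate(dplyr::filter(tbl, .data$term == "education_years"),
                  measure = o, .before = 1)
  })
  list(correlation = corr, subnetwork = subnet, hubs = hubs,
       top_pairs = top_flow_pairs(flows, k = 10),
       summary_measures = meas, summary_regression = reg)
}

#' Run the full two-group flow-reliability analysis
#'
#' Executes the whole pipeline: binarization, all-pairs maximum flow,
#' covariate-adjusted education-flow correlation, the suprathreshold
#' cluster-size permutation test per group (positive direction for the
#' control-like group, negative for the patient-like group), edgewise group
#' ANCOVA with Bonferroni correction, Fisher z comparison of the two
#' correlation matrices, cross-application of each subnetwork to the other
#' group, network summary-measure regressions, and hub reports. Rerunning
#' with the same configuration and seed reproduces every output
#' bit-exactly.
#'
#' @param config an [pipeline_config()].
#' @return A (invisible) list: per-group results (`nc`, `ad`), group
#'   comparisons (`ancova`, `bonferroni`, `mean_flow`, `correlation_diff`,
#'   `cross_nc_in_ad`, `cross_ad_in_nc`) and the `manifest`. When
#'   `config$out_dir` is set all tables are also written there.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "fr_pipeline_config"))
  nc <- load_cohort_arg(config$nc, config$fiber_threshold)
  flows_nc <- cohort_flows(nc)
  res <- list()
  res$nc <- run_group(nc, flows_nc, config$r_threshold_positive, "positive",
                      config$covariates_nc, config, seed_offset = 1L)

  if (!is.null(config$ad)) {
    ad <- load_cohort_arg(config$ad, config$fiber_threshold)
    flows_ad <- cohort_flows(ad)
    res$ad <- run_group(ad, flows_ad, config$r_threshold_negative, "negative",
                        config$covariates_ad, config, seed_offset = 2L)
    p_ancova <- edgewise_ancova(nc, flows_nc, ad, flows_ad)
    res$ancova <- p_ancova
    res$bonferroni <- bonferroni(p_ancova, config$alpha)
    res$mean_flow <- mean_flow_comparison(nc, flows_nc, ad, flows_ad)
    res$correlation_diff <- compare_correlations(res$ad$correlation,
                                                 res$nc$correlation,
                                                 alternative = "less")
    if (res$nc$subnetwork$observed_size > 0) {
      res$cross_nc_in_ad <- cross_apply_subnetwork(res$nc$subnetwork, ad,
                                                   flows_ad, config$covariates_ad)
    }
    if (res$ad$subnetwork$observed_size > 0) {
      res$cross_ad_in_nc <- cross_apply_subnetwork(res$ad$subnetwork, nc,
                                                   flows_nc, config$covariates_nc)
    }
  }

  cfg_for_hash <- config[setdiff(names(config), c("nc", "ad", "out_dir"))]
  res$manifest <- list(
    package = "flowreserve",
    version = as.character(utils::packageVersion("flowreserve")),
    seed = config$seed,
    fiber_threshold = config$fiber_threshold,
    n_permutations = config$n_permutations,
    alpha = config$alpha,
    r_threshold_positive = config$r_threshold_positive,
    r_threshold_negative = config$r_threshold_negative,
    covariates_nc = config$covariates_nc,
    covariates_ad = config$covariates_ad,
    config_hash = rlang::hash(cfg_for_hash)
  )

  if (!is.null(config$out_dir)) write_analysis(res, config$out_dir)
  invisible(res)
}

write_analysis <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (grp in intersect(c("nc", "ad"), names(res))) {
    g <- res[[grp]]
    write_report(g$subnetwork, file.path(out_dir, paste0(grp, "_subnetwork.json")), "json")
    write_report(g$subnetwork, file.path(out_dir, paste0(grp, "_subnetwork.csv")), "csv")
    write_report(g$correlation, file.path(out_dir, paste0(grp, "_correlation.csv")), "csv")
    write_report(g$top_pairs, file.path(out_dir, paste0(grp, "_top_flow_pairs.csv")), "csv")
    write_report(g$summary_measures, file.path(out_dir, paste0(grp, "_summary_measures.csv")), "csv")
    write_report(g$summary_regression, file.path(out_dir, paste0(grp, "_summary_regression.csv")), "csv")
    if (!is.null(g$hubs)) {
      write_report(tidy(g$hubs), file.path(out_dir, paste0(grp, "_hubs.csv")), "csv")
    }
  }
  if (!is.null(res$bonferroni)) {
    write_report(res$bonferroni$significant,
                 file.path(out_dir, "group_ancova_significant.csv"), "csv")
    write_report(res$mean_flow, file.path(out_dir, "group_mean_flow.csv"), "csv")
  }
  invisible(out_dir)
}

#' Cluster test across fiber-count binarization thresholds
#'
#' Rebinarizes each subject's fiber-count matrix at every threshold,
#' recomputes the flows and reruns the cluster test (sub-seed `seed +
#' threshold`), mirroring the robustness check that the subnetwork finding
#' does not hinge on the streamline cutoff.
#'
#' @param cohort an [cohort()] with fiber-count matrices.
#' @param thresholds integer thresholds to test (default 1:5).
#' @param r_threshold,direction,n_permutations,seed,covariates,alpha as in
#'   [cluster_config()].
#' @return Tibble with one row per fiber threshold: `fiber_threshold`,
#'   `r_threshold`, `observed_size`, `p_value`, `p_low`, `p_high`,
#'   `significant`, plus the `result` list-column.
#' @export
sweep_fiber_thresholds <- function(cohort, thresholds = 1:5, r_threshold = 0.32,
                                   direction = c("positive", "negative"),
                                   n_permutations = 1000, seed = 1,
                                   covariates = NULL, alpha = 0.05) {
  direction <- match.arg(direction)
  purrr::map_dfr(thresholds, function(th) {
    reb <- apply_fiber_threshold(cohort, th, required = TRUE)
    flows <- cohort_flows(reb)
    cfg <- cluster_config(r_threshold, direction, n_permutations,
                          seed = seed + th, covariates = covariates,
                          alpha = alpha)
    res <- cluster_size_test(reb, flows, cfg)
    dplyr::mutate(glance(res), fiber_threshold = th, result = list(res),
                  .before = 1)
  })
}
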