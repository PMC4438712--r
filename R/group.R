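# pooled design for ANCOVA-style models: intercept, group indicator, covariates
pooled_design <- function(cohortA, cohortB, covariates) {
  XA <- covariate_matrix(cohortA, covariates)
  XB <- covariate_matrix(cohortB, covariates)
  X <- cbind(intercept = 1,
             group = rep(c(0, 1), c(nrow(XA), nrow(XB))),
             rbind(XA, XB))
  qx <- qr(X)
  if (qx$rank < ncol(X)) abort("pooled covariate design matrix is rank deficient")
  list(X = X, qx = qx)
}

# vectorized linear-model t-test of one coefficient across many outcomes
coef_test <- function(X, qx, Y, coef_name) {
  n <- nrow(X); pcol <- ncol(X)
  if (n <= pcol + 1) abort("too few subjects for the model (n <= parameters + 1)")
  Y <- as.matrix(Y)
  beta <- qr.coef(qx, Y)
  res <- qr.resid(qx, Y)
  sigma2 <- colSums(res^2) / (n - pcol)
  xtx_inv <- chol2inv(qr.R(qx))
  g <- match(coef_name, colnames(X))
  se <- sqrt(sigma2 * xtx_inv[g, g])
  est <- beta[g, ]
  t_stat <- ifelse(se > 0, est / se, NA_real_)
  p <- 2 * pt(-abs(t_stat), df = n - pcol)
  valid <- residual_valid(res, Y) & se > 0
  list(estimate = est, se = se, t = t_stat, p = p, valid = valid,
       df = n - pcol)
}

#' Edgewise group comparison of maximum flow (ANCOVA)
#'
#' For every pair of regions, fits `flow ~ group + covariates` on the pooled
#' subjects of two cohorts and tests the group coefficient (two-sided).
#' Equivalent to a classical one-way ANCOVA with one between-group degree of
#' freedom. Age, sex and education are adjusted for by default. Pairs with
#' zero pooled residual variance are masked.
#'
#' @param cohortA,cohortB two [cohort()]s over the same parcellation.
#' @param flowsA,flowsB their aligned flow lists.
#' @param covariates adjusted covariates (columns of the covariate table).
#' @return An `fr_edge_stat` of kind `"p_value"`, with group-coefficient
#'   estimates in `$estimates` (positive = higher flow in cohort B).
#' @export
edgewise_ancova <- function(cohortA, flowsA, cohortB, flowsB,
                            covariates = c("age", "sex", "education_years")) {
  labels <- flowsA[[1]]$region_labels
  if (!identical(labels, flowsB[[1]]$region_labels)) {
    abort("the two cohorts use different region labels")
  }
  d <- pooled_design(cohortA, cohortB, covariates)
  Y <- rbind(flow_stack(flowsA), flow_stack(flowsB))
  ct <- coef_test(d$X, d$qx, Y, "group")
  V <- length(labels)
  ut <- upper.tri(matrix(0, V, V))
  p <- matrix(0, V, V); est <- matrix(0, V, V); valid <- matrix(FALSE, V, V)
  p[ut] <- ifelse(ct$valid, ct$p, 1)
  est[ut] <- ifelse(ct$valid, ct$estimate, 0)
  valid[ut] <- ct$valid
  p <- p + t(p)
  est <- est + t(est)
  valid <- valid | t(valid)
  diag(p) <- 1
  out <- new_edge_stat(p, valid, "p_value", covariates,
                       nrow(cohortA$covariates) + nrow(cohortB$covariates), labels)
  out$estimates <- est
  out
}

#' Bonferroni correction of an edgewise p-value matrix
#'
#' Multiplies each valid pair's p-value by the number of valid pairs
#' (capped at 1) and lists the pairs significant at `alpha` under the strict
#' `corrected p < alpha` rule, sorted by corrected p.
#'
#' @param p_matrix an `fr_edge_stat` of kind `"p_value"`.
#' @param alpha familywise significance level.
#' @return List with `corrected` (an `fr_edge_stat`) and `significant`
#'   (tibble `region_i`, `region_j`, `i`, `j`, `p`, `p_corrected`, sorted
#'   ascending).
#' @export
bonferroni <- function(p_matrix, alpha = 0.05) {
  stopifnot(inherits(p_matrix, "fr_edge_stat"))
  if (p_matrix$statistic_kind != "p_value") abort("input must be a p-value edge statistic")
  ut <- upper.tri(p_matrix$values)
  m <- sum(p_matrix$valid[ut])
  corrected <- p_matrix
  v <- p_matrix$values * m
  v[v > 1] <- 1
  diag(v) <- 1
  corrected$values <- v
  idx <- which(ut & p_matrix$valid, arr.ind = TRUE)
  sig <- tibble(
    region_i = p_matrix$region_labels[idx[, 1]],
    region_j = p_matrix$region_labels[idx[, 2]],
    i = as.integer(idx[, 1]), j = as.integer(idx[, 2]),
    p = p_matrix$values[idx],
    p_corrected = corrected$values[idx]
  )
  sig <- dplyr::arrange(dplyr::filter(sig, .data$p_corrected < alpha),
                        .data$p_corrected, .data$region_i, .data$region_j)
  list(corrected = corrected, significant = sig, m = m, alpha = alpha)
}

#' Group comparison of per-subject mean flow
#'
#' Averages each subject's flow matrix (over all unordered pairs by default,
#' or only over that subject's realized edges) and compares the two groups
#' with the same ANCOVA model as [edgewise_ancova()].
#'
#' @inheritParams edgewise_ancova
#' @param pairs `"all"` (all V(V-1)/2 pairs) or `"edges"` (each subject's
#'   realized edges only).
#' @return One-row tibble: group difference estimate (B minus A, adjusted),
#'   standard error, t, p.
#' @export
mean_flow_comparison <- function(cohortA, flowsA, cohortB, flowsB,
                                 covariates = c("age", "sex", "education_years"),
                                 pairs = c("all", "edges")) {
  pairs <- match.arg(pairs)
  if (nrow(cohortA$covariates) < 2 || nrow(cohortB$covariates) < 2) {
    abort("each group needs at least two subjects")
  }
  subject_mean <- function(cohort, flows) {
    vapply(seq_along(flows), function(s) {
      v <- flows[[s]]$values
      if (pairs == "all") mean(v[upper.tri(v)])
      else {
        a <- cohort$connectomes[[s]]$adjacency
        sel <- upper.tri(v) & a == 1L
        if (!any(sel)) 0 else mean(v[sel])
      }
    }, numeric(1))
  }
  y <- c(subject_mean(cohortA, flowsA), subject_mean(cohortB, flowsB))
  d <- pooled_design(cohortA, cohortB, covariates)
  ct <- coef_test(d$X, d$qx, matrix(y, ncol = 1), "group")
  tibble(estimate = unname(ct$estimate), se = unname(ct$se),
         t = unname(ct$t), p_value = unname(ct$p), df = ct$df)
}

#' Apply a subnetwork's edge set to another cohort
#'
#' Computes the education-flow partial correlations of another cohort
#' restricted to the pairs of an identified subnetwork, and their mean —
#' e.g. testing whether a subnetwork found in controls carries any education
#' association in patients.
#'
#' @param subnetwork an `fr_subnetwork`.
#' @param cohort,flows the other cohort and its aligned flows.
#' @param covariates covariates for the partial correlation (`NULL` = the
#'   cohort's default).
#' @return List with `mean_r` and `edges` (tibble with per-edge `r`; `NA`
#'   where undefined).
#' @export
cross_apply_subnetwork <- function(subnetwork, cohort, flows, covariates = NULL) {
  stopifnot(inherits(subnetwork, "fr_subnetwork"))
  if (nrow(subnetwork$edges) == 0) abort("subnetwork has no edges")
  if (!identical(subnetwork$region_labels, flows[[1]]$region_labels)) {
    abort("region labels differ between subnetwork and cohort")
  }
  stat <- education_flow_correlation(cohort, flows, covariates)
  edges <- subnetwork$edges[c("region_i", "region_j", "i", "j")]
  edges$r <- ifelse(stat$valid[cbind(edges$i, edges$j)],
                    stat$values[cbind(edges$i, edges$j)], NA_real_)
  list(mean_r = mean(edges$r, na.rm = TRUE), edges = as_tibble(edges))
}

#' Per-subject network summary measures
#'
#' Total edge count, total streamlines, FA sum and maximum-flow sum, each
#' over unordered pairs. Streamline/FA totals are `NA` when the source
#' matrices are absent.
#'
#' @param connectome an [connectome()].
#' @param flow the subject's `fr_flow`.
#' @return One-row tibble: `total_edges`, `total_streamlines`, `fa_sum`,
#'   `flow_sum`.
#' @export
summary_measures <- function(connectome, flow) {
  ut <- upper.tri(connectome$adjacency)
  tibble(
    total_edges = as.integer(sum(connectome$adjacency[ut])),
    total_streamlines = if (is.null(connectome$fiber_count)) NA_integer_
                        else as.integer(sum(connectome$fiber_count[ut])),
    fa_sum = if (is.null(connectome$fa)) NA_real_ else sum(connectome$fa[ut]),
    flow_sum = as.integer(sum(flow$values[ut]))
  )
}

#' Summary measures for every subject of a cohort
#'
#' @param cohort an [cohort()].
#' @param flows aligned flow list.
#' @return Tibble with one row per subject: covariates joined with
#'   [summary_measures()].
#' @export
cohort_summary_measures <- function(cohort, flows) {
  meas <- purrr::map2_dfr(cohort$connectomes, flows, summary_measures)
  dplyr::bind_cols(cohort$covariates, meas)
}

#' Regress a network summary measure on education
#'
#' Gaussian (identity-link) linear regression of one summary measure on
#' education with age and sex as covariates: the model behind tables of
#' education coefficients for global network measures.
#'
#' @param data tibble from [cohort_summary_measures()] (or any table with
#'   the outcome plus `education_years`, `age`, `sex`).
#' @param outcome name of the measure column (e.g. `"flow_sum"`).
#' @param covariates adjusted covariates.
#' @return Tibble of model terms (broom-style): `term`, `estimate`,
#'   `std_error`, `statistic`, `p_value`; the `education_years` row carries
#'   the coefficient of interest.
#' @export
summary_regression <- function(data, outcome,
                               covariates = c("age", "sex")) {
  if (nrow(data) <= 4) abort("need more than 4 subjects")
  vars <- c("education_years", covariates)
  fml <- stats::as.formula(paste(outcome, "~", paste(vars, collapse = " + ")))
  X <- cbind(1, as.matrix(data[vars]))
  if (qr(X)$rank < ncol(X)) abort("regression design is rank deficient (collinear covariates)")
  fit <- lm(fml, data = data)
  sm <- summary(fit)$coefficients
  tibble(term = rownames(sm), estimate = sm[, 1], std_error = sm[, 2],
         statistic = sm[, 3], p_value = sm[, 4])
}
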