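new_edge_stat <- function(values, valid, kind, covariate_names, n_subjects, labels) {
  dimnames(values) <- list(labels, labels)
  structure(list(values = values, valid = valid, statistic_kind = kind,
                 covariate_names = covariate_names, n_subjects = n_subjects,
                 region_labels = labels),
            class = "fr_edge_stat")
}

#' @export
print.fr_edge_stat <- function(x, ...) {
  cat(sprintf("<fr_edge_stat> %s over %d regions, n = %d, covariates: %s; %d/%d valid pairs\n",
              x$statistic_kind, length(x$region_labels), x$n_subjects,
              if (length(x$covariate_names)) paste(x$covariate_names, collapse = ", ") else "none",
              sum(x$valid[upper.tri(x$valid)]), sum(upper.tri(x$valid))))
  invisible(x)
}

#' @describeIn education_flow_correlation Tidy an edge-statistic matrix into
#'   a pair-per-row tibble (`value` is `NA` where the statistic is
#'   undefined).
#' @param x an `fr_edge_stat`.
#' @param ... unused.
#' @export
tidy.fr_edge_stat <- function(x, ...) {
  idx <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble(region_i = x$region_labels[idx[, 1]], region_j = x$region_labels[idx[, 2]],
         i = as.integer(idx[, 1]), j = as.integer(idx[, 2]),
         value = ifelse(x$valid[idx], x$values[idx], NA_real_),
         valid = x$valid[idx])
}

#' @export
autoplot.fr_edge_stat <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(name = object$statistic_kind) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "region j", y = "region i") +
    ggplot2::theme_minimal()
}

design_matrix <- function(covariates) {
  X <- cbind(intercept = 1, as.matrix(covariates))
  qx <- qr(X)
  if (qx$rank < ncol(X)) abort("covariate design matrix is rank deficient")
  qx
}

residual_valid <- function(res, raw) {
  ss_res <- colSums(res^2)
  scale <- pmax(1, colSums(scale(raw, scale = FALSE)^2))
  sqrt(ss_res) > 1e-8 * sqrt(scale)
}

#' Partial correlation by residualization
#'
#' Regresses `x` and `y` on an intercept plus the covariate columns by least
#' squares and returns the Pearson correlation of the two residual vectors.
#' With no covariates this is the plain Pearson correlation.
#'
#' @param x,y numeric vectors of equal length n.
#' @param covariates optional n x k numeric matrix (or data frame).
#' @return The partial correlation in `[-1, 1]`, or `NA_real_` when either
#'   residual vector has (numerically) zero variance, in which case the
#'   statistic is undefined.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) abort("`x` and `y` must have equal length")
  k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n <= k + 2) abort("need n > k + 2 observations")
  if (is.null(covariates)) {
    qx <- qr(matrix(1, n, 1))
  } else {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) abort("`covariates` must have n rows")
    qx <- design_matrix(covariates)
  }
  rx <- qr.resid(qx, x)
  ry <- qr.resid(qx, y)
  ok <- residual_valid(cbind(rx, ry), cbind(x, y))
  if (!all(ok)) return(NA_real_)
  sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
}

default_covariates <- function(cohort) {
  if (identical(unique(as.character(cohort$covariates$group)), "AD") &&
      !anyNA(cohort$covariates$cdr_sob)) {
    c("age", "sex", "cdr_sob")
  } else {
    c("age", "sex")
  }
}

covariate_matrix <- function(cohort, covariate_names) {
  bad <- setdiff(covariate_names, c("age", "sex", "cdr_sob", "education_years"))
  if (length(bad)) abort(paste0("unknown covariates: ", paste(bad, collapse = ", ")))
  cv <- cohort$covariates
  if ("cdr_sob" %in% covariate_names && anyNA(cv$cdr_sob)) {
    abort(paste0("cdr_sob requested as covariate but missing for subjects: ",
                 paste(cv$subject_id[is.na(cv$cdr_sob)], collapse = ", ")))
  }
  as.matrix(cv[covariate_names])
}

flow_stack <- function(flows) {
  ut <- upper.tri(flows[[1]]$values)
  m <- vapply(flows, function(f) as.numeric(f$values[ut]), numeric(sum(ut)))
  t(matrix(m, nrow = sum(ut)))  # n x P
}

# Precompute everything that stays fixed across education permutations:
# covariate QR, residualized flow columns and their norms, and the validity
# mask (pairs whose flow residuals are numerically constant carry no test).
prepare_association <- function(cohort, flows, covariate_names) {
  stopifnot(inherits(cohort, "fr_cohort"))
  if (length(flows) != nrow(cohort$covariates)) {
    abort("`flows` must align with the cohort's subject order")
  }
  labels <- flows[[1]]$region_labels
  Fm <- flow_stack(flows)
  n <- nrow(Fm)
  k <- length(covariate_names)
  if (n <= k + 2) abort("need n > k + 2 subjects")
  qx <- if (k == 0) qr(matrix(1, n, 1)) else
    design_matrix(covariate_matrix(cohort, covariate_names))
  F_res <- qr.resid(qx, Fm)
  valid <- residual_valid(F_res, Fm)
  f_norm <- sqrt(colSums(F_res^2))
  education <- as.numeric(cohort$covariates$education_years)
  list(qx = qx, education = education, F_res = F_res, f_norm = f_norm,
       valid = valid, labels = labels, n = n, k = k,
       covariate_names = covariate_names)
}

# correlation of (residualized) education vector(s) with all flow columns;
# E may be a matrix with one permutation per column -> returns perms x pairs
edu_flow_r <- function(prep, E) {
  E <- as.matrix(E)
  E_res <- qr.resid(prep$qx, E)
  e_norm <- sqrt(colSums(E_res^2))
  r <- crossprod(E_res, prep$F_res) / outer(e_norm, prep$f_norm)
  r[, !prep$valid] <- NA_real_
  r
}

#' Covariate-adjusted correlation of education with pairwise maximum flow
#'
#' For every pair of regions, computes the partial correlation between the
#' subjects' education (years) and their maximum flow values for that pair,
#' adjusting for the requested covariates. Defaults to age and sex; for an
#' AD-labelled cohort with complete CDR-SOB, dementia severity (cdr_sob) is
#' additionally adjusted for so the education effect is not confounded by
#' clinical severity.
#'
#' @param cohort an [cohort()].
#' @param flows list of `fr_flow` aligned with the cohort (see
#'   [cohort_flows()]).
#' @param covariates character subset of `c("age", "sex", "cdr_sob")`;
#'   `NULL` picks the group default described above.
#' @return An `fr_edge_stat` of kind `"partial_r"`. Pairs whose flow is
#'   constant after covariate adjustment are masked invalid rather than set
#'   to zero, and can never enter a suprathreshold edge set.
#' @export
education_flow_correlation <- function(cohort, flows, covariates = NULL) {
  covariates <- covariates %||% default_covariates(cohort)
  prep <- prepare_association(cohort, flows, covariates)
  r <- drop(edu_flow_r(prep, prep$education))
  V <- length(prep$labels)
  values <- matrix(0, V, V)
  valid <- matrix(FALSE, V, V)
  ut <- upper.tri(values)
  values[ut] <- ifelse(is.na(r), 0, r)
  valid[ut] <- prep$valid & !is.na(r)
  values <- values + t(values)
  valid <- valid | t(valid)
  new_edge_stat(values, valid, "partial_r", covariates, prep$n, prep$labels)
}

#' Compare two correlation matrices edgewise with Fisher's z test
#'
#' Tests, for every pair of regions, whether the education-flow correlation
#' differs between two independent groups:
#' `z = (atanh rA - atanh rB) / sqrt(1/(nA-3-kA) + 1/(nB-3-kB))`, where the
#' effective sample sizes subtract the number of adjusted covariates because
#' the inputs are partial correlations. A correlation of +/-1 yields an
#' infinite z, treated as p = 0 (two-sided).
#'
#' @param rA,rB `fr_edge_stat` objects of kind `"partial_r"` with identical
#'   region labels.
#' @param alternative `"two.sided"`, or `"less"`/`"greater"` for the
#'   one-sided hypothesis that rA is smaller/greater than rB.
#' @return An `fr_edge_stat` of kind `"p_value"` with the z matrix stored in
#'   `$z_values`; pairs invalid in either input are masked.
#' @export
compare_correlations <- function(rA, rB, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(rA, "fr_edge_stat"), inherits(rB, "fr_edge_stat"))
  if (rA$statistic_kind != "partial_r" || rB$statistic_kind != "partial_r") {
    abort("both inputs must be partial_r edge statistics")
  }
  if (!identical(rA$region_labels, rB$region_labels)) {
    abort("region labels differ between the two matrices")
  }
  dfA <- rA$n_subjects - 3 - length(rA$covariate_names)
  dfB <- rB$n_subjects - 3 - length(rB$covariate_names)
  if (dfA <= 0 || dfB <= 0) abort("effective sample size n - 3 - k must be positive in both groups")
  se <- sqrt(1 / dfA + 1 / dfB)
  z <- (atanh(rA$values) - atanh(rB$values)) / se
  p <- switch(alternative,
              two.sided = 2 * pnorm(-abs(z)),
              less = pnorm(z),
              greater = pnorm(-z))
  valid <- rA$valid & rB$valid
  diag(z) <- 0
  diag(p) <- 1
  out <- new_edge_stat(p, valid, "p_value",
                       union(rA$covariate_names, rB$covariate_names),
                       rA$n_subjects + rB$n_subjects, rA$region_labels)
  out$z_values <- z
  out$alternative <- alternative
  out
}
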