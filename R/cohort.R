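#' Assemble a cohort from covariates and connectomes
#'
#' A cohort binds a covariate table to one connectome per subject. Row order
#' of `covariates` is the binding between covariate rows and matrices and is
#' preserved by every downstream function.
#'
#' @param covariates tibble/data frame with columns `subject_id`, `group`,
#'   `age`, `sex` (male 0, female 1), `education_years` (0-22) and optionally
#'   `cdr_sob` (Clinical Dementia Rating Sum of Boxes).
#' @param connectomes list of [connectome()] objects, one per covariate row
#'   (optionally named by subject id), all sharing the same region labels.
#' @param name cohort name (e.g. `"NC"` or `"AD"`).
#' @return An object of class `fr_cohort`: list with `name`, `covariates`
#'   (tibble) and `connectomes`.
#' @export
cohort <- function(covariates, connectomes, name = "cohort") {
  covariates <- as_tibble(covariates)
  required <- c("subject_id", "group", "age", "sex", "education_years")
  missing <- setdiff(required, names(covariates))
  if (length(missing)) {
    abort(paste0("covariate table lacks columns: ", paste(missing, collapse = ", ")))
  }
  if (!"cdr_sob" %in% names(covariates)) covariates$cdr_sob <- NA_real_
  covariates$subject_id <- as.character(covariates$subject_id)
  if (anyDuplicated(covariates$subject_id)) abort("subject ids must be unique")
  if (any(!covariates$sex %in% c(0, 1))) abort("`sex` must be coded 0 (male) / 1 (female)")
  if (any(covariates$age <= 0)) abort("`age` must be positive")
  if (any(covariates$education_years < 0 | covariates$education_years > 22)) {
    abort("`education_years` must lie in [0, 22]")
  }
  if (length(connectomes) != nrow(covariates)) {
    abort("need exactly one connectome per covariate row")
  }
  labs <- lapply(connectomes, function(cn) cn$region_labels)
  if (length(unique(labs)) > 1) abort("all connectomes must share identical region labels")
  names(connectomes) <- covariates$subject_id
  structure(list(name = name, covariates = covariates, connectomes = connectomes),
            class = "fr_cohort")
}

#' @export
print.fr_cohort <- function(x, ...) {
  cat(sprintf("<fr_cohort> '%s': %d subjects, %d regions\n",
              x$name, nrow(x$covariates), length(x$connectomes[[1]]$region_labels)))
  print(x$covariates, n = 5)
  invisible(x)
}

#' Number of subjects and regions of a cohort
#' @param x an `fr_cohort`.
#' @param ... unused.
#' @return One-row tibble with `name`, `n_subjects`, `n_regions`,
#'   `mean_education`, `mean_degree`.
#' @export
glance.fr_cohort <- function(x, ...) {
  degs <- vapply(x$connectomes, function(cn) mean(rowSums(cn$adjacency)), numeric(1))
  tibble(
    name = x$name,
    n_subjects = nrow(x$covariates),
    n_regions = length(x$connectomes[[1]]$region_labels),
    mean_education = mean(x$covariates$education_years),
    mean_degree = mean(degs)
  )
}

read_matrix_file <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  dimnames(m) <- NULL
  if (anyNA(m)) abort(sprintf("matrix file '%s' contains NA/NaN entries", basename(path)))
  if (nrow(m) != ncol(m)) {
    abort(sprintf("matrix file '%s' is not square (%d x %d)",
                  basename(path), nrow(m), ncol(m)))
  }
  m
}

symmetrize <- function(m, path, integer_valued, tol = 1e-8) {
  asym <- max(abs(m - t(m)))
  limit <- if (integer_valued) 0 else tol
  if (asym > limit) {
    abort(sprintf("matrix file '%s' is asymmetric (max |a_ij - a_ji| = %g)",
                  basename(path), asym))
  }
  m <- pmax(m, t(m))
  diag(m) <- 0
  m
}

#' Read a cohort from a covariate table plus one matrix file per subject
#'
#' @param covariate_table_path CSV with header
#'   `subject_id,group,age,sex,education_years,cdr_sob`.
#' @param matrix_dir directory containing one delimited (comma or whitespace)
#'   dense V x V matrix file named `<subject_id>.csv` per subject.
#' @param matrix_kind `"fiber_count"` (binarized at `fiber_threshold`),
#'   `"binary"` (already an adjacency matrix), or `"fa"` (FA weights; the
#'   adjacency is taken as FA > 0).
#' @param fiber_threshold streamline threshold for `matrix_kind =
#'   "fiber_count"` (default 3).
#' @param name cohort name; defaults to the unique `group` value if there is
#'   one.
#' @param region_labels optional label vector; defaults to
#'   [default_region_labels()].
#' @return An [cohort()] object. Matrices are symmetrized by `max(a_ij,
#'   a_ji)` only when the asymmetry is within tolerance (exact for integer
#'   kinds, 1e-8 for FA); the diagonal is forced to zero.
#' @export
read_cohort <- function(covariate_table_path, matrix_dir,
                        matrix_kind = c("fiber_count", "binary", "fa"),
                        fiber_threshold = 3, name = NULL, region_labels = NULL) {
  matrix_kind <- match.arg(matrix_kind)
  covariates <- readr::read_csv(covariate_table_path, show_col_types = FALSE)
  connectomes <- vector("list", nrow(covariates))
  V <- NULL
  for (s in seq_len(nrow(covariates))) {
    id <- as.character(covariates$subject_id[s])
    path <- file.path(matrix_dir, paste0(id, ".csv"))
    if (!file.exists(path)) abort(sprintf("no matrix file for subject '%s' (%s)", id, path))
    m <- read_matrix_file(path)
    if (is.null(V)) V <- nrow(m)
    if (nrow(m) != V) {
      abort(sprintf("matrix file '%s' has dimension %d, expected %d",
                    basename(path), nrow(m), V))
    }
    m <- symmetrize(m, path, integer_valued = matrix_kind != "fa")
    labs <- region_labels %||% default_region_labels(V)
    connectomes[[s]] <- switch(matrix_kind,
      fiber_count = connectome(fiber_count = m, region_labels = labs,
                               fiber_threshold = fiber_threshold),
      binary = connectome(adjacency = m, region_labels = labs),
      fa = connectome(adjacency = (m > 0) * 1L, fa = m, region_labels = labs)
    )
  }
  name <- name %||% {
    g <- unique(as.character(covariates$group))
    if (length(g) == 1) g else "cohort"
  }
  cohort(covariates, connectomes, name = name)
}

#' Write a cohort as a covariate CSV plus per-subject matrix files
#'
#' Inverse of [read_cohort()]: writes `covariates.csv` and one
#' `<subject_id>.csv` per subject into `dir`.
#'
#' @param x an `fr_cohort`.
#' @param dir output directory (created if needed).
#' @param matrix_kind which matrix to write per subject.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(x, dir, matrix_kind = c("fiber_count", "binary", "fa")) {
  matrix_kind <- match.arg(matrix_kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(x$covariates, file.path(dir, "covariates.csv"))
  for (s in seq_len(nrow(x$covariates))) {
    cn <- x$connectomes[[s]]
    m <- switch(matrix_kind, fiber_count = cn$fiber_count,
                binary = cn$adjacency, fa = cn$fa)
    if (is.null(m)) abort(sprintf("subject '%s' has no %s matrix",
                                  x$covariates$subject_id[s], matrix_kind))
    utils::write.table(m, file.path(dir, paste0(x$covariates$subject_id[s], ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}
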