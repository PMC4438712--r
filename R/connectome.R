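#' Construct a single-subject connectome
#'
#' A connectome bundles the matrices describing one subject's white-matter
#' network over a fixed parcellation: a binary adjacency matrix (always
#' present), and optionally the fiber-count (streamline) matrix it was
#' thresholded from and a fractional-anisotropy (FA) matrix. All matrices are
#' square, symmetric, zero-diagonal and share the region labels.
#'
#' @param adjacency V x V binary symmetric matrix (0/1, zero diagonal). If
#'   omitted and `fiber_count` is given, it is derived with [binarize()] at
#'   `fiber_threshold`.
#' @param fiber_count optional V x V nonnegative integer matrix of streamline
#'   counts.
#' @param fa optional V x V matrix of mean FA values in `[0, 1]`.
#' @param region_labels character vector of region names; defaults to
#'   [default_region_labels()] of the matrix dimension.
#' @param fiber_threshold threshold used when deriving `adjacency` from
#'   `fiber_count` (default 3 streamlines, i.e. an edge requires a bundle of
#'   three or more fiber tracts).
#' @return An object of class `fr_connectome`: a list with elements
#'   `region_labels`, `adjacency`, `fiber_count`, `fa`, `fiber_threshold`.
#' @export
connectome <- function(adjacency = NULL, fiber_count = NULL, fa = NULL,
                       region_labels = NULL, fiber_threshold = 3) {
  if (is.null(adjacency) && is.null(fiber_count)) {
    abort("supply `adjacency` or `fiber_count`")
  }
  if (!is.null(fiber_count)) {
    check_square_symmetric(fiber_count, "fiber_count")
    if (any(fiber_count < 0)) abort("`fiber_count` has negative entries")
    storage.mode(fiber_count) <- "integer"
    diag(fiber_count) <- 0L
  }
  if (is.null(adjacency)) {
    adjacency <- binarize(fiber_count, fiber_threshold)
  } else {
    check_square_symmetric(adjacency, "adjacency")
    if (!all(adjacency %in% c(0, 1))) abort("`adjacency` must be binary (0/1)")
    storage.mode(adjacency) <- "integer"
    diag(adjacency) <- 0L
  }
  V <- nrow(adjacency)
  if (!is.null(fiber_count) && nrow(fiber_count) != V) {
    abort("`fiber_count` and `adjacency` dimensions differ")
  }
  if (!is.null(fa)) {
    check_square_symmetric(fa, "fa")
    if (nrow(fa) != V) abort("`fa` dimension differs from `adjacency`")
    if (any(fa < 0 | fa > 1)) abort("`fa` entries must lie in [0, 1]")
    diag(fa) <- 0
  }
  region_labels <- region_labels %||% default_region_labels(V)
  if (length(region_labels) != V) abort("`region_labels` length must equal V")
  if (anyDuplicated(region_labels)) abort("`region_labels` must be unique")
  dimnames(adjacency) <- list(region_labels, region_labels)
  structure(
    list(region_labels = region_labels, adjacency = adjacency,
         fiber_count = fiber_count, fa = fa, fiber_threshold = fiber_threshold),
    class = "fr_connectome"
  )
}

check_square_symmetric <- function(m, what, tol = 1e-8) {
  if (!is.matrix(m)) abort(paste0("`", what, "` must be a matrix"))
  if (nrow(m) != ncol(m)) {
    abort(sprintf("`%s` must be square (got %d x %d)", what, nrow(m), ncol(m)))
  }
  if (anyNA(m)) abort(paste0("`", what, "` contains NA/NaN entries"))
  if (max(abs(m - t(m))) > tol) abort(paste0("`", what, "` is not symmetric"))
  invisible(m)
}

#' Threshold a fiber-count matrix into a binary adjacency matrix
#'
#' Two regions are connected iff the fiber bundle between them contains at
#' least `threshold` streamlines. The default of 3 follows the common rule
#' that a bundle of three or more fiber tracts is required, which suppresses
#' false-positive connections from tractography noise.
#'
#' @param fiber_count symmetric nonnegative integer matrix.
#' @param threshold positive integer; an entry of `threshold` or more becomes
#'   an edge.
#' @return Integer 0/1 matrix with zero diagonal. Monotone in `threshold`:
#'   raising the threshold can only remove edges.
#' @export
binarize <- function(fiber_count, threshold = 3) {
  if (length(threshold) != 1 || is.na(threshold) || threshold < 1) {
    abort("`threshold` must be a single integer >= 1")
  }
  check_square_symmetric(fiber_count, "fiber_count")
  if (any(fiber_count < 0)) abort("`fiber_count` has negative entries")
  adj <- (fiber_count >= threshold) * 1L
  diag(adj) <- 0L
  storage.mode(adj) <- "integer"
  dimnames(adj) <- dimnames(fiber_count)
  adj
}

#' Region labels for a parcellation of V nodes
#'
#' For V = 90 returns the standard AAL-90 label ordering (78 cortical plus 12
#' subcortical regions, left/right interleaved), shipped with the package.
#' Input matrices must follow this row order for region names in reports to
#' be meaningful. For any other V, generic labels `"R001"`, `"R002"`, ... are
#' returned.
#'
#' @param V number of nodes.
#' @return Character vector of V unique labels, stable across calls.
#' @export
default_region_labels <- function(V) {
  if (length(V) != 1 || is.na(V) || V < 1) abort("`V` must be a positive integer")
  if (V == 90) {
    path <- system.file("extdata", "aal90_labels.tsv", package = "flowreserve")
    tbl <- utils::read.delim(path, stringsAsFactors = FALSE)
    return(tbl$label[order(tbl$index)])
  }
  sprintf("R%03d", seq_len(V))
}

#' @export
print.fr_connectome <- function(x, ...) {
  V <- length(x$region_labels)
  cat(sprintf("<fr_connectome> %d regions, %d edges", V, sum(x$adjacency) / 2L))
  if (!is.null(x$fiber_count)) cat(", fiber counts present")
  if (!is.null(x$fa)) cat(", FA present")
  cat("\n")
  invisible(x)
}

#' @export
tidy.fr_connectome <- function(x, ...) {
  idx <- which(upper.tri(x$adjacency) & x$adjacency == 1L, arr.ind = TRUE)
  tibble(
    region_i = x$region_labels[idx[, 1]],
    region_j = x$region_labels[idx[, 2]],
    i = as.integer(idx[, 1]), j = as.integer(idx[, 2]),
    fiber_count = if (is.null(x$fiber_count)) NA_integer_ else x$fiber_count[idx],
    fa = if (is.null(x$fa)) NA_real_ else x$fa[idx]
  )
}
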