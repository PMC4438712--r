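#' Maximum flow between two nodes of a binary network
#'
#' For a binary (unit-capacity) undirected graph the maximum flow from
#' `source` to `sink` equals the number of pairwise edge-disjoint paths
#' between them (Menger's theorem), which is the reliability notion used
#' throughout this package: how many alternative routes connect two regions.
#' The computation replaces each undirected edge by two opposite unit arcs
#' and runs shortest (BFS) augmenting paths; the result is an exact integer.
#'
#' @param adjacency symmetric binary matrix with zero diagonal.
#' @param source,sink distinct node indices in `1:V`.
#' @return Nonnegative integer count of edge-disjoint paths.
#' @seealso [brute_force_min_cut()] for the enumeration cross-check,
#'   [pairwise_flow()] for all pairs at once.
#' @export
max_flow <- function(adjacency, source, sink) {
  check_square_symmetric(adjacency, "adjacency")
  if (!all(adjacency %in% c(0, 1))) abort("`adjacency` must be binary (0/1)")
  V <- nrow(adjacency)
  if (source < 1 || source > V || sink < 1 || sink > V) {
    abort("`source`/`sink` out of range")
  }
  if (source == sink) abort("`source` and `sink` must differ")
  storage.mode(adjacency) <- "integer"
  diag(adjacency) <- 0L
  .cpp_max_flow(adjacency, source - 1L, sink - 1L)
}

#' Brute-force minimum edge cut (test oracle)
#'
#' Enumerates every vertex bipartition separating `source` from `sink` and
#' returns the minimum number of crossing edges. By the max-flow-min-cut
#' theorem this equals [max_flow()]; it is deliberately independent of the
#' augmenting-path implementation and is intended for validation on small
#' graphs only.
#'
#' @inheritParams max_flow
#' @return Minimum crossing-edge count over all separating bipartitions.
#' @export
brute_force_min_cut <- function(adjacency, source, sink) {
  check_square_symmetric(adjacency, "adjacency")
  V <- nrow(adjacency)
  if (V > 12) abort("brute_force_min_cut enumerates 2^(V-2) cuts; V must be <= 12 (use in tests only)")
  if (source == sink) abort("`source` and `sink` must differ")
  others <- setdiff(seq_len(V), c(source, sink))
  k <- length(others)
  n_sets <- 2^k
  # side matrix: 1 = source side; all subsets of `others`
  side <- matrix(0L, n_sets, V)
  side[, source] <- 1L
  if (k > 0) {
    bits <- vapply(seq_len(k), function(b) bitwAnd(seq_len(n_sets) - 1L, bitwShiftL(1L, b - 1L)) > 0,
                   logical(n_sets))
    side[, others] <- bits * 1L
  }
  cuts <- rowSums((side %*% adjacency) * (1L - side))
  as.integer(min(cuts))
}

#' All-pairs maximum flow for one connectome
#'
#' Computes the maximum flow value between every pair of regions of a binary
#' network. Internally a Gomory-Hu-style flow-equivalent tree (Gusfield's
#' algorithm) reduces the work to V - 1 max-flow computations; the values are
#' identical to calling [max_flow()] on every pair.
#'
#' @param connectome an [connectome()] (its `adjacency` is used), or a bare
#'   binary adjacency matrix.
#' @return An `fr_flow` object: list with `values` (symmetric integer V x V
#'   matrix, zero diagonal) and `region_labels`.
#' @export
pairwise_flow <- function(connectome) {
  if (inherits(connectome, "fr_connectome")) {
    adj <- connectome$adjacency
    labels <- connectome$region_labels
  } else {
    check_square_symmetric(connectome, "adjacency")
    adj <- connectome
    labels <- rownames(adj) %||% default_region_labels(nrow(adj))
  }
  storage.mode(adj) <- "integer"
  diag(adj) <- 0L
  values <- .cpp_all_pairs_flow(adj)
  dimnames(values) <- list(labels, labels)
  structure(list(values = values, region_labels = labels), class = "fr_flow")
}

#' All-pairs flow matrices for every subject of a cohort
#'
#' @param cohort an [cohort()].
#' @return Named list of `fr_flow`, aligned to (and named by) the cohort's
#'   subject order.
#' @export
cohort_flows <- function(cohort) {
  stopifnot(inherits(cohort, "fr_cohort"))
  purrr::map(cohort$connectomes, pairwise_flow)
}

#' @export
print.fr_flow <- function(x, ...) {
  cat(sprintf("<fr_flow> %d regions, flow range %d..%d\n",
              length(x$region_labels), min(x$values), max(x$values)))
  invisible(x)
}

#' @export
tidy.fr_flow <- function(x, ...) {
  idx <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble(region_i = x$region_labels[idx[, 1]], region_j = x$region_labels[idx[, 2]],
         i = as.integer(idx[, 1]), j = as.integer(idx[, 2]),
         flow = as.integer(x$values[idx]))
}

#' Rank node pairs by group-level maximum flow
#'
#' Aggregates each pair's flow value across subjects (mean by default,
#' median by option) and ranks pairs in decreasing order; ties are broken
#' lexicographically by region labels.
#'
#' @param flows list of `fr_flow` with identical labels (e.g. from
#'   [cohort_flows()]).
#' @param k number of top pairs to return; clamped to the number of pairs.
#' @param aggregate `"mean"` or `"median"`.
#' @return Tibble with `rank`, `region_i`, `region_j`, `i`, `j`, `value`.
#' @export
top_flow_pairs <- function(flows, k = 10, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  if (length(flows) == 0) abort("`flows` is empty")
  if (k < 1) abort("`k` must be >= 1")
  labels <- flows[[1]]$region_labels
  same <- vapply(flows, function(f) identical(f$region_labels, labels), logical(1))
  if (!all(same)) abort("all flow matrices must share identical region labels")
  ut <- upper.tri(flows[[1]]$values)
  stacked <- vapply(flows, function(f) f$values[ut], numeric(sum(ut)))
  stacked <- matrix(stacked, nrow = sum(ut))
  value <- if (aggregate == "mean") rowMeans(stacked) else
    apply(stacked, 1, stats::median)
  idx <- which(ut, arr.ind = TRUE)
  out <- tibble(region_i = labels[idx[, 1]], region_j = labels[idx[, 2]],
                i = as.integer(idx[, 1]), j = as.integer(idx[, 2]), value = value)
  out <- dplyr::arrange(out, dplyr::desc(.data$value), .data$region_i, .data$region_j)
  out$rank <- seq_len(nrow(out))
  head(dplyr::relocate(out, "rank"), min(k, nrow(out)))
}

#' @export
autoplot.fr_flow <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i, fill = .data$flow)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "max flow") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "region j", y = "region i",
                  title = "Pairwise maximum flow (edge-disjoint paths)") +
    ggplot2::theme_minimal()
}
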