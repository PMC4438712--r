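check_writable <- function(path) {
  if (!dir.exists(dirname(path))) {
    abort(sprintf("cannot write '%s': directory does not exist", path))
  }
  invisible(path)
}

#' Write an analysis result to disk
#'
#' CSV output is an edge list (`region_i`, `region_j`, `value` rows); JSON
#' output additionally carries the test metadata (threshold, direction,
#' p-value and interval, permutation count, seed) and round-trips through
#' [read_subnetwork()] losslessly for the fields written.
#'
#' @param x an `fr_subnetwork`, `fr_edge_stat`, or data frame.
#' @param path output file path (its directory must exist).
#' @param format `"json"` or `"csv"`; data frames are always CSV.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("json", "csv")) {
  UseMethod("write_report")
}

#' @export
write_report.fr_subnetwork <- function(x, path, format = c("json", "csv")) {
  format <- match.arg(format)
  check_writable(path)
  if (format == "csv") {
    edges <- x$edges[c("region_i", "region_j", "r")]
    names(edges)[3] <- "value"
    readr::write_csv(edges, path)
  } else {
    payload <- list(
      type = "subnetwork",
      r_threshold = x$config$r_threshold,
      direction = x$config$direction,
      n_permutations = x$config$n_permutations,
      seed = x$config$seed,
      alpha = x$config$alpha,
      covariates = x$covariate_names,
      n_subjects = x$n_subjects,
      observed_size = x$observed_size,
      p_value = x$p_value,
      p_interval = as.list(x$p_interval),
      significant = x$significant,
      nodes = x$nodes,
      edges = x$edges,
      null_sizes = x$null_sizes
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  }
  invisible(path)
}

#' Read a subnetwork JSON report back into an `fr_subnetwork`
#'
#' @param path a JSON file written by [write_report()].
#' @return An `fr_subnetwork` equivalent to the one written (for the fields
#'   serialized).
#' @export
read_subnetwork <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$type, "subnetwork")) abort("not a subnetwork report")
  cfg <- cluster_config(x$r_threshold, x$direction, x$n_permutations,
                        seed = x$seed, covariates = x$covariates,
                        alpha = x$alpha)
  nodes <- as.integer(unlist(x$nodes))
  ed <- x$edges
  if (is.null(ed) || length(ed) == 0 || length(unlist(ed$i)) == 0) {
    edges <- tibble(region_i = character(0), region_j = character(0),
                    i = integer(0), j = integer(0), r = numeric(0))
  } else {
    edges <- as_tibble(lapply(ed, unlist))
  }
  labels <- character(max(c(nodes, 1L, edges$i, edges$j)))
  labels[edges$i] <- edges$region_i
  labels[edges$j] <- edges$region_j
  structure(list(
    edges = edges, nodes = nodes,
    observed_size = as.integer(x$observed_size), p_value = x$p_value,
    p_interval = c(low = x$p_interval$low, high = x$p_interval$high),
    null_sizes = as.integer(unlist(x$null_sizes)), config = cfg,
    covariate_names = x$covariates, n_subjects = x$n_subjects,
    region_labels = labels, significant = isTRUE(x$significant)
  ), class = "fr_subnetwork")
}

#' @export
write_report.fr_edge_stat <- function(x, path, format = c("json", "csv")) {
  format <- match.arg(format)
  check_writable(path)
  df <- tidy(x)
  if (format == "csv") {
    out <- dplyr::filter(df, .data$valid)[c("region_i", "region_j", "value")]
    readr::write_csv(out, path)
  } else {
    jsonlite::write_json(
      list(type = "edge_stat", statistic_kind = x$statistic_kind,
           covariates = x$covariate_names, n_subjects = x$n_subjects,
           edges = dplyr::filter(df, .data$valid)),
      path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  invisible(path)
}

#' @export
write_report.data.frame <- function(x, path, format = c("json", "csv")) {
  format <- match.arg(format)
  check_writable(path)
  if (format == "csv") readr::write_csv(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                            dataframe = "columns")
  invisible(path)
}
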