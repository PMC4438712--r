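edge_graph <- function(edges) {
  edges <- as.data.frame(edges)
  nodes <- sort(unique(c(edges$i, edges$j)))
  g <- igraph::graph_from_edgelist(
    cbind(match(edges$i, nodes), match(edges$j, nodes)), directed = FALSE)
  list(g = g, nodes = nodes)
}

#' Node degrees within a subnetwork
#'
#' @param edges tibble/matrix of node pairs (`i`, `j`).
#' @return Tibble `node`, `degree` (count of incident subnetwork edges),
#'   covering the nodes touched by the edge set; empty edge set gives an
#'   empty table. Degrees sum to twice the edge count.
#' @export
subnetwork_degrees <- function(edges) {
  edges <- as.data.frame(edges)
  if (nrow(edges) == 0) return(tibble(node = integer(0), degree = integer(0)))
  tab <- table(factor(c(edges$i, edges$j)))
  tibble(node = as.integer(names(tab)), degree = as.integer(tab))
}

#' Betweenness centrality of subnetwork nodes
#'
#' Unweighted shortest-path betweenness on the graph induced by the edge
#' set: for each node, the number of shortest paths between other node
#' pairs passing through it, with ties split equally across equal-length
#' shortest paths. Raw pair counts (no normalization) — rankings, the use
#' made of hubs, are unaffected by normalization.
#'
#' @param edges edge set forming one connected cluster.
#' @return Tibble `node`, `betweenness`.
#' @export
betweenness <- function(edges) {
  eg <- connected_edge_graph(edges, "betweenness")
  tibble(node = eg$nodes,
         betweenness = as.numeric(igraph::betweenness(eg$g, directed = FALSE)))
}

#' Closeness centrality of subnetwork nodes
#'
#' `(N - 1) / sum(shortest-path distances to the other cluster nodes)`,
#' computed within the (connected) cluster.
#'
#' @inheritParams betweenness
#' @return Tibble `node`, `closeness`.
#' @export
closeness <- function(edges) {
  eg <- connected_edge_graph(edges, "closeness")
  tibble(node = eg$nodes,
         closeness = as.numeric(igraph::closeness(eg$g, normalized = TRUE)))
}

connected_edge_graph <- function(edges, what) {
  edges <- as.data.frame(edges)
  if (nrow(edges) == 0) abort(paste0(what, " needs a non-empty edge set"))
  eg <- edge_graph(edges)
  if (igraph::components(eg$g)$no > 1) {
    abort(paste0(what, " requires a connected cluster; compute it per cluster"))
  }
  eg
}

#' Hub characterization of a subnetwork
#'
#' Per-node degree, betweenness and closeness within the subnetwork, plus
#' the hub nodes — those attaining the maximum of each metric. Ties are
#' reported as lists of nodes, never silently broken.
#'
#' @param subnetwork an `fr_subnetwork` (or a bare edge tibble).
#' @param labels region labels; taken from the subnetwork when available.
#' @return An `fr_hub_report`: list with `table` (tibble `node`, `label`,
#'   `degree`, `betweenness`, `closeness`) and `hubs` (named list of label
#'   vectors per metric).
#' @export
hub_report <- function(subnetwork, labels = NULL) {
  if (inherits(subnetwork, "fr_subnetwork")) {
    edges <- subnetwork$edges
    labels <- labels %||% subnetwork$region_labels
  } else {
    edges <- as.data.frame(subnetwork)
  }
  if (nrow(edges) == 0) abort("subnetwork has no edges")
  labels <- labels %||% default_region_labels(max(c(edges$i, edges$j)))
  deg <- subnetwork_degrees(edges)
  btw <- betweenness(edges)
  cls <- closeness(edges)
  tab <- dplyr::left_join(dplyr::left_join(deg, btw, by = "node"), cls, by = "node")
  tab$label <- labels[tab$node]
  tab <- dplyr::relocate(dplyr::arrange(tab, dplyr::desc(.data$degree)), "node", "label")
  argmax <- function(col) tab$label[which(tab[[col]] == max(tab[[col]]))]
  structure(list(
    table = tab,
    hubs = list(degree = argmax("degree"), betweenness = argmax("betweenness"),
                closeness = argmax("closeness"))
  ), class = "fr_hub_report")
}

#' @export
print.fr_hub_report <- function(x, ...) {
  cat(sprintf("<fr_hub_report> %d nodes\n", nrow(x$table)))
  cat("  hub by degree:      ", paste(x$hubs$degree, collapse = ", "), "\n")
  cat("  hub by betweenness: ", paste(x$hubs$betweenness, collapse = ", "), "\n")
  cat("  hub by closeness:   ", paste(x$hubs$closeness, collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn hub_report Per-node metric table.
#' @param x an `fr_hub_report`.
#' @param ... unused.
#' @export
tidy.fr_hub_report <- function(x, ...) x$table
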