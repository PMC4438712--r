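# independent oracles and graph builders used across the suite;
# deliberately naive implementations, kept separate from the package's own
# algorithms so agreement is informative

k_graph <- function(n) {
  a <- matrix(1L, n, n); diag(a) <- 0L; a
}

cycle_graph <- function(n) {
  a <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a[i, j] <- a[j, i] <- 1L
  }
  a
}

star_graph <- function(leaves) {
  a <- matrix(0L, leaves + 1, leaves + 1)
  a[1, -1] <- a[-1, 1] <- 1L
  a
}

path_graph <- function(n) {
  a <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1L
  a
}

rand_graph <- function(V, p) {
  a <- matrix(0L, V, V)
  ut <- upper.tri(a)
  a[ut] <- stats::rbinom(sum(ut), 1L, p)
  a + t(a)
}

rand_connected_graph <- function(V, p) {
  repeat {
    a <- rand_graph(V, p)
    if (igraph::is_connected(igraph::graph_from_adjacency_matrix(a, "undirected"))) {
      return(a)
    }
  }
}

random_tree <- function(n) {
  a <- matrix(0L, n, n)
  for (i in 2:n) {
    j <- sample.int(i - 1, 1)
    a[i, j] <- a[j, i] <- 1L
  }
  a
}

# union-find oracle for clustering node pairs that share a node
uf_cluster_sizes <- function(i, j) {
  if (length(i) == 0) return(integer(0))
  nodes <- sort(unique(c(i, j)))
  parent <- seq_along(nodes)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (e in seq_along(i)) {
    a <- find(match(i[e], nodes)); b <- find(match(j[e], nodes))
    if (a != b) parent[a] <- b
  }
  roots <- vapply(match(i, nodes), find, integer(1))
  as.integer(sort(table(roots), decreasing = TRUE))
}

bfs_dist <- function(adj, from) {
  V <- nrow(adj)
  d <- rep(Inf, V); d[from] <- 0
  frontier <- from
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) {
      nb <- which(adj[u, ] == 1L & is.infinite(d))
      d[nb] <- d[u] + 1
      nxt <- c(nxt, nb)
    }
    frontier <- unique(nxt)
  }
  d
}

# all simple paths between s and t by DFS (tiny graphs only)
all_simple_paths <- function(adj, s, t) {
  paths <- list()
  walk <- function(u, visited) {
    if (u == t) {
      paths[[length(paths) + 1]] <<- visited
      return(invisible())
    }
    for (v in which(adj[u, ] == 1L)) {
      if (!(v %in% visited)) walk(v, c(visited, v))
    }
  }
  walk(s, s)
  paths
}

# brute-force betweenness: enumerate shortest paths for every pair, credit
# interior nodes 1/(number of shortest paths)
brute_betweenness <- function(adj) {
  V <- nrow(adj)
  btw <- numeric(V)
  for (s in 1:(V - 1)) for (t in (s + 1):V) {
    paths <- all_simple_paths(adj, s, t)
    if (!length(paths)) next
    lens <- vapply(paths, length, integer(1))
    short <- paths[lens == min(lens)]
    for (p in short) {
      interior <- setdiff(p, c(s, t))
      btw[interior] <- btw[interior] + 1 / length(short)
    }
  }
  btw
}

brute_closeness <- function(adj) {
  V <- nrow(adj)
  vapply(1:V, function(v) (V - 1) / sum(bfs_dist(adj, v)[-v]), numeric(1))
}

# residualize-then-Pearson partial correlation via explicit normal equations
oracle_partial_cor <- function(x, y, Z = NULL) {
  n <- length(x)
  X <- cbind(rep(1, n), Z)
  solve_beta <- function(v) solve(t(X) %*% X, t(X) %*% v)
  rx <- x - X %*% solve_beta(x)
  ry <- y - X %*% solve_beta(y)
  sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
}

# small planted cohort used by several tests
tiny_cohort <- function(n = 20, V = 15, beta = 0.8, seed = 1, group = "NC") {
  pp <- if (V >= 14) 2L else 1L
  rr <- if (V >= 14) 2L else 1L
  cfg <- sim_config(n_subjects = n, V = V, n_planted_pairs = pp,
                    n_relays_per_pair = rr,
                    n_hub_anchors = min(2L, V - 1L - pp * (1L + rr)),
                    effect_beta = beta, group = group, seed = seed)
  generate_cohort(cfg)
}

set_education <- function(cohort, edu) {
  cohort$covariates$education_years <- as.integer(edu)
  cohort
}

flow_obj <- function(values, labels = NULL) {
  labels <- labels %||% sprintf("R%03d", seq_len(nrow(values)))
  dimnames(values) <- list(labels, labels)
  structure(list(values = values, region_labels = labels), class = "fr_flow")
}

all_permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (k in seq_along(x)) {
    for (rest in all_permutations(x[-k])) out[[length(out) + 1]] <- c(x[k], rest)
  }
  out
}
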