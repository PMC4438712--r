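#' Configuration for the synthetic-cohort generator
#'
#' Describes a cohort of binary connectomes in which the maximum flow over a
#' planted subnetwork is stochastically linked to education. Subjects share a
#' modular backbone graph; independent per-subject edge flips add noise; and
#' for each planted node pair (hub, partner) a pool of dedicated relay nodes
#' carries 2-paths hub-relay-partner whose presence probability follows a
#' logistic model in the subject's standardized education. Each present relay
#' path contributes one extra edge-disjoint route, so the hub-partner maximum
#' flow rises (or falls) with education.
#'
#' Demographic defaults follow a two-group memory-clinic design: education in
#' years as a rounded normal clipped to 0-22 (NC-like mean 11.33, sd 4.77;
#' AD-like 10.18, 5.41), age ~70 (5.99) / ~72 (9.09), balanced sex coded
#' male 0 / female 1, and CDR-SOB ~5.72 (2.90) for the AD-like preset.
#'
#' @param n_subjects subjects to generate (default 80).
#' @param V nodes (default 90).
#' @param base_density overall backbone edge probability; the generator uses
#'   a 5:1 within:between module density ratio that matches this average.
#'   Default 0.17 (mean degree about 15 at V = 90).
#' @param n_modules modular blocks in the backbone (default 6).
#' @param edge_noise per-subject, per-cell flip rate outside the planted
#'   machinery (default 0.05).
#' @param planted_hub hub node index; defaults to 63 (left supramarginal
#'   gyrus in the AAL-90 ordering) when V = 90, else 1.
#' @param planted_pairs optional two-column matrix of planted node pairs; by
#'   default `n_planted_pairs` partners are drawn for the hub.
#' @param n_planted_pairs number of hub-partner pairs (default 8).
#' @param n_relays_per_pair dedicated relay nodes per planted pair (default 2).
#' @param n_hub_anchors fixed backbone edges given to the hub (default 2).
#'   The hub takes part in the backbone only through these anchors, so its
#'   connectivity — and therefore the maximum flow between the hub and any
#'   well-connected region — is dominated by how many of its relay routes
#'   are present. This concentrates the education effect on the hub's node
#'   pairs instead of letting partner/relay degree fluctuations spread it
#'   over the whole network.
#' @param effect_beta logistic slope on standardized education for relay-path
#'   presence; sign sets the direction, 0 is the null. The default 0.26 is
#'   calibrated so the mean planted-pair partial correlation with education
#'   is about 0.44 at n = 80.
#' @param alpha0 logistic intercept; 0 gives baseline relay inclusion 0.5.
#' @param education_dist `"empirical"` (rounded clipped normal) or
#'   `"uniform"` (integers 0-22).
#' @param education_mean,education_sd parameters of the empirical education
#'   distribution.
#' @param age_mean,age_sd,sex_p,cdr_mean,cdr_sd demographic parameters;
#'   `cdr_mean = NA` omits CDR-SOB.
#' @param group `"NC"` or `"AD"`; picks demographic defaults for any of the
#'   above left `NULL`.
#' @param graded_fibers if `TRUE`, draw dispersed fiber counts (planted
#'   machinery 5 + Poisson(2), other edges 1 + Poisson(2.5)) and define the
#'   adjacency by thresholding at 3, so fiber-threshold sweeps are
#'   non-trivial; if `FALSE` every edge carries exactly 3 fibers and
#'   binarization at the default threshold is the identity.
#' @param include_fa attach a constant-FA matrix (0.4 on edges).
#' @param seed RNG seed; identical config + seed gives a bit-identical
#'   cohort.
#' @param structure_seed separate seed for the shared anatomy (backbone graph
#'   and planted-machinery placement). Defaults to `seed`. Give two group
#'   configs the same `structure_seed` (and different `seed`s) to generate
#'   cohorts over a common anatomy, as for subjects drawn from one
#'   population — group comparisons are only meaningful in that setting.
#' @return A validated `fr_sim_config` list.
#' @export
sim_config <- function(n_subjects = 80, V = 90, base_density = 0.17,
                       n_modules = 6, edge_noise = 0.05, planted_hub = NULL,
                       planted_pairs = NULL, n_planted_pairs = 8,
                       n_relays_per_pair = 2, n_hub_anchors = 2,
                       effect_beta = 0.26, alpha0 = 0,
                       education_dist = c("empirical", "uniform"),
                       education_mean = NULL, education_sd = NULL,
                       age_mean = NULL, age_sd = NULL, sex_p = 0.5,
                       cdr_mean = NULL, cdr_sd = NULL, group = "NC",
                       graded_fibers = FALSE, include_fa = FALSE, seed = 1,
                       structure_seed = NULL) {
  education_dist <- match.arg(education_dist)
  ad_like <- identical(group, "AD")
  cfg <- list(
    n_subjects = n_subjects, V = V, base_density = base_density,
    n_modules = n_modules, edge_noise = edge_noise,
    planted_hub = planted_hub %||% (if (V == 90) 63L else 1L),
    planted_pairs = planted_pairs, n_planted_pairs = n_planted_pairs,
    n_relays_per_pair = n_relays_per_pair, n_hub_anchors = n_hub_anchors,
    effect_beta = effect_beta,
    alpha0 = alpha0, education_dist = education_dist,
    education_mean = education_mean %||% (if (ad_like) 10.18 else 11.33),
    education_sd = education_sd %||% (if (ad_like) 5.41 else 4.77),
    age_mean = age_mean %||% (if (ad_like) 72.09 else 70.18),
    age_sd = age_sd %||% (if (ad_like) 9.09 else 5.99),
    sex_p = sex_p,
    cdr_mean = cdr_mean %||% (if (ad_like) 5.72 else NA_real_),
    cdr_sd = cdr_sd %||% (if (ad_like) 2.90 else NA_real_),
    group = group, graded_fibers = graded_fibers, include_fa = include_fa,
    seed = as.integer(seed),
    structure_seed = as.integer(structure_seed %||% seed)
  )
  stopifnot(cfg$n_subjects >= 2, cfg$V >= 3, cfg$n_modules >= 1,
            cfg$n_relays_per_pair >= 1)
  if (cfg$base_density < 0 || cfg$base_density > 1) abort("`base_density` must lie in [0, 1]")
  if (cfg$edge_noise < 0 || cfg$edge_noise > 1) abort("`edge_noise` must lie in [0, 1]")
  if (!is.finite(cfg$effect_beta)) abort("`effect_beta` must be finite")
  structure(cfg, class = "fr_sim_config")
}

draw_education <- function(cfg, n) {
  if (cfg$education_dist == "uniform") {
    sample(0:22, n, replace = TRUE)
  } else {
    pmin(22, pmax(0, round(stats::rnorm(n, cfg$education_mean, cfg$education_sd))))
  }
}

plan_machinery <- function(cfg) {
  V <- cfg$V
  hub <- as.integer(cfg$planted_hub)
  if (hub < 1 || hub > V) abort("`planted_hub` out of range")
  if (is.null(cfg$planted_pairs)) {
    partners <- sample(setdiff(seq_len(V), hub), cfg$n_planted_pairs)
    pairs <- cbind(hub, partners)
  } else {
    pairs <- as.matrix(cfg$planted_pairs)
    partners <- ifelse(pairs[, 1] == hub, pairs[, 2], pairs[, 1])
  }
  P <- nrow(pairs)
  pool <- setdiff(seq_len(V), c(hub, partners))
  need <- P * cfg$n_relays_per_pair
  if (length(pool) < need) {
    abort(sprintf(
      "V = %d is too small for %d planted pairs with %d relays each (need %d free nodes, have %d)",
      V, P, cfg$n_relays_per_pair, need, length(pool)))
  }
  relay_nodes <- sample(pool, need)
  relays <- split(relay_nodes, rep(seq_len(P), each = cfg$n_relays_per_pair))
  anchor_pool <- setdiff(pool, relay_nodes)
  if (length(anchor_pool) < cfg$n_hub_anchors) {
    abort(sprintf("V = %d leaves no room for %d hub anchor edges", V, cfg$n_hub_anchors))
  }
  anchors <- sample(anchor_pool, cfg$n_hub_anchors)
  list(hub = hub, partners = as.integer(partners), pairs = pairs,
       relays = relays, anchors = as.integer(anchors))
}

#' Generate a synthetic cohort with a planted education-flow association
#'
#' @param config an [sim_config()].
#' @return An [cohort()] with an extra `ground_truth` element recording the
#'   planted hub, pairs, relay nodes, `effect_beta`, `alpha0` and seed.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "fr_sim_config"))
  anatomy <- withr::with_seed(config$structure_seed, plan_anatomy(config))
  # subject-level draws use an offset stream so a cohort sharing its
  # structure_seed with another still gets independent subjects
  withr::with_seed(config$seed + 499979L,
                   generate_cohort_impl(config, anatomy))
}

# everything shared across subjects: modular backbone and planted machinery
plan_anatomy <- function(cfg) {
  V <- cfg$V
  ut <- upper.tri(matrix(0L, V, V))
  ut_idx <- which(ut)

  # modular backbone: 5:1 within/between density, matching base_density overall
  module <- sort(rep_len(seq_len(cfg$n_modules), V))
  mod_i <- module[row(ut)[ut_idx]]
  mod_j <- module[col(ut)[ut_idx]]
  f_within <- mean(mod_i == mod_j)
  p_between <- cfg$base_density / (5 * f_within + (1 - f_within))
  p_within <- min(1, 5 * p_between)
  p_cell <- ifelse(mod_i == mod_j, p_within, p_between)
  backbone <- stats::rbinom(length(ut_idx), 1L, p_cell)

  mach <- plan_machinery(cfg)
  P <- nrow(mach$pairs)
  R <- cfg$n_relays_per_pair
  cell_id <- function(i, j) {
    lo <- pmin(i, j); hi <- pmax(i, j)
    ((hi - 1L) * (hi - 2L)) %/% 2L + lo  # rank among upper-tri cells, col-major
  }
  ut_rank <- cell_id(row(ut)[ut_idx], col(ut)[ut_idx])
  mach_cells <- integer(0)
  relay_edge_idx <- vector("list", P)  # per pair: 2R positions into ut_idx
  for (p in seq_len(P)) {
    h <- mach$pairs[p, 1]; j <- mach$pairs[p, 2]; rl <- mach$relays[[p]]
    ranks <- c(cell_id(rep(h, R), rl), cell_id(rl, rep(j, R)))
    relay_edge_idx[[p]] <- match(ranks, ut_rank)
    mach_cells <- c(mach_cells, relay_edge_idx[[p]])
  }
  # the hub joins the backbone only through its fixed anchor edges; all its
  # other connectivity is the relay machinery, so hub flow tracks education
  hub_cells <- which(row(ut)[ut_idx] == mach$hub | col(ut)[ut_idx] == mach$hub)
  anchor_cells <- match(cell_id(rep(mach$hub, length(mach$anchors)), mach$anchors),
                        ut_rank)
  free_cells <- setdiff(seq_along(ut_idx), c(mach_cells, hub_cells))
  backbone[c(mach_cells, hub_cells)] <- 0L
  backbone[anchor_cells] <- 1L

  list(ut_idx = ut_idx, backbone = backbone, mach = mach,
       mach_cells = mach_cells, anchor_cells = anchor_cells,
       free_cells = free_cells, relay_edge_idx = relay_edge_idx)
}

# subject-level draws on a fixed anatomy
generate_cohort_impl <- function(cfg, anatomy) {
  V <- cfg$V
  n <- cfg$n_subjects
  ut_idx <- anatomy$ut_idx
  backbone <- anatomy$backbone
  mach <- anatomy$mach
  mach_cells <- anatomy$mach_cells
  anchor_cells <- anatomy$anchor_cells
  free_cells <- anatomy$free_cells
  relay_edge_idx <- anatomy$relay_edge_idx
  P <- nrow(mach$pairs)
  R <- cfg$n_relays_per_pair

  education <- draw_education(cfg, n)
  if (sd(education) == 0) {
    abort("degenerate education distribution (zero variance); enlarge n or sd")
  }
  z <- as.numeric(scale(education))
  # covariates are drawn independently of education, then redrawn (bounded)
  # while their sample correlation with education exceeds 0.2 — emulating a
  # cohort recruited so that education is not confounded with demographics
  balanced_draw <- function(draw) {
    for (try in 1:100) {
      v <- draw()
      if (sd(v) == 0 || abs(cor(education, v)) < 0.2) return(v)
    }
    v
  }
  age <- balanced_draw(function() stats::rnorm(n, cfg$age_mean, cfg$age_sd))
  sex <- balanced_draw(function() stats::rbinom(n, 1L, cfg$sex_p))
  cdr <- if (is.na(cfg$cdr_mean)) rep(NA_real_, n) else
    balanced_draw(function() pmax(0, round(stats::rnorm(n, cfg$cdr_mean, cfg$cdr_sd), 1)))

  labels <- default_region_labels(V)
  connectomes <- vector("list", n)
  for (s in seq_len(n)) {
    edge_vec <- backbone
    if (cfg$edge_noise > 0) {
      flips <- stats::rbinom(length(free_cells), 1L, cfg$edge_noise)
      edge_vec[free_cells] <- (edge_vec[free_cells] + flips) %% 2L
    }
    pr <- stats::plogis(cfg$alpha0 + cfg$effect_beta * z[s])
    for (p in seq_len(P)) {
      present <- stats::rbinom(R, 1L, pr)
      edge_vec[relay_edge_idx[[p]]] <- rep(present, 2L)
    }
    adj <- matrix(0L, V, V)
    adj[ut_idx] <- edge_vec
    adj <- adj + t(adj)
    if (cfg$graded_fibers) {
      counts <- integer(length(edge_vec))
      on <- edge_vec == 1L
      is_mach <- seq_along(edge_vec) %in% c(mach_cells, anchor_cells)
      counts[on & is_mach] <- 5L + stats::rpois(sum(on & is_mach), 2)
      counts[on & !is_mach] <- 1L + stats::rpois(sum(on & !is_mach), 2.5)
      fib <- matrix(0L, V, V)
      fib[ut_idx] <- counts
      fib <- fib + t(fib)
      connectomes[[s]] <- connectome(fiber_count = fib, region_labels = labels,
                                     fiber_threshold = 3)
    } else {
      fib <- adj * 3L
      connectomes[[s]] <- connectome(adjacency = adj, fiber_count = fib,
                                     region_labels = labels, fiber_threshold = 3)
    }
    if (cfg$include_fa) connectomes[[s]]$fa <- connectomes[[s]]$adjacency * 0.4
  }

  covariates <- tibble(
    subject_id = sprintf("%s%03d", cfg$group, seq_len(n)),
    group = cfg$group, age = age, sex = sex,
    education_years = as.integer(education), cdr_sob = cdr
  )
  out <- cohort(covariates, connectomes, name = cfg$group)
  out$ground_truth <- list(
    planted_hub = mach$hub,
    planted_pairs = tibble(i = pmin(mach$pairs[, 1], mach$pairs[, 2]),
                           j = pmax(mach$pairs[, 1], mach$pairs[, 2])),
    relays = mach$relays, anchors = mach$anchors,
    effect_beta = cfg$effect_beta,
    alpha0 = cfg$alpha0, seed = cfg$seed, structure_seed = cfg$structure_seed
  )
  out
}

#' Generate a null cohort (no education-network association)
#'
#' [generate_cohort()] with `effect_beta` forced to 0, so relay paths are
#' included at the baseline rate independently of education.
#'
#' @param config an [sim_config()].
#' @return An [cohort()] object with `ground_truth$effect_beta = 0`.
#' @export
null_cohort <- function(config) {
  stopifnot(inherits(config, "fr_sim_config"))
  config$effect_beta <- 0
  generate_cohort(config)
}
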