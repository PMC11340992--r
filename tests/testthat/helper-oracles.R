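# Independent oracles and fixture builders shared across the suite.
# Oracles deliberately use a different computational route than the package
# (loops and residualization instead of vectorized index math and
# correlation-matrix inversion).

# Partial Spearman by the residualize-ranks-then-correlate route: rank every
# column, regress the ranked x and y on the ranked covariates with lm(),
# then Pearson-correlate the residuals.
oracle_partial_spearman <- function(data, x, y, covariates = character()) {
  d <- data[stats::complete.cases(data[, c(x, y, covariates)]), ]
  rk <- as.data.frame(lapply(d[, c(x, y, covariates), drop = FALSE],
    rank,
    ties.method = "average"
  ))
  if (length(covariates) == 0) {
    return(stats::cor(rk[[x]], rk[[y]]))
  }
  fx <- stats::lm(
    stats::reformulate(covariates, response = x),
    data = rk
  )
  fy <- stats::lm(
    stats::reformulate(covariates, response = y),
    data = rk
  )
  stats::cor(stats::resid(fx), stats::resid(fy))
}

# Mean connectivity over an edge list by explicit accumulation.
oracle_strength <- function(m, edges) {
  total <- 0
  count <- 0
  for (k in seq_len(nrow(edges))) {
    i <- as.character(edges$node_i[k])
    j <- as.character(edges$node_j[k])
    total <- total + m[i, j]
    count <- count + 1
  }
  total / count
}

# Edges surviving the removal of a node set, by per-edge membership checks.
oracle_lesioned_edges <- function(edges, removed_nodes) {
  keep <- logical(nrow(edges))
  for (k in seq_len(nrow(edges))) {
    keep[k] <- !(edges$node_i[k] %in% removed_nodes) &&
      !(edges$node_j[k] %in% removed_nodes)
  }
  edges[keep, , drop = FALSE]
}

# Random symmetric Fisher-z-like cohort with no planted structure.
random_cohort <- function(n_participants, n_nodes, seed) {
  withr::with_seed(seed, {
    mats <- lapply(seq_len(n_participants), function(i) {
      m <- matrix(rnorm(n_nodes^2, sd = 0.3), n_nodes)
      m <- (m + t(m)) / 2
      diag(m) <- NA_real_
      dimnames(m) <- list(as.character(1:n_nodes), as.character(1:n_nodes))
      m
    })
    names(mats) <- sprintf("p%03d", seq_len(n_participants))
    conncpm::conn_cohort(mats, node_ids = 1:n_nodes)
  })
}

# Random edge mask over 1:n_nodes.
random_mask <- function(n_nodes, n_edges, seed, polarity = "high") {
  withr::with_seed(seed, {
    all_pairs <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
    pick <- sample(nrow(all_pairs), n_edges)
    conncpm::edge_mask(
      data.frame(node_i = all_pairs[pick, 1], node_j = all_pairs[pick, 2]),
      node_ids = 1:n_nodes, polarity = polarity
    )
  })
}

# Small cohort where a chosen set of edges carries the behavior exactly
# (optionally with noise) and every other edge is pure noise.
planted_cohort <- function(n_participants, n_nodes, signal_edges, behavior,
                           effect = 1, noise_sd = 0, seed = 1) {
  withr::with_seed(seed, {
    mats <- lapply(seq_len(n_participants), function(i) {
      m <- matrix(rnorm(n_nodes^2, sd = 0.2), n_nodes)
      m <- (m + t(m)) / 2
      for (k in seq_len(nrow(signal_edges))) {
        v <- effect * behavior[i] +
          if (noise_sd > 0) rnorm(1, sd = noise_sd) else 0
        m[signal_edges$node_i[k], signal_edges$node_j[k]] <- v
        m[signal_edges$node_j[k], signal_edges$node_i[k]] <- v
      }
      diag(m) <- NA_real_
      dimnames(m) <- list(as.character(1:n_nodes), as.character(1:n_nodes))
      m
    })
    names(mats) <- sprintf("p%03d", seq_len(n_participants))
    conncpm::conn_cohort(mats, node_ids = 1:n_nodes)
  })
}

# Null sim_config shortcut: no planted correlations, no QC failures.
null_sim_config <- function(n = 50, p = 15, seed = 1, ...) {
  conncpm::sim_config(
    n_participants = n, n_nodes = p,
    n_signal_pos_edges = 5, n_signal_neg_edges = 5,
    effect_size = 0,
    target_strength_outcome_rho = 0,
    motion_confound_rho = 0,
    composite_rhos = c(pacc_like = 0, mem_like = 0, ef_like = 0),
    frac_missing_nodes = 0, frac_coverage_fail = 0, frac_fd_fail = 0,
    seed = seed, ...
  )
}
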