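#' Configuration for the synthetic connectome cohort generator
#'
#' Bundles and validates every parameter of [generate_cohort()]. The
#' defaults describe the cohort the package's validation studies assume: a
#' 268-node parcellation with 6 nodes missing in three or more participants,
#' a 324-participant roster of which 5 fail coverage checks and 30 exceed
#' the 0.15 mm mean-FD limit (leaving 289 analyzable), 134 planted
#' positive-signal and 134 negative-signal edges, a positively skewed
#' biomarker whose planted rank correlation with high-network strength is
#' 0.137, and a motion confound of rank correlation 0.48 with high-network
#' strength.
#'
#' Planted rank correlations are achieved through a one-factor Gaussian
#' copula: the latent behavior is the factor, and the biomarker, mean FD
#' and the cognitive composites load on it. A requested correlation that
#' would need a loading outside \[-1, 1\] (e.g. a large
#' `target_strength_outcome_rho` with a weak `effect_size`) is infeasible
#' and raises an error naming the offending parameter.
#'
#' @param n_participants,n_nodes,n_timepoints Cohort dimensions.
#'   `n_timepoints = 0` emits connectivity matrices directly; a positive
#'   value emits node x time series instead (intended for small cohorts:
#'   each participant costs an eigendecomposition of the node x node
#'   matrix).
#' @param n_signal_pos_edges,n_signal_neg_edges Numbers of planted signal
#'   edges whose Fisher-z value increases (resp. decreases) with the latent
#'   behavior.
#' @param effect_size Coupling (z units per SD of behavior) between the
#'   latent behavior and each signal edge.
#' @param edge_noise_sd Participant-level noise SD of each edge (z units).
#' @param baseline_z_mean,baseline_z_sd Across-edge distribution of mean
#'   connectivity.
#' @param target_strength_outcome_rho Planted Spearman correlation between
#'   positive-signal-edge mean strength and the biomarker.
#' @param motion_confound_rho Planted Spearman correlation between mean FD
#'   and high-network strength.
#' @param composite_rhos Named numeric: planted Spearman correlations
#'   between high-network strength and each cognitive composite column.
#' @param biomarker_skew Log-normal shape of the biomarker (SD of its log);
#'   larger is more right-skewed.
#' @param biomarker_scale Multiplicative scale of the biomarker.
#' @param frac_missing_nodes Proportion of nodes rendered missing (all-NA)
#'   in at least 3 participants each.
#' @param frac_coverage_fail,frac_fd_fail Proportions of participants
#'   failing coverage QC, and exceeding the FD limit (assigned as exact
#'   counts, `round(frac * n)`, so cohort accounting is deterministic).
#' @param fd_threshold Mean-FD QC threshold in mm.
#' @param fd_meanlog,fd_sdlog Log-normal parameters of mean FD for
#'   passing participants (defaults match a mean of 0.0768 mm and SD of
#'   0.0278 mm).
#' @param group_probs Named sampling probabilities for the diagnostic
#'   group label.
#' @param signal_nodes Optional integer node ids; when given, signal edges
#'   are drawn only among these nodes (used to confine signal to one
#'   canonical network).
#' @param seed Mandatory RNG seed (integer).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 324,
                       n_nodes = 268,
                       n_timepoints = 0,
                       n_signal_pos_edges = 134,
                       n_signal_neg_edges = 134,
                       effect_size = 0.1,
                       edge_noise_sd = 0.2,
                       baseline_z_mean = 0.25,
                       baseline_z_sd = 0.15,
                       target_strength_outcome_rho = 0.137,
                       motion_confound_rho = 0.48,
                       composite_rhos = c(
                         pacc_like = -0.198,
                         mem_like = -0.147,
                         ef_like = -0.111
                       ),
                       biomarker_skew = 0.8,
                       biomarker_scale = 0.025,
                       frac_missing_nodes = 6 / 268,
                       frac_coverage_fail = 5 / 324,
                       frac_fd_fail = 30 / 324,
                       fd_threshold = 0.15,
                       fd_meanlog = NULL,
                       fd_sdlog = NULL,
                       group_probs = c(CN = 149, MCI = 109, AD = 31) / 289,
                       signal_nodes = NULL,
                       seed) {
  if (missing(seed)) abort("`seed` is mandatory in sim_config().")
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_nodes = as.integer(n_nodes),
    n_timepoints = as.integer(n_timepoints),
    n_signal_pos_edges = as.integer(n_signal_pos_edges),
    n_signal_neg_edges = as.integer(n_signal_neg_edges),
    effect_size = effect_size,
    edge_noise_sd = edge_noise_sd,
    baseline_z_mean = baseline_z_mean,
    baseline_z_sd = baseline_z_sd,
    target_strength_outcome_rho = target_strength_outcome_rho,
    motion_confound_rho = motion_confound_rho,
    composite_rhos = composite_rhos,
    biomarker_skew = biomarker_skew,
    biomarker_scale = biomarker_scale,
    frac_missing_nodes = frac_missing_nodes,
    frac_coverage_fail = frac_coverage_fail,
    frac_fd_fail = frac_fd_fail,
    fd_threshold = fd_threshold,
    group_probs = group_probs,
    signal_nodes = if (!is.null(signal_nodes)) as.integer(signal_nodes),
    seed = as.integer(seed)
  )
  # log-normal moments matched to the target mean/SD of passing FD
  if (is.null(fd_meanlog) || is.null(fd_sdlog)) {
    fd_mean <- 0.0768
    fd_sd <- 0.0278
    cv2 <- (fd_sd / fd_mean)^2
    cfg$fd_sdlog <- sqrt(log(1 + cv2))
    cfg$fd_meanlog <- log(fd_mean) - cfg$fd_sdlog^2 / 2
  } else {
    cfg$fd_meanlog <- fd_meanlog
    cfg$fd_sdlog <- fd_sdlog
  }
  with(cfg, {
    stopifnot(
      n_participants > 0, n_nodes > 1, n_timepoints >= 0,
      n_signal_pos_edges >= 0, n_signal_neg_edges >= 0,
      edge_noise_sd >= 0, effect_size >= 0, biomarker_skew >= 0
    )
    props <- c(frac_missing_nodes, frac_coverage_fail, frac_fd_fail)
    if (any(props < 0 | props > 1)) abort("Proportions must lie in [0, 1].")
    if (n_signal_pos_edges + n_signal_neg_edges > n_nodes * (n_nodes - 1) / 2) {
      abort("More signal edges requested than node pairs available.")
    }
  })
  structure(cfg, class = "sim_config")
}

# Spearman -> Pearson for a bivariate Gaussian pair: rho_P = 2 sin(pi rho_S / 6)
spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

# Latent Pearson correlation between biomarker and FD that makes the
# FD-partialled correlation of (strength, biomarker) equal its marginal
# value A = cor(S, y), given B = cor(S, f). Root of
#   A - B t = A sqrt((1 - B^2)(1 - t^2)),
# i.e. motion adjustment leaves the planted association unbiased.
balanced_confound_cor <- function(A, B) {
  if (A == 0 || B == 0) {
    return(0)
  }
  A * B * (1 - sqrt((1 - A^2) * (1 - B^2))) / (B^2 + A^2 * (1 - B^2))
}

# Copula loading on the latent behavior needed so that a Gaussian variable
# attains Spearman `rho_s` with the high-signal strength, whose own
# correlation with behavior is `c_s`. Errors when infeasible.
copula_loading <- function(rho_s, c_s, what) {
  if (rho_s == 0) {
    return(0)
  }
  if (!is.finite(c_s) || c_s == 0) {
    abort(paste0(
      "Infeasible correlation structure: `", what, "` = ", rho_s,
      " requires planted edge signal (effect_size > 0 and n_signal_pos_edges > 0)."
    ), class = "conncpm_infeasible")
  }
  a <- spearman_to_pearson(rho_s) / c_s
  if (abs(a) > 1) {
    abort(paste0(
      "Infeasible correlation structure: `", what, "` = ", rho_s,
      " needs copula loading ", signif(a, 4),
      " (|loading| > 1). Increase effect_size or lower the target."
    ), class = "conncpm_infeasible")
  }
  a
}

#' Generate a synthetic connectome cohort with planted signal
#'
#' Simulates a cohort matching the generative model described in
#' `vignette("conncpm-methods")`: a standard-normal latent behavior drives
#' a set of planted signal edges (`z = baseline + effect_size * behavior +
#' noise` for positive edges, minus for negative edges); the biomarker,
#' mean framewise displacement and cognitive composites are coupled to the
#' behavior through a one-factor Gaussian copula so that their planted rank
#' correlations with high-network strength hit the configured targets in
#' expectation; QC failures (coverage, high FD) and missing nodes are
#' assigned at the configured rates. Identical configuration and seed give
#' identical output.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_cohort`:
#'   * `cohort` — a [conn_cohort()] (when `n_timepoints = 0`), else `NULL`;
#'   * `timeseries` — named list of node x time matrices (when
#'     `n_timepoints > 0`), else `NULL`;
#'   * `phenotypes` — tibble `participant_id`, `behavior`, `biomarker`,
#'     `pacc_like`, `mem_like`, `ef_like`, `mean_fd`, `coverage_ok`,
#'     `group`;
#'   * `truth` — ground-truth record: signal edge sets, latent behavior,
#'     planted rhos, copula loadings, the analytic strength-behavior
#'     correlation `c_s`, and the missing-node map;
#'   * `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_participants
  p <- cfg$n_nodes
  node_ids <- seq_len(p)
  pid <- sprintf("sub%04d", seq_len(n))

  # --- edge universe and planted signal edges -----------------------------
  ut <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  edges_all <- tibble(node_i = ut[, 1], node_j = ut[, 2])
  candidates <- seq_len(nrow(edges_all))
  if (!is.null(cfg$signal_nodes)) {
    candidates <- which(
      edges_all$node_i %in% cfg$signal_nodes &
        edges_all$node_j %in% cfg$signal_nodes
    )
  }
  n_sig <- cfg$n_signal_pos_edges + cfg$n_signal_neg_edges
  if (length(candidates) < n_sig) {
    abort("Not enough candidate node pairs for the requested signal edges.")
  }
  sig_idx <- if (n_sig > 0) sample(candidates, n_sig) else integer(0)
  pos_idx <- head(sig_idx, cfg$n_signal_pos_edges)
  neg_idx <- sig_idx[seq_len(cfg$n_signal_neg_edges) + cfg$n_signal_pos_edges]

  # analytic correlation between behavior and mean strength over the
  # positive-signal edges: effect / sqrt(effect^2 + sigma^2 / K)
  k_pos <- cfg$n_signal_pos_edges
  c_s <- if (k_pos > 0 && cfg$effect_size > 0) {
    cfg$effect_size /
      sqrt(cfg$effect_size^2 + cfg$edge_noise_sd^2 / k_pos)
  } else {
    0
  }

  # --- latent behavior and copula-coupled phenotypes ----------------------
  loadings <- c(
    biomarker = copula_loading(
      cfg$target_strength_outcome_rho, c_s, "target_strength_outcome_rho"
    ),
    mean_fd = copula_loading(cfg$motion_confound_rho, c_s, "motion_confound_rho"),
    vapply(
      seq_along(cfg$composite_rhos),
      function(i) {
        copula_loading(
          cfg$composite_rhos[[i]], c_s,
          paste0("composite_rhos[", names(cfg$composite_rhos)[i], "]")
        )
      },
      numeric(1)
    ) |> setNames(names(cfg$composite_rhos))
  )
  b <- rnorm(n)
  # biomarker and FD latents form a trivariate Gaussian copula with the
  # behavior: their cross-correlation is planted so that partialling FD
  # out of the strength-biomarker association neither shrinks nor inflates
  # the marginal target (see balanced_confound_cor()).
  a_y <- loadings[["biomarker"]]
  a_f <- loadings[["mean_fd"]]
  r_sy <- a_y * c_s
  r_sf <- a_f * c_s
  r_yf <- balanced_confound_cor(r_sy, r_sf)
  rho_e <- if (a_y^2 < 1 && a_f^2 < 1) {
    (r_yf - a_y * a_f) / sqrt((1 - a_y^2) * (1 - a_f^2))
  } else {
    0
  }
  if (abs(rho_e) > 1) {
    abort(paste0(
      "Infeasible correlation structure between `target_strength_outcome_rho`",
      " and `motion_confound_rho` (residual copula correlation ",
      signif(rho_e, 4), ")."
    ), class = "conncpm_infeasible")
  }
  u_y <- rnorm(n)
  g_y <- a_y * b + sqrt(1 - a_y^2) * u_y
  g_f <- a_f * b + sqrt(1 - a_f^2) *
    (rho_e * u_y + sqrt(1 - rho_e^2) * rnorm(n))
  comp_names <- names(cfg$composite_rhos)
  latent <- vapply(comp_names, function(nm) {
    a <- loadings[[nm]]
    a * b + sqrt(1 - a^2) * rnorm(n)
  }, numeric(n))
  if (is.null(dim(latent))) latent <- matrix(latent, nrow = n)
  colnames(latent) <- comp_names
  biomarker <- cfg$biomarker_scale * exp(cfg$biomarker_skew * g_y)
  mean_fd <- qlnorm(pnorm(g_f), cfg$fd_meanlog, cfg$fd_sdlog)

  # --- QC assignment (exact counts for deterministic cohort accounting) ---
  n_cov_fail <- round(cfg$frac_coverage_fail * n)
  n_fd_fail <- round(cfg$frac_fd_fail * n)
  resample <- function(x, k) x[sample.int(length(x), k)]
  cov_fail <- resample(seq_len(n), n_cov_fail)
  fd_fail <- resample(setdiff(seq_len(n), cov_fail), n_fd_fail)
  mean_fd[fd_fail] <- cfg$fd_threshold + rexp(n_fd_fail, rate = 1 / 0.03)
  pass <- setdiff(seq_len(n), fd_fail)
  mean_fd[pass] <- pmin(mean_fd[pass], cfg$fd_threshold)
  coverage_ok <- rep(TRUE, n)
  coverage_ok[cov_fail] <- FALSE

  group <- sample(
    names(cfg$group_probs), n,
    replace = TRUE, prob = cfg$group_probs
  )

  phenotypes <- tibble(
    participant_id = pid,
    behavior = b,
    biomarker = biomarker,
    pacc_like = latent[, "pacc_like"],
    mem_like = latent[, "mem_like"],
    ef_like = latent[, "ef_like"],
    mean_fd = mean_fd,
    coverage_ok = coverage_ok,
    group = group
  )

  # --- edge values: baseline + signed coupling * behavior + noise ---------
  n_edge <- nrow(edges_all)
  mu <- rnorm(n_edge, cfg$baseline_z_mean, cfg$baseline_z_sd)
  s <- numeric(n_edge)
  s[pos_idx] <- cfg$effect_size
  s[neg_idx] <- -cfg$effect_size
  z_values <- matrix(mu, n, n_edge, byrow = TRUE) +
    outer(b, s) +
    matrix(rnorm(n * n_edge, sd = cfg$edge_noise_sd), n, n_edge)

  # --- missing nodes: all-NA in >= 3 random participants each -------------
  n_miss <- round(cfg$frac_missing_nodes * p)
  missing_map <- list()
  if (n_miss > 0) {
    if (n < 3) abort("frac_missing_nodes > 0 needs at least 3 participants.")
    miss_nodes <- node_ids[sample.int(p, n_miss)]
    missing_map <- lapply(miss_nodes, function(nd) {
      sort(sample(n, min(n, 3 + stats::rpois(1, 1))))
    })
    names(missing_map) <- as.character(miss_nodes)
  }

  truth <- structure(
    list(
      signal_pos_edges = edges_all[pos_idx, ],
      signal_neg_edges = edges_all[neg_idx, ],
      latent_behavior = tibble(participant_id = pid, behavior = b),
      planted_rhos = list(
        strength_outcome = cfg$target_strength_outcome_rho,
        motion_confound = cfg$motion_confound_rho,
        biomarker_fd_latent_cor = r_yf,
        composites = as.list(cfg$composite_rhos)
      ),
      copula_loadings = loadings,
      strength_behavior_cor = c_s,
      missing_nodes = missing_map
    ),
    class = "cohort_truth"
  )

  # --- materialize matrices or time series --------------------------------
  build_matrix <- function(i) {
    m <- matrix(0, p, p)
    m[upper.tri(m)] <- z_values[i, ]
    m <- m + t(m)
    diag(m) <- NA_real_
    for (nd in names(missing_map)) {
      if (i %in% missing_map[[nd]]) {
        j <- as.integer(nd)
        m[j, ] <- NA_real_
        m[, j] <- NA_real_
      }
    }
    dimnames(m) <- list(as.character(node_ids), as.character(node_ids))
    m
  }

  if (cfg$n_timepoints == 0) {
    mats <- lapply(seq_len(n), build_matrix)
    names(mats) <- pid
    cohort <- conn_cohort(mats, node_ids = node_ids)
    timeseries <- NULL
  } else {
    cohort <- NULL
    timeseries <- lapply(seq_len(n), function(i) {
      simulate_timeseries(build_matrix(i), cfg$n_timepoints)
    })
    names(timeseries) <- pid
  }

  structure(
    list(
      cohort = cohort, timeseries = timeseries,
      phenotypes = phenotypes, truth = truth, config = cfg
    ),
    class = "sim_cohort"
  )
}

# Draw a node x time Gaussian series whose population correlation matrix is
# tanh(z) (projected to the nearest feasible PSD correlation by eigenvalue
# flooring). Missing nodes (NA rows in z) come back as all-NA rows.
simulate_timeseries <- function(z, n_timepoints) {
  p <- nrow(z)
  present <- which(rowSums(!is.na(z)) > 0)
  r <- tanh(z[present, present, drop = FALSE])
  diag(r) <- 1
  e <- eigen(r, symmetric = TRUE)
  vals <- pmax(e$values, 1e-6)
  r_psd <- e$vectors %*% diag(vals, length(vals)) %*% t(e$vectors)
  d <- sqrt(diag(r_psd))
  r_psd <- r_psd / outer(d, d)
  ch <- chol(r_psd)
  ts <- matrix(NA_real_, p, n_timepoints)
  ts[present, ] <- t(ch) %*% matrix(rnorm(length(present) * n_timepoints),
    length(present), n_timepoints
  )
  rownames(ts) <- rownames(z)
  ts
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "<sim_cohort> %d participants x %d nodes (seed %d)\n",
    x$config$n_participants, x$config$n_nodes, x$config$seed
  ))
  invisible(x)
}

#' Edge mask of the planted ground-truth signal edges
#'
#' @param truth The `truth` element of a [generate_cohort()] result.
#' @param node_ids Node universe (defaults to all nodes referenced).
#' @param polarity `"high"` (positive-signal edges) or `"low"`.
#' @return An [edge_mask()].
#' @export
truth_mask <- function(truth, node_ids = NULL, polarity = c("high", "low")) {
  polarity <- match.arg(polarity)
  edges <- if (polarity == "high") {
    truth$signal_pos_edges
  } else {
    truth$signal_neg_edges
  }
  ids <- node_ids %||% sort(unique(c(
    truth$signal_pos_edges$node_i, truth$signal_pos_edges$node_j,
    truth$signal_neg_edges$node_i, truth$signal_neg_edges$node_j
  )))
  edge_mask(edges, node_ids = ids, polarity = polarity)
}

#' Write a simulated cohort to disk
#'
#' Produces one TSV matrix (or time-series TSV) per participant under
#' `matrices/` (`timeseries/`), `phenotypes.csv`, ground-truth sidecars
#' (`truth_edges.csv` with columns `node_i`, `node_j`, `polarity`;
#' `truth_behavior.csv`; `truth_missing.csv`), and `manifest.json` listing
#' every file together with the generating seed and planted correlations.
#'
#' @param sim A `sim_cohort` from [generate_cohort()].
#' @param out_dir Output directory (created; must be writable).
#' @return Invisibly, the manifest as a list.
#' @export
write_cohort <- function(sim, out_dir) {
  stopifnot(inherits(sim, "sim_cohort"))
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(paste0("Cannot create directory: ", out_dir))
  files <- character(0)
  if (!is.null(sim$cohort)) {
    mdir <- file.path(out_dir, "matrices")
    dir.create(mdir, showWarnings = FALSE)
    for (id in participants(sim$cohort)) {
      f <- file.path(mdir, paste0(id, ".tsv"))
      write_matrix_tsv(sim$cohort$matrices[[id]], f)
      files <- c(files, file.path("matrices", paste0(id, ".tsv")))
    }
  }
  if (!is.null(sim$timeseries)) {
    tdir <- file.path(out_dir, "timeseries")
    dir.create(tdir, showWarnings = FALSE)
    for (id in names(sim$timeseries)) {
      ts <- sim$timeseries[[id]]
      df <- dplyr::bind_cols(
        tibble(node_id = as.integer(rownames(ts))),
        as_tibble(ts, .name_repair = ~ paste0("t", seq_along(.x)))
      )
      f <- file.path(tdir, paste0(id, ".tsv"))
      readr::write_tsv(df, f)
      files <- c(files, file.path("timeseries", paste0(id, ".tsv")))
    }
  }
  readr::write_csv(sim$phenotypes, file.path(out_dir, "phenotypes.csv"))
  truth_edges <- dplyr::bind_rows(
    dplyr::mutate(sim$truth$signal_pos_edges, polarity = "high"),
    dplyr::mutate(sim$truth$signal_neg_edges, polarity = "low")
  )
  readr::write_csv(truth_edges, file.path(out_dir, "truth_edges.csv"))
  readr::write_csv(
    sim$truth$latent_behavior, file.path(out_dir, "truth_behavior.csv")
  )
  missing_df <- purrr::imap_dfr(sim$truth$missing_nodes, function(rows, nd) {
    tibble(
      node_id = as.integer(nd),
      participant_id = sim$phenotypes$participant_id[rows]
    )
  })
  if (nrow(missing_df) == 0) {
    missing_df <- tibble(node_id = integer(0), participant_id = character(0))
  }
  readr::write_csv(missing_df, file.path(out_dir, "truth_missing.csv"))
  files <- c(
    files, "phenotypes.csv", "truth_edges.csv",
    "truth_behavior.csv", "truth_missing.csv"
  )
  manifest <- list(
    seed = sim$config$seed,
    n_participants = sim$config$n_participants,
    n_nodes = sim$config$n_nodes,
    planted_rhos = sim$truth$planted_rhos,
    files = files
  )
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.json`.
#' @return A list with `cohort` (a [conn_cohort()], or `NULL` for a
#'   time-series cohort), `timeseries`, `phenotypes`, `truth` (edge sets,
#'   latent behavior, missing map), and `manifest`.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  phenotypes <- readr::read_csv(
    file.path(dir, "phenotypes.csv"),
    show_col_types = FALSE
  )
  mat_files <- sort(list.files(file.path(dir, "matrices"), full.names = TRUE))
  cohort <- NULL
  if (length(mat_files) > 0) {
    mats <- lapply(mat_files, read_matrix_tsv)
    names(mats) <- sub("\\.tsv$", "", basename(mat_files))
    cohort <- conn_cohort(mats)
  }
  ts_files <- sort(list.files(file.path(dir, "timeseries"), full.names = TRUE))
  timeseries <- NULL
  if (length(ts_files) > 0) {
    timeseries <- lapply(ts_files, function(f) {
      df <- readr::read_tsv(f, show_col_types = FALSE)
      ts <- as.matrix(df[, -1])
      rownames(ts) <- as.character(df$node_id)
      ts
    })
    names(timeseries) <- sub("\\.tsv$", "", basename(ts_files))
  }
  truth_edges <- readr::read_csv(
    file.path(dir, "truth_edges.csv"),
    show_col_types = FALSE
  )
  truth_missing <- readr::read_csv(
    file.path(dir, "truth_missing.csv"),
    show_col_types = FALSE
  )
  truth <- list(
    signal_pos_edges = dplyr::select(
      dplyr::filter(truth_edges, .data$polarity == "high"), -"polarity"
    ),
    signal_neg_edges = dplyr::select(
      dplyr::filter(truth_edges, .data$polarity == "low"), -"polarity"
    ),
    latent_behavior = readr::read_csv(
      file.path(dir, "truth_behavior.csv"),
      show_col_types = FALSE
    ),
    missing_nodes = split(
      truth_missing$participant_id, truth_missing$node_id
    )
  )
  list(
    cohort = cohort, timeseries = timeseries, phenotypes = phenotypes,
    truth = truth, manifest = manifest
  )
}
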