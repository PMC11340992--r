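test_that("generated matrices are symmetric with NA diagonal and finite edges", {
  sim <- generate_cohort(sim_config(
    n_participants = 8, n_nodes = 12, n_signal_pos_edges = 4,
    n_signal_neg_edges = 4, frac_missing_nodes = 0,
    frac_coverage_fail = 0, frac_fd_fail = 0, seed = 11
  ))
  for (m in sim$cohort$matrices) {
    expect_identical(m, t(m))
    expect_true(all(is.na(diag(m))))
    expect_true(all(is.finite(m[upper.tri(m)])))
  }
  expect_setequal(names(sim$phenotypes), c(
    "participant_id", "behavior", "biomarker", "pacc_like", "mem_like",
    "ef_like", "mean_fd", "coverage_ok", "group"
  ))
  expect_true(all(sim$phenotypes$biomarker > 0))
  expect_true(all(sim$phenotypes$mean_fd > 0))
})

test_that("identical config and seed give identical cohorts; seeds differ", {
  cfg <- sim_config(
    n_participants = 6, n_nodes = 10, n_signal_pos_edges = 3,
    n_signal_neg_edges = 3, seed = 42
  )
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$cohort$matrices, b$cohort$matrices)
  expect_identical(a$phenotypes, b$phenotypes)
  cfg2 <- cfg
  cfg2$seed <- 43L
  expect_false(identical(
    generate_cohort(cfg2)$phenotypes$behavior, a$phenotypes$behavior
  ))
})

test_that("signal edge sets are disjoint and sized as configured", {
  sim <- generate_cohort(sim_config(
    n_participants = 5, n_nodes = 20, n_signal_pos_edges = 7,
    n_signal_neg_edges = 9, seed = 3
  ))
  pos <- sim$truth$signal_pos_edges
  neg <- sim$truth$signal_neg_edges
  expect_equal(nrow(pos), 7)
  expect_equal(nrow(neg), 9)
  key <- function(e) paste(e$node_i, e$node_j)
  expect_length(intersect(key(pos), key(neg)), 0)
  expect_equal(nrow(sim$truth$latent_behavior), 5)
})

test_that("with no planted signal the strength-biomarker Spearman is null-scale", {
  # mean |rho| over replicates should sit near the null expectation
  # E|rho| ~ sqrt(2/pi)/sqrt(n - 1), far from any planted value
  n <- 200
  reps <- 20
  rhos <- vapply(seq_len(reps), function(s) {
    sim <- generate_cohort(null_sim_config(n = n, p = 12, seed = 100 + s))
    mask <- truth_mask(sim$truth,
      node_ids = sim$cohort$node_ids, polarity = "high"
    )
    strength <- vapply(
      sim$cohort$matrices, network_strength, numeric(1), mask = mask
    )
    cor(strength, sim$phenotypes$biomarker, method = "spearman")
  }, numeric(1))
  expect_lt(mean(abs(rhos)), 3 * sqrt(2 / pi) / sqrt(n - 1))
  expect_lt(abs(mean(rhos)), 0.05)
})

test_that("planted strength-outcome rank correlation is recovered in expectation", {
  target <- 0.4
  reps <- 40
  rhos <- vapply(seq_len(reps), function(s) {
    sim <- generate_cohort(sim_config(
      n_participants = 150, n_nodes = 16, n_signal_pos_edges = 8,
      n_signal_neg_edges = 8, target_strength_outcome_rho = target,
      frac_missing_nodes = 0, frac_coverage_fail = 0, frac_fd_fail = 0,
      seed = 500 + s
    ))
    mask <- truth_mask(sim$truth,
      node_ids = sim$cohort$node_ids, polarity = "high"
    )
    strength <- vapply(
      sim$cohort$matrices, network_strength, numeric(1), mask = mask
    )
    cor(strength, sim$phenotypes$biomarker, method = "spearman")
  }, numeric(1))
  # unbiasedness within Monte-Carlo error of the replicate mean
  mc_err <- 3 * sd(rhos) / sqrt(reps)
  expect_lt(abs(mean(rhos) - target), mc_err + 0.02)
})

test_that("motion confound and composite couplings carry their planted signs", {
  sim <- generate_cohort(sim_config(
    n_participants = 300, n_nodes = 16, n_signal_pos_edges = 8,
    n_signal_neg_edges = 8, frac_missing_nodes = 0,
    frac_coverage_fail = 0, frac_fd_fail = 0, seed = 77
  ))
  mask <- truth_mask(sim$truth,
    node_ids = sim$cohort$node_ids, polarity = "high"
  )
  strength <- vapply(
    sim$cohort$matrices, network_strength, numeric(1), mask = mask
  )
  expect_gt(cor(strength, sim$phenotypes$mean_fd, method = "spearman"), 0.2)
  expect_lt(cor(strength, sim$phenotypes$pacc_like, method = "spearman"), 0)
})

test_that("infeasible planted correlations fail naming the parameter", {
  expect_error(
    generate_cohort(sim_config(
      n_participants = 10, n_nodes = 10, n_signal_pos_edges = 2,
      n_signal_neg_edges = 2, effect_size = 0.01, edge_noise_sd = 1,
      target_strength_outcome_rho = 0.9, seed = 1
    )),
    "target_strength_outcome_rho",
    class = "conncpm_infeasible"
  )
  expect_error(
    generate_cohort(sim_config(
      n_participants = 10, n_nodes = 10, n_signal_pos_edges = 0,
      n_signal_neg_edges = 2, effect_size = 0.2,
      target_strength_outcome_rho = 0.3, seed = 1
    )),
    "requires planted edge signal",
    class = "conncpm_infeasible"
  )
})

test_that("missing nodes appear as all-NA rows in at least 3 participants", {
  sim <- generate_cohort(sim_config(
    n_participants = 12, n_nodes = 20, n_signal_pos_edges = 4,
    n_signal_neg_edges = 4, frac_missing_nodes = 2 / 20,
    frac_coverage_fail = 0, frac_fd_fail = 0, seed = 9
  ))
  miss <- sim$truth$missing_nodes
  expect_length(miss, 2)
  for (nd in names(miss)) {
    expect_gte(length(miss[[nd]]), 3)
    for (i in miss[[nd]]) {
      row <- sim$cohort$matrices[[i]][nd, ]
      expect_true(all(is.na(row)))
    }
  }
})

test_that("QC fractions become exact counts and FD failures exceed the threshold", {
  sim <- generate_cohort(sim_config(
    n_participants = 40, n_nodes = 10, n_signal_pos_edges = 3,
    n_signal_neg_edges = 3, frac_coverage_fail = 2 / 40,
    frac_fd_fail = 5 / 40, frac_missing_nodes = 0, seed = 21
  ))
  ph <- sim$phenotypes
  expect_equal(sum(!ph$coverage_ok), 2)
  expect_equal(sum(ph$coverage_ok & ph$mean_fd > 0.15), 5)
})

test_that("written cohorts round-trip exactly and record the seed", {
  sim <- generate_cohort(sim_config(
    n_participants = 3, n_nodes = 10, n_signal_pos_edges = 3,
    n_signal_neg_edges = 3, frac_missing_nodes = 0,
    frac_coverage_fail = 0, frac_fd_fail = 0, seed = 123
  ))
  dir <- withr::local_tempdir()
  manifest <- write_cohort(sim, dir)
  expect_equal(manifest$seed, 123)
  mats <- list.files(file.path(dir, "matrices"))
  expect_length(mats, 3)
  # header row + 10 node rows per matrix file
  expect_equal(length(readLines(file.path(dir, "matrices", mats[1]))), 11)
  back <- read_cohort(dir)
  expect_identical(back$cohort$matrices, sim$cohort$matrices)
  expect_equal(back$truth$signal_pos_edges, sim$truth$signal_pos_edges)
  # byte-identical rewrite under the same seed
  dir2 <- withr::local_tempdir()
  write_cohort(generate_cohort(sim$config), dir2)
  f1 <- file.path(dir, "phenotypes.csv")
  f2 <- file.path(dir2, "phenotypes.csv")
  expect_identical(readLines(f1), readLines(f2))
  m1 <- file.path(dir, "matrices", mats[1])
  m2 <- file.path(dir2, "matrices", mats[1])
  expect_identical(readLines(m1), readLines(m2))
})

test_that("time-series mode emits series whose connectomes echo the planted z", {
  cfg <- sim_config(
    n_participants = 4, n_nodes = 8, n_timepoints = 600,
    n_signal_pos_edges = 2, n_signal_neg_edges = 2,
    baseline_z_mean = 0.3, baseline_z_sd = 0.05, edge_noise_sd = 0.05,
    frac_missing_nodes = 0, frac_coverage_fail = 0, frac_fd_fail = 0,
    seed = 5
  )
  sim <- generate_cohort(cfg)
  expect_null(sim$cohort)
  expect_length(sim$timeseries, 4)
  expect_equal(dim(sim$timeseries[[1]]), c(8, 600))
  cohort <- cohort_from_timeseries(sim$timeseries)
  # empirical mean z should land near the planted baseline
  zbar <- mean(vapply(cohort$matrices, function(m) {
    mean(m[upper.tri(m)])
  }, numeric(1)))
  expect_lt(abs(zbar - 0.3), 0.1)
})
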