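test_that("select_edges picks behavior-aligned edges with disjoint polarities", {
  beh <- c(0.2, -1.1, 0.5, 1.4, -0.8, 0.1, 2.0, -1.6)
  sig <- data.frame(node_i = 1, node_j = 2)
  coh <- planted_cohort(8, 6, sig, beh, effect = 1, noise_sd = 0, seed = 10)
  # a second edge carrying -behavior exactly
  for (i in seq_along(beh)) {
    coh$matrices[[i]]["3", "4"] <- -beh[i]
    coh$matrices[[i]]["4", "3"] <- -beh[i]
  }
  sel <- select_edges(coh, beh, threshold = 0.01)
  expect_true(any(sel$pos_edges$node_i == 1 & sel$pos_edges$node_j == 2))
  expect_true(any(sel$neg_edges$node_i == 3 & sel$neg_edges$node_j == 4))
  key <- function(e) paste(e$node_i, e$node_j)
  expect_length(intersect(key(sel$pos_edges), key(sel$neg_edges)), 0)
})

test_that("constant edges and constant behavior are rejected from selection", {
  beh <- rnorm(10)
  coh <- random_cohort(10, 5, seed = 11)
  for (i in 1:10) {
    coh$matrices[[i]]["1", "2"] <- 0.5
    coh$matrices[[i]]["2", "1"] <- 0.5
  }
  sel <- select_edges(coh, beh, threshold = 0.99)
  expect_false(any(sel$pos_edges$node_i == 1 & sel$pos_edges$node_j == 2))
  expect_false(any(sel$neg_edges$node_i == 1 & sel$neg_edges$node_j == 2))
  expect_error(select_edges(coh, rep(1, 10)), "constant")
})

test_that("selections shrink weakly as the threshold tightens", {
  coh <- random_cohort(30, 10, seed = 12)
  beh <- withr::with_seed(13, rnorm(30))
  sizes <- vapply(c(0.5, 0.1, 0.01), function(th) {
    sel <- select_edges(coh, beh, threshold = th)
    nrow(sel$pos_edges) + nrow(sel$neg_edges)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("network_strength equals simple means and the exhaustive oracle", {
  coh <- random_cohort(1, 30, seed = 14)
  m <- coh$matrices[[1]]
  single <- edge_mask(data.frame(node_i = 3, node_j = 17), 1:30)
  expect_identical(network_strength(m, single), m["3", "17"])
  m["5", "6"] <- m["6", "5"] <- 0.2
  m["7", "9"] <- m["9", "7"] <- 0.4
  two <- edge_mask(data.frame(node_i = c(5, 7), node_j = c(6, 9)), 1:30)
  expect_equal(network_strength(m, two), 0.3)
  # full upper triangle equals the brute-force mean of all off-diagonal pairs
  full <- mask_from_matrix(
    matrix(1, 30, 30, dimnames = list(1:30, 1:30)) - diag(30)
  )
  expect_equal(
    network_strength(m, full), mean(m[upper.tri(m)]),
    tolerance = 1e-12
  )
  # random masks against the accumulation oracle
  for (s in 1:5) {
    mask <- random_mask(30, 25, seed = 100 + s)
    expect_equal(
      network_strength(m, mask), oracle_strength(m, mask),
      tolerance = 1e-12
    )
  }
})

test_that("network_strength errors on empty masks and missing nodes", {
  coh <- random_cohort(1, 6, seed = 15)
  empty <- edge_mask(data.frame(node_i = integer(0), node_j = integer(0)), 1:6)
  expect_error(network_strength(coh$matrices[[1]], empty), "undefined")
  mask9 <- edge_mask(data.frame(node_i = 1, node_j = 9), 1:9)
  expect_error(network_strength(coh$matrices[[1]], mask9), "9")
})

test_that("noise-free single-edge cohort trains to that edge with near-perfect LOO", {
  withr::with_seed(20, {
    beh <- rnorm(20)
  })
  sig <- data.frame(node_i = 2, node_j = 5)
  coh <- planted_cohort(20, 8, sig, beh, effect = 1, noise_sd = 0, seed = 21)
  model <- train_cpm_loo(coh, beh, threshold = 0.01)
  expect_true(any(
    model$consensus_high$node_i == 2 & model$consensus_high$node_j == 5
  ))
  pr <- model$predictions
  ok <- stats::complete.cases(pr$predicted_high, pr$observed)
  expect_gt(cor(pr$predicted_high[ok], pr$observed[ok]), 0.99)
})

test_that("LOO bookkeeping: n folds, consensus contained in every fold", {
  beh <- c(-1.2, 0.3, 0.8, -0.5, 1.9)
  sig <- data.frame(node_i = 1, node_j = 3)
  coh <- planted_cohort(5, 6, sig, beh, effect = 1, noise_sd = 0.05, seed = 22)
  model <- train_cpm_loo(coh, beh, threshold = 0.05)
  expect_equal(nrow(model$folds), 5)
  key <- function(e) paste(e$node_i, e$node_j)
  for (f in model$fold_edges) {
    expect_true(all(key(model$consensus_high) %in% key(f$pos)))
    expect_true(all(key(model$consensus_low) %in% key(f$neg)))
  }
})

test_that("training on permuted behavior carries no predictive signal", {
  # each replicate draws a fresh cohort with a planted edge, then permutes
  # the behavior before training, severing every edge-behavior link
  reps <- 20
  cors <- vapply(seq_len(reps), function(s) {
    beh <- withr::with_seed(700 + s, rnorm(60))
    coh <- planted_cohort(
      60, 10, data.frame(node_i = 1, node_j = 2), beh,
      effect = 1, noise_sd = 0, seed = 750 + s
    )
    perm <- withr::with_seed(800 + s, sample(beh))
    model <- tryCatch(
      train_cpm_loo(coh, perm, threshold = 0.5),
      error = function(e) NULL
    )
    if (is.null(model)) {
      return(NA_real_)
    }
    pr <- model$predictions
    ok <- stats::complete.cases(pr$predicted_high, pr$observed)
    if (sum(ok) < 5 || sd(pr$predicted_high[ok]) == 0) {
      return(NA_real_)
    }
    cor(pr$predicted_high[ok], pr$observed[ok])
  }, numeric(1))
  expect_lt(abs(mean(cors, na.rm = TRUE)), 0.15)
})

test_that("apply_model scores are stable, linear in edge shifts, and tidy-able", {
  beh <- withr::with_seed(30, rnorm(12))
  sig <- data.frame(node_i = c(1, 2), node_j = c(4, 6))
  coh <- planted_cohort(12, 8, sig, beh, effect = 1, noise_sd = 0.1, seed = 31)
  model <- train_cpm_loo(coh, beh, threshold = 0.05)
  scores <- apply_model(coh, model)
  expect_equal(nrow(scores), 12)
  # identical matrices -> identical scores
  same <- conn_cohort(
    list(a = coh$matrices[[1]], b = coh$matrices[[1]]),
    node_ids = coh$node_ids
  )
  sc <- apply_model(same, model)
  expect_equal(sc$high_strength[1], sc$high_strength[2])
  # adding c to every masked edge shifts strength by exactly c
  shifted <- coh
  hm <- model$consensus_high
  for (i in seq_along(shifted$matrices)) {
    for (k in seq_len(nrow(hm))) {
      a <- as.character(hm$node_i[k])
      b <- as.character(hm$node_j[k])
      shifted$matrices[[i]][a, b] <- shifted$matrices[[i]][a, b] + 0.7
      shifted$matrices[[i]][b, a] <- shifted$matrices[[i]][b, a] + 0.7
    }
  }
  sc2 <- apply_model(shifted, model)
  expect_equal(sc2$high_strength, scores$high_strength + 0.7, tolerance = 1e-12)
  # broom-style accessors
  expect_equal(nrow(tidy(model)), 12)
  g <- glance(model)
  expect_equal(g$n, 12)
  expect_true(g$loo_cor_high > 0.8)
  # combined score is high minus low
  sc3 <- apply_model(coh, model, combined = TRUE)
  expect_equal(
    sc3$combined_strength, sc3$high_strength - sc3$low_strength
  )
})

test_that("model bundles write consensus masks that read back identically", {
  beh <- withr::with_seed(40, rnorm(10))
  sig <- data.frame(node_i = 1, node_j = 2)
  coh <- planted_cohort(10, 6, sig, beh, effect = 1, noise_sd = 0, seed = 41)
  model <- train_cpm_loo(coh, beh, threshold = 0.05)
  dir <- withr::local_tempdir()
  write_cpm_model(model, dir)
  back <- read_edge_mask(file.path(dir, "consensus_high_edges.csv"),
    node_ids = coh$node_ids
  )
  expect_equal(
    as.data.frame(back)[, c("node_i", "node_j")],
    as.data.frame(model$consensus_high)[, c("node_i", "node_j")]
  )
  back_m <- read_edge_mask(file.path(dir, "consensus_high_matrix.tsv"))
  expect_identical(mask_matrix(back_m), mask_matrix(model$consensus_high))
})
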