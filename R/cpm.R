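#' Select behavior-correlated edges
#'
#' Correlates every upper-triangle edge with the behavioral score across
#' participants (Pearson) and selects edges whose two-tailed p-value falls
#' below `threshold`, split by sign: positively correlated edges form the
#' candidate "high" network, negatively correlated edges the "low" network.
#' The two sets are disjoint by construction. Edges that are constant across
#' participants have an undefined correlation and are never selected.
#'
#' @param cohort A [conn_cohort()].
#' @param behavior Numeric vector, one value per participant (in cohort
#'   order), or a data frame with `participant_id` and a `behavior` column.
#' @param threshold Two-tailed p-value threshold for selection
#'   (default 0.01).
#' @return A list of class `edge_selection`: tibbles `pos_edges` and
#'   `neg_edges` (`node_i`, `node_j`, `r`, `p`), plus `n` and `threshold`.
#' @export
select_edges <- function(cohort, behavior, threshold = 0.01) {
  behavior <- behavior_vector(behavior, cohort)
  n <- length(behavior)
  if (n < 4) abort("Edge selection needs at least 4 participants.")
  if (sd(behavior) == 0) abort("`behavior` is constant; correlations undefined.")
  ev <- cohort_edge_values(cohort)
  stats <- edge_behavior_stats(ev$values, behavior)
  sel_pos <- !is.na(stats$r) & stats$r > 0 & stats$p < threshold
  sel_neg <- !is.na(stats$r) & stats$r < 0 & stats$p < threshold
  out <- list(
    pos_edges = dplyr::bind_cols(ev$edges[sel_pos, ], stats[sel_pos, ]),
    neg_edges = dplyr::bind_cols(ev$edges[sel_neg, ], stats[sel_neg, ]),
    n = n, threshold = threshold
  )
  structure(out, class = "edge_selection")
}

# Pearson r and two-tailed p of each edge (column of `values`) vs behavior.
# Constant edges yield NA r and NA p.
edge_behavior_stats <- function(values, behavior) {
  n <- length(behavior)
  r <- suppressWarnings(as.vector(cor(values, behavior)))
  r[!is.finite(r)] <- NA_real_
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  tibble(r = r, p = p)
}

behavior_vector <- function(behavior, cohort) {
  if (is.data.frame(behavior)) {
    idx <- match(participants(cohort), as.character(behavior$participant_id))
    if (anyNA(idx)) abort("`behavior` table lacks some cohort participants.")
    behavior <- behavior$behavior[idx]
  }
  behavior <- as.numeric(behavior)
  if (length(behavior) != length(participants(cohort))) {
    abort("`behavior` must have one value per participant.")
  }
  if (anyNA(behavior)) abort("`behavior` contains missing values.")
  behavior
}

#' @export
print.edge_selection <- function(x, ...) {
  cat(sprintf(
    "<edge_selection> n=%d, p<%g: %d positive, %d negative edges\n",
    x$n, x$threshold, nrow(x$pos_edges), nrow(x$neg_edges)
  ))
  invisible(x)
}

#' Network strength: mean connectivity over a mask's edges
#'
#' The arithmetic mean of the Fisher-z values at the mask's edges, each
#' unordered edge counted exactly once.
#'
#' @param matrix Symmetric connectivity matrix with node-id dimnames (one
#'   participant).
#' @param mask An [edge_mask()]; must be nonempty and its nodes must all be
#'   present in the matrix.
#' @return A single numeric strength value.
#' @export
network_strength <- function(matrix, mask) {
  if (n_edges(mask) == 0) {
    abort("Empty mask: network strength is undefined.")
  }
  ids <- rownames(matrix)
  missing <- setdiff(
    as.character(unique(c(mask$node_i, mask$node_j))), ids
  )
  if (length(missing) > 0) {
    abort(paste0(
      "Mask node(s) absent from matrix: ", paste(missing, collapse = ", ")
    ))
  }
  ri <- match(as.character(mask$node_i), ids)
  ci <- match(as.character(mask$node_j), ids)
  mean(matrix[cbind(ri, ci)])
}

#' Train a connectome-based predictive model with leave-one-out CV
#'
#' For each left-out participant, edges are selected on the remaining
#' training participants ([select_edges()]); the training participants'
#' network strengths (mean connectivity over the fold's positive edges, and
#' separately over its negative edges) are each regressed on behavior by
#' ordinary least squares, and the fitted line predicts the left-out
#' participant's behavior from their own strength. The consensus masks are
#' the edges selected in every fold. A fold that selects no edges of a
#' polarity contributes an undefined (`NA`) prediction and an empty set to
#' the intersection for that polarity; if no fold selects any edge of
#' either polarity, training fails.
#'
#' @inheritParams select_edges
#' @return An object of class `cpm_model`: list with `consensus_high` and
#'   `consensus_low` ([edge_mask()]s), `folds` (per-fold tibble, see
#'   [tidy.cpm_model()]), `predictions` (tibble `participant_id`,
#'   `observed`, `predicted_high`, `predicted_low`), `threshold`, `n`,
#'   `node_ids`.
#' @export
train_cpm_loo <- function(cohort, behavior, threshold = 0.01) {
  behavior <- behavior_vector(behavior, cohort)
  n <- length(behavior)
  if (n < 5) abort("Leave-one-out CPM training needs at least 5 participants.")
  ev <- cohort_edge_values(cohort)
  values <- ev$values
  fold_list <- purrr::map(seq_len(n), function(i) {
    tr_vals <- values[-i, , drop = FALSE]
    tr_beh <- behavior[-i]
    stats <- edge_behavior_stats(tr_vals, tr_beh)
    pos <- which(!is.na(stats$r) & stats$r > 0 & stats$p < threshold)
    neg <- which(!is.na(stats$r) & stats$r < 0 & stats$p < threshold)
    fit_one <- function(cols) {
      if (length(cols) == 0) {
        return(list(coef = c(NA_real_, NA_real_), pred = NA_real_))
      }
      s_tr <- rowMeans(tr_vals[, cols, drop = FALSE])
      fit <- stats::lm.fit(cbind(1, s_tr), tr_beh)
      s_i <- mean(values[i, cols])
      list(coef = unname(fit$coefficients), pred = sum(c(1, s_i) * fit$coefficients))
    }
    high <- fit_one(pos)
    low <- fit_one(neg)
    list(
      pos = pos, neg = neg,
      fit_high = high$coef, fit_low = low$coef,
      pred_high = high$pred, pred_low = low$pred
    )
  })
  if (all(vapply(fold_list, function(f) {
    length(f$pos) + length(f$neg) == 0
  }, logical(1)))) {
    abort("No fold selected any edge; cannot train a CPM at this threshold.")
  }
  consensus_idx <- function(field) {
    Reduce(intersect, lapply(fold_list, `[[`, field))
  }
  make_mask <- function(idx, pol) {
    edge_mask(ev$edges[idx, , drop = FALSE], cohort$node_ids, polarity = pol)
  }
  folds <- purrr::imap_dfr(fold_list, function(f, i) {
    tibble(
      fold = i,
      left_out = participants(cohort)[i],
      n_pos_edges = length(f$pos),
      n_neg_edges = length(f$neg),
      intercept_high = f$fit_high[1], slope_high = f$fit_high[2],
      intercept_low = f$fit_low[1], slope_low = f$fit_low[2]
    )
  })
  structure(
    list(
      consensus_high = make_mask(consensus_idx("pos"), "high"),
      consensus_low = make_mask(consensus_idx("neg"), "low"),
      folds = folds,
      fold_edges = lapply(fold_list, function(f) {
        list(pos = ev$edges[f$pos, ], neg = ev$edges[f$neg, ])
      }),
      predictions = tibble(
        participant_id = participants(cohort),
        observed = behavior,
        predicted_high = vapply(fold_list, `[[`, numeric(1), "pred_high"),
        predicted_low = vapply(fold_list, `[[`, numeric(1), "pred_low")
      ),
      threshold = threshold, n = n, node_ids = cohort$node_ids
    ),
    class = "cpm_model"
  )
}

#' @export
print.cpm_model <- function(x, ...) {
  cat(sprintf(
    "<cpm_model> n=%d, %d LOO folds, p<%g\n  consensus: %d high / %d low edges\n",
    x$n, nrow(x$folds), x$threshold,
    n_edges(x$consensus_high), n_edges(x$consensus_low)
  ))
  invisible(x)
}

#' @describeIn train_cpm_loo Per-fold selection sizes and fitted
#'   coefficients, one row per leave-one-out fold.
#' @param x,object A `cpm_model`.
#' @param ... Unused.
#' @export
tidy.cpm_model <- function(x, ...) x$folds

#' @describeIn train_cpm_loo One-row model summary: sample size, threshold,
#'   consensus mask sizes, and leave-one-out prediction correlations.
#' @export
glance.cpm_model <- function(x, ...) {
  pr <- x$predictions
  safe_cor <- function(a, b) {
    ok <- complete.cases(a, b)
    if (sum(ok) < 3 || sd(a[ok]) == 0 || sd(b[ok]) == 0) {
      return(NA_real_)
    }
    cor(a[ok], b[ok])
  }
  tibble(
    n = x$n,
    threshold = x$threshold,
    n_consensus_high = n_edges(x$consensus_high),
    n_consensus_low = n_edges(x$consensus_low),
    loo_cor_high = safe_cor(pr$predicted_high, pr$observed),
    loo_cor_low = safe_cor(pr$predicted_low, pr$observed)
  )
}

#' Score a cohort with a trained CPM's consensus masks
#'
#' Applies the consensus high and low masks to every participant matrix and
#' returns mean network-strength scores.
#'
#' @param cohort A [conn_cohort()]; its nodes must include all mask nodes.
#' @param model A `cpm_model` from [train_cpm_loo()], or a list with
#'   elements `consensus_high` and `consensus_low` ([edge_mask()]s).
#' @param combined Also return `combined_strength = high - low`? This
#'   difference score is an interpretation some CPM studies report; it is
#'   off by default.
#' @return Tibble of class `strength_scores`: `participant_id`,
#'   `high_strength`, `low_strength` (and optionally `combined_strength`).
#' @export
apply_model <- function(cohort, model, combined = FALSE) {
  high <- model$consensus_high
  low <- model$consensus_low
  if (n_edges(high) == 0 && n_edges(low) == 0) {
    abort("Both consensus masks are empty: strengths undefined.")
  }
  score <- function(mask) {
    if (n_edges(mask) == 0) {
      return(rep(NA_real_, length(participants(cohort))))
    }
    unname(vapply(cohort$matrices, network_strength, numeric(1), mask = mask))
  }
  out <- tibble(
    participant_id = participants(cohort),
    high_strength = score(high),
    low_strength = score(low)
  )
  if (combined) {
    out$combined_strength <- out$high_strength - out$low_strength
  }
  class(out) <- c("strength_scores", class(out))
  out
}

#' Save a trained CPM to a directory
#'
#' Writes the consensus masks (matrix TSV + edge-list CSV), the per-fold
#' edge lists and coefficients, and a training manifest (threshold, n, node
#' count).
#'
#' @param model A `cpm_model`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_cpm_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_edge_mask(model$consensus_high, file.path(dir, "consensus_high"))
  write_edge_mask(model$consensus_low, file.path(dir, "consensus_low"))
  readr::write_csv(model$folds, file.path(dir, "folds.csv"))
  fold_edges <- purrr::imap_dfr(model$fold_edges, function(f, i) {
    dplyr::bind_rows(
      dplyr::mutate(f$pos, fold = i, polarity = "high"),
      dplyr::mutate(f$neg, fold = i, polarity = "low")
    )
  })
  readr::write_csv(fold_edges, file.path(dir, "fold_edges.csv"))
  jsonlite::write_json(
    list(
      threshold = model$threshold, n = model$n,
      n_nodes = length(model$node_ids),
      n_consensus_high = n_edges(model$consensus_high),
      n_consensus_low = n_edges(model$consensus_low)
    ),
    file.path(dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(dir)
}
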