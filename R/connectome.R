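#' Fisher-z functional connectivity from node time series
#'
#' Computes the Pearson correlation between every pair of node time courses
#' and applies the Fisher z (inverse hyperbolic tangent) transform. To keep
#' z finite for (anti)perfectly correlated pairs, |r| is clipped at
#' `1 - clip_eps` before `atanh()`; with the default `clip_eps = 1e-7` the
#' clipped z is about 8.4, far outside the range of real connectivity values,
#' so clipping never affects ordinary data.
#'
#' A node whose time course is entirely `NA` is treated as a missing node:
#' its row and column of the output are `NA` (see [harmonize_nodes()]).
#' A constant (zero-variance) time course is an error, because its
#' correlations are undefined.
#'
#' @param timeseries Numeric matrix, nodes as rows and timepoints as
#'   columns (at least 3), or a data frame whose first column is `node_id`.
#' @param node_ids Integer node ids; defaults to rownames / the `node_id`
#'   column / `1:n`.
#' @param clip_eps Clipping margin for |r| before `atanh()`.
#' @return Symmetric numeric matrix of Fisher-z values with node-id
#'   dimnames; diagonal `NA`.
#' @examples
#' ts <- rbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4))
#' fisher_z_connectivity(ts, node_ids = 1:2) # z = atanh(0.8)
#' @export
fisher_z_connectivity <- function(timeseries, node_ids = NULL,
                                  clip_eps = 1e-7) {
  if (is.data.frame(timeseries)) {
    node_ids <- node_ids %||% timeseries$node_id
    timeseries <- as.matrix(timeseries[, setdiff(names(timeseries), "node_id")])
  }
  ts <- as.matrix(timeseries)
  storage.mode(ts) <- "double"
  if (ncol(ts) < 3) abort("At least 3 timepoints are required.")
  node_ids <- as.integer(node_ids %||% rownames(ts) %||% seq_len(nrow(ts)))
  all_na <- apply(ts, 1, function(x) all(is.na(x)))
  sds <- apply(ts, 1, sd)
  const <- !all_na & (is.na(sds) | sds == 0)
  if (any(const)) {
    abort(paste0(
      "Constant time series for node(s): ",
      paste(node_ids[const], collapse = ", ")
    ))
  }
  r <- suppressWarnings(cor(t(ts)))
  r <- pmin(pmax(r, -(1 - clip_eps)), 1 - clip_eps)
  z <- atanh(r)
  diag(z) <- NA_real_
  nm <- as.character(node_ids)
  dimnames(z) <- list(nm, nm)
  z
}

#' Build a cohort of connectomes from per-participant time series
#'
#' @param timeseries_list Named list (participant id -> node x time matrix).
#' @param node_ids Common node ids.
#' @param clip_eps Passed to [fisher_z_connectivity()].
#' @return A [conn_cohort()].
#' @export
cohort_from_timeseries <- function(timeseries_list, node_ids = NULL,
                                   clip_eps = 1e-7) {
  mats <- lapply(
    timeseries_list, fisher_z_connectivity,
    node_ids = node_ids, clip_eps = clip_eps
  )
  conn_cohort(mats, node_ids = node_ids)
}

#' Remove nodes that are missing in too many participants
#'
#' A node is "missing" for a participant when its whole off-diagonal
#' row is `NA`. Every node missing in at least `min_participants_missing`
#' participants is removed from all participants, so that the cohort stays
#' on a common node list; nodes missing in fewer participants are kept (and
#' those participants retain `NA` rows). The ordering of surviving nodes is
#' preserved, and re-running the operation is idempotent.
#'
#' @param cohort A [conn_cohort()].
#' @param missing Optional named list (participant id -> integer node ids)
#'   declaring missing nodes explicitly; by default missingness is detected
#'   from all-`NA` rows.
#' @param min_participants_missing Removal threshold (default 3).
#' @return The harmonized [conn_cohort()], with attribute `removed_nodes`
#'   (integer node ids, possibly empty).
#' @export
harmonize_nodes <- function(cohort, missing = NULL,
                            min_participants_missing = 3) {
  ids <- cohort$node_ids
  if (is.null(missing)) {
    missing <- lapply(cohort$matrices, function(m) {
      ids[rowSums(!is.na(m)) == 0]
    })
  } else {
    bad <- setdiff(unlist(missing), ids)
    if (length(bad) > 0) {
      abort(paste0("Missing-node ids not in cohort: ", paste(bad, collapse = ", ")))
    }
  }
  counts <- table(factor(unlist(missing), levels = ids))
  removed <- ids[as.vector(counts) >= min_participants_missing]
  if (length(removed) == length(ids)) {
    abort("Harmonization would remove every node.")
  }
  out <- if (length(removed) == 0) {
    cohort
  } else {
    cohort_subset(cohort, node_ids = setdiff(ids, removed))
  }
  attr(out, "removed_nodes") <- removed
  out
}

#' Motion and coverage quality-control filter
#'
#' Applies the cohort exclusion rules in their narrative order: first drop
#' participants whose scan failed coverage / global-signal checks
#' (`coverage_ok` is `FALSE`), then drop participants with excessive head
#' motion (mean framewise displacement strictly greater than
#' `fd_threshold`; a participant at exactly the threshold is retained).
#' Each participant is counted under exactly one exclusion reason.
#'
#' @param phenotypes Data frame with columns `participant_id`, `mean_fd`
#'   (mm) and logical `coverage_ok`.
#' @param fd_threshold Mean-FD exclusion threshold in mm (default 0.15).
#' @return A list of class `qc_result`: `retained` (character participant
#'   ids), `exclusions` (tibble `reason`, `n`), `n_in`, `n_out`,
#'   `fd_threshold`.
#' @examples
#' ph <- tibble::tibble(
#'   participant_id = as.character(1:4),
#'   mean_fd = c(0.05, 0.15, 0.30, 0.08),
#'   coverage_ok = c(TRUE, TRUE, TRUE, FALSE)
#' )
#' qc_filter(ph)$retained # "1" "2": 0.15 is retained, 0.30 and bad coverage out
#' @export
qc_filter <- function(phenotypes, fd_threshold = 0.15) {
  need <- c("participant_id", "mean_fd", "coverage_ok")
  miss <- setdiff(need, names(phenotypes))
  if (length(miss) > 0) {
    abort(paste0("Missing required column(s): ", paste(miss, collapse = ", ")))
  }
  ph <- as_tibble(phenotypes)
  cov_fail <- !ph$coverage_ok
  fd_fail <- ph$coverage_ok & ph$mean_fd > fd_threshold
  retained <- as.character(ph$participant_id[!cov_fail & !fd_fail])
  structure(
    list(
      retained = retained,
      exclusions = tibble(
        reason = c("coverage_or_global_signal", "mean_fd_above_threshold"),
        n = c(sum(cov_fail), sum(fd_fail))
      ),
      n_in = nrow(ph),
      n_out = length(retained),
      fd_threshold = fd_threshold
    ),
    class = "qc_result"
  )
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf(
    "<qc_result> %d in -> %d retained (FD threshold %.3g mm)\n",
    x$n_in, x$n_out, x$fd_threshold
  ))
  print(x$exclusions)
  invisible(x)
}

#' Read a node atlas CSV
#'
#' @param path CSV with columns `node_id`, `network_name`.
#' @return Tibble with unique integer `node_id` and character `network_name`.
#' @export
read_atlas <- function(path) {
  atlas <- readr::read_csv(path, show_col_types = FALSE)
  validate_atlas(atlas)
}

validate_atlas <- function(atlas) {
  if (!all(c("node_id", "network_name") %in% names(atlas))) {
    abort("Atlas needs columns `node_id` and `network_name`.")
  }
  atlas <- as_tibble(atlas)
  atlas$node_id <- as.integer(atlas$node_id)
  if (anyDuplicated(atlas$node_id)) abort("Atlas node ids must be unique.")
  atlas
}

#' Deterministic synthetic node atlas
#'
#' Assigns node ids to canonical networks in contiguous blocks whose sizes
#' are proportional to `weights`. This mimics a functional parcellation's
#' network lookup for simulation studies; it is synthetic and carries no
#' anatomical meaning.
#'
#' @param node_ids Integer node ids to label.
#' @param networks Character vector of network names.
#' @param weights Relative block sizes (recycled default: equal).
#' @return Atlas tibble (`node_id`, `network_name`).
#' @export
synthetic_atlas <- function(node_ids,
                            networks = c(
                              "DMN", "VAN", "DAN", "FPN",
                              "visual", "somatomotor", "subcortical"
                            ),
                            weights = NULL) {
  node_ids <- as.integer(node_ids)
  k <- length(networks)
  weights <- weights %||% rep(1, k)
  stopifnot(length(weights) == k, all(weights > 0))
  n <- length(node_ids)
  sizes <- diff(round(cumsum(c(0, weights)) / sum(weights) * n))
  # rounding can starve a block; guarantee >= 1 node per network when possible
  while (any(sizes == 0) && n >= k) {
    i <- which(sizes == 0)[1]
    j <- which.max(sizes)
    sizes[i] <- sizes[i] + 1L
    sizes[j] <- sizes[j] - 1L
  }
  tibble(
    node_id = node_ids,
    network_name = rep(networks, times = sizes)
  )
}
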