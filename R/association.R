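#' Partial Spearman correlation
#'
#' Rank-based association between two variables adjusting for covariates.
#' All variables (x, y, and each covariate) are rank-transformed with
#' average ranks for ties, then the partial Pearson correlation of the
#' ranked x and y given the ranked covariates is computed from the inverse
#' of their joint correlation matrix. With no covariates this is exactly
#' Spearman's rho. Because ranks are invariant to strictly monotone
#' transforms, so is the estimate.
#'
#' The p-value uses the usual t approximation,
#' `t = rho * sqrt((n - 2 - k) / (1 - rho^2))` on `n - 2 - k` degrees of
#' freedom (k = number of covariates), two-tailed.
#'
#' Rows with a missing value in any involved column are dropped (listwise
#' deletion). A covariate that is constant after deletion carries no
#' information and is dropped with a warning, so the result degrades to the
#' unadjusted Spearman correlation.
#'
#' @param data A data frame.
#' @param x,y Column names (strings) of the two variables.
#' @param covariates Character vector of covariate column names (possibly
#'   empty).
#' @return One-row tibble: `predictor`, `outcome`, `covariates`
#'   (comma-separated), `rho`, `p`, `n`.
#' @examples
#' d <- data.frame(a = 1:10, b = (1:10)^3, fd = rnorm(10))
#' partial_spearman(d, "a", "b", "fd") # rho = 1: monotone invariance
#' @export
partial_spearman <- function(data, x, y, covariates = character()) {
  cols <- c(x, y, covariates)
  miss <- setdiff(cols, names(data))
  if (length(miss) > 0) {
    abort(paste0("Unknown column(s): ", paste(miss, collapse = ", ")))
  }
  d <- as.data.frame(data)[, cols, drop = FALSE]
  d <- d[complete.cases(d), , drop = FALSE]
  k <- length(covariates)
  n <- nrow(d)
  if (n < 4 + k) {
    abort(sprintf(
      "Need at least %d complete rows for %d covariate(s); have %d.",
      4 + k, k, n
    ))
  }
  ranked <- as.matrix(as.data.frame(lapply(d, rank, ties.method = "average")))
  if (sd(ranked[, 1]) == 0 || sd(ranked[, 2]) == 0) {
    abort("`x` or `y` is constant after listwise deletion.")
  }
  const_cov <- covariates[apply(
    ranked[, -(1:2), drop = FALSE], 2, sd
  ) == 0]
  if (length(const_cov) > 0) {
    warn(paste0(
      "Dropping constant covariate(s): ", paste(const_cov, collapse = ", ")
    ))
    covariates <- setdiff(covariates, const_cov)
    ranked <- ranked[, c(x, y, covariates), drop = FALSE]
    k <- length(covariates)
  }
  if (k == 0) {
    rho <- cor(ranked[, 1], ranked[, 2])
  } else {
    cm <- cor(ranked)
    prec <- solve(cm)
    rho <- -prec[1, 2] / sqrt(prec[1, 1] * prec[2, 2])
  }
  df <- n - 2 - k
  tstat <- rho * sqrt(df / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = df, lower.tail = FALSE)
  tibble(
    predictor = x, outcome = y,
    covariates = paste(covariates, collapse = ","),
    rho = rho, p = p, n = n
  )
}

#' Steiger's Z for two dependent correlations sharing one variable
#'
#' Tests whether two correlations `r_jk` and `r_jh`, measured on the same
#' `n` cases and sharing the variable `j` (here typically: the outcome's
#' correlation with whole-brain strength vs with lesioned strength), differ.
#' Uses the Steiger (1980) statistic
#' \deqn{Z = (z_{jk} - z_{jh}) \sqrt{\frac{n - 3}{2 - 2\bar c}}}
#' where \eqn{z} are Fisher transforms,
#' \eqn{\bar c = \bar\psi / (1 - \bar r^2)^2},
#' \eqn{\bar\psi = r_{kh}(1 - 2\bar r^2) - \tfrac12 \bar r^2
#'   (1 - 2\bar r^2 - r_{kh}^2)},
#' and \eqn{\bar r} is the back-transformed mean correlation
#' \eqn{\tanh((z_{jk} + z_{jh})/2)}. The p-value is two-tailed normal,
#' `p = 2 * (1 - pnorm(|Z|))`. Positive Z means `r_jk > r_jh` on the Fisher
#' scale; swapping the two correlations flips the sign exactly.
#'
#' No clipping is applied here: a correlation of exactly +/-1 is an error,
#' since its Fisher transform is infinite.
#'
#' @param r_jk,r_jh The two dependent correlations sharing variable j
#'   (|r| < 1).
#' @param r_kh Correlation between the two non-shared variables (|r| <= 1).
#' @param n Common sample size (>= 4).
#' @return One-row tibble of class `steiger_result`: `z`, `p`, `r_jk`,
#'   `r_jh`, `r_kh`, `n`, `psd_ok` (whether the implied 3x3 correlation
#'   matrix is positive semidefinite; if not, a warning is also raised).
#' @export
steiger_z <- function(r_jk, r_jh, r_kh, n) {
  if (n < 4) abort("Steiger's Z needs n >= 4.")
  if (abs(r_jk) >= 1 || abs(r_jh) >= 1) {
    abort("Steiger's Z is undefined for |r| = 1 (infinite Fisher z).")
  }
  if (abs(r_kh) > 1) abort("`r_kh` must lie in [-1, 1].")
  R <- matrix(c(1, r_jk, r_jh, r_jk, 1, r_kh, r_jh, r_kh, 1), 3, 3)
  psd_ok <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) >= -1e-12
  if (!psd_ok) {
    warn("(r_jk, r_jh, r_kh) do not form a positive semidefinite correlation matrix.")
  }
  z_jk <- atanh(r_jk)
  z_jh <- atanh(r_jh)
  if (z_jk == z_jh) {
    # identical correlations: the difference is exactly zero whatever the
    # (possibly degenerate, e.g. r_kh = 1) covariance term
    z <- 0
  } else {
    rbar <- tanh((z_jk + z_jh) / 2)
    psi <- r_kh * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r_kh^2)
    cbar <- psi / (1 - rbar^2)^2
    denom <- 2 - 2 * cbar
    if (denom <= 0) {
      warn("Degenerate Steiger variance (covariance term >= 1); returning NA.")
      z <- NA_real_
    } else {
      z <- (z_jk - z_jh) * sqrt((n - 3) / denom)
    }
  }
  out <- tibble(
    z = z, p = 2 * pnorm(abs(z), lower.tail = FALSE),
    r_jk = r_jk, r_jh = r_jh, r_kh = r_kh, n = as.integer(n),
    psd_ok = psd_ok
  )
  class(out) <- c("steiger_result", class(out))
  out
}

#' Run the full strength-by-outcome association battery
#'
#' Computes one covariate-adjusted partial Spearman association
#' ([partial_spearman()]) for every combination of strength score (high,
#' low, and `combined` if present) and outcome, with per-pair listwise
#' deletion and per-row n. P-values are reported unadjusted for multiple
#' testing (recorded in the result's `multiple_testing` attribute).
#'
#' @param scores A `strength_scores` tibble from [apply_model()].
#' @param phenotypes Phenotype table with `participant_id`, the outcome
#'   columns and the covariate columns.
#' @param outcomes Character vector of outcome column names. A duplicated
#'   name is kept (producing identical rows) with a warning.
#' @param covariates Character vector of covariate column names
#'   (default `"mean_fd"`).
#' @return Tibble of class `cpm_associations`, one row per
#'   (predictor, outcome): `predictor`, `outcome`, `covariates`, `rho`,
#'   `p`, `n`.
#' @export
run_association_battery <- function(scores, phenotypes, outcomes,
                                    covariates = "mean_fd") {
  miss <- setdiff(c(outcomes, covariates), names(phenotypes))
  if (length(miss) > 0) {
    abort(paste0("Unknown column(s) in `phenotypes`: ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(outcomes)) {
    warn("Duplicated outcome(s) requested; identical rows will be returned.")
  }
  d <- dplyr::inner_join(
    as_tibble(scores),
    dplyr::mutate(as_tibble(phenotypes), participant_id = as.character(.data$participant_id)) |>
      dplyr::select(dplyr::all_of(c("participant_id", unique(c(outcomes, covariates))))),
    by = "participant_id"
  )
  predictors <- intersect(
    c("high_strength", "low_strength", "combined_strength"), names(scores)
  )
  grid <- tidyr::expand_grid(predictor = predictors, outcome = outcomes)
  out <- purrr::pmap_dfr(grid, function(predictor, outcome) {
    partial_spearman(d, predictor, outcome, covariates)
  })
  attr(out, "multiple_testing") <- "none"
  class(out) <- c("cpm_associations", class(out))
  out
}
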