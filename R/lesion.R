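#' Computationally lesion a canonical network
#'
#' Removes every node labeled `network_name` in the atlas from all
#' participant matrices (rows and columns), and deletes from the mask every
#' edge incident to a removed node — both within-network and between-network
#' connections. Surviving node ordering is preserved. Lesioning is
#' idempotent and commutes across networks.
#'
#' @param cohort A [conn_cohort()].
#' @param mask An [edge_mask()] on the cohort's nodes.
#' @param atlas Atlas tibble (`node_id`, `network_name`), e.g. from
#'   [read_atlas()] or [synthetic_atlas()].
#' @param network_name Canonical network to remove.
#' @return A list of class `lesioned`: `cohort` (lesioned), `mask`
#'   (lesioned; possibly empty, in which case downstream strength is
#'   undefined), `removed_nodes` (integer ids), `network_name`.
#' @export
lesion_network <- function(cohort, mask, atlas, network_name) {
  atlas <- validate_atlas(atlas)
  if (!network_name %in% atlas$network_name) {
    abort(paste0("Network not in atlas: ", network_name))
  }
  target <- atlas$node_id[atlas$network_name == network_name]
  removed <- intersect(cohort$node_ids, target)
  if (length(removed) == 0) {
    warn(paste0(
      "Network '", network_name, "' has no member nodes in this cohort; no-op."
    ))
    out <- list(
      cohort = cohort, mask = mask,
      removed_nodes = integer(0), network_name = network_name
    )
    return(structure(out, class = "lesioned"))
  }
  keep <- setdiff(cohort$node_ids, removed)
  if (length(keep) == 0) abort("Lesion would remove every node.")
  structure(
    list(
      cohort = cohort_subset(cohort, node_ids = keep),
      mask = mask_restrict(mask, keep),
      removed_nodes = removed,
      network_name = network_name
    ),
    class = "lesioned"
  )
}

#' @export
print.lesioned <- function(x, ...) {
  cat(sprintf(
    "<lesioned> network=%s: removed %d nodes, %d mask edges remain (%d nodes)\n",
    x$network_name, length(x$removed_nodes), n_edges(x$mask),
    length(x$cohort$node_ids)
  ))
  invisible(x)
}

#' Whole-brain vs lesioned association comparison
#'
#' For each requested canonical network: lesion it ([lesion_network()]),
#' recompute network strength from the surviving mask edges (mean over what
#' remains, not rescaled), estimate the covariate-adjusted partial Spearman
#' association of the lesioned strength with the outcome, and compare it to
#' the whole-brain association with [steiger_z()]. All three correlations
#' entering Steiger's Z (outcome vs whole strength, outcome vs lesioned
#' strength, whole vs lesioned strength) are computed on the same
#' listwise-complete participant set, so n is shared; `r_kh` is the plain
#' (unadjusted) Spearman correlation between the two strength scores. The
#' rank-based rhos are fed into the normal-theory Steiger formula, an
#' approximation recorded in the result's `steiger_inputs` attribute.
#'
#' A lesion that empties the mask yields a row with explicit `NA`
#' association and Z fields, never a silent omission.
#'
#' @param cohort A [conn_cohort()] (harmonized).
#' @param model A `cpm_model` (or list with consensus masks).
#' @param atlas Atlas tibble (`node_id`, `network_name`).
#' @param phenotypes Phenotype table (`participant_id`, outcome,
#'   covariates).
#' @param outcome Outcome column name.
#' @param covariates Covariate column names (default `"mean_fd"`).
#' @param networks Character vector of networks to lesion.
#' @param polarity Which consensus mask to lesion (default `"high"`).
#' @return Tibble of class `cpm_lesion`, one row per network:
#'   `network`, `removed_nodes`, `remaining_mask_edges`, `rho_whole`,
#'   `p_whole`, `rho_lesioned`, `p_lesioned`, `r_strengths`, `steiger_z`,
#'   `steiger_p`, `n`.
#' @export
lesion_analysis <- function(cohort, model, atlas, phenotypes, outcome,
                            covariates = "mean_fd",
                            networks = c("DMN", "VAN", "DAN", "FPN"),
                            polarity = c("high", "low")) {
  polarity <- match.arg(polarity)
  mask <- if (polarity == "high") model$consensus_high else model$consensus_low
  if (n_edges(mask) == 0) abort("Whole-brain consensus mask is empty.")
  ph <- dplyr::mutate(
    as_tibble(phenotypes),
    participant_id = as.character(.data$participant_id)
  )
  whole <- tibble(
    participant_id = participants(cohort),
    whole_strength = unname(vapply(
      cohort$matrices, network_strength, numeric(1), mask = mask
    ))
  )
  rows <- purrr::map_dfr(networks, function(net) {
    les <- lesion_network(cohort, mask, atlas, net)
    base <- tibble(
      network = net,
      removed_nodes = length(les$removed_nodes),
      remaining_mask_edges = n_edges(les$mask)
    )
    if (n_edges(les$mask) == 0) {
      return(dplyr::mutate(base,
        rho_whole = NA_real_, p_whole = NA_real_,
        rho_lesioned = NA_real_, p_lesioned = NA_real_,
        r_strengths = NA_real_, steiger_z = NA_real_, steiger_p = NA_real_,
        n = NA_integer_
      ))
    }
    d <- whole
    d$lesioned_strength <- unname(vapply(
      les$cohort$matrices, network_strength, numeric(1), mask = les$mask
    ))
    d <- dplyr::inner_join(d, ph, by = "participant_id")
    d <- d[complete.cases(
      d[, c("whole_strength", "lesioned_strength", outcome, covariates)]
    ), ]
    a_whole <- partial_spearman(d, "whole_strength", outcome, covariates)
    a_les <- partial_spearman(d, "lesioned_strength", outcome, covariates)
    r_kh <- cor(d$whole_strength, d$lesioned_strength, method = "spearman")
    st <- if (abs(a_whole$rho) >= 1 || abs(a_les$rho) >= 1) {
      tibble(z = NA_real_, p = NA_real_)
    } else {
      steiger_z(a_whole$rho, a_les$rho, r_kh, nrow(d))
    }
    dplyr::mutate(base,
      rho_whole = a_whole$rho, p_whole = a_whole$p,
      rho_lesioned = a_les$rho, p_lesioned = a_les$p,
      r_strengths = r_kh, steiger_z = st$z, steiger_p = st$p,
      n = nrow(d)
    )
  })
  attr(rows, "steiger_inputs") <-
    "rank-based partial rhos in normal-theory Steiger Z (approximation)"
  attr(rows, "outcome") <- outcome
  attr(rows, "polarity") <- polarity
  class(rows) <- c("cpm_lesion", class(rows))
  rows
}
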