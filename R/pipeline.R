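#' Configuration for an end-to-end pipeline run
#'
#' @param sim A [sim_config()] describing the synthetic cohort (ignored
#'   when `input_dir` points at an existing cohort on disk).
#' @param input_dir Optional directory from [write_cohort()] to analyze
#'   instead of simulating.
#' @param selection_threshold Edge-selection p threshold for
#'   [train_cpm_loo()].
#' @param fd_threshold Mean-FD QC threshold (mm) for [qc_filter()].
#' @param behavior_col Training behavior column in the phenotype table.
#' @param outcomes Outcome columns for [run_association_battery()].
#' @param covariates Covariate columns for the associations.
#' @param lesion_networks Canonical networks to lesion; `character(0)`
#'   skips the lesion stage.
#' @param lesion_outcome Outcome for the lesion comparison (defaults to
#'   the first of `outcomes`).
#' @param atlas Optional atlas tibble; defaults to [synthetic_atlas()]
#'   over the harmonized nodes.
#' @param stages Character subset of
#'   `c("qc", "harmonize", "train", "score", "associate", "lesion")`;
#'   stages not listed are skipped (earlier stages feed later ones).
#' @param combined Also compute the high-minus-low combined score.
#' @param seed Seed for the run; defaults to `sim$seed`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(seed = 1L),
                       input_dir = NULL,
                       selection_threshold = 0.01,
                       fd_threshold = 0.15,
                       behavior_col = "behavior",
                       outcomes = c("biomarker", "pacc_like", "mem_like", "ef_like"),
                       covariates = "mean_fd",
                       lesion_networks = c("DMN", "VAN", "DAN", "FPN"),
                       lesion_outcome = NULL,
                       atlas = NULL,
                       stages = c(
                         "qc", "harmonize", "train", "score",
                         "associate", "lesion"
                       ),
                       combined = FALSE,
                       seed = NULL) {
  structure(
    list(
      sim = sim, input_dir = input_dir,
      selection_threshold = selection_threshold,
      fd_threshold = fd_threshold,
      behavior_col = behavior_col,
      outcomes = outcomes, covariates = covariates,
      lesion_networks = lesion_networks,
      lesion_outcome = lesion_outcome %||% outcomes[1],
      atlas = atlas,
      stages = stages,
      combined = combined,
      seed = as.integer(seed %||% sim$seed)
    ),
    class = "run_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> QC -> node harmonization -> leave-one-out
#' CPM training -> strength scoring -> covariate-adjusted associations ->
#' computational lesioning, writing every stage's table to `out_dir`
#' together with a machine-readable run manifest (seed, configuration
#' hash, file list, stage log). A rerun with the identical configuration
#' and seed reproduces all numeric outputs exactly. A stage failure aborts
#' with the failing stage named and leaves a `FAILED` marker file beside
#' the partial outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created).
#' @return A list of class `cpm_run` with elements `qc`, `cohort`
#'   (harmonized), `removed_nodes`, `model`, `scores`, `associations`,
#'   `lesions`, `phenotypes`, `truth`, `manifest`, `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("cpm_run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(stage, msg) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
    log_lines <<- c(log_lines, line)
    inform(line)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(
        c(paste0("failed stage: ", stage), conditionMessage(e)),
        file.path(out_dir, "FAILED")
      )
      abort(
        paste0("Pipeline failed in stage '", stage, "': ", conditionMessage(e)),
        parent = e
      )
    })
  }
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(df, path)
    files <<- c(files, name)
  }

  # --- input: simulate or load -------------------------------------------
  truth <- NULL
  if (is.null(config$input_dir)) {
    note("simulate", sprintf(
      "generating synthetic cohort (n=%d, nodes=%d, seed=%d)",
      config$sim$n_participants, config$sim$n_nodes, config$seed
    ))
    sim <- run_stage("simulate", {
      cfg <- config$sim
      cfg$seed <- config$seed
      generate_cohort(cfg)
    })
    cohort <- sim$cohort %||%
      cohort_from_timeseries(sim$timeseries)
    phenotypes <- sim$phenotypes
    truth <- sim$truth
  } else {
    note("load", paste0("reading cohort from ", config$input_dir))
    loaded <- run_stage("load", read_cohort(config$input_dir))
    cohort <- loaded$cohort %||% cohort_from_timeseries(loaded$timeseries)
    phenotypes <- loaded$phenotypes
    truth <- loaded$truth
  }

  qc <- NULL
  if ("qc" %in% config$stages) {
    qc <- run_stage("qc", qc_filter(phenotypes, config$fd_threshold))
    note("qc", sprintf(
      "%d -> %d participants (%s)", qc$n_in, qc$n_out,
      paste(sprintf("%s: %d", qc$exclusions$reason, qc$exclusions$n),
        collapse = ", "
      )
    ))
    emit(qc$exclusions, "exclusions.csv")
    cohort <- cohort_subset(cohort, participant_ids = qc$retained)
    phenotypes <- dplyr::filter(
      phenotypes, .data$participant_id %in% qc$retained
    )
  }

  removed_nodes <- integer(0)
  if ("harmonize" %in% config$stages) {
    cohort <- run_stage("harmonize", harmonize_nodes(cohort))
    removed_nodes <- attr(cohort, "removed_nodes")
    note("harmonize", sprintf(
      "removed %d node(s); %d remain",
      length(removed_nodes), length(cohort$node_ids)
    ))
    emit(tibble(removed_node_id = removed_nodes), "removed_nodes.csv")
  }

  model <- NULL
  if ("train" %in% config$stages) {
    model <- run_stage("train", train_cpm_loo(
      cohort, phenotypes[, c("participant_id", config$behavior_col)] |>
        dplyr::rename(behavior = dplyr::all_of(config$behavior_col)),
      threshold = config$selection_threshold
    ))
    note("train", sprintf(
      "consensus masks: %d high, %d low edges",
      n_edges(model$consensus_high), n_edges(model$consensus_low)
    ))
    run_stage("train", write_cpm_model(model, file.path(out_dir, "model")))
    files <- c(files, "model/")
  }

  scores <- NULL
  if ("score" %in% config$stages && !is.null(model)) {
    scores <- run_stage(
      "score",
      apply_model(cohort, model, combined = config$combined)
    )
    emit(scores, "strengths.csv")
    note("score", sprintf("scored %d participants", nrow(scores)))
  }

  associations <- NULL
  if ("associate" %in% config$stages && !is.null(scores)) {
    associations <- run_stage("associate", run_association_battery(
      scores, phenotypes, config$outcomes, config$covariates
    ))
    emit(associations, "associations.csv")
    note("associate", sprintf("%d association rows", nrow(associations)))
  }

  lesions <- NULL
  atlas <- config$atlas %||% synthetic_atlas(cohort$node_ids)
  if ("lesion" %in% config$stages && length(config$lesion_networks) > 0 &&
    !is.null(model) && n_edges(model$consensus_high) > 0) {
    lesions <- run_stage("lesion", lesion_analysis(
      cohort, model, atlas, phenotypes,
      outcome = config$lesion_outcome,
      covariates = config$covariates,
      networks = config$lesion_networks,
      polarity = "high"
    ))
    emit(lesions, "lesions.csv")
    note("lesion", sprintf("%d lesion rows", nrow(lesions)))
  }

  manifest <- list(
    seed = config$seed,
    config_hash = rlang::hash(config),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("conncpm")),
    n_in = if (!is.null(qc)) qc$n_in else length(participants(cohort)),
    n_retained = length(participants(cohort)),
    n_nodes = length(cohort$node_ids),
    removed_nodes = removed_nodes,
    stages = config$stages,
    files = files,
    log = log_lines
  )
  jsonlite::write_json(
    manifest, file.path(out_dir, "run_manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  writeLines(log_lines, file.path(out_dir, "run.log"))

  structure(
    list(
      qc = qc, cohort = cohort, removed_nodes = removed_nodes,
      model = model, scores = scores, associations = associations,
      lesions = lesions, phenotypes = phenotypes, truth = truth,
      manifest = manifest, out_dir = out_dir
    ),
    class = "cpm_run"
  )
}

#' @export
print.cpm_run <- function(x, ...) {
  cat(sprintf("<cpm_run> %s\n", x$out_dir))
  summarize_run(x)
  invisible(x)
}

#' Human-readable summary of a pipeline run
#'
#' Prints cohort accounting (retained n and per-reason exclusions),
#' harmonization, consensus-mask sizes, every association rho/p, and every
#' lesion comparison's Steiger Z/p. Undefined quantities (e.g. strengths
#' after a lesion emptied the mask) are rendered as `undefined`, never as
#' zero. Every number shown is a cell of one of the run's CSV outputs.
#'
#' @param run A `cpm_run` from [run_pipeline()], or the path of its output
#'   directory.
#' @return Invisibly, `run`.
#' @export
summarize_run <- function(run) {
  if (is.character(run)) {
    run <- read_run(run)
  }
  fmt <- function(v, digits = 3) {
    ifelse(is.na(v), "undefined", format(round(v, digits), nsmall = digits))
  }
  if (!is.null(run$qc)) {
    cat(sprintf(
      "Cohort: %d screened -> %d retained\n", run$qc$n_in, run$qc$n_out
    ))
    for (i in seq_len(nrow(run$qc$exclusions))) {
      cat(sprintf(
        "  excluded (%s): %d\n",
        run$qc$exclusions$reason[i], run$qc$exclusions$n[i]
      ))
    }
  }
  if (!is.null(run$cohort)) {
    cat(sprintf(
      "Nodes: %d (removed in harmonization: %d)\n",
      length(run$cohort$node_ids), length(run$removed_nodes)
    ))
  }
  if (!is.null(run$model)) {
    cat(sprintf(
      "Consensus masks: %d high / %d low edges (p < %g)\n",
      n_edges(run$model$consensus_high), n_edges(run$model$consensus_low),
      run$model$threshold
    ))
  }
  if (!is.null(run$scores)) {
    und <- sum(!complete.cases(run$scores[, -1]))
    if (und > 0) cat(sprintf("Strengths: %d participant(s) undefined\n", und))
  }
  if (!is.null(run$associations)) {
    cat("Associations (partial Spearman):\n")
    for (i in seq_len(nrow(run$associations))) {
      a <- run$associations[i, ]
      cat(sprintf(
        "  %s ~ %s | %s: rho = %s, p = %s, n = %d\n",
        a$predictor, a$outcome, a$covariates, fmt(a$rho), fmt(a$p, 4), a$n
      ))
    }
  }
  if (!is.null(run$lesions)) {
    cat("Computational lesions (high model):\n")
    for (i in seq_len(nrow(run$lesions))) {
      l <- run$lesions[i, ]
      cat(sprintf(
        "  %s: rho_whole = %s, rho_lesioned = %s, Steiger Z = %s, p = %s\n",
        l$network, fmt(l$rho_whole), fmt(l$rho_lesioned),
        fmt(l$steiger_z), fmt(l$steiger_p, 4)
      ))
    }
  }
  invisible(run)
}

# Rehydrate the tabular pieces of a run from its output directory (used by
# summarize_run() on a path). Model matrices are not reloaded.
read_run <- function(dir) {
  manifest_path <- file.path(dir, "run_manifest.json")
  if (!file.exists(manifest_path)) {
    abort(paste0("Not a run directory (missing run_manifest.json): ", dir))
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  read_if <- function(name) {
    f <- file.path(dir, name)
    if (file.exists(f)) readr::read_csv(f, show_col_types = FALSE) else NULL
  }
  excl <- read_if("exclusions.csv")
  qc <- if (!is.null(excl)) {
    list(
      n_in = manifest$n_in, n_out = manifest$n_retained,
      exclusions = excl
    )
  }
  list(
    qc = qc, cohort = NULL,
    removed_nodes = manifest$removed_nodes,
    model = NULL,
    scores = read_if("strengths.csv"),
    associations = read_if("associations.csv"),
    lesions = read_if("lesions.csv"),
    manifest = manifest, out_dir = dir
  )
}
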