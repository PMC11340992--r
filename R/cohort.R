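#' Cohorts of connectivity matrices
#'
#' A `conn_cohort` holds one symmetric Fisher-z connectivity matrix per
#' participant on a common ordered node list. The diagonal carries no
#' information and is stored as `NA`; a node that is missing for a
#' participant appears as an all-`NA` row/column (see [harmonize_nodes()]).
#'
#' @param matrices Named list of square numeric matrices (names are
#'   participant ids). All must share dimensions and node ordering.
#' @param node_ids Integer node ids; defaults to the matrices' dimnames, or
#'   `1:p` when absent.
#' @return An object of class `conn_cohort`: a list with elements
#'   `matrices` (named list) and `node_ids` (integer vector).
#' @export
conn_cohort <- function(matrices, node_ids = NULL) {
  if (length(matrices) == 0) abort("A cohort needs at least one participant.")
  if (is.null(names(matrices)) || anyDuplicated(names(matrices))) {
    abort("`matrices` must be a named list with unique participant ids.")
  }
  p <- nrow(matrices[[1]])
  node_ids <- as.integer(
    node_ids %||% rownames(matrices[[1]]) %||% seq_len(p)
  )
  if (length(node_ids) != p) abort("`node_ids` length must match matrix dimension.")
  nm <- as.character(node_ids)
  matrices <- lapply(matrices, function(m) {
    m <- as.matrix(m)
    if (nrow(m) != p || ncol(m) != p) {
      abort("All matrices must share the same dimension.")
    }
    if (!isTRUE(all.equal(m, t(m), check.attributes = FALSE))) {
      abort("Connectivity matrices must be symmetric.")
    }
    diag(m) <- NA_real_
    dimnames(m) <- list(nm, nm)
    m
  })
  structure(list(matrices = matrices, node_ids = node_ids),
    class = "conn_cohort"
  )
}

#' @export
print.conn_cohort <- function(x, ...) {
  cat(sprintf(
    "<conn_cohort> %d participants x %d nodes\n",
    length(x$matrices), length(x$node_ids)
  ))
  invisible(x)
}

#' Participant ids of a cohort
#' @param cohort A [conn_cohort()].
#' @return Character vector of participant ids.
#' @export
participants <- function(cohort) names(cohort$matrices)

#' Upper-triangle edge values for a whole cohort
#'
#' Flattens every participant matrix into one row of upper-triangle edge
#' values, in a fixed canonical edge order (column-major upper triangle,
#' i.e. edges sorted by `node_j` then `node_i`).
#'
#' @param cohort A [conn_cohort()].
#' @return A list with `values` (participants x edges numeric matrix, row
#'   names = participant ids) and `edges` (tibble `node_i`, `node_j` giving
#'   each column's unordered pair).
#' @export
cohort_edge_values <- function(cohort) {
  ids <- cohort$node_ids
  p <- length(ids)
  ut <- upper.tri(matrix(0, p, p))
  idx <- which(ut, arr.ind = TRUE)
  vals <- t(vapply(
    cohort$matrices, function(m) m[ut], numeric(sum(ut))
  ))
  rownames(vals) <- participants(cohort)
  list(
    values = vals,
    edges = tibble(node_i = ids[idx[, 1]], node_j = ids[idx[, 2]])
  )
}

#' Subset a cohort
#'
#' @param cohort A [conn_cohort()].
#' @param participant_ids Optional participant ids to keep (in this order).
#' @param node_ids Optional node ids to keep (original ordering preserved).
#' @return A [conn_cohort()].
#' @export
cohort_subset <- function(cohort, participant_ids = NULL, node_ids = NULL) {
  mats <- cohort$matrices
  if (!is.null(participant_ids)) {
    participant_ids <- as.character(participant_ids)
    missing <- setdiff(participant_ids, names(mats))
    if (length(missing) > 0) {
      abort(paste0("Unknown participants: ", paste(missing, collapse = ", ")))
    }
    mats <- mats[participant_ids]
  }
  keep_ids <- cohort$node_ids
  if (!is.null(node_ids)) {
    node_ids <- as.integer(node_ids)
    keep_ids <- cohort$node_ids[cohort$node_ids %in% node_ids]
    if (length(keep_ids) == 0) abort("No nodes left after subsetting.")
    sel <- match(keep_ids, cohort$node_ids)
    mats <- lapply(mats, function(m) m[sel, sel, drop = FALSE])
  }
  conn_cohort(mats, node_ids = keep_ids)
}

#' Write one connectivity matrix as TSV
#'
#' Square numeric table; first column `node_id`, remaining columns named by
#' node id. The diagonal is written as `NA`.
#'
#' @param m Square symmetric matrix with node-id dimnames.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_matrix_tsv <- function(m, path) {
  # values are written with 17 significant digits so the decimal round-trip
  # reproduces every double bit-exactly
  header <- paste(c("node_id", rownames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])), collapse = "\t")
  }, character(1))
  body <- gsub("(?<=\t)nan|^nan", "NA", body, perl = TRUE)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a connectivity matrix TSV written by [write_matrix_tsv()]
#'
#' @param path File path.
#' @return A symmetric numeric matrix with node-id dimnames and `NA` diagonal.
#' @export
read_matrix_tsv <- function(path) {
  # base read.delim: strtod parsing is correctly rounded, so the decimal
  # representation written by write_matrix_tsv() round-trips bit-exactly
  df <- utils::read.delim(path, check.names = FALSE)
  ids <- as.character(as.integer(df$node_id))
  m <- as.matrix(df[, -1])
  dimnames(m) <- list(ids, ids)
  m
}
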