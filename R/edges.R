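#' Edge masks
#'
#' An edge mask is the set of edges (unordered node pairs) belonging to one
#' CPM network, together with its polarity ("high": edges positively related
#' to the training behavior; "low": negatively related). Masks render as
#' symmetric binary matrices with 1s exactly at mask edges and can be written
#' to disk both as a binary matrix TSV and as an edge-list CSV.
#'
#' Edges are canonicalised so that `node_i < node_j` (by integer node id);
#' every unordered pair is stored and counted exactly once.
#'
#' @param edges A data frame with integer columns `node_i`, `node_j` (node
#'   ids, any order; canonicalised internally). Self-loops are an error.
#' @param node_ids Integer vector of node ids that defines the matrix
#'   rendering and the admissible node universe.
#' @param polarity `"high"` or `"low"`.
#' @return An object of class `edge_mask`: a tibble of canonical edges with
#'   attributes `node_ids` and `polarity`.
#' @examples
#' m <- edge_mask(data.frame(node_i = c(2, 1), node_j = c(1, 3)), 1:4, "high")
#' n_edges(m)
#' @export
edge_mask <- function(edges, node_ids, polarity = c("high", "low")) {
  polarity <- match.arg(polarity)
  node_ids <- as.integer(node_ids)
  stopifnot(!anyDuplicated(node_ids))
  edges <- as_tibble(edges)
  if (!all(c("node_i", "node_j") %in% names(edges))) {
    abort("`edges` must have columns `node_i` and `node_j`.")
  }
  i <- as.integer(edges$node_i)
  j <- as.integer(edges$node_j)
  if (any(i == j)) abort("Self-loops are not valid edges.")
  bad <- setdiff(c(i, j), node_ids)
  if (length(bad) > 0) {
    abort(paste0("Edge nodes not in `node_ids`: ", paste(bad, collapse = ", ")))
  }
  canon <- tibble(node_i = pmin(i, j), node_j = pmax(i, j))
  canon <- dplyr::distinct(dplyr::arrange(canon, .data$node_i, .data$node_j))
  structure(canon,
    node_ids = node_ids, polarity = polarity,
    class = c("edge_mask", class(canon))
  )
}

#' Number of edges in a mask
#' @param mask An [edge_mask()].
#' @return Integer count of unordered edges.
#' @export
n_edges <- function(mask) nrow(mask)

#' @export
print.edge_mask <- function(x, ...) {
  cat(sprintf(
    "<edge_mask> polarity=%s, %d edges over %d nodes\n",
    attr(x, "polarity"), nrow(x), length(attr(x, "node_ids"))
  ))
  print(as_tibble(x), ...)
  invisible(x)
}

#' Render an edge mask as a symmetric binary matrix
#'
#' @param mask An [edge_mask()].
#' @return A symmetric 0/1 integer matrix with node ids as dimnames and 1s
#'   exactly at mask edges (both triangles); diagonal 0.
#' @export
mask_matrix <- function(mask) {
  ids <- attr(mask, "node_ids")
  p <- length(ids)
  m <- matrix(0L, p, p, dimnames = list(as.character(ids), as.character(ids)))
  if (nrow(mask) > 0) {
    ri <- match(mask$node_i, ids)
    ci <- match(mask$node_j, ids)
    m[cbind(ri, ci)] <- 1L
    m[cbind(ci, ri)] <- 1L
  }
  m
}

#' Build an edge mask from a binary matrix
#'
#' @param m Square symmetric 0/1 matrix; dimnames (if present) are parsed as
#'   integer node ids, otherwise ids `1:nrow(m)` are used.
#' @param polarity `"high"` or `"low"`.
#' @return An [edge_mask()].
#' @export
mask_from_matrix <- function(m, polarity = c("high", "low")) {
  polarity <- match.arg(polarity)
  m <- as.matrix(m)
  stopifnot(nrow(m) == ncol(m))
  if (!isTRUE(all.equal(m, t(m), check.attributes = FALSE))) {
    abort("Mask matrix must be symmetric.")
  }
  ids <- if (!is.null(rownames(m))) as.integer(rownames(m)) else seq_len(nrow(m))
  idx <- which(upper.tri(m) & m != 0, arr.ind = TRUE)
  edge_mask(
    tibble(node_i = ids[idx[, 1]], node_j = ids[idx[, 2]]),
    node_ids = ids, polarity = polarity
  )
}

#' Restrict an edge mask to a set of surviving nodes
#'
#' Drops every edge incident to a node outside `keep_ids` (e.g. after node
#' harmonization or computational lesioning).
#'
#' @param mask An [edge_mask()].
#' @param keep_ids Integer node ids to keep.
#' @return An [edge_mask()] over `keep_ids`.
#' @export
mask_restrict <- function(mask, keep_ids) {
  keep_ids <- as.integer(keep_ids)
  kept <- dplyr::filter(
    as_tibble(mask),
    .data$node_i %in% keep_ids & .data$node_j %in% keep_ids
  )
  edge_mask(kept, node_ids = keep_ids, polarity = attr(mask, "polarity"))
}

#' Write an edge mask to disk (matrix TSV and edge-list CSV)
#'
#' Emits two equivalent renderings: `<prefix>_matrix.tsv` (binary square
#' matrix, node ids as first column/header) and `<prefix>_edges.csv`
#' (columns `node_i`, `node_j`, `polarity`).
#'
#' @param mask An [edge_mask()].
#' @param prefix Path prefix (directory must exist).
#' @return Invisibly, the two file paths.
#' @export
write_edge_mask <- function(mask, prefix) {
  mat_path <- paste0(prefix, "_matrix.tsv")
  edg_path <- paste0(prefix, "_edges.csv")
  m <- mask_matrix(mask)
  df <- tibble(node_id = as.integer(rownames(m)))
  df <- dplyr::bind_cols(df, as_tibble(m, .name_repair = "minimal"))
  readr::write_tsv(df, mat_path)
  readr::write_csv(
    dplyr::mutate(as_tibble(mask), polarity = attr(mask, "polarity")),
    edg_path
  )
  invisible(c(matrix = mat_path, edges = edg_path))
}

#' Read an edge mask from disk
#'
#' Accepts either rendering written by [write_edge_mask()]: a binary matrix
#' TSV (first column `node_id`) or an edge-list CSV (`node_i`, `node_j`,
#' `polarity`). The format is detected from the header.
#'
#' @param path File path.
#' @param node_ids Node universe for an edge-list file (defaults to the ids
#'   appearing in the list).
#' @return An [edge_mask()].
#' @export
read_edge_mask <- function(path, node_ids = NULL) {
  hdr <- names(readr::read_tsv(path, n_max = 0, show_col_types = FALSE))
  if (length(hdr) == 1) {
    hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  }
  if ("node_id" %in% hdr) {
    df <- readr::read_tsv(path, show_col_types = FALSE)
    ids <- as.integer(df$node_id)
    m <- as.matrix(df[, -1])
    dimnames(m) <- list(as.character(ids), as.character(ids))
    return(mask_from_matrix(m, polarity = "high"))
  }
  df <- readr::read_csv(path, show_col_types = FALSE)
  pol <- if ("polarity" %in% names(df)) as.character(df$polarity[1]) else "high"
  ids <- node_ids %||% sort(unique(c(df$node_i, df$node_j)))
  edge_mask(df[, c("node_i", "node_j")], node_ids = ids, polarity = pol)
}
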