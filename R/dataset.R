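#' Binary subtree dataset
#'
#' The central data container: a genes-by-points matrix of Boolean expression
#' states laid out along a cell-lineage tree.  Each column ("point") is one
#' interpolation of one cell; within a cell points are consecutive; the first
#' point of a daughter cell is linked to the last point of its parent so that
#' lagged states can be looked up across cell divisions.  Cells without a
#' parent among the candidate cells are roots; each root cell together with
#' its descendants forms one likelihood segment.
#'
#' @param states Integer matrix, genes x points, entries 0, 1 or `NA`
#'   (missing).  Row names, if present, are used as gene names.
#' @param points A data frame with one row per point and columns `point`
#'   (1-based index matching the columns of `states`), `cell` (cell name),
#'   `k` (1-based index of the point within its cell) and `pred` (the point
#'   index one time unit earlier along the lineage path: the previous point
#'   of the same cell, the last point of the parent cell for a cell's first
#'   point, or `NA` for the first point of a root cell).
#' @param roots Character vector of root cell names.
#' @param subtree Optional subtree label (e.g. `"D"`).
#' @param delta_t Time between successive interpolations, in normalised
#'   units.  Delays are expressed as multiples of this unit.
#' @return An object of class `subtree_dataset`.
#' @export
subtree_dataset <- function(states, points, roots, subtree = NA_character_,
                            delta_t = 1) {
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  points <- as_tibble(points)
  stopifnot(all(c("point", "cell", "k", "pred") %in% names(points)))
  points$point <- as.integer(points$point)
  points$k <- as.integer(points$k)
  points$pred <- as.integer(points$pred)
  points$cell <- as.character(points$cell)
  if (nrow(points) != ncol(states)) {
    abort("`points` must have one row per column of `states`.")
  }
  if (!identical(sort(points$point), seq_len(ncol(states)))) {
    abort("`points$point` must enumerate 1..ncol(states).")
  }
  points <- arrange(points, .data$point)
  bad <- states[!is.na(states) & !(states %in% c(0L, 1L))]
  if (length(bad) > 0) abort("`states` entries must be 0, 1 or NA.")
  if (is.null(rownames(states)) && nrow(states) > 0) {
    rownames(states) <- paste0("g", seq_len(nrow(states)))
  }
  # structural checks: consecutive k within cells, pred wiring
  by_cell <- split(points, points$cell)
  for (seg in by_cell) {
    if (!identical(seg$k, seq_len(nrow(seg)))) {
      abort(paste0("points of cell '", seg$cell[1],
                   "' are not consecutive (k must run 1..n)."))
    }
    if (!identical(seg$point, seg$point[1] + seq_len(nrow(seg)) - 1L)) {
      abort(paste0("points of cell '", seg$cell[1],
                   "' must occupy consecutive columns."))
    }
  }
  first <- points[points$k == 1L, ]
  miss <- is.na(first$pred)
  if (!setequal(first$cell[miss], roots)) {
    abort("cells whose first point has no predecessor must be exactly `roots`.")
  }
  structure(
    list(states = states, points = points, roots = as.character(roots),
         subtree = subtree, delta_t = delta_t),
    class = "subtree_dataset"
  )
}

#' @export
print.subtree_dataset <- function(x, ...) {
  n_missing <- sum(is.na(x$states))
  cat("<subtree_dataset>",
      sprintf("  subtree: %s", x$subtree),
      sprintf("  genes:   %d", nrow(x$states)),
      sprintf("  cells:   %d (%d root%s)", length(unique(x$points$cell)),
              length(x$roots), if (length(x$roots) == 1) "" else "s"),
      sprintf("  points:  %d (%d usable for likelihood)", ncol(x$states),
              length(usable_points(x))),
      sprintf("  missing: %d (%.2f%%)", n_missing,
              100 * n_missing / length(x$states)),
      sep = "\n")
  invisible(x)
}

#' @export
dim.subtree_dataset <- function(x) dim(x$states)

genes.subtree_dataset <- function(x) rownames(x$states)

#' Lineage-resolved lag lookup table
#'
#' For every point, the point index at lag `m = 0..max_lag` time units
#' earlier along the lineage path (through the parent cell at divisions).
#' `NA` where the history runs out before the root cell's first point.
#'
#' @param x A [subtree_dataset].
#' @param max_lag Largest lag needed; the model uses delays up to 5.
#' @return Integer matrix, points x (max_lag + 1); column `m + 1` holds lag
#'   `m` (column 1 is the point itself).
#' @export
lag_index <- function(x, max_lag = 5L) {
  stopifnot(inherits(x, "subtree_dataset"))
  pred <- x$points$pred[order(x$points$point)]
  Tn <- length(pred)
  out <- matrix(NA_integer_, Tn, max_lag + 1L)
  out[, 1L] <- seq_len(Tn)
  for (m in seq_len(max_lag)) {
    prev <- out[, m]
    ok <- !is.na(prev)
    out[ok, m + 1L] <- pred[prev[ok]]
  }
  out
}

#' Points with a fully resolved delay history
#'
#' The likelihood conditions on states up to 5 time units back, so it runs
#' over points whose full 5-lag history resolves along the lineage path; in
#' a root cell these are points 6 onward, and all points of descendant cells
#' (through the shared parent history) provided the path back is long enough.
#'
#' @param x A [subtree_dataset].
#' @param max_lag Required history depth (default 5).
#' @return Integer vector of point indices.
#' @export
usable_points <- function(x, max_lag = 5L) {
  li <- lag_index(x, max_lag)
  which(!is.na(li[, max_lag + 1L]))
}

#' Lay out lineage points for a set of cells
#'
#' Builds the `points` table of a [subtree_dataset] from a cell table:
#' cells are placed in breadth-first order, each contributing `inters`
#' consecutive points, and the first point of every non-root cell is wired
#' to the last point of its parent.
#'
#' @param cells A data frame with columns `cell` and `parent` (`NA` for
#'   roots); at most two daughters per parent.
#' @param inters Number of interpolation points per cell (scalar, or vector
#'   named by cell).
#' @return A tibble with columns `point`, `cell`, `k`, `pred`.
#' @export
lineage_points <- function(cells, inters) {
  cells <- as_tibble(cells)
  stopifnot(all(c("cell", "parent") %in% names(cells)))
  if (length(inters) == 1L) {
    inters <- setNames(rep(as.integer(inters), nrow(cells)), cells$cell)
  }
  stopifnot(all(cells$cell %in% names(inters)))
  # breadth-first order from the roots
  ord <- character(0)
  frontier <- cells$cell[is.na(cells$parent)]
  while (length(frontier) > 0) {
    ord <- c(ord, frontier)
    frontier <- cells$cell[!is.na(cells$parent) & cells$parent %in% frontier]
  }
  if (length(ord) != nrow(cells)) {
    abort("cell table is not a forest reachable from its roots.")
  }
  n_pts <- as.integer(inters[ord])
  offset <- cumsum(c(0L, head(n_pts, -1L)))
  names(offset) <- ord
  parent_of <- setNames(cells$parent, cells$cell)
  pts <- purrr::map2(ord, n_pts, function(cl, np) {
    k <- seq_len(np)
    point <- offset[[cl]] + k
    pred <- c(NA_integer_, point[-np])
    par <- parent_of[[cl]]
    if (!is.na(par)) pred[1L] <- offset[[par]] + as.integer(inters[[par]])
    tibble(point = point, cell = cl, k = k, pred = as.integer(pred))
  })
  bind_rows(pts)
}

#' Write / read a subtree dataset
#'
#' Lossless plain-text serialisation: a long-format TSV of states
#' (`<prefix>_states.tsv`), a TSV of the point layout
#' (`<prefix>_points.tsv`), and a JSON sidecar (`<prefix>.json`) holding the
#' gene order, root cells, subtree label, time unit and a schema version.
#'
#' @param x A [subtree_dataset].
#' @param prefix Path prefix for the three files.
#' @return `write_dataset` returns `prefix` invisibly; `read_dataset`
#'   returns the reconstructed [subtree_dataset].
#' @export
write_dataset <- function(x, prefix) {
  stopifnot(inherits(x, "subtree_dataset"))
  long <- if (nrow(x$states) > 0) {
    tidyr::pivot_longer(
      as_tibble(t(x$states)) |> mutate(point = dplyr::row_number()),
      -"point", names_to = "gene", values_to = "state"
    )
  } else {
    tibble(point = integer(), gene = character(), state = integer())
  }
  readr::write_tsv(long, paste0(prefix, "_states.tsv"), progress = FALSE)
  readr::write_tsv(x$points, paste0(prefix, "_points.tsv"), progress = FALSE)
  jsonlite::write_json(
    list(schema = dataset_schema_version, genes = rownames(x$states),
         roots = x$roots, subtree = x$subtree, delta_t = x$delta_t),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(prefix)
}

dataset_schema_version <- "treebn-dataset-1"

#' @rdname write_dataset
#' @export
read_dataset <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  if (!identical(meta$schema, dataset_schema_version)) {
    abort(paste0("dataset schema mismatch: found '", meta$schema,
                 "', expected '", dataset_schema_version, "'."))
  }
  long <- readr::read_tsv(paste0(prefix, "_states.tsv"),
                          col_types = readr::cols(
                            point = readr::col_integer(),
                            gene = readr::col_character(),
                            state = readr::col_integer()))
  pts <- readr::read_tsv(paste0(prefix, "_points.tsv"),
                         col_types = readr::cols(
                           point = readr::col_integer(),
                           cell = readr::col_character(),
                           k = readr::col_integer(),
                           pred = readr::col_integer()))
  genes <- as.character(meta$genes)
  states <- matrix(NA_integer_, length(genes), nrow(pts),
                   dimnames = list(genes, NULL))
  if (nrow(long) > 0) {
    states[cbind(match(long$gene, genes), long$point)] <- long$state
  }
  subtree <- if (is.null(meta$subtree)) NA_character_ else meta$subtree
  subtree_dataset(states, pts, roots = meta$roots, subtree = subtree,
                  delta_t = meta$delta_t)
}
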