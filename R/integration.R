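#' Normalise a cell's lifetime to the unit interval
#'
#' Because only one gene is labelled per embryo, the same cell lives for
#' different numbers of 1.5-min samples in different files; absolute time is
#' therefore not comparable across files.  Step 1 of the integration maps
#' each cell's sampling times affinely onto `[0, 1]`, after which every copy
#' of a cell shares a common clock.
#'
#' @param times Numeric vector of sampling times or indices (length >= 2).
#' @return Numeric vector on `[0, 1]` with first element 0 and last 1.
#' @export
#' @examples
#' normalize_lifetime(c(10, 11, 12, 13))
normalize_lifetime <- function(times) {
  stopifnot(is.numeric(times), length(times) >= 2L)
  (times - times[1L]) / (times[length(times)] - times[1L])
}

#' Expression rates: first-order differences of intensity
#'
#' Fluorescence accumulates and rarely decreases, so the raw intensity does
#' not reflect switching of expression; its first-order difference (the
#' expression rate) does.
#'
#' @param intensity Numeric vector (length >= 2).
#' @return Numeric vector of length `length(intensity) - 1`.
#' @export
expression_rates <- function(intensity) {
  stopifnot(is.numeric(intensity), length(intensity) >= 2L)
  diff(intensity)
}

#' Resample a cell's rate series to a common length
#'
#' Fits the Forsythe--Malcolm--Moler cubic spline (`stats::spline`,
#' `method = "fmm"`) through the series placed at equispaced abscissae on
#' `[0, 1]` and evaluates it at `n_target` equispaced abscissae, so that
#' every cell ends up with the same number of points.  A one-point series
#' cannot be splined and is replicated with a message.
#'
#' @param values Numeric rate series of a single cell.
#' @param n_target Number of output points (>= 2).
#' @return Numeric vector of length `n_target`.
#' @export
interpolate_cell <- function(values, n_target) {
  stopifnot(n_target >= 2L)
  if (length(values) == 1L) {
    inform("one-point series: value replicated across interpolations.")
    return(rep(values, n_target))
  }
  stopifnot(length(values) >= 2L)
  xout <- seq(0, 1, length.out = n_target)
  spline(x = seq(0, 1, length.out = length(values)), y = values,
         xout = xout, method = "fmm")$y
}

#' Common number of interpolation points for a subtree
#'
#' The median of the per-cell point counts; with an even number of cells the
#' lower median is taken so the result is always one of the observed counts
#' (an integer).
#'
#' @param point_counts Integer vector, points per cell.
#' @return A single integer.
#' @export
choose_n_target <- function(point_counts) {
  stopifnot(length(point_counts) >= 1L, all(point_counts >= 1))
  s <- sort(as.integer(point_counts))
  s[ceiling(length(s) / 2)]
}

#' Binarise expression rates against the subtree median
#'
#' State 1 means a high expression rate: strictly greater than the
#' threshold, which defaults to the median of all rates supplied (in the
#' pipeline, pooled over every gene, copy and cell of the subtree).  Values
#' equal to the threshold are "low" (state 0), so a constant series maps to
#' all zeros.  `NA` rates stay `NA`.
#'
#' @param rates Numeric vector.
#' @param threshold Binarisation threshold; defaults to `median(rates)`.
#' @return Integer vector of 0/1 (with `NA` preserved).
#' @export
binarize <- function(rates, threshold = stats::median(rates, na.rm = TRUE)) {
  as.integer(rates > threshold)
}

#' Merge gene copies by strict majority
#'
#' At each time point the merged state is 1 when more than half of the
#' available (non-missing) copies are 1, otherwise 0; a point at which every
#' copy is missing stays missing.  With two disagreeing copies the merged
#' state is 0 (one of two is not more than half).
#'
#' @param copies Integer matrix, copies x points, entries 0/1/`NA`; a
#'   single vector is treated as one copy.
#' @return Integer vector of merged states, length `ncol(copies)`.
#' @export
merge_copies <- function(copies) {
  if (is.null(dim(copies))) copies <- matrix(copies, nrow = 1L)
  n_avail <- colSums(!is.na(copies))
  n_one <- colSums(copies == 1L, na.rm = TRUE)
  out <- ifelse(n_avail == 0L, NA_integer_,
                as.integer(n_one > n_avail / 2))
  as.integer(out)
}

#' Impute residual missing states as low expression
#'
#' After candidate filtering, the few remaining missing values (below a
#' small per-gene cap) are treated as low expression rate, i.e. state 0.  A
#' gene whose missing fraction exceeds the cap is excluded from the dataset
#' with a warning rather than imputed.
#'
#' @param x A [subtree_dataset].
#' @param max_missing Per-gene missing-fraction cap (default 0.05).
#' @return A [subtree_dataset] with no missing states; excluded gene names
#'   are recorded in attribute `"excluded_genes"`.
#' @export
fill_missing <- function(x, max_missing = 0.05) {
  stopifnot(inherits(x, "subtree_dataset"))
  frac <- rowMeans(is.na(x$states))
  drop <- frac > max_missing
  if (any(drop)) {
    warn(sprintf("gene(s) %s exceed the %.0f%% missing cap; excluded.",
                 paste(rownames(x$states)[drop], collapse = ", "),
                 100 * max_missing))
  }
  states <- x$states[!drop, , drop = FALSE]
  states[is.na(states)] <- 0L
  out <- subtree_dataset(states, x$points, x$roots, x$subtree, x$delta_t)
  attr(out, "excluded_genes") <- rownames(x$states)[drop]
  out
}

#' Integrate per-embryo files into a pairwise binary subtree dataset
#'
#' The full four-step integration: (1) each cell's lifetime is normalised to
#' a standard unit; (2) expression rates (first-order intensity differences)
#' are computed and FMM-spline interpolated so every cell carries the same
#' number of points (the lower median of per-cell point counts unless
#' overridden); (3) rates are binarised at the pooled subtree median; (4)
#' copies of the same gene are merged by strict majority, with points
#' missing in all copies left missing.  Cells and genes whose missing
#' fraction exceeds the configurable caps are dropped, and remaining missing
#' values are imputed as state 0.  The result is pairwise: every copy of
#' every gene is observed on the same lineage-indexed grid.
#'
#' @param files A list of record tibbles from [read_embryo_file()], or a
#'   single tibble with a `gene` column (multiple files of one gene are its
#'   copies).
#' @param subtree Founder label: `"AB"`, `"C"`, `"D"`, `"E"` or `"MS"`.
#' @param n_target Override for the per-cell interpolation count.
#' @param max_missing_gene,max_missing_cell Missing-fraction caps above
#'   which a gene / a cell is excluded.
#' @param cells Optional character vector restricting the candidate cells
#'   (e.g. gene-expression-onset cells from external annotation).
#' @param aliases Founder alias table, see [founder_aliases()].
#' @return A [subtree_dataset]; attribute `"integration_log"` holds a
#'   one-row tibble of per-step summary counts.
#' @export
integrate_subtree <- function(files, subtree, n_target = NULL,
                              max_missing_gene = 0.05,
                              max_missing_cell = 0.5,
                              cells = NULL, aliases = founder_aliases()) {
  if (is.data.frame(files)) files <- list(files)
  recs <- bind_rows(lapply(seq_along(files), function(i) {
    mutate(as_tibble(files[[i]]), .copy = i)
  }))
  stopifnot(all(c("gene", "cell", "time", "intensity") %in% names(recs)))
  keep <- is_descendant(recs$cell, subtree)
  if (!is.null(cells)) keep <- keep & recs$cell %in% cells
  recs <- recs[keep, , drop = FALSE]
  if (nrow(recs) == 0) abort("no records left after subtree/cell filtering.")

  # Step 2 sizing: one common interpolation count across the subtree
  counts <- recs |> group_by(.data$.copy, .data$gene, .data$cell) |>
    summarise(n = n(), .groups = "drop")
  if (is.null(n_target)) n_target <- choose_n_target(counts$n)
  n_target <- as.integer(n_target)

  # Steps 1-2 per (copy, cell): normalise lifetime, difference, interpolate
  per_cell <- recs |> arrange(.data$.copy, .data$gene, .data$cell, .data$time) |>
    group_by(.data$.copy, .data$gene, .data$cell) |>
    summarise(rates = list(interp_rates(.data$intensity, n_target)),
              .groups = "drop")

  # Step 3: binarise at the pooled subtree median
  pooled <- unlist(per_cell$rates)
  thr <- stats::median(pooled, na.rm = TRUE)
  per_cell$state <- lapply(per_cell$rates, binarize, threshold = thr)

  genes <- sort(unique(per_cell$gene))
  all_cells <- sort(unique(per_cell$cell))

  # Step 4: merge copies gene-wise on the common (cell x n_target) grid
  merged <- lapply(genes, function(g) {
    sub <- per_cell[per_cell$gene == g, , drop = FALSE]
    copy_ids <- unique(sub$.copy)
    vapply(all_cells, function(cl) {
      rows <- sub[sub$cell == cl, , drop = FALSE]
      m <- matrix(NA_integer_, length(copy_ids), n_target)
      if (nrow(rows) > 0) {
        m[match(rows$.copy, copy_ids), ] <-
          do.call(rbind, rows$state)
      }
      merge_copies(m)
    }, integer(n_target))
  })

  # per-cell missing fraction over genes, then candidate-cell exclusion
  miss_cell <- vapply(seq_along(all_cells), function(ci) {
    mean(vapply(merged, function(m) mean(is.na(m[, ci])), numeric(1)))
  }, numeric(1))
  cell_drop <- all_cells[miss_cell > max_missing_cell]
  kept_cells <- setdiff(all_cells, cell_drop)
  if (length(cell_drop) > 0) {
    warn(sprintf("cell(s) %s exceed the %.0f%% missing cap; excluded.",
                 paste(cell_drop, collapse = ", "), 100 * max_missing_cell))
  }
  if (length(kept_cells) == 0) abort("all cells excluded by the missing cap.")

  tree <- build_tree(tibble(cell = kept_cells), subtree = subtree,
                     aliases = aliases)
  pts <- lineage_points(tree$cells[, c("cell", "parent")], n_target)
  states <- matrix(NA_integer_, length(genes), nrow(pts),
                   dimnames = list(genes, NULL))
  ci_of <- match(pts$cell, all_cells)
  for (gi in seq_along(genes)) {
    states[gi, ] <- merged[[gi]][cbind(pts$k, ci_of)]
  }
  ds <- subtree_dataset(states, pts,
                        roots = tree$cells$cell[is.na(tree$cells$parent)],
                        subtree = subtree)
  n_miss <- sum(is.na(ds$states))
  ds <- fill_missing(ds, max_missing = max_missing_gene)
  attr(ds, "integration_log") <- tibble(
    n_files = length(files), n_genes_in = length(genes),
    n_genes = nrow(ds$states), n_cells = length(kept_cells),
    cells_dropped = length(cell_drop), n_target = n_target,
    threshold = thr, n_filled = n_miss
  )
  ds
}

# Steps 1-2 for one cell: lifetime-normalised rate series interpolated to
# n_target points.  Cells with a single measurement carry no rate
# information and are returned as missing.
interp_rates <- function(intensity, n_target) {
  if (length(intensity) < 2L) return(rep(NA_real_, n_target))
  interpolate_cell(expression_rates(intensity), n_target)
}
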