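#' Signed regulatory network with per-edge time delay
#'
#' A gene regulatory network over `N` genes is a pair of `N x N` matrices:
#' the signed adjacency `A` with `A[i, j] = 1` for activation of target gene
#' `i` by regulator gene `j`, `-1` for repression and `0` for no regulation
#' (self-regulation is excluded, so the diagonal is zero), and the delay
#' matrix `delta` with entries in `0:5` giving, in interpolation time units,
#' how far back the regulator's state acts.  Where `A[i, j] == 0` the delay
#' entry is retained (the spike-and-slab prior keeps the parameter dimension
#' fixed) but carries no meaning.
#'
#' @param A Integer matrix with entries in `-1:1`, zero diagonal.  Row
#'   names, if present, name the genes.
#' @param delta Integer matrix of the same dimension with entries in `0:5`.
#' @return An object of class `grn`.
#' @export
grn <- function(A, delta = NULL) {
  A <- as.matrix(A)
  storage.mode(A) <- "integer"
  n <- nrow(A)
  stopifnot(ncol(A) == n)
  if (is.null(delta)) delta <- matrix(0L, n, n)
  delta <- as.matrix(delta)
  storage.mode(delta) <- "integer"
  stopifnot(identical(dim(delta), dim(A)))
  if (any(!(A %in% c(-1L, 0L, 1L)))) abort("`A` entries must be -1, 0 or 1.")
  if (n > 0 && any(diag(A) != 0L)) abort("`A` must have a zero diagonal.")
  if (any(!(delta %in% 0:5))) abort("`delta` entries must be in 0..5.")
  if (is.null(rownames(A))) rownames(A) <- paste0("g", seq_len(n))
  colnames(A) <- rownames(A)
  dimnames(delta) <- dimnames(A)
  structure(list(A = A, delta = delta), class = "grn")
}

#' @export
print.grn <- function(x, ...) {
  e <- sum(x$A != 0)
  cat(sprintf("<grn> %d genes, %d edge%s (%d activating, %d repressing)\n",
              nrow(x$A), e, if (e == 1) "" else "s",
              sum(x$A == 1), sum(x$A == -1)))
  invisible(x)
}

#' Edge-list view of a network
#'
#' @param x A [grn].
#' @return A tibble with columns `regulator`, `target`, `sign`
#'   (`1`/`-1`) and `delay_units`, one row per nonzero edge, ordered by
#'   target then regulator.
#' @export
as_edges <- function(x) {
  stopifnot(inherits(x, "grn"))
  idx <- which(x$A != 0, arr.ind = TRUE)
  out <- tibble(
    regulator = colnames(x$A)[idx[, "col"]],
    target = rownames(x$A)[idx[, "row"]],
    sign = as.integer(x$A[idx]),
    delay_units = as.integer(x$delta[idx])
  )
  arrange(out, .data$target, .data$regulator)
}

#' Export / import a network
#'
#' Writes the edge list as TSV (`regulator`, `target`, `sign`,
#' `delay_units`; header always present, so an empty network yields a
#' header-only file) and, optionally, GraphML with `sign` and `delay_units`
#' edge attributes for use in graph tools.  `import_network` reverses the
#' TSV export; isolated genes are preserved through the `genes` argument.
#'
#' @param x A [grn].
#' @param path Output TSV path.
#' @param graphml Optional GraphML output path.
#' @return `export_network` returns `path` invisibly; `import_network`
#'   returns a [grn].
#' @export
export_network <- function(x, path, graphml = NULL) {
  edges <- as_edges(x)
  readr::write_tsv(edges, path, progress = FALSE)
  if (!is.null(graphml)) {
    g <- igraph::graph_from_data_frame(
      edges, directed = TRUE,
      vertices = tibble(name = rownames(x$A))
    )
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(path)
}

#' @rdname export_network
#' @param genes Gene names (fixes the matrix dimension and order); by
#'   default the genes appearing in the file.
#' @export
import_network <- function(path, genes = NULL) {
  edges <- readr::read_tsv(path, col_types = readr::cols(
    regulator = readr::col_character(),
    target = readr::col_character(),
    sign = readr::col_integer(),
    delay_units = readr::col_integer()
  ))
  if (is.null(genes)) {
    genes <- sort(unique(c(edges$regulator, edges$target)))
  }
  n <- length(genes)
  A <- matrix(0L, n, n, dimnames = list(genes, genes))
  delta <- matrix(0L, n, n, dimnames = list(genes, genes))
  if (nrow(edges) > 0) {
    ij <- cbind(match(edges$target, genes), match(edges$regulator, genes))
    if (any(is.na(ij))) abort("edge list names not all present in `genes`.")
    A[ij] <- edges$sign
    delta[ij] <- edges$delay_units
  }
  grn(A, delta)
}
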