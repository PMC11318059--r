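#' Founder-cell alias table
#'
#' Parent links in the early C. elegans embryo that are not expressible as
#' name prefixes under Sulston nomenclature: the zygote P0 divides into AB
#' and P1, P1 into EMS and P2, EMS into MS and E, P2 into C and P3, P3 into
#' D and P4, and P4 into the germline precursors Z2 and Z3.  Within any one
#' founder subtree (AB, C, D, E, MS) plain prefix matching suffices; this
#' table is consulted above the founders and to recognise non-descendant
#' names such as "EMS" when selecting a subtree.
#'
#' @return A tibble with columns `cell` and `parent`.
#' @export
founder_aliases <- function() {
  tibble(
    cell   = c("AB", "P1", "EMS", "P2", "MS", "E", "C", "P3", "D", "P4",
               "Z2", "Z3"),
    parent = c("P0", "P0", "P1", "P1", "EMS", "EMS", "P2", "P2", "P3", "P3",
               "P4", "P4")
  )
}

# Division suffix letters of Sulston nomenclature (anterior/posterior,
# dorsal/ventral, left/right).
sulston_suffix_re <- "^[apdvlr]+$"

#' Is a cell name a lineage descendant of a founder?
#'
#' TRUE when the name equals the founder or extends it by Sulston division
#' letters only, so "Ea" and "Earp" descend from "E" while "EMS" does not.
#'
#' @param cell Character vector of cell names.
#' @param founder Single founder name ("AB", "C", "D", "E" or "MS").
#' @return Logical vector.
#' @export
is_descendant <- function(cell, founder) {
  rest <- ifelse(startsWith(cell, founder),
                 substring(cell, nchar(founder) + 1L), NA_character_)
  !is.na(rest) & (rest == "" | grepl(sulston_suffix_re, rest))
}

#' Read one EPIC-style embryo file
#'
#' Each raw file reports the quantified fluorescence of a single labelled
#' gene in one embryo: one row per (cell, time index) at a 1.5-minute
#' sampling interval.  The on-disk schema varies between dialects, so the
#' delimiter is auto-detected (comma or tab) and column names are
#' configurable.
#'
#' @param path Path to a delimited text file.
#' @param gene Gene name; by default parsed from the file name
#'   (`CD<date>_<gene>_<copy>.csv` gives `<gene>`).
#' @param cols Named character vector mapping the required fields `cell`,
#'   `time` and `intensity` to column names in the file.  For `intensity`,
#'   the first of the configured name, `"blot"`, `"intensity"` or `"value"`
#'   found in the file is used.
#' @param delim Field delimiter; `NULL` (default) auto-detects `,` vs tab.
#' @return A tibble with columns `gene`, `cell`, `time` (1-based integer
#'   index of the 1.5-min sampling grid) and `intensity`, in file order
#'   within each cell.
#' @export
read_embryo_file <- function(path, gene = NULL,
                             cols = c(cell = "cell", time = "time",
                                      intensity = "blot"),
                             delim = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (is.null(delim)) {
    first <- readLines(path, n = 1L)
    delim <- if (lengths(regmatches(first, gregexpr("\t", first))) >
                 lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, progress = FALSE,
                           show_col_types = FALSE)
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed row at line %d of '%s': %s",
                  probs$row[1] + 1L, path, probs$expected[1]))
  }
  int_col <- intersect(unique(c(cols[["intensity"]], "blot", "intensity",
                                "value")), names(raw))
  if (length(int_col) == 0) {
    abort(paste0("no intensity column found in '", path, "'."))
  }
  needed <- c(cols[["cell"]], cols[["time"]])
  if (!all(needed %in% names(raw))) {
    abort(sprintf("missing column(s) %s in '%s'.",
                  paste(setdiff(needed, names(raw)), collapse = ", "), path))
  }
  if (is.null(gene)) {
    base <- sub("\\.[^.]*$", "", basename(path))
    parts <- strsplit(base, "_")[[1]]
    gene <- if (length(parts) >= 2) parts[2] else base
  }
  out <- tibble(
    gene = gene,
    cell = as.character(raw[[cols[["cell"]]]]),
    time = as.integer(raw[[cols[["time"]]]]),
    intensity = as.numeric(raw[[int_col[1]]])
  )
  dup <- duplicated(out[, c("cell", "time")])
  if (any(dup)) {
    d <- out[which(dup)[1], ]
    abort(sprintf("duplicate (cell, time) record in '%s': (%s, %d).",
                  path, d$cell, d$time))
  }
  if (any(is.na(out$time)) || any(out$time < 1)) {
    abort(paste0("time indices must be positive integers in '", path, "'."))
  }
  out
}

#' Assemble a lineage tree from per-cell records
#'
#' Links every cell to its parent by the longest proper prefix present in
#' the data (the resolution rule implied by Sulston nomenclature, in which a
#' daughter's name extends her mother's by one division letter), with
#' founder-level links taken from an explicit alias table.  Cells outside
#' the labelled founder's subtree are dropped.  A cell with no resolvable
#' parent that is not the founder itself is kept as an extra root with a
#' warning, since gaps in candidate-cell coverage legitimately split a
#' subtree into several root segments.
#'
#' @param records A tibble as returned by [read_embryo_file()] (columns
#'   `cell` plus any others, which are carried along), or any data frame
#'   with a `cell` column.
#' @param subtree One of `"AB"`, `"C"`, `"D"`, `"E"`, `"MS"`, or `NULL` to
#'   keep all cells.
#' @param aliases Alias table as from [founder_aliases()].
#' @return An object of class `lineage_tree`: a list with `cells` (tibble:
#'   `cell`, `parent`, `n_points`), `data` (the retained records) and
#'   `subtree`.
#' @export
build_tree <- function(records, subtree = NULL, aliases = founder_aliases()) {
  records <- as_tibble(records)
  stopifnot("cell" %in% names(records))
  if (!is.null(subtree)) {
    keep <- is_descendant(records$cell, subtree)
    records <- records[keep, , drop = FALSE]
    if (nrow(records) == 0) {
      abort(paste0("no cells of subtree '", subtree, "' in the records."))
    }
  }
  cells <- unique(records$cell)
  alias_parent <- setNames(aliases$parent, aliases$cell)
  parent <- vapply(cells, function(cl) {
    resolve_parent(cl, cells, alias_parent)
  }, character(1))
  parent[parent == ""] <- NA_character_
  orphan <- is.na(parent) & !(cells %in% c(subtree, aliases$cell))
  if (!is.null(subtree) && any(orphan)) {
    warn(sprintf("cell(s) %s have no resolvable parent; treated as roots.",
                 paste(cells[orphan], collapse = ", ")))
  }
  counts <- records |> group_by(.data$cell) |> summarise(n_points = n())
  cells_tbl <- tibble(cell = cells, parent = unname(parent)) |>
    left_join(counts, by = "cell")
  structure(list(cells = cells_tbl, data = records, subtree = subtree),
            class = "lineage_tree")
}

# Longest proper prefix of `cell` present in `cells`; falls back to the
# alias table (transitively, so E -> EMS -> P1 resolves even when EMS is
# absent).  Returns "" when nothing resolves.
resolve_parent <- function(cell, cells, alias_parent) {
  for (len in rev(seq_len(nchar(cell) - 1L))) {
    cand <- substr(cell, 1L, len)
    if (cand %in% cells && cand != cell) return(cand)
  }
  anc <- cell
  while (anc %in% names(alias_parent)) {
    anc <- alias_parent[[anc]]
    if (anc %in% cells) return(anc)
  }
  ""
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat("<lineage_tree>",
      sprintf("  subtree: %s", x$subtree %||% "(all)"),
      sprintf("  cells:   %d (%d root%s)", nrow(x$cells),
              sum(is.na(x$cells$parent)),
              if (sum(is.na(x$cells$parent)) == 1) "" else "s"),
      sprintf("  records: %d", nrow(x$data)),
      sep = "\n")
  invisible(x)
}
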