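#' Identifier tables
#'
#' The sparse table the resolver fills in: one row per metabolite of
#' interest, one column (cell set) per database. Cells hold zero or more
#' canonical identifiers; multi-valued cells arise when resolution discovers
#' several candidates (ambiguity) or retired aliases.
#'
#' @param rows a list; each element is a named list of character vectors,
#'   names being database tags (missing tags mean empty cells). Identifiers
#'   are canonicalized with [normalize_id()].
#' @param labels optional character vector of row labels (e.g. metabolite
#'   names), recycled NA if absent.
#' @return An object of class `identifier_table`.
#' @export
#' @examples
#' identifier_table(list(list(HMDB = "HMDB00122"), list(KEGG = "C00031")))
identifier_table <- function(rows, labels = NULL) {
  if (!length(rows)) stop("an identifier table needs at least one row", call. = FALSE)
  if (is.null(labels)) labels <- rep(NA_character_, length(rows))
  stopifnot(length(labels) == length(rows))
  out <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    cells <- empty_cells()
    r <- rows[[i]]
    for (tag in names(r)) {
      t <- as_db_tag(tag)
      ids <- r[[tag]]
      ids <- ids[!is.na(ids) & nzchar(trimws(ids))]
      if (length(ids)) cells[[t]] <- sort(unique(normalize_id(t, ids)))
    }
    out[[i]] <- list(row_key = i, label = labels[i], cells = cells)
  }
  structure(list(rows = out), class = "identifier_table")
}

empty_cells <- function() {
  stats::setNames(rep(list(character()), length(db_tags())), db_tags())
}

#' @rdname identifier_table
#' @param x an `identifier_table`.
#' @return `n_rows()` returns the number of rows.
#' @export
n_rows <- function(x) length(x$rows)

#' @rdname identifier_table
#' @param i row index.
#' @return `row_cells()` returns the named list of cell sets for row `i`.
#' @export
row_cells <- function(x, i) x$rows[[i]]$cells

#' @export
print.identifier_table <- function(x, ...) {
  cat(sprintf("<identifier_table> %d row(s)\n", n_rows(x)))
  print(utils::head(as.data.frame(x), 10))
  if (n_rows(x) > 10) cat("...\n")
  invisible(x)
}

#' Flatten an identifier table to a data frame
#'
#' Multi-valued cells are joined with `sep`; empty cells become `""`. Column
#' order follows [db_tags()].
#'
#' @param x an [identifier_table()].
#' @param row.names,optional ignored (base generic signature).
#' @param sep separator for multi-valued cells; must not occur inside any
#'   canonical identifier (the default `"|"` cannot).
#' @param ... unused.
#' @return A data frame with columns `row_key`, `label`, then one per tag.
#' @export
as.data.frame.identifier_table <- function(x, row.names = NULL, optional = FALSE,
                                           sep = "|", ...) {
  df <- data.frame(
    row_key = vapply(x$rows, `[[`, 0L, "row_key"),
    label = vapply(x$rows, function(r) as.character(r$label), ""),
    stringsAsFactors = FALSE
  )
  for (tag in db_tags()) {
    df[[tag]] <- vapply(x$rows, function(r) paste(r$cells[[tag]], collapse = sep), "")
  }
  df
}
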