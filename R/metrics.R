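## Mapping-performance measures over identifier tables.
##
## For identifier type d and a table produced by tool X:
##   mapping rate(d)      = #rows with a non-empty d cell / #rows
##   average mapping rate = mean of mapping rate over the k types considered
##   pct unmapped(d)      = #rows with an empty d cell / #rows  (= 1 - rate)
##   matching pct(d; X,Y) = #rows where X's and Y's d cells agree /
##                          #rows with a non-empty d cell in Y
## The matching denominator is the comparator's non-empty count — asymmetric
## by design, exactly as the measure is defined. Two multi-valued cells
## agree when both are non-empty and intersect.

as_table <- function(x) {
  if (inherits(x, "resolution_result")) x$table
  else if (inherits(x, "identifier_table")) x
  else stop("expected an identifier_table or resolution_result", call. = FALSE)
}

#' Mapping rate for one identifier type
#'
#' @param table an [identifier_table()] or [resolve_table()] result.
#' @param db database tag.
#' @return Fraction in `[0, 1]` of rows whose `db` cell is non-empty.
#' @export
mapping_rate <- function(table, db) {
  table <- as_table(table)
  db <- as_db_tag(db)
  if (!n_rows(table)) stop("mapping rate undefined for a table with zero rows", call. = FALSE)
  mean(vapply(table$rows, function(r) length(r$cells[[db]]) > 0L, NA))
}

#' Average mapping rate over identifier types
#'
#' Unweighted mean of [mapping_rate()] over the given tags; invariant under
#' permutation of `dbs`.
#'
#' @inheritParams mapping_rate
#' @param dbs non-empty subset of [db_tags()].
#' @return Fraction in `[0, 1]`.
#' @export
average_mapping_rate <- function(table, dbs = db_tags()) {
  if (!length(dbs)) stop("need at least one identifier type", call. = FALSE)
  dbs <- as_db_tag(dbs)
  mean(vapply(dbs, function(d) mapping_rate(table, d), 0))
}

#' Percentage of unmapped fields for one identifier type
#'
#' Complements [mapping_rate()]: the two sum to one exactly.
#'
#' @inheritParams mapping_rate
#' @return Fraction in `[0, 1]` of rows whose `db` cell is empty.
#' @export
percentage_unmapped <- function(table, db) {
  table <- as_table(table)
  db <- as_db_tag(db)
  if (!n_rows(table)) stop("percentage unmapped undefined for a table with zero rows", call. = FALSE)
  mean(vapply(table$rows, function(r) length(r$cells[[db]]) == 0L, NA))
}

#' Full mapping-metrics report
#'
#' @inheritParams average_mapping_rate
#' @param tool_label free-text label for the tool that produced the table.
#' @return An object of class `metrics_report`: per-db counts and rates,
#'   plus the average mapping rate over `dbs`.
#' @export
mapping_metrics <- function(table, dbs = db_tags(), tool_label = "metamapr") {
  table <- as_table(table)
  dbs <- as_db_tag(dbs)
  n <- n_rows(table)
  per_db <- lapply(stats::setNames(nm = dbs), function(d) {
    ne <- sum(vapply(table$rows, function(r) length(r$cells[[d]]) > 0L, NA))
    list(mapping_rate = ne / n, pct_unmapped = (n - ne) / n,
         n_nonempty = ne, n_empty = n - ne)
  })
  structure(list(tool_label = tool_label, per_db = per_db,
                 average_mapping_rate = mean(vapply(per_db, `[[`, 0, "mapping_rate")),
                 included_dbs = dbs, k = length(dbs), total_records = n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s over %d record(s)\n", x$tool_label, x$total_records))
  for (d in x$included_dbs)
    cat(sprintf("  %-9s mapping rate %.3f  unmapped %.3f  (%d/%d non-empty)\n",
                d, x$per_db[[d]]$mapping_rate, x$per_db[[d]]$pct_unmapped,
                x$per_db[[d]]$n_nonempty, x$total_records))
  cat(sprintf("  average mapping rate (k=%d): %.3f\n", x$k, x$average_mapping_rate))
  invisible(x)
}

#' Matching percentage between two tools' tables
#'
#' `table_ref` and `table_other` must index the same rows in the same order.
#' A row counts as matching for `db` when both cells are non-empty and share
#' at least one identifier. The denominator is the number of rows with a
#' non-empty `db` cell in `table_other` (the comparator tool).
#'
#' @param table_ref,table_other identifier tables (or resolution results).
#' @param db database tag.
#' @return A list: `matching_percentage` (NaN when the comparator has no
#'   non-empty cells), `n_matching`, `n_nonempty_reference`.
#' @export
matching_percentage <- function(table_ref, table_other, db) {
  table_ref <- as_table(table_ref); table_other <- as_table(table_other)
  db <- as_db_tag(db)
  if (n_rows(table_ref) != n_rows(table_other) ||
      !identical(vapply(table_ref$rows, `[[`, 0L, "row_key"),
                 vapply(table_other$rows, `[[`, 0L, "row_key")))
    stop("tables must index the same rows in the same order", call. = FALSE)
  n_match <- 0L; n_other <- 0L
  for (i in seq_len(n_rows(table_ref))) {
    a <- table_ref$rows[[i]]$cells[[db]]
    b <- table_other$rows[[i]]$cells[[db]]
    if (length(b)) {
      n_other <- n_other + 1L
      if (length(a) && length(intersect(a, b))) n_match <- n_match + 1L
    }
  }
  list(matching_percentage = n_match / n_other, n_matching = n_match,
       n_nonempty_reference = n_other)
}

#' @rdname matching_percentage
#' @param dbs tags to report on.
#' @return `match_report()` returns a `match_report` object with one
#'   [matching_percentage()] entry per tag.
#' @export
match_report <- function(table_ref, table_other, dbs = db_tags()) {
  dbs <- as_db_tag(dbs)
  per_db <- lapply(stats::setNames(nm = dbs), function(d)
    matching_percentage(table_ref, table_other, d))
  structure(list(per_db = per_db), class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat("<match_report>\n")
  for (d in names(x$per_db)) {
    e <- x$per_db[[d]]
    cat(sprintf("  %-9s matching %.3f (%d/%d)\n", d,
                e$matching_percentage, e$n_matching, e$n_nonempty_reference))
  }
  invisible(x)
}
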