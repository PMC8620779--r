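## Queue-based identifier resolution.
##
## Main flow: seed a FIFO queue with a row's known identifiers (database-tag
## order, then lexicographic id order), pop one, look it up as a primary
## accession, falling back to the secondary-accession index, absorb the
## matched record (its primary id, retired aliases and cross-references all
## enter the row's cells) and enqueue every newly seen identifier. A visited
## set guarantees each (db, id) pair is queried at most once per row.
##
## Exceptional flow: once the queue drains, reverse queries search every
## database for records whose cross-references point back at identifiers the
## row has already collected; hits are absorbed and the main flow re-runs.
## Iterated to fixpoint, resolution equals connected-component membership in
## the undirected graph linking each record to its cross-references and to
## its secondary accessions. Reverse queries deliberately target all five
## databases, not just the still-empty ones: a second same-db record that is
## reachable only backwards is exactly what marks an ambiguous mapping, and
## restricting reverse queries to empty cells would hide it.

#' Resolve a single table row
#'
#' @param cells named list of cell sets (as from [row_cells()]); identifiers
#'   must be canonical.
#' @param store a [local_store()].
#' @param remote optional remote-client bundle from [remote_backend()];
#'   `NULL` resolves offline (local store only).
#' @param reverse run the exceptional reverse-query flow (default `TRUE`).
#'   Disabling it restricts resolution to forward reachability; exposed
#'   because the difference between the two is itself informative about
#'   cross-reference asymmetry in the data.
#' @param max_passes safety cap on exceptional-flow iterations; fixpoint is
#'   normally reached in at most two.
#' @return A resolution fragment: list with `cells` (filled), `matched`
#'   (per-db primary ids of distinct matched records), `ambiguous_dbs`,
#'   `unresolved`, `secondary_hits`, `transport_errors`, `provenance`,
#'   `input_cells`, `iterations`, `passes`, `empty_input`, `capped`.
#' @export
resolve_row <- function(cells, store, remote = NULL, reverse = TRUE,
                        max_passes = 10L) {
  input_cells <- cells
  if (sum(lengths(cells)) == 0L) {
    return(list(cells = cells, matched = empty_cells(), ambiguous_dbs = character(),
                unresolved = id_pairs(), secondary_hits = id_pairs(),
                transport_errors = id_pairs(), provenance = prov_frame(),
                input_cells = input_cells, iterations = 0L, passes = 0L,
                empty_input = TRUE, capped = FALSE))
  }

  q_db <- character(); q_id <- character(); q_head <- 1L
  visited <- new.env(parent = emptyenv())
  reverse_done <- new.env(parent = emptyenv())
  matched <- empty_cells()
  unresolved <- list(); secondary_hits <- list(); transport_errors <- list()
  prov <- list()
  iterations <- 0L; passes <- 0L; capped <- FALSE
  n_added <- 0L  # counts cell additions; used to detect fixpoint

  enqueue <- function(db, id) {
    key <- store_key(db, id)
    if (!exists(key, envir = visited, inherits = FALSE)) {
      q_db[length(q_db) + 1L] <<- db
      q_id[length(q_id) + 1L] <<- id
    }
  }

  add_id <- function(db, id, from_db, from_id, via, pass) {
    if (!id %in% cells[[db]]) {
      cells[[db]] <<- sort(c(cells[[db]], id))
      n_added <<- n_added + 1L
      prov[[length(prov) + 1L]] <<- data.frame(
        db = db, id = id, via = via, from_db = from_db, from_id = from_id,
        pass = pass, stringsAsFactors = FALSE)
    }
    enqueue(db, id)
  }

  absorb <- function(rec, from_db, from_id, via, pass) {
    db2 <- rec$source_db
    if (!rec$primary_id %in% matched[[db2]])
      matched[[db2]] <<- sort(c(matched[[db2]], rec$primary_id))
    add_id(db2, rec$primary_id, from_db, from_id, via, pass)
    for (sid in rec$secondary_ids)
      add_id(db2, sid, db2, rec$primary_id, "secondary_alias", pass)
    for (tag in names(rec$xrefs))
      for (xid in rec$xrefs[[tag]])
        add_id(tag, xid, db2, rec$primary_id, "xref", pass)
  }

  # seed: tag order, then lexicographic ids; inputs get provenance too
  for (tag in db_tags()) {
    for (id in sort(cells[[tag]])) {
      prov[[length(prov) + 1L]] <- data.frame(
        db = tag, id = id, via = "input", from_db = NA_character_,
        from_id = NA_character_, pass = "main", stringsAsFactors = FALSE)
      enqueue(tag, id)
    }
  }

  main_flow <- function(pass) {
    while (q_head <= length(q_db)) {
      db <- q_db[q_head]; id <- q_id[q_head]; q_head <<- q_head + 1L
      key <- store_key(db, id)
      if (exists(key, envir = visited, inherits = FALSE)) next
      assign(key, TRUE, envir = visited)
      iterations <<- iterations + 1L
      recs <- list()
      rec <- lookup_primary(store, db, id)
      via <- "primary"
      if (!is.null(rec)) {
        recs <- list(rec)
      } else {
        sec <- lookup_secondary(store, db, id)
        if (length(sec)) {
          recs <- sec
          via <- "secondary"
          secondary_hits[[length(secondary_hits) + 1L]] <<-
            data.frame(db = db, id = id, stringsAsFactors = FALSE)
        } else if (!is.null(remote) && db %in% c("KEGG", "PUBCHEM")) {
          out <- if (db == "KEGG")
            fetch_kegg(store, id, remote$transport, remote$config)
          else
            fetch_pubchem(store, id, remote$transport, remote$config)
          if (out$status %in% c("hit_cache", "fetched")) {
            recs <- list(out$record)
            via <- "remote"
          } else if (out$status == "transport_error") {
            transport_errors[[length(transport_errors) + 1L]] <<-
              data.frame(db = db, id = id, stringsAsFactors = FALSE)
            next
          }
        }
      }
      if (!length(recs)) {
        unresolved[[length(unresolved) + 1L]] <<-
          data.frame(db = db, id = id, stringsAsFactors = FALSE)
        next
      }
      for (r in recs) absorb(r, db, id, via, pass)
    }
  }

  exceptional_flow <- function() {
    for (tag in db_tags()) {
      for (id in cells[[tag]]) {  # ids added during this pass are picked up next pass
        key <- store_key(tag, id)
        if (exists(key, envir = reverse_done, inherits = FALSE)) next
        assign(key, TRUE, envir = reverse_done)
        for (target in setdiff(db_tags(), tag)) {
          for (r in lookup_by_xref(store, target, tag, id))
            absorb(r, tag, id, "reverse", "exceptional")
        }
      }
    }
  }

  main_flow("main")
  if (reverse) {
    repeat {
      if (passes >= max_passes) { capped <- TRUE; break }
      passes <- passes + 1L
      before <- n_added
      exceptional_flow()
      main_flow("exceptional")
      if (n_added == before && q_head > length(q_db)) break
    }
  }

  bindrows <- function(lst) if (length(lst)) {
    df <- do.call(rbind, lst); rownames(df) <- NULL; df
  } else id_pairs()
  ambiguous_dbs <- db_tags()[vapply(db_tags(), function(t) length(matched[[t]]) > 1L, NA)]
  provenance <- if (length(prov)) {
    df <- do.call(rbind, prov); rownames(df) <- NULL; df
  } else prov_frame()
  list(cells = cells, matched = matched, ambiguous_dbs = ambiguous_dbs,
       unresolved = bindrows(unresolved), secondary_hits = bindrows(secondary_hits),
       transport_errors = bindrows(transport_errors), provenance = provenance,
       input_cells = input_cells, iterations = iterations, passes = passes,
       empty_input = FALSE, capped = capped)
}

id_pairs <- function() data.frame(db = character(), id = character(),
                                  stringsAsFactors = FALSE)
prov_frame <- function() data.frame(db = character(), id = character(),
                                    via = character(), from_db = character(),
                                    from_id = character(), pass = character(),
                                    stringsAsFactors = FALSE)

#' Resolve every row of an identifier table
#'
#' Rows are resolved independently and deterministically: the same input
#' table against the same store yields an identical result. With a remote
#' backend attached, records fetched for one row persist in the store, so
#' later rows (and later runs) hit the cache instead of the network.
#'
#' Input identifiers are never removed or overwritten — cells only grow.
#'
#' @param table an [identifier_table()].
#' @param store a [local_store()].
#' @inheritParams resolve_row
#' @return An object of class `resolution_result`: the filled `table`,
#'   per-row `row_info` (status, ambiguity flag, queue iterations),
#'   `ambiguous_cells`, `unresolved_ids`, `secondary_hits`,
#'   `transport_errors` and `provenance` data frames (all carrying
#'   `row_key`), and `matched` — per row, the distinct matched primary
#'   records per database.
#' @export
#' @examples
#' st <- local_store()
#' upsert_record(st, compound_record("HMDB", "HMDB0000122",
#'                                   xrefs = list(KEGG = "C00031")))
#' upsert_record(st, compound_record("KEGG", "C00031",
#'                                   xrefs = list(CHEBI = "17234")))
#' res <- resolve_table(identifier_table(list(list(HMDB = "HMDB0000122"))), st)
#' as.data.frame(res$table)
resolve_table <- function(table, store, remote = NULL, reverse = TRUE,
                          max_passes = 10L) {
  stopifnot(inherits(table, "identifier_table"))
  if (!n_rows(table)) stop("empty identifier table", call. = FALSE)
  frags <- vector("list", n_rows(table))
  filled <- table
  for (i in seq_len(n_rows(table))) {
    fr <- resolve_row(row_cells(table, i), store, remote = remote,
                      reverse = reverse, max_passes = max_passes)
    filled$rows[[i]]$cells <- fr$cells
    frags[[i]] <- fr
  }
  keyed <- function(field) {
    parts <- lapply(seq_along(frags), function(i) {
      df <- frags[[i]][[field]]
      if (!nrow(df)) return(NULL)
      cbind(data.frame(row_key = table$rows[[i]]$row_key), df)
    })
    parts <- parts[!vapply(parts, is.null, NA)]
    if (!length(parts)) {
      proto <- frags[[1]][[field]]
      return(cbind(data.frame(row_key = integer()), proto))
    }
    df <- do.call(rbind, parts); rownames(df) <- NULL; df
  }
  amb <- do.call(rbind, lapply(seq_along(frags), function(i) {
    dbs <- frags[[i]]$ambiguous_dbs
    if (!length(dbs)) return(NULL)
    data.frame(row_key = table$rows[[i]]$row_key, db = dbs,
               n_candidates = vapply(dbs, function(t) length(frags[[i]]$matched[[t]]), 0L),
               stringsAsFactors = FALSE)
  }))
  if (is.null(amb)) amb <- data.frame(row_key = integer(), db = character(),
                                      n_candidates = integer(), stringsAsFactors = FALSE)
  rownames(amb) <- NULL
  status <- vapply(frags, function(fr) {
    if (fr$empty_input) "empty_input"
    else if (all(lengths(fr$cells) > 0L)) "complete"
    else "partial"
  }, "")
  row_info <- data.frame(
    row_key = vapply(table$rows, `[[`, 0L, "row_key"),
    label = vapply(table$rows, function(r) as.character(r$label), ""),
    status = status,
    ambiguous = vapply(frags, function(fr) length(fr$ambiguous_dbs) > 0L, NA),
    iterations = vapply(frags, `[[`, 0L, "iterations"),
    passes = vapply(frags, `[[`, 0L, "passes"),
    stringsAsFactors = FALSE
  )
  structure(list(
    table = filled,
    row_info = row_info,
    ambiguous_cells = amb,
    unresolved_ids = keyed("unresolved"),
    secondary_hits = keyed("secondary_hits"),
    transport_errors = keyed("transport_errors"),
    provenance = keyed("provenance"),
    matched = lapply(frags, `[[`, "matched"),
    input_table = table
  ), class = "resolution_result")
}

#' @export
print.resolution_result <- function(x, ...) {
  ri <- x$row_info
  cat(sprintf("<resolution_result> %d row(s): %d complete, %d partial, %d unresolved-input\n",
              nrow(ri), sum(ri$status == "complete"), sum(ri$status == "partial"),
              sum(ri$status == "empty_input")))
  cat(sprintf("  ambiguous rows: %d | unresolved ids: %d | secondary-id hits: %d\n",
              sum(ri$ambiguous), nrow(x$unresolved_ids), nrow(x$secondary_hits)))
  invisible(x)
}

#' @export
summary.resolution_result <- function(object, ...) {
  tab <- object$table
  rates <- vapply(db_tags(), function(t) mapping_rate(tab, t), 0)
  out <- list(n = n_rows(tab), mapping_rate = rates,
              average_mapping_rate = mean(rates),
              n_ambiguous_rows = sum(object$row_info$ambiguous),
              n_unresolved_ids = nrow(object$unresolved_ids))
  class(out) <- "summary.resolution_result"
  out
}

#' @export
print.summary.resolution_result <- function(x, ...) {
  cat(sprintf("Resolution of %d row(s)\n", x$n))
  for (t in names(x$mapping_rate))
    cat(sprintf("  mapping rate %-9s %.3f\n", t, x$mapping_rate[[t]]))
  cat(sprintf("  average mapping rate %.3f\n", x$average_mapping_rate))
  cat(sprintf("  ambiguous rows %d, unresolved ids %d\n",
              x$n_ambiguous_rows, x$n_unresolved_ids))
  invisible(x)
}
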