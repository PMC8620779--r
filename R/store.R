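## The local store is the package's cache of compound records. It plays the
## role a relational cache database would in a server deployment, but is
## embedded: environment-backed hash maps in memory, serialized as a
## directory of TSV files. The interface is backend-agnostic; only the
## functions in this file touch the representation.

STORE_SCHEMA_VERSION <- 1L

store_key <- function(db, id) paste0(db, "::", id)

#' Create an empty local store
#'
#' The store indexes [compound_record()]s by `(source_db, primary_id)` and
#' maintains two derived indexes: a secondary-accession index (retired id to
#' current primary id) and a reverse cross-reference index (foreign id to the
#' records that carry it). Both are exactly derivable from the records; see
#' [rebuild_indexes()].
#'
#' Stores have reference semantics (environment-backed): `upsert_record()`
#' mutates in place and returns the store invisibly.
#'
#' @return An object of class `local_store`.
#' @export
local_store <- function() {
  s <- new.env(parent = emptyenv())
  s$records <- new.env(parent = emptyenv())    # key db::primary -> compound_record
  s$sec <- new.env(parent = emptyenv())        # key db::secondary -> character of primary ids
  s$rx <- new.env(parent = emptyenv())         # key xref_db::xref_id -> character of db::primary
  s$provenance <- new.env(parent = emptyenv()) # key db::primary -> flag
  s$negcache <- new.env(parent = emptyenv())   # session-only remote not_found memo
  s$conflicts <- list()
  s$schema_version <- STORE_SCHEMA_VERSION
  class(s) <- "local_store"
  s
}

#' @export
print.local_store <- function(x, ...) {
  n <- store_size(x)
  cat(sprintf("<local_store> %d record(s)\n", n))
  per <- table(factor(vapply(ls(x$records), function(k) sub("::.*$", "", k),
                             character(1)), levels = db_tags()))
  for (tag in db_tags()) cat(sprintf("  %-9s %d\n", tag, per[[tag]]))
  if (length(x$conflicts)) cat(sprintf("  %d structure conflict(s) logged\n", length(x$conflicts)))
  invisible(x)
}

#' @rdname local_store
#' @param store a `local_store`.
#' @return `store_size()` returns the number of records held.
#' @export
store_size <- function(store) length(ls(store$records))

#' @rdname local_store
#' @param db database tag.
#' @return `store_ids()` returns the sorted primary identifiers held for `db`.
#' @export
store_ids <- function(store, db) {
  db <- as_db_tag(db)
  keys <- ls(store$records)
  pre <- paste0(db, "::")
  sort(substring(keys[startsWith(keys, pre)], nchar(pre) + 1L))
}

index_add <- function(env, key, value) {
  cur <- if (exists(key, envir = env, inherits = FALSE)) get(key, envir = env) else character()
  if (!value %in% cur) assign(key, sort(c(cur, value)), envir = env)
}

#' Insert or merge a compound record
#'
#' Inserting a record whose `(source_db, primary_id)` already exists merges:
#' secondary ids, names and cross-references are unioned; structure strings
#' are kept first-seen — a conflicting later value is dropped and a conflict
#' event is appended to `store$conflicts` (never an error). Indexes are
#' updated incrementally; merges only ever add entries, so incremental
#' updates and a full rebuild agree.
#'
#' @param store a [local_store()].
#' @param rec a [compound_record()].
#' @param provenance origin flag, one of `"dump"`, `"remote_cache"`, `"fixture"`.
#' @return The store, invisibly (mutated in place).
#' @export
upsert_record <- function(store, rec, provenance = "fixture") {
  stopifnot(inherits(store, "local_store"), inherits(rec, "compound_record"))
  provenance <- match.arg(provenance, c("dump", "remote_cache", "fixture"))
  key <- store_key(rec$source_db, rec$primary_id)
  if (exists(key, envir = store$records, inherits = FALSE)) {
    old <- get(key, envir = store$records)
    merged <- old
    merged$secondary_ids <- sort(union(old$secondary_ids, rec$secondary_ids))
    merged$names <- unique(c(old$names, rec$names))
    for (fld in c("smiles", "inchi", "inchikey")) {
      o <- old[[fld]]; n <- rec[[fld]]
      if (is.na(o) || !nzchar(o)) {
        merged[[fld]] <- n
      } else if (!is.na(n) && nzchar(n) && !identical(o, n)) {
        store$conflicts <- c(store$conflicts, sprintf(
          "%s %s: conflicting %s kept first-seen value", key, fld, fld))
      }
    }
    for (tag in names(rec$xrefs)) {
      merged$xrefs[[tag]] <- sort(union(merged$xrefs[[tag]], rec$xrefs[[tag]]))
    }
    merged$xrefs <- merged$xrefs[intersect(db_tags(), names(merged$xrefs))]
    rec <- merged
  } else {
    assign(key, provenance, envir = store$provenance)
  }
  assign(key, rec, envir = store$records)
  for (sid in rec$secondary_ids)
    index_add(store$sec, store_key(rec$source_db, sid), rec$primary_id)
  for (tag in names(rec$xrefs))
    for (xid in rec$xrefs[[tag]])
      index_add(store$rx, store_key(tag, xid), key)
  invisible(store)
}

#' Look up a record by primary identifier
#'
#' Consults only the primary index: an identifier that exists solely as a
#' secondary accession is not found here (use [lookup_secondary()]).
#'
#' @param store a [local_store()].
#' @param db database tag.
#' @param id canonical identifier.
#' @return The [compound_record()] or `NULL` (absence is a value, not an error).
#' @export
lookup_primary <- function(store, db, id) {
  key <- store_key(as_db_tag(db), id)
  if (exists(key, envir = store$records, inherits = FALSE))
    get(key, envir = store$records)
  else NULL
}

#' Look up records by secondary (retired/alternate) identifier
#'
#' Several databases retire accessions but keep them resolvable; this lookup
#' maps such an identifier to the current record(s). If two records claim the
#' same secondary accession, both are returned and the result carries
#' `attr(, "ambiguous") == TRUE`.
#'
#' @inheritParams lookup_primary
#' @return A list of [compound_record()]s (possibly empty).
#' @export
lookup_secondary <- function(store, db, id) {
  key <- store_key(as_db_tag(db), id)
  prim <- if (exists(key, envir = store$sec, inherits = FALSE))
    get(key, envir = store$sec) else character()
  out <- lapply(prim, function(p) lookup_primary(store, db, p))
  attr(out, "ambiguous") <- length(out) > 1L
  out
}

#' Reverse cross-reference lookup
#'
#' Finds every record of `target_db` whose cross-references to `xref_db`
#' contain `xref_id`. This is the reverse query the resolver's exceptional
#' flow issues when forward cross-references cannot fill a field.
#'
#' @param store a [local_store()].
#' @param target_db database whose records are searched.
#' @param xref_db database the foreign identifier belongs to (`!= target_db`).
#' @param xref_id canonical foreign identifier.
#' @return A list of matching [compound_record()]s, sorted by primary id.
#' @export
lookup_by_xref <- function(store, target_db, xref_db, xref_id) {
  target_db <- as_db_tag(target_db)
  xref_db <- as_db_tag(xref_db)
  stopifnot(target_db != xref_db)
  key <- store_key(xref_db, xref_id)
  carriers <- if (exists(key, envir = store$rx, inherits = FALSE))
    get(key, envir = store$rx) else character()
  pre <- paste0(target_db, "::")
  hits <- sort(carriers[startsWith(carriers, pre)])
  lapply(hits, function(k) get(k, envir = store$records))
}

#' Rebuild derived indexes from scratch
#'
#' Recomputes the secondary and reverse-xref indexes by scanning every
#' record. Used to assert index coherence: after any sequence of upserts the
#' rebuilt indexes must equal the incrementally maintained ones.
#'
#' @param store a [local_store()].
#' @return A list with elements `sec` and `rx`: plain named lists mapping
#'   index keys to sorted character vectors.
#' @export
rebuild_indexes <- function(store) {
  sec <- list(); rx <- list()
  for (key in ls(store$records)) {
    rec <- get(key, envir = store$records)
    for (sid in rec$secondary_ids) {
      k <- store_key(rec$source_db, sid)
      sec[[k]] <- sort(union(sec[[k]], rec$primary_id))
    }
    for (tag in names(rec$xrefs)) for (xid in rec$xrefs[[tag]]) {
      k <- store_key(tag, xid)
      rx[[k]] <- sort(union(rx[[k]], key))
    }
  }
  list(sec = sec[order(names(sec))], rx = rx[order(names(rx))])
}

#' @rdname rebuild_indexes
#' @return `live_indexes()` returns the incrementally maintained indexes in
#'   the same plain-list form, for comparison.
#' @export
live_indexes <- function(store) {
  as_list <- function(env) {
    keys <- sort(ls(env))
    stats::setNames(lapply(keys, function(k) get(k, envir = env)), keys)
  }
  list(sec = as_list(store$sec), rx = as_list(store$rx))
}

## ---- canonical tabular view & serialization ----

na_blank <- function(x) ifelse(is.na(x), "", x)

#' Canonical tabular view of a store
#'
#' Flattens the store into sorted data frames (records, names, secondary
#' accessions, cross-references). Two stores with equal content yield
#' identical tables regardless of insertion order, so this view backs both
#' [store_equal()] and the on-disk serialization.
#'
#' @param store a [local_store()].
#' @param dbs optional subset of tags to restrict to.
#' @param provenance include the per-record origin flag column.
#' @return A named list of data frames.
#' @export
store_tables <- function(store, dbs = NULL, provenance = TRUE) {
  keys <- sort(ls(store$records))
  if (!is.null(dbs)) {
    dbs <- as_db_tag(dbs)
    keys <- keys[sub("::.*$", "", keys) %in% dbs]
  }
  recs <- lapply(keys, function(k) get(k, envir = store$records))
  rec_df <- data.frame(
    source_db = vapply(recs, `[[`, "", "source_db"),
    primary_id = vapply(recs, `[[`, "", "primary_id"),
    smiles = na_blank(vapply(recs, `[[`, "", "smiles")),
    inchi = na_blank(vapply(recs, `[[`, "", "inchi")),
    inchikey = na_blank(vapply(recs, `[[`, "", "inchikey")),
    stringsAsFactors = FALSE
  )
  if (provenance) {
    rec_df$provenance <- vapply(keys, function(k)
      if (exists(k, envir = store$provenance, inherits = FALSE))
        get(k, envir = store$provenance) else "", "", USE.NAMES = FALSE)
  }
  bind <- function(lst, cols) {
    lst <- lst[lengths(lst) > 0]
    if (!length(lst)) {
      df <- as.data.frame(stats::setNames(rep(list(character()), length(cols)), cols),
                          stringsAsFactors = FALSE)
      return(df)
    }
    df <- do.call(rbind, lst)
    rownames(df) <- NULL
    df[do.call(order, df), , drop = FALSE]
  }
  name_df <- bind(lapply(recs, function(r) {
    if (!length(r$names)) return(NULL)
    data.frame(source_db = r$source_db, primary_id = r$primary_id,
               name = r$names, stringsAsFactors = FALSE)
  }), c("source_db", "primary_id", "name"))
  sec_df <- bind(lapply(recs, function(r) {
    if (!length(r$secondary_ids)) return(NULL)
    data.frame(source_db = r$source_db, primary_id = r$primary_id,
               secondary_id = r$secondary_ids, stringsAsFactors = FALSE)
  }), c("source_db", "primary_id", "secondary_id"))
  xref_df <- bind(lapply(recs, function(r) {
    if (!length(r$xrefs)) return(NULL)
    do.call(rbind, lapply(names(r$xrefs), function(tag)
      data.frame(source_db = r$source_db, primary_id = r$primary_id,
                 xref_db = tag, xref_id = r$xrefs[[tag]], stringsAsFactors = FALSE)))
  }), c("source_db", "primary_id", "xref_db", "xref_id"))
  rownames(rec_df) <- NULL
  list(records = rec_df, names = name_df, secondary = sec_df, xrefs = xref_df)
}

#' Compare two stores for content equality
#'
#' @param a,b stores.
#' @param dbs optional subset of tags to compare.
#' @param provenance compare the origin flags too (default `FALSE`: a record
#'   loaded from a dump equals the same record inserted directly).
#' @return `TRUE` or `FALSE`.
#' @export
store_equal <- function(a, b, dbs = NULL, provenance = FALSE) {
  identical(store_tables(a, dbs, provenance), store_tables(b, dbs, provenance))
}

#' Serialize a store to a directory of TSV files
#'
#' Writes the canonical tabular view ([store_tables()]) plus a `meta.tsv`
#' carrying `schema_version`. The layout is deterministic: equal stores
#' produce byte-identical directories.
#'
#' @param store a [local_store()].
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_store <- function(store, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- store_tables(store, provenance = TRUE)
  write_tsv <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "", eol = "\n", fileEncoding = "UTF-8")
  }
  write_tsv(data.frame(key = "schema_version", value = store$schema_version,
                       stringsAsFactors = FALSE), "meta.tsv")
  write_tsv(tabs$records, "records.tsv")
  write_tsv(tabs$names, "names.tsv")
  write_tsv(tabs$secondary, "secondary.tsv")
  write_tsv(tabs$xrefs, "xrefs.tsv")
  invisible(dir)
}

#' @rdname write_store
#' @return `read_store()` returns the deserialized [local_store()].
#' @export
read_store <- function(dir) {
  read_tsv <- function(name) {
    utils::read.delim(file.path(dir, name), sep = "\t", colClasses = "character",
                      quote = "", na.strings = NULL, stringsAsFactors = FALSE)
  }
  meta <- read_tsv("meta.tsv")
  ver <- as.integer(meta$value[meta$key == "schema_version"])
  if (!identical(ver, STORE_SCHEMA_VERSION))
    stop(sprintf("store schema version %s not supported (expected %d)", ver, STORE_SCHEMA_VERSION))
  recs <- read_tsv("records.tsv")
  nms <- read_tsv("names.tsv")
  secs <- read_tsv("secondary.tsv")
  xrs <- read_tsv("xrefs.tsv")
  store <- local_store()
  for (i in seq_len(nrow(recs))) {
    db <- recs$source_db[i]; pid <- recs$primary_id[i]
    pick <- function(df, col) df[[col]][df$source_db == db & df$primary_id == pid]
    xr_rows <- xrs[xrs$source_db == db & xrs$primary_id == pid, , drop = FALSE]
    xr <- split(xr_rows$xref_id, xr_rows$xref_db)
    blank_na <- function(x) if (!nzchar(x)) NA_character_ else x
    rec <- compound_record(db, pid,
                           secondary_ids = pick(secs, "secondary_id"),
                           names = pick(nms, "name"),
                           smiles = blank_na(recs$smiles[i]),
                           inchi = blank_na(recs$inchi[i]),
                           inchikey = blank_na(recs$inchikey[i]),
                           xrefs = xr)
    prov <- recs$provenance[i]
    upsert_record(store, rec, provenance = if (nzchar(prov)) prov else "fixture")
  }
  store
}
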