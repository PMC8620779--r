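#' Database tags
#'
#' The five small-compound databases the package maps between, in their
#' fixed canonical order. The order is load-bearing: it fixes output column
#' order, queue seeding order and therefore run-to-run determinism.
#'
#' @return Character vector `c("HMDB", "CHEBI", "KEGG", "PUBCHEM", "LIPIDMAPS")`.
#' @export
#' @examples
#' db_tags()
db_tags <- function() {
  c("HMDB", "CHEBI", "KEGG", "PUBCHEM", "LIPIDMAPS")
}

#' @rdname db_tags
#' @param tag character vector to validate.
#' @return `as_db_tag()` returns the matched tag(s) or errors.
#' @export
as_db_tag <- function(tag) {
  up <- toupper(trimws(as.character(tag)))
  up[up %in% c("LIPID MAPS", "LM", "LIPID_MAPS")] <- "LIPIDMAPS"
  up[up == "CHEBI"] <- "CHEBI"
  bad <- setdiff(unique(up), db_tags())
  if (length(bad)) {
    stop(sprintf("unknown database tag(s): %s (expected one of %s)",
                 paste(bad, collapse = ", "), paste(db_tags(), collapse = ", ")),
         call. = FALSE)
  }
  up
}

bad_id_condition <- function(db, raw, reason) {
  structure(
    class = c("metamapr_bad_id", "error", "condition"),
    list(message = sprintf("malformed %s identifier %s: %s",
                           db, deparse(as.character(raw)), reason),
         call = NULL, db = db, raw = raw, reason = reason)
  )
}

normalize_one <- function(db, raw) {
  x <- toupper(trimws(raw))
  if (!nzchar(x)) stop(bad_id_condition(db, raw, "empty identifier"))
  switch(db,
    HMDB = {
      m <- regmatches(x, regexec("^HMDB([0-9]{5}|[0-9]{7})$", x))[[1]]
      if (length(m) == 0) stop(bad_id_condition(db, raw, "expected HMDB + 5 or 7 digits"))
      sprintf("HMDB%07d", as.integer(m[2]))
    },
    CHEBI = {
      body <- sub("^CHEBI:", "", x)
      if (!grepl("^[0-9]+$", body)) stop(bad_id_condition(db, raw, "expected CHEBI:<integer> or a bare integer"))
      paste0("CHEBI:", as.character(as.integer(body)))
    },
    KEGG = {
      body <- sub("^CPD:", "", x)
      if (!grepl("^C[0-9]{5}$", body)) stop(bad_id_condition(db, raw, "expected C + 5 digits"))
      body
    },
    PUBCHEM = {
      body <- sub("^CID:?", "", x)
      if (!grepl("^[0-9]+$", body)) stop(bad_id_condition(db, raw, "expected a decimal CID"))
      body <- sub("^0+(?=[0-9])", "", body, perl = TRUE)
      body
    },
    LIPIDMAPS = {
      if (!grepl("^LM[A-Z]{2}[A-Z0-9]+$", x)) stop(bad_id_condition(db, raw, "expected an LM-prefixed accession"))
      x
    },
    stop(bad_id_condition(db, raw, "unknown database tag"))
  )
}

#' Canonicalize a database identifier
#'
#' Every identifier crossing a package boundary (input tables, dump loaders,
#' remote responses) is normalized once, here. Canonical forms: HMDB accessions
#' are `HMDB` + 7 digits (legacy 5-digit accessions are zero-padded); ChEBI is
#' `CHEBI:` + integer without leading zeros (bare integers accepted); KEGG is
#' `C` + 5 digits (an optional `cpd:` prefix is stripped); PubChem is the
#' decimal CID without leading zeros; LIPID MAPS accessions are upper-cased
#' and otherwise kept verbatim.
#'
#' Normalization is idempotent: applying it to an already-canonical identifier
#' returns it unchanged.
#'
#' @param db a database tag (see [db_tags()]).
#' @param raw character vector of raw identifiers.
#' @return Character vector of canonical identifiers.
#'   A malformed identifier raises a condition of class `metamapr_bad_id`
#'   carrying the offending `db` and `raw` value.
#' @export
#' @examples
#' normalize_id("HMDB", "HMDB00001")   # "HMDB0000001"
#' normalize_id("CHEBI", "15377")      # "CHEBI:15377"
normalize_id <- function(db, raw) {
  db <- as_db_tag(db)
  stopifnot(length(db) == 1L)
  vapply(raw, function(r) normalize_one(db, r), character(1), USE.NAMES = FALSE)
}

#' @rdname normalize_id
#' @return `normalize_id_quietly()` returns a list with `ids` (canonical, NA
#'   where malformed) and `problems` (data frame of `raw`, `reason`).
#' @export
normalize_id_quietly <- function(db, raw) {
  db <- as_db_tag(db)
  ids <- character(length(raw))
  probs <- list()
  for (i in seq_along(raw)) {
    ids[i] <- tryCatch(normalize_one(db, raw[i]), metamapr_bad_id = function(e) {
      probs[[length(probs) + 1L]] <<- data.frame(raw = as.character(raw[i]),
                                                 reason = e$reason,
                                                 stringsAsFactors = FALSE)
      NA_character_
    })
  }
  problems <- if (length(probs)) do.call(rbind, probs) else
    data.frame(raw = character(), reason = character(), stringsAsFactors = FALSE)
  list(ids = ids, problems = problems)
}
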