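#' Construct a compound record
#'
#' One database's entry for a compound: a canonical primary accession,
#' optional retired/alternate accessions in the same database, names,
#' structure strings (payload only — they never participate in matching), and
#' cross-references to the putatively same compound in the other databases.
#'
#' All identifiers, including every cross-reference, are canonicalized with
#' [normalize_id()] at construction.
#'
#' @param source_db database tag of the home database.
#' @param primary_id the current canonical accession.
#' @param secondary_ids character vector of retired/alternate accessions in
#'   `source_db` (never contains `primary_id`).
#' @param names character vector of compound names.
#' @param smiles,inchi,inchikey optional structure strings.
#' @param xrefs named list, names being database tags other than `source_db`,
#'   values character vectors of foreign identifiers.
#' @return An object of class `compound_record`.
#' @export
#' @examples
#' compound_record("HMDB", "HMDB0000122", names = "D-glucose",
#'                 xrefs = list(KEGG = "C00031", CHEBI = "17234"))
compound_record <- function(source_db, primary_id,
                            secondary_ids = character(),
                            names = character(),
                            smiles = NA_character_,
                            inchi = NA_character_,
                            inchikey = NA_character_,
                            xrefs = list()) {
  source_db <- as_db_tag(source_db)
  primary_id <- normalize_id(source_db, primary_id)
  secondary_ids <- if (length(secondary_ids)) sort(unique(normalize_id(source_db, secondary_ids))) else character()
  secondary_ids <- setdiff(secondary_ids, primary_id)
  xr <- list()
  if (length(xrefs)) {
    for (tag in names(xrefs)) {
      t <- as_db_tag(tag)
      if (t == source_db) {
        stop(sprintf("xrefs of a %s record must not target %s itself", source_db, source_db),
             call. = FALSE)
      }
      ids <- xrefs[[tag]]
      if (length(ids)) {
        xr[[t]] <- sort(unique(c(xr[[t]], normalize_id(t, ids))))
      }
    }
  }
  # fixed tag order for determinism
  xr <- xr[intersect(db_tags(), names(xr))]
  structure(list(
    source_db = source_db,
    primary_id = primary_id,
    secondary_ids = secondary_ids,
    names = unique(as.character(names)),
    smiles = as.character(smiles)[1],
    inchi = as.character(inchi)[1],
    inchikey = as.character(inchikey)[1],
    xrefs = xr
  ), class = "compound_record")
}

#' @export
print.compound_record <- function(x, ...) {
  cat(sprintf("<compound_record> %s:%s\n", x$source_db, x$primary_id))
  if (length(x$secondary_ids))
    cat("  secondary:", paste(x$secondary_ids, collapse = ", "), "\n")
  if (length(x$names))
    cat("  names:", paste(utils::head(x$names, 3), collapse = "; "),
        if (length(x$names) > 3) "..." else "", "\n")
  for (tag in names(x$xrefs))
    cat(sprintf("  xref %s: %s\n", tag, paste(x$xrefs[[tag]], collapse = ", ")))
  invisible(x)
}
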