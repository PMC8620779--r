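## Bulk loaders for the three databases that publish full dumps. Each loader
## parses the minimal field subset the resolver needs (accessions, names,
## structure strings, foreign identifiers); unknown fields are ignored,
## never errors. Loads are transactional per file: records are parsed first
## and inserted only if no hard failure occurred, so a malformed file leaves
## the store untouched.

load_report <- function(source_db, n_parsed, n_inserted, malformed) {
  malformed <- utils::head(malformed, 100)
  structure(list(source_db = source_db, n_parsed = n_parsed,
                 n_inserted = n_inserted, n_malformed = n_parsed - n_inserted,
                 malformed_samples = malformed),
            class = "load_report")
}

#' @export
print.load_report <- function(x, ...) {
  cat(sprintf("<load_report> %s: %d parsed, %d inserted, %d malformed/dropped\n",
              x$source_db, x$n_parsed, x$n_inserted, x$n_malformed))
  for (m in utils::head(x$malformed_samples, 5))
    cat(sprintf("  %s: %s\n", m$where, m$reason))
  invisible(x)
}

safe_norm <- function(db, raw) {
  if (is.null(raw) || is.na(raw) || !nzchar(trimws(raw))) return(NULL)
  tryCatch(normalize_id(db, raw), metamapr_bad_id = function(e) NULL)
}

#' Load an HMDB metabolite XML dump
#'
#' Parses per-metabolite elements: `accession`, `secondary_accessions`,
#' `name`, `smiles`, `inchi`, `inchikey`, and the foreign-identifier elements
#' `chebi_id`, `kegg_id`, `pubchem_compound_id`. An element lacking a usable
#' accession is counted malformed and skipped; malformed XML fails the whole
#' load with the parser's locator and leaves the store unchanged.
#'
#' @param path path to the XML file.
#' @param store a [local_store()]; records are upserted with provenance
#'   `"dump"`.
#' @return A `load_report` (`n_parsed == n_inserted + n_malformed`).
#' @export
load_hmdb_xml <- function(path, store) {
  doc <- xml2::read_xml(path)  # malformed XML errors here, store untouched
  xml2::xml_ns_strip(doc)
  mets <- xml2::xml_find_all(doc, "//metabolite")
  recs <- list(); malformed <- list()
  grab <- function(node, xp) {
    v <- xml2::xml_text(xml2::xml_find_first(node, xp))
    if (is.na(v) || !nzchar(trimws(v))) NA_character_ else trimws(v)
  }
  for (i in seq_along(mets)) {
    m <- mets[[i]]
    acc <- safe_norm("HMDB", grab(m, "./accession"))
    if (is.null(acc)) {
      malformed[[length(malformed) + 1L]] <-
        list(where = sprintf("metabolite %d", i), reason = "missing or malformed accession")
      next
    }
    secs <- xml2::xml_text(xml2::xml_find_all(m, "./secondary_accessions/accession"))
    secs <- unlist(lapply(secs, function(s) safe_norm("HMDB", s)))
    xr <- list()
    # foreign-id elements may repeat (one element per identifier)
    for (spec in list(c("CHEBI", "./chebi_id"), c("KEGG", "./kegg_id"),
                      c("PUBCHEM", "./pubchem_compound_id"))) {
      vals <- xml2::xml_text(xml2::xml_find_all(m, spec[2]))
      vals <- unlist(lapply(vals, function(v) safe_norm(spec[1], v)))
      if (length(vals)) xr[[spec[1]]] <- vals
    }
    nm <- grab(m, "./name")
    recs[[length(recs) + 1L]] <- compound_record(
      "HMDB", acc, secondary_ids = if (is.null(secs)) character() else secs,
      names = if (is.na(nm)) character() else nm,
      smiles = grab(m, "./smiles"), inchi = grab(m, "./inchi"),
      inchikey = grab(m, "./inchikey"), xrefs = xr)
  }
  for (r in recs) upsert_record(store, r, provenance = "dump")
  load_report("HMDB", length(mets), length(recs), malformed)
}

require_cols <- function(df, cols, what) {
  names(df) <- toupper(names(df))
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s) %s", what, paste(missing, collapse = ", ")),
         call. = FALSE)
  df
}

chebi_xref_types <- c(
  "KEGG COMPOUND accession" = "KEGG",
  "HMDB accession" = "HMDB",
  "Pubchem accession" = "PUBCHEM",
  "LIPID MAPS instance accession" = "LIPIDMAPS"
)

#' Load a ChEBI flat-table dump
#'
#' Consumes the three tab-separated tables of the ChEBI public dump layout:
#' a compounds table (`ID`, `NAME`, `STATUS`, `PARENT_ID`), a names table
#' (`COMPOUND_ID`, `NAME`) and a database-accessions table (`COMPOUND_ID`,
#' `TYPE`, `ACCESSION_NUMBER`). A row with a `PARENT_ID` is a merged child:
#' its identifier becomes a secondary accession of the parent record. A row
#' with status `O` (obsolete) and no parent yields no record. Accession
#' types for the four other databases become cross-references; all other
#' registry types (e.g. CAS) are ignored.
#'
#' The `n_malformed` bucket of the report counts every parsed row that
#' produced no stored identifier: bad ids and dropped obsolete entries alike
#' (the sample reasons distinguish them).
#'
#' @param compounds_path,names_path,accessions_path dump file paths.
#' @param store a [local_store()].
#' @return A `load_report`.
#' @export
load_chebi_tables <- function(compounds_path, names_path, accessions_path, store) {
  read_tab <- function(p) utils::read.delim(p, sep = "\t", quote = "",
                                            colClasses = "character",
                                            na.strings = NULL,
                                            stringsAsFactors = FALSE)
  comp <- require_cols(read_tab(compounds_path),
                       c("ID", "NAME", "STATUS", "PARENT_ID"), "compounds table")
  nms <- require_cols(read_tab(names_path), c("COMPOUND_ID", "NAME"), "names table")
  accs <- require_cols(read_tab(accessions_path),
                       c("COMPOUND_ID", "TYPE", "ACCESSION_NUMBER"), "accessions table")
  is_null_tok <- function(x) is.na(x) | !nzchar(trimws(x)) | tolower(trimws(x)) == "null"

  malformed <- list(); n_contrib <- 0L
  live <- list()       # canonical id -> list(names=, secondary=)
  note_bad <- function(where, reason)
    malformed[[length(malformed) + 1L]] <<- list(where = where, reason = reason)

  for (i in seq_len(nrow(comp))) {
    id <- safe_norm("CHEBI", comp$ID[i])
    if (is.null(id)) { note_bad(sprintf("compounds row %d", i), "malformed ID"); next }
    parent_raw <- comp$PARENT_ID[i]
    if (!is_null_tok(parent_raw)) {
      parent <- safe_norm("CHEBI", parent_raw)
      if (is.null(parent)) { note_bad(sprintf("compounds row %d", i), "malformed PARENT_ID"); next }
      ent <- live[[parent]]
      if (is.null(ent)) ent <- list(names = character(), secondary = character())
      ent$secondary <- union(ent$secondary, id)
      live[[parent]] <- ent
      n_contrib <- n_contrib + 1L
      next
    }
    if (toupper(trimws(comp$STATUS[i])) == "O") {
      note_bad(sprintf("compounds row %d", i), "obsolete without parent, dropped")
      next
    }
    ent <- live[[id]]
    if (is.null(ent)) ent <- list(names = character(), secondary = character())
    if (!is_null_tok(comp$NAME[i])) ent$names <- union(ent$names, trimws(comp$NAME[i]))
    live[[id]] <- ent
    n_contrib <- n_contrib + 1L
  }

  extra_names <- list(); xrefs <- list()
  for (i in seq_len(nrow(nms))) {
    id <- safe_norm("CHEBI", nms$COMPOUND_ID[i])
    if (is.null(id) || is.null(live[[id]])) next
    if (!is_null_tok(nms$NAME[i]))
      live[[id]]$names <- union(live[[id]]$names, trimws(nms$NAME[i]))
  }
  for (i in seq_len(nrow(accs))) {
    tag <- chebi_xref_types[trimws(accs$TYPE[i])]
    if (is.na(tag)) next
    id <- safe_norm("CHEBI", accs$COMPOUND_ID[i])
    if (is.null(id) || is.null(live[[id]])) next
    v <- safe_norm(tag, accs$ACCESSION_NUMBER[i])
    if (is.null(v)) next
    xrefs[[id]][[tag]] <- union(xrefs[[id]][[tag]], v)
  }

  for (id in sort(names(live))) {
    upsert_record(store, compound_record(
      "CHEBI", id, secondary_ids = live[[id]]$secondary,
      names = live[[id]]$names, xrefs = if (is.null(xrefs[[id]])) list() else xrefs[[id]]),
      provenance = "dump")
  }
  load_report("CHEBI", nrow(comp), n_contrib, malformed)
}

lipidmaps_xref_fields <- c(PUBCHEM_CID = "PUBCHEM", HMDB_ID = "HMDB",
                           KEGG_ID = "KEGG", CHEBI_ID = "CHEBI")

#' Load a LIPID MAPS structure-data (SDF) dump
#'
#' Reads the data fields of each molecule block (`LM_ID`, `NAME`, `SMILES`,
#' `INCHI`, `INCHI_KEY`, `PUBCHEM_CID`, `HMDB_ID`, `KEGG_ID`, `CHEBI_ID`);
#' MOL connection tables are skipped, not parsed. A block without a usable
#' `LM_ID` is counted malformed and skipped. Foreign-identifier fields are
#' canonicalized (`HMDB01234` is stored as `HMDB0001234`).
#'
#' @param path SDF file path.
#' @param store a [local_store()].
#' @return A `load_report`.
#' @export
load_lipidmaps_sdf <- function(path, store) {
  lines <- readLines(path, warn = FALSE)
  ends <- which(trimws(lines) == "$$$$")
  starts <- c(1L, utils::head(ends, -1) + 1L)
  blocks <- Map(function(s, e) lines[s:(e - 1L)], starts, ends)
  recs <- list(); malformed <- list()
  # a data field holds one value per line until the blank terminator;
  # identifier fields may therefore be multi-valued
  parse_fields <- function(block) {
    tags <- grep("^>", block)
    out <- list()
    for (t in tags) {
      name <- sub("^>\\s*<([^>]*)>.*$", "\\1", block[t])
      vals <- character(); j <- t + 1L
      while (j <= length(block) && nzchar(trimws(block[j])) && !startsWith(block[j], ">")) {
        vals <- c(vals, trimws(block[j])); j <- j + 1L
      }
      out[[toupper(name)]] <- vals
    }
    out
  }
  first_or_na <- function(x) if (is.null(x) || !length(x)) NA_character_ else x[1]
  for (i in seq_along(blocks)) {
    f <- parse_fields(blocks[[i]])
    lm <- safe_norm("LIPIDMAPS", first_or_na(f[["LM_ID"]]))
    if (is.null(lm)) {
      malformed[[length(malformed) + 1L]] <-
        list(where = sprintf("block %d", i), reason = "missing or malformed LM_ID")
      next
    }
    xr <- list()
    for (fld in names(lipidmaps_xref_fields)) {
      tag <- lipidmaps_xref_fields[[fld]]
      vals <- unlist(lapply(f[[fld]], function(v) safe_norm(tag, v)))
      if (length(vals)) xr[[tag]] <- vals
    }
    nm <- first_or_na(f[["NAME"]])
    recs[[length(recs) + 1L]] <- compound_record(
      "LIPIDMAPS", lm,
      names = if (is.na(nm)) character() else nm,
      smiles = first_or_na(f[["SMILES"]]), inchi = first_or_na(f[["INCHI"]]),
      inchikey = first_or_na(f[["INCHI_KEY"]]), xrefs = xr)
  }
  for (r in recs) upsert_record(store, r, provenance = "dump")
  load_report("LIPIDMAPS", length(blocks), length(recs), malformed)
}
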