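## Synthetic five-database universes with controlled cross-reference
## topology. The generator emulates the failure modes real small-compound
## databases exhibit — duplicate entries for one metabolite (forks),
## records with no foreign references (isolated), retired accessions still
## in circulation (retired), and asymmetric cross-referencing (one-way
## edges) — while staying fully offline and deterministic under a seed.
## Compounds are partitioned into the planted classes first and structure
## is sampled second, so the planted fractions are realized exactly
## (rounded), not merely in expectation.

#' Specification of a synthetic universe
#'
#' @param n_compounds number of ground-truth compounds.
#' @param db_presence named probabilities that a compound has a record in
#'   each database. Defaults reflect coverage of a typical targeted
#'   metabolomics panel: near-universal PubChem coverage, high HMDB/ChEBI/
#'   KEGG coverage, LIPID MAPS restricted to the lipid-like minority.
#' @param xref_density probability that a linked record pair of a compound
#'   actually carries cross-references; below 1 some links are simply
#'   missing, as in real dumps.
#' @param frac_fork fraction of compounds given two records in one database
#'   (the ambiguity mode).
#' @param frac_isolated fraction of compounds whose records carry and
#'   receive no cross-references at all (the unresolved mode).
#' @param frac_retired fraction of compounds whose record in one database
#'   is referenced only through a retired secondary accession. Planted only
#'   in HMDB/ChEBI, the databases whose dump formats carry secondary
#'   accessions.
#' @param one_way_frac fraction of cross-reference links made
#'   unidirectional; these are recoverable only by reverse queries.
#' @param fork_db optional tag: plant all forks in this database (default:
#'   drawn per compound). Useful when auditing a specific database, so the
#'   audited database itself stays single-record.
#' @param seed integer seed; the same spec and seed reproduce the universe
#'   exactly.
#' @return A list of class `universe_spec`.
#' @export
universe_spec <- function(n_compounds = 100L,
                          db_presence = c(HMDB = 0.9, CHEBI = 0.85, KEGG = 0.8,
                                          PUBCHEM = 0.95, LIPIDMAPS = 0.4),
                          xref_density = 0.7,
                          frac_fork = 0.05,
                          frac_isolated = 0.15,
                          frac_retired = 0.05,
                          one_way_frac = 0.25,
                          fork_db = NULL,
                          seed = 1L) {
  stopifnot(n_compounds >= 1)
  db_presence <- db_presence[db_tags()]
  names(db_presence) <- db_tags()
  if (any(is.na(db_presence)) || any(db_presence < 0 | db_presence > 1))
    stop("db_presence must give a probability in [0,1] for each of the five tags",
         call. = FALSE)
  for (p in list(xref_density, frac_fork, frac_isolated, frac_retired, one_way_frac))
    if (p < 0 || p > 1) stop("probabilities and fractions must lie in [0,1]", call. = FALSE)
  if (frac_fork + frac_isolated + frac_retired > 1)
    stop("frac_fork + frac_isolated + frac_retired must not exceed 1", call. = FALSE)
  if (!is.null(fork_db)) fork_db <- as_db_tag(fork_db)
  structure(list(n_compounds = as.integer(n_compounds), db_presence = db_presence,
                 xref_density = xref_density, frac_fork = frac_fork,
                 frac_isolated = frac_isolated, frac_retired = frac_retired,
                 one_way_frac = one_way_frac, fork_db = fork_db,
                 seed = as.integer(seed)),
            class = "universe_spec")
}

## canonical id grammars, one counter per database
make_id <- function(db, n) {
  switch(db,
    HMDB = sprintf("HMDB%07d", n),
    CHEBI = paste0("CHEBI:", 10000L + n),
    KEGG = sprintf("C%05d", n),
    PUBCHEM = as.character(100000L + n),
    LIPIDMAPS = sprintf("LMFA%08d", n))
}

## HMDB metabolite XML has no LIPID MAPS foreign-id field, so that edge
## direction cannot exist; the link is carried by the LIPID MAPS side and
## recovered by reverse queries.
xref_feasible <- function(from_db, to_db) {
  from_db != to_db && !(from_db == "HMDB" && to_db == "LIPIDMAPS")
}

#' Generate a synthetic universe
#'
#' @param spec a [universe_spec()].
#' @return A list of class `universe`: `store` (a [local_store()] with
#'   provenance `"fixture"`) and `truth` — the ground truth: `compounds`
#'   (compound index and planted class), `memberships` (compound, db,
#'   primary id), `secondary` (planted retired accessions) and `edges` (the
#'   directed cross-references as written, including those written against
#'   a retired accession).
#' @export
generate_universe <- function(spec) {
  stopifnot(inherits(spec, "universe_spec"))
  rng <- local_rng(spec$seed)
  on.exit(restore_rng(rng))
  n <- spec$n_compounds
  n_fork <- round(spec$frac_fork * n)
  n_iso <- round(spec$frac_isolated * n)
  n_ret <- round(spec$frac_retired * n)
  if (n_fork + n_iso + n_ret > n)
    stop("planted class counts exceed n_compounds after rounding", call. = FALSE)
  classes <- sample(rep(c("fork", "isolated", "retired", "clean"),
                        c(n_fork, n_iso, n_ret, n - n_fork - n_iso - n_ret)))
  counters <- stats::setNames(rep(0L, 5), db_tags())
  next_id <- function(db) {
    counters[[db]] <<- counters[[db]] + 1L
    make_id(db, counters[[db]])
  }

  memberships <- list(); secondary <- list(); edge_rows <- list()
  xref_map <- list()  # "db::id" -> list(tag -> ids as written)
  rec_meta <- list()  # "db::id" -> list(db, id, secondary, compound)

  for (i in seq_len(n)) {
    cls <- classes[i]
    present <- db_tags()[stats::runif(5) < spec$db_presence]
    if (!length(present))
      present <- sample(db_tags(), 1, prob = pmax(spec$db_presence, 1e-6))
    fork_db <- NULL
    if (cls == "fork") {
      fork_db <- if (!is.null(spec$fork_db)) spec$fork_db else sample(present, 1)
      present <- union(present, fork_db)
    }
    ret_db <- NULL
    if (cls == "retired") {
      avail <- intersect(present, c("HMDB", "CHEBI"))
      ret_db <- if (length(avail)) sample(avail, 1) else "HMDB"
      present <- union(present, ret_db)
    }
    present <- intersect(db_tags(), present)  # fixed order
    recs <- list()
    for (db in present) {
      k <- if (!is.null(fork_db) && db == fork_db) 2L else 1L
      for (j in seq_len(k)) {
        id <- next_id(db)
        recs[[length(recs) + 1L]] <- list(db = db, id = id)
        memberships[[length(memberships) + 1L]] <-
          data.frame(compound = i, db = db, primary_id = id, stringsAsFactors = FALSE)
      }
    }
    ret_alias <- NULL
    if (cls == "retired") {
      ridx <- which(vapply(recs, function(r) r$db == ret_db, NA))[1]
      ret_alias <- list(db = ret_db, primary = recs[[ridx]]$id, alias = next_id(ret_db))
      secondary[[length(secondary) + 1L]] <- data.frame(
        compound = i, db = ret_db, primary_id = ret_alias$primary,
        secondary_id = ret_alias$alias, stringsAsFactors = FALSE)
    }
    for (r in recs) {
      key <- store_key(r$db, r$id)
      rec_meta[[key]] <- list(db = r$db, id = r$id, compound = i,
                              secondary = if (!is.null(ret_alias) &&
                                              identical(ret_alias$primary, r$id))
                                ret_alias$alias else NULL)
    }
    if (cls == "isolated" || length(recs) < 2) next
    # written id for incoming references: retired records are referenced
    # through their alias only
    written_id <- function(r) {
      if (!is.null(ret_alias) && identical(ret_alias$primary, r$id)) ret_alias$alias else r$id
    }
    for (a in seq_len(length(recs) - 1L)) for (b in seq((a + 1L), length(recs))) {
      r1 <- recs[[a]]; r2 <- recs[[b]]
      if (r1$db == r2$db) next  # fork twins never cross-reference each other
      if (stats::runif(1) >= spec$xref_density) next
      dirs <- list()
      if (xref_feasible(r1$db, r2$db)) dirs <- c(dirs, list(c(1, 2)))
      if (xref_feasible(r2$db, r1$db)) dirs <- c(dirs, list(c(2, 1)))
      if (!length(dirs)) next
      if (length(dirs) == 2 && stats::runif(1) < spec$one_way_frac)
        dirs <- dirs[sample(2, 1)]
      pair <- list(r1, r2)
      for (d in dirs) {
        src <- pair[[d[1]]]; dst <- pair[[d[2]]]
        wid <- written_id(dst)
        key <- store_key(src$db, src$id)
        xref_map[[key]][[dst$db]] <- union(xref_map[[key]][[dst$db]], wid)
        edge_rows[[length(edge_rows) + 1L]] <- data.frame(
          src_db = src$db, src_id = src$id, dst_db = dst$db,
          dst_id_written = wid, dst_primary = dst$id, stringsAsFactors = FALSE)
      }
    }
  }

  store <- local_store()
  for (key in sort(names(rec_meta))) {
    m <- rec_meta[[key]]
    has_structure <- m$db != "CHEBI"  # the ChEBI flat-table dialect carries none
    upsert_record(store, compound_record(
      m$db, m$id,
      secondary_ids = if (is.null(m$secondary)) character() else m$secondary,
      names = sprintf("compound-%04d", m$compound),
      smiles = if (has_structure) sprintf("SMILES[%s]", m$id) else NA_character_,
      inchi = if (has_structure) sprintf("InChI=1S/%s", m$id) else NA_character_,
      inchikey = if (has_structure) sprintf("KEY-%s", m$id) else NA_character_,
      xrefs = if (is.null(xref_map[[key]])) list() else xref_map[[key]]),
      provenance = "fixture")
  }
  bind <- function(lst, proto) if (length(lst)) {
    df <- do.call(rbind, lst); rownames(df) <- NULL; df
  } else proto
  truth <- list(
    compounds = data.frame(compound = seq_len(n), class = classes,
                           stringsAsFactors = FALSE),
    memberships = bind(memberships, data.frame(compound = integer(), db = character(),
                                               primary_id = character())),
    secondary = bind(secondary, data.frame(compound = integer(), db = character(),
                                           primary_id = character(),
                                           secondary_id = character())),
    edges = bind(edge_rows, data.frame(src_db = character(), src_id = character(),
                                       dst_db = character(), dst_id_written = character(),
                                       dst_primary = character())),
    spec = spec)
  structure(list(store = store, truth = truth), class = "universe")
}

#' @export
print.universe <- function(x, ...) {
  cat(sprintf("<universe> %d compound(s), %d record(s), seed %d\n",
              nrow(x$truth$compounds), store_size(x$store), x$truth$spec$seed))
  print(table(x$truth$compounds$class))
  invisible(x)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Export a universe in the three dump dialects
#'
#' Writes the HMDB records as metabolite XML, the ChEBI records as the
#' three flat tables (merged children encode the planted retired
#' accessions), and the LIPID MAPS records as an SDF with minimal V2000
#' headers and the standard data fields. Loading these files back with the
#' dump loaders reproduces the store content for those three databases
#' exactly; KEGG and PubChem records have no dump dialect (they are fetched
#' per identifier) and are not exported.
#'
#' @param universe a [generate_universe()] result (or any `local_store` in
#'   which case pass it as `universe$store` equivalent via `list(store =)`).
#' @param out_dir output directory, created if needed.
#' @return Named character vector of the files written, invisibly.
#' @export
export_dump_dialects <- function(universe, out_dir) {
  store <- universe$store
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(hmdb = file.path(out_dir, "hmdb_metabolites.xml"),
             chebi_compounds = file.path(out_dir, "chebi_compounds.tsv"),
             chebi_names = file.path(out_dir, "chebi_names.tsv"),
             chebi_accessions = file.path(out_dir, "chebi_database_accessions.tsv"),
             lipidmaps = file.path(out_dir, "lipidmaps.sdf"))

  ## HMDB XML
  hmdb_ids <- store_ids(store, "HMDB")
  con <- file(files[["hmdb"]], "w", encoding = "UTF-8")
  writeLines('<?xml version="1.0" encoding="UTF-8"?>', con)
  writeLines("<hmdb>", con)
  xml_tag_map <- c(CHEBI = "chebi_id", KEGG = "kegg_id", PUBCHEM = "pubchem_compound_id")
  for (id in hmdb_ids) {
    r <- lookup_primary(store, "HMDB", id)
    writeLines("  <metabolite>", con)
    writeLines(sprintf("    <accession>%s</accession>", xml_escape(r$primary_id)), con)
    if (length(r$secondary_ids)) {
      writeLines("    <secondary_accessions>", con)
      for (s in r$secondary_ids)
        writeLines(sprintf("      <accession>%s</accession>", xml_escape(s)), con)
      writeLines("    </secondary_accessions>", con)
    }
    if (length(r$names))
      writeLines(sprintf("    <name>%s</name>", xml_escape(r$names[1])), con)
    for (fld in c("smiles", "inchi", "inchikey"))
      if (!is.na(r[[fld]]))
        writeLines(sprintf("    <%s>%s</%s>", fld, xml_escape(r[[fld]]), fld), con)
    for (tag in names(xml_tag_map))
      for (x in r$xrefs[[tag]])
        writeLines(sprintf("    <%s>%s</%s>", xml_tag_map[[tag]], xml_escape(x),
                           xml_tag_map[[tag]]), con)
    writeLines("  </metabolite>", con)
  }
  writeLines("</hmdb>", con)
  close(con)

  ## ChEBI flat tables
  chebi_ids <- store_ids(store, "CHEBI")
  comp_rows <- list(); name_rows <- list(); acc_rows <- list()
  bare <- function(id) sub("^CHEBI:", "", id)
  inv_types <- stats::setNames(names(chebi_xref_types), chebi_xref_types)
  for (id in chebi_ids) {
    r <- lookup_primary(store, "CHEBI", id)
    comp_rows[[length(comp_rows) + 1L]] <- data.frame(
      ID = bare(id), NAME = if (length(r$names)) r$names[1] else "",
      STATUS = "C", PARENT_ID = "null", stringsAsFactors = FALSE)
    for (s in r$secondary_ids)
      comp_rows[[length(comp_rows) + 1L]] <- data.frame(
        ID = bare(s), NAME = "", STATUS = "O", PARENT_ID = bare(id),
        stringsAsFactors = FALSE)
    for (nm in r$names)
      name_rows[[length(name_rows) + 1L]] <- data.frame(
        COMPOUND_ID = bare(id), NAME = nm, stringsAsFactors = FALSE)
    for (tag in names(r$xrefs))
      for (x in r$xrefs[[tag]])
        acc_rows[[length(acc_rows) + 1L]] <- data.frame(
          COMPOUND_ID = bare(id), TYPE = inv_types[[tag]], ACCESSION_NUMBER = x,
          stringsAsFactors = FALSE)
  }
  write_flat <- function(rows, proto_cols, path) {
    df <- if (length(rows)) do.call(rbind, rows) else
      as.data.frame(stats::setNames(rep(list(character()), length(proto_cols)),
                                    proto_cols), stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "", eol = "\n", fileEncoding = "UTF-8")
  }
  write_flat(comp_rows, c("ID", "NAME", "STATUS", "PARENT_ID"), files[["chebi_compounds"]])
  write_flat(name_rows, c("COMPOUND_ID", "NAME"), files[["chebi_names"]])
  write_flat(acc_rows, c("COMPOUND_ID", "TYPE", "ACCESSION_NUMBER"),
             files[["chebi_accessions"]])

  ## LIPID MAPS SDF
  lm_ids <- store_ids(store, "LIPIDMAPS")
  con <- file(files[["lipidmaps"]], "w", encoding = "UTF-8")
  sdf_field_map <- c(PUBCHEM = "PUBCHEM_CID", HMDB = "HMDB_ID",
                     KEGG = "KEGG_ID", CHEBI = "CHEBI_ID")
  for (id in lm_ids) {
    r <- lookup_primary(store, "LIPIDMAPS", id)
    writeLines(c(id, "  metamapr synthetic", "",
                 "  0  0  0  0  0  0  0  0  0  0999 V2000", "M  END"), con)
    put <- function(tag, vals) {
      if (!length(vals)) return()
      writeLines(c(sprintf("> <%s>", tag), vals, ""), con)
    }
    put("LM_ID", r$primary_id)
    put("NAME", if (length(r$names)) r$names[1] else character())
    if (!is.na(r$smiles)) put("SMILES", r$smiles)
    if (!is.na(r$inchi)) put("INCHI", r$inchi)
    if (!is.na(r$inchikey)) put("INCHI_KEY", r$inchikey)
    for (tag in names(sdf_field_map)) put(sdf_field_map[[tag]], r$xrefs[[tag]])
    writeLines("$$$$", con)
  }
  close(con)
  invisible(files)
}
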