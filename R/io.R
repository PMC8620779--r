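## Reading the user's sparse identifier table and writing resolution
## results. Column aliases are case-insensitive; multi-valued cells use a
## configurable separator ("|" by default — a character that cannot occur
## inside any canonical identifier). Output files are written in a fixed
## column and row order, so identical runs produce byte-identical files.

id_column_aliases <- list(
  HMDB = c("hmdb_id", "hmdb"),
  CHEBI = c("chebi_id", "chebi"),
  KEGG = c("kegg_id", "kegg"),
  PUBCHEM = c("pubchem_id", "pubchem_cid", "pubchem", "cid"),
  LIPIDMAPS = c("lipidmaps_id", "lm_id", "lipidmaps", "lipid_maps_id")
)
label_aliases <- c("name", "label", "metabolite", "compound")
na_tokens <- c("", "na", "n/a", "null", "none", "-")

#' Read a sparse identifier table from CSV/TSV
#'
#' The header may name any subset of the five identifier columns
#' (case-insensitive aliases: `hmdb_id`, `chebi_id`, `kegg_id`,
#' `pubchem_id`/`pubchem_cid`, `lipidmaps_id`/`lm_id`) plus an optional
#' label column (`name`/`label`/...). Cells are canonicalized with
#' [normalize_id()]; empty strings and NA tokens become empty cells.
#' Malformed identifiers never drop a row: they are removed from the cell
#' and collected in the `malformed` attribute of the result
#' (`row`, `db`, `raw`, `reason`).
#'
#' @param path file path; comma-separated for `.csv`, tab-separated
#'   otherwise.
#' @param sep separator for multi-valued cells (default `"|"`).
#' @return An [identifier_table()]; `attr(x, "malformed")` holds the
#'   rejected identifiers.
#' @export
read_input_table <- function(path, sep = "|") {
  field_sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = field_sep, quote = "\"",
                          colClasses = "character", na.strings = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  lower <- tolower(trimws(names(df)))
  col_of <- stats::setNames(rep(NA_integer_, 5), db_tags())
  for (tag in db_tags()) {
    hits <- which(lower %in% id_column_aliases[[tag]])
    if (length(hits) > 1)
      stop(sprintf("duplicate %s identifier columns: %s", tag,
                   paste(names(df)[hits], collapse = ", ")), call. = FALSE)
    if (length(hits)) col_of[[tag]] <- hits
  }
  if (all(is.na(col_of)))
    stop("no recognized identifier column in header (expected e.g. hmdb_id, chebi_id, kegg_id, pubchem_id, lipidmaps_id)",
         call. = FALSE)
  label_col <- which(lower %in% label_aliases)[1]
  labels <- if (!is.na(label_col)) df[[label_col]] else rep(NA_character_, nrow(df))

  rows <- vector("list", nrow(df))
  bad <- list()
  for (i in seq_len(nrow(df))) {
    cells <- list()
    for (tag in db_tags()) {
      ci <- col_of[[tag]]
      if (is.na(ci)) next
      raw <- trimws(strsplit(df[[ci]][i], sep, fixed = TRUE)[[1]])
      raw <- raw[!(tolower(raw) %in% na_tokens)]
      if (!length(raw)) next
      nq <- normalize_id_quietly(tag, raw)
      if (nrow(nq$problems)) {
        bad[[length(bad) + 1L]] <- cbind(data.frame(row = i, db = tag), nq$problems)
      }
      ids <- nq$ids[!is.na(nq$ids)]
      if (length(ids)) cells[[tag]] <- ids
    }
    rows[[i]] <- cells
  }
  tab <- identifier_table(rows, labels = labels)
  malformed <- if (length(bad)) {
    m <- do.call(rbind, bad); rownames(m) <- NULL; m
  } else data.frame(row = integer(), db = character(), raw = character(),
                    reason = character(), stringsAsFactors = FALSE)
  attr(tab, "malformed") <- malformed
  tab
}

#' Write a resolution result to TSV files
#'
#' Writes the main table (`<prefix>.tsv`: row key, label, the five
#' identifier columns with multi-valued cells joined by `sep`, the
#' databases flagged ambiguous, and the per-row status) plus three sidecar
#' files carrying the tracked diagnostics: `<prefix>_unresolved.tsv`
#' (identifiers used for mapping that returned no result),
#' `<prefix>_secondary_hits.tsv` (identifiers resolved only through the
#' secondary-accession index) and `<prefix>_provenance.tsv` (for every
#' filled identifier, the query that discovered it and the pass).
#'
#' @param result a [resolve_table()] result.
#' @param prefix output path prefix.
#' @param sep multi-value separator.
#' @return Named character vector of files written, invisibly.
#' @export
write_output <- function(result, prefix, sep = "|") {
  stopifnot(inherits(result, "resolution_result"))
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  main <- as.data.frame(result$table, sep = sep)
  amb <- result$ambiguous_cells
  main$ambiguous_dbs <- vapply(main$row_key, function(k)
    paste(amb$db[amb$row_key == k], collapse = ","), "")
  main$status <- result$row_info$status[match(main$row_key, result$row_info$row_key)]
  files <- c(main = paste0(prefix, ".tsv"),
             unresolved = paste0(prefix, "_unresolved.tsv"),
             secondary_hits = paste0(prefix, "_secondary_hits.tsv"),
             provenance = paste0(prefix, "_provenance.tsv"))
  wt <- function(df, path)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "", eol = "\n", fileEncoding = "UTF-8")
  wt(main, files[["main"]])
  wt(result$unresolved_ids, files[["unresolved"]])
  wt(result$secondary_hits, files[["secondary_hits"]])
  wt(result$provenance, files[["provenance"]])
  invisible(files)
}
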