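## Per-identifier fetching of KEGG and PubChem records with cache-through
## into the local store. The network sits behind a pluggable transport so
## the whole stack runs offline: tests and the quality assessment use a mock
## transport; a curl-backed transport is provided for live use. Fetched
## records are upserted with provenance "remote_cache", so any identifier is
## fetched over the wire at most once per store lifetime. Negative results
## (404) are memoized in memory for the session only — databases gain
## entries over time, so absence is never persisted.

#' Remote-client configuration
#'
#' @param kegg_base_url,pubchem_base_url endpoint bases (config, not code,
#'   so fixture servers can be swapped in).
#' @param rate_limit_s minimum inter-request interval in seconds. The
#'   default 0.35 s respects PubChem's published courtesy limit of at most
#'   3 requests per second.
#' @param max_retries attempts before giving up with `transport_error`.
#' @param backoff multiplier on the sleep between retries.
#' @return A list of class `remote_config`.
#' @export
remote_config <- function(kegg_base_url = "https://rest.kegg.jp",
                          pubchem_base_url = "https://pubchem.ncbi.nlm.nih.gov/rest/pug",
                          rate_limit_s = 0.35, max_retries = 3L, backoff = 2) {
  structure(list(kegg_base_url = kegg_base_url,
                 pubchem_base_url = pubchem_base_url,
                 rate_limit_s = rate_limit_s,
                 max_retries = as.integer(max_retries),
                 backoff = backoff), class = "remote_config")
}

#' Bundle a transport and configuration for the resolver
#'
#' @param transport a transport (see [mock_transport()], [curl_transport()]).
#' @param config a [remote_config()].
#' @return A list passed as the `remote` argument of [resolve_table()].
#' @export
remote_backend <- function(transport, config = remote_config()) {
  list(transport = transport, config = config)
}

new_transport <- function(send, label) {
  env <- new.env(parent = emptyenv())
  env$send <- send
  env$calls <- 0L
  env$last_request_time <- -Inf
  env$request_times <- numeric()
  env$label <- label
  class(env) <- "transport"
  env
}

#' Mock transport
#'
#' Serves canned responses keyed by URL and counts every call — the
#' deterministic stand-in the test suite and quality assessment use instead
#' of the network. A handler function may be supplied instead of a response
#' map for programmable behaviour (e.g. always timing out).
#'
#' @param responses named list: URL -> list(status =, body =). Unknown URLs
#'   get a 404.
#' @param handler optional `function(method, url, params)` returning
#'   `list(status =, body =)`; overrides `responses`.
#' @return A transport. Calls made so far are in `transport$calls`;
#'   request timestamps in `transport$request_times`.
#' @export
mock_transport <- function(responses = list(), handler = NULL) {
  send <- function(method, url, params = list()) {
    if (!is.null(handler)) return(handler(method, url, params))
    if (!is.null(responses[[url]])) responses[[url]] else list(status = 404L, body = "")
  }
  new_transport(send, "mock")
}

#' Curl-backed live transport
#'
#' Shells out to the `curl` binary; the status code is read from curl's
#' `%{http_code}` write-out. Intended for interactive live use only — the
#' test suite and all offline workflows use [mock_transport()].
#'
#' @return A transport.
#' @export
curl_transport <- function() {
  send <- function(method, url, params = list()) {
    out <- tryCatch(
      system2("curl", c("-s", "-w", "\\n%{http_code}", shQuote(url)),
              stdout = TRUE, stderr = FALSE),
      error = function(e) character(), warning = function(w) character())
    if (!length(out)) return(list(status = 599L, body = ""))
    status <- suppressWarnings(as.integer(out[length(out)]))
    if (is.na(status)) status <- 599L
    list(status = status, body = paste(out[-length(out)], collapse = "\n"))
  }
  new_transport(send, "curl")
}

transport_send <- function(transport, config, method, url, params = list()) {
  now <- as.numeric(Sys.time())
  wait <- config$rate_limit_s - (now - transport$last_request_time)
  if (is.finite(wait) && wait > 0) Sys.sleep(wait)
  transport$last_request_time <- as.numeric(Sys.time())
  transport$request_times <- c(transport$request_times, transport$last_request_time)
  transport$calls <- transport$calls + 1L
  tryCatch(transport$send(method, url, params),
           error = function(e) list(status = 599L, body = ""))
}

fetch_outcome <- function(record, status, attempts) {
  stopifnot(xor(is.null(record), status %in% c("hit_cache", "fetched")))
  structure(list(record = record, status = status, attempts = attempts),
            class = "fetch_outcome")
}

#' @export
print.fetch_outcome <- function(x, ...) {
  cat(sprintf("<fetch_outcome> %s (attempts: %d)\n", x$status, x$attempts))
  if (!is.null(x$record)) print(x$record)
  invisible(x)
}

fetch_generic <- function(store, db, id, transport, config, url, parser) {
  id <- normalize_id(db, id)
  cached <- lookup_primary(store, db, id)
  if (!is.null(cached)) return(fetch_outcome(cached, "hit_cache", 0L))
  negkey <- store_key(db, id)
  if (exists(negkey, envir = store$negcache, inherits = FALSE))
    return(fetch_outcome(NULL, "not_found", 0L))
  attempts <- 0L
  repeat {
    attempts <- attempts + 1L
    resp <- transport_send(transport, config, "GET", url)
    if (identical(resp$status, 200L) || identical(resp$status, 200)) {
      rec <- tryCatch(parser(id, resp$body), error = function(e) NULL)
      if (is.null(rec)) {  # unparseable body counts as not found
        assign(negkey, TRUE, envir = store$negcache)
        return(fetch_outcome(NULL, "not_found", attempts))
      }
      upsert_record(store, rec, provenance = "remote_cache")
      return(fetch_outcome(lookup_primary(store, db, rec$primary_id), "fetched", attempts))
    }
    if (identical(resp$status, 404L) || identical(resp$status, 404)) {
      assign(negkey, TRUE, envir = store$negcache)
      return(fetch_outcome(NULL, "not_found", attempts))
    }
    if (attempts >= config$max_retries)
      return(fetch_outcome(NULL, "transport_error", attempts))
    Sys.sleep(config$rate_limit_s * config$backoff^(attempts - 1L))
  }
}

kegg_dblink_tags <- c("ChEBI" = "CHEBI", "PubChem" = "PUBCHEM",
                      "HMDB" = "HMDB", "LIPIDMAPS" = "LIPIDMAPS")

parse_kegg_flat <- function(id, body) {
  lines <- strsplit(body, "\n", fixed = TRUE)[[1]]
  if (!length(lines)) return(NULL)
  field <- ""
  entry <- NULL; nms <- character(); xr <- list()
  for (ln in lines) {
    if (grepl("^\\S", ln)) field <- trimws(substr(ln, 1, 12))
    content <- trimws(substring(ln, 13))
    if (field == "ENTRY" && is.null(entry)) {
      entry <- strsplit(content, "\\s+")[[1]][1]
    } else if (field == "NAME" && nzchar(content)) {
      nms <- c(nms, sub(";$", "", content))
    } else if (field == "DBLINKS" && nzchar(content)) {
      parts <- strsplit(content, ":", fixed = TRUE)[[1]]
      if (length(parts) >= 2) {
        tag <- kegg_dblink_tags[trimws(parts[1])]
        if (!is.na(tag)) {
          ids <- strsplit(trimws(paste(parts[-1], collapse = ":")), "\\s+")[[1]]
          ids <- unlist(lapply(ids, function(v) safe_norm(tag, v)))
          if (length(ids)) xr[[tag]] <- union(xr[[tag]], ids)
        }
      }
    }
  }
  pid <- if (!is.null(entry)) safe_norm("KEGG", entry) else NULL
  if (is.null(pid)) pid <- id
  compound_record("KEGG", pid, names = nms, xrefs = xr)
}

#' Fetch a KEGG compound record (cache-through)
#'
#' A store hit returns immediately with zero transport calls. On a miss the
#' KEGG flat-file endpoint is queried (`<base>/get/<id>`), the `ENTRY`,
#' `NAME` and `DBLINKS` sections are parsed into a [compound_record()], and
#' the record is upserted so the identifier is never fetched again. HTTP 404
#' memoizes a session-local negative; transport failures are retried with
#' backoff up to `max_retries` and then reported as `transport_error` —
#' the resolver treats that as a miss but logs it distinctly.
#'
#' @param store a [local_store()].
#' @param id canonical KEGG identifier.
#' @param transport a transport.
#' @param config a [remote_config()].
#' @return A `fetch_outcome`: `record` (present iff status is `hit_cache`
#'   or `fetched`), `status`, `attempts`.
#' @export
fetch_kegg <- function(store, id, transport, config = remote_config()) {
  id <- normalize_id("KEGG", id)
  fetch_generic(store, "KEGG", id, transport, config,
                url = sprintf("%s/get/%s", config$kegg_base_url, id),
                parser = parse_kegg_flat)
}

parse_pubchem_json <- function(id, body) {
  doc <- tryCatch(jsonlite::fromJSON(body, simplifyVector = TRUE),
                  error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  cid <- doc[["CID"]]
  pid <- if (!is.null(cid)) safe_norm("PUBCHEM", as.character(cid)) else NULL
  if (is.null(pid)) pid <- id
  xr <- list()
  for (tag in names(doc[["xrefs"]])) {
    t <- tryCatch(as_db_tag(tag), error = function(e) NA_character_)
    if (is.na(t) || t == "PUBCHEM") next
    ids <- unlist(lapply(as.character(doc[["xrefs"]][[tag]]),
                         function(v) safe_norm(t, v)))
    if (length(ids)) xr[[t]] <- ids
  }
  val <- function(k) if (is.null(doc[[k]])) NA_character_ else as.character(doc[[k]])[1]
  compound_record("PUBCHEM", pid,
                  names = as.character(doc[["synonyms"]]),
                  smiles = val("smiles"), inchi = val("inchi"),
                  inchikey = val("inchikey"), xrefs = xr)
}

#' Fetch a PubChem compound record (cache-through)
#'
#' Same contract as [fetch_kegg()]. The endpoint
#' (`<base>/compound/cid/<cid>/JSON`) is expected to serve a JSON record
#' with fields `CID`, `synonyms`, optional `smiles`/`inchi`/`inchikey`, and
#' an optional `xrefs` map from database tags to identifier arrays; the
#' mock transport in the test suite serves exactly this shape.
#'
#' @inheritParams fetch_kegg
#' @param id canonical PubChem CID.
#' @return A `fetch_outcome`.
#' @export
fetch_pubchem <- function(store, id, transport, config = remote_config()) {
  id <- normalize_id("PUBCHEM", id)
  fetch_generic(store, "PUBCHEM", id, transport, config,
                url = sprintf("%s/compound/cid/%s/JSON", config$pubchem_base_url, id),
                parser = parse_pubchem_json)
}
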