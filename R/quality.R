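## Database-quality assessment: draw random identifiers from one database,
## resolve each as a single-identifier row against the local store, and
## classify the outcome as consistent (one-to-one everywhere something was
## found), ambiguous (some other database offered multiple candidate
## records) or unresolved (no link found in any other database). Replicated
## draws give a distribution per metric, the basis for box-plot style
## comparisons between databases.

#' Classify a single resolved case
#'
#' The row must have been seeded with exactly one identifier, in
#' `source_db`'s cell. Classification, in precedence order: *ambiguous* if
#' any non-source database matched more than one distinct record;
#' *unresolved* if every non-source cell is empty; otherwise *consistent*.
#'
#' Ambiguity is judged on distinct matched records, not raw cell
#' cardinality, so a retired accession stored alongside its current primary
#' id does not count as ambiguity. Partial resolutions (some databases
#' one-to-one, others empty) count as consistent: unresolved requires
#' failure in all other databases. This reading inflates consistency
#' relative to a stricter "fully filled" one and is deliberate.
#'
#' @param fragment a [resolve_row()] fragment.
#' @param source_db the database the seed identifier came from.
#' @return One of `"consistent"`, `"ambiguous"`, `"unresolved"`.
#' @export
classify_case <- function(fragment, source_db) {
  source_db <- as_db_tag(source_db)
  seeds <- fragment$input_cells
  if (sum(lengths(seeds)) != 1L || length(seeds[[source_db]]) != 1L)
    stop("classify_case expects a row seeded with exactly one identifier in source_db",
         call. = FALSE)
  others <- setdiff(db_tags(), source_db)
  if (any(vapply(others, function(d) length(fragment$matched[[d]]) > 1L, NA)))
    return("ambiguous")
  if (all(vapply(others, function(d) length(fragment$cells[[d]]) == 0L, NA)))
    return("unresolved")
  "consistent"
}

#' Assess the quality of one database by repeated random sampling
#'
#' Per replicate, `n_per_replicate` primary identifiers of `source_db` are
#' drawn uniformly without replacement (RNG seeded with
#' `seed + replicate - 1`, so replicates are independent and the whole
#' report is reproducible), each is resolved offline as a single-identifier
#' row, and the three class fractions are recorded. Defaults mirror a
#' full-scale audit: 1000 identifiers, 100 replicates.
#'
#' @param store a [local_store()].
#' @param source_db database to audit.
#' @param n_per_replicate identifiers drawn per replicate; capped (with a
#'   warning) at the number of records available.
#' @param n_replicates number of replicates.
#' @param seed integer base seed.
#' @return An object of class `quality_report`: `replicates` data frame
#'   (`replicate`, `pct_consistent`, `pct_ambiguous`, `pct_unresolved`,
#'   fractions summing to one), and `summary` (median and quartiles per
#'   metric).
#' @export
assess_database <- function(store, source_db, n_per_replicate = 1000L,
                            n_replicates = 100L, seed = 1L) {
  source_db <- as_db_tag(source_db)
  ids <- store_ids(store, source_db)
  if (!length(ids)) stop(sprintf("store holds no %s records", source_db), call. = FALSE)
  if (length(ids) < n_per_replicate) {
    warning(sprintf("only %d %s records available; sampling all of them per replicate",
                    length(ids), source_db))
    n_per_replicate <- length(ids)
  }
  cls_cache <- new.env(parent = emptyenv())  # id -> class; rows are independent
  classify_id <- function(id) {
    if (exists(id, envir = cls_cache, inherits = FALSE)) return(get(id, envir = cls_cache))
    cells <- empty_cells()
    cells[[source_db]] <- id
    cls <- classify_case(resolve_row(cells, store), source_db)
    assign(id, cls, envir = cls_cache)
    cls
  }
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    rng <- local_rng(seed + r - 1L)
    picked <- ids[sample.int(length(ids), n_per_replicate)]
    restore_rng(rng)
    cls <- vapply(picked, classify_id, "")
    reps[[r]] <- data.frame(
      replicate = r,
      pct_consistent = mean(cls == "consistent"),
      pct_ambiguous = mean(cls == "ambiguous"),
      pct_unresolved = mean(cls == "unresolved"))
  }
  replicates <- do.call(rbind, reps)
  qs <- function(col) stats::quantile(replicates[[col]], c(0.25, 0.5, 0.75), names = FALSE)
  summ <- data.frame(
    metric = c("pct_consistent", "pct_ambiguous", "pct_unresolved"),
    q1 = c(qs("pct_consistent")[1], qs("pct_ambiguous")[1], qs("pct_unresolved")[1]),
    median = c(qs("pct_consistent")[2], qs("pct_ambiguous")[2], qs("pct_unresolved")[2]),
    q3 = c(qs("pct_consistent")[3], qs("pct_ambiguous")[3], qs("pct_unresolved")[3]),
    mean = c(mean(replicates$pct_consistent), mean(replicates$pct_ambiguous),
             mean(replicates$pct_unresolved)),
    stringsAsFactors = FALSE)
  structure(list(source_db = source_db, n_sampled = n_per_replicate,
                 n_replicates = n_replicates, seed = seed,
                 replicates = replicates, summary = summ),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> %s: %d id(s) x %d replicate(s), seed %d\n",
              x$source_db, x$n_sampled, x$n_replicates, x$seed))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

## Seed scoping: sampling runs under its own RNG state and restores the
## caller's, so assessment never perturbs surrounding simulations.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
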