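test_that("a forward xref chain fills all five cells", {
  st <- chain_store()
  fr <- resolve_row(single_row_cells("HMDB", "HMDB0000001"), st)
  expect_identical(fr$cells$HMDB, "HMDB0000001")
  expect_identical(fr$cells$KEGG, "C00001")
  expect_identical(fr$cells$CHEBI, "CHEBI:15377")
  expect_identical(fr$cells$PUBCHEM, "962")
  expect_identical(fr$cells$LIPIDMAPS, "LMFA00000001")
  # matches the independent component oracle
  comps <- oracle_components(st)
  expect_identical(fr$cells, oracle_cells(comps, "HMDB::HMDB0000001"))
  expect_equal(nrow(fr$unresolved), 0L)
  expect_length(fr$ambiguous_dbs, 0L)
})

test_that("an identifier absent everywhere stays alone and is reported unresolved", {
  st <- chain_store()
  fr <- resolve_row(single_row_cells("KEGG", "C09999"), st)
  expect_identical(fr$cells$KEGG, "C09999")
  for (d in setdiff(db_tags(), "KEGG")) expect_length(fr$cells[[d]], 0L)
  expect_identical(fr$unresolved, data.frame(db = "KEGG", id = "C09999",
                                             stringsAsFactors = FALSE))
})

test_that("two same-db records referencing one compound mark the cell ambiguous", {
  st <- local_store()
  upsert_record(st, compound_record("HMDB", "HMDB0000010", xrefs = list(KEGG = "C00010")))
  upsert_record(st, compound_record("HMDB", "HMDB0000011", xrefs = list(KEGG = "C00010")))
  upsert_record(st, compound_record("KEGG", "C00010",
                                    xrefs = list(HMDB = c("HMDB0000010", "HMDB0000011"))))
  fr <- resolve_row(single_row_cells("KEGG", "C00010"), st)
  expect_identical(fr$cells$HMDB, c("HMDB0000010", "HMDB0000011"))
  expect_identical(fr$ambiguous_dbs, "HMDB")
  expect_identical(fr$cells, oracle_cells(oracle_components(st), "KEGG::C00010"))
})

test_that("one-way xrefs are recovered by the exceptional reverse flow", {
  st <- local_store()
  upsert_record(st, compound_record("HMDB", "HMDB0000020", xrefs = list(KEGG = "C00020")))
  upsert_record(st, compound_record("KEGG", "C00020"))  # no back-reference
  fr <- resolve_row(single_row_cells("KEGG", "C00020"), st)
  expect_identical(fr$cells$HMDB, "HMDB0000020")
  prov <- fr$provenance
  expect_identical(prov$pass[prov$db == "HMDB" & prov$id == "HMDB0000020"], "exceptional")
  # with the reverse flow disabled the link is invisible
  fr0 <- resolve_row(single_row_cells("KEGG", "C00020"), st, reverse = FALSE)
  expect_length(fr0$cells$HMDB, 0L)
})

test_that("a retired accession resolves through the secondary index and is logged", {
  st <- chain_store()
  upsert_record(st, compound_record("HMDB", "HMDB0000001", secondary_ids = "HMDB0004999"))
  fr <- resolve_row(single_row_cells("HMDB", "HMDB0004999"), st)
  expect_true("HMDB0000001" %in% fr$cells$HMDB)
  expect_identical(fr$cells$KEGG, "C00001")
  expect_true(any(fr$secondary_hits$id == "HMDB0004999"))
  expect_length(fr$ambiguous_dbs, 0L)  # a retired alias is not ambiguity
})

test_that("resolution equals the undirected-component oracle on random universes", {
  for (s in 1:6) {
    uni <- generate_universe(universe_spec(
      n_compounds = 40, xref_density = 0.6, frac_fork = 0.1, frac_isolated = 0.1,
      frac_retired = 0.1, one_way_frac = 0.4, seed = 400 + s))
    comps <- oracle_components(uni$store)
    for (seed_row in universe_seed_rows(uni)) {
      fr <- resolve_row(single_row_cells(seed_row$db, seed_row$id), uni$store)
      expect_identical(fr$cells,
                       oracle_cells(comps, paste0(seed_row$db, "::", seed_row$id)))
    }
  }
})

test_that("cells only grow, inputs survive, and re-resolution is a fixpoint", {
  uni <- generate_universe(universe_spec(n_compounds = 50, one_way_frac = 0.5,
                                         frac_retired = 0.1, seed = 55))
  rows <- universe_seed_rows(uni)[1:20]
  tab <- identifier_table(lapply(rows, function(r)
    stats::setNames(list(r$id), r$db)))
  res <- resolve_table(tab, uni$store)
  for (i in seq_along(rows)) {
    inp <- row_cells(tab, i); out <- row_cells(res$table, i)
    for (d in db_tags()) expect_true(all(inp[[d]] %in% out[[d]]))
  }
  res2 <- resolve_table(res$table, uni$store)
  expect_identical(as.data.frame(res2$table), as.data.frame(res$table))
  expect_equal(nrow(res2$secondary_hits), nrow(res$secondary_hits))
})

test_that("queue pops are bounded by the distinct reachable identifiers", {
  uni <- generate_universe(universe_spec(n_compounds = 50, seed = 66))
  for (seed_row in universe_seed_rows(uni)[1:20]) {
    fr <- resolve_row(single_row_cells(seed_row$db, seed_row$id), uni$store)
    expect_lte(fr$iterations, sum(lengths(fr$cells)))
    expect_false(fr$capped)
  }
})

test_that("row order does not change any row's resolution", {
  uni <- generate_universe(universe_spec(n_compounds = 30, one_way_frac = 0.3, seed = 77))
  rows <- universe_seed_rows(uni)
  cells <- lapply(rows, function(r) stats::setNames(list(r$id), r$db))
  tab <- identifier_table(cells)
  perm <- rev(seq_along(cells))
  tab_perm <- identifier_table(cells[perm])
  res <- resolve_table(tab, uni$store)
  res_perm <- resolve_table(tab_perm, uni$store)
  a <- as.data.frame(res$table); b <- as.data.frame(res_perm$table)
  for (i in seq_along(cells))
    expect_identical(a[i, db_tags()], b[match(i, perm), db_tags()],
                     ignore_attr = TRUE)
})

test_that("fully empty rows are flagged, never dropped; empty tables error", {
  st <- chain_store()
  tab <- identifier_table(list(list(), list(HMDB = "HMDB0000001")))
  res <- resolve_table(tab, st)
  expect_identical(res$row_info$status, c("empty_input", "complete"))
  expect_equal(n_rows(res$table), 2L)
  expect_error(resolve_table(structure(list(rows = list()), class = "identifier_table"), st))
})

test_that("a transport error is logged distinctly and never aborts the row", {
  st <- chain_store()
  tr <- mock_transport(handler = function(...) list(status = 503L, body = ""))
  remote <- remote_backend(tr, remote_config(rate_limit_s = 0, max_retries = 2L))
  cells <- single_row_cells("HMDB", "HMDB0000001")
  cells$KEGG <- "C55555"  # unknown locally, unreachable remotely
  fr <- resolve_row(cells, st, remote = remote)
  expect_identical(fr$transport_errors, data.frame(db = "KEGG", id = "C55555",
                                                   stringsAsFactors = FALSE))
  expect_false("C55555" %in% fr$unresolved$id)
  expect_identical(fr$cells$CHEBI, "CHEBI:15377")  # rest of the row still resolved
})

test_that("remote fetches fill rows and later rows hit the cache", {
  st <- local_store()
  upsert_record(st, compound_record("HMDB", "HMDB0000122", xrefs = list(KEGG = "C00031")))
  body <- paste("ENTRY       C00031  Compound", "DBLINKS     ChEBI: 4167", sep = "\n")
  tr <- mock_transport(list("kegg://test/get/C00031" = list(status = 200L, body = body)))
  remote <- remote_backend(tr, remote_config(kegg_base_url = "kegg://test",
                                             rate_limit_s = 0))
  tab <- identifier_table(list(list(HMDB = "HMDB0000122"), list(KEGG = "C00031")))
  res <- resolve_table(tab, st, remote = remote)
  expect_identical(row_cells(res$table, 1)$CHEBI, "CHEBI:4167")
  expect_identical(row_cells(res$table, 2)$CHEBI, "CHEBI:4167")
  expect_identical(tr$calls, 1L)
})
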