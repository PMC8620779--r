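test_that("upsert merges records idempotently and unions their content", {
  st <- local_store()
  a <- compound_record("HMDB", "HMDB0000001", xrefs = list(KEGG = "C00001"))
  upsert_record(st, a)
  upsert_record(st, a)
  expect_equal(store_size(st), 1L)
  a2 <- compound_record("HMDB", "HMDB0000001", xrefs = list(KEGG = "C00001",
                                                            CHEBI = "15377"))
  upsert_record(st, a2)
  expect_equal(store_size(st), 1L)
  rec <- lookup_primary(st, "HMDB", "HMDB0000001")
  expect_identical(rec$xrefs, list(CHEBI = "CHEBI:15377", KEGG = "C00001"))
  upsert_record(st, compound_record("HMDB", "HMDB0000002"))
  expect_equal(store_size(st), 2L)
})

test_that("conflicting structure strings keep the first-seen value and log, never fail", {
  st <- local_store()
  upsert_record(st, compound_record("KEGG", "C00001", smiles = "O"))
  upsert_record(st, compound_record("KEGG", "C00001", smiles = "OCC"))
  expect_identical(lookup_primary(st, "KEGG", "C00001")$smiles, "O")
  expect_length(st$conflicts, 1L)
  # a blank slot is filled, not a conflict
  upsert_record(st, compound_record("KEGG", "C00001", inchi = "InChI=1S/H2O"))
  expect_identical(lookup_primary(st, "KEGG", "C00001")$inchi, "InChI=1S/H2O")
  expect_length(st$conflicts, 1L)
})

test_that("primary lookup never consults the secondary index", {
  st <- local_store()
  upsert_record(st, compound_record("HMDB", "HMDB0000002",
                                    secondary_ids = "HMDB0099999"))
  expect_null(lookup_primary(st, "HMDB", "HMDB0099999"))
  expect_identical(lookup_primary(st, "HMDB", "HMDB0000002")$primary_id, "HMDB0000002")
  hits <- lookup_secondary(st, "HMDB", "HMDB0099999")
  expect_length(hits, 1L)
  expect_false(attr(hits, "ambiguous"))
  expect_length(lookup_secondary(st, "HMDB", "HMDB0011111"), 0L)
})

test_that("a secondary id shared by two records returns both, flagged ambiguous", {
  st <- local_store()
  upsert_record(st, compound_record("CHEBI", "CHEBI:1", secondary_ids = "CHEBI:900"))
  upsert_record(st, compound_record("CHEBI", "CHEBI:2", secondary_ids = "CHEBI:900"))
  hits <- lookup_secondary(st, "CHEBI", "CHEBI:900")
  expect_length(hits, 2L)
  expect_true(attr(hits, "ambiguous"))
  # oracle: a linear scan over all records claiming the id
  scan <- Filter(function(k) {
    r <- get(k, envir = st$records)
    "CHEBI:900" %in% r$secondary_ids
  }, ls(st$records))
  expect_setequal(vapply(hits, `[[`, "", "primary_id"),
                  sub("^CHEBI::", "", scan))
})

test_that("reverse xref lookup equals a brute-force scan on random stores", {
  set.seed(11)
  for (trial in 1:3) {
    uni <- generate_universe(universe_spec(n_compounds = 60, seed = 200 + trial))
    st <- uni$store
    keys <- ls(st$records)
    # pick random (target, xref_db, xref_id) probes, half from real edges
    tabs <- store_tables(st)
    probes <- list()
    if (nrow(tabs$xrefs)) {
      idx <- sample(nrow(tabs$xrefs), min(20, nrow(tabs$xrefs)))
      for (i in idx) probes[[length(probes) + 1L]] <-
        list(t = tabs$xrefs$source_db[i], x = tabs$xrefs$xref_db[i],
             id = tabs$xrefs$xref_id[i])
    }
    probes[[length(probes) + 1L]] <- list(t = "HMDB", x = "KEGG", id = "C99999")
    for (p in probes) {
      if (p$t == p$x) next
      got <- vapply(lookup_by_xref(st, p$t, p$x, p$id), `[[`, "", "primary_id")
      want <- sort(unlist(lapply(keys, function(k) {
        r <- get(k, envir = st$records)
        if (r$source_db == p$t && p$id %in% r$xrefs[[p$x]]) r$primary_id else NULL
      })))
      expect_identical(got, if (is.null(want)) character() else want)
    }
  }
})

test_that("incrementally maintained indexes equal a from-scratch rebuild", {
  uni <- generate_universe(universe_spec(n_compounds = 80, frac_retired = 0.2,
                                         seed = 31))
  st <- uni$store
  # extra merging upserts on top of the generated content
  upsert_record(st, compound_record("KEGG", "C00001", xrefs = list(CHEBI = "10001")))
  upsert_record(st, compound_record("KEGG", "C00001", xrefs = list(HMDB = "HMDB0000001")))
  expect_identical(live_indexes(st), rebuild_indexes(st))
})

test_that("store serialization round-trips and is byte-deterministic", {
  uni <- generate_universe(universe_spec(n_compounds = 40, frac_retired = 0.15,
                                         seed = 17))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir(); d3 <- withr::local_tempdir()
  write_store(uni$store, d1)
  back <- read_store(d1)
  expect_true(store_equal(uni$store, back, provenance = TRUE))
  write_store(back, d2)
  write_store(uni$store, d3)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d2, f)), readLines(file.path(d1, f)))
    expect_identical(readLines(file.path(d3, f)), readLines(file.path(d1, f)))
  }
})
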