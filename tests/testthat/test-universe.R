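test_that("planted classes are realized at the exact rounded counts", {
  spec <- universe_spec(n_compounds = 100, frac_fork = 0.1, frac_isolated = 0.2,
                        frac_retired = 0.1, seed = 1)
  uni <- generate_universe(spec)
  counts <- table(uni$truth$compounds$class)
  expect_equal(counts[["fork"]], 10L)
  expect_equal(counts[["isolated"]], 20L)
  expect_equal(counts[["retired"]], 10L)
  expect_equal(counts[["clean"]], 60L)
  # isolated compounds: xref-free records, never referenced
  iso <- uni$truth$compounds$compound[uni$truth$compounds$class == "isolated"]
  mem <- uni$truth$memberships
  iso_ids <- mem$primary_id[mem$compound %in% iso]
  expect_false(any(uni$truth$edges$src_id %in% iso_ids))
  expect_false(any(uni$truth$edges$dst_primary %in% iso_ids))
  # fork compounds: exactly one database holds two records
  for (i in uni$truth$compounds$compound[uni$truth$compounds$class == "fork"]) {
    per_db <- table(mem$db[mem$compound == i])
    expect_equal(sum(per_db == 2), 1L)
  }
})

test_that("the same spec and seed reproduce a byte-identical store", {
  spec <- universe_spec(n_compounds = 40, frac_retired = 0.1, seed = 9)
  u1 <- generate_universe(spec)
  u2 <- generate_universe(spec)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_store(u1$store, d1); write_store(u2$store, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  expect_identical(u1$truth$edges, u2$truth$edges)
  u3 <- generate_universe(universe_spec(n_compounds = 40, frac_retired = 0.1, seed = 10))
  expect_false(store_equal(u1$store, u3$store))
})

test_that("infeasible specs are rejected", {
  expect_error(universe_spec(frac_fork = 0.6, frac_isolated = 0.5), "exceed 1")
  expect_error(universe_spec(xref_density = 1.2), "\\[0,1\\]")
  expect_error(universe_spec(db_presence = c(HMDB = 0.5)), "five tags")
})

test_that("on a clean fully-linked universe the resolver reproduces the truth exactly", {
  uni <- generate_universe(universe_spec(
    n_compounds = 60, xref_density = 1, frac_fork = 0, frac_isolated = 0,
    frac_retired = 0, one_way_frac = 0, seed = 14))
  mem <- uni$truth$memberships
  for (i in unique(mem$compound)) {
    m <- mem[mem$compound == i, ]
    fr <- resolve_row(single_row_cells(m$db[1], m$primary_id[1]), uni$store)
    for (d in db_tags())
      expect_identical(fr$cells[[d]], sort(m$primary_id[m$db == d]))
  }
})

test_that("fully one-way universes resolve strictly better with the reverse flow", {
  uni <- generate_universe(universe_spec(
    n_compounds = 60, xref_density = 1, frac_isolated = 0, frac_fork = 0,
    frac_retired = 0, one_way_frac = 1, seed = 23))
  comps <- oracle_components(uni$store)
  strictly_poorer <- 0L
  for (seed_row in universe_seed_rows(uni)) {
    cells <- single_row_cells(seed_row$db, seed_row$id)
    full <- resolve_row(cells, uni$store)$cells
    fwd <- resolve_row(cells, uni$store, reverse = FALSE)$cells
    for (d in db_tags()) expect_true(all(fwd[[d]] %in% full[[d]]))
    if (sum(lengths(fwd)) < sum(lengths(full))) strictly_poorer <- strictly_poorer + 1L
    expect_identical(full, oracle_cells(comps, paste0(seed_row$db, "::", seed_row$id)))
  }
  expect_gt(strictly_poorer, 0L)
})

test_that("exported dump dialects load back to the directly-built store", {
  for (s in 1:3) {
    uni <- generate_universe(universe_spec(n_compounds = 50, frac_fork = 0.1,
                                           frac_retired = 0.15, seed = 500 + s))
    d <- withr::local_tempdir()
    files <- export_dump_dialects(uni, d)
    st <- local_store()
    load_hmdb_xml(files[["hmdb"]], st)
    load_chebi_tables(files[["chebi_compounds"]], files[["chebi_names"]],
                      files[["chebi_accessions"]], st)
    load_lipidmaps_sdf(files[["lipidmaps"]], st)
    expect_true(store_equal(uni$store, st, dbs = c("HMDB", "CHEBI", "LIPIDMAPS")))
  }
})

test_that("dump exports are schema-valid even for minimal universes", {
  uni <- generate_universe(universe_spec(
    n_compounds = 2, db_presence = c(HMDB = 1, CHEBI = 1, KEGG = 1,
                                     PUBCHEM = 1, LIPIDMAPS = 0),
    frac_fork = 0, frac_isolated = 0, frac_retired = 0, seed = 2))
  d <- withr::local_tempdir()
  files <- export_dump_dialects(uni, d)
  st <- local_store()
  expect_equal(load_lipidmaps_sdf(files[["lipidmaps"]], st)$n_parsed, 0L)
  expect_equal(load_hmdb_xml(files[["hmdb"]], st)$n_inserted, 2L)
  # SDF block count equals the LIPID MAPS record count
  uni2 <- generate_universe(universe_spec(n_compounds = 30, seed = 3))
  files2 <- export_dump_dialects(uni2, withr::local_tempdir())
  n_blocks <- sum(trimws(readLines(files2[["lipidmaps"]])) == "$$$$")
  expect_equal(n_blocks, length(store_ids(uni2$store, "LIPIDMAPS")))
})
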