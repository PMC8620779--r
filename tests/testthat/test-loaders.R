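hmdb_fixture <- function(path) {
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    "<hmdb>",
    "  <metabolite>",
    "    <accession>HMDB00001</accession>",
    "    <secondary_accessions><accession>HMDB04990</accession></secondary_accessions>",
    "    <name>1-Methylhistidine</name>",
    "    <smiles>CN1C=NC(C[C@H](N)C(O)=O)=C1</smiles>",
    "    <kegg_id>C01152</kegg_id>",
    "    <chebi_id>50599</chebi_id>",
    "    <pubchem_compound_id>92105</pubchem_compound_id>",
    "  </metabolite>",
    "  <metabolite>",
    "    <name>orphan without accession</name>",
    "  </metabolite>",
    "  <metabolite>",
    "    <accession>HMDB00002</accession>",
    "    <name>1,3-Diaminopropane</name>",
    "  </metabolite>",
    "</hmdb>"), path)
  path
}

test_that("HMDB XML loader parses accessions, secondaries and foreign ids", {
  st <- local_store()
  rep <- load_hmdb_xml(hmdb_fixture(withr::local_tempfile(fileext = ".xml")), st)
  expect_equal(rep$n_parsed, 3L)
  expect_equal(rep$n_inserted, 2L)
  expect_equal(rep$n_malformed, 1L)
  expect_equal(rep$n_parsed, rep$n_inserted + rep$n_malformed)
  rec <- lookup_primary(st, "HMDB", "HMDB0000001")  # 5-digit accession padded
  expect_identical(rec$secondary_ids, "HMDB0004990")
  expect_identical(rec$xrefs$KEGG, "C01152")
  expect_identical(rec$xrefs$CHEBI, "CHEBI:50599")
  expect_identical(rec$xrefs$PUBCHEM, "92105")
  expect_identical(rec$names, "1-Methylhistidine")
})

test_that("malformed or empty HMDB XML fails and leaves the store untouched", {
  st <- local_store()
  upsert_record(st, compound_record("HMDB", "HMDB0000009"))
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<hmdb><metabolite>", bad)
  expect_error(load_hmdb_xml(bad, st))
  empty <- withr::local_tempfile(fileext = ".xml")
  writeLines(character(), empty)
  expect_error(load_hmdb_xml(empty, st))
  expect_equal(store_size(st), 1L)
})

chebi_fixture <- function(dir) {
  comp <- file.path(dir, "compounds.tsv")
  nms <- file.path(dir, "names.tsv")
  acc <- file.path(dir, "accessions.tsv")
  writeLines(c("ID\tNAME\tSTATUS\tPARENT_ID",
               "15377\twater\tC\tnull",
               "44701\t\tO\t15377",      # merged child -> secondary of parent
               "99998\told entry\tO\tnull",  # obsolete without parent -> dropped
               "16236\tethanol\tC\tnull"), comp)
  writeLines(c("COMPOUND_ID\tNAME", "15377\toxidane", "16236\tethyl alcohol"), nms)
  writeLines(c("COMPOUND_ID\tTYPE\tACCESSION_NUMBER",
               "15377\tKEGG COMPOUND accession\tC00001",
               "15377\tHMDB accession\tHMDB02111",
               "15377\tCAS Registry Number\t7732-18-5",  # ignored type
               "16236\tPubchem accession\t702"), acc)
  list(comp = comp, nms = nms, acc = acc)
}

test_that("ChEBI table loader merges children, unions names, maps accession types", {
  d <- withr::local_tempdir()
  f <- chebi_fixture(d)
  st <- local_store()
  rep <- load_chebi_tables(f$comp, f$nms, f$acc, st)
  expect_equal(rep$n_parsed, 4L)
  expect_equal(rep$n_inserted, 3L)  # two live + one merged child
  expect_equal(rep$n_parsed, rep$n_inserted + rep$n_malformed)
  water <- lookup_primary(st, "CHEBI", "CHEBI:15377")
  expect_identical(water$secondary_ids, "CHEBI:44701")
  expect_setequal(water$names, c("water", "oxidane"))
  expect_identical(water$xrefs$KEGG, "C00001")
  expect_identical(water$xrefs$HMDB, "HMDB0002111")
  expect_null(water$xrefs$PUBCHEM)  # CAS ignored, nothing else planted
  expect_null(lookup_primary(st, "CHEBI", "CHEBI:99998"))
  expect_identical(lookup_primary(st, "CHEBI", "CHEBI:16236")$xrefs$PUBCHEM, "702")
})

test_that("a ChEBI table missing a required column names the column", {
  d <- withr::local_tempdir()
  f <- chebi_fixture(d)
  broken <- file.path(d, "broken.tsv")
  writeLines(c("ID\tNAME\tSTATUS", "15377\twater\tC"), broken)
  st <- local_store()
  expect_error(load_chebi_tables(broken, f$nms, f$acc, st), "PARENT_ID")
  expect_equal(store_size(st), 0L)
})

sdf_fixture <- function(path) {
  writeLines(c(
    "LMFA01010001", "  synthetic", "",
    "  0  0  0  0  0  0  0  0  0  0999 V2000", "M  END",
    "> <LM_ID>", "LMFA01010001", "",
    "> <NAME>", "Palmitic acid", "",
    "> <PUBCHEM_CID>", "985", "",
    "> <HMDB_ID>", "HMDB00220", "",
    "$$$$",
    "no LM_ID here", "", "",
    "  0  0  0  0  0  0  0  0  0  0999 V2000", "M  END",
    "> <NAME>", "orphan", "",
    "$$$$"), path)
  path
}

test_that("SDF loader reads data fields, normalizes foreign ids, skips blocks without LM_ID", {
  st <- local_store()
  rep <- load_lipidmaps_sdf(sdf_fixture(withr::local_tempfile(fileext = ".sdf")), st)
  expect_equal(rep$n_parsed, 2L)
  expect_equal(rep$n_inserted, 1L)
  expect_equal(rep$n_malformed, 1L)
  rec <- lookup_primary(st, "LIPIDMAPS", "LMFA01010001")
  expect_identical(rec$xrefs$PUBCHEM, "985")
  expect_identical(rec$xrefs$HMDB, "HMDB0000220")  # normalized to 7 digits
  expect_identical(rec$names, "Palmitic acid")
})

test_that("loaders only touch their own database plus merged xrefs", {
  st <- local_store()
  upsert_record(st, compound_record("KEGG", "C00001", xrefs = list(CHEBI = "15377")))
  before <- store_tables(st, dbs = c("KEGG", "PUBCHEM"))
  load_lipidmaps_sdf(sdf_fixture(withr::local_tempfile(fileext = ".sdf")), st)
  expect_identical(store_tables(st, dbs = c("KEGG", "PUBCHEM")), before)
})
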