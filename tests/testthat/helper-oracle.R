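# Independent brute-force oracle for resolution: connected components of the
# undirected graph whose edges link each record to its cross-references and
# to its secondary accessions. Built with igraph from the store's flat
# tables — it never touches the queue-based resolver it checks.

oracle_components <- function(store) {
  tabs <- store_tables(store)
  key <- function(db, id) paste0(db, "::", id)
  e1 <- if (nrow(tabs$secondary))
    cbind(key(tabs$secondary$source_db, tabs$secondary$primary_id),
          key(tabs$secondary$source_db, tabs$secondary$secondary_id)) else NULL
  e2 <- if (nrow(tabs$xrefs))
    cbind(key(tabs$xrefs$source_db, tabs$xrefs$primary_id),
          key(tabs$xrefs$xref_db, tabs$xrefs$xref_id)) else NULL
  edges <- rbind(e1, e2)
  verts <- unique(c(key(tabs$records$source_db, tabs$records$primary_id),
                    as.vector(edges)))
  g <- if (is.null(edges)) igraph::make_empty_graph(directed = FALSE)
       else igraph::graph_from_edgelist(edges, directed = FALSE)
  missing <- setdiff(verts, igraph::V(g)$name)
  g <- igraph::add_vertices(g, length(missing), name = missing)
  comp <- igraph::components(g)
  split(names(comp$membership), comp$membership)
}

# Expected filled cells for a row seeded with node keys "DB::id": the union
# of every component containing a seed, grouped by database.
oracle_cells <- function(comps, seed_keys) {
  hit <- unlist(lapply(comps, function(nodes) if (any(seed_keys %in% nodes)) nodes))
  nodes <- union(hit, seed_keys)
  out <- stats::setNames(rep(list(character()), length(db_tags())), db_tags())
  for (n in nodes) {
    p <- strsplit(n, "::", fixed = TRUE)[[1]]
    out[[p[1]]] <- sort(c(out[[p[1]]], p[2]))
  }
  out
}

single_row_cells <- function(db, id) {
  cells <- stats::setNames(rep(list(character()), length(db_tags())), db_tags())
  cells[[db]] <- id
  cells
}

# One seeded single-id row per compound of a universe, drawn from its
# ground-truth memberships (first membership in tag order).
universe_seed_rows <- function(uni) {
  mem <- uni$truth$memberships
  lapply(unique(mem$compound), function(i) {
    m <- mem[mem$compound == i, ][1, ]
    list(compound = i, db = m$db, id = m$primary_id)
  })
}

# A small hand-built store: glucose-like chain across the five databases.
chain_store <- function() {
  st <- local_store()
  upsert_record(st, compound_record("HMDB", "HMDB0000001", xrefs = list(KEGG = "C00001")))
  upsert_record(st, compound_record("KEGG", "C00001",
                                    xrefs = list(CHEBI = "15377", PUBCHEM = "962")))
  upsert_record(st, compound_record("CHEBI", "CHEBI:15377",
                                    xrefs = list(LIPIDMAPS = "LMFA00000001")))
  upsert_record(st, compound_record("PUBCHEM", "962"))
  upsert_record(st, compound_record("LIPIDMAPS", "LMFA00000001"))
  st
}
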