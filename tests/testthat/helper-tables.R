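# Random sparse identifier tables (independent of any store) for exercising
# the mapping metrics against brute-force recounts.
random_table <- function(n, p_fill = 0.5, multi = FALSE) {
  rows <- lapply(seq_len(n), function(i) {
    cells <- list()
    for (tag in db_tags()) {
      if (stats::runif(1) < p_fill) {
        k <- if (multi && stats::runif(1) < 0.3) 2L else 1L
        cells[[tag]] <- vapply(sample.int(50, k), function(j) switch(tag,
          HMDB = sprintf("HMDB%07d", j), CHEBI = paste0("CHEBI:", j),
          KEGG = sprintf("C%05d", j), PUBCHEM = as.character(j),
          LIPIDMAPS = sprintf("LMFA%08d", j)), "")
      }
    }
    cells
  })
  identifier_table(rows)
}
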