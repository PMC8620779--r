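---
title: "Queue-based resolution of small-compound identifiers: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Queue-based resolution of small-compound identifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metamapr)
```

## The problem and the data model

Five public small-compound databases — HMDB, ChEBI, KEGG, PubChem and
LIPID MAPS — each keep their own accession scheme for metabolites, plus
*cross-references* (xrefs) to the putatively same compound elsewhere.
These xrefs are incomplete, frequently one-directional, and accessions are
retired over time while remaining in circulation in published datasets.
`metamapr` models a database entry as a `compound_record`: home database,
current primary accession, retired *secondary* accessions, names,
structure strings (SMILES/InChI/InChIKey), and a per-database set of
foreign identifiers. Structure strings are payload only — they never
participate in matching. Chemistry-aware identity (tautomers, salts,
InChIKey reconciliation) is explicitly out of scope: two records are the
"same compound" exactly when the reference graph says so.

Records live in a `local_store`, the cache tier of the system: an embedded,
environment-backed map with two derived indexes (secondary accession →
current primary; foreign id → the records carrying it). A server-backed
relational store would work identically behind the same five-function
surface (`upsert_record`, `lookup_primary`, `lookup_secondary`,
`lookup_by_xref`, plus serialization); the embedded one keeps the package
dependency-free and the on-disk form (a directory of sorted TSVs with a
schema version) diff-able and byte-deterministic.

Identifier dialects differ in the wild (5- versus 7-digit HMDB accessions,
bare ChEBI integers, `cpd:`-prefixed KEGG ids), so every identifier
crossing a package boundary is canonicalized once by `normalize_id()`:
HMDB as `HMDB` + 7 digits, ChEBI as `CHEBI:` + integer, KEGG as `C` + 5
digits, PubChem as the bare CID, LIPID MAPS accessions upper-cased
verbatim. Normalization is idempotent, and malformed identifiers carry a
typed condition with the offending database and value rather than a bare
string error.

## The resolution procedure

For each input row the resolver runs a **main flow**: a FIFO queue is
seeded with the row's known identifiers (database-tag order, then
lexicographic order — ties broken this way purely for reproducibility; no
ordering claim is scientific). Popping `(db, id)` looks the identifier up
as a primary accession, then as a secondary accession; the matched record's
primary id, secondary ids and xrefs all join the row's cells, and each
newly seen identifier is enqueued. A visited set bounds work by the number
of distinct reachable identifiers. When the queue drains, an **exceptional
flow** issues reverse queries — which records of database *t* cross-reference
an identifier the row already holds? — absorbs the hits and re-runs the
main flow, iterating to a fixpoint (a cap of 10 passes exists as a safety
net and is flagged if ever hit; two passes suffice in practice).

Three design points here were genuinely open and are worth stating:

* **Reverse queries target all five databases, not only the still-empty
  cells.** Restricting the reverse pass to empty cells would make it
  blind to a second same-database record reachable only backwards — which
  is precisely an ambiguity the user should see. With the unrestricted
  pass, resolution has a clean closed form: the filled cells equal the
  connected component of the input identifiers in the undirected graph
  whose edges join each record to its xrefs and to its secondary
  accessions. That equivalence is what the test suite checks against an
  independent igraph BFS oracle on randomized universes.
* **Retired aliases stay in the cells.** A matched record contributes its
  secondary accessions to the row (they are identifiers of that compound,
  and datasets in circulation still use them), and every use of the
  secondary index is logged in `secondary_hits`. Consequently *ambiguity
  is judged on distinct matched records per database*, not raw cell
  cardinality — an alias next to its current primary is not a fork.
* **Ambiguity is accumulated, never scored or pruned.** All candidate
  records are kept and flagged; choosing among them is curation, not
  resolution.

Unresolved identifiers (queried, found nowhere) and transport failures are
tracked separately — a failed HTTP call is a different fact about the data
than an identifier that genuinely has no record, and only the former can
disappear on re-run. Rows resolve independently; input cells are never
overwritten, so resolution is monotone and idempotent.

Remote fetching applies to KEGG and PubChem only (the three dump-backed
databases are assumed complete locally). Fetches go through a pluggable
transport — the shipped live transport shells out to `curl`; tests and all
offline workflows use a counting mock — and write through to the store, so
any identifier costs at most one successful network call per store
lifetime. Negative results are memoized for the session but never
persisted: databases gain entries over time. The default rate limit of
0.35 s between requests follows PubChem's courtesy limit of at most three
requests per second; retries back off geometrically (factor 2, 3 attempts).

## Metrics and the quality audit

The four mapping measures are literal counting definitions (non-empty
fields over total rows; their complement; the unweighted mean over the k
identifier types considered; and agreement with a comparator tool divided
by the *comparator's* non-empty count). Two conventions are ours: a
multi-valued cell matches a comparator cell when the intersection is
non-empty, and the asymmetric denominator is kept exactly as defined, so
`matching_percentage(x, y, d)` and `matching_percentage(y, x, d)` answer
different questions. A duplicated-term typo in the printed form of the
average is resolved to the plain mean, per its prose definition.

The quality audit draws `n_per_replicate` identifiers uniformly without
replacement from one database, resolves each as a single-identifier row
offline, and classifies it: *ambiguous* if any other database matched more
than one record, else *unresolved* if no other database yielded anything,
else *consistent*. The defaults (1000 identifiers, 100 replicates) mirror
a full-scale audit; replicate r re-seeds the RNG with `seed + r - 1`, so
reports are exactly reproducible and replicates independent. Note the
deliberately permissive reading of *consistent*: a row resolved one-to-one
in two databases and empty in the rest counts as consistent, because
unresolved is defined as failure in **all** other databases. This inflates
consistency relative to a stricter "fully filled" reading; anyone wanting
the stricter number can recompute it from the per-row output.

## The synthetic universe generator

`generate_universe()` builds a five-database world with known ground truth,
emulating the pathologies the resolver exists to handle: **fork** compounds
(two records in one database — the ambiguity mode), **isolated** compounds
(records carrying and receiving no xrefs — the unresolved mode),
**retired** compounds (one record referenced only through a secondary
accession), one-way xref edges (recoverable only by the reverse pass) and
sub-unit `xref_density` (links simply missing). Compounds are partitioned
into the planted classes *first* and structure is sampled second, so
planted fractions are realized exactly after rounding — sharper tests than
in-expectation planting.

Default parameters are chosen to look like a realistic targeted-panel
world: per-database presence probabilities (HMDB 0.90, ChEBI 0.85, KEGG
0.80, PubChem 0.95, LIPID MAPS 0.40 — lipids are a minority of a typical
panel), `xref_density` 0.7, 5% forks, 15% isolated, 5% retired, 25%
one-way edges. Two structural constraints mirror the real dump formats:
HMDB records never carry a LIPID MAPS xref (the HMDB metabolite XML has no
such field — the link lives on the LIPID MAPS side and is recovered in
reverse), and retired accessions are planted only in HMDB/ChEBI, the two
dump dialects that can express them. What the generator does *not*
emulate: real chemistry (names and structure strings are synthetic
tokens), cross-*compound* reference errors (an xref pointing at a genuinely
different compound), shared secondary accessions, and the scale and
curation biases of the real databases. Passing tests therefore demonstrate
algorithmic correctness on the stated graph semantics, not the empirical
quality of any real database snapshot — audits of real data require
loading the real dumps.

Dump export (`export_dump_dialects()`) writes the HMDB XML, ChEBI
flat-table and LIPID MAPS SDF dialects such that loading them back equals
direct insertion, which pins the loaders' semantics. In the ChEBI dialect
a merged child is a row whose `PARENT_ID` is set (becoming a secondary
accession of the parent); a row with status `O` and no parent is dropped.
Load reports keep the invariant `parsed = inserted + not-inserted`, with
the not-inserted bucket carrying human-readable reasons (malformed id,
obsolete, missing accession). Loads are transactional per file: a hard
parse failure leaves the store untouched.

## Numerical and testing choices

Everything user-visible is deterministic: fixed tag order for columns and
queue seeding, sorted iteration everywhere, seeded RNG for every stochastic
step, and sorted TSV serialization — identical runs give byte-identical
files. Degenerate inputs have defined behaviour rather than surprises:
empty rows are flagged and passed through, empty tables error, an absent
identifier is a value (`NULL` / empty set), and a zero-row metric is an
error rather than `NaN`.

Test problem sizes were picked to exercise the properties at a scale where
failures are not plausible flukes while keeping the default suite quick:
resolver-oracle equivalence on 50 random universes of 20–80 compounds
(roughly 1,000 resolved rows against the BFS oracle), metric recounts on
1,000 random tables, planted-fraction recovery at 200 identifiers × 50
replicates against a 1,000-compound universe (mean within three binomial
standard errors of the planted 60/20/20), ten-universe dump round-trips,
and run-to-run byte determinism. `scripts/acceptance.R` re-runs the same
computations from scratch under a caller-provided seed.

## Known limitations

* Matching is purely reference-graph based; a wrong xref in a source
  database propagates (the audit surfaces it as ambiguity at best).
* An identifier that is simultaneously a primary accession of one record
  and a secondary accession of another resolves to the primary only — the
  secondary index is a fallback, not a union.
* The permissive consistency definition above.
* Negative remote results are only memoized per session, so a missing
  remote identifier is re-asked once per run.
* The live transport is deliberately minimal (GET + status code via
  `curl`); anything fancier (auth, bulk endpoints) belongs in a custom
  transport.
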