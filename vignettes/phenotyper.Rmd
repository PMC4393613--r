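---
title: "Design and methods: controlled-vocabulary phenotyping data management"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design and methods: controlled-vocabulary phenotyping data management}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenotyper)
```

## The problem

Field phenotyping produces data that are *sparse* and *volatile*: of
all traits that could be scored on a plant, plot or organ, only a few
are, and the chosen set changes as a project learns which traits are
predictive. Spreadsheet-per-campaign workflows break down here — column
sets drift, free-text trait names diverge, provenance evaporates, and
data die with the intern who collected them. This package implements a
complete pipeline around two ideas:

1. every recorded value is expressed in a **controlled vocabulary**
   (entity scored, attribute measured, categorical value chosen),
   cross-referenced where possible to the Plant Ontology (PO) and Plant
   Trait Ontology (TO) so meanings outlive the project;
2. results are stored **entity–attribute–value (EAV)**: one database
   row per recorded measurement, none for unmeasured parameters.

## Vocabulary and schemes

A `term_registry()` holds terms of kind `entity`, `attribute` or
`value`, each with multilingual labels, an optional CURIE
(`PREFIX:digits`), an optional unit (attributes), and optional
illustrating images (values). Label resolution is deterministic:
requested language, then the registry default, then the first remaining
language by sorted code, so resolution always succeeds. Term ids and
kinds are immutable after creation; labels, definitions and images may
evolve. Project *subsets* restrict which terms a project's schemes can
use — a pragmatic control for large institutional vocabularies.

`compose_scheme()` assembles ordered entity blocks of ordered numeric
or categorical parameters and embeds a snapshot of every referenced
term (label in the scheme language, CURIE, unit, value images). The
snapshot makes scheme files self-contained: capture devices work fully
offline. We fixed one language per scheme; per-parameter language
mixing complicates the capture surface for no clear field benefit, and
a second language is one `clone_scheme()` plus recomposition away.

The XML dialect is ours by necessity — a normative XSD
(`inst/xsd/scheme.xsd`) ships with the package, serialization is
canonical (fixed attribute order, fixed declaration, 2-space indent)
so identical schemes give identical bytes, and
`scheme_from_xml(scheme_to_xml(s))` is an exact identity, which the
test suite checks property-style over randomly generated schemes.
Duplicate scheme names are allowed; the UUID `scheme_id` is the
identity, because name-based identity punishes the common
clone-and-tweak workflow.

## Capture semantics

The capture engine is a headless re-creation of a mobile data-entry
GUI, with three deliberate contracts:

* **Injected clock.** No function reads ambient time; `device_config()`
  carries a clock closure (`manual_clock()` for deterministic tests,
  `system_clock` in production). Every timestamp behaviour is thereby
  testable to the second.
* **Identifier multiplication.** One scanned id with factor *n* > 1
  expands to `id-1` … `id-n` (hyphen, 1-based); factor 1 leaves the id
  untouched. The (base id, index) provenance is kept structurally, not
  re-parsed from strings, so base ids may themselves contain hyphens.
* **Crash safety.** The session file is rewritten after *every*
  recorded value; `load_session()` restores the full record set. The
  invariant tested is exact: reload after any prefix of entries equals
  the in-memory state.

Numeric entry honours the device decimal separator (`","` keyboards
are common on European devices) but serialized files always use `"."`:
the separator is an input affordance, not a file format. Categorical
entry accepts a domain value id or its label in the scheme language and
stores the id. Re-recording a key overwrites — last write wins, no
history at capture stage; history begins at QC, where it matters for
accountability.

Results are written twice: a wide csv (one row per identifier, three
header rows — entity labels, attribute labels with units, machine
term-id keys) for spreadsheets and statistics packages, and an XML
document (XSD: `inst/xsd/results.xsd`) where every measurement is
tagged with its term ids, making parsing order-independent and sparse
objects representable without placeholders. `merge_result_tables()`
unions csv columns across schemes in first-appearance order and leaves
cells empty where a variable is absent from a row's source scheme;
duplicate identifiers across merged files abort with a conflict rather
than silently overwriting — the safer default for a merge whose inputs
were collected independently.

## Quality control

`apply_qc()` never edits in place: the raw device file is immutable
(checksum asserted before and after; writing the curated file over the
raw path is refused), and every change is one `edit_log()` entry with
the targeted record, the expected old value, the new value and a
reason. The old-value match is deliberate: an edit written against a
stale view of the data fails loudly instead of corrupting silently.
The log is persisted beside the curated file, so the raw→curated delta
is reproducible — the suite checks that applying the log to the parsed
raw records with an independent in-memory oracle yields exactly the
curated record set.

## The results store

The store is an embedded SQLite file (RSQLite) with tables for users,
projects, m:n memberships, the mirrored vocabulary, dataset metadata
(owner, project, upload stamp, raw/curated paths and SHA-256
checksums, row count) and the EAV rows themselves. Design choices:

* **Typed EAV.** Numeric and categorical values occupy separate typed
  columns with a kind discriminator, instead of one text column:
  numerics stay lossless and sortable in SQL.
* **Vocabulary mirroring.** `mirror_to_store()` copies the registry
  (ids preserved) into the store, so results remain interpretable with
  no access to the vocabulary's source; a store should mirror from one
  source only to avoid id ambiguity.
* **Atomic ingest.** A dataset inserts all rows or none
  (`dbWithTransaction`); an unresolvable term rejects the whole
  upload. Duplicate uploads are caught by curated-file checksum and
  need an explicit `force`.
* **Opaque identifiers.** Object ids are text; a small
  `object_metadata` hook table links them to external information
  (field plans, sample sheets) without importing any LIMS schema.

`query_eav()` applies the conjunction of optional filters with a
stable result order; the suite holds it equal to a brute-force scan of
the flat row list over hundreds of random filters. `pivot_wide()`
produces the wide export view, labelling columns and categorical
values through the mirror; conflicting duplicate values for the same
(identifier, entity, attribute) abort with the offenders listed, while
identical duplicates (the same observation ingested in two datasets)
collapse.

## Access policy

A dataset is readable by a user at instant *t* iff

> owner(user, dataset) ∨ member(user, dataset.project) ∨
> *t* ≥ uploaded_at + embargo_days × 86400 s

with `embargo_days` taken from the project when the dataset has one,
else from the store-level `access_policy()` default. Two boundary
decisions are ours: the embargo instant itself is **open** (≥, not >) —
a closed boundary invites off-by-one-day disputes and the difference is
one second — and the embargo clock runs from the **upload** stamp, the
only timestamp the access layer controls; measurement dates are data,
not policy inputs. The suite enumerates the full
owner × membership × project × {before, at, after} truth table against
an independent evaluation of the three clauses, and checks
monotonicity (access once granted never lapses) plus a no-leak
property: no export contains a row of a dataset the requester may not
read, and withheld data surface as a count only — never as metadata.

The spreadsheet export format is Excel 2003 SpreadsheetML: a
single-file, plain-XML spreadsheet that mainstream spreadsheet
software opens directly. Choosing a text format here is deliberate and
consistent with the package's archival stance; csv remains the
canonical, bit-specified format and both renderings carry identical
cell values (tested).

`ascii_report()` is the archive exit: one dataset as deterministic,
line-oriented UTF-8 — ownership, project, upload stamp, file
checksums, the vocabulary of every referenced term with CURIEs, and
all observations. `read_ascii_report()` is the reference reader; the
suite checks byte-determinism and information-completeness (every EAV
row and dataset field recovered). Layout: `docs/archive_report.md`.

## Synthetic data

All fixtures are generated in code (`fixture_spec()`,
`generate_vocabulary()`, `generate_scheme()`, `simulate_session()`).
Every generator is a pure function of its spec: one seed, split into
stable sub-streams (vocabulary, scheme, session), so adding a
generator never perturbs existing fixtures and identical specs are
byte-identical. Defaults model a small field campaign: a handful of
entities, single-digit attribute counts, 4-value categorical domains,
~40 % categorical parameters, a 10 % missing rate, numeric scores
uniform on [0, 100] rounded to 0.1 (the resolution of typical field
instruments). Synthetic CURIEs use a reserved high-numbered id range
(`PO:9xxxxxx`, `TO:9xxxxxx`) so they can never collide with real
ontology terms; the shipped `seed_vocabulary()` uses genuine PO/TO ids
only where they are well established and leaves the rest user-defined.

`sparse_project_scenario()` encodes the canonical sparse-data story:
phase 1 scores 20 parameters per plant, phase 2 keeps the 5 most
predictive and adds 1 newly discovered — 6 in total. Each phase is a
fully scored single-plant session on its own plant; ingesting them
yields 20 and 6 EAV rows per plant with no schema change in between,
and the combined pivot shows the phase-2 row empty in the 15
discontinued columns. Using distinct plants per phase keeps the pivot
illustration well-defined; re-measuring the same plant over time would
make (identifier, entity, attribute) a time series, which the wide
pivot intentionally refuses as a conflict.

What the simulations do *not* model: realistic trait distributions and
correlations, device failures, barcode mis-scans, and observer effects.
Passing tests therefore demonstrate the correctness of the data
machinery — formats, invariants, policies — not statistical properties
of any real phenotyping campaign.

## Numerical and formatting choices

* Timestamps: POSIXct UTC internally; ISO-8601 with explicit `+00:00`
  offset on disk.
* Numbers serialize as `%.15g`, enough to round-trip every value a
  human can type; the suite checks exact `","`/`"."` entry →
  serialization → parse identity.
* Checksums: SHA-256 hex.
* Scheme/dataset identities: UUIDs.
* Problem sizes in the test and acceptance runs (100 round-trip
  schemes, 100 permutations, 200 random filters, 10 QC fuzz rounds)
  were chosen to exercise each property across its structural cases —
  datatype mixes, entity counts, missing-data patterns — while keeping
  the default suite quick to run during development.

## Known limitations

* Single-writer stores; no concurrency control beyond SQLite's.
* QC supplies the mechanism (edit logs), not plausibility rules; range
  or outlier checks are the analyst's job upstream of `apply_qc()`.
* Deleting vocabulary referenced by existing schemes is not supported;
  terms are append-and-amend.
* The access layer trusts the supplied user id; authentication lives
  outside the library.
* Embargo precedence is project-then-default; institution-level
  embargo tiers would need an extra policy source.
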