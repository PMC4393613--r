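# phenotyper

Headless data acquisition and management for field phenotyping.

Phenotyping campaigns score many traits on many biological objects —
plants, plots, leaves, tubers — with parameter sets that change as a
project learns which traits matter. `phenotyper` is an R toolkit for
the whole life cycle of such data, built for research groups that need
field-capable capture, auditable curation and shareable, archivable
results without a LIMS:

* a **controlled vocabulary** of entity, attribute and value terms,
  cross-referenced to the Plant Ontology (PO) and Plant Trait Ontology
  (TO) by CURIEs (e.g. `PO:0025034` = leaf, `TO:0000207` = plant
  height), with multilingual labels and project-specific subsets;
* **phenotyping schemes** — user-composed forms pairing entities with
  numeric or categorical parameters — exchanged as self-contained,
  XSD-validated XML so offline capture devices need no database access;
* a **capture engine** replicating mobile-device entry semantics:
  identifier multiplication (`p42` with factor 2 → `p42-1`, `p42-2`),
  locale-aware numeric entry, label-or-id categorical entry,
  recall/edit, injected clocks, and persistence to permanent storage
  after every value so a crash loses at most the entry in progress;
* a **QC stage** that keeps the raw device file immutable (SHA-256
  asserted) and derives a curated file through a structured, persisted
  edit log — the raw→curated delta stays auditable;
* an **entity–attribute–value (EAV) results store** (embedded SQLite):
  one row per recorded measurement and none for unmeasured parameters,
  so growing or shrinking the parameter set between datasets changes
  row contents, never table definitions. In the canonical sparse
  scenario, 20 parameters per plant at project start become 6 (the 5
  most predictive plus 1 newly discovered) later — 20 then 6 EAV rows
  per plant, same schema, same queries;
* an **access and export layer**: datasets are private to their owner
  by default, shared with project members, and open to everyone once
  the embargo has run out
  (`owner ∨ member(project) ∨ as_of ≥ uploaded_at + embargo_days`);
  exports are filtered, pivoted wide, and rendered as csv or a
  spreadsheet file, plus a deterministic plain-text archive report for
  long-term repositories.

## Worked example

```r
library(phenotyper)

reg <- seed_vocabulary()                      # PO/TO cross-referenced starter vocabulary
scheme <- compose_scheme(
  reg, name = "leaf screen", owner = "ada",
  blocks = list(
    entity_block("e.leaf", list(
      parameter("a.length", "numeric"),
      parameter("a.color", "categorical",
                domain = c("v.green", "v.yellow", "v.brown")))),
    entity_block("e.plant", list(parameter("a.height", "numeric")))),
  clock = manual_clock("2015-04-07T08:00:00+00:00"))
scheme_file <- tempfile(fileext = ".xml")
scheme_to_xml(scheme, scheme_file)
validate_scheme_document(scheme_file)
#> <validation report: ok, 0 finding(s)>

cfg <- device_config("elf01", tempfile("dev"), decimal_separator = ",",
                     clock = manual_clock("2015-04-07T09:00:00+00:00"))
field <- start_session(scheme_file, cfg)
open_object(field, "p42", 2)                  # one scanned id, two plants
#> [1] "p42-1" "p42-2"
record_value(field, "p42-1", "e.leaf", "a.length", "3,5")  # comma keyboard -> 3.5
record_value(field, "p42-1", "e.leaf", "a.color", "yellow") # label -> v.yellow
record_value(field, "p42-2", "e.plant", "a.height", "101")
raw <- write_results_xml(field)

# QC: fix a decimal typo; the raw file stays byte-identical
pair <- apply_qc(raw, edit_log("p42-2", "e.plant", "a.height",
                               "101", "10.1", "decimal typo"),
                 file.path(dirname(raw), "curated.xml"), scheme = scheme)

st <- store_create()
add_user(st, "ada", "Ada", "Lovelace"); add_user(st, "grace", "Grace", "Hopper")
add_project(st, "P1", "potato trial", embargo_days = 365)
manage_membership(st, "ada", "P1", "add")
mirror_to_store(st, mirror(reg))
ds <- ingest_dataset(st, build_dataset(pair, "ada", "P1",
        clock = manual_clock("2015-04-08T12:00:00+00:00"), store = st))
st
#> <results store :memory:: 2 user(s), 1 project(s), 1 dataset(s), 3 EAV row(s)>

is_accessible(st, "grace", ds, "2015-06-01T00:00:00+00:00")  # embargoed
#> [1] FALSE
is_accessible(st, "grace", ds, "2016-04-08T00:00:00+00:00")  # embargo over
#> [1] TRUE

ex <- export_query(st, query_filter(requesting_user = "ada",
                                    as_of = "2015-06-01T00:00:00+00:00"))
as.data.frame(ex$table)
#>   identifier                 timestamp device e.leaf|a.color e.leaf|a.length e.plant|a.height
#> 1      p42-1 2015-04-07T09:00:02+00:00                yellow             3.5
#> 2      p42-2 2015-04-07T09:00:03+00:00                                                   10.1
```

Three EAV rows: exactly the three recorded measurements, with the
unscored cells empty in the wide view rather than stored as
placeholders. `ascii_report(st, ds)` renders the same dataset —
ownership stamp, checksums, vocabulary with CURIEs, every observation —
as deterministic plain text for archive submission, and
`read_ascii_report()` reads it back.

## Format documentation

* `docs/formats.md` — vocabulary, scheme, results XML/csv and edit-log
  layouts (XSDs ship under `inst/xsd/`);
* `docs/archive_report.md` — the bit-exact archive report layout;
* `vignettes/phenotyper.Rmd` — design and methods notes.
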