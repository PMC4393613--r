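# Archive report layout

`ascii_report()` renders one dataset as deterministic, line-oriented
UTF-8 text intended for decades-scale archives: readable with no
software, complete enough to reconstruct every observation.

```
=== PHENOTYPING DATASET REPORT ===
format: phenotyping-archive-report/1
dataset_id: <uuid>
owner_id: <user id>
owner_name: <given family>
project: <project id or ->
uploaded_at: <ISO-8601>
raw_file: <path or ->
raw_sha256: <hex or ->
curated_file: <path or ->
curated_sha256: <hex or ->
record_count: <integer>
--- vocabulary (term_id, kind, ontology_ref, unit, label) ---
<term_id>\t<kind>\t<CURIE or ->\t<unit or ->\t<label>
...
--- observations (identifier, entity, entity_ref, attribute, attribute_ref, value, value_label, unit, recorded_at) ---
<identifier>\t<entity_id>\t<CURIE or ->\t<attribute_id>\t<CURIE or ->\t<value>\t<value label or ->\t<unit or ->\t<ISO-8601>
...
=== END OF REPORT ===
```

Rules:

* header block: `key: value`, one per line, fixed key order as above;
* vocabulary block: one tab-separated line per term referenced by the
  dataset, sorted by term id;
* observation block: one tab-separated line per EAV row, in
  (identifier, entity, attribute) order; numeric values use `.`
  decimals (`%.15g`), categorical values are the value-term id with the
  resolved label in the next field;
* absent optional fields are a single `-`;
* output is byte-identical across invocations for an unchanged dataset.

`read_ascii_report()` is the shipped reference reader; it recovers the
metadata and every observation row.
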