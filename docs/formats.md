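# File formats

All files are UTF-8 text. Timestamps are ISO-8601 with an explicit
offset (`2015-04-07T09:00:00+00:00`); all writers emit UTC.

## Vocabulary registry (`vocabulary.xml`)

```xml
<vocabulary default_language="en">
  <term id="e.leaf" kind="entity" ontology_ref="PO:0025034">
    <label lang="en">leaf</label>
    <label lang="de">Blatt</label>
    <definition>optional free text</definition>
    <image href="..." checksum="..."/>      <!-- value terms only -->
  </term>
  ...
  <subset project="P1">
    <member ref="e.leaf"/>
  </subset>
</vocabulary>
```

* `kind` is one of `entity`, `attribute`, `value`.
* `ontology_ref` is an optional CURIE (`PREFIX:digits`), typically a
  Plant Ontology (PO) id on entities and a Plant Trait Ontology (TO) id
  on attributes.
* `unit` (attribute on `<term>`) is allowed for attributes only.
* Checksums are SHA-256 hex digests.

## Scheme interchange (`*.xml`, XSD: `inst/xsd/scheme.xsd`)

Self-contained: labels (in the scheme language), CURIEs, units,
categorical domains and value-image references are embedded, so capture
devices need no registry or network access.

```xml
<phenotyping_scheme id="<uuid>" name="..." owner="..." language="en"
                    created="2015-04-07T08:00:00+00:00">
  <entity id="e.leaf" ontology_ref="PO:0025034">
    <label>leaf</label>
    <parameter id="a.length" datatype="numeric" unit="cm" required="false">
      <label>length</label>
    </parameter>
    <parameter id="a.color" datatype="categorical" required="false">
      <label>colour class</label>
      <value id="v.green" image="..." image_checksum="...">
        <label>green</label>
      </value>
    </parameter>
  </entity>
</phenotyping_scheme>
```

Serialization is canonical (fixed attribute order, 2-space indent,
fixed XML declaration): the same scheme always produces identical
bytes. `datatype` is `numeric` or `categorical`; categorical parameters
carry at least one `<value>`, numeric ones none.

## Results (`*.xml`, XSD: `inst/xsd/results.xsd`)

```xml
<phenotyping_results device="elf01" started="..." scheme="<uuid>">
  <object id="p42-1">
    <measurement entity="e.leaf" attribute="a.length" datatype="numeric"
                 value="3.5" unit="cm" timestamp="..."/>
  </object>
</phenotyping_results>
```

Every measurement is tagged with its entity/attribute term ids, so
parsing does not depend on element order and objects may carry
different variable sets without placeholders. Categorical values are
stored as value-term ids. Numbers always use `.` as decimal separator
regardless of the device entry setting.

Session persistence files (`*.session.xml`) wrap the scheme document
and a results document under `<capture_session>` together with the open
identifier list; they are rewritten after every recorded value.

## Results csv

Comma-delimited, `"`-quoted, one row per identifier, with three header
rows before the data:

1. entity labels (first columns: `identifier,timestamp,device`),
2. attribute labels with the unit in parentheses,
3. machine keys: `#key,,,<entity_id>|<attribute_id>,...`

Cells are empty where a pair was not scored. Merging csv files from
schemes with different variable sets unions the columns (first
appearance order) and leaves cells empty for variables absent from a
row's source scheme.

## Edit logs (`*.editlog.xml`)

```xml
<edit_log>
  <edit identifier="p42-2" entity="e.plant" attribute="a.height"
        old_value="101" new_value="10.1" reason="decimal typo"/>
</edit_log>
```

Written by `apply_qc()` beside every curated file; applying the log to
the raw record set reproduces the curated record set exactly.
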