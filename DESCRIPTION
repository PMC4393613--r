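Package: phenotyper
Title: Controlled-Vocabulary Field Phenotyping Data Acquisition and Management
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless toolkit for acquiring and managing plant phenotypic
    data. Phenotyping schemes are composed from a controlled vocabulary
    cross-referenced to the Plant Ontology (PO) and Plant Trait Ontology
    (TO), serialized to a validated XML interchange format, and scored in
    capture sessions that replicate mobile-device entry semantics
    (identifier multiplication, typed value recording, recall and edit,
    crash-safe persistence). A quality-control stage preserves immutable
    raw files next to curated files with an auditable edit log. Results
    are ingested into an entity-attribute-value (EAV) store with users,
    projects and m:n membership, queried with filters, pivoted to wide
    tables, and exported under an owner/project/embargo access policy,
    including a deterministic plain-text report for long-term archives.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    xml2,
    digest,
    DBI,
    RSQLite,
    uuid,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
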