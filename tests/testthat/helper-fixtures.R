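# Shared builders used across the suite. Everything is generated in
# code with injected clocks, so tests are deterministic and need no
# stored fixture files.

demo_registry <- function() seed_vocabulary()

demo_scheme <- function(reg = demo_registry(), language = "en",
                        owner = "u1", project_id = NULL) {
  doms <- phenotyper:::seed_domains()
  compose_scheme(
    reg, name = "demo", owner = owner, project_id = project_id,
    language = language,
    blocks = list(
      entity_block("e.leaf", list(
        parameter("a.length", "numeric"),
        parameter("a.color", "categorical", domain = doms$a.color))),
      entity_block("e.plant", list(
        parameter("a.height", "numeric")))),
    clock = manual_clock("2015-04-07T08:00:00+00:00"))
}

demo_session <- function(scheme = demo_scheme(), dir = tempfile("capdir"),
                         sep = ".", start = "2015-04-07T09:00:00+00:00") {
  cfg <- device_config("elf01", dir, decimal_separator = sep,
                       clock = manual_clock(start))
  ses <- start_session(scheme, cfg)
  open_object(ses, "p42", 2)
  record_value(ses, "p42-1", "e.leaf", "a.length",
               if (sep == ",") "3,5" else "3.5")
  record_value(ses, "p42-1", "e.leaf", "a.color", "v.yellow")
  record_value(ses, "p42-1", "e.plant", "a.height", "80")
  record_value(ses, "p42-2", "e.leaf", "a.length", "4")
  record_value(ses, "p42-2", "e.plant", "a.height", "101")
  ses
}

# store with two users, one project (u1 member), mirrored seed vocabulary
demo_store <- function(reg = demo_registry(), embargo_days = 365L) {
  st <- store_create()
  add_user(st, "u1", "Ada", "Lovelace")
  add_user(st, "u2", "Grace", "Hopper")
  add_project(st, "P1", "potato trial", embargo_days = embargo_days)
  manage_membership(st, "u1", "P1", "add")
  mirror_to_store(st, mirror(reg))
  st
}

# run a session through QC (no edits) into an upload-ready draft
session_to_pair <- function(ses, dir = tempfile("qcdir")) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  raw <- write_results_xml(ses, file.path(dir, "raw.xml"))
  apply_qc(raw, edit_log(), file.path(dir, "curated.xml"))
}

record_set <- function(df) {
  # canonical comparable view of a record data.frame
  key <- sprintf("%s|%s|%s|%s", df$identifier, df$entity_id, df$attribute_id,
                 ifelse(df$value_kind == "numeric",
                        sprintf("%.15g", df$numeric_value), df$value_term_id))
  sort(key)
}

expect_pheno_error <- function(expr, class) {
  expect_error(expr, class = class)
}
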