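#' Validate a results document
#'
#' Checks well-formedness and conformance to the shipped results XSD;
#' when a (mirrored) vocabulary registry is supplied, every entity,
#' attribute and categorical-value term reference must also resolve in
#' it with the right kind, and numeric values must parse. All problems
#' are reported as findings, nothing is raised.
#'
#' @param x file path or `xml2::xml_document`.
#' @param registry optional [term_registry()] (typically the mirror held
#'   by the results side) to resolve term references against.
#' @return A `validation_report`.
#' @export
validate_results_document <- function(x, registry = NULL) {
  doc <- tryCatch(as_xml_input(x), error = function(e) e)
  if (inherits(doc, "error")) {
    return(validation_report(finding("error", "/", conditionMessage(doc))))
  }
  f <- xsd_findings(doc, results_xsd_path())
  if (!any(f$severity == "error")) {
    for (m in xml2::xml_find_all(doc, "./object/measurement")) {
      oid <- xml2::xml_attr(xml2::xml_parent(m), "id")
      mpath <- sprintf("/phenotyping_results/object[@id='%s']/measurement[@entity='%s'][@attribute='%s']",
                       oid, xml2::xml_attr(m, "entity"), xml2::xml_attr(m, "attribute"))
      kind <- xml2::xml_attr(m, "datatype")
      val <- xml2::xml_attr(m, "value")
      if (kind == "numeric" && is.na(suppressWarnings(as.numeric(val)))) {
        f <- rbind(f, finding("error", mpath,
                              paste0("unparseable numeric value: ", val)))
      }
      if (!is.null(registry)) {
        check_ref <- function(id, want_kind) {
          t <- registry$terms[[id]]
          if (is.null(t)) {
            f <<- rbind(f, finding("error", mpath,
                                   paste0("unknown term: ", id)))
          } else if (t$kind != want_kind) {
            f <<- rbind(f, finding("error", mpath,
                                   paste0("term '", id, "' has kind ", t$kind,
                                          ", expected ", want_kind)))
          }
        }
        check_ref(xml2::xml_attr(m, "entity"), "entity")
        check_ref(xml2::xml_attr(m, "attribute"), "attribute")
        if (kind == "categorical") check_ref(val, "value")
      }
    }
  }
  validation_report(f)
}

#' Parse a results document into observation records
#'
#' Parsing keys on the entity/attribute tags of each measurement, so it
#' is completely independent of the order in which variables appear, and
#' objects may carry different variable sets without placeholders.
#'
#' @param x file path or `xml2::xml_document` of a valid results file.
#' @return A data.frame with one row per observation: `identifier`,
#'   `entity_id`, `attribute_id`, `value_kind`, `numeric_value`,
#'   `value_term_id`, `unit`, `recorded_at`, `device_name`.
#' @export
parse_results_document <- function(x) {
  doc <- as_xml_input(x)
  rep <- validate_results_document(doc)
  if (!rep$ok) {
    pheno_error("validation_error",
                paste0("invalid results document: ",
                       paste(rep$findings$message, collapse = "; ")),
                report = rep)
  }
  device <- xml2::xml_attr(doc, "device")
  ms <- xml2::xml_find_all(doc, "./object/measurement")
  if (!length(ms)) {
    return(data.frame(identifier = character(), entity_id = character(),
                      attribute_id = character(), value_kind = character(),
                      numeric_value = numeric(), value_term_id = character(),
                      unit = character(),
                      recorded_at = as.POSIXct(character(), tz = "UTC"),
                      device_name = character(), stringsAsFactors = FALSE))
  }
  kind <- xml2::xml_attr(ms, "datatype")
  val <- xml2::xml_attr(ms, "value")
  out <- data.frame(
    identifier = vapply(ms, function(m)
      xml2::xml_attr(xml2::xml_parent(m), "id"), ""),
    entity_id = xml2::xml_attr(ms, "entity"),
    attribute_id = xml2::xml_attr(ms, "attribute"),
    value_kind = kind,
    numeric_value = ifelse(kind == "numeric",
                           suppressWarnings(as.numeric(val)), NA_real_),
    value_term_id = ifelse(kind == "categorical", val, NA_character_),
    unit = xml2::xml_attr(ms, "unit"),
    recorded_at = parse_ts(xml2::xml_attr(ms, "timestamp")),
    device_name = device, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Build an edit log
#'
#' Quality control never edits files free-form: every correction is one
#' structured entry naming the targeted record, the value it replaces,
#' the new value and a reason. The log is persisted beside the curated
#' file, making the raw-to-curated delta auditable.
#'
#' @param identifier,entity_id,attribute_id vectors addressing the
#'   targeted records (recycled to common length).
#' @param old_value,new_value values as serialized text (numeric values
#'   with `"."` decimals, categorical values as value term ids).
#' @param reason free-text justification per edit.
#' @return An object of class `edit_log` (a data.frame).
#' @export
edit_log <- function(identifier = character(), entity_id = character(),
                     attribute_id = character(), old_value = character(),
                     new_value = character(), reason = character()) {
  df <- data.frame(identifier = as.character(identifier),
                   entity_id = as.character(entity_id),
                   attribute_id = as.character(attribute_id),
                   old_value = as.character(old_value),
                   new_value = as.character(new_value),
                   reason = as.character(reason), stringsAsFactors = FALSE)
  structure(df, class = c("edit_log", "data.frame"))
}

write_edit_log <- function(log, path) {
  doc <- xml2::xml_new_root("edit_log")
  for (i in seq_len(nrow(log))) {
    xml2::xml_add_child(doc, "edit",
                        identifier = log$identifier[i],
                        entity = log$entity_id[i],
                        attribute = log$attribute_id[i],
                        old_value = log$old_value[i],
                        new_value = log$new_value[i],
                        reason = log$reason[i])
  }
  write_doc(doc, path)
  invisible(path)
}

#' Read a persisted edit log
#' @param path an `*.editlog.xml` written by [apply_qc()].
#' @return An `edit_log`.
#' @export
read_edit_log <- function(path) {
  pheno_assert(file.exists(path), "not_found_error", paste0("no such file: ", path))
  doc <- xml2::read_xml(path)
  edits <- xml2::xml_find_all(doc, "./edit")
  edit_log(identifier = xml2::xml_attr(edits, "identifier"),
           entity_id = xml2::xml_attr(edits, "entity"),
           attribute_id = xml2::xml_attr(edits, "attribute"),
           old_value = xml2::xml_attr(edits, "old_value"),
           new_value = xml2::xml_attr(edits, "new_value"),
           reason = xml2::xml_attr(edits, "reason"))
}

#' A raw + curated result file pair
#'
#' @param raw_path,curated_path the immutable device file and the
#'   QC-curated file derived from it.
#' @param edit_log_path path of the persisted edit log, if any.
#' @return An object of class `result_file_pair` with SHA-256 checksums
#'   of both files.
#' @export
result_file_pair <- function(raw_path, curated_path, edit_log_path = NULL) {
  structure(list(raw_path = raw_path, curated_path = curated_path,
                 raw_checksum = sha256_file(raw_path),
                 curated_checksum = sha256_file(curated_path),
                 edit_log_path = edit_log_path),
            class = "result_file_pair")
}

#' Apply quality-control edits to a raw results file
#'
#' Writes a curated copy of the raw file with the logged edits applied;
#' the raw file itself is never touched (its checksum is asserted
#' unchanged, and writing the curated file over the raw path is
#' refused). Each edit must target an existing record whose current
#' value equals the edit's `old_value`, and the new value must
#' type-check against the measurement's datatype (and, when a scheme is
#' supplied, lie in the categorical domain). The edit log is persisted
#' beside the curated file as `<out_path>.editlog.xml`.
#'
#' @param raw_path raw results XML from the capture device.
#' @param edits an [edit_log()] (may be empty: identity curation).
#' @param out_path path for the curated file; must differ from
#'   `raw_path`.
#' @param scheme optional `pheno_scheme` for categorical domain checks.
#' @return A [result_file_pair()].
#' @export
apply_qc <- function(raw_path, edits, out_path, scheme = NULL) {
  stopifnot(inherits(edits, "edit_log"))
  pheno_assert(file.exists(raw_path), "not_found_error",
               paste0("no such file: ", raw_path))
  pheno_assert(normalizePath(raw_path, mustWork = FALSE) !=
                 normalizePath(out_path, mustWork = FALSE),
               "validation_error",
               "out_path equals raw_path; refusing to overwrite the raw file")
  raw_before <- sha256_file(raw_path)

  doc <- as_xml_input(raw_path)
  rep <- validate_results_document(doc)
  pheno_assert(rep$ok, "validation_error",
               paste0("raw file invalid: ", paste(rep$findings$message, collapse = "; ")))

  for (i in seq_len(nrow(edits))) {
    xp <- sprintf("./object[@id='%s']/measurement[@entity='%s' and @attribute='%s']",
                  edits$identifier[i], edits$entity_id[i], edits$attribute_id[i])
    m <- xml2::xml_find_first(doc, xp)
    pheno_assert(!inherits(m, "xml_missing"), "not_found_error",
                 sprintf("edit %d targets a missing record (%s, %s, %s)",
                         i, edits$identifier[i], edits$entity_id[i],
                         edits$attribute_id[i]))
    cur <- xml2::xml_attr(m, "value")
    kind <- xml2::xml_attr(m, "datatype")
    cur_cmp <- if (kind == "numeric") fmt_num(as.numeric(cur)) else cur
    old_cmp <- if (kind == "numeric") fmt_num(as.numeric(edits$old_value[i])) else edits$old_value[i]
    pheno_assert(identical(cur_cmp, old_cmp), "conflict_error",
                 sprintf("edit %d: old_value '%s' does not match current value '%s'",
                         i, edits$old_value[i], cur))
    new <- edits$new_value[i]
    if (kind == "numeric") {
      nv <- suppressWarnings(as.numeric(new))
      pheno_assert(!is.na(nv), "type_error",
                   sprintf("edit %d: new value '%s' is not numeric", i, new))
      new <- fmt_num(nv)
    } else if (!is.null(scheme)) {
      p <- scheme_parameter(scheme, edits$entity_id[i], edits$attribute_id[i])
      pheno_assert(!is.null(p) && new %in% p$domain, "domain_violation_error",
                   sprintf("edit %d: '%s' is not in the categorical domain", i, new))
    }
    xml2::xml_set_attr(m, "value", new)
  }

  write_doc(doc, out_path)
  log_path <- paste0(out_path, ".editlog.xml")
  write_edit_log(edits, log_path)

  pheno_assert(identical(sha256_file(raw_path), raw_before), "integrity_error",
               "raw file changed during QC (this is a bug)")
  result_file_pair(raw_path, out_path, log_path)
}

#' Assemble an upload-ready dataset draft
#'
#' Stamps the curated records with the uploading user (ownership stamp),
#' the upload time from the injected clock, and the chosen project —
#' defaulting to no project, i.e. private data. When a store is supplied
#' and a project is chosen, the user must be affiliated with it.
#'
#' @param files a [result_file_pair()].
#' @param user uploading user's id (becomes the dataset owner).
#' @param project project id or `NULL` ("no project").
#' @param clock time source for the upload stamp.
#' @param store optional [store_create()] handle used to verify project
#'   membership at draft time (ingest verifies it again).
#' @return An object of class `dataset_draft`.
#' @export
build_dataset <- function(files, user, project = NULL, clock = system_clock,
                          store = NULL) {
  stopifnot(inherits(files, "result_file_pair"))
  pheno_assert(is.character(user) && nzchar(user), "validation_error",
               "user must be a non-empty id")
  if (!is.null(project) && !is.null(store)) {
    pheno_assert(is_member(store, user, project), "authorization_error",
                 paste0("user '", user, "' is not affiliated with project '",
                        project, "'"))
  }
  records <- parse_results_document(files$curated_path)
  structure(list(records = records, owner = user, project = project,
                 uploaded_at = clock(), files = files),
            class = "dataset_draft")
}

#' @export
print.dataset_draft <- function(x, ...) {
  cat(sprintf("<dataset draft: %d record(s), owner %s, project %s, uploaded %s>\n",
              nrow(x$records), x$owner, x$project %||% "(none)",
              fmt_ts(x$uploaded_at)))
  invisible(x)
}
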