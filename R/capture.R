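#' Capture device configuration
#'
#' Settings of one (virtual) capture device: its name (used in result
#' file names), the decimal separator accepted during numeric entry,
#' where session and result files are stored, and the clock that stamps
#' every measurement. The clock is injected rather than read ambiently,
#' so timestamp behaviour is reproducible.
#'
#' @param device_name filename-safe device name (no path separators).
#' @param storage_dir directory for session persistence and result
#'   files; created if missing.
#' @param decimal_separator `"."` or `","`; applies to value entry only,
#'   serialized files always use `"."`.
#' @param clock zero-argument function returning a POSIXct; see
#'   [manual_clock()].
#' @return An object of class `device_config`.
#' @export
device_config <- function(device_name, storage_dir,
                          decimal_separator = ".", clock = system_clock) {
  pheno_assert(is.character(device_name) && length(device_name) == 1L &&
                 nzchar(device_name) && !grepl("[/\\\\]", device_name),
               "validation_error",
               "device_name must be non-empty and contain no path separators")
  pheno_assert(decimal_separator %in% c(".", ","), "validation_error",
               'decimal_separator must be "." or ","')
  if (!dir.exists(storage_dir)) dir.create(storage_dir, recursive = TRUE)
  structure(list(device_name = device_name, storage_dir = storage_dir,
                 decimal_separator = decimal_separator, clock = clock),
            class = "device_config")
}

#' Unique result-file name
#'
#' Result files are named from the device name plus date and time,
#' `<device>_<YYYYMMDD>_<HHMMSS>`, so files from different devices or
#' seconds never collide. Writers append `_<n>` in the (rare) case of a
#' same-second collision on one device.
#'
#' @param config a [device_config()].
#' @param t POSIXct timestamp.
#' @return The file name stem (no extension).
#' @examples
#' cfg <- device_config("elf01", tempdir())
#' result_file_name(cfg, as.POSIXct("2015-04-07 14:03:09", tz = "UTC"))
#' @export
result_file_name <- function(config, t) {
  stopifnot(inherits(config, "device_config"), inherits(t, "POSIXct"))
  paste0(config$device_name, "_", format(t, "%Y%m%d_%H%M%S", tz = "UTC"))
}

# next free path for a given stem+extension, appending _<n> on collision
fresh_path <- function(dir, stem, ext) {
  path <- file.path(dir, paste0(stem, ext))
  n <- 1L
  while (file.exists(path)) {
    path <- file.path(dir, paste0(stem, "_", n, ext))
    n <- n + 1L
  }
  path
}

rec_key <- function(entity_id, attribute_id) paste0(entity_id, "\n", attribute_id)

#' Start a capture session
#'
#' Loads and checks a scheme document the way the device start page
#' does: a missing file or an invalid scheme aborts with the validation
#' findings attached. The session is an in-memory object persisted to
#' `config$storage_dir` after every recorded value, so a crash loses at
#' most the entry in progress (see [load_session()]).
#'
#' @param scheme_doc path to a scheme XML file (or a `pheno_scheme`).
#' @param config a [device_config()].
#' @return An object of class `capture_session` (mutable).
#' @export
start_session <- function(scheme_doc, config) {
  stopifnot(inherits(config, "device_config"))
  if (inherits(scheme_doc, "pheno_scheme")) {
    scheme <- scheme_doc
  } else {
    pheno_assert(file.exists(scheme_doc), "not_found_error",
                 paste0("no scheme file found: ", scheme_doc))
    rep <- validate_scheme_document(scheme_doc)
    if (!rep$ok) {
      pheno_error("validation_error",
                  paste0("invalid scheme file: ",
                         paste(rep$findings$message, collapse = "; ")),
                  report = rep)
    }
    scheme <- scheme_from_xml(scheme_doc)
  }
  session <- new.env(parent = emptyenv())
  session$scheme <- scheme
  session$config <- config
  session$started_at <- config$clock()
  session$records <- list()            # identifier -> key -> record
  session$open_identifiers <- character()
  session$objects <- data.frame(identifier = character(), base_id = character(),
                                index = integer(), stringsAsFactors = FALSE)
  session$file <- file.path(config$storage_dir,
                            paste0(result_file_name(config, session$started_at),
                                   ".session.xml"))
  class(session) <- "capture_session"
  session
}

#' @export
print.capture_session <- function(x, ...) {
  cat(sprintf("<capture session on '%s' (%s)>\n  started: %s, %d identifier(s) open, %d record(s)\n",
              x$scheme$name, x$config$device_name, fmt_ts(x$started_at),
              length(x$open_identifiers), nrow(session_records(x))))
  invisible(x)
}

#' Open an object for scoring, with identifier multiplication
#'
#' One scanned or typed id can stand for several individuals (e.g.
#' plants in a plot). A multiplication factor n > 1 expands the base id
#' into n unique identifiers by appending a hyphen and a 1-based count
#' (`id-1`, `id-2`, ...); factor 1 keeps the id unchanged. Re-opening an
#' existing identifier is allowed and enables recall/edit.
#'
#' @param session a [start_session()] result.
#' @param base_id non-empty identifier as entered or scanned.
#' @param multiplication positive integer repeat count.
#' @return Character vector of the opened identifiers, in order.
#' @examples
#' \dontrun{open_object(session, "p42", 2)  # "p42-1" "p42-2"}
#' @export
open_object <- function(session, base_id, multiplication = 1L) {
  stopifnot(inherits(session, "capture_session"))
  pheno_assert(is.character(base_id) && length(base_id) == 1L && nzchar(base_id),
               "validation_error", "base_id must be a non-empty string")
  multiplication <- as.integer(multiplication)
  pheno_assert(!is.na(multiplication) && multiplication >= 1L, "domain_error",
               "multiplication factor must be a positive integer")
  if (multiplication == 1L) {
    ids <- base_id
    idx <- NA_integer_
  } else {
    idx <- seq_len(multiplication)
    ids <- paste0(base_id, "-", idx)
  }
  new <- !ids %in% session$open_identifiers
  session$open_identifiers <- c(session$open_identifiers, ids[new])
  if (any(new)) {
    session$objects <- rbind(session$objects,
                             data.frame(identifier = ids[new], base_id = base_id,
                                        index = idx[new], stringsAsFactors = FALSE))
  }
  ids
}

parse_numeric_entry <- function(raw, sep) {
  sep_re <- if (sep == ".") "\\." else ","
  pat <- paste0("^[+-]?([0-9]+(", sep_re, "[0-9]+)?|", sep_re, "[0-9]+)$")
  pheno_assert(grepl(pat, raw), "parse_error",
               paste0("unparseable numeric entry '", raw,
                      "' (decimal separator '", sep, "')"))
  as.numeric(if (sep == ",") sub(",", ".", raw, fixed = TRUE) else raw)
}

#' Record one measured value
#'
#' Parses the raw entry according to the parameter's datatype — numeric
#' entries honour the device decimal separator; categorical entries may
#' be a domain value id or its display label in the scheme language —
#' stamps it with the device clock, and stores it under
#' (identifier, entity, attribute). Re-recording the same key replaces
#' the previous value (edit semantics; no history at capture stage).
#' The session is persisted to permanent storage after every record.
#'
#' @param session a [start_session()] result.
#' @param identifier an identifier previously opened via [open_object()].
#' @param entity_id,attribute_id a pair present in the scheme.
#' @param raw value as entered (character).
#' @return The stored observation record (a named list), invisibly.
#' @export
record_value <- function(session, identifier, entity_id, attribute_id, raw) {
  stopifnot(inherits(session, "capture_session"))
  pheno_assert(identifier %in% session$open_identifiers, "not_found_error",
               paste0("identifier not opened: ", identifier))
  p <- scheme_parameter(session$scheme, entity_id, attribute_id)
  pheno_assert(!is.null(p), "not_found_error",
               paste0("(", entity_id, ", ", attribute_id, ") is not in the scheme"))
  raw <- as.character(raw)

  if (p$datatype == "numeric") {
    value <- parse_numeric_entry(raw, session$config$decimal_separator)
    rec <- list(identifier = identifier, entity_id = entity_id,
                attribute_id = attribute_id, value_kind = "numeric",
                numeric_value = value, value_term_id = NA_character_,
                unit = p$unit %||% NA_character_)
  } else {
    vid <- if (raw %in% p$domain) {
      raw
    } else {
      labels <- vapply(p$domain, function(v) session$scheme$snapshot$terms[[v]]$label, "")
      hit <- p$domain[labels == raw]
      pheno_assert(length(hit) == 1L, "domain_violation_error",
                   paste0("'", raw, "' is not in the domain of (", entity_id,
                          ", ", attribute_id, ")"))
      hit
    }
    rec <- list(identifier = identifier, entity_id = entity_id,
                attribute_id = attribute_id, value_kind = "categorical",
                numeric_value = NA_real_, value_term_id = vid,
                unit = NA_character_)
  }
  rec$recorded_at <- session$config$clock()
  rec$device_name <- session$config$device_name

  if (is.null(session$records[[identifier]])) session$records[[identifier]] <- list()
  session$records[[identifier]][[rec_key(entity_id, attribute_id)]] <- rec
  persist_session(session)
  invisible(rec)
}

#' Recall all current entries for an identifier
#'
#' Returns the stored records of one identifier for review; subsequent
#' [record_value()] calls on the same (entity, attribute) keys overwrite
#' them (modify-and-save semantics).
#'
#' @param session a [start_session()] result.
#' @param identifier identifier with at least one record.
#' @return Named list of observation records, keyed
#'   `"<entity_id>\n<attribute_id>"`.
#' @export
recall_entry <- function(session, identifier) {
  stopifnot(inherits(session, "capture_session"))
  recs <- session$records[[identifier]]
  pheno_assert(!is.null(recs) && length(recs) > 0L, "not_found_error",
               paste0("no entries recorded for identifier: ", identifier))
  recs
}

# flat data.frame view of all records, in stable (identifier-open, scheme) order
session_records <- function(session) {
  rows <- list()
  pairs <- scheme_pairs(session$scheme)
  for (id in session$open_identifiers) {
    recs <- session$records[[id]]
    if (is.null(recs)) next
    for (i in seq_len(nrow(pairs))) {
      rec <- recs[[rec_key(pairs$entity_id[i], pairs$attribute_id[i])]]
      if (is.null(rec)) next
      rows[[length(rows) + 1L]] <- data.frame(
        identifier = rec$identifier, entity_id = rec$entity_id,
        attribute_id = rec$attribute_id, value_kind = rec$value_kind,
        numeric_value = rec$numeric_value, value_term_id = rec$value_term_id,
        unit = rec$unit, recorded_at = rec$recorded_at,
        device_name = rec$device_name, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(identifier = character(), entity_id = character(),
                      attribute_id = character(), value_kind = character(),
                      numeric_value = numeric(), value_term_id = character(),
                      unit = character(),
                      recorded_at = as.POSIXct(character(), tz = "UTC"),
                      device_name = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

fmt_num <- function(x) sprintf("%.15g", x)

records_to_xml <- function(records, device, started, scheme_id = NULL) {
  doc <- xml2::xml_new_root("phenotyping_results",
                            device = device, started = fmt_ts(started))
  if (!is.null(scheme_id)) xml2::xml_set_attr(doc, "scheme", scheme_id)
  for (id in unique(records$identifier)) {
    onode <- xml2::xml_add_child(doc, "object", id = id)
    sub <- records[records$identifier == id, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      m <- xml2::xml_add_child(onode, "measurement",
                               entity = sub$entity_id[i],
                               attribute = sub$attribute_id[i],
                               datatype = sub$value_kind[i],
                               value = if (sub$value_kind[i] == "numeric") {
                                 fmt_num(sub$numeric_value[i])
                               } else sub$value_term_id[i])
      if (!is.na(sub$unit[i])) xml2::xml_set_attr(m, "unit", sub$unit[i])
      xml2::xml_set_attr(m, "timestamp", fmt_ts(sub$recorded_at[i]))
    }
  }
  doc
}

persist_session <- function(session) {
  doc <- xml2::xml_new_root("capture_session",
                            device = session$config$device_name,
                            started = fmt_ts(session$started_at))
  ids <- xml2::xml_add_child(doc, "open_identifiers")
  for (i in seq_len(nrow(session$objects))) {
    node <- xml2::xml_add_child(ids, "identifier",
                                id = session$objects$identifier[i],
                                base_id = session$objects$base_id[i])
    if (!is.na(session$objects$index[i])) {
      xml2::xml_set_attr(node, "index", as.character(session$objects$index[i]))
    }
  }
  xml2::xml_add_child(doc, scheme_to_xml(session$scheme))
  xml2::xml_add_child(doc, records_to_xml(session_records(session),
                                          session$config$device_name,
                                          session$started_at,
                                          session$scheme$scheme_id))
  write_doc(doc, session$file)
  invisible(session$file)
}

#' Reload a persisted capture session
#'
#' Reconstructs a session from the file written after every
#' [record_value()] call, recovering the full record set after a device
#' crash or power loss.
#'
#' @param path session file (`*.session.xml`) in the device storage dir.
#' @param config the [device_config()] to resume with.
#' @return A `capture_session`.
#' @export
load_session <- function(path, config) {
  pheno_assert(file.exists(path), "not_found_error", paste0("no such file: ", path))
  doc <- xml2::read_xml(path)
  pheno_assert(xml2::xml_name(doc) == "capture_session", "validation_error",
               "not a capture session file")
  scheme <- scheme_from_xml(xml2::xml_find_first(doc, "./phenotyping_scheme"))

  session <- new.env(parent = emptyenv())
  session$scheme <- scheme
  session$config <- config
  session$started_at <- parse_ts(xml2::xml_attr(doc, "started"))
  idnodes <- xml2::xml_find_all(doc, "./open_identifiers/identifier")
  session$open_identifiers <- xml2::xml_attr(idnodes, "id")
  idx <- suppressWarnings(as.integer(xml2::xml_attr(idnodes, "index")))
  session$objects <- data.frame(identifier = xml2::xml_attr(idnodes, "id"),
                                base_id = xml2::xml_attr(idnodes, "base_id"),
                                index = idx, stringsAsFactors = FALSE)
  session$records <- list()
  session$file <- path
  class(session) <- "capture_session"

  res <- xml2::xml_find_first(doc, "./phenotyping_results")
  for (onode in xml2::xml_find_all(res, "./object")) {
    oid <- xml2::xml_attr(onode, "id")
    for (m in xml2::xml_find_all(onode, "./measurement")) {
      kind <- xml2::xml_attr(m, "datatype")
      rec <- list(identifier = oid,
                  entity_id = xml2::xml_attr(m, "entity"),
                  attribute_id = xml2::xml_attr(m, "attribute"),
                  value_kind = kind,
                  numeric_value = if (kind == "numeric")
                    as.numeric(xml2::xml_attr(m, "value")) else NA_real_,
                  value_term_id = if (kind == "categorical")
                    xml2::xml_attr(m, "value") else NA_character_,
                  unit = xml2::xml_attr(m, "unit"),
                  recorded_at = parse_ts(xml2::xml_attr(m, "timestamp")),
                  device_name = xml2::xml_attr(doc, "device"))
      if (is.null(session$records[[oid]])) session$records[[oid]] <- list()
      session$records[[oid]][[rec_key(rec$entity_id, rec$attribute_id)]] <- rec
    }
  }
  session
}

#' Write session results as XML
#'
#' Every measurement is tagged with its entity and attribute ids, which
#' makes later parsing independent of element order, and objects carry
#' only the variables actually scored — no placeholders.
#'
#' @param session a `capture_session` with at least one record.
#' @param path output path; defaults to a uniquely named file in the
#'   device storage dir.
#' @return The output path, invisibly.
#' @export
write_results_xml <- function(session, path = NULL) {
  stopifnot(inherits(session, "capture_session"))
  records <- session_records(session)
  pheno_assert(nrow(records) > 0L, "empty_output_error",
               "session has no records to write")
  if (is.null(path)) {
    path <- fresh_path(session$config$storage_dir,
                       result_file_name(session$config, session$config$clock()),
                       ".xml")
  }
  write_doc(records_to_xml(records, session$config$device_name,
                           session$started_at, session$scheme$scheme_id),
            path)
  invisible(path)
}

#' Write session results as csv
#'
#' One row per identifier, one column per (entity, attribute) pair of
#' the scheme, preceded by identifier, timestamp and device columns.
#' Three header rows identify the cells: entity labels, attribute labels
#' with units, and machine-readable term-id keys. Cells are empty where
#' a pair was not scored. Serialized numbers always use `"."` regardless
#' of the device's entry separator.
#'
#' @param session a `capture_session` with at least one record.
#' @param path output path; defaults to a uniquely named file in the
#'   device storage dir.
#' @return The [results_table] written, invisibly (with the path in
#'   attribute `"path"`).
#' @export
write_results_csv <- function(session, path = NULL) {
  stopifnot(inherits(session, "capture_session"))
  records <- session_records(session)
  pheno_assert(nrow(records) > 0L, "empty_output_error",
               "session has no records to write")
  if (is.null(path)) {
    path <- fresh_path(session$config$storage_dir,
                       result_file_name(session$config, session$config$clock()),
                       ".csv")
  }
  tab <- session_results_table(session, records)
  write_results_table(tab, path)
  attr(tab, "path") <- path
  invisible(tab)
}
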