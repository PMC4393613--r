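#' Access policy
#'
#' Store-level defaults for the read policy. The only tunable is the
#' default embargo duration, used for datasets without a project (a
#' project's own `embargo_days` takes precedence for its datasets).
#'
#' @param default_embargo_days non-negative integer.
#' @return An object of class `access_policy`.
#' @export
access_policy <- function(default_embargo_days = 0L) {
  default_embargo_days <- as.integer(default_embargo_days)
  pheno_assert(!is.na(default_embargo_days) && default_embargo_days >= 0L,
               "validation_error", "default_embargo_days must be non-negative")
  structure(list(default_embargo_days = default_embargo_days),
            class = "access_policy")
}

dataset_embargo_days <- function(store, dataset, policy) {
  if (!is.na(dataset$project)) {
    get_rows(store, "projects", "project_id", dataset$project)$embargo_days
  } else {
    policy$default_embargo_days
  }
}

#' Evaluate the dataset read policy
#'
#' A dataset is readable by a user at a given instant iff at least one
#' of three clauses holds: the user is the dataset's owner (data are
#' private by default); the dataset is assigned to a project and the
#' user is affiliated with it; or the embargo has run out, which opens
#' the dataset to everyone. The embargo clock starts at the upload
#' stamp and uses the project's `embargo_days` when the dataset has a
#' project, else the policy default; the boundary instant
#' `uploaded_at + embargo_days` itself is already open (inclusive).
#'
#' @param store a `pheno_store`.
#' @param user requesting user's id (must exist).
#' @param dataset a dataset id or a row from [get_dataset()].
#' @param as_of POSIXct (or ISO-8601 string) at which access is evaluated.
#' @param policy an [access_policy()].
#' @return Logical scalar.
#' @export
is_accessible <- function(store, user, dataset, as_of,
                          policy = access_policy()) {
  stopifnot(inherits(policy, "access_policy"))
  pheno_assert(nrow(get_rows(store, "users", "user_id", user)) == 1L,
               "not_found_error", paste0("unknown user: ", user))
  if (is.character(dataset) && length(dataset) == 1L) {
    dataset <- get_dataset(store, dataset)
  }
  if (is.character(as_of)) as_of <- parse_ts(as_of)

  if (identical(user, dataset$owner)) return(TRUE)
  if (!is.na(dataset$project) && is_member(store, user, dataset$project)) {
    return(TRUE)
  }
  embargo_end <- parse_ts(dataset$uploaded_at) +
    dataset_embargo_days(store, dataset, policy) * 86400
  as_of >= embargo_end
}

#' Access-controlled export of query results
#'
#' Runs the filter, drops every row whose dataset the requesting user
#' may not read at `filter$as_of`, pivots the remainder to a wide table
#' and renders it. Withheld data are reported as a count only — no
#' metadata of inaccessible datasets leaks into the export.
#'
#' @param store a `pheno_store`.
#' @param filter a [query_filter()] with `requesting_user` and `as_of` set.
#' @param policy an [access_policy()].
#' @param format `"csv"` (canonical) or `"spreadsheet"` (Excel 2003
#'   SpreadsheetML, a plain-XML format spreadsheet programs open
#'   directly); both carry identical cell values.
#' @param path output file; defaults to a tempfile with a fitting
#'   extension.
#' @return List with `table` (the `results_table`), `path`,
#'   `n_withheld` (datasets excluded by the policy) and `n_datasets`
#'   (datasets that matched the filter).
#' @export
export_query <- function(store, filter, policy = access_policy(),
                         format = c("csv", "spreadsheet"), path = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(filter, "query_filter"))
  pheno_assert(!is.null(filter$requesting_user) && !is.null(filter$as_of),
               "validation_error",
               "filter must carry requesting_user and as_of for an export")
  rows <- query_eav(store, filter)
  ds_ids <- unique(rows$dataset_id)
  ok <- vapply(ds_ids, function(d) {
    is_accessible(store, filter$requesting_user, d, filter$as_of, policy)
  }, TRUE)
  rows <- rows[rows$dataset_id %in% ds_ids[ok], , drop = FALSE]
  tab <- pivot_wide(store, rows)
  if (is.null(path)) {
    path <- tempfile(fileext = if (format == "csv") ".csv" else ".xml")
  }
  if (format == "csv") {
    write_results_table(tab, path)
  } else {
    write_spreadsheet(tab, path)
  }
  list(table = tab, path = path,
       n_withheld = sum(!ok), n_datasets = length(ds_ids))
}

# Excel 2003 SpreadsheetML: one worksheet, same three header rows as the
# csv dialect, numbers typed as Number so spreadsheets sort them natively.
write_spreadsheet <- function(table, path) {
  stopifnot(inherits(table, "results_table"))
  k <- table$keys
  doc <- xml2::xml_new_root("Workbook",
    xmlns = "urn:schemas-microsoft-com:office:spreadsheet",
    "xmlns:ss" = "urn:schemas-microsoft-com:office:spreadsheet")
  ws <- xml2::xml_add_child(doc, "Worksheet")
  xml2::xml_set_attr(ws, "ss:Name", "export")
  tbl <- xml2::xml_add_child(ws, "Table")
  add_row <- function(values, types = NULL) {
    r <- xml2::xml_add_child(tbl, "Row")
    for (j in seq_along(values)) {
      c_ <- xml2::xml_add_child(r, "Cell")
      d <- xml2::xml_add_child(c_, "Data", values[[j]])
      xml2::xml_set_attr(d, "ss:Type",
                         if (is.null(types)) "String" else types[[j]])
    }
  }
  add_row(c("identifier", "timestamp", "device", k$entity_label))
  add_row(c("", "", "", ifelse(is.na(k$unit), k$attribute_label,
                               paste0(k$attribute_label, " (", k$unit, ")"))))
  add_row(c("#key", "", "", k$column))
  num_re <- "^[+-]?[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?$"
  for (i in seq_len(nrow(table$data))) {
    vals <- vapply(table$data[i, , drop = FALSE], as.character, "")
    types <- ifelse(grepl(num_re, vals) & seq_along(vals) > 3, "Number", "String")
    add_row(vals, types)
  }
  # the processing instruction tells Office this is a spreadsheet document
  txt <- doc_to_string(doc)
  txt <- sub("\\?>", "?>\n<?mso-application progid=\"Excel.Sheet\"?>", txt)
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

# read a SpreadsheetML export back (format-equivalence checks)
read_spreadsheet <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  rows <- xml2::xml_find_all(doc, "./Worksheet/Table/Row")
  cells <- lapply(rows, function(r) {
    xml2::xml_text(xml2::xml_find_all(r, "./Cell/Data"))
  })
  do.call(rbind, cells)
}

#' Deterministic plain-text archive report of one dataset
#'
#' Renders the complete information of one dataset — ownership and
#' project stamps, file checksums, the vocabulary of every referenced
#' term with ontology CURIEs and labels, and the full observation list —
#' as line-oriented UTF-8 text readable with no software, the format
#' handed to decades-scale archives. Output is byte-identical across
#' invocations for an unchanged dataset. [read_ascii_report()] is the
#' shipped reference reader.
#'
#' Access control is the caller's duty (check [is_accessible()] first);
#' the report itself is policy-free so archive pipelines can run under a
#' service identity.
#'
#' @param store a `pheno_store`.
#' @param dataset_id dataset to render.
#' @param path optional output file.
#' @return Character vector of report lines, invisibly when `path` is
#'   given.
#' @export
ascii_report <- function(store, dataset_id, path = NULL) {
  d <- get_dataset(store, dataset_id)
  owner <- get_rows(store, "users", "user_id", d$owner)
  rows <- query_eav(store, query_filter(dataset_ids = dataset_id))
  reg <- store_registry(store)

  term_ids <- sort(unique(c(rows$entity_id, rows$attribute_id,
                            rows$value_term_id[!is.na(rows$value_term_id)])))
  na_dash <- function(x) ifelse(is.na(x) | !nzchar(x), "-", x)
  tline <- function(...) paste(..., sep = "\t")

  vocab_lines <- vapply(term_ids, function(id) {
    t <- reg$terms[[id]]
    if (is.null(t)) return(tline(id, "-", "-", "-", "-"))
    tline(id, t$kind, t$ontology_ref %||% "-", t$unit %||% "-",
          resolve_label(reg, id))
  }, "")

  curie_of <- function(id) {
    t <- reg$terms[[id]]
    if (is.null(t) || is.null(t$ontology_ref)) "-" else t$ontology_ref
  }
  obs_lines <- vapply(seq_len(nrow(rows)), function(i) {
    val <- if (rows$value_kind[i] == "numeric") {
      fmt_num(rows$numeric_value[i])
    } else rows$value_term_id[i]
    vlab <- if (rows$value_kind[i] == "categorical" &&
                rows$value_term_id[i] %in% names(reg$terms)) {
      resolve_label(reg, rows$value_term_id[i])
    } else "-"
    tline(rows$object_identifier[i],
          rows$entity_id[i], curie_of(rows$entity_id[i]),
          rows$attribute_id[i], curie_of(rows$attribute_id[i]),
          val, vlab, na_dash(rows$unit[i]), fmt_ts(rows$recorded_at[i]))
  }, "")

  lines <- c(
    "=== PHENOTYPING DATASET REPORT ===",
    "format: phenotyping-archive-report/1",
    paste0("dataset_id: ", d$dataset_id),
    paste0("owner_id: ", d$owner),
    paste0("owner_name: ", trimws(paste(owner$given_name, owner$family_name))),
    paste0("project: ", na_dash(d$project)),
    paste0("uploaded_at: ", d$uploaded_at),
    paste0("raw_file: ", na_dash(d$raw_path)),
    paste0("raw_sha256: ", na_dash(d$raw_checksum)),
    paste0("curated_file: ", na_dash(d$curated_path)),
    paste0("curated_sha256: ", na_dash(d$curated_checksum)),
    paste0("record_count: ", d$row_count),
    "--- vocabulary (term_id, kind, ontology_ref, unit, label) ---",
    vocab_lines,
    "--- observations (identifier, entity, entity_ref, attribute, attribute_ref, value, value_label, unit, recorded_at) ---",
    obs_lines,
    "=== END OF REPORT ===")
  lines <- unname(lines)

  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, useBytes = TRUE)
    return(invisible(lines))
  }
  lines
}

#' Reference reader for archive reports
#'
#' Parses a report produced by [ascii_report()] back into dataset
#' metadata and observation records; the report is information-complete,
#' so every EAV row and dataset field is recoverable.
#'
#' @param x path to a report file, or the report lines themselves.
#' @return List with `meta` (named character vector), `vocabulary` and
#'   `observations` (data.frames).
#' @export
read_ascii_report <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) {
    readLines(x, encoding = "UTF-8", warn = FALSE)
  } else x
  pheno_assert(identical(lines[1], "=== PHENOTYPING DATASET REPORT ==="),
               "validation_error", "not an archive report")
  vstart <- grep("^--- vocabulary", lines)
  ostart <- grep("^--- observations", lines)
  oend <- grep("^=== END OF REPORT ===$", lines)

  header <- lines[2:(vstart - 1L)]
  kv <- regmatches(header, regexpr("^[a-z0-9_]+:", header))
  meta <- setNames(sub("^[a-z0-9_]+: ?", "", header),
                   sub(":$", "", kv))

  parse_block <- function(block, cols) {
    if (!length(block)) {
      return(setNames(data.frame(matrix(character(), ncol = length(cols)),
                                 stringsAsFactors = FALSE), cols))
    }
    parts <- strsplit(block, "\t", fixed = TRUE)
    setNames(as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE), cols)
  }
  vocab <- parse_block(lines[seq.int(vstart + 1L, length.out = ostart - vstart - 1L)],
                       c("term_id", "kind", "ontology_ref", "unit", "label"))
  obs <- parse_block(lines[seq.int(ostart + 1L, length.out = oend - ostart - 1L)],
                     c("identifier", "entity_id", "entity_ref", "attribute_id",
                       "attribute_ref", "value", "value_label", "unit",
                       "recorded_at"))
  list(meta = meta, vocabulary = vocab, observations = obs)
}
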