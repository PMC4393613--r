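# Results store: an embedded SQLite database file holding users,
# projects (with m:n membership), the mirrored vocabulary, dataset
# metadata linked to raw/curated file pairs, and the EAV observation
# rows themselves. One row exists per recorded measurement and never
# for an unmeasured parameter, so changing the measured parameter set
# between datasets changes row contents, not table definitions.

store_schema <- c(
  "CREATE TABLE users (
     user_id TEXT PRIMARY KEY, given_name TEXT, family_name TEXT,
     is_admin INTEGER NOT NULL DEFAULT 0, external_researcher_id TEXT)",
  "CREATE TABLE projects (
     project_id TEXT PRIMARY KEY, name TEXT, embargo_days INTEGER NOT NULL)",
  "CREATE TABLE memberships (
     user_id TEXT NOT NULL REFERENCES users(user_id),
     project_id TEXT NOT NULL REFERENCES projects(project_id),
     PRIMARY KEY (user_id, project_id))",
  "CREATE TABLE vocab_terms (
     term_id TEXT PRIMARY KEY, kind TEXT NOT NULL, ontology_ref TEXT,
     unit TEXT, definition TEXT)",
  "CREATE TABLE vocab_labels (
     term_id TEXT NOT NULL REFERENCES vocab_terms(term_id),
     lang TEXT NOT NULL, label TEXT NOT NULL, PRIMARY KEY (term_id, lang))",
  "CREATE TABLE store_meta (key TEXT PRIMARY KEY, value TEXT)",
  "CREATE TABLE datasets (
     dataset_id TEXT PRIMARY KEY,
     owner TEXT NOT NULL REFERENCES users(user_id),
     project TEXT REFERENCES projects(project_id),
     uploaded_at TEXT NOT NULL,
     raw_path TEXT, curated_path TEXT,
     raw_checksum TEXT, curated_checksum TEXT,
     row_count INTEGER NOT NULL)",
  "CREATE TABLE eav_rows (
     dataset_id TEXT NOT NULL REFERENCES datasets(dataset_id),
     object_identifier TEXT NOT NULL,
     entity_id TEXT NOT NULL, attribute_id TEXT NOT NULL,
     value_kind TEXT NOT NULL,
     numeric_value REAL, unit TEXT, value_term_id TEXT,
     recorded_at TEXT NOT NULL)",
  "CREATE INDEX idx_eav_dataset ON eav_rows(dataset_id)",
  "CREATE INDEX idx_eav_attr ON eav_rows(attribute_id)",
  "CREATE TABLE object_metadata (
     identifier TEXT NOT NULL, key TEXT NOT NULL, value TEXT,
     PRIMARY KEY (identifier, key))"
)

#' Create a results store
#'
#' @param path SQLite file path, or `":memory:"` for a transient store.
#' @return A store handle of class `pheno_store`.
#' @seealso [store_open()], [store_close()]
#' @export
store_create <- function(path = ":memory:") {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  for (sql in store_schema) DBI::dbExecute(con, sql)
  s <- new.env(parent = emptyenv())
  s$con <- con
  s$path <- path
  class(s) <- "pheno_store"
  s
}

#' Open an existing results store
#' @param path SQLite file created by [store_create()].
#' @return A `pheno_store` handle.
#' @export
store_open <- function(path) {
  pheno_assert(file.exists(path), "not_found_error", paste0("no such store: ", path))
  s <- new.env(parent = emptyenv())
  s$con <- DBI::dbConnect(RSQLite::SQLite(), path)
  s$path <- path
  class(s) <- "pheno_store"
  s
}

#' Close a store handle
#' @param store a `pheno_store`.
#' @export
store_close <- function(store) {
  DBI::dbDisconnect(store$con)
  invisible(NULL)
}

#' @export
print.pheno_store <- function(x, ...) {
  n <- DBI::dbGetQuery(x$con, "SELECT
      (SELECT COUNT(*) FROM users) AS users,
      (SELECT COUNT(*) FROM projects) AS projects,
      (SELECT COUNT(*) FROM datasets) AS datasets,
      (SELECT COUNT(*) FROM eav_rows) AS rows")
  cat(sprintf("<results store %s: %d user(s), %d project(s), %d dataset(s), %d EAV row(s)>\n",
              x$path, n$users, n$projects, n$datasets, n$rows))
  invisible(x)
}

#' Register a user
#'
#' @param store a `pheno_store`.
#' @param user_id unique user id.
#' @param given_name,family_name the names shown next to ownership stamps.
#' @param is_admin administrator flag (gates vocabulary/project
#'   administration at the CLI level; the library itself is policy-free).
#' @param external_researcher_id optional free-text external researcher
#'   identifier.
#' @return `user_id`, invisibly.
#' @export
add_user <- function(store, user_id, given_name = "", family_name = "",
                     is_admin = FALSE, external_researcher_id = NULL) {
  pheno_assert(nzchar(user_id), "validation_error", "user_id must be non-empty")
  pheno_assert(nrow(get_rows(store, "users", "user_id", user_id)) == 0L,
               "conflict_error", paste0("user already exists: ", user_id))
  DBI::dbExecute(store$con,
    "INSERT INTO users VALUES (:i, :g, :f, :a, :e)",
    params = list(i = user_id, g = given_name, f = family_name,
                  a = as.integer(is_admin),
                  e = external_researcher_id %||% NA_character_))
  invisible(user_id)
}

#' Register a project
#'
#' @param store a `pheno_store`.
#' @param project_id unique project id.
#' @param name display name.
#' @param embargo_days non-negative embargo duration for datasets
#'   assigned to this project.
#' @return `project_id`, invisibly.
#' @export
add_project <- function(store, project_id, name = project_id, embargo_days = 0L) {
  pheno_assert(nzchar(project_id), "validation_error", "project_id must be non-empty")
  embargo_days <- as.integer(embargo_days)
  pheno_assert(!is.na(embargo_days) && embargo_days >= 0L, "validation_error",
               "embargo_days must be a non-negative integer")
  pheno_assert(nrow(get_rows(store, "projects", "project_id", project_id)) == 0L,
               "conflict_error", paste0("project already exists: ", project_id))
  DBI::dbExecute(store$con, "INSERT INTO projects VALUES (:i, :n, :e)",
                 params = list(i = project_id, n = name, e = embargo_days))
  invisible(project_id)
}

get_rows <- function(store, table, col, val) {
  DBI::dbGetQuery(store$con,
                  sprintf("SELECT * FROM %s WHERE %s = :v", table, col),
                  params = list(v = val))
}

#' Manage project membership
#'
#' Users and projects are in an m:n relationship: each user can belong
#' to several projects and each project can be shared by several users.
#' Both actions are idempotent.
#'
#' @param store a `pheno_store`.
#' @param user_id,project_id existing user and project.
#' @param action `"add"` or `"remove"`.
#' @return The store, invisibly.
#' @export
manage_membership <- function(store, user_id, project_id,
                              action = c("add", "remove")) {
  action <- match.arg(action)
  pheno_assert(nrow(get_rows(store, "users", "user_id", user_id)) == 1L,
               "not_found_error", paste0("unknown user: ", user_id))
  pheno_assert(nrow(get_rows(store, "projects", "project_id", project_id)) == 1L,
               "not_found_error", paste0("unknown project: ", project_id))
  if (action == "add") {
    DBI::dbExecute(store$con,
      "INSERT OR IGNORE INTO memberships VALUES (:u, :p)",
      params = list(u = user_id, p = project_id))
  } else {
    DBI::dbExecute(store$con,
      "DELETE FROM memberships WHERE user_id = :u AND project_id = :p",
      params = list(u = user_id, p = project_id))
  }
  invisible(store)
}

#' Is a user affiliated with a project?
#' @inheritParams manage_membership
#' @return Logical scalar.
#' @export
is_member <- function(store, user_id, project_id) {
  nrow(DBI::dbGetQuery(store$con,
    "SELECT 1 FROM memberships WHERE user_id = :u AND project_id = :p",
    params = list(u = user_id, p = project_id))) > 0L
}

#' Projects a user belongs to
#' @param store a `pheno_store`.
#' @param user_id user id.
#' @return Character vector of project ids.
#' @export
user_projects <- function(store, user_id) {
  DBI::dbGetQuery(store$con,
    "SELECT project_id FROM memberships WHERE user_id = :u ORDER BY project_id",
    params = list(u = user_id))$project_id
}

#' Mirror a vocabulary registry into the store
#'
#' Replaces the store's vocabulary mirror with the given registry
#' (terms, CURIEs, units and all labels), so results data stay
#' interpretable without access to the vocabulary's source database.
#'
#' @param store a `pheno_store`.
#' @param registry a [term_registry()].
#' @return The store, invisibly.
#' @export
mirror_to_store <- function(store, registry) {
  stopifnot(inherits(registry, "term_registry"))
  DBI::dbWithTransaction(store$con, {
    DBI::dbExecute(store$con, "DELETE FROM vocab_labels")
    DBI::dbExecute(store$con, "DELETE FROM vocab_terms")
    DBI::dbExecute(store$con,
      "INSERT OR REPLACE INTO store_meta VALUES ('default_language', :v)",
      params = list(v = registry$default_language))
    for (t in registry$terms) {
      DBI::dbExecute(store$con,
        "INSERT INTO vocab_terms VALUES (:i, :k, :o, :u, :d)",
        params = list(i = t$term_id, k = t$kind,
                      o = t$ontology_ref %||% NA_character_,
                      u = t$unit %||% NA_character_,
                      d = t$definition %||% NA_character_))
      for (lang in names(t$labels)) {
        DBI::dbExecute(store$con, "INSERT INTO vocab_labels VALUES (:i, :l, :t)",
                       params = list(i = t$term_id, l = lang, t = t$labels[[lang]]))
      }
    }
  })
  invisible(store)
}

#' Read the store's vocabulary mirror back as a registry
#' @param store a `pheno_store`.
#' @return A [term_registry()].
#' @export
store_registry <- function(store) {
  lang <- DBI::dbGetQuery(store$con,
    "SELECT value FROM store_meta WHERE key = 'default_language'")$value
  reg <- term_registry(if (length(lang)) lang else "en")
  terms <- DBI::dbGetQuery(store$con, "SELECT * FROM vocab_terms ORDER BY term_id")
  labels <- DBI::dbGetQuery(store$con, "SELECT * FROM vocab_labels")
  for (i in seq_len(nrow(terms))) {
    labs <- labels[labels$term_id == terms$term_id[i], , drop = FALSE]
    reg <- add_term(reg, term(
      terms$term_id[i], terms$kind[i],
      setNames(labs$label, labs$lang),
      ontology_ref = if (is.na(terms$ontology_ref[i])) NULL else terms$ontology_ref[i],
      definition = if (is.na(terms$definition[i])) NULL else terms$definition[i],
      unit = if (is.na(terms$unit[i])) NULL else terms$unit[i]))
  }
  reg
}

#' Ingest a dataset draft into the store
#'
#' Inserts the dataset metadata and one EAV row per observation record,
#' atomically: an unresolvable term reference (or any other failure)
#' rolls back the whole ingest and leaves no rows behind. Re-ingesting a
#' file with an already-known curated checksum is refused unless
#' `force = TRUE`.
#'
#' @param store a `pheno_store` whose vocabulary mirror covers the
#'   draft's terms.
#' @param draft a [build_dataset()] result.
#' @param force re-ingest even if the curated checksum is already present.
#' @return The new `dataset_id`.
#' @export
ingest_dataset <- function(store, draft, force = FALSE) {
  stopifnot(inherits(draft, "dataset_draft"))
  pheno_assert(nrow(get_rows(store, "users", "user_id", draft$owner)) == 1L,
               "not_found_error", paste0("unknown owner: ", draft$owner))
  if (!is.null(draft$project)) {
    pheno_assert(nrow(get_rows(store, "projects", "project_id", draft$project)) == 1L,
                 "not_found_error", paste0("unknown project: ", draft$project))
    pheno_assert(is_member(store, draft$owner, draft$project),
                 "authorization_error",
                 paste0("owner '", draft$owner, "' is not a member of project '",
                        draft$project, "'"))
  }
  cks <- draft$files$curated_checksum
  if (!force && !is.null(cks)) {
    dup <- DBI::dbGetQuery(store$con,
      "SELECT dataset_id FROM datasets WHERE curated_checksum = :c",
      params = list(c = cks))
    pheno_assert(nrow(dup) == 0L, "conflict_error",
                 paste0("curated file already ingested as dataset ",
                        paste(dup$dataset_id, collapse = ", "),
                        " (use force = TRUE to re-ingest)"))
  }

  dataset_id <- new_id()
  r <- draft$records
  DBI::dbWithTransaction(store$con, {
    known <- DBI::dbGetQuery(store$con, "SELECT term_id FROM vocab_terms")$term_id
    refs <- unique(c(r$entity_id, r$attribute_id,
                     r$value_term_id[!is.na(r$value_term_id)]))
    missing <- setdiff(refs, known)
    pheno_assert(length(missing) == 0L, "not_found_error",
                 paste0("term(s) not in vocabulary mirror: ",
                        paste(missing, collapse = ", ")))
    DBI::dbExecute(store$con,
      "INSERT INTO datasets VALUES (:d, :o, :p, :t, :rp, :cp, :rc, :cc, :n)",
      params = list(d = dataset_id, o = draft$owner,
                    p = draft$project %||% NA_character_,
                    t = fmt_ts(draft$uploaded_at),
                    rp = draft$files$raw_path, cp = draft$files$curated_path,
                    rc = draft$files$raw_checksum, cc = cks,
                    n = nrow(r)))
    if (nrow(r)) {
      DBI::dbExecute(store$con,
        "INSERT INTO eav_rows VALUES (:d, :i, :e, :a, :k, :nv, :u, :v, :t)",
        params = list(d = rep(dataset_id, nrow(r)), i = r$identifier,
                      e = r$entity_id, a = r$attribute_id, k = r$value_kind,
                      nv = r$numeric_value, u = r$unit, v = r$value_term_id,
                      t = fmt_ts(r$recorded_at)))
    }
  })
  dataset_id
}

#' Dataset metadata
#' @param store a `pheno_store`.
#' @param dataset_id id returned by [ingest_dataset()].
#' @return One-row data.frame of dataset metadata.
#' @export
get_dataset <- function(store, dataset_id) {
  d <- get_rows(store, "datasets", "dataset_id", dataset_id)
  pheno_assert(nrow(d) == 1L, "not_found_error",
               paste0("unknown dataset: ", dataset_id))
  d
}

#' List all datasets
#' @param store a `pheno_store`.
#' @return Data.frame of dataset metadata, ordered by dataset id.
#' @export
list_datasets <- function(store) {
  DBI::dbGetQuery(store$con, "SELECT * FROM datasets ORDER BY dataset_id")
}

#' Query filter
#'
#' All fields are optional and combine as a conjunction; `NULL` means
#' "no restriction". `requesting_user` and `as_of` are only needed when
#' the filter drives an access-controlled export.
#'
#' @param entity_ids,attribute_ids,object_identifiers,dataset_ids
#'   character vectors restricting the respective columns.
#' @param project restrict to datasets of one project.
#' @param from,to inclusive bounds on the measurement timestamp
#'   (POSIXct or ISO-8601 strings).
#' @param requesting_user user on whose behalf an export runs.
#' @param as_of instant at which access is evaluated.
#' @return An object of class `query_filter`.
#' @export
query_filter <- function(entity_ids = NULL, attribute_ids = NULL,
                         object_identifiers = NULL, dataset_ids = NULL,
                         project = NULL, from = NULL, to = NULL,
                         requesting_user = NULL, as_of = NULL) {
  to_time <- function(x) {
    if (is.null(x)) NULL else if (is.character(x)) parse_ts(x) else as.POSIXct(x, tz = "UTC")
  }
  structure(list(entity_ids = entity_ids, attribute_ids = attribute_ids,
                 object_identifiers = object_identifiers,
                 dataset_ids = dataset_ids, project = project,
                 from = to_time(from), to = to_time(to),
                 requesting_user = requesting_user, as_of = to_time(as_of)),
            class = "query_filter")
}

#' Query EAV rows
#'
#' Returns the observation rows satisfying the conjunction of the
#' filter's provided fields, in stable
#' (dataset, identifier, entity, attribute) order. An empty result is
#' valid. No access policy is applied here; see [export_query()] for
#' policy-enforcing reads.
#'
#' @param store a `pheno_store`.
#' @param filter a [query_filter()] (default: no restriction).
#' @return Data.frame of EAV rows with `recorded_at` as POSIXct.
#' @export
query_eav <- function(store, filter = query_filter()) {
  stopifnot(inherits(filter, "query_filter"))
  where <- character()
  params <- list()
  add_in <- function(col, vals, tag) {
    if (is.null(vals)) return()
    ph <- paste0(":", tag, seq_along(vals))
    where <<- c(where, sprintf("r.%s IN (%s)", col, paste(ph, collapse = ", ")))
    params[sub(":", "", ph)] <<- as.list(as.character(vals))
  }
  add_in("entity_id", filter$entity_ids, "e")
  add_in("attribute_id", filter$attribute_ids, "a")
  add_in("object_identifier", filter$object_identifiers, "i")
  add_in("dataset_id", filter$dataset_ids, "d")
  if (!is.null(filter$project)) {
    where <- c(where, "d2.project = :proj")
    params$proj <- filter$project
  }
  if (!is.null(filter$from)) {
    where <- c(where, "r.recorded_at >= :from")
    params$from <- fmt_ts(filter$from)
  }
  if (!is.null(filter$to)) {
    where <- c(where, "r.recorded_at <= :upto")
    params$upto <- fmt_ts(filter$to)
  }
  sql <- paste0(
    "SELECT r.* FROM eav_rows r JOIN datasets d2 ON r.dataset_id = d2.dataset_id",
    if (length(where)) paste0(" WHERE ", paste(where, collapse = " AND ")) else "",
    " ORDER BY r.dataset_id, r.object_identifier, r.entity_id, r.attribute_id")
  out <- if (length(params)) {
    DBI::dbGetQuery(store$con, sql, params = params)
  } else {
    DBI::dbGetQuery(store$con, sql)
  }
  out$recorded_at <- if (nrow(out)) parse_ts(out$recorded_at) else
    as.POSIXct(character(), tz = "UTC")
  out
}

#' Pivot EAV rows to a wide table
#'
#' One output row per object identifier, one column per
#' (entity, attribute) pair present in the rows, in sorted pair order;
#' cells stay empty where an object was not scored for a pair.
#' Column headers and categorical values are labelled via the store's
#' vocabulary mirror. Conflicting duplicate values for the same
#' (identifier, entity, attribute) abort with a conflict listing the
#' offenders.
#'
#' @param store a `pheno_store` (for the vocabulary mirror).
#' @param rows EAV rows from [query_eav()].
#' @return A `results_table` (see [write_results_table()]).
#' @export
pivot_wide <- function(store, rows) {
  reg <- store_registry(store)
  lab <- function(id) {
    if (id %in% names(reg$terms)) resolve_label(reg, id) else id
  }
  pairs <- unique(rows[, c("entity_id", "attribute_id"), drop = FALSE])
  pairs <- pairs[order(pairs$entity_id, pairs$attribute_id), , drop = FALSE]
  keys <- data.frame(
    column = col_key(pairs$entity_id, pairs$attribute_id),
    entity_id = pairs$entity_id, attribute_id = pairs$attribute_id,
    entity_label = vapply(pairs$entity_id, lab, ""),
    attribute_label = vapply(pairs$attribute_id, lab, ""),
    unit = vapply(seq_len(nrow(pairs)), function(i) {
      u <- unique(stats::na.omit(rows$unit[rows$entity_id == pairs$entity_id[i] &
                                             rows$attribute_id == pairs$attribute_id[i]]))
      if (length(u)) u[1] else NA_character_
    }, ""), stringsAsFactors = FALSE)
  rownames(keys) <- NULL

  key_of <- sprintf("%s\n%s\n%s", rows$object_identifier, rows$entity_id,
                    rows$attribute_id)
  val_of <- ifelse(rows$value_kind == "numeric",
                   fmt_num_vec(rows$numeric_value),
                   vapply(rows$value_term_id, function(v)
                     if (is.na(v)) "" else lab(v), ""))
  conf <- tapply(val_of, key_of, function(v) length(unique(v)) > 1L)
  if (length(conf) && any(conf)) {
    offenders <- vapply(strsplit(names(conf)[conf], "\n", fixed = TRUE), `[[`, "", 1L)
    pheno_error("conflict_error",
                paste0("conflicting duplicate values for identifier(s): ",
                       paste(unique(offenders), collapse = ", ")))
  }

  ids <- unique(rows$object_identifier)
  data <- data.frame(identifier = ids, stringsAsFactors = FALSE,
                     check.names = FALSE)
  data$timestamp <- vapply(ids, function(id) {
    sel <- rows$object_identifier == id
    if (any(sel)) fmt_ts(max(rows$recorded_at[sel])) else ""
  }, "")
  data$device <- rep("", length(ids))
  for (k in seq_len(nrow(keys))) {
    col <- rep("", length(ids))
    sel <- rows$entity_id == keys$entity_id[k] &
      rows$attribute_id == keys$attribute_id[k]
    sub <- rows[sel, , drop = FALSE]
    col[match(sub$object_identifier, ids)] <- val_of[sel]
    data[[keys$column[k]]] <- col
  }
  results_table(data, keys)
}

#' Attach free metadata to an object identifier
#'
#' Hook for linking opaque object identifiers to external information
#' (field plans, sample sheets) in stand-alone use.
#'
#' @param store a `pheno_store`.
#' @param identifier object identifier.
#' @param key,value metadata entry (last write wins per key).
#' @return The store, invisibly.
#' @export
set_object_metadata <- function(store, identifier, key, value) {
  DBI::dbExecute(store$con,
    "INSERT OR REPLACE INTO object_metadata VALUES (:i, :k, :v)",
    params = list(i = identifier, k = key, v = as.character(value)))
  invisible(store)
}

#' Read metadata of an object identifier
#' @param store a `pheno_store`.
#' @param identifier object identifier.
#' @return Named character vector of metadata entries.
#' @export
get_object_metadata <- function(store, identifier) {
  df <- DBI::dbGetQuery(store$con,
    "SELECT key, value FROM object_metadata WHERE identifier = :i ORDER BY key",
    params = list(i = identifier))
  setNames(df$value, df$key)
}
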