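# Wide result tables: the csv surface of capture sessions and exports.
#
# A results_table is a wide data.frame (identifier, timestamp, device,
# then one character column per (entity, attribute) pair) plus a key
# table mapping each value column to its term ids, labels and unit.
# Column names are the machine keys "<entity_id>|<attribute_id>".

results_table <- function(data, keys) {
  stopifnot(is.data.frame(data), is.data.frame(keys))
  structure(list(data = data, keys = keys), class = "results_table")
}

#' @export
print.results_table <- function(x, ...) {
  cat(sprintf("<results table: %d row(s) x %d variable column(s)>\n",
              nrow(x$data), nrow(x$keys)))
  print(utils::head(x$data, 10))
  invisible(x)
}

#' @export
as.data.frame.results_table <- function(x, ...) x$data

col_key <- function(entity_id, attribute_id) {
  sprintf("%s|%s", entity_id, attribute_id)  # length-0-safe, unlike paste0
}

# build the wide table for a session: columns in scheme order, rows in
# identifier-open order, only identifiers with at least one record
session_results_table <- function(session, records = session_records(session)) {
  scheme <- session$scheme
  pairs <- scheme_pairs(scheme)
  snap <- scheme$snapshot$terms
  keys <- data.frame(
    column = col_key(pairs$entity_id, pairs$attribute_id),
    entity_id = pairs$entity_id, attribute_id = pairs$attribute_id,
    entity_label = vapply(pairs$entity_id, function(i) snap[[i]]$label, ""),
    attribute_label = vapply(pairs$attribute_id, function(i) snap[[i]]$label, ""),
    unit = vapply(seq_len(nrow(pairs)), function(i) {
      p <- scheme_parameter(scheme, pairs$entity_id[i], pairs$attribute_id[i])
      p$unit %||% NA_character_
    }, ""),
    stringsAsFactors = FALSE)
  rownames(keys) <- NULL

  ids <- unique(records$identifier)
  data <- data.frame(identifier = ids, stringsAsFactors = FALSE,
                     check.names = FALSE)
  data$timestamp <- vapply(ids, function(id) {
    fmt_ts(max(records$recorded_at[records$identifier == id]))
  }, "")
  data$device <- vapply(ids, function(id) {
    records$device_name[records$identifier == id][1]
  }, "")
  for (k in seq_len(nrow(keys))) {
    col <- rep("", length(ids))
    sel <- records$entity_id == keys$entity_id[k] &
      records$attribute_id == keys$attribute_id[k]
    sub <- records[sel, , drop = FALSE]
    m <- match(sub$identifier, ids)
    col[m] <- ifelse(sub$value_kind == "numeric",
                     fmt_num_vec(sub$numeric_value), sub$value_term_id)
    data[[keys$column[k]]] <- col
  }
  results_table(data, keys)
}

fmt_num_vec <- function(x) vapply(x, fmt_num, "")

csv_quote <- function(x) {
  needs <- grepl('[",\n]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

#' Write a results table to csv
#'
#' Canonical dialect: comma delimiter, `"` quoting, UTF-8, `"."`
#' decimals, three header rows (entity labels; attribute labels with
#' unit in parentheses; machine term-id keys) before the data rows.
#'
#' @param table a `results_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(table, path) {
  stopifnot(inherits(table, "results_table"))
  k <- table$keys
  h1 <- c("identifier", "timestamp", "device", k$entity_label)
  h2 <- c("", "", "", ifelse(is.na(k$unit), k$attribute_label,
                             paste0(k$attribute_label, " (", k$unit, ")")))
  h3 <- c("#key", "", "", k$column)
  lines <- c(paste(csv_quote(h1), collapse = ","),
             paste(csv_quote(h2), collapse = ","),
             paste(csv_quote(h3), collapse = ","))
  for (i in seq_len(nrow(table$data))) {
    row <- vapply(table$data[i, , drop = FALSE], as.character, "")
    lines <- c(lines, paste(csv_quote(row), collapse = ","))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

split_csv_line <- function(line) {
  out <- character()
  field <- ""
  in_q <- FALSE
  chars <- strsplit(line, "")[[1]]
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (in_q) {
      if (ch == '"') {
        if (i < length(chars) && chars[i + 1L] == '"') {
          field <- paste0(field, '"'); i <- i + 1L
        } else in_q <- FALSE
      } else field <- paste0(field, ch)
    } else if (ch == '"') {
      in_q <- TRUE
    } else if (ch == ",") {
      out <- c(out, field); field <- ""
    } else field <- paste0(field, ch)
    i <- i + 1L
  }
  c(out, field)
}

#' Read a results csv back into a results table
#'
#' @param path csv file written by [write_results_table()] (directly or
#'   via [write_results_csv()] / [merge_result_tables()]).
#' @return A `results_table`.
#' @export
read_results_table <- function(path) {
  pheno_assert(file.exists(path), "not_found_error", paste0("no such file: ", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  pheno_assert(length(lines) >= 3L, "validation_error",
               "not a results csv: fewer than 3 header rows")
  h1 <- split_csv_line(lines[1]); h2 <- split_csv_line(lines[2])
  h3 <- split_csv_line(lines[3])
  pheno_assert(identical(h1[1:3], c("identifier", "timestamp", "device")) &&
                 identical(h3[1], "#key"),
               "validation_error", "not a results csv: unexpected headers")
  ncol <- length(h1)
  cols <- if (ncol > 3L) h3[4:ncol] else character()
  parts <- strsplit(cols, "|", fixed = TRUE)
  units <- sub("^.* \\(([^)]*)\\)$", "\\1", h2[-(1:3)])
  units[units == h2[-(1:3)]] <- NA_character_
  keys <- data.frame(
    column = cols,
    entity_id = vapply(parts, `[[`, "", 1L),
    attribute_id = vapply(parts, `[[`, "", 2L),
    entity_label = if (ncol > 3L) h1[4:ncol] else character(),
    attribute_label = sub(" \\([^)]*\\)$", "", h2[-(1:3)]),
    unit = units, stringsAsFactors = FALSE)

  rows <- lapply(lines[-(1:3)], split_csv_line)
  data <- data.frame(identifier = vapply(rows, `[[`, "", 1L),
                     timestamp = vapply(rows, `[[`, "", 2L),
                     device = vapply(rows, `[[`, "", 3L),
                     stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_along(cols)) {
    data[[cols[j]]] <- vapply(rows, function(r) {
      if (length(r) >= j + 3L) r[[j + 3L]] else ""
    }, "")
  }
  results_table(data, keys)
}

# long view of a results table: one row per non-empty cell
results_table_records <- function(table) {
  stopifnot(inherits(table, "results_table"))
  out <- list()
  for (k in seq_len(nrow(table$keys))) {
    col <- table$data[[table$keys$column[k]]]
    sel <- nzchar(col)
    if (!any(sel)) next
    out[[length(out) + 1L]] <- data.frame(
      identifier = table$data$identifier[sel],
      entity_id = table$keys$entity_id[k],
      attribute_id = table$keys$attribute_id[k],
      value = col[sel], stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(identifier = character(), entity_id = character(),
                      attribute_id = character(), value = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Merge result csv tables from different schemes
#'
#' Combines tables column-wise by the union of their (entity, attribute)
#' variables, in order of first appearance across the inputs. Rows keep
#' their source values; cells stay empty for variables absent from a
#' row's source scheme — the expected shape when phases of a project
#' score different parameter sets. Identifiers must be unique across
#' inputs; duplicates abort with a conflict listing them.
#'
#' @param tables list of `results_table`s or csv file paths.
#' @param path optional output csv path.
#' @return The merged `results_table`.
#' @export
merge_result_tables <- function(tables, path = NULL) {
  pheno_assert(length(tables) >= 1L, "validation_error",
               "need at least one table to merge")
  tables <- lapply(tables, function(t) {
    if (inherits(t, "results_table")) t else read_results_table(t)
  })

  all_ids <- unlist(lapply(tables, function(t) t$data$identifier))
  dup <- unique(all_ids[duplicated(all_ids)])
  pheno_assert(length(dup) == 0L, "conflict_error",
               paste0("duplicate identifier(s) across merged files: ",
                      paste(dup, collapse = ", ")))

  keys <- tables[[1]]$keys
  for (t in tables[-1]) {
    keys <- rbind(keys, t$keys[!t$keys$column %in% keys$column, , drop = FALSE])
  }
  rownames(keys) <- NULL

  data <- data.frame(identifier = all_ids, stringsAsFactors = FALSE,
                     check.names = FALSE)
  data$timestamp <- unlist(lapply(tables, function(t) t$data$timestamp))
  data$device <- unlist(lapply(tables, function(t) t$data$device))
  for (col in keys$column) {
    data[[col]] <- unlist(lapply(tables, function(t) {
      if (col %in% names(t$data)) t$data[[col]] else rep("", nrow(t$data))
    }))
  }
  out <- results_table(data, keys)
  if (!is.null(path)) write_results_table(out, path)
  out
}
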