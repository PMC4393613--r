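#' @importFrom stats setNames runif rbinom
#' @importFrom utils head modifyList read.csv write.csv
NULL

# Structured conditions: every user-facing failure carries a class so callers
# (and tests) can discriminate without string matching.
pheno_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "phenotyper_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

pheno_assert <- function(ok, class, message, ...) {
  if (!isTRUE(ok)) pheno_error(class, message, ...)
  invisible(TRUE)
}

#' Check a compact ontology identifier (CURIE)
#'
#' A CURIE of the shape `PREFIX:digits` (e.g. `PO:0025034`, `TO:0000207`)
#' links a vocabulary term back to its source ontology.
#'
#' @param x character string to test.
#' @return `TRUE` if `x` is a well-formed CURIE.
#' @export
is_curie <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) &&
    grepl("^[A-Za-z][A-Za-z0-9]*:[0-9]+$", x)
}

# ---- timestamps ------------------------------------------------------------
# All timestamps are POSIXct in UTC internally and ISO-8601 with explicit
# offset ("+00:00") on disk, so files are unambiguous across devices.

fmt_ts <- function(t) {
  stopifnot(inherits(t, "POSIXct"))
  paste0(format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC"), "+00:00")
}

parse_ts <- function(s) {
  t <- as.POSIXct(sub("([+-][0-9]{2}):?([0-9]{2})$", "\\1\\2", s),
                  format = "%Y-%m-%dT%H:%M:%S%z", tz = "UTC")
  pheno_assert(!any(is.na(t)), "validation_error",
               paste0("unparseable timestamp: ", paste(s[is.na(t)], collapse = ", ")))
  t
}

utc_time <- function(y, mo, d, h = 0L, mi = 0L, s = 0L) {
  as.POSIXct(sprintf("%04d-%02d-%02d %02d:%02d:%02d", y, mo, d, h, mi, s),
             tz = "UTC")
}

#' Deterministic injectable clock
#'
#' Capture and upload timestamps are never read from the ambient system
#' clock; every time-dependent operation takes a clock function. A manual
#' clock starts at a given instant and advances by a fixed step on each
#' call, which makes timestamp behaviour fully reproducible.
#'
#' @param start POSIXct (or ISO-8601 string) of the first tick.
#' @param step_seconds seconds added per call (default 1).
#' @return A zero-argument function returning a POSIXct (UTC).
#' @examples
#' clk <- manual_clock("2015-04-07T09:00:00+00:00")
#' clk(); clk()
#' @export
manual_clock <- function(start, step_seconds = 1) {
  t <- if (is.character(start)) parse_ts(start) else as.POSIXct(start, tz = "UTC")
  first <- TRUE
  function() {
    if (!first) t <<- t + step_seconds
    first <<- FALSE
    t
  }
}

#' System clock in UTC
#' @return POSIXct of the current instant.
#' @export
system_clock <- function() as.POSIXct(Sys.time(), tz = "UTC")

# ---- misc ------------------------------------------------------------------

sha256_file <- function(path) {
  pheno_assert(file.exists(path), "not_found_error", paste0("no such file: ", path))
  digest::digest(path, algo = "sha256", file = TRUE)
}

new_id <- function() uuid::UUIDgenerate()

`%||%` <- function(a, b) if (is.null(a)) b else a

# xml2 attribute helper: NA when absent -> NULL
xattr <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) NULL else v
}

# deterministic canonical write: UTF-8, 2-space-equivalent indent via xml2
write_doc <- function(doc, path) {
  xml2::write_xml(doc, path, options = c("format", "no_declaration"))
  # prepend a fixed declaration so output bytes do not depend on libxml2 defaults
  txt <- readLines(path, encoding = "UTF-8", warn = FALSE)
  writeLines(c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>", txt), path, useBytes = TRUE)
  invisible(path)
}

doc_to_string <- function(doc) {
  tmp <- tempfile(fileext = ".xml")
  on.exit(unlink(tmp))
  write_doc(doc, tmp)
  paste(readLines(tmp, encoding = "UTF-8", warn = FALSE), collapse = "\n")
}
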