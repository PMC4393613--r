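test_that("identifier multiplication suffixes with hyphen and 1-based count", {
  ses <- demo_session()
  expect_equal(open_object(ses, "plot7", 2), c("plot7-1", "plot7-2"))
  expect_equal(open_object(ses, "plot8", 1), "plot8")       # no suffix
  expect_equal(open_object(ses, "plot9", 4),
               c("plot9-1", "plot9-2", "plot9-3", "plot9-4"))
  # base ids containing hyphens are fine; provenance is structural
  expect_equal(open_object(ses, "blk-3", 2), c("blk-3-1", "blk-3-2"))
  obj <- ses$objects
  expect_equal(obj$base_id[obj$identifier == "blk-3-2"], "blk-3")
  expect_equal(obj$index[obj$identifier == "blk-3-2"], 2L)

  expect_pheno_error(open_object(ses, "p", 0), "domain_error")
  expect_pheno_error(open_object(ses, "", 1), "validation_error")

  n <- 7L
  ids <- open_object(ses, "m", n)
  expect_length(unique(ids), n)
  expect_true(all(startsWith(ids, "m")))
})

test_that("session start validates the scheme file and uses the injected clock", {
  dir <- withr::local_tempdir()
  cfg <- device_config("dev", dir, clock = manual_clock("2015-04-07T09:00:00+00:00"))
  expect_pheno_error(start_session(file.path(dir, "absent.xml"), cfg),
                     "not_found_error")

  bad <- file.path(dir, "bad.xml")
  writeLines("<phenotyping_scheme/>", bad)
  err <- tryCatch(start_session(bad, cfg), error = identity)
  expect_s3_class(err, "validation_error")
  expect_s3_class(err$report, "validation_report")

  good <- file.path(dir, "good.xml")
  scheme_to_xml(demo_scheme(), good)
  ses <- start_session(good, cfg)
  expect_equal(ses$started_at, phenotyper:::parse_ts("2015-04-07T09:00:00+00:00"))
  expect_length(ses$open_identifiers, 0L)
})

test_that("values parse per datatype, separator and label, and edits overwrite", {
  dir <- withr::local_tempdir()
  cfg <- device_config("dev", dir, decimal_separator = ",",
                       clock = manual_clock("2015-04-07T09:00:00+00:00"))
  ses <- start_session(demo_scheme(), cfg)
  open_object(ses, "p1", 1)

  rec <- record_value(ses, "p1", "e.leaf", "a.length", "3,5")
  expect_identical(rec$numeric_value, 3.5)
  expect_equal(rec$unit, "cm")
  expect_pheno_error(record_value(ses, "p1", "e.leaf", "a.length", "3.5"),
                     "parse_error")       # wrong separator for this device
  expect_pheno_error(record_value(ses, "p1", "e.leaf", "a.length", "abc"),
                     "parse_error")

  # categorical: value id or its label in the scheme language
  r1 <- record_value(ses, "p1", "e.leaf", "a.color", "v.green")
  expect_equal(r1$value_term_id, "v.green")
  r2 <- record_value(ses, "p1", "e.leaf", "a.color", "yellow")
  expect_equal(r2$value_term_id, "v.yellow")
  expect_pheno_error(record_value(ses, "p1", "e.leaf", "a.color", "purple"),
                     "domain_violation_error")

  expect_pheno_error(record_value(ses, "unopened", "e.leaf", "a.length", "1"),
                     "not_found_error")
  expect_pheno_error(record_value(ses, "p1", "e.leaf", "a.height", "1"),
                     "not_found_error")

  # recall returns only the latest value per key
  rc <- recall_entry(ses, "p1")
  expect_length(rc, 2L)
  expect_equal(rc[[phenotyper:::rec_key("e.leaf", "a.color")]]$value_term_id,
               "v.yellow")
  expect_pheno_error(recall_entry(ses, "nope"), "not_found_error")

  # timestamps from the clock are strictly ordered across records
  recs <- phenotyper:::session_records(ses)
  expect_false(is.unsorted(recs$recorded_at))
})

test_that("result file names combine device, date and time uniquely", {
  cfg1 <- device_config("elf01", withr::local_tempdir())
  cfg2 <- device_config("elf02", withr::local_tempdir())
  t1 <- phenotyper:::utc_time(2015, 4, 7, 14, 3, 9)
  expect_equal(result_file_name(cfg1, t1), "elf01_20150407_140309")
  expect_false(result_file_name(cfg1, t1) == result_file_name(cfg1, t1 + 1))
  expect_false(result_file_name(cfg1, t1) == result_file_name(cfg2, t1))
})

test_that("csv writer produces one row per identifier with empty unscored cells", {
  ses <- demo_session()
  tab <- write_results_csv(ses, withr::local_tempfile(fileext = ".csv"))
  df <- as.data.frame(tab)
  expect_equal(nrow(df), 2L)
  expect_equal(names(df)[1:3], c("identifier", "timestamp", "device"))
  expect_equal(nrow(tab$keys), 3L)
  # p42-2 lacks a.color: exactly one empty cell in its row
  vals <- unlist(df[df$identifier == "p42-2", tab$keys$column])
  expect_equal(sum(vals == ""), 1L)
  vals1 <- unlist(df[df$identifier == "p42-1", tab$keys$column])
  expect_equal(sum(vals1 == ""), 0L)

  # csv round trip preserves the record set
  back <- read_results_table(attr(tab, "path"))
  expect_identical(phenotyper:::results_table_records(back),
                   phenotyper:::results_table_records(tab))

  empty <- start_session(demo_scheme(),
                         device_config("d", withr::local_tempdir()))
  expect_pheno_error(write_results_csv(empty), "empty_output_error")
})

test_that("xml writer emits only scored measurements and validates", {
  ses <- demo_session()
  path <- write_results_xml(ses, withr::local_tempfile(fileext = ".xml"))
  expect_true(validate_results_document(path)$ok)
  doc <- xml2::read_xml(path)
  expect_length(xml2::xml_find_all(doc, "./object"), 2L)
  p422 <- xml2::xml_find_all(doc, "./object[@id='p42-2']/measurement")
  expect_length(p422, 2L)   # 2 of 3 parameters scored, no placeholders
})

test_that("csv and xml writers agree on the record set", {
  ses <- demo_session()
  xml_recs <- parse_results_document(
    write_results_xml(ses, withr::local_tempfile(fileext = ".xml")))
  tab <- write_results_csv(ses, withr::local_tempfile(fileext = ".csv"))
  csv_recs <- phenotyper:::results_table_records(tab)
  key_xml <- sort(sprintf("%s|%s|%s|%s", xml_recs$identifier, xml_recs$entity_id,
                          xml_recs$attribute_id,
                          ifelse(xml_recs$value_kind == "numeric",
                                 sprintf("%.15g", xml_recs$numeric_value),
                                 xml_recs$value_term_id)))
  key_csv <- sort(sprintf("%s|%s|%s|%s", csv_recs$identifier, csv_recs$entity_id,
                          csv_recs$attribute_id, csv_recs$value))
  expect_identical(key_csv, key_xml)
})

test_that("numeric values survive entry and serialization exactly", {
  for (sep in c(".", ",")) {
    dir <- withr::local_tempdir()
    cfg <- device_config("dev", dir, decimal_separator = sep,
                         clock = manual_clock("2015-04-07T09:00:00+00:00"))
    ses <- start_session(demo_scheme(), cfg)
    open_object(ses, "p", 1)
    vals <- c("0.1", "3.5", "101", "-2.25", "99.9")
    entered <- if (sep == ",") sub(".", ",", vals, fixed = TRUE) else vals
    for (i in seq_along(vals)) {
      record_value(ses, "p", "e.leaf", "a.length", entered[i])
      xml <- write_results_xml(ses, withr::local_tempfile(fileext = ".xml"))
      back <- parse_results_document(xml)
      expect_identical(back$numeric_value, as.numeric(vals[i]))
    }
  }
})

test_that("session persists after every record and reloads losslessly", {
  dir <- withr::local_tempdir()
  cfg <- device_config("dev", dir, clock = manual_clock("2015-04-07T09:00:00+00:00"))
  ses <- start_session(demo_scheme(), cfg)
  open_object(ses, "p1", 2)
  record_value(ses, "p1-1", "e.leaf", "a.length", "1.5")
  expect_true(file.exists(ses$file))

  reloaded <- load_session(ses$file, cfg)
  expect_identical(phenotyper:::session_records(reloaded),
                   phenotyper:::session_records(ses))

  record_value(ses, "p1-2", "e.plant", "a.height", "80")
  record_value(ses, "p1-1", "e.leaf", "a.color", "green")
  reloaded2 <- load_session(ses$file, cfg)
  expect_identical(phenotyper:::session_records(reloaded2),
                   phenotyper:::session_records(ses))
  expect_identical(reloaded2$open_identifiers, ses$open_identifiers)
  expect_identical(reloaded2$scheme, ses$scheme)
})

test_that("merging tables from different schemes leaves the right cells empty", {
  reg <- demo_registry()
  doms <- phenotyper:::seed_domains()
  # scheme A measures {length, color}; scheme B measures {color, height}
  sA <- compose_scheme(reg, "A", "u1", blocks = list(
    entity_block("e.leaf", list(parameter("a.length", "numeric"),
                                parameter("a.color", "categorical",
                                          domain = doms$a.color)))),
    clock = manual_clock("2015-04-01T08:00:00+00:00"))
  sB <- compose_scheme(reg, "B", "u1", blocks = list(
    entity_block("e.leaf", list(parameter("a.color", "categorical",
                                          domain = doms$a.color))),
    entity_block("e.plant", list(parameter("a.height", "numeric")))),
    clock = manual_clock("2015-04-02T08:00:00+00:00"))

  mk <- function(s, ids, dev) {
    cfg <- device_config(dev, withr::local_tempdir(),
                         clock = manual_clock("2015-04-07T09:00:00+00:00"))
    ses <- start_session(s, cfg)
    for (id in ids) {
      open_object(ses, id, 1)
      pairs <- phenotyper:::scheme_pairs(s)
      for (i in seq_len(nrow(pairs))) {
        p <- phenotyper:::scheme_parameter(s, pairs$entity_id[i],
                                           pairs$attribute_id[i])
        record_value(ses, id, pairs$entity_id[i], pairs$attribute_id[i],
                     if (p$datatype == "numeric") "5" else p$domain[1])
      }
    }
    write_results_csv(ses, withr::local_tempfile(fileext = ".csv"))
  }
  tA <- mk(sA, c("x1", "x2"), "devA")
  tB <- mk(sB, c("y1"), "devB")

  merged <- merge_result_tables(list(tA, tB))
  expect_setequal(merged$keys$column,
                  c("e.leaf|a.length", "e.leaf|a.color", "e.plant|a.height"))
  df <- as.data.frame(merged)
  expect_equal(nrow(df), 3L)

  # independent dense-table oracle: expected emptiness per (row, column)
  expected_empty <- rbind(
    c(FALSE, FALSE, TRUE),   # x1: no height
    c(FALSE, FALSE, TRUE),   # x2: no height
    c(TRUE,  FALSE, FALSE))  # y1: no length
  got_empty <- as.matrix(df[, c("e.leaf|a.length", "e.leaf|a.color",
                                "e.plant|a.height")]) == ""
  dimnames(got_empty) <- NULL
  expect_identical(got_empty, expected_empty)
  # the shared color column is populated from both sources
  expect_true(all(df[["e.leaf|a.color"]] != ""))

  # merge of one table is the identity
  expect_identical(merge_result_tables(list(tA))$data, tA$data)

  # duplicate identifiers across files conflict, naming the ids
  err <- tryCatch(merge_result_tables(list(tA, tA)), error = identity)
  expect_s3_class(err, "conflict_error")
  expect_match(conditionMessage(err), "x1")

  # merged output is still a readable results csv
  out <- withr::local_tempfile(fileext = ".csv")
  write_results_table(merged, out)
  expect_identical(phenotyper:::results_table_records(read_results_table(out)),
                   phenotyper:::results_table_records(merged))
})
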