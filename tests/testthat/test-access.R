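# One store, four datasets spanning the owner/member/project/embargo
# combinations used throughout this file.
access_fixture <- function(embargo_days = 30L, default_embargo = 10L) {
  st <- demo_store(embargo_days = embargo_days)
  clk <- manual_clock("2015-04-08T12:00:00+00:00", step_seconds = 0)
  pair <- session_to_pair(demo_session())
  ds_proj <- ingest_dataset(st, build_dataset(pair, "u1", "P1",
                                              clock = clk, store = st))
  ds_priv <- ingest_dataset(st, build_dataset(pair, "u1", clock = clk),
                            force = TRUE)
  list(store = st, ds_proj = ds_proj, ds_priv = ds_priv,
       uploaded = phenotyper:::parse_ts("2015-04-08T12:00:00+00:00"),
       policy = access_policy(default_embargo))
}

test_that("the 24-case access truth table matches the three-clause rule", {
  fx <- access_fixture()
  st <- fx$store
  withr::defer(store_close(st))
  add_user(st, "u3", "No", "Body")          # neither owner nor member
  manage_membership(st, "u2", "P1", "add")  # member, not owner

  # independent evaluation of the published rule
  rule <- function(is_owner, is_member, has_project, phase, embargo_days) {
    after <- phase %in% c("at", "after")
    is_owner || (has_project && is_member) || after
  }
  for (user in c("u1", "u2", "u3")) {
    for (ds_id in c(fx$ds_proj, fx$ds_priv)) {
      has_project <- identical(ds_id, fx$ds_proj)
      embargo <- if (has_project) 30L else fx$policy$default_embargo_days
      for (phase in c("before", "at", "after")) {
        as_of <- fx$uploaded + embargo * 86400 +
          switch(phase, before = -1, at = 0, after = 86400)
        got <- is_accessible(st, user, ds_id, as_of, fx$policy)
        want <- rule(user == "u1",
                     is_member(st, user, "P1"),
                     has_project, phase, embargo)
        expect_identical(got, want,
                         info = sprintf("user=%s project=%s phase=%s",
                                        user, has_project, phase))
      }
    }
  }
  expect_pheno_error(
    is_accessible(st, "ghost", fx$ds_priv, fx$uploaded), "not_found_error")
})

test_that("embargo boundary is inclusive and access is monotone in time", {
  fx <- access_fixture()
  st <- fx$store
  withr::defer(store_close(st))
  boundary <- fx$uploaded + 30 * 86400
  expect_false(is_accessible(st, "u2", fx$ds_proj, boundary - 1, fx$policy))
  expect_true(is_accessible(st, "u2", fx$ds_proj, boundary, fx$policy))

  # monotonicity: once true, stays true at any later instant
  withr::local_seed(11)
  times <- fx$uploaded + sort(round(runif(40, -5, 60)) * 86400)
  for (user in c("u1", "u2")) {
    for (ds in c(fx$ds_proj, fx$ds_priv)) {
      acc <- vapply(times, function(t)
        is_accessible(st, user, ds, t, fx$policy), TRUE)
      expect_false(is.unsorted(acc))   # FALSE...TRUE, never back
    }
  }
})

test_that("exports contain only accessible rows and report withheld counts", {
  fx <- access_fixture()
  st <- fx$store
  withr::defer(store_close(st))
  before <- "2015-04-10T00:00:00+00:00"

  # u2: not owner, not member -> both datasets withheld before embargo ends
  ex <- export_query(st, query_filter(requesting_user = "u2", as_of = before),
                     fx$policy)
  expect_equal(nrow(as.data.frame(ex$table)), 0L)
  expect_equal(ex$n_withheld, 2L)

  # u1 owns both
  ex1 <- export_query(st, query_filter(requesting_user = "u1", as_of = before),
                      fx$policy)
  expect_equal(ex1$n_withheld, 0L)
  expect_equal(nrow(as.data.frame(ex1$table)), 2L)

  # time shift: after both embargoes elapse everything opens to u2
  after <- "2015-06-30T00:00:00+00:00"
  ex2 <- export_query(st, query_filter(requesting_user = "u2", as_of = after),
                      fx$policy)
  expect_equal(ex2$n_withheld, 0L)
  expect_identical(as.data.frame(ex2$table), as.data.frame(ex1$table))

  # csv and spreadsheet renderings carry identical cell values
  csvp <- withr::local_tempfile(fileext = ".csv")
  ssp <- withr::local_tempfile(fileext = ".xml")
  export_query(st, query_filter(requesting_user = "u1", as_of = before),
               fx$policy, format = "csv", path = csvp)
  export_query(st, query_filter(requesting_user = "u1", as_of = before),
               fx$policy, format = "spreadsheet", path = ssp)
  csv_cells <- unname(as.matrix(read_results_table(csvp)$data))
  ss <- phenotyper:::read_spreadsheet(ssp)
  expect_identical(unname(ss[-(1:3), , drop = FALSE]), csv_cells)
})

test_that("no export leaks rows from inaccessible datasets", {
  fx <- access_fixture()
  st <- fx$store
  withr::defer(store_close(st))
  withr::local_seed(23)
  users <- c("u1", "u2")
  for (i in 1:20) {
    user <- sample(users, 1)
    as_of <- fx$uploaded + round(runif(1, -2, 45)) * 86400
    ex <- export_query(st, query_filter(requesting_user = user, as_of = as_of),
                       fx$policy)
    allowed <- vapply(c(fx$ds_proj, fx$ds_priv), function(d)
      is_accessible(st, user, d, as_of, fx$policy), TRUE)
    rows_allowed <- query_eav(st, query_filter(
      dataset_ids = c(fx$ds_proj, fx$ds_priv)[allowed]))
    got <- phenotyper:::results_table_records(ex$table)
    # both datasets hold the same observations; the pivot collapses them
    expect_equal(nrow(got),
                 length(unique(sprintf("%s|%s|%s",
                                       rows_allowed$object_identifier,
                                       rows_allowed$entity_id,
                                       rows_allowed$attribute_id))))
  }
})

test_that("archive reports are deterministic, complete and readable", {
  fx <- access_fixture()
  st <- fx$store
  withr::defer(store_close(st))
  rep1 <- ascii_report(st, fx$ds_proj)
  rep2 <- ascii_report(st, fx$ds_proj)
  expect_identical(rep1, rep2)                       # byte-deterministic

  d <- get_dataset(st, fx$ds_proj)
  rows <- query_eav(st, query_filter(dataset_ids = fx$ds_proj))
  # one observation line per EAV row
  obs <- grep("^p42-", rep1, value = TRUE)
  expect_length(obs, d$row_count)

  # attribute CURIEs appear on the record lines that use them
  expect_true(any(grepl("\ta.height\tTO:0000207\t", obs, fixed = TRUE)))
  expect_true(all(grepl("\tPO:0025034\t", obs[grepl("\te.leaf\t", obs)])))

  # the reference reader recovers every field and row
  back <- read_ascii_report(rep1)
  expect_equal(unname(back$meta[["dataset_id"]]), fx$ds_proj)
  expect_equal(unname(back$meta[["owner_id"]]), "u1")
  expect_equal(unname(back$meta[["owner_name"]]), "Ada Lovelace")
  expect_equal(unname(back$meta[["project"]]), "P1")
  expect_equal(unname(back$meta[["uploaded_at"]]), d$uploaded_at)
  expect_equal(unname(back$meta[["raw_sha256"]]), d$raw_checksum)
  expect_equal(unname(back$meta[["curated_sha256"]]), d$curated_checksum)
  expect_equal(as.integer(back$meta[["record_count"]]), d$row_count)

  got <- sort(sprintf("%s|%s|%s|%s", back$observations$identifier,
                      back$observations$entity_id,
                      back$observations$attribute_id, back$observations$value))
  expect_identical(got, record_set(data.frame(
    identifier = rows$object_identifier, entity_id = rows$entity_id,
    attribute_id = rows$attribute_id, value_kind = rows$value_kind,
    numeric_value = rows$numeric_value, value_term_id = rows$value_term_id)))

  # file output is byte-identical to the returned lines
  path <- withr::local_tempfile(fileext = ".txt")
  ascii_report(st, fx$ds_proj, path)
  expect_identical(readLines(path), rep1)
  expect_pheno_error(ascii_report(st, "nope"), "not_found_error")
})
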