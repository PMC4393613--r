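test_that("membership is m:n and idempotent", {
  st <- demo_store()
  withr::defer(store_close(st))
  add_project(st, "P2", "tomato trial")
  manage_membership(st, "u1", "P1", "add")          # second add: no-op
  manage_membership(st, "u1", "P2", "add")
  expect_equal(user_projects(st, "u1"), c("P1", "P2"))
  expect_equal(nrow(DBI::dbGetQuery(st$con,
    "SELECT * FROM memberships WHERE user_id='u1' AND project_id='P1'")), 1L)

  manage_membership(st, "u2", "P1", "remove")       # nonexistent: no-op
  expect_false(is_member(st, "u2", "P1"))
  expect_pheno_error(manage_membership(st, "ghost", "P1", "add"),
                     "not_found_error")
  expect_pheno_error(manage_membership(st, "u1", "ghost", "add"),
                     "not_found_error")
  expect_pheno_error(add_user(st, "u1"), "conflict_error")
  expect_pheno_error(add_project(st, "P1"), "conflict_error")
})

test_that("vocabulary mirrors into the store and back", {
  reg <- demo_registry()
  st <- demo_store(reg)
  withr::defer(store_close(st))
  back <- store_registry(st)
  expect_identical(sort(names(back$terms)), sort(names(reg$terms)))
  expect_identical(back$terms$a.height, reg$terms$a.height)
  expect_identical(back$default_language, reg$default_language)
})

test_that("ingest stores one EAV row per record, atomically", {
  st <- demo_store()
  withr::defer(store_close(st))
  pair <- session_to_pair(demo_session())
  clk <- manual_clock("2015-04-08T12:00:00+00:00")

  id <- ingest_dataset(st, build_dataset(pair, "u1", "P1", clock = clk, store = st))
  d <- get_dataset(st, id)
  expect_equal(d$row_count, 5L)
  expect_equal(d$owner, "u1")
  expect_equal(d$project, "P1")
  expect_equal(d$curated_checksum, pair$curated_checksum)
  rows <- query_eav(st, query_filter(dataset_ids = id))
  expect_equal(nrow(rows), 5L)

  # duplicate curated checksum refused unless forced
  expect_pheno_error(
    ingest_dataset(st, build_dataset(pair, "u1", clock = clk)),
    "conflict_error")
  id2 <- ingest_dataset(st, build_dataset(pair, "u1", clock = clk), force = TRUE)
  expect_false(identical(id2, id))

  # unresolvable term rolls the whole ingest back: no dataset, no rows
  draft <- build_dataset(pair, "u1", clock = clk)
  draft$records$attribute_id[3] <- "a.unknown"
  n_ds <- nrow(list_datasets(st))
  n_rows <- nrow(query_eav(st))
  err <- tryCatch(ingest_dataset(st, draft, force = TRUE), error = identity)
  expect_s3_class(err, "not_found_error")
  expect_match(conditionMessage(err), "a.unknown")
  expect_equal(nrow(list_datasets(st)), n_ds)
  expect_equal(nrow(query_eav(st)), n_rows)

  expect_pheno_error(
    ingest_dataset(st, build_dataset(pair, "ghost", clock = clk)),
    "not_found_error")
  expect_pheno_error(
    ingest_dataset(st, {
      d <- build_dataset(pair, "u2", clock = clk); d$project <- "P1"; d
    }),
    "authorization_error")
})

test_that("EAV storage is sparse: rows exist only for recorded measurements", {
  st <- demo_store()
  withr::defer(store_close(st))
  scen <- sparse_project_scenario(withr::local_tempdir())
  mirror_to_store(st, mirror(scen$registry))
  clk <- manual_clock("2015-07-01T12:00:00+00:00")

  id1 <- ingest_dataset(st, build_dataset(session_to_pair(scen$phase1_session),
                                          "u1", clock = clk))
  id2 <- ingest_dataset(st, build_dataset(session_to_pair(scen$phase2_session),
                                          "u1", clock = clk))
  r1 <- query_eav(st, query_filter(dataset_ids = id1))
  r2 <- query_eav(st, query_filter(dataset_ids = id2))
  # phase 1: 20 parameters per plant; phase 2: the 5 retained + 1 new = 6
  expect_equal(as.vector(table(r1$object_identifier)), 20L)
  expect_equal(as.vector(table(r2$object_identifier)), 6L)
  # total row count == number of recorded measurements, never padded
  expect_equal(nrow(query_eav(st)), 26L)

  # pivoting the union: phase-2 object empty in columns unique to phase 1
  tab <- pivot_wide(st, query_eav(st))
  df <- as.data.frame(tab)
  expect_equal(nrow(df), 2L)
  p1_only <- setdiff(
    phenotyper:::col_key(r1$entity_id, r1$attribute_id),
    phenotyper:::col_key(r2$entity_id, r2$attribute_id))
  expect_length(unique(p1_only), 15L)
  p2_obj <- unique(r2$object_identifier)
  expect_true(all(df[df$identifier == p2_obj, unique(p1_only)] == ""))
})

test_that("filtered queries equal a brute-force scan", {
  st <- demo_store()
  withr::defer(store_close(st))
  clk <- manual_clock("2015-04-08T12:00:00+00:00")
  specs <- lapply(1:3, function(i)
    fixture_spec(seed = i, n_entities = 2, n_attributes = 4, n_objects = 3,
                 fraction_categorical = 0.5, missing_rate = 0.2))
  for (i in seq_along(specs)) {
    reg <- generate_vocabulary(specs[[i]])
    sch <- generate_scheme(specs[[i]], reg)
    ses <- simulate_session(specs[[i]], sch,
                            clock = manual_clock(sprintf("2015-04-%02dT09:00:00+00:00", i)),
                            storage_dir = withr::local_tempdir())
    mr <- store_registry(st)
    for (t in reg$terms) if (!t$term_id %in% names(mr$terms)) mr <- add_term(mr, t)
    mirror_to_store(st, mr)
    ingest_dataset(st, build_dataset(session_to_pair(ses), "u1", clock = clk))
  }
  all_rows <- query_eav(st)
  expect_gt(nrow(all_rows), 0L)
  # empty filter returns everything
  expect_equal(nrow(query_eav(st, query_filter())), nrow(all_rows))

  withr::local_seed(7)
  brute <- function(df, f) {
    keep <- rep(TRUE, nrow(df))
    if (!is.null(f$entity_ids)) keep <- keep & df$entity_id %in% f$entity_ids
    if (!is.null(f$attribute_ids)) keep <- keep & df$attribute_id %in% f$attribute_ids
    if (!is.null(f$object_identifiers)) keep <- keep & df$object_identifier %in% f$object_identifiers
    if (!is.null(f$dataset_ids)) keep <- keep & df$dataset_id %in% f$dataset_ids
    if (!is.null(f$from)) keep <- keep & df$recorded_at >= f$from
    if (!is.null(f$to)) keep <- keep & df$recorded_at <= f$to
    out <- df[keep, , drop = FALSE]
    out[order(out$dataset_id, out$object_identifier, out$entity_id,
              out$attribute_id), , drop = FALSE]
  }
  for (i in 1:25) {
    f <- query_filter(
      entity_ids = if (runif(1) < 0.5) sample(unique(all_rows$entity_id), 1) else NULL,
      attribute_ids = if (runif(1) < 0.5) sample(unique(all_rows$attribute_id), 2) else NULL,
      object_identifiers = if (runif(1) < 0.3) sample(unique(all_rows$object_identifier), 1) else NULL,
      dataset_ids = if (runif(1) < 0.3) sample(unique(all_rows$dataset_id), 1) else NULL,
      from = if (runif(1) < 0.3) sample(all_rows$recorded_at, 1) else NULL,
      to = if (runif(1) < 0.3) sample(all_rows$recorded_at, 1) else NULL)
    got <- query_eav(st, f)
    want <- brute(all_rows, f)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("pivot labels values, keeps empties, and detects conflicts", {
  st <- demo_store()
  withr::defer(store_close(st))
  pair <- session_to_pair(demo_session())
  clk <- manual_clock("2015-04-08T12:00:00+00:00")
  id <- ingest_dataset(st, build_dataset(pair, "u1", clock = clk))
  rows <- query_eav(st)

  tab <- pivot_wide(st, rows)
  df <- as.data.frame(tab)
  expect_equal(nrow(df), 2L)
  expect_equal(df[df$identifier == "p42-1", "e.leaf|a.color"], "yellow")
  expect_equal(tab$keys$attribute_label[tab$keys$column == "e.plant|a.height"],
               "plant height")
  # round trip: non-empty cells match the EAV rows
  back <- phenotyper:::results_table_records(tab)
  expect_equal(nrow(back), nrow(rows))

  # header-only table for empty input
  empty <- pivot_wide(st, rows[0, , drop = FALSE])
  expect_equal(nrow(as.data.frame(empty)), 0L)
  expect_equal(nrow(empty$keys), 0L)

  # same identifier with a conflicting duplicate from a second dataset
  id2 <- ingest_dataset(st, {
    ses2 <- demo_session()
    record_value(ses2, "p42-1", "e.plant", "a.height", "999")
    build_dataset(session_to_pair(ses2), "u1", clock = clk)
  })
  err <- tryCatch(pivot_wide(st, query_eav(st)), error = identity)
  expect_s3_class(err, "conflict_error")
  expect_match(conditionMessage(err), "p42-1")
})

test_that("stores persist to disk and reopen", {
  path <- withr::local_tempfile(fileext = ".sqlite")
  st <- store_create(path)
  add_user(st, "u1", "Ada", "Lovelace")
  mirror_to_store(st, demo_registry())
  pair <- session_to_pair(demo_session())
  id <- ingest_dataset(st, build_dataset(
    pair, "u1", clock = manual_clock("2015-04-08T12:00:00+00:00")))
  store_close(st)

  st2 <- store_open(path)
  withr::defer(store_close(st2))
  expect_equal(get_dataset(st2, id)$row_count, 5L)
  expect_equal(nrow(query_eav(st2)), 5L)
  set_object_metadata(st2, "p42-1", "genotype", "Desiree")
  expect_equal(get_object_metadata(st2, "p42-1"),
               c(genotype = "Desiree"))
})
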