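test_that("drug-related classification is a prefix rule on IPC/CPC", {
  expect_true(is_drug_related("A61K31/00"))
  expect_true(is_drug_related(character(), "A61P35/00"))
  expect_false(is_drug_related("C07D498/04", "C07D"))
  expect_false(is_drug_related(character(), character()))
  expect_true(is_drug_related(" a61k 31/00 "))  # whitespace + case normalized
  expect_equal(
    is_drug_related(list("A61K1/00", "C07D"), list(character(), "B01J")),
    c(TRUE, FALSE)
  )
})

test_that("database build applies the stated filters with exact arithmetic", {
  # 10 compounds, 6 linked to drug-related patents, 2 of those OCR-flagged
  compounds <- tibble::tibble(
    external_id = sprintf("CMP%02d", 1:10),
    smiles = rep(c("c1ccccc1O", "CCc1ccccc1", "Cc1ccncc1", "OCc1ccccc1",
                   "c1ccc2ccccc2c1"), 2),
    ocr_flag = c(TRUE, TRUE, rep(FALSE, 8)),
    patent_numbers = c(rep("DRUG-1", 6), rep("OTHER-1", 4))
  )
  patents <- tibble::tibble(
    patent_number = c("DRUG-1", "OTHER-1"),
    ipc_codes = c("A61K31/00", "C07D1/00"),
    cpc_codes = c("", "")
  )
  db <- build_db(compounds, patents, exclude_ocr = TRUE)
  expect_equal(db$n_entries, 4L)
  expect_true(db$has_key_index)

  db_all <- build_db(compounds, patents, exclude_ocr = FALSE)
  expect_equal(db_all$n_entries, 6L)

  # filter monotonicity
  expect_lte(db$n_entries, db_all$n_entries)

  # no drug-related links at all -> valid empty database
  none <- build_db(compounds[7:10, ], patents)
  expect_equal(none$n_entries, 0L)
  expect_equal(db_stats(none)$n_entries, 0L)
  expect_false(lookup(none, "LFQSCWFLJHTTHZ-UHFFFAOYSA-N")$matched)
})

test_that("malformed rows and unknown patent numbers are counted, not lost", {
  compounds <- tibble::tibble(
    external_id = c("A", "", "C"),
    smiles = c("c1ccccc1", "CCO", NA),
    ocr_flag = FALSE,
    patent_numbers = c("P1", "P1", "P2")
  )
  patents <- tibble::tibble(patent_number = "P1", ipc_codes = "A61K9/00",
                            cpc_codes = "")
  db <- build_db(compounds, patents)
  expect_equal(db$n_entries, 1L)
  expect_equal(db$report$n_malformed, 2L)
  expect_equal(db$report$n_unknown_patent_refs, 0L)
})

test_that("fixture database equals a linear-scan oracle and is deterministic", {
  split <- fixture_split()
  db <- fixture_db()
  # oracle: set membership over the stereo-free keys of retained entries
  truth <- split$patented$inchikey_nostereo
  expect_equal(db$n_entries, nrow(split$patented))

  set.seed(99)
  some <- sample(nrow(fixture_universe()), 1000)
  keys <- fixture_universe()$inchikey_nostereo[some]
  res <- lookup(db, keys)
  expect_equal(res$matched, keys %in% truth)

  st <- db_stats(db)
  expect_lte(st$n_distinct_keys, st$n_entries)
  expect_equal(st$n_entries, nrow(split$patented))

  # rebuilding from identical input yields the identical key multiset
  tabs <- write_fixture_tables(split, file.path(fixture_dir(), "rebuild"))
  db2 <- build_db(read_compound_table(tabs["compounds"]),
                  read_compound_table(tabs["patents"]),
                  path = file.path(fixture_dir(), "rebuild", "db.sqlite"))
  con1 <- DBI::dbConnect(RSQLite::SQLite(), db$path)
  con2 <- DBI::dbConnect(RSQLite::SQLite(), db2$path)
  k1 <- DBI::dbGetQuery(con1, "SELECT inchikey FROM compounds ORDER BY inchikey")
  k2 <- DBI::dbGetQuery(con2, "SELECT inchikey FROM compounds ORDER BY inchikey")
  DBI::dbDisconnect(con1); DBI::dbDisconnect(con2)
  expect_identical(k1, k2)
})

test_that("OCR flags and non-drug patents in fixtures thin the database", {
  spec <- fixture_spec(n_target = 300, frac_ocr = 0.1)
  uni <- make_universe(spec)
  expect_equal(sum(uni$ocr_flag), 30L)
  split <- split_universe(uni, frac_patented = 0.5, seed = 7,
                          frac_nondrug = 0.2)
  tabs <- write_fixture_tables(split, file.path(fixture_dir(), "thin"))
  db <- build_db(read_compound_table(tabs["compounds"]),
                 read_compound_table(tabs["patents"]),
                 path = file.path(fixture_dir(), "thin", "db.sqlite"))
  n_pat <- nrow(split$patented)
  drug_linked <- purrr::map_lgl(split$patented$patent_numbers,
                                ~ any(startsWith(.x, "SYNPAT")))
  expected <- sum(drug_linked & !split$patented$ocr_flag)
  expect_equal(db$n_entries, expected)
  expect_lt(db$n_entries, n_pat)
})

test_that("the published-layout reader resolves alternative column names", {
  # synthetic stand-in for the released database layout
  path <- file.path(fixture_dir(), "zenodo_synthetic.sqlite")
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  DBI::dbExecute(con, "CREATE TABLE compounds (InChIKey TEXT, SCHEMBL_ID TEXT)")
  DBI::dbExecute(con,
    "INSERT INTO compounds VALUES ('LFQSCWFLJHTTHZ-UHFFFAOYSA-N', 'SCHEMBL1')")
  DBI::dbDisconnect(con)
  db <- open_db(path)
  expect_equal(db$n_entries, 1L)
  res <- lookup(db, c("LFQSCWFLJHTTHZ-UHFFFAOYSA-N", "AAAAAAAAAAAAAA-BBBBBBBBBB-C"))
  expect_equal(res$matched, c(TRUE, FALSE))
  expect_equal(res$matched_ids[[1]], "SCHEMBL1")
})
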