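# Drug-related patented-compound database: build, index, query.
#
# Storage is a single-file SQLite database with one hot table
# compounds(inchikey TEXT, external_id TEXT) and an index on inchikey,
# mirroring the design used for the full-scale database. Patent numbers
# and stage counts live in a JSON build-report sidecar, not in the lookup
# table.

#' Is a patent drug-related?
#'
#' A patent is drug-related when any of its IPC or CPC classification
#' codes, after whitespace normalization and uppercasing, starts with
#' `A61K` (medicinal preparations) or `A61P` (therapeutic activity).
#'
#' @param ipc_codes,cpc_codes Character vectors of classification codes
#'   (either may be empty), or list-columns of such vectors for the
#'   vectorized form.
#' @return Logical.
#' @examples
#' \dontrun{
#' is_drug_related("A61K31/00", character())
#' }
#' @export
is_drug_related <- function(ipc_codes, cpc_codes = character()) {
  if (is.list(ipc_codes) || is.list(cpc_codes)) {
    return(purrr::map2_lgl(ipc_codes, cpc_codes, is_drug_related))
  }
  codes <- toupper(gsub("\\s+", "", c(ipc_codes, cpc_codes)))
  codes <- codes[nzchar(codes)]
  any(startsWith(codes, "A61K") | startsWith(codes, "A61P"))
}

#' Build the drug-related patented-compound database
#'
#' Retains compounds linked to at least one drug-related patent
#' (see [is_drug_related()]), optionally drops OCR-derived structures,
#' standardizes the survivors ([standardize_molecules()]) and stores
#' `(inchikey_nostereo, external_id)` rows in an indexed SQLite file.
#' Distinct external ids may collide on one key; duplicates are kept.
#' Compounds citing patent numbers absent from `patents` are treated as
#' non-drug-related and counted in the report. Malformed rows (missing id
#' or SMILES) are skipped and counted, never silently dropped.
#'
#' @param compounds Data frame with columns `external_id`, `smiles`,
#'   `ocr_flag` (logical), `patent_numbers` (list-column of character, or
#'   semicolon-joined strings).
#' @param patents Data frame with columns `patent_number`, `ipc_codes`,
#'   `cpc_codes` (list-columns or semicolon-joined strings).
#' @param path File path for the SQLite database.
#' @param exclude_ocr Drop compounds whose structure came from image
#'   recognition (`ocr_flag = TRUE`).
#' @return A `drug_patent_db` object: list with `path`, `n_entries`,
#'   `has_key_index` and the build `report` (stage counts; also written to
#'   `<path>.report.json`).
#' @export
build_db <- function(compounds, patents, path = tempfile(fileext = ".sqlite"),
                     exclude_ocr = TRUE) {
  compounds <- tibble::as_tibble(compounds)
  patents <- tibble::as_tibble(patents)
  req <- c("external_id", "smiles", "ocr_flag", "patent_numbers")
  if (!all(req %in% names(compounds))) {
    rlang::abort(paste("compounds must have columns:", paste(req, collapse = ", ")),
                 class = "patgen_ingestion_error")
  }
  split_codes <- function(x) {
    if (is.list(x)) lapply(x, as.character)
    else stringr::str_split(dplyr::coalesce(as.character(x), ""), ";\\s*")
  }
  patents$ipc_codes <- split_codes(patents$ipc_codes)
  patents$cpc_codes <- split_codes(patents$cpc_codes)
  compounds$patent_numbers <- split_codes(compounds$patent_numbers)

  n_input <- nrow(compounds)
  malformed <- is.na(compounds$external_id) | !nzchar(compounds$external_id) |
    is.na(compounds$smiles) | !nzchar(compounds$smiles)
  compounds <- compounds[!malformed, ]

  drug_patents <- patents$patent_number[
    is_drug_related(patents$ipc_codes, patents$cpc_codes)
  ]
  known <- unlist(compounds$patent_numbers) %in% patents$patent_number
  n_unknown_patent_refs <- sum(!known)
  linked <- purrr::map_lgl(
    compounds$patent_numbers, ~ any(.x %in% drug_patents)
  )
  comp_drug <- compounds[linked, ]
  n_drug_related <- nrow(comp_drug)

  if (exclude_ocr) comp_drug <- comp_drug[!comp_drug$ocr_flag, ]
  n_after_ocr <- nrow(comp_drug)

  std <- if (nrow(comp_drug) > 0) {
    standardize_molecules(comp_drug[, c("external_id", "smiles")])
  } else {
    tibble::tibble(external_id = character(), ok = logical(),
                   inchikey_nostereo = character())
  }
  kept <- std[std$ok, ]
  n_std_failed <- sum(!std$ok)

  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  DBI::dbExecute(con, "DROP TABLE IF EXISTS compounds")
  DBI::dbExecute(con,
    "CREATE TABLE compounds (inchikey TEXT NOT NULL, external_id TEXT NOT NULL)")
  if (nrow(kept) > 0) {
    DBI::dbWriteTable(con, "compounds",
      data.frame(inchikey = kept$inchikey_nostereo,
                 external_id = kept$external_id),
      append = TRUE)
  }
  DBI::dbExecute(con, "CREATE INDEX idx_inchikey ON compounds (inchikey)")

  report <- list(
    stage_counts = list(
      input = n_input,
      well_formed = n_input - sum(malformed),
      drug_related = n_drug_related,
      after_ocr_filter = n_after_ocr,
      standardized = nrow(kept)
    ),
    n_malformed = sum(malformed),
    n_unknown_patent_refs = n_unknown_patent_refs,
    n_standardization_failures = n_std_failed,
    exclude_ocr = exclude_ocr,
    n_source_patents = length(unique(unlist(comp_drug$patent_numbers))),
    source_patents = sort(unique(unlist(comp_drug$patent_numbers)))
  )
  jsonlite::write_json(report, paste0(path, ".report.json"),
                       auto_unbox = TRUE, digits = NA)

  structure(
    list(path = path, n_entries = nrow(kept), has_key_index = TRUE,
         report = report),
    class = "drug_patent_db"
  )
}

#' Open an existing drug-patent database file
#'
#' Also reads databases in the published layout (a `compounds` table with
#' an InChIKey column and an external-accession column); column names are
#' matched case-insensitively against `inchikey`/`external_id` synonyms.
#'
#' @param path SQLite file path.
#' @return A `drug_patent_db` object.
#' @export
open_db <- function(path) {
  if (!file.exists(path)) {
    rlang::abort("database file not found", class = "patgen_db_not_built")
  }
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  tabs <- DBI::dbListTables(con)
  if (!"compounds" %in% tabs) {
    rlang::abort("no 'compounds' table in database",
                 class = "patgen_db_not_built")
  }
  cols <- DBI::dbListFields(con, "compounds")
  key_col <- cols[tolower(cols) %in% c("inchikey", "inchi_key", "key")][1]
  id_col <- cols[tolower(cols) %in%
                   c("external_id", "schembl_id", "surechembl_id", "entry_id")][1]
  if (is.na(key_col) || is.na(id_col)) {
    rlang::abort("could not identify key/id columns",
                 class = "patgen_db_not_built")
  }
  if (key_col != "inchikey" || id_col != "external_id") {
    DBI::dbExecute(con, sprintf(
      "CREATE VIEW IF NOT EXISTS compounds_std AS SELECT %s AS inchikey, %s AS external_id FROM compounds",
      DBI::dbQuoteIdentifier(con, key_col), DBI::dbQuoteIdentifier(con, id_col)))
  }
  n <- DBI::dbGetQuery(con, "SELECT COUNT(*) AS n FROM compounds")$n
  structure(
    list(path = path, n_entries = n, has_key_index = TRUE, report = NULL),
    class = "drug_patent_db"
  )
}

db_connect <- function(db) {
  if (!inherits(db, "drug_patent_db")) {
    rlang::abort("not a drug_patent_db", class = "patgen_db_not_built")
  }
  if (!file.exists(db$path)) {
    rlang::abort("database file not found", class = "patgen_db_not_built")
  }
  DBI::dbConnect(RSQLite::SQLite(), db$path)
}

db_table <- function(con) {
  if ("compounds_std" %in% DBI::dbListTables(con)) "compounds_std" else "compounds"
}

#' Look up stereo-free InChIKeys in the database
#'
#' Membership by full 27-character key equality via an indexed SQL SELECT.
#'
#' @param db A `drug_patent_db`.
#' @param keys Character vector of stereo-free InChIKeys.
#' @return A tibble with columns `query_id` (the key), `matched` and
#'   `matched_ids` (list-column of external ids).
#' @export
lookup <- function(db, keys) {
  con <- db_connect(db)
  on.exit(DBI::dbDisconnect(con))
  tab <- db_table(con)
  rs <- DBI::dbSendQuery(
    con, sprintf("SELECT external_id FROM %s WHERE inchikey = ?", tab))
  on.exit(DBI::dbClearResult(rs), add = TRUE, after = FALSE)
  matched_ids <- lapply(keys, function(k) {
    DBI::dbBind(rs, list(k))
    DBI::dbFetch(rs)$external_id
  })
  tibble::tibble(
    query_id = keys,
    matched = lengths(matched_ids) > 0,
    matched_ids = matched_ids
  )
}

#' Database summary counts
#'
#' @param db A `drug_patent_db`.
#' @return A tibble with `n_entries`, `n_distinct_keys`, `n_source_patents`
#'   (`NA` when the build report sidecar is unavailable).
#' @export
db_stats <- function(db) {
  con <- db_connect(db)
  on.exit(DBI::dbDisconnect(con))
  tab <- db_table(con)
  q <- DBI::dbGetQuery(con, sprintf(
    "SELECT COUNT(*) AS n, COUNT(DISTINCT inchikey) AS k FROM %s", tab))
  n_pat <- if (!is.null(db$report)) db$report$n_source_patents else {
    side <- paste0(db$path, ".report.json")
    if (file.exists(side)) {
      jsonlite::fromJSON(side)$n_source_patents
    } else {
      NA_integer_
    }
  }
  tibble::tibble(
    n_entries = q$n,
    n_distinct_keys = q$k,
    n_source_patents = n_pat
  )
}

#' @export
print.drug_patent_db <- function(x, ...) {
  cat("<drug_patent_db> ", x$n_entries, " entries at ", x$path, "\n", sep = "")
  invisible(x)
}

#' @rdname db_stats
#' @param x A `drug_patent_db` object.
#' @param ... Unused.
#' @export
glance.drug_patent_db <- function(x, ...) db_stats(x)

#' Read compound / patent tables from delimited text
#'
#' Compounds: columns `external_id`, `smiles`, `ocr_flag`,
#' `patent_numbers` (semicolon-joined). Patents: `patent_number`,
#' `ipc_codes`, `cpc_codes` (semicolon-joined). Tab- or comma-separated;
#' chosen from the file extension (`.csv` vs anything else).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_compound_table <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  tibble::as_tibble(utils::read.table(
    path, sep = sep, header = TRUE, quote = "\"",
    stringsAsFactors = FALSE, comment.char = ""
  ))
}
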