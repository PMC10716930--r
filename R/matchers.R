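# Three interchangeable exact-structure match engines plus a latency
# benchmark: text-based InChIKey lookup against the indexed SQLite store,
# MHFP6 MinHash LSH with identity verification, and Morgan-fingerprint
# brute force with identity verification. All three answer the same
# question -- is the query structure in the reference set -- so their
# matched sets must agree.

# Packed fingerprint matrix via binary file transport (column = molecule).
fingerprint_matrix <- function(smiles, kind = c("morgan_r2", "morgan_r3", "mhfp6"),
                               mhfp_seed = 42L) {
  kind <- rlang::arg_match(kind)
  words <- if (kind == "mhfp6") 2048L else 64L
  path <- tempfile(fileext = ".fpbin")
  on.exit(unlink(path))
  total <- 0L
  smiles <- as.character(smiles)
  out <- matrix(0L, nrow = words, ncol = length(smiles))
  chunk <- 50000L
  for (start in seq(1, length(smiles), by = chunk)) {
    ii <- start:min(length(smiles), start + chunk - 1)
    n <- chem_request("fingerprint_file", list(
      smiles = as.list(smiles[ii]), kind = kind,
      path = path, seed = as.integer(mhfp_seed)
    ))
    stopifnot(n == length(ii))
    vals <- readBin(path, "integer", n = words * length(ii), size = 4,
                    endian = "little")
    out[, ii] <- vals
    total <- total + n
  }
  attr(out, "kind") <- kind
  if (kind == "mhfp6") attr(out, "mhfp_seed") <- as.integer(mhfp_seed)
  out
}

as_standard_molecules <- function(x) {
  if (is.character(x)) x <- standardize_molecules(x)
  x <- tibble::as_tibble(x)
  if (!all(c("canonical_smiles", "inchikey_nostereo") %in% names(x))) {
    rlang::abort("expected StandardMolecule columns canonical_smiles, inchikey_nostereo")
  }
  if (!"query_id" %in% names(x)) {
    x$query_id <- x[["external_id"]] %||% x$canonical_smiles
  }
  x
}

#' Exact matching by InChIKey text lookup
#'
#' Per-query membership by full 27-character stereo-free InChIKey equality
#' against the indexed database (an SQL SELECT per query).
#'
#' @param db A `drug_patent_db`.
#' @param queries Standardized molecules: a data frame with
#'   `canonical_smiles` and `inchikey_nostereo` (plus optional `query_id`),
#'   or a character vector of SMILES that will be standardized first.
#' @return A tibble of match results: `query_id`, `matched`, `matched_ids`.
#' @export
match_inchikey <- function(db, queries) {
  queries <- as_standard_molecules(queries)
  res <- lookup(db, queries$inchikey_nostereo)
  tibble::tibble(
    query_id = queries$query_id,
    matched = res$matched,
    matched_ids = res$matched_ids
  )
}

#' Build a MinHash LSH index over reference molecules
#'
#' Encodes each reference as a 2048-permutation MHFP6 minhash vector and
#' hashes it into `n_bands` bands of `2048 / n_bands` rows each; queries
#' retrieve candidates by band collision. Deterministic for a fixed
#' permutation seed.
#'
#' @param refs Standardized reference molecules (see [match_inchikey()]).
#' @param n_bands Number of LSH bands (must divide 2048).
#' @param mhfp_seed MinHash permutation seed.
#' @return An `lsh_index` object (session-bound; holds a C++ handle).
#' @export
build_lsh_index <- function(refs, n_bands = 128L, mhfp_seed = 42L) {
  refs <- as_standard_molecules(refs)
  if (nrow(refs) == 0) {
    rlang::abort("empty reference set", class = "patgen_empty_reference_set")
  }
  mh <- fingerprint_matrix(refs$canonical_smiles, "mhfp6", mhfp_seed)
  structure(
    list(
      ptr = cpp_lsh_build(mh, as.integer(n_bands)),
      minhash = mh,
      refs = refs,
      n_bands = as.integer(n_bands),
      mhfp_seed = as.integer(mhfp_seed)
    ),
    class = "lsh_index"
  )
}

#' @export
print.lsh_index <- function(x, ...) {
  cat("<lsh_index> ", nrow(x$refs), " references, ", x$n_bands,
      " bands, mhfp seed ", x$mhfp_seed, "\n", sep = "")
  invisible(x)
}

#' Exact matching by MHFP6 LSH retrieval plus identity verification
#'
#' Retrieves up to `k` nearest candidates per query from the LSH index; a
#' query matches only if some candidate has an identical minhash vector
#' and an identical stereo-free InChIKey (the verification step makes
#' fingerprint collisions harmless).
#'
#' @param index An [build_lsh_index()] object.
#' @param queries Standardized query molecules.
#' @param k Candidate count retrieved per query.
#' @return A tibble of match results (as [match_inchikey()]).
#' @export
match_mhfp_lsh <- function(index, queries, k = 10L) {
  if (!inherits(index, "lsh_index")) {
    rlang::abort("index not built", class = "patgen_index_not_built")
  }
  stopifnot(k >= 1)
  queries <- as_standard_molecules(queries)
  qmh <- fingerprint_matrix(queries$canonical_smiles, "mhfp6", index$mhfp_seed)
  cands <- cpp_lsh_query(index$ptr, index$minhash, qmh, as.integer(k))
  ref_keys <- index$refs$inchikey_nostereo
  ref_ids <- index$refs$query_id
  matched_ids <- purrr::map2(cands, seq_len(nrow(queries)), function(cc, qi) {
    ids <- cc$ids[cc$est_jaccard == 1]
    ids <- ids[ref_keys[ids] == queries$inchikey_nostereo[qi]]
    ref_ids[ids]
  })
  tibble::tibble(
    query_id = queries$query_id,
    matched = lengths(matched_ids) > 0,
    matched_ids = matched_ids
  )
}

#' Exact matching by Morgan-fingerprint brute force
#'
#' Scans every reference per query with radius-3 2048-bit Morgan
#' fingerprints; a query matches only if the maximum Tanimoto equals 1 and
#' a unit-similarity reference also shares the query's stereo-free
#' InChIKey (collision guard).
#'
#' @param refs,queries Standardized molecules.
#' @param ref_fps Optional precomputed packed reference fingerprints from
#'   `fingerprint_matrix(refs$canonical_smiles, "morgan_r3")`.
#' @return A tibble of match results.
#' @export
match_morgan_bruteforce <- function(refs, queries, ref_fps = NULL) {
  refs <- as_standard_molecules(refs)
  if (nrow(refs) == 0) {
    rlang::abort("empty reference set", class = "patgen_empty_reference_set")
  }
  queries <- as_standard_molecules(queries)
  if (is.null(ref_fps)) {
    ref_fps <- fingerprint_matrix(refs$canonical_smiles, "morgan_r3")
  }
  qfps <- fingerprint_matrix(queries$canonical_smiles, "morgan_r3")
  mx <- cpp_max_tanimoto(ref_fps, qfps)
  matched_ids <- vector("list", nrow(queries))
  for (qi in seq_len(nrow(queries))) {
    if (mx$max_sim[qi] == 1) {
      hits <- cpp_columns_equal(ref_fps, qfps[, qi])
      hits <- hits[refs$inchikey_nostereo[hits] == queries$inchikey_nostereo[qi]]
      matched_ids[[qi]] <- refs$query_id[hits]
    } else {
      matched_ids[[qi]] <- character()
    }
  }
  tibble::tibble(
    query_id = queries$query_id,
    matched = lengths(matched_ids) > 0,
    matched_ids = matched_ids
  )
}

# Build an SQLite store directly from already-standardized molecules
# (keys are trusted; used by the benchmark and by fixtures).
db_from_standard <- function(refs, path = tempfile(fileext = ".sqlite")) {
  refs <- as_standard_molecules(refs)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  DBI::dbExecute(con,
    "CREATE TABLE compounds (inchikey TEXT NOT NULL, external_id TEXT NOT NULL)")
  DBI::dbWriteTable(con, "compounds",
    data.frame(inchikey = refs$inchikey_nostereo,
               external_id = as.character(refs$query_id)),
    append = TRUE)
  DBI::dbExecute(con, "CREATE INDEX idx_inchikey ON compounds (inchikey)")
  structure(
    list(path = path, n_entries = nrow(refs), has_key_index = TRUE,
         report = NULL),
    class = "drug_patent_db"
  )
}

#' Benchmark the three exact-match engines
#'
#' Prepares all three engines over the same reference set (index and
#' database construction time is reported separately, never added to query
#' time), runs the full query set through each, and reports per-method
#' elapsed query-phase seconds plus the pairwise agreement of the matched
#' sets. Query-side fingerprint/key conversion is part of the timed query
#' phase; reference-side preparation is not.
#'
#' @param refs,queries Standardized molecules (or character SMILES).
#' @param methods Subset of `c("inchikey", "mhfp6_lsh", "morgan_bruteforce")`.
#' @param k LSH candidate count.
#' @param mhfp_seed MinHash permutation seed.
#' @return A `bench_report` tibble: one row per method with `method`,
#'   `n_queries`, `n_refs`, `prep_seconds`, `elapsed_seconds`, `n_matched`
#'   and a `results` list-column; pairwise agreement matrix in attribute
#'   `"agreement"`.
#' @export
benchmark_matchers <- function(refs, queries,
                               methods = c("inchikey", "mhfp6_lsh",
                                           "morgan_bruteforce"),
                               k = 10L, mhfp_seed = 42L) {
  refs <- as_standard_molecules(refs)
  queries <- as_standard_molecules(queries)
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  timed <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    list(val = val, secs = proc.time()[["elapsed"]] - t0)
  }
  if ("inchikey" %in% methods) {
    prep <- timed(db_from_standard(refs))
    run <- timed(match_inchikey(prep$val, queries))
    rows$inchikey <- list(prep = prep$secs, run = run$secs, res = run$val)
  }
  if ("mhfp6_lsh" %in% methods) {
    prep <- timed(build_lsh_index(refs, mhfp_seed = mhfp_seed))
    run <- timed(match_mhfp_lsh(prep$val, queries, k = k))
    rows$mhfp6_lsh <- list(prep = prep$secs, run = run$secs, res = run$val)
  }
  if ("morgan_bruteforce" %in% methods) {
    prep <- timed(fingerprint_matrix(refs$canonical_smiles, "morgan_r3"))
    run <- timed(match_morgan_bruteforce(refs, queries, ref_fps = prep$val))
    rows$morgan_bruteforce <- list(prep = prep$secs, run = run$secs,
                                   res = run$val)
  }
  out <- tibble::tibble(
    method = names(rows),
    n_queries = nrow(queries),
    n_refs = nrow(refs),
    prep_seconds = unname(purrr::map_dbl(rows, "prep")),
    elapsed_seconds = unname(purrr::map_dbl(rows, "run")),
    n_matched = unname(purrr::map_int(rows, ~ sum(.x$res$matched))),
    results = unname(purrr::map(rows, "res"))
  )
  agree <- outer(
    seq_along(rows), seq_along(rows),
    Vectorize(function(i, j) {
      mean(rows[[i]]$res$matched == rows[[j]]$res$matched)
    })
  )
  dimnames(agree) <- list(names(rows), names(rows))
  attr(out, "agreement") <- agree
  class(out) <- c("bench_report", class(out))
  out
}
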