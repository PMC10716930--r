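# Metrics and visual analytics over generation logs.

valid_unique_smiles <- function(log) {
  rec <- log$records
  unique(rec$canonical_smiles[rec$parse_valid & rec$passed])
}

#' Validity, uniqueness and patent-match count of a generation log
#'
#' Validity is the fraction of all proposed strings that are interpretable
#' and pass every enabled filter; uniqueness is the fraction of valid
#' strings that are distinct (by canonical SMILES). With a database,
#' `n_db_matches` counts the distinct valid molecules whose stereo-free
#' key is present.
#'
#' @param log A `generation_log` (or list of logs for replicate
#'   statistics via [metrics_replicates()]).
#' @param db Optional `drug_patent_db`.
#' @return A `generation_metrics` tibble (one row).
#' @export
compute_metrics <- function(log, db = NULL) {
  n_all <- log$totals$n_all
  if (n_all == 0) {
    rlang::abort("empty generation log", class = "patgen_empty_log")
  }
  rec <- log$records
  valid <- rec$parse_valid & rec$passed
  n_valid <- sum(valid)
  uniq <- unique(rec$canonical_smiles[valid])
  validity <- n_valid / n_all
  uniqueness <- if (n_valid == 0) {
    warning("no valid molecules; uniqueness undefined")
    NA_real_
  } else {
    length(uniq) / n_valid
  }
  n_db <- NA_integer_
  if (!is.null(db) && n_valid > 0) {
    # one key per distinct canonical SMILES (matches are counted over the
    # valid-unique set, not over raw generation events)
    dd <- rec[valid, c("canonical_smiles", "inchikey_nostereo")]
    dd <- dd[!duplicated(dd$canonical_smiles), ]
    n_db <- sum(lookup(db, dd$inchikey_nostereo)$matched)
  }
  out <- tibble::tibble(
    reward = log$reward_name %||% NA_character_,
    c_explore = log$config$c_explore %||% NA_real_,
    n_all = n_all,
    n_valid = n_valid,
    n_valid_unique = length(uniq),
    validity = validity,
    uniqueness = uniqueness,
    n_db_matches = n_db
  )
  class(out) <- c("generation_metrics", class(out))
  out
}

#' Replicate statistics of generation metrics
#'
#' @param logs List of `generation_log`s (replicate runs of one
#'   condition, or mixed conditions; grouped by reward and C).
#' @param db Optional `drug_patent_db`.
#' @return A tibble with per-condition mean and standard deviation of
#'   validity, uniqueness and database match counts.
#' @export
metrics_replicates <- function(logs, db = NULL) {
  per <- dplyr::bind_rows(lapply(logs, compute_metrics, db = db))
  out <- per |>
    dplyr::group_by(.data$reward, .data$c_explore) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      validity_mean = mean(.data$validity),
      validity_sd = sd(.data$validity),
      uniqueness_mean = mean(.data$uniqueness),
      uniqueness_sd = sd(.data$uniqueness),
      db_matches_mean = mean(.data$n_db_matches),
      db_matches_sd = sd(.data$n_db_matches),
      .groups = "drop"
    )
  class(out) <- c("generation_metrics_summary", class(out))
  attr(out, "per_replicate") <- per
  out
}

similarity_bins <- function() {
  tibble::tibble(bin_lo = seq(0, 0.95, by = 0.05),
                 bin_hi = seq(0.05, 1, by = 0.05))
}

bin_similarity <- function(sims) {
  # left-closed, right-open bins of width 0.05; the final bin [0.95, 1]
  # is closed so exact matches (1.0) land in it; rounding guards against
  # binary representation error at bin edges (0.35 * 20 < 7 in doubles)
  pmin(floor(round(sims * 20, 9)), 19) + 1
}

#' Maximum-similarity distribution against a reference set
#'
#' Per molecule, the maximum Tanimoto coefficient (Morgan radius-2,
#' 2048-bit fingerprints) over the references, histogrammed in 0.05-wide
#' bins; also reports the fraction with similarity at least 0.7 and the
#' exact-match fraction (similarity 1).
#'
#' @param mols,refs Character SMILES vectors or data frames with a
#'   `canonical_smiles` column.
#' @return A `similarity_distribution`: list with `histogram` (tibble),
#'   `similarities`, `fraction_ge_07`, `fraction_eq_1`.
#' @export
max_similarity_distribution <- function(mols, refs) {
  mols <- if (is.data.frame(mols)) mols$canonical_smiles else as.character(mols)
  refs <- if (is.data.frame(refs)) refs$canonical_smiles else as.character(refs)
  if (length(refs) == 0) {
    rlang::abort("empty reference set", class = "patgen_empty_reference_set")
  }
  rfp <- fingerprint_matrix(refs, "morgan_r2")
  qfp <- fingerprint_matrix(mols, "morgan_r2")
  mx <- cpp_max_tanimoto(rfp, qfp)
  sims <- as.numeric(mx$max_sim)
  hist <- similarity_bins()
  hist$count <- tabulate(bin_similarity(sims), nbins = 20)
  structure(
    list(histogram = hist, similarities = sims,
         fraction_ge_07 = mean(sims >= 0.7),
         fraction_eq_1 = mean(sims == 1)),
    class = "similarity_distribution"
  )
}

#' @export
print.similarity_distribution <- function(x, ...) {
  cat("<similarity_distribution> n ", length(x$similarities),
      ", >=0.7: ", signif(100 * x$fraction_ge_07, 3),
      "%, exact: ", signif(100 * x$fraction_eq_1, 3), "%\n", sep = "")
  invisible(x)
}

#' @rdname max_similarity_distribution
#' @param x A `similarity_distribution`.
#' @param ... Unused.
#' @export
tidy.similarity_distribution <- function(x, ...) x$histogram

#' QED drug-likeness distribution
#'
#' @param mols Character SMILES or data frame with `canonical_smiles`.
#' @return A `qed_distribution`: list with `values`, `histogram`
#'   (0.05-wide bins), `mean`, `median`.
#' @export
qed_distribution <- function(mols) {
  mols <- if (is.data.frame(mols)) mols$canonical_smiles else as.character(mols)
  qed <- compute_descriptors(mols)$qed
  hist <- similarity_bins()
  hist$count <- tabulate(bin_similarity(qed), nbins = 20)
  structure(
    list(values = qed, histogram = hist, mean = mean(qed),
         median = median(qed)),
    class = "qed_distribution"
  )
}

#' @export
print.qed_distribution <- function(x, ...) {
  cat("<qed_distribution> n ", length(x$values), ", mean ",
      signif(x$mean, 3), ", median ", signif(x$median, 3), "\n", sep = "")
  invisible(x)
}

#' Two-dimensional chemical-space embedding
#'
#' UMAP projection of Morgan radius-2 2048-bit fingerprints under the
#' Jaccard metric (exact nearest neighbours computed over fingerprint bit
#' sets, then embedded with uwot). Deterministic for a fixed seed.
#'
#' @param mols Query molecules (character SMILES or data frame with
#'   `canonical_smiles`).
#' @param refs Optional reference molecules plotted alongside.
#' @param seed Embedding seed.
#' @param n_neighbors UMAP neighbourhood size.
#' @return A `chem_embedding` tibble: `set` (`"query"`/`"reference"`),
#'   `smiles`, `x`, `y`.
#' @export
embed_chemical_space <- function(mols, refs = NULL, seed = 42L,
                                 n_neighbors = 15L) {
  mols <- if (is.data.frame(mols)) mols$canonical_smiles else as.character(mols)
  refs <- if (is.data.frame(refs)) refs$canonical_smiles else as.character(refs %||% character())
  all_smiles <- c(mols, refs)
  if (length(all_smiles) < 10) {
    rlang::abort("need at least 10 molecules to embed",
                 class = "patgen_too_few_molecules")
  }
  fp <- fingerprint_matrix(all_smiles, "morgan_r2")
  k <- min(n_neighbors, length(all_smiles) - 1) + 1
  nn <- cpp_jaccard_knn(fp, as.integer(k))
  set.seed(seed)
  coords <- uwot::umap(
    data.frame(i = seq_along(all_smiles), j = 0),
    nn_method = list(idx = nn$idx, dist = nn$dist),
    n_threads = 1, n_sgd_threads = 0, verbose = FALSE
  )
  out <- tibble::tibble(
    set = rep(c("query", "reference"), c(length(mols), length(refs))),
    smiles = all_smiles,
    x = coords[, 1],
    y = coords[, 2]
  )
  attr(out, "metric") <- "jaccard"
  attr(out, "fingerprint") <- "morgan_r2"
  attr(out, "seed") <- seed
  class(out) <- c("chem_embedding", class(out))
  out
}

#' Analogs of a drug among generated molecules
#'
#' Valid unique generated molecules with Tanimoto similarity (Morgan
#' radius-2) of at least `threshold` to the query drug, annotated with
#' QED and, when a database is given, the patent-membership flag.
#'
#' @param log A `generation_log`.
#' @param drug_smiles Query drug SMILES.
#' @param threshold Similarity threshold (default 0.5).
#' @param db Optional `drug_patent_db`.
#' @return A tibble sorted by descending similarity: `canonical_smiles`,
#'   `similarity`, `qed`, `db_match`.
#' @export
find_analogs <- function(log, drug_smiles, threshold = 0.5, db = NULL) {
  q <- parse_smiles(drug_smiles)
  if (!q$valid[1]) {
    rlang::abort("query drug SMILES is not interpretable",
                 class = "patgen_invalid_query")
  }
  mols <- valid_unique_smiles(log)
  if (length(mols) == 0) {
    return(tibble::tibble(canonical_smiles = character(),
                          similarity = numeric(), qed = numeric(),
                          db_match = logical()))
  }
  mfp <- fingerprint_matrix(mols, "morgan_r2")
  dfp <- fingerprint_matrix(q$canonical_smiles[1], "morgan_r2")
  sims <- as.numeric(cpp_tanimoto_cross(mfp, dfp))
  keep <- sims >= threshold
  hits <- tibble::tibble(canonical_smiles = mols[keep],
                         similarity = sims[keep])
  if (nrow(hits) == 0) {
    hits$qed <- numeric()
    hits$db_match <- logical()
    return(hits)
  }
  hits$qed <- compute_descriptors(hits$canonical_smiles)$qed
  hits$db_match <- if (!is.null(db)) {
    lookup(db, inchikey_nostereo(hits$canonical_smiles))$matched
  } else {
    NA
  }
  dplyr::arrange(hits, dplyr::desc(.data$similarity))
}
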