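# Deterministic synthetic patent universe.
#
# Molecules are enumerated as scaffold x substituent combinations (never
# random SMILES mutation) so patented/unpatented membership is exact
# ground truth, stable across platforms, and large enough to exercise the
# matchers and the generator at test scale.

default_fixture_scaffolds <- function() {
  c(
    "c1ccc({R1})c({R2})c1",              # benzene, ortho sites
    "c1ccc(-c2ccc({R1})cc2)c({R2})c1",   # biphenyl
    "c1ccc2cc({R1})c({R2})cc2c1",        # naphthalene
    "c1cc({R1})cc({R2})n1",              # pyridine
    "c1cc({R1})c(N2CCN({R2})CC2)cc1",    # arylpiperazine
    "C1CCN({R1})C({R2})C1",              # piperidine
    "c1csc({R1})c1{R2}",                 # thiophene
    "c1cc2c(cc1{R1})OCO2",               # benzodioxole (single site)
    "c1cc({R1})c2ncccc2c1{R2}",          # quinoline
    "C1COC({R1})CN1{R2}"                 # morpholine
  )
}

default_fixture_substituents <- function() {
  c(
    "C", "CC", "CCC", "C(C)C", "O", "OC", "OCC", "N", "NC", "N(C)C",
    "F", "Cl", "Br", "C#N", "C(F)(F)F", "CO", "C(=O)O", "C(=O)N",
    "C(=O)OC", "S(C)(=O)=O", "c8ccccc8", "c8ccncc8", "C8CC8",
    "C8CCCC8", "OC(F)(F)F", "C=C", "CNC", "CCO", "CCN", "N8CCOCC8"
  )
}

#' Specification of a synthetic patent universe
#'
#' @param scaffolds Ring-containing SMILES templates with substitution
#'   sites written as `({R1})`, `({R2})`, ... (a site vanishes when left
#'   unsubstituted).
#' @param substituents Fragment SMILES insertable as branches (ring
#'   closures inside substituents use digits 8-9 to avoid clashing with
#'   scaffold ring numbering).
#' @param max_substitutions Maximum number of occupied sites per molecule.
#' @param frac_patented Fraction of the universe assigned to the patented
#'   partition by [split_universe()].
#' @param n_target Universe size after deduplication.
#' @param seed Seed for all random choices (OCR flags, partitioning).
#' @param frac_ocr Fraction of records flagged as OCR-derived structures.
#' @param frac_nondrug Fraction of the patented partition wired to
#'   non-drug patent classifications (to exercise the database filters).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(scaffolds = default_fixture_scaffolds(),
                         substituents = default_fixture_substituents(),
                         max_substitutions = 2L, frac_patented = 0.6,
                         n_target = 5000L, seed = 42L,
                         frac_ocr = 0, frac_nondrug = 0) {
  stopifnot(length(scaffolds) > 0, length(substituents) > 0,
            frac_patented > 0, frac_patented < 1, n_target >= 1)
  structure(
    list(scaffolds = scaffolds, substituents = substituents,
         max_substitutions = as.integer(max_substitutions),
         frac_patented = frac_patented, n_target = as.integer(n_target),
         seed = as.integer(seed), frac_ocr = frac_ocr,
         frac_nondrug = frac_nondrug),
    class = "fixture_spec"
  )
}

enumerate_scaffold <- function(template, substituents, max_substitutions) {
  sites <- stringr::str_extract_all(template, "\\{R[0-9]+\\}")[[1]]
  options <- c("", substituents)
  grids <- expand.grid(rep(list(options), length(sites)),
                       stringsAsFactors = FALSE)
  n_sub <- rowSums(grids != "")
  grids <- grids[n_sub <= max_substitutions, , drop = FALSE]
  out <- rep(template, nrow(grids))
  for (si in seq_along(sites)) {
    sub <- grids[[si]]
    filled <- stringr::str_replace(out, stringr::fixed(sites[si]), sub)
    # unsubstituted site: remove the whole empty branch "()"
    out <- stringr::str_replace(filled, stringr::fixed("()"), "")
  }
  out
}

#' Enumerate the deterministic synthetic molecule universe
#'
#' Enumerates all scaffold x substituent combinations (up to
#' `max_substitutions` occupied sites), standardizes them, deduplicates by
#' stereo-free InChIKey in enumeration order, and truncates to `n_target`
#' records. A seeded fraction receives `ocr_flag = TRUE`.
#'
#' @param spec A [fixture_spec()].
#' @return A tibble of molecule records: `source_id`, `smiles` (canonical),
#'   `inchikey_nostereo`, `ocr_flag`.
#' @export
make_universe <- function(spec) {
  raw <- unlist(lapply(spec$scaffolds, enumerate_scaffold,
                       substituents = spec$substituents,
                       max_substitutions = spec$max_substitutions))
  std <- standardize_molecules(raw)
  std <- std[std$ok, ]
  std <- std[!duplicated(std$inchikey_nostereo), ]
  if (nrow(std) < spec$n_target) {
    rlang::abort(
      sprintf("enumerable space (%d) smaller than n_target (%d)",
              nrow(std), spec$n_target),
      class = "patgen_space_too_small"
    )
  }
  std <- std[seq_len(spec$n_target), ]
  set.seed(spec$seed)
  ocr <- rep(FALSE, nrow(std))
  if (spec$frac_ocr > 0) {
    ocr[sample.int(nrow(std), round(spec$frac_ocr * nrow(std)))] <- TRUE
  }
  tibble::tibble(
    source_id = sprintf("FIX%06d", seq_len(nrow(std))),
    smiles = std$canonical_smiles,
    inchikey_nostereo = std$inchikey_nostereo,
    ocr_flag = ocr
  )
}

#' Partition a universe into patented and novel sets
#'
#' Draws a seeded `frac_patented` fraction as the patented set and wires
#' it to synthetic drug-related (A61K/A61P) patent records, 50 compounds
#' per patent; a `frac_nondrug` fraction of the patented set is instead
#' wired to non-drug (C07D) patents. The novel set shares no stereo-free
#' key with the patented set (the universe is key-deduplicated).
#'
#' @param universe Output of [make_universe()].
#' @param frac_patented Fraction assigned patents.
#' @param seed Sampling seed.
#' @param frac_nondrug Fraction of the patented set given only non-drug
#'   classifications.
#' @return A list with `patented` (records plus `patent_numbers`
#'   list-column), `novel` (records), `patents` (patent table with
#'   `patent_number`, `ipc_codes`, `cpc_codes`).
#' @export
split_universe <- function(universe, frac_patented = 0.6, seed = 42L,
                           frac_nondrug = 0) {
  stopifnot(nrow(universe) > 0)
  set.seed(seed)
  n_pat <- round(frac_patented * nrow(universe))
  idx <- sort(sample.int(nrow(universe), n_pat))
  patented <- universe[idx, ]
  novel <- universe[-idx, ]

  n_nondrug <- round(frac_nondrug * n_pat)
  is_nondrug <- rep(FALSE, n_pat)
  if (n_nondrug > 0) is_nondrug[sample.int(n_pat, n_nondrug)] <- TRUE

  drug_pat_no <- sprintf("SYNPAT-%05d", ceiling(seq_len(sum(!is_nondrug)) / 50))
  nond_pat_no <- sprintf("NONPAT-%05d", ceiling(seq_len(sum(is_nondrug)) / 50))
  patent_numbers <- character(n_pat)
  patent_numbers[!is_nondrug] <- drug_pat_no
  patent_numbers[is_nondrug] <- nond_pat_no
  patented$patent_numbers <- as.list(patent_numbers)

  patents <- tibble::tibble(
    patent_number = unique(patent_numbers),
    ipc_codes = ifelse(startsWith(unique(patent_numbers), "SYNPAT"),
                       "A61K31/00", "C07D498/04"),
    cpc_codes = ifelse(startsWith(unique(patent_numbers), "SYNPAT"),
                       "A61P35/00", "")
  )
  list(patented = patented, novel = novel, patents = patents)
}

#' Sample a training corpus from the patented set
#'
#' @param patented Patented records from [split_universe()].
#' @param n Corpus size (at most the patented set size).
#' @param seed Sampling seed.
#' @param path Optional output path; when given, written as a SMILES line
#'   file.
#' @return Character vector of canonical SMILES.
#' @export
make_corpus <- function(patented, n, seed = 42L, path = NULL) {
  if (n > nrow(patented)) {
    rlang::abort("corpus sample larger than the patented set",
                 class = "patgen_sample_too_large")
  }
  set.seed(seed)
  smiles <- patented$smiles[sort(sample.int(nrow(patented), n))]
  if (!is.null(path)) write_smiles_file(smiles, path)
  smiles
}

#' Write fixture tables in the formats the database builder consumes
#'
#' @param split Output of [split_universe()].
#' @param dir Output directory.
#' @return Paths of `compounds.tsv` and `patents.tsv` (invisibly).
#' @export
write_fixture_tables <- function(split, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  comp <- dplyr::bind_rows(
    dplyr::mutate(split$patented,
                  patent_numbers = purrr::map_chr(.data$patent_numbers,
                                                  paste, collapse = ";")),
    dplyr::mutate(split$novel, patent_numbers = "")
  )
  comp <- dplyr::transmute(comp,
    external_id = .data$source_id, smiles = .data$smiles,
    ocr_flag = .data$ocr_flag, patent_numbers = .data$patent_numbers
  )
  comp_path <- file.path(dir, "compounds.tsv")
  pat_path <- file.path(dir, "patents.tsv")
  utils::write.table(comp, comp_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(split$patents, pat_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(compounds = comp_path, patents = pat_path))
}
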