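#' Parse SMILES strings
#'
#' Checks each string for chemical interpretability and returns the
#' RDKit-canonical form of the parseable ones. Invalid strings are kept in
#' the result with `valid = FALSE` so generation logs can account for them;
#' set `must_work = TRUE` to turn any invalid string into an error instead.
#'
#' @param smiles Character vector of SMILES strings.
#' @param must_work Error (class `patgen_invalid_smiles`) on any
#'   uninterpretable string.
#' @return A tibble with columns `smiles`, `valid`, `canonical_smiles`,
#'   `n_heavy_atoms`.
#' @examples
#' \dontrun{
#' parse_smiles(c("CCO", "C1CC"))
#' }
#' @export
parse_smiles <- function(smiles, must_work = FALSE) {
  stopifnot(is.character(smiles))
  if (any(!nzchar(smiles) | is.na(smiles))) {
    rlang::abort("empty SMILES string", class = "patgen_invalid_smiles")
  }
  res <- chem_request_chunked("parse", smiles)
  out <- tibble::tibble(
    smiles = smiles,
    valid = purrr::map_lgl(res, "valid"),
    canonical_smiles = purrr::map_chr(res, ~ .x$canonical_smiles %||% NA_character_),
    n_heavy_atoms = purrr::map_int(res, ~ as.integer(.x$n_heavy_atoms %||% NA))
  )
  if (must_work && !all(out$valid)) {
    rlang::abort(
      paste0(
        "uninterpretable SMILES: ",
        paste(utils::head(out$smiles[!out$valid], 5), collapse = ", ")
      ),
      class = "patgen_invalid_smiles"
    )
  }
  out
}

#' Standardize molecules to parent structures with stereo-free identity keys
#'
#' Applies ChEMBL-structure-pipeline-style rules via RDKit: functional-group
#' cleanup, retention of the largest organic fragment (desalting), and
#' neutralization. The identity key is the full 27-character InChIKey of the
#' structure with all stereochemistry removed, so stereoisomers collide by
#' design. Records with no organic component (all-inorganic salts) fail with
#' `error = "StandardizationFailure"`.
#'
#' @param smiles Character vector, or a data frame with a `smiles` column
#'   (any other columns, e.g. `source_id`, are carried through).
#' @return A tibble with columns `ok`, `canonical_smiles`,
#'   `inchikey_nostereo`, `error` appended to the input columns.
#' @export
standardize_molecules <- function(smiles) {
  if (is.data.frame(smiles)) {
    df <- tibble::as_tibble(smiles)
    stopifnot("smiles" %in% names(df))
  } else {
    df <- tibble::tibble(smiles = as.character(smiles))
  }
  res <- chem_request_chunked("standardize", df$smiles)
  df$ok <- purrr::map_lgl(res, "ok")
  df$canonical_smiles <- purrr::map_chr(res, ~ .x$canonical_smiles %||% NA_character_)
  df$inchikey_nostereo <- purrr::map_chr(res, ~ .x$inchikey_nostereo %||% NA_character_)
  df$error <- purrr::map_chr(res, ~ .x$error %||% NA_character_)
  df
}

#' Stereo-free InChIKey of molecules
#'
#' The 27-character InChIKey computed after removing all stereocenters and
#' bond stereo, the structure identity used throughout the package.
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of keys (`NA` for unparseable input).
#' @export
inchikey_nostereo <- function(smiles) {
  res <- chem_request_chunked("inchikey", as.character(smiles))
  purrr::map_chr(res, ~ .x %||% NA_character_)
}

#' Canonical SMILES and stereo-free keys without standardization
#'
#' A light-weight identity pass for molecules already known to be
#' single-component and neutral (e.g. enumerated fixtures): canonical
#' SMILES plus the stereo-free InChIKey, skipping the standardization
#' rules.
#'
#' @param smiles Character vector of SMILES.
#' @return A tibble with `smiles`, `valid`, `canonical_smiles`,
#'   `inchikey_nostereo`.
#' @export
molecule_keys <- function(smiles) {
  res <- chem_request_chunked("parse_key", as.character(smiles))
  tibble::tibble(
    smiles = as.character(smiles),
    valid = purrr::map_lgl(res, "valid"),
    canonical_smiles = purrr::map_chr(res, ~ .x$canonical_smiles %||% NA_character_),
    inchikey_nostereo = purrr::map_chr(res, ~ .x$inchikey_nostereo %||% NA_character_)
  )
}

#' Molecular descriptors
#'
#' Computes the descriptor set used by the curation and generation filters:
#' molecular weight, SlogP, atom counts, aromatic ring count, fraction of
#' sp3 carbons, Lipinski H-bond donors/acceptors, QED drug-likeness,
#' Ertl-Schuffenhauer synthetic accessibility score, largest ring size,
#' radical electron count and the Bemis-Murcko scaffold.
#'
#' @param smiles Character vector, or data frame with a `smiles` column.
#' @return A tibble of descriptors, one row per molecule.
#' @export
compute_descriptors <- function(smiles) {
  if (is.data.frame(smiles)) {
    df <- tibble::as_tibble(smiles)
  } else {
    df <- tibble::tibble(smiles = as.character(smiles))
  }
  res <- chem_request_chunked("descriptors", df$smiles)
  bad <- purrr::map_lgl(res, ~ !is.null(.x$error))
  if (any(bad)) {
    rlang::abort(
      paste0("descriptor failure: ", res[[which(bad)[1]]]$error,
             " for ", df$smiles[which(bad)[1]]),
      class = "patgen_descriptor_failure"
    )
  }
  num <- function(f) purrr::map_dbl(res, f)
  int <- function(f) as.integer(purrr::map_dbl(res, f))
  dplyr::bind_cols(df, tibble::tibble(
    mol_weight = num("mol_weight"),
    slogp = num("slogp"),
    n_atoms = int("n_atoms"),
    n_heavy_atoms = int("n_heavy_atoms"),
    n_aromatic_rings = int("n_aromatic_rings"),
    fraction_csp3 = num("fraction_csp3"),
    hbd = int("hbd"),
    hba = int("hba"),
    qed = num("qed"),
    sa_score = num("sa_score"),
    max_ring_size = int("max_ring_size"),
    n_radical_electrons = int("n_radical_electrons"),
    murcko_scaffold = purrr::map_chr(res, "murcko_scaffold")
  ))
}

#' Molecular fingerprints
#'
#' Three kinds: `morgan_r2` and `morgan_r3` (2048-bit circular fingerprints,
#' returned as 0-based on-bit index sets) and `mhfp6` (MinHash fingerprint,
#' a 2048-long integer minhash vector suited to locality-sensitive hashing).
#'
#' @param smiles Character vector of SMILES.
#' @param kind One of `"morgan_r2"`, `"morgan_r3"`, `"mhfp6"`.
#' @param mhfp_seed Permutation seed for the MinHash encoder; fingerprints
#'   are only comparable when computed with the same seed.
#' @return A list of integer vectors with attribute `kind` (and `mhfp_seed`
#'   for mhfp6); `NULL` elements for unparseable SMILES.
#' @export
fingerprint <- function(smiles, kind = c("morgan_r2", "morgan_r3", "mhfp6"),
                        mhfp_seed = 42L) {
  kind <- rlang::arg_match(kind)
  res <- chem_request_chunked(
    "fingerprint", as.character(smiles),
    extra = list(kind = kind, seed = as.integer(mhfp_seed))
  )
  out <- purrr::map(res, ~ if (is.null(.x)) NULL else as.integer(unlist(.x)))
  attr(out, "kind") <- kind
  if (kind == "mhfp6") attr(out, "mhfp_seed") <- as.integer(mhfp_seed)
  out
}

fp_kind <- function(fp) attr(fp, "kind") %||% "morgan_r2"

#' Tanimoto similarity of two fingerprints
#'
#' For Morgan bit sets this is the Jaccard index of the on-bit sets; for
#' MHFP6 minhash vectors it is the fraction of matching minhash positions
#' (an unbiased Jaccard estimate). Both fingerprints must be of the same
#' kind.
#'
#' @param a,b Integer vectors as returned (element-wise) by [fingerprint()].
#' @param kind Fingerprint kind; defaults to the `kind` attribute of `a`.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b, kind = NULL) {
  kind <- kind %||% attr(a, "kind") %||% "morgan_r2"
  kb <- attr(b, "kind")
  if (!is.null(kb) && !identical(kind, kb)) {
    rlang::abort("fingerprint kinds differ", class = "patgen_kind_mismatch")
  }
  a <- as.integer(a)
  b <- as.integer(b)
  if (kind == "mhfp6") {
    if (length(a) != length(b)) {
      rlang::abort("minhash vectors of unequal length",
                   class = "patgen_kind_mismatch")
    }
    return(mean(a == b))
  }
  n_union <- length(union(a, b))
  if (n_union == 0) return(1)
  length(intersect(a, b)) / n_union
}

#' Murcko scaffold of molecules
#'
#' Bemis-Murcko framework: ring systems plus the linkers connecting them,
#' side chains removed. Acyclic molecules have an empty scaffold.
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of scaffold SMILES (`""` for acyclic, `NA` for
#'   unparseable input).
#' @export
murcko_scaffold <- function(smiles) {
  res <- chem_request_chunked("murcko", as.character(smiles))
  purrr::map_chr(res, ~ .x %||% NA_character_)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
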