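# Training-corpus curation.
#
# The staged pipeline removes compounds unsuited to language-model
# training: unparseable or ringless structures, non-drug-like elements,
# isotope labels, reactive substructures, salts, and the property-
# distribution tails; the survivors are standardized and emitted as
# canonical SMILES.

default_substructure_blacklist <- function() {
  c(
    acyl_halide = "[CX3](=O)[F,Cl,Br,I]",
    isocyanate = "[NX2]=C=O",
    peroxide = "[OX2][OX2]",
    n_nitroso = "[NX3][NX2]=O",
    azide = "[NX2]=[NX2+]=[NX1-]",
    alkyl_halide_nonbenzylic = "[CX4;!$([CX4]a)][Cl,Br,I]"
  )
}

default_allowed_elements <- function() {
  c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I")
}

#' Curation configuration
#'
#' @param initial_sample_size Compounds drawn (seeded) from the source
#'   before filtering.
#' @param allowed_elements Permitted element symbols.
#' @param substructure_blacklist Named character vector of SMARTS patterns
#'   whose matches are removed (default: a small shipped list of reactive
#'   or undesirable groups; replaceable config).
#' @param forbid_isotopes Remove molecules carrying isotope labels.
#' @param property_trim_quantiles Length-2 numeric `(low, high)`; for each
#'   trimmed descriptor (atom count, heavy-atom count, molecular weight,
#'   SlogP, aromatic ring count, fraction sp3 carbon) molecules outside
#'   these quantiles of the post-desalting population are removed.
#' @param final_sample_size Seeded subsample size after trimming.
#' @param seed Seed for both sampling stages.
#' @return A `curation_config` list.
#' @export
curation_config <- function(initial_sample_size = 5e6,
                            allowed_elements = default_allowed_elements(),
                            substructure_blacklist = default_substructure_blacklist(),
                            forbid_isotopes = TRUE,
                            property_trim_quantiles = c(0.005, 0.995),
                            final_sample_size = 250000,
                            seed = 1L) {
  q <- property_trim_quantiles
  if (!(length(q) == 2 && q[1] >= 0 && q[1] < q[2] && q[2] <= 1)) {
    rlang::abort("property_trim_quantiles must satisfy 0 <= low < high <= 1",
                 class = "patgen_config_error")
  }
  if (final_sample_size > initial_sample_size) {
    rlang::abort("final_sample_size must not exceed initial_sample_size",
                 class = "patgen_config_error")
  }
  structure(
    list(initial_sample_size = initial_sample_size,
         allowed_elements = allowed_elements,
         substructure_blacklist = substructure_blacklist,
         forbid_isotopes = forbid_isotopes,
         property_trim_quantiles = q,
         final_sample_size = final_sample_size,
         seed = as.integer(seed)),
    class = "curation_config"
  )
}

TRIMMED_DESCRIPTORS <- c("n_atoms", "n_heavy_atoms", "mol_weight", "slogp",
                         "n_aromatic_rings", "fraction_csp3")

#' Curate a language-model training corpus
#'
#' Staged pipeline, in order: (1) seeded random sample of
#' `initial_sample_size`; (2) drop unparseable/empty SMILES; (3) drop
#' ringless molecules; (4) drop molecules with disallowed elements,
#' isotope labels, or blacklist substructures; (5) desalt to the largest
#' organic component; (6) trim the property-distribution tails (quantiles
#' computed on the post-desalting population); (7) seeded subsample of
#' `final_sample_size`; (8) standardize and emit canonical SMILES.
#'
#' @param source Character vector of SMILES, a data frame with a `smiles`
#'   column, or a path to a SMILES line file.
#' @param config A [curation_config()].
#' @param output_path Optional path; corpus written as a SMILES line file.
#' @return A list with `corpus` (character vector of canonical SMILES) and
#'   `report` (a `curation_report`: `stage_counts` tibble,
#'   `n_unique_scaffolds`, `output_path`).
#' @export
curate_training_set <- function(source, config = curation_config(),
                                output_path = NULL) {
  if (is.character(source) && length(source) == 1 && file.exists(source)) {
    source <- read_smiles_file(source)
  }
  if (is.data.frame(source)) source <- source$smiles
  source <- as.character(source)
  if (length(source) == 0) {
    rlang::abort("empty curation source", class = "patgen_empty_source")
  }
  stages <- list()
  note <- function(name, x) {
    stages[[name]] <<- length(x)
    x
  }

  set.seed(config$seed)
  smiles <- if (length(source) > config$initial_sample_size) {
    source[sort(sample.int(length(source), config$initial_sample_size))]
  } else {
    source
  }
  smiles <- note("sampled", smiles)

  smiles <- smiles[!is.na(smiles) & nzchar(smiles)]
  audit <- purrr::map(
    chem_request_chunked("atom_audit", smiles,
                         extra = list(allowed_elements = as.list(config$allowed_elements))),
    identity
  )
  parseable <- purrr::map_lgl(audit, "parseable")
  smiles <- note("parseable", smiles[parseable])
  audit <- audit[parseable]

  has_ring <- purrr::map_int(audit, "n_rings") > 0
  smiles <- note("has_ring", smiles[has_ring])
  audit <- audit[has_ring]

  elements_ok <- purrr::map_lgl(audit, "elements_ok")
  iso_ok <- if (config$forbid_isotopes) {
    !purrr::map_lgl(audit, "has_isotope")
  } else {
    rep(TRUE, length(audit))
  }
  black_ok <- if (length(config$substructure_blacklist) > 0) {
    hits <- chem_request_chunked(
      "match_smarts", smiles,
      extra = list(patterns = as.list(unname(config$substructure_blacklist)))
    )
    !purrr::map_lgl(hits, ~ any(unlist(.x)))
  } else {
    rep(TRUE, length(smiles))
  }
  smiles <- note("composition", smiles[elements_ok & iso_ok & black_ok])

  desalted <- standardize_molecules(smiles)
  desalted <- desalted[desalted$ok, ]
  smiles <- note("desalted", desalted$canonical_smiles)

  desc <- compute_descriptors(smiles)
  keep <- rep(TRUE, nrow(desc))
  for (d in TRIMMED_DESCRIPTORS) {
    qq <- quantile(desc[[d]], config$property_trim_quantiles, names = FALSE)
    keep <- keep & desc[[d]] >= qq[1] & desc[[d]] <= qq[2]
  }
  smiles <- note("property_trimmed", smiles[keep])

  if (length(smiles) > config$final_sample_size) {
    smiles <- smiles[sort(sample.int(length(smiles), config$final_sample_size))]
  }
  smiles <- note("final_sample", smiles)

  # survivors are already standardized; re-emission is the canonical form
  corpus <- smiles
  scaffolds <- murcko_scaffold(corpus)

  if (!is.null(output_path)) write_smiles_file(corpus, output_path)
  report <- structure(
    list(
      stage_counts = tibble::tibble(
        stage = names(stages),
        surviving = as.integer(unlist(stages))
      ),
      n_unique_scaffolds = length(unique(scaffolds[nzchar(scaffolds)])),
      output_path = output_path
    ),
    class = "curation_report"
  )
  list(corpus = corpus, report = report)
}

#' @export
print.curation_report <- function(x, ...) {
  cat("<curation_report>\n")
  print(x$stage_counts)
  cat("unique Murcko scaffolds:", x$n_unique_scaffolds, "\n")
  invisible(x)
}

#' @rdname curate_training_set
#' @param x A `curation_report`.
#' @param ... Unused.
#' @export
tidy.curation_report <- function(x, ...) x$stage_counts
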