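corpus_source <- function() {
  c(
    fixture_split()$patented$smiles[1:400],
    "CC(C)C",            # no ring
    "CCCCCC",            # no ring
    "[Fe]c1ccccc1",      # disallowed element (would also fail elsewhere)
    "C[Si](C)(C)c1ccccc1C[Ge]",  # Ge disallowed
    "[13C]c1ccccc1",     # isotope label
    "CC(=O)Cl",          # blacklist: acyl halide (also ringless)
    "ClCCc1ccccc1",      # blacklist: non-benzylic alkyl chloride
    "CC(=O)[O-].[Na+]"   # salt, ringless after desalting
  )
}

test_that("curation removes ringless, metal, isotope and blacklist inputs", {
  cfg <- curation_config(
    initial_sample_size = 1000, final_sample_size = 1000,
    property_trim_quantiles = c(0, 1), seed = 5
  )
  src <- corpus_source()
  res <- curate_training_set(src, cfg)
  corpus <- res$corpus

  # independent per-rule oracle over the same input, applied brute force
  audit <- purrr::map(
    patgen:::chem_request_chunked(
      "atom_audit", src,
      extra = list(allowed_elements = as.list(cfg$allowed_elements))
    ), identity
  )
  hits <- patgen:::chem_request_chunked(
    "match_smarts", src,
    extra = list(patterns = as.list(unname(cfg$substructure_blacklist)))
  )
  ok <- purrr::map_lgl(audit, ~ isTRUE(.x$parseable)) &
    purrr::map_int(audit, ~ as.integer(.x$n_rings %||% 0)) > 0 &
    purrr::map_lgl(audit, ~ isTRUE(.x$elements_ok)) &
    !purrr::map_lgl(audit, ~ isTRUE(.x$has_isotope)) &
    !purrr::map_lgl(hits, ~ any(unlist(.x)))
  oracle <- standardize_molecules(src[ok])
  expect_setequal(corpus, oracle$canonical_smiles[oracle$ok])

  expect_false(any(c("CC(C)C", "CCCCCC") %in% corpus))
  expect_false(any(grepl("Fe|Ge|13C", corpus)))
  expect_false("CC(=O)Cl" %in% corpus)
  expect_false("ClCCc1ccccc1" %in% corpus)

  counts <- res$report$stage_counts
  expect_equal(counts$surviving[counts$stage == "sampled"], length(src))
  # stage counts never increase after sampling
  expect_true(all(diff(counts$surviving) <= 0))
  expect_lte(res$report$n_unique_scaffolds, length(corpus))
})

test_that("curation output is a fixed point of its own filters", {
  cfg <- curation_config(
    initial_sample_size = 500, final_sample_size = 200,
    property_trim_quantiles = c(0.05, 0.95), seed = 9
  )
  res <- curate_training_set(fixture_split()$patented$smiles[1:500], cfg)
  corpus <- res$corpus
  expect_equal(length(corpus), 200L)

  p <- parse_smiles(corpus)
  expect_true(all(p$valid))
  audit <- purrr::map(
    patgen:::chem_request_chunked(
      "atom_audit", corpus,
      extra = list(allowed_elements = as.list(cfg$allowed_elements))
    ), identity
  )
  expect_true(all(purrr::map_int(audit, "n_rings") > 0))
  expect_true(all(purrr::map_lgl(audit, "elements_ok")))
  expect_true(all(purrr::map_int(audit, "n_components") == 1))

  # re-application with no trimming or subsampling keeps every molecule
  cfg2 <- curation_config(
    initial_sample_size = 500, final_sample_size = 500,
    property_trim_quantiles = c(0, 1), seed = 9
  )
  res2 <- curate_training_set(corpus, cfg2)
  expect_setequal(res2$corpus, corpus)
})

test_that("curation is deterministic for identical input, config and seed", {
  cfg <- curation_config(initial_sample_size = 300, final_sample_size = 100,
                         seed = 21)
  src <- fixture_split()$patented$smiles[1:350]
  out1 <- file.path(fixture_dir(), "corpus1.smi")
  out2 <- file.path(fixture_dir(), "corpus2.smi")
  curate_training_set(src, cfg, output_path = out1)
  curate_training_set(src, cfg, output_path = out2)
  expect_identical(readLines(out1), readLines(out2))
})

test_that("curation configs are validated", {
  expect_error(curation_config(property_trim_quantiles = c(0.9, 0.1)),
               class = "patgen_config_error")
  expect_error(curation_config(initial_sample_size = 10,
                               final_sample_size = 20),
               class = "patgen_config_error")
  expect_error(curate_training_set(character(), curation_config()),
               class = "patgen_empty_source")
})

test_that("Murcko scaffolds strip side chains and vanish for acyclic input", {
  expect_equal(murcko_scaffold("CCc1ccccc1"), "c1ccccc1")
  expect_equal(murcko_scaffold("c1ccc(-c2ccccc2)cc1"), "c1ccc(-c2ccccc2)cc1")
  expect_equal(murcko_scaffold("CCCCCC"), "")
})
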