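test_that("SMILES parsing separates valid from invalid strings", {
  res <- parse_smiles(c("CCO", "c1ccccc1"))
  expect_true(all(res$valid))
  expect_equal(res$n_heavy_atoms[1], 3L)

  bad <- parse_smiles("C1CC")  # unclosed ring
  expect_false(bad$valid[1])
  expect_error(parse_smiles("C1CC", must_work = TRUE),
               class = "patgen_invalid_smiles")
  expect_error(parse_smiles(""), class = "patgen_invalid_smiles")
})

test_that("standardization desalts, neutralizes and is idempotent", {
  res <- standardize_molecules(c("CC(=O)[O-].[Na+]", "CCO"))
  expect_equal(res$canonical_smiles, c("CC(=O)O", "CCO"))
  expect_true(all(res$ok))

  # all-inorganic records have no organic parent
  salt <- standardize_molecules("[Na+].[Cl-]")
  expect_false(salt$ok[1])
  expect_equal(salt$error[1], "StandardizationFailure")

  # idempotence over the fixture universe (1,000 molecules)
  first <- fixture_universe()$smiles[1:1000]
  twice <- standardize_molecules(standardize_molecules(first)$canonical_smiles)
  expect_equal(twice$canonical_smiles, first)
})

test_that("stereo-free InChIKeys collapse stereoisomers and keep format", {
  expect_equal(inchikey_nostereo("CCO"), "LFQSCWFLJHTTHZ-UHFFFAOYSA-N")
  keys <- inchikey_nostereo(c("C[C@H](N)C(=O)O", "C[C@@H](N)C(=O)O",
                              "CC(N)C(=O)O"))
  expect_equal(keys[1], keys[2])
  expect_equal(keys[1], keys[3])
  expect_false(inchikey_nostereo("CCO") == inchikey_nostereo("CCN"))
  expect_match(keys, "^[A-Z]{14}-[A-Z]{10}-[A-Z]$", all = TRUE)
})

test_that("stereo erasure in the input never changes the stereo-free key", {
  smiles <- fixture_universe()$smiles[1:50]
  # fixtures are achiral; build stereo-bearing variants instead
  stereo <- c("C[C@H](N)C(=O)O", "F/C=C/F", "F/C=C\\F",
              "O[C@@H]1CCCC[C@H]1O")
  plain <- gsub("[@/\\\\]", "", stereo)
  expect_equal(inchikey_nostereo(stereo), inchikey_nostereo(plain))
  # and equal canonical structures imply equal keys
  keys <- inchikey_nostereo(smiles)
  expect_equal(inchikey_nostereo(smiles), keys)
})

test_that("descriptor set covers the filter inputs", {
  d <- compute_descriptors(c("c1ccccc1", "C", "C1CCCCC1"))
  expect_equal(d$n_aromatic_rings, c(1L, 0L, 0L))
  expect_equal(d$fraction_csp3, c(0, 1, 1))
  expect_equal(d$murcko_scaffold, c("c1ccccc1", "", "C1CCCCC1"))
  expect_equal(d$max_ring_size, c(6L, 0L, 6L))
  expect_equal(d$n_radical_electrons, c(0L, 0L, 0L))
  expect_true(all(d$qed >= 0 & d$qed <= 1))
  expect_true(all(d$sa_score >= 1 & d$sa_score <= 10))
  expect_error(compute_descriptors("C1CC"),
               class = "patgen_descriptor_failure")
})

test_that("fingerprints are deterministic and keyed to canonical structure", {
  fp1 <- fingerprint(c("c1ccccc1O", "c1ccccc1O"), "morgan_r2")
  expect_identical(fp1[[1]], fp1[[2]])
  # same molecule written two ways
  fp2 <- fingerprint(c("OC1=CC=CC=C1"), "morgan_r2")
  expect_identical(fp1[[1]], fp2[[1]])
  for (kind in c("morgan_r2", "morgan_r3", "mhfp6")) {
    fp <- fingerprint("CCO", kind)
    expect_equal(tanimoto(fp[[1]], fp[[1]], kind = kind), 1.0)
  }
  mh <- fingerprint("CCO", "mhfp6")
  expect_length(mh[[1]], 2048)
  fpm <- fingerprint("CCO", "morgan_r3")
  expect_true(all(fpm[[1]] >= 0 & fpm[[1]] < 2048))
})

test_that("tanimoto follows the set formula and rejects kind mismatch", {
  expect_equal(tanimoto(c(1L, 2L, 3L), c(2L, 3L, 4L)), 0.5)
  expect_equal(tanimoto(c(1L, 2L), c(3L, 4L)), 0)
  expect_equal(tanimoto(c(5L, 9L), c(9L, 5L)), 1)
  a <- fingerprint("CCO", "morgan_r2")[[1]]
  attr(a, "kind") <- "morgan_r2"
  b <- fingerprint("CCO", "mhfp6")[[1]]
  attr(b, "kind") <- "mhfp6"
  expect_error(tanimoto(a, b), class = "patgen_kind_mismatch")
  # symmetry on a small sample
  fps <- fingerprint(fixture_universe()$smiles[1:10], "morgan_r2")
  for (i in 1:5) {
    expect_equal(tanimoto(fps[[i]], fps[[i + 5]]),
                 tanimoto(fps[[i + 5]], fps[[i]]))
  }
})
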