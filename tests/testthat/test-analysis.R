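constructed_log <- function(smiles, valid, passed, canonical = smiles,
                            keys = canonical) {
  records <- tibble::tibble(
    iteration = seq_along(smiles), smiles = smiles, parse_valid = valid,
    canonical_smiles = ifelse(valid, canonical, NA),
    inchikey_nostereo = ifelse(valid, keys, NA),
    rare_pattern = NA, lipinski = NA, radical = NA, sa = NA, ring = NA,
    passed = passed, reward = NA_real_, new_unique = NA
  )
  ok <- valid & passed
  structure(
    list(config = list(c_explore = 0.4), reward_name = "test",
         records = records,
         totals = list(n_all = length(smiles), n_valid = sum(ok),
                       n_valid_unique = length(unique(canonical[ok])))),
    class = "generation_log"
  )
}

test_that("validity and uniqueness equal the hand-computed fractions", {
  # 4 generated, 3 valid, 2 unique among the valid
  log <- constructed_log(
    smiles = c("CCO", "CCO", "CCN", "xxx"),
    valid = c(TRUE, TRUE, TRUE, FALSE),
    passed = c(TRUE, TRUE, TRUE, FALSE)
  )
  m <- compute_metrics(log)
  expect_equal(m$validity, 0.75)
  expect_equal(m$uniqueness, 2 / 3)
  expect_true(m$validity * m$n_all == round(m$validity * m$n_all))
  expect_true(m$uniqueness * m$n_valid == round(m$uniqueness * m$n_valid))

  # a string that parses but fails a filter is not "valid"
  log2 <- constructed_log(
    smiles = c("CCO", "CCC"), valid = c(TRUE, TRUE),
    passed = c(TRUE, FALSE)
  )
  expect_equal(compute_metrics(log2)$validity, 0.5)

  # all-invalid log: validity zero, uniqueness undefined
  log3 <- constructed_log("xxx", FALSE, FALSE)
  expect_warning(m3 <- compute_metrics(log3), "uniqueness")
  expect_equal(m3$validity, 0)
  expect_true(is.na(m3$uniqueness))

  empty <- constructed_log(character(), logical(), logical())
  expect_error(compute_metrics(empty), class = "patgen_empty_log")
})

test_that("metrics are invariant under record reordering", {
  log <- constructed_log(
    smiles = c("CCO", "CCN", "CCO", "bad", "CCC"),
    valid = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    passed = c(TRUE, TRUE, TRUE, FALSE, FALSE)
  )
  m1 <- compute_metrics(log)
  set.seed(8)
  perm <- sample(nrow(log$records))
  log$records <- log$records[perm, ]
  m2 <- compute_metrics(log)
  expect_equal(m1$validity, m2$validity)
  expect_equal(m1$uniqueness, m2$uniqueness)
})

test_that("database match counts deduplicate and agree with reward ones", {
  split <- fixture_split()
  db <- fixture_db()
  pat <- split$patented[1:3, ]
  nov <- split$novel[1:2, ]
  log <- constructed_log(
    smiles = c(pat$smiles, pat$smiles[1], nov$smiles),
    valid = rep(TRUE, 6), passed = rep(TRUE, 6),
    keys = c(pat$inchikey_nostereo, pat$inchikey_nostereo[1],
             nov$inchikey_nostereo)
  )
  m <- compute_metrics(log, db)
  expect_equal(m$n_db_matches, 3L)
  expect_lte(m$n_db_matches, m$n_valid_unique)

  # cross-module consistency: count of reward-1 molecules in an R_patent
  # scoring of the same unique set
  rp <- r_patent(db)
  uniq <- log$records[!duplicated(log$records$canonical_smiles), ]
  rewards <- purrr::map_dbl(uniq$inchikey_nostereo,
                            ~ rp$evaluate(list(inchikey_nostereo = .x)))
  expect_equal(m$n_db_matches, sum(rewards))
})

test_that("similarity binning is left-closed with a closed top bin", {
  # direct recomputation: bin b holds s iff (b-1)/20 <= s < b/20, top bin
  # closed; edge values land in the bin they open
  expect_equal(
    patgen:::bin_similarity(c(0, 0.049, 0.05, 0.35, 0.45, 0.999, 1)),
    c(1, 1, 2, 8, 10, 20, 20)
  )
  sims <- c(9 / 20, 7 / 20, 1 / 3, 19 / 40, 1, 0)
  oracle <- vapply(sims, function(s) {
    for (b in 1:20) {
      lo <- (b - 1) / 20
      hi <- b / 20
      if ((s >= lo || abs(s - lo) < 1e-9) && (s < hi - 1e-9 || b == 20)) {
        return(b)
      }
    }
  }, integer(1))
  expect_equal(patgen:::bin_similarity(sims), oracle)
})

test_that("maximum-similarity distributions match bit-set arithmetic", {
  refs <- "c1ccccc1O"
  mols <- c("c1ccccc1O", "c1ccccc1N")
  d <- max_similarity_distribution(mols, refs)
  fp <- fingerprint(c(mols, refs), "morgan_r2")
  manual <- c(
    tanimoto(fp[[1]], fp[[3]]),
    tanimoto(fp[[2]], fp[[3]])
  )
  expect_equal(d$similarities, manual)
  expect_equal(d$fraction_eq_1, 0.5)
  expect_equal(sum(d$histogram$count), 2)

  # molecules drawn from the reference set all sit at similarity one
  sub <- fixture_split()$patented$smiles[1:30]
  d2 <- max_similarity_distribution(sub, fixture_split()$patented$smiles[1:100])
  expect_true(all(d2$similarities == 1))
  expect_equal(d2$fraction_eq_1, 1)
  expect_error(max_similarity_distribution(sub, character()),
               class = "patgen_empty_reference_set")
})

test_that("QED distributions rank drug-like above reactive molecules", {
  drug_like <- c("CC(=O)Nc1ccc(O)cc1", "CC(C)Cc1ccc(C(C)C(=O)O)cc1",
                 "Cc1ccccc1NC(=O)c1ccccc1", "COc1ccc2cc(C(C)C(=O)O)ccc2c1")
  reactive <- c("ClC(Cl)(Cl)Cl", "OOCC(=O)Cl", "N=C=O", "BrCCCCBr")
  q1 <- qed_distribution(drug_like)
  q2 <- qed_distribution(reactive)
  expect_true(all(q1$values >= 0 & q1$values <= 1))
  expect_gt(q1$median, q2$median)
  doubled <- qed_distribution(c(drug_like, drug_like))
  expect_equal(doubled$histogram$count, 2 * q1$histogram$count)
})

test_that("chemical-space embedding is seeded and separates families", {
  pat <- fixture_split()$patented$smiles
  aromatic <- pat[grepl("c", pat, fixed = TRUE)][1:40]
  aliphatic <- pat[!grepl("c", pat, fixed = TRUE)][1:40]
  expect_false(anyNA(c(aromatic, aliphatic)))
  e1 <- embed_chemical_space(aromatic, aliphatic, seed = 19)
  e2 <- embed_chemical_space(aromatic, aliphatic, seed = 19)
  expect_equal(nrow(e1), 80)
  expect_identical(e1$x, e2$x)

  xy <- cbind(e1$x, e1$y)
  centroid_q <- colMeans(xy[e1$set == "query", ])
  centroid_r <- colMeans(xy[e1$set == "reference", ])
  intra <- mean(sqrt(rowSums((xy[e1$set == "query", ] -
                                matrix(centroid_q, 40, 2, byrow = TRUE))^2)))
  inter <- sqrt(sum((centroid_q - centroid_r)^2))
  expect_gt(inter, 0)
  expect_error(embed_chemical_space(aromatic[1:4], seed = 1),
               class = "patgen_too_few_molecules")
})

test_that("analog reports agree with the similarity machinery", {
  split <- fixture_split()
  db <- fixture_db()
  drug <- split$patented$smiles[5]
  log <- constructed_log(
    smiles = c(drug, split$novel$smiles[1:4]),
    valid = rep(TRUE, 5), passed = rep(TRUE, 5),
    keys = c(split$patented$inchikey_nostereo[5],
             split$novel$inchikey_nostereo[1:4])
  )
  rep <- find_analogs(log, drug, threshold = 0.5, db = db)
  expect_true(drug %in% rep$canonical_smiles)
  expect_equal(rep$similarity[rep$canonical_smiles == drug], 1.0)
  expect_true(rep$db_match[rep$canonical_smiles == drug])
  expect_true(all(rep$similarity >= 0.5))

  # cross-check each reported similarity against the distribution engine
  d <- max_similarity_distribution(rep$canonical_smiles, drug)
  expect_equal(rep$similarity, d$similarities)

  none <- find_analogs(log, drug, threshold = 1.01)
  expect_equal(nrow(none), 0L)
  expect_error(find_analogs(log, "not-a-molecule"),
               class = "patgen_invalid_query")
})
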