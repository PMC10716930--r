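test_that("patent rewards are the exact membership indicator and complement", {
  split <- fixture_split()
  db <- fixture_db()
  rp <- r_patent(db)
  rn <- r_not_patent(db)
  pat <- list(inchikey_nostereo = split$patented$inchikey_nostereo[1])
  nov <- list(inchikey_nostereo = split$novel$inchikey_nostereo[1])
  expect_equal(rp$evaluate(pat), 1)
  expect_equal(rp$evaluate(nov), 0)
  expect_equal(rn$evaluate(pat), 0)
  expect_equal(rn$evaluate(nov), 1)
})

test_that("the random reward is a seeded uniform stream on [0, 1)", {
  rr1 <- r_rand(7)
  rr2 <- r_rand(7)
  mol <- list(inchikey_nostereo = "ignored")
  d1 <- replicate(100, rr1$evaluate(mol))
  d2 <- replicate(100, rr2$evaluate(mol))
  expect_identical(d1, d2)
  big <- replicate(10000, rr1$evaluate(mol))
  expect_true(all(big >= 0 & big < 1))
  expect_lt(abs(mean(big) - 0.5), 0.01)
})

test_that("each generation filter trips on its intended target", {
  panel <- c(
    heavy = strrep("C", 40),                             # MW > 500 alkane
    seven_ring = "C1CCCCCC1",
    radical = "CC(C)(C)[CH2]",
    high_sa = "C1C2C3C1C1C2C31",                         # cubane-like cage
    blacklist = "CC(=O)Cl"
  )
  desc <- compute_descriptors(unname(panel))
  hits <- patgen:::chem_request_chunked(
    "match_smarts", unname(panel),
    extra = list(patterns = as.list(unname(default_substructure_blacklist())))
  )
  desc$blacklist_hit <- purrr::map_lgl(hits, ~ any(unlist(.x)))
  v <- apply_filters(desc)
  fail_matrix <- !as.matrix(v[, c("rare_pattern", "lipinski", "radical",
                                  "sa", "ring")])
  expected <- matrix(FALSE, 5, 5, dimnames = dimnames(fail_matrix))
  expected[1, "lipinski"] <- TRUE
  expected[2, "ring"] <- TRUE
  expected[3, "radical"] <- TRUE
  expected[4, "sa"] <- TRUE
  expected[5, "rare_pattern"] <- TRUE
  expect_identical(fail_matrix, expected)
  expect_equal(v$pass, rep(FALSE, 5))

  # disabling a filter reports NA and no longer gates the verdict
  v2 <- apply_filters(desc[2, ], filter_switches(ring = FALSE))
  expect_true(is.na(v2$ring))
  expect_true(v2$pass)
})

test_that("cyclohexane passes the physicochemical filters", {
  d <- compute_descriptors("C1CCCCC1")
  d$blacklist_hit <- FALSE
  v <- apply_filters(d)
  expect_true(all(unlist(v[, c("lipinski", "radical", "ring")])))
})

test_that("UCT selection follows the score formula with tie-breaks", {
  # exploitation only: pick the higher mean
  expect_equal(uct_select(c(9, 1), c(4.5, 0), 10, 0), 1L)
  # exploration-dominated: pick the rarely visited child
  expect_equal(uct_select(c(9, 1), c(4.5, 0), 10, 10), 2L)
  # unvisited children take priority
  expect_equal(uct_select(c(3, 0, 2), c(1, 0, 1), 5, 0.5), 2L)

  # brute-force score oracle over random trees
  set.seed(71)
  for (i in 1:1000) {
    n_children <- sample(2:8, 1)
    N <- sample(1:50, n_children, replace = TRUE)
    W <- runif(n_children) * N
    Np <- sum(N) + sample(0:5, 1)
    cc <- runif(1, 0, 2)
    oracle <- which.max(W / N + cc * sqrt(2 * log(Np) / N))
    expect_identical(uct_select(N, W, Np, cc), oracle)
  }
})

test_that("search on an enumerable toy language finds the rewarded string", {
  # language: strings over {A, B} of length <= 3; exhaustive enumeration
  # gives 14 terminal strings; reward 1 only on "BAB"
  lm <- toy_lm()
  terminals <- unlist(lapply(1:3, function(k) {
    apply(expand.grid(rep(list(c("A", "B")), k)), 1, paste, collapse = "")
  }))
  expect_length(unique(terminals), 14)
  target <- "BAB"
  reward <- reward_function("target", function(mol) {
    as.numeric(identical(mol$canonical_smiles, target))
  })
  cfg <- generation_config(c_explore = 0.5, max_iterations = 200, seed = 13)
  log <- mcts_generate(lm, reward, cfg, evaluator = toy_evaluator)
  expect_true(target %in% log$records$smiles)
  expect_equal(max(log$records$reward[log$records$smiles == target]), 1)
  # every other evaluated terminal earns 0, as exhaustive enumeration
  # dictates (empty completions are invalid and carry no reward)
  rec <- log$records
  others <- rec$reward[rec$passed & rec$smiles != target]
  expect_true(all(others == 0))
  expect_true(all(is.na(rec$reward[!rec$passed])))
})

test_that("zero budget yields an empty log and totals stay recomputable", {
  lm <- toy_lm()
  reward <- reward_function("zero", function(mol) 0)
  cfg <- generation_config(max_iterations = 0, seed = 1)
  log <- mcts_generate(lm, reward, cfg, evaluator = toy_evaluator)
  expect_equal(log$totals$n_all, 0L)
  expect_equal(nrow(log$records), 0L)

  cfg2 <- generation_config(max_iterations = 60, seed = 2)
  log2 <- mcts_generate(lm, reward, cfg2, evaluator = toy_evaluator)
  rec <- log2$records
  expect_equal(log2$totals$n_all, nrow(rec))
  expect_equal(log2$totals$n_valid, sum(rec$parse_valid & rec$passed))
  expect_equal(log2$totals$n_valid_unique,
               length(unique(rec$canonical_smiles[rec$parse_valid & rec$passed])))
})

test_that("rewards are only ever evaluated on filter-passing molecules", {
  lm <- fixture_lm()
  db <- fixture_db()
  cfg <- generation_config(c_explore = 0.4, max_iterations = 400, seed = 23)
  log <- mcts_generate(lm, r_patent(db), cfg)
  rec <- log$records
  expect_true(all(is.na(rec$reward[!rec$passed])))
  expect_true(all(!is.na(rec$reward[rec$passed])))
  expect_true(all(rec$passed[!is.na(rec$reward)]))
  # filter columns are NA exactly when parsing failed
  expect_true(all(is.na(rec$lipinski[!rec$parse_valid])))
  # rewards are the patent indicator on the fixture ground truth
  scored <- rec[rec$passed, ]
  truth <- scored$inchikey_nostereo %in%
    fixture_split()$patented$inchikey_nostereo
  expect_equal(scored$reward, as.numeric(truth))
})

test_that("generation logs round-trip through JSON-lines", {
  lm <- toy_lm()
  reward <- reward_function("zero", function(mol) 0.25)
  cfg <- generation_config(max_iterations = 40, seed = 4)
  log <- mcts_generate(lm, reward, cfg, evaluator = toy_evaluator)
  path <- file.path(fixture_dir(), "log.jsonl")
  write_generation_log(log, path)
  back <- read_generation_log(path)
  expect_equal(back$totals$n_all, log$totals$n_all)
  expect_equal(back$records$smiles, log$records$smiles)
  expect_equal(back$records$reward, log$records$reward)
})
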