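test_that("tokenization is lossless and keeps composite tokens whole", {
  toks <- tokenize_smiles("c1ccccc1Cl")
  expect_length(toks, 9)
  expect_equal(toks[9], "Cl")

  toks2 <- tokenize_smiles("C[NH3+]C")
  expect_length(toks2, 3)
  expect_equal(toks2[2], "[NH3+]")

  ring <- tokenize_smiles("C%12CC%12")
  expect_true("%12" %in% ring)

  for (s in fixture_corpus()[1:200]) {
    expect_identical(detokenize_smiles(tokenize_smiles(s)), s)
  }
  expect_error(tokenize_smiles("C?C"), class = "patgen_untokenizable")
})

test_that("vocabulary records every corpus token and the longest length", {
  corpus <- c("CCO", "c1ccccc1Cl", "C[NH3+]C")
  v <- build_vocabulary(corpus)
  expect_true(all(c("<pad>", "<s>", "</s>") %in% v$tokens))
  expect_false(anyDuplicated(v$tokens) > 0)
  expect_equal(v$max_len, 9 + 2)  # longest tokenization plus start/end
  for (s in corpus) {
    expect_silent(patgen:::encode_smiles(s, v))
  }
})

test_that("an overfit model reproduces its single training string greedily", {
  hp <- lm_hyperparams(dropout = 0, learning_rate = 0.01, batch_size = 16,
                       hidden_units = 24, epochs = 50,
                       validation_fraction = 0, embedding_dim = 8, seed = 3)
  target <- "c1ccc(Cl)cc1"
  lm <- train_lm(rep(target, 100), hp)
  expect_equal(sample_completion(lm, temperature = 0), target)
  expect_lt(glance(lm)$final_train_loss, 0.05)
})

test_that("training reduces loss and is reproducible under a fixed seed", {
  hp <- lm_hyperparams(dropout = 0.1, learning_rate = 0.003, batch_size = 64,
                       hidden_units = 32, epochs = 3,
                       validation_fraction = 0.1, embedding_dim = 16,
                       seed = 17)
  corpus <- fixture_corpus()[1:400]
  lm1 <- train_lm(corpus, hp)
  lm2 <- train_lm(corpus, hp)
  expect_equal(glance(lm1)$final_train_loss, glance(lm2)$final_train_loss)
  expect_identical(lm1$params$Why, lm2$params$Why)
  losses <- tidy(lm1)
  expect_true(all(is.finite(losses$train_loss)))
  expect_lt(losses$val_loss[3], losses$val_loss[1])
  expect_error(train_lm(corpus[1:50], hp), class = "patgen_corpus_too_small")
})

test_that("next-token distributions are normalized, pure, and end in pad", {
  lm <- fixture_lm()
  for (prefix in list(character(), "C", c("c", "1", "c", "c"))) {
    p <- next_token_distribution(lm, prefix)
    expect_equal(sum(p), 1, tolerance = 1e-6)
    expect_true(all(p >= 0))
    expect_identical(p, next_token_distribution(lm, prefix))
  }
  p_end <- next_token_distribution(lm, c("C", "C", "O", "</s>"))
  expect_equal(unname(p_end["<pad>"]), 1)
  long_prefix <- rep("C", lm$vocab$max_len)
  expect_error(next_token_distribution(lm, long_prefix),
               class = "patgen_prefix_too_long")
})

test_that("sampling is seeded-reproducible and greedy mode is deterministic", {
  lm <- fixture_lm()
  set.seed(31)
  s1 <- replicate(20, sample_completion(lm))
  set.seed(31)
  s2 <- replicate(20, sample_completion(lm))
  expect_identical(s1, s2)
  g1 <- sample_completion(lm, prefix = c("C", "C"), temperature = 0)
  g2 <- sample_completion(lm, prefix = c("C", "C"), temperature = 0)
  expect_identical(g1, g2)
  expect_true(startsWith(g1, "CC"))
})

test_that("checkpoints restore bit-identical next-token distributions", {
  lm <- fixture_lm()
  dir <- file.path(fixture_dir(), "lm_ckpt")
  save_lm(lm, dir)
  lm2 <- load_lm(dir)
  expect_identical(lm$vocab$tokens, lm2$vocab$tokens)
  for (prefix in list(character(), c("C", "("), c("c", "1"))) {
    expect_identical(next_token_distribution(lm, prefix),
                     next_token_distribution(lm2, prefix))
  }
  expect_equal(glance(lm2)$final_val_loss, glance(lm)$final_val_loss)
})

test_that("a model trained at fixture scale emits mostly valid SMILES", {
  # scaled quality floor: >= 50% syntactic validity over 500 samples
  lm <- fixture_lm()
  expect_lte(glance(lm)$final_val_loss, tidy(lm)$train_loss[1])
  set.seed(5)
  samples <- replicate(500, sample_completion(lm))
  ok <- nzchar(samples)
  validity <- mean(ok & parse_smiles(ifelse(ok, samples, "*invalid*"))$valid)
  expect_gte(validity, 0.5)
})
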