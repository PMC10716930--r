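# Shared fixtures, built once per test session and memoized.
#
# The default universe is the study condition for the fixture-scale
# checks: 5,000 enumerated molecules, 60/40 patented/novel split, seeded.

.fixture_env <- new.env(parent = emptyenv())

`%||%` <- function(x, y) if (is.null(x)) y else x

memo <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

fixture_universe <- function() {
  memo("universe", function() make_universe(fixture_spec(n_target = 5000)))
}

fixture_split <- function() {
  memo("split", function() {
    split_universe(fixture_universe(), frac_patented = 0.6, seed = 42)
  })
}

fixture_db <- function() {
  memo("db", function() {
    split <- fixture_split()
    db_path <- file.path(fixture_dir(), "fixture_db.sqlite")
    tabs <- write_fixture_tables(split, fixture_dir())
    build_db(read_compound_table(tabs["compounds"]),
             read_compound_table(tabs["patents"]),
             path = db_path)
  })
}

fixture_dir <- function() {
  memo("dir", function() {
    d <- file.path(tempdir(), "patgen-fixtures")
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
    d
  })
}

fixture_corpus <- function() {
  memo("corpus", function() make_corpus(fixture_split()$patented, 2000, seed = 1))
}

# language model trained under the scaled study conditions: 30 epochs on
# the 2,000-molecule fixture corpus
fixture_lm <- function() {
  memo("lm", function() {
    train_lm(fixture_corpus(), fixture_lm_hyperparams())
  })
}

fixture_lm_hyperparams <- function() {
  lm_hyperparams(
    dropout = 0.1, learning_rate = 0.003, batch_size = 64,
    hidden_units = 64, epochs = 30, validation_fraction = 0.1,
    embedding_dim = 32, seed = 11
  )
}

# StandardMolecule view of universe records (keys precomputed at build)
as_std <- function(records) {
  tibble::tibble(
    query_id = records$source_id,
    canonical_smiles = records$smiles,
    inchikey_nostereo = records$inchikey_nostereo
  )
}

# a tiny deterministic token language over {A, B} used for search tests:
# vocabulary A/B with terminal strings of length <= 3
toy_lm <- function(p_end = 0.25) {
  vocab <- structure(
    list(tokens = c("<pad>", "<s>", "</s>", "A", "B"),
         start_symbol = "<s>", end_symbol = "</s>", pad_symbol = "<pad>",
         max_len = 5L),
    class = "token_vocabulary"
  )
  structure(list(vocab = vocab, p_end = p_end), class = "toy_lm")
}

next_token_distribution.toy_lm <- function(lm, prefix) {
  v <- lm$vocab
  p <- setNames(numeric(length(v$tokens)), v$tokens)
  if (length(prefix) > 0 && prefix[length(prefix)] == v$end_symbol) {
    p[v$pad_symbol] <- 1
    return(p)
  }
  if (length(prefix) >= v$max_len - 2L) {
    p[v$end_symbol] <- 1
    return(p)
  }
  p[c("A", "B")] <- (1 - lm$p_end) / 2
  p[v$end_symbol] <- lm$p_end
  p
}

sample_completion.toy_lm <- function(lm, prefix = character(),
                                     temperature = 1.0) {
  v <- lm$vocab
  toks <- prefix
  repeat {
    p <- next_token_distribution(lm, toks)
    p <- p[!names(p) %in% c(v$pad_symbol, v$start_symbol)]
    tok <- sample(names(p), 1, prob = p)
    if (tok == v$end_symbol) break
    toks <- c(toks, tok)
    if (length(toks) >= v$max_len - 2L) break
  }
  paste(toks, collapse = "")
}

# evaluator for toy token strings: everything is "valid" and passes the
# filters; identity is the string itself
toy_evaluator <- function(smiles) {
  list(parse_valid = TRUE, canonical_smiles = smiles,
       inchikey_nostereo = smiles, mol_weight = 100, slogp = 1, hbd = 0,
       hba = 0, n_radical_electrons = 0, sa_score = 1, max_ring_size = 6,
       blacklist_hit = FALSE)
}

# register S3 methods for the toy class inside the test session
registerS3method("next_token_distribution", "toy_lm",
                 next_token_distribution.toy_lm,
                 envir = asNamespace("patgen"))
registerS3method("sample_completion", "toy_lm", sample_completion.toy_lm,
                 envir = asNamespace("patgen"))
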