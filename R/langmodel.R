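#' Language-model hyperparameters
#'
#' Defaults are the optimized values used for the full-scale patent
#' language model: dropout 0.1077, learning rate 0.000434, batch size 384,
#' 896 hidden units, 500 epochs with 10 percent of the data held out for
#' validation. Tests and desk-scale runs pass smaller values.
#'
#' @param dropout Dropout rate between stacked recurrent layers.
#' @param learning_rate Adam step size.
#' @param batch_size Sequences per gradient step.
#' @param hidden_units Hidden state dimension of each recurrent layer.
#' @param epochs Training epochs.
#' @param validation_fraction Fraction of sequences held out for validation.
#' @param embedding_dim Token embedding dimension.
#' @param n_layers Number of stacked recurrent layers.
#' @param seed Integer seed controlling init, shuffling and dropout.
#' @return A list of class `lm_hyperparams`.
#' @export
lm_hyperparams <- function(dropout = 0.1077, learning_rate = 0.000434,
                           batch_size = 384L, hidden_units = 896L,
                           epochs = 500L, validation_fraction = 0.1,
                           embedding_dim = 64L, n_layers = 2L, seed = 1L) {
  stopifnot(dropout >= 0, dropout < 1, batch_size >= 1, epochs >= 1,
            validation_fraction >= 0, validation_fraction < 1,
            hidden_units >= 1, n_layers >= 1, learning_rate > 0)
  structure(
    list(
      dropout = dropout, learning_rate = learning_rate,
      batch_size = as.integer(batch_size),
      hidden_units = as.integer(hidden_units),
      epochs = as.integer(epochs),
      validation_fraction = validation_fraction,
      embedding_dim = as.integer(embedding_dim),
      n_layers = as.integer(n_layers), seed = as.integer(seed)
    ),
    class = "lm_hyperparams"
  )
}

#' Train the SMILES language model
#'
#' Fits a gated-recurrent-unit next-token model (embedding, stacked GRU
#' layers, softmax head; Adam optimizer) on start-prefixed, end-terminated,
#' pad-filled token sequences. The held-out fraction is split off after a
#' seeded shuffle and scored once per epoch.
#'
#' @param corpus Character vector of SMILES strings, or path to a SMILES
#'   line file.
#' @param hp Hyperparameters from [lm_hyperparams()].
#' @param vocab Optional pre-built [build_vocabulary()] object; by default
#'   built from `corpus`.
#' @return An object of class `patent_lm`: list with `vocab`, `params`
#'   (weights), `losses` (per-epoch train/validation), `hp`,
#'   `corpus_fingerprint`.
#' @export
train_lm <- function(corpus, hp = lm_hyperparams(), vocab = NULL) {
  if (length(corpus) == 1 && file.exists(corpus)) {
    corpus <- read_smiles_file(corpus)
  }
  if (length(corpus) < 100) {
    rlang::abort("corpus must contain at least 100 sequences",
                 class = "patgen_corpus_too_small")
  }
  vocab <- vocab %||% build_vocabulary(corpus)
  seqs <- lapply(corpus, encode_smiles, vocab = vocab)
  pad_id <- encode_tokens(vocab$pad_symbol, vocab)
  set.seed(hp$seed)
  params <- cpp_gru_new(length(vocab$tokens), hp$embedding_dim,
                        hp$hidden_units, hp$n_layers)
  fit <- cpp_gru_train(
    params, seqs, pad_id,
    epochs = hp$epochs, batch_size = hp$batch_size,
    lr = hp$learning_rate, dropout = hp$dropout,
    val_frac = hp$validation_fraction
  )
  structure(
    list(
      vocab = vocab,
      params = fit$params,
      losses = tibble::tibble(
        epoch = seq_len(hp$epochs),
        train_loss = as.numeric(fit$train_loss),
        val_loss = as.numeric(fit$val_loss)
      ),
      hp = hp,
      corpus_fingerprint = corpus_fingerprint(corpus)
    ),
    class = "patent_lm"
  )
}

# cheap content fingerprint without extra dependencies: length + a
# polynomial hash of the concatenated corpus
corpus_fingerprint <- function(corpus) {
  codes <- utf8ToInt(paste(corpus, collapse = "\n"))
  h <- 0
  for (chunk in split(codes, ceiling(seq_along(codes) / 4096))) {
    h <- (h * 31 + sum(chunk * seq_along(chunk))) %% 2147483647
  }
  sprintf("n%d-h%d", length(corpus), as.integer(h))
}

#' @export
print.patent_lm <- function(x, ...) {
  cat("<patent_lm> vocab ", length(x$vocab$tokens), " tokens, ",
      x$hp$n_layers, "x", x$hp$hidden_units, " GRU, ",
      nrow(x$losses), " epochs (final train loss ",
      signif(x$losses$train_loss[nrow(x$losses)], 4), ")\n", sep = "")
  invisible(x)
}

#' @rdname train_lm
#' @param x A `patent_lm` object.
#' @param ... Unused.
#' @export
tidy.patent_lm <- function(x, ...) x$losses

#' @rdname train_lm
#' @export
glance.patent_lm <- function(x, ...) {
  n <- nrow(x$losses)
  tibble::tibble(
    n_tokens = length(x$vocab$tokens),
    max_len = x$vocab$max_len,
    hidden_units = x$hp$hidden_units,
    n_layers = x$hp$n_layers,
    epochs = n,
    final_train_loss = x$losses$train_loss[n],
    final_val_loss = x$losses$val_loss[n]
  )
}

lm_handle <- function(lm) {
  h <- attr(lm, "handle", exact = TRUE)
  if (is.null(h)) h <- cpp_gru_handle(lm$params)
  h
}

# attach a cached inference handle (used by generation loops)
lm_with_handle <- function(lm) {
  attr(lm, "handle") <- cpp_gru_handle(lm$params)
  lm
}

#' Next-token distribution of the language model
#'
#' @param lm A fitted model ([train_lm()]) or other object with a
#'   `next_token_distribution` method.
#' @param prefix Character vector of tokens already emitted (without the
#'   start symbol).
#' @return Named numeric probability vector over the vocabulary, summing
#'   to one. After the end symbol the distribution is a point mass on the
#'   pad symbol.
#' @export
next_token_distribution <- function(lm, prefix) {
  UseMethod("next_token_distribution")
}

#' @export
next_token_distribution.patent_lm <- function(lm, prefix) {
  vocab <- lm$vocab
  if (length(prefix) + 2L > vocab$max_len) {
    rlang::abort("prefix longer than the model maximum length",
                 class = "patgen_prefix_too_long")
  }
  if (length(prefix) > 0 && prefix[length(prefix)] == vocab$end_symbol) {
    p <- setNames(numeric(length(vocab$tokens)), vocab$tokens)
    p[vocab$pad_symbol] <- 1
    return(p)
  }
  ids <- encode_tokens(c(vocab$start_symbol, prefix), vocab)
  p <- cpp_gru_probs(lm_handle(lm), ids)
  setNames(as.numeric(p), vocab$tokens)
}

#' Sample a SMILES completion from the language model
#'
#' Extends the prefix token-by-token (multinomial sampling at the given
#' temperature, greedy for `temperature = 0`) until the end symbol or the
#' model's maximum length, then detokenizes. The result is not guaranteed
#' to be chemically valid; validity is checked downstream.
#'
#' @inheritParams next_token_distribution
#' @param prefix Character vector of tokens already emitted.
#' @param temperature Sampling temperature; `0` means greedy decoding.
#' @return A single SMILES string (prefix plus completion).
#' @export
sample_completion <- function(lm, prefix = character(), temperature = 1.0) {
  UseMethod("sample_completion")
}

#' @export
sample_completion.patent_lm <- function(lm, prefix = character(),
                                        temperature = 1.0) {
  vocab <- lm$vocab
  ids <- encode_tokens(c(vocab$start_symbol, prefix), vocab)
  end_id <- encode_tokens(vocab$end_symbol, vocab)
  max_new <- vocab$max_len - length(ids)
  if (max_new <= 0) return(detokenize_smiles(prefix))
  new_ids <- cpp_gru_sample(lm_handle(lm), ids, max_new, temperature, end_id)
  paste0(detokenize_smiles(prefix), decode_ids(new_ids, vocab))
}

#' Save / load a trained language model checkpoint
#'
#' A checkpoint is a directory holding the weights plus a JSON metadata
#' file (vocabulary, hyperparameters, corpus fingerprint, losses); loading
#' restores a model whose next-token distributions are bit-identical.
#'
#' @param lm A `patent_lm` object.
#' @param path Checkpoint directory.
#' @return `save_lm` returns `path` invisibly; `load_lm` returns the model.
#' @export
save_lm <- function(lm, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  saveRDS(lm$params, file.path(path, "weights.rds"))
  meta <- list(
    vocab = unclass(lm$vocab),
    hp = unclass(lm$hp),
    losses = lm$losses,
    corpus_fingerprint = lm$corpus_fingerprint
  )
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_lm
#' @export
load_lm <- function(path) {
  meta <- jsonlite::fromJSON(file.path(path, "metadata.json"),
                             simplifyVector = TRUE)
  vocab <- structure(
    list(
      tokens = meta$vocab$tokens,
      start_symbol = meta$vocab$start_symbol,
      end_symbol = meta$vocab$end_symbol,
      pad_symbol = meta$vocab$pad_symbol,
      max_len = as.integer(meta$vocab$max_len)
    ),
    class = "token_vocabulary"
  )
  structure(
    list(
      vocab = vocab,
      params = readRDS(file.path(path, "weights.rds")),
      losses = tibble::as_tibble(meta$losses),
      hp = structure(as.list(meta$hp), class = "lm_hyperparams"),
      corpus_fingerprint = meta$corpus_fingerprint
    ),
    class = "patent_lm"
  )
}

#' Read / write SMILES line files
#'
#' One SMILES per line, optional tab-separated second column with an
#' identifier.
#'
#' @param path File path.
#' @return `read_smiles_file`: character vector (ids, when present, as
#'   names); `write_smiles_file`: `path` invisibly.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- stringr::str_split_fixed(lines, "\t", 2)
  out <- parts[, 1]
  if (any(nzchar(parts[, 2]))) names(out) <- parts[, 2]
  out
}

#' @rdname read_smiles_file
#' @param smiles Character vector of SMILES (names, if set, written as a
#'   second column).
#' @export
write_smiles_file <- function(smiles, path) {
  lines <- if (is.null(names(smiles))) smiles else
    paste(smiles, names(smiles), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
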