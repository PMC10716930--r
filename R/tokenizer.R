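# SMILES tokenization.
#
# Tokens are: bracket atoms as single tokens ("[NH3+]"), the two-letter
# organic-subset symbols Cl and Br, two-digit ring closures "%nn", and all
# remaining single characters (atoms, bonds, branch parens, ring digits).
# The scheme is lossless: paste(tokens) reproduces the input string.

SMILES_TOKEN_REGEX <- "\\[[^\\]]*\\]|Br|Cl|%[0-9]{2}|."

SMILES_SINGLE_CHARS <- c(
  "B", "C", "N", "O", "S", "P", "F", "I",
  "b", "c", "n", "o", "s", "p",
  as.character(0:9), "%",
  "(", ")", "=", "#", "-", "+", "/", "\\", ".", ":", "@", "*", "~", "$"
)

#' Tokenize SMILES strings
#'
#' Splits a SMILES string into the token alphabet used by the language
#' model. Multi-character element symbols (`Cl`, `Br`), bracket atoms and
#' two-digit ring closures are single tokens; the split is lossless.
#'
#' @param s A single SMILES string.
#' @return Character vector of tokens.
#' @examples
#' \dontrun{
#' tokenize_smiles("c1ccccc1Cl")
#' }
#' @export
tokenize_smiles <- function(s) {
  stopifnot(is.character(s), length(s) == 1, nzchar(s))
  toks <- stringr::str_extract_all(s, SMILES_TOKEN_REGEX)[[1]]
  bad <- !grepl("^\\[", toks) & nchar(toks) == 1 &
    !toks %in% c(SMILES_SINGLE_CHARS, LETTERS, letters)
  if (any(bad)) {
    rlang::abort(
      paste0("untokenizable character(s): ", paste(unique(toks[bad]), collapse = " ")),
      class = "patgen_untokenizable"
    )
  }
  if (paste(toks, collapse = "") != s) {
    rlang::abort("tokenization is not lossless for this string",
                 class = "patgen_untokenizable")
  }
  toks
}

#' Reassemble tokens into a SMILES string
#' @param tokens Character vector of tokens.
#' @return A single string.
#' @export
detokenize_smiles <- function(tokens) paste(tokens, collapse = "")

#' Build a token vocabulary from a SMILES corpus
#'
#' Collects all tokens occurring in the corpus, adds the start/end/pad
#' control symbols, and records the maximum tokenized sequence length
#' (which becomes the padding length of the language model).
#'
#' @param corpus Character vector of SMILES strings.
#' @return An object of class `token_vocabulary`: list with `tokens`
#'   (ordered, controls first), `start_symbol`, `end_symbol`, `pad_symbol`,
#'   `max_len` (longest corpus sequence including start and end tokens).
#' @export
build_vocabulary <- function(corpus) {
  stopifnot(length(corpus) > 0)
  tok_lists <- lapply(corpus, tokenize_smiles)
  toks <- sort(unique(unlist(tok_lists)))
  controls <- c("<pad>", "<s>", "</s>")
  vocab <- structure(
    list(
      tokens = c(controls, toks),
      start_symbol = "<s>",
      end_symbol = "</s>",
      pad_symbol = "<pad>",
      max_len = max(lengths(tok_lists)) + 2L
    ),
    class = "token_vocabulary"
  )
  vocab
}

#' @export
print.token_vocabulary <- function(x, ...) {
  cat("<token_vocabulary> ", length(x$tokens), " tokens, max_len ",
      x$max_len, "\n", sep = "")
  invisible(x)
}

# token character vector -> 0-based integer ids (for the C++ model)
encode_tokens <- function(tokens, vocab) {
  ids <- match(tokens, vocab$tokens) - 1L
  if (anyNA(ids)) {
    rlang::abort(
      paste0("token(s) outside vocabulary: ",
             paste(unique(tokens[is.na(ids)]), collapse = " ")),
      class = "patgen_untokenizable"
    )
  }
  ids
}

# SMILES -> [start, tokens..., end] as 0-based ids
encode_smiles <- function(s, vocab) {
  encode_tokens(c(vocab$start_symbol, tokenize_smiles(s), vocab$end_symbol),
                vocab)
}

decode_ids <- function(ids, vocab) {
  toks <- vocab$tokens[ids + 1L]
  toks <- toks[!toks %in% c(vocab$start_symbol, vocab$end_symbol, vocab$pad_symbol)]
  detokenize_smiles(toks)
}
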