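# SMILES tokenization and vocabulary handling.

# Ordered by priority: bracket atoms, two-letter halogens, ring-closure
# %nn, then single-character symbols. Atom-denoting alternatives come first
# so the atom mask can be decided from the matched lexeme alone.
.smiles_token_re <- paste0(
  "(\\[[^\\]]+\\])|",           # bracketed atom, e.g. [nH], [O-], [N+]
  "(Cl|Br)|",                   # two-letter organic-subset elements
  "(%[0-9]{2})|",               # two-digit ring closure
  "([BCNOSPFIbcnops])|",        # one-letter elements (aromatic lowercase)
  "([0-9])|",                   # ring closure digit
  "([=#$:/\\\\.()+-])"          # bonds, branches, disconnection
)

.atom_token_re <- "^(\\[[^\\]]+\\]|Cl|Br|[BCNOSPFIbcnops])$"

tokenize_one <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      nchar(smiles) == 0L) {
    stop("`smiles` must be a single non-empty string")
  }
  m <- gregexpr(.smiles_token_re, smiles, perl = TRUE)[[1]]
  tokens <- regmatches(smiles, list(m))[[1]]
  # the matches must tile the input; the first gap is the offending position
  covered <- paste0(tokens, collapse = "")
  if (!identical(covered, smiles)) {
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    pos <- 1L
    for (k in seq_along(starts)) {
      if (starts[k] != pos) break
      pos <- pos + lens[k]
    }
    stop(sprintf("cannot tokenize SMILES '%s': unrecognized character '%s' at position %d",
                 smiles, substr(smiles, pos, pos), pos))
  }
  list(tokens = tokens,
       atom_mask = grepl(.atom_token_re, tokens, perl = TRUE))
}

#' Tokenize SMILES strings
#'
#' Splits each SMILES string into chemically meaningful tokens: bracketed
#' atoms (`[nH]`, `[O-]`) and the two-letter elements `Cl`/`Br` are single
#' tokens, as are ring-closure labels (`1`, `%12`) and bond/branch symbols.
#' Concatenating the tokens of a molecule reproduces its input string exactly.
#'
#' @param smiles character vector of SMILES strings.
#' @return A tibble with one row per token: `smiles_id` (index into the
#'   input), `position`, `token`, and `is_atom` (`TRUE` where the token
#'   denotes an atom, in left-to-right order matching the atom order of
#'   [smiles_to_graph()]).
#' @examples
#' smiles_tokenize(c("CCO", "c1ccccc1", "CC(=O)[O-]"))
#' @export
smiles_tokenize <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  out <- lapply(seq_along(smiles), function(i) {
    tk <- tokenize_one(smiles[[i]])
    tibble::tibble(smiles_id = i,
                   position = seq_along(tk$tokens),
                   token = tk$tokens,
                   is_atom = tk$atom_mask)
  })
  dplyr::bind_rows(out)
}

#' Build a token vocabulary from a corpus
#'
#' Ids are dense from 0, with `PAD = 0` and `UNK = 1` reserved; corpus tokens
#' follow in sorted order so the mapping is reproducible.
#'
#' @param corpus character vector of SMILES strings (non-empty).
#' @return An object of class `smiles_vocab`: a named integer vector mapping
#'   token to id, with attributes `pad_id` and `unk_id`.
#' @export
build_vocab <- function(corpus) {
  if (length(corpus) == 0L) stop("corpus is empty; cannot build a vocabulary")
  toks <- unique(unlist(lapply(corpus, function(s) tokenize_one(s)$tokens)))
  toks <- sort(toks)
  ids <- c(0L, 1L, seq_along(toks) + 1L)
  names(ids) <- c("<pad>", "<unk>", toks)
  structure(ids, pad_id = 0L, unk_id = 1L, class = "smiles_vocab")
}

#' @export
print.smiles_vocab <- function(x, ...) {
  cat("<smiles_vocab> ", length(x), " tokens (incl. <pad>, <unk>)\n", sep = "")
  invisible(x)
}

#' Encode tokens as integer ids
#'
#' Tokens absent from the vocabulary map to the UNK id.
#'
#' @param tokens character vector of tokens (from [smiles_tokenize()]).
#' @param vocab a `smiles_vocab`.
#' @return Integer vector of ids.
#' @export
encode_tokens <- function(tokens, vocab) {
  stopifnot(inherits(vocab, "smiles_vocab"))
  ids <- unname(vocab[tokens])
  ids[is.na(ids)] <- attr(vocab, "unk_id")
  as.integer(ids)
}

# tokenize + encode one molecule into the list form the encoders consume
encode_smiles <- function(smiles, vocab, max_len = 256L) {
  tk <- tokenize_one(smiles)
  if (length(tk$tokens) > max_len) {
    stop(sprintf("SMILES has %d tokens, exceeding max_len = %d (refusing to truncate)",
                 length(tk$tokens), max_len))
  }
  list(tokens = tk$tokens,
       token_ids = encode_tokens(tk$tokens, vocab),
       atom_mask = tk$atom_mask,
       length = length(tk$tokens))
}
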