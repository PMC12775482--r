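#' Token scheme for peptide sequence models
#'
#' Fixes the integer vocabulary used by the sequence models. The PAD token is
#' index 0 and the 20 canonical residues occupy indices 1 to 20 in
#' alphabetical one-letter order ([AA_ALPHABET]). Special tokens follow the
#' residues: the predictor (regression) scheme adds a `CLS` token whose
#' contextual representation is pooled for the regression head; the generator
#' scheme adds `START` and `STOP` tokens that bracket each sequence.
#'
#' @param mode `"predictor"` or `"generator"`.
#' @param max_length Maximum peptide length the scheme pads to (residues,
#'   excluding special tokens). Default 10, the substrate register length.
#' @return An object of class `token_scheme`: a list with `mode`, `vocab`
#'   (named integer vector, 0-based indices), `max_length` and the special
#'   token indices.
#' @export
#' @examples
#' sc <- token_scheme("generator")
#' tokenize("AAA", sc)
token_scheme <- function(mode = c("predictor", "generator"), max_length = 10L) {
  mode <- match.arg(mode)
  vocab <- c(PAD = 0L, setNames(seq_along(AA_ALPHABET), AA_ALPHABET))
  if (mode == "predictor") {
    vocab <- c(vocab, CLS = 21L)
  } else {
    vocab <- c(vocab, START = 21L, STOP = 22L)
  }
  structure(
    list(mode = mode, vocab = vocab, max_length = as.integer(max_length),
         n_tokens = length(vocab)),
    class = "token_scheme"
  )
}

validate_peptides <- function(sequences) {
  sequences <- toupper(sequences)
  bad <- !grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"), sequences)
  if (any(bad)) {
    s <- sequences[which(bad)[1]]
    chars <- strsplit(s, "")[[1]]
    pos <- which(!chars %in% AA_ALPHABET)[1]
    stop(sprintf("invalid residue '%s' at position %d of sequence '%s'",
                 chars[pos], pos, s), call. = FALSE)
  }
  sequences
}

#' Tokenize peptides
#'
#' Maps a peptide to its integer token sequence under a [token_scheme()]. In
#' predictor mode the `CLS` token is prepended; in generator mode the sequence
#' is wrapped in `START`/`STOP`. With `pad = TRUE`, sequences are right-padded
#' with `PAD` (index 0) up to the scheme's maximum length.
#'
#' @param sequences Character vector of peptides (uppercased before
#'   validation).
#' @param scheme A [token_scheme()].
#' @param pad Pad to the scheme's maximum length?
#' @return A list of integer vectors (0-based token indices), one per peptide.
#' @export
tokenize <- function(sequences, scheme, pad = FALSE) {
  stopifnot(inherits(scheme, "token_scheme"))
  sequences <- validate_peptides(sequences)
  v <- scheme$vocab
  lapply(sequences, function(s) {
    idx <- unname(v[strsplit(s, "")[[1]]])
    tok <- if (scheme$mode == "predictor") {
      c(v[["CLS"]], idx)
    } else {
      c(v[["START"]], idx, v[["STOP"]])
    }
    if (pad) {
      full <- scheme$max_length + if (scheme$mode == "predictor") 1L else 2L
      tok <- c(tok, rep(v[["PAD"]], max(0L, full - length(tok))))
    }
    as.integer(tok)
  })
}

#' Invert tokenization
#'
#' Drops special and PAD tokens and maps residue indices back to one-letter
#' codes; `detokenize(tokenize(x, sc), sc)` is the identity on valid peptides.
#'
#' @param tokens A list of integer token vectors (or a single vector).
#' @param scheme The [token_scheme()] used to produce them.
#' @return Character vector of peptides.
#' @export
detokenize <- function(tokens, scheme) {
  stopifnot(inherits(scheme, "token_scheme"))
  if (!is.list(tokens)) tokens <- list(tokens)
  vapply(tokens, function(tok) {
    res <- tok[tok >= 1 & tok <= 20]
    paste(AA_ALPHABET[res], collapse = "")
  }, character(1))
}

# Stack tokenized peptides into the (matrix, lengths) form the C++ models
# consume; rows padded with 0.
token_matrix <- function(sequences, scheme) {
  toks <- tokenize(sequences, scheme, pad = FALSE)
  lens <- lengths(toks)
  m <- matrix(0L, nrow = length(toks), ncol = max(lens))
  for (i in seq_along(toks)) m[i, seq_len(lens[i])] <- toks[[i]]
  list(tokens = m, lengths = as.integer(lens))
}
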