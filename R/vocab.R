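#' Token vocabulary for protein sequences
#'
#' The model vocabulary covers the 20 standard amino acids plus five special
#' tokens: `<pad>` (alignment gap / padding), `<cls>`, `<eos>`, `<unk>`
#' (non-standard residue) and `<mask>` (masked-LM corruption), for a total of
#' 25 symbols. All logit and counting matrices in the package have one column
#' per vocabulary token, in this order.
#'
#' @return Character vector of length 25, the ordered token symbols.
#' @export
#' @examples
#' v <- token_vocabulary()
#' length(v)  # 25
token_vocabulary <- function() {
  c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
    "<pad>", "<cls>", "<eos>", "<unk>", "<mask>")
}

#' @rdname token_vocabulary
#' @export
vocab_size <- function() length(token_vocabulary())

STANDARD_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
PAD_TOKEN <- "<pad>"
UNK_TOKEN <- "<unk>"
MASK_TOKEN <- "<mask>"

# residues with no standard one-letter vocabulary entry; observed residues,
# mapped to <unk> rather than <pad> (they are not gaps)
NONSTANDARD_AA <- c("B", "Z", "J", "O", "U", "X")

token_to_id <- function(tokens, vocab = token_vocabulary()) {
  ids <- match(tokens, vocab)
  if (anyNA(ids)) {
    stop("unknown token(s): ", paste(unique(tokens[is.na(ids)]), collapse = ", "))
  }
  ids
}

#' Tokenize an amino-acid sequence
#'
#' Maps a sequence string to integer token ids and a one-hot matrix over the
#' 25-token vocabulary. Non-standard residue letters (B, Z, J, O, U, X) map to
#' `<unk>`; any other unrecognized character also maps to `<unk>`.
#'
#' @param seq Character scalar, the amino-acid sequence.
#' @param vocab Token vocabulary (default [token_vocabulary()]).
#' @return List with `ids` (integer vector, length L), `tokens` (character)
#'   and `one_hot` (L x 25 matrix with exactly one 1 per row).
#' @export
#' @examples
#' tokenize_sequence("ACD")$ids
tokenize_sequence <- function(seq, vocab = token_vocabulary()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) stop("empty sequence")
  chars <- toupper(strsplit(seq, "")[[1]])
  tokens <- ifelse(chars %in% STANDARD_AA, chars, UNK_TOKEN)
  ids <- token_to_id(tokens, vocab)
  oh <- matrix(0L, nrow = length(ids), ncol = length(vocab),
               dimnames = list(NULL, vocab))
  oh[cbind(seq_along(ids), ids)] <- 1L
  list(ids = ids, tokens = tokens, one_hot = oh)
}

# Normalize one alignment row (character vector of single characters) to
# vocabulary tokens: uppercase, gap-like characters -> pad, non-standard
# residues -> unk. Idempotent on token vectors already in the vocabulary.
normalize_alignment_chars <- function(chars, pad_token = PAD_TOKEN) {
  vocab <- token_vocabulary()
  out <- ifelse(nchar(chars) == 1L, toupper(chars), chars)
  keep <- out %in% c(STANDARD_AA, vocab[21:25])
  nonstd <- out %in% NONSTANDARD_AA
  out[nonstd] <- UNK_TOKEN
  out[!keep & !nonstd] <- pad_token
  out
}
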