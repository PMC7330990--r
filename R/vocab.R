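#' The 20 canonical amino acids
#'
#' Single-letter codes in alphabetical order. Ambiguous residues
#' (B, J, O, U, X, Z) are deliberately excluded: records containing them are
#' rejected rather than wildcarded, since silent substitution would corrupt
#' an affinity regression.
#'
#' @return Character vector of length 20.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Amino-acid token vocabulary
#'
#' Builds the token vocabulary used by the sequence models: the 20 canonical
#' amino acids plus a padding token `<pad>` (reserved index 1) and a
#' beginning-of-sequence token `<bos>` (index 2), for a total size of 22.
#' The learned embedding layer indexes into this space.
#'
#' @return An object of class `pep_vocab`: a list with `tokens` (ordered
#'   character vector), `pad` and `bos` (their integer indices), and `size`.
#' @examples
#' v <- aa_vocabulary()
#' v$size              # 22
#' v$tokens[v$pad]     # "<pad>"
#' @export
aa_vocabulary <- function() {
  tokens <- c("<pad>", "<bos>", amino_acids())
  structure(
    list(
      tokens = tokens,
      index = stats::setNames(seq_along(tokens), tokens),
      pad = 1L,
      bos = 2L,
      size = length(tokens)
    ),
    class = "pep_vocab"
  )
}

#' @export
print.pep_vocab <- function(x, ...) {
  cat("<pep_vocab> size", x$size, "\n")
  cat("  tokens:", paste(x$tokens, collapse = " "), "\n")
  invisible(x)
}

assert_valid_peptide <- function(peptide) {
  if (!is.character(peptide) || length(peptide) != 1L || is.na(peptide) ||
      nchar(peptide) == 0L) {
    stop("peptide must be a single non-empty string", call. = FALSE)
  }
  chars <- strsplit(peptide, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% amino_acids())
  if (length(bad) > 0L) {
    stop(sprintf(
      "invalid character '%s' at position %d in peptide '%s'",
      chars[bad[1]], bad[1], peptide
    ), call. = FALSE)
  }
  invisible(chars)
}

#' Tokenize a peptide
#'
#' Maps a peptide string to a sequence of integer token indices, prepending a
#' single `<bos>` token so the recurrence has a defined start state. No
#' end-of-sequence token is appended: the hidden state at the final residue
#' feeds the pooling layer directly. Peptides are read N-terminus to
#' C-terminus (left to right).
#'
#' @param peptide A single peptide string over the 20-letter amino-acid
#'   alphabet (uppercase).
#' @param vocab A vocabulary from [aa_vocabulary()].
#' @return An object of class `pep_encoded`: a list with `indices` (integer
#'   vector, `<bos>` first) and `length` (`nchar(peptide) + 1`).
#' @examples
#' enc <- tokenize("ACD")
#' enc$length  # 4
#' detokenize(enc)  # "ACD"
#' @seealso [detokenize()], [pad_batch()]
#' @export
tokenize <- function(peptide, vocab = aa_vocabulary()) {
  chars <- assert_valid_peptide(peptide)
  idx <- c(vocab$bos, unname(vocab$index[chars]))
  structure(list(indices = idx, length = length(idx)), class = "pep_encoded")
}

#' Invert tokenization
#'
#' Reconstructs the peptide string from an encoded peptide, dropping the
#' `<bos>` sentinel and any `<pad>` positions. `detokenize(tokenize(p))`
#' is the identity on valid peptides.
#'
#' @param encoded A `pep_encoded` object or a bare integer index vector.
#' @inheritParams tokenize
#' @return A peptide string.
#' @export
detokenize <- function(encoded, vocab = aa_vocabulary()) {
  idx <- if (inherits(encoded, "pep_encoded")) encoded$indices else as.integer(encoded)
  idx <- idx[idx != vocab$pad & idx != vocab$bos]
  paste(vocab$tokens[idx], collapse = "")
}

#' Pad a set of encoded peptides into a rectangular batch
#'
#' Stacks encoded peptides into an n-by-max-length integer matrix padded on
#' the right with the `<pad>` index, carrying the true (non-pad) lengths
#' alongside. Downstream pooling reads only the first `lengths[i]` positions
#' of row i, so pad positions can never leak into model outputs.
#'
#' @param encoded A non-empty list of `pep_encoded` objects (see
#'   [tokenize()]).
#' @inheritParams tokenize
#' @return A list of class `pep_batch` with `indices` (integer matrix) and
#'   `lengths` (integer vector).
#' @export
pad_batch <- function(encoded, vocab = aa_vocabulary()) {
  if (!is.list(encoded) || length(encoded) == 0L) {
    stop("pad_batch() requires a non-empty list of encoded peptides", call. = FALSE)
  }
  lens <- vapply(encoded, function(e) e$length, integer(1))
  width <- max(lens)
  mat <- matrix(vocab$pad, nrow = length(encoded), ncol = width)
  for (i in seq_along(encoded)) {
    mat[i, seq_len(lens[i])] <- encoded[[i]]$indices
  }
  structure(list(indices = mat, lengths = lens), class = "pep_batch")
}

#' Recover peptides from a padded batch
#'
#' @param batch A `pep_batch` from [pad_batch()].
#' @inheritParams tokenize
#' @return Character vector of peptides, one per batch row.
#' @export
unpad_batch <- function(batch, vocab = aa_vocabulary()) {
  vapply(
    seq_len(nrow(batch$indices)),
    function(i) detokenize(batch$indices[i, seq_len(batch$lengths[i])], vocab),
    character(1)
  )
}

# Tokenize a character vector of peptides straight into a padded batch.
encode_batch <- function(peptides, vocab = aa_vocabulary()) {
  pad_batch(lapply(peptides, tokenize, vocab = vocab), vocab)
}
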