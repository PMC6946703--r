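# Low-level DNA utilities shared by the simulator, the array parser and the
# matcher.  Sequences are plain upper-case character scalars internally;
# Biostrings is used at the boundaries (I/O, reverse complement).

.DNA_BASES <- c("A", "C", "G", "T")

#' Random DNA sequences
#'
#' Uniform i.i.d. ACGT sequences, drawn from the current RNG stream.
#'
#' @param n number of sequences.
#' @param len length in bases (recycled to `n`).
#' @return character vector of length `n`.
#' @keywords internal
random_dna <- function(n, len) {
  len <- rep_len(as.integer(len), n)
  vapply(len, function(l) {
    paste(sample(.DNA_BASES, l, replace = TRUE), collapse = "")
  }, character(1))
}

#' Reverse complement
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("AACGT")
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Hamming mismatch count of `pat` against every offset of `seq`.
# Returns integer vector of length nchar(seq) - nchar(pat) + 1 (empty if
# seq shorter than pat).
.hamming_scan <- function(seq, pat) {
  s <- charToRaw(seq)
  p <- charToRaw(pat)
  n <- length(s)
  m <- length(p)
  if (n < m || m == 0L) return(integer(0))
  nw <- n - m + 1L
  idx <- rep(seq_len(nw), m) + rep(0L:(m - 1L), each = nw)
  hit <- matrix(s[idx], nrow = nw) != matrix(p, nrow = nw, ncol = m, byrow = TRUE)
  as.integer(rowSums(hit))
}

# Set of distinct k-mers of a sequence (forward strand only).
.kmer_set <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  starts <- seq_len(L - k + 1L)
  unique(substring(seq, starts, starts + k - 1L))
}

# TRUE if any k-mer (either strand of `a`) occurs in `b`.
.shares_kmer <- function(a, b, k = 16L) {
  ka <- unique(c(.kmer_set(a, k), .kmer_set(revcomp(a), k)))
  kb <- .kmer_set(b, k)
  any(ka %in% kb)
}

.is_dna <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) &&
    !grepl("[^ACGT]", x)
}

.assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single value in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}
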