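# Internal sequence utilities shared across modules.

RNA_BASES <- c("A", "C", "G", "U")

#' Normalise a nucleotide string to uppercase RNA
#'
#' Uppercases the input and maps T to U. Used on all sequence input so the
#' rest of the package works on a single alphabet.
#'
#' @param x character vector of sequences.
#' @param validate if `TRUE`, reject characters outside `{A,C,G,U}` after
#'   normalisation.
#' @return character vector of the same length over `{A,C,G,U}`.
#' @keywords internal
rna_normalize <- function(x, validate = TRUE) {
  x <- chartr("acgut", "ACGUU", x)
  x <- chartr("T", "U", x)
  if (validate) {
    bad <- grepl("[^ACGU]", x)
    if (any(bad)) {
      offending <- unique(unlist(strsplit(gsub("[ACGU]", "", x[bad]), "")))
      stop("invalid nucleotide symbol(s): ", paste(offending, collapse = ", "),
           call. = FALSE)
    }
  }
  x
}

# Map a concatenated base string to integer codes A=0, C=1, G=2, U=3.
# Returns an integer vector of the same length as the number of characters.
base_codes <- function(seq_concat) {
  lut <- integer(128)
  lut[] <- NA_integer_
  lut[utf8ToInt("A")] <- 0L
  lut[utf8ToInt("C")] <- 1L
  lut[utf8ToInt("G")] <- 2L
  lut[utf8ToInt("U")] <- 3L
  lut[utf8ToInt(seq_concat)]
}

# Integer code of each k-mer window over a set of sequences.
# Returns a list with `code` (0..4^k-1), `seq_index` and `offset` (0-based),
# one entry per valid window, in sequence order then offset order.
kmer_window_codes <- function(seqs, k) {
  n <- nchar(seqs)
  concat <- paste(seqs, collapse = "")
  b <- base_codes(concat)
  if (length(b) == 0L || all(n < k)) {
    return(list(code = integer(0), seq_index = integer(0), offset = integer(0)))
  }
  # rolling code of window ending at position t: filter coefficients 4^0..4^(k-1)
  f <- 4^(0:(k - 1))
  code_end <- as.numeric(stats::filter(b, f, sides = 1))
  ends <- cumsum(n)
  starts <- ends - n + 1L
  keep_idx <- unlist(lapply(seq_along(seqs), function(i) {
    if (n[i] < k) return(integer(0))
    (starts[i] + k - 1L):ends[i]
  }))
  seq_index <- rep.int(seq_along(seqs), pmax(n - k + 1L, 0L))
  offset <- unlist(lapply(n, function(len) if (len < k) integer(0) else 0:(len - k)))
  list(code = as.integer(code_end[keep_idx]), seq_index = seq_index, offset = offset)
}

# Decode integer k-mer codes back to strings.
decode_kmers <- function(codes, k) {
  out <- character(length(codes))
  rem <- codes
  chars <- matrix("", nrow = length(codes), ncol = k)
  for (j in k:1) {
    chars[, j] <- RNA_BASES[rem %% 4L + 1L]
    rem <- rem %/% 4L
  }
  apply(chars, 1L, paste, collapse = "")
}

# All 4^k k-mers in lexicographic (A<C<G<U) order; code i maps to kmer i+1.
all_kmers <- function(k) {
  decode_kmers(0:(4^k - 1L), k)
}

# Reverse complement of RNA strings (A<->U, C<->G), base R.
rna_revcomp <- function(x) {
  comp <- chartr("ACGU", "UGCA", x)
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), character(1))
}
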