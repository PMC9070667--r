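# Independent oracles used across the suite. These deliberately take a
# different computational route than the package (regexes and brute-force
# enumeration rather than integer k-mer codes).

# Naive regex scan for motif matches; returns data.frame(offset, class)
# with 0-based offsets, bona fide taking precedence at each offset.
scan_oracle <- function(seq) {
  seq <- chartr("t", "u", tolower(seq))
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 7) return(data.frame(offset = integer(0), class = character(0)))
  bona_re <- "(?=(UUUUAC[ACGU]|UUUUA[ACGU]A|UUUU[ACGU]CA|UUUUUUU))"
  m <- gregexpr(bona_re, seq, perl = TRUE)[[1]]
  bona_off <- if (m[1] == -1) integer(0) else as.integer(m) - 1L
  bona_off <- bona_off[bona_off + 7L <= n]
  u_off <- integer(0)
  for (i in seq_len(n - 6L)) {
    if (substr(seq, i, i + 3L) == "UUUU" &&
        grepl("U", substr(seq, i + 4L, i + 6L)) &&
        !((i - 1L) %in% bona_off)) {
      u_off <- c(u_off, i - 1L)
    }
  }
  out <- rbind(
    data.frame(offset = bona_off, class = rep("bona_fide", length(bona_off))),
    data.frame(offset = u_off, class = rep("u_rich", length(u_off)))
  )
  out[order(out$offset), , drop = FALSE]
}

# Random RNA string generator for property tests.
rand_rna <- function(len, bases = c("A", "C", "G", "U")) {
  paste(sample(bases, len, replace = TRUE), collapse = "")
}

# Brute-force enumeration of all concrete words of a degenerate pattern,
# via expand.grid rather than the package's outer-product expansion.
expand_oracle <- function(pattern) {
  alts <- lapply(strsplit(pattern, "")[[1]], function(ch) {
    if (ch == "N") c("A", "C", "G", "U") else ch
  })
  sort(unique(apply(do.call(expand.grid, alts), 1, paste, collapse = "")))
}
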