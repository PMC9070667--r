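#' The degenerate U-rich motif grammar
#'
#' The grammar distinguishes two motif classes in 7-nt windows:
#'
#' * `bona_fide` — an exact match to one of four degenerate heptamer
#'   patterns: `UUUUACN`, `UUUUANA`, `UUUUNCA`, `UUUUUUU` (`N` = any base).
#'   Expanded, the four patterns cover 13 words counted per pattern and 11
#'   distinct words (`UUUUACA` satisfies all three degenerate patterns).
#' * `u_rich` — four consecutive uridines followed by three nucleotides that
#'   contain at least one additional U, excluding words that already match a
#'   bona fide pattern.
#'
#' A bona fide word takes precedence over the U-rich rule at the word, window
#' and gene level, so the two classes are disjoint.
#'
#' @param bona_fide character vector of degenerate 7-mer patterns over
#'   `{A,C,G,U,N}` defining the bona fide class.
#' @param u_rich include the U-rich rule in the grammar?
#' @return an object of class `motif_grammar` with components `patterns`
#'   (data frame: `pattern_id`, `definition`, `motif_class`), `words`
#'   (named character vector mapping each distinct bona fide word to the
#'   first pattern it matches, in pattern order) and `u_rich` (logical).
#' @examples
#' g <- motif_grammar()
#' length(g$words)  # 11 distinct bona fide words
#' @export
motif_grammar <- function(bona_fide = c("UUUUACN", "UUUUANA", "UUUUNCA", "UUUUUUU"),
                          u_rich = TRUE) {
  bona_fide <- toupper(bona_fide)
  words <- character(0)
  for (p in bona_fide) {
    for (w in expand_degenerate(p)) {
      if (!(w %in% names(words))) words[w] <- p
    }
  }
  patterns <- data.frame(
    pattern_id = c(bona_fide, if (u_rich) "u_rich"),
    definition = c(bona_fide, if (u_rich) "UUUU then 3 nt with >=1 U"),
    motif_class = c(rep("bona_fide", length(bona_fide)), if (u_rich) "u_rich"),
    stringsAsFactors = FALSE
  )
  structure(list(patterns = patterns,
                 words = structure(unname(words), names = names(words)),
                 u_rich = u_rich),
            class = "motif_grammar")
}

#' @export
print.motif_grammar <- function(x, ...) {
  cat("Motif grammar:", sum(x$patterns$motif_class == "bona_fide"),
      "bona fide pattern(s) expanding to", length(x$words), "distinct word(s);",
      if (x$u_rich) "U-rich rule active" else "no U-rich rule", "\n")
  invisible(x)
}

#' Expand a degenerate 7-mer pattern into concrete words
#'
#' `N` expands to each of the four bases; all other positions must be literal
#' bases. The result has set semantics: words are distinct and returned in
#' lexicographic order.
#'
#' @param pattern a length-7 string over `{A,C,G,U,N}` (T accepted as U,
#'   lowercase accepted).
#' @return character vector of `4^(#N)` concrete 7-mer words.
#' @examples
#' expand_degenerate("UUUUACN")
#' @export
expand_degenerate <- function(pattern) {
  stopifnot(length(pattern) == 1L)
  pattern <- chartr("t", "u", tolower(pattern))
  pattern <- toupper(pattern)
  chars <- strsplit(pattern, "")[[1]]
  bad <- setdiff(chars, c(RNA_BASES, "N"))
  if (length(bad) > 0L) {
    stop("invalid pattern symbol(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  if (length(chars) != 7L) {
    stop("pattern must have length 7, got ", length(chars), call. = FALSE)
  }
  words <- ""
  for (ch in chars) {
    alt <- if (ch == "N") RNA_BASES else ch
    words <- as.vector(outer(words, alt, paste0))
  }
  sort(unique(words))
}

# Cached lookup structures for a grammar: logical membership over 4^7 codes
# for the bona fide words and the full (bona fide + U-rich) word set, plus an
# integer index from word code to the pattern row.
grammar_lookup <- function(grammar) {
  word_codes <- kmer_codes_of(names(grammar$words))
  bona <- logical(4^7)
  bona[word_codes + 1L] <- TRUE
  pattern_of <- rep(NA_character_, 4^7)
  pattern_of[word_codes + 1L] <- unname(grammar$words)
  urich <- logical(4^7)
  if (grammar$u_rich) {
    tails <- all_kmers(3)
    tails <- tails[grepl("U", tails)]
    uw <- paste0("UUUU", tails)
    urich[kmer_codes_of(uw) + 1L] <- TRUE
    urich[bona] <- FALSE  # precedence: bona fide wins
  }
  list(bona = bona, urich = urich, pattern_of = pattern_of)
}

# Integer codes of concrete k-mers.
kmer_codes_of <- function(words) {
  k <- nchar(words[1])
  b <- matrix(base_codes(paste(words, collapse = "")), nrow = k)
  as.integer(colSums(b * 4^((k - 1):0)))
}

#' Classify a concrete heptamer
#'
#' Assigns each 7-mer to `bona_fide`, `u_rich` or `none` under the grammar,
#' with bona fide taking precedence over the U-rich rule.
#'
#' @param word character vector of length-7 words over `{A,C,G,U}` (T/lowercase
#'   accepted).
#' @param grammar a [motif_grammar()].
#' @return character vector in `{"bona_fide","u_rich","none"}`.
#' @examples
#' classify_heptamer(c("UUUUACA", "UUUUCUG", "UUGUUAA"))
#' @export
classify_heptamer <- function(word, grammar = motif_grammar()) {
  word <- rna_normalize(word)
  if (any(nchar(word) != 7L)) {
    stop("heptamer classification requires length-7 words", call. = FALSE)
  }
  lk <- grammar_lookup(grammar)
  codes <- kmer_codes_of(word) + 1L
  out <- rep("none", length(word))
  out[lk$urich[codes]] <- "u_rich"
  out[lk$bona[codes]] <- "bona_fide"
  out
}

#' Scan a sequence for motif matches in every 7-nt window
#'
#' Every window of width 7 is classified; all matches are reported, including
#' overlapping ones, sorted by offset. Each offset appears at most once, with
#' its highest-precedence class (bona fide over U-rich).
#'
#' @param seq a single RNA string over `{A,C,G,U}`; T is mapped to U and
#'   lowercase is accepted. Sequences shorter than 7 give an empty result.
#' @param grammar a [motif_grammar()].
#' @return data frame with columns `offset` (0-based start), `word`,
#'   `motif_class` and `pattern_id`.
#' @examples
#' scan_window("ACAUUUUACAACA")
#' @export
scan_window <- function(seq, grammar = motif_grammar()) {
  stopifnot(length(seq) == 1L)
  seq <- rna_normalize(seq)
  empty <- data.frame(offset = integer(0), word = character(0),
                      motif_class = character(0), pattern_id = character(0),
                      stringsAsFactors = FALSE)
  if (nchar(seq) < 7L) return(empty)
  win <- kmer_window_codes(seq, 7L)
  lk <- grammar_lookup(grammar)
  idx <- win$code + 1L
  cls <- rep(NA_character_, length(idx))
  cls[lk$urich[idx]] <- "u_rich"
  cls[lk$bona[idx]] <- "bona_fide"
  hit <- !is.na(cls)
  if (!any(hit)) return(empty)
  data.frame(
    offset = win$offset[hit],
    word = decode_kmers(win$code[hit], 7L),
    motif_class = cls[hit],
    pattern_id = ifelse(cls[hit] == "bona_fide",
                        lk$pattern_of[idx[hit]], "u_rich"),
    stringsAsFactors = FALSE
  )
}

#' Write / read a motif grammar as structured text
#'
#' Serialises the grammar as a three-column TSV (`pattern_id`, `definition`,
#' `motif_class`) so it can be versioned and edited alongside an analysis.
#'
#' @param grammar a [motif_grammar()].
#' @param path file path.
#' @return `write_grammar` returns `path` invisibly; `read_grammar` returns a
#'   [motif_grammar()].
#' @export
write_grammar <- function(grammar, path) {
  utils::write.table(grammar$patterns, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_grammar
#' @export
read_grammar <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("pattern_id", "definition", "motif_class")
  if (!all(need %in% names(tab))) {
    stop("grammar file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  motif_grammar(bona_fide = tab$pattern_id[tab$motif_class == "bona_fide"],
                u_rich = any(tab$motif_class == "u_rich"))
}

#' Export motif matches as TSV
#'
#' @param matches a data frame of matches as returned by [scan_window()], with
#'   an additional `sequence_id` column (added here if `sequence_id` given).
#' @param path file path.
#' @param sequence_id optional single id recycled over all rows.
#' @return `path`, invisibly.
#' @export
write_matches <- function(matches, path, sequence_id = NULL) {
  if (!is.null(sequence_id)) matches$sequence_id <- sequence_id
  cols <- c("sequence_id", "offset", "word", "motif_class", "pattern_id")
  matches <- matches[, intersect(cols, names(matches)), drop = FALSE]
  utils::write.table(matches, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
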