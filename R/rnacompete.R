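#' Read / write probe-intensity tables
#'
#' Probe tables are TSV files with columns `probe_id`, `set_label` (`A` or
#' `B`), `sequence` and `intensity` (arbitrary fluorescence units, >= 0).
#'
#' @param path file path.
#' @return `read_probe_table` returns a data frame of probe records;
#'   `write_probe_table` returns `path` invisibly.
#' @export
read_probe_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = c(probe_id = "character",
                                          set_label = "character",
                                          sequence = "character",
                                          intensity = "numeric"))
  validate_probes(tab)
  tab$sequence <- rna_normalize(tab$sequence)
  tab
}

#' @rdname read_probe_table
#' @param probes a probe data frame.
#' @export
write_probe_table <- function(probes, path) {
  utils::write.table(probes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_probes <- function(probes) {
  need <- c("probe_id", "set_label", "sequence", "intensity")
  miss <- setdiff(need, names(probes))
  if (length(miss)) stop("probe table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(probes) == 0L) stop("empty probe list", call. = FALSE)
  if (!all(probes$set_label %in% c("A", "B"))) {
    stop("set_label must be 'A' or 'B'", call. = FALSE)
  }
  if (any(probes$intensity < 0)) stop("negative intensities", call. = FALSE)
  if (any(nchar(probes$sequence) < 7L)) {
    stop("probe sequences must be at least 7 nt", call. = FALSE)
  }
  invisible(probes)
}

#' Aggregate per-k-mer binding scores from probe intensities
#'
#' For every k-mer, the aggregate score is the symmetric trimmed mean of the
#' intensities of probes containing that k-mer at least once (each probe
#' counted once). K-mers absent from all probes of a set are flagged missing
#' (`n_probes = 0`, `NA` score) rather than scored.
#'
#' @param probes probe data frame (see [read_probe_table()]); may contain one
#'   or both set labels — one score table is returned per set present.
#' @param k k-mer length (7 for the standard analysis).
#' @param trim_fraction fraction trimmed from each tail of the per-k-mer
#'   intensity distribution, in `[0, 0.5)`.
#' @return a named list of `kmer_score_table` data frames (one per set) with
#'   columns `kmer`, `aggregate_score`, `n_probes`, `missing`.
#' @export
aggregate_kmer_scores <- function(probes, k = 7, trim_fraction = 0.025) {
  validate_probes(probes)
  if (trim_fraction < 0 || trim_fraction >= 0.5) {
    stop("trim_fraction must be in [0, 0.5)", call. = FALSE)
  }
  probes$sequence <- rna_normalize(probes$sequence)
  sets <- sort(unique(probes$set_label))
  out <- lapply(sets, function(s) {
    sub <- probes[probes$set_label == s, , drop = FALSE]
    aggregate_one_set(sub, k, trim_fraction)
  })
  names(out) <- sets
  if (all(vapply(out, function(t) all(t$missing), logical(1)))) {
    stop("no k-mer could be scored in any set", call. = FALSE)
  }
  out
}

aggregate_one_set <- function(probes, k, trim_fraction) {
  win <- kmer_window_codes(probes$sequence, k)
  # one (probe, kmer) pair per distinct containment
  key <- as.numeric(win$seq_index) * 4^k + win$code
  keep <- !duplicated(key)
  code <- win$code[keep]
  inten <- probes$intensity[win$seq_index[keep]]
  groups <- split(inten, code)
  score <- vapply(groups, function(x) mean(x, trim = trim_fraction), numeric(1))
  n_univ <- 4L^k
  agg <- rep(NA_real_, n_univ)
  np <- integer(n_univ)
  idx <- as.integer(names(groups)) + 1L
  agg[idx] <- score
  np[idx] <- lengths(groups)
  tab <- data.frame(kmer = all_kmers(k),
                    aggregate_score = agg,
                    n_probes = np,
                    missing = np == 0L,
                    stringsAsFactors = FALSE)
  class(tab) <- c("kmer_score_table", class(tab))
  tab
}

#' Z-score and rank a k-mer score table
#'
#' Standardises aggregate scores over the scored (non-missing) k-mers using
#' the population standard deviation, and ranks by descending Z with ties
#' broken lexicographically by k-mer for determinism.
#'
#' @param table a `kmer_score_table` from [aggregate_kmer_scores()].
#' @return the table with `z_score` and `rank` columns filled (missing k-mers
#'   keep `NA`).
#' @export
zscore_and_rank <- function(table) {
  scored <- !table$missing
  x <- table$aggregate_score[scored]
  if (length(unique(x)) < 2L) {
    stop("degenerate score distribution: fewer than 2 distinct aggregate scores",
         call. = FALSE)
  }
  mu <- mean(x)
  sdev <- sqrt(mean((x - mu)^2))  # population SD
  if (sdev == 0) stop("degenerate score distribution: zero standard deviation",
                      call. = FALSE)
  z <- rep(NA_real_, nrow(table))
  z[scored] <- (x - mu) / sdev
  table$z_score <- z
  ord <- order(-table$z_score[scored], table$kmer[scored])
  rk <- rep(NA_integer_, nrow(table))
  rk[which(scored)[ord]] <- seq_along(ord)
  table$rank <- rk
  table
}

#' Split-half concordance of Z-scored tables
#'
#' Joins the Set A and Set B tables on their k-mer universe, emits per-k-mer
#' `(Z_A, Z_B, Z_avg)` scatter rows with `Z_avg = (Z_A + Z_B)/2`, and a
#' Spearman rank correlation between the two halves.
#'
#' @param tableA,tableB Z-scored tables from [zscore_and_rank()], covering the
#'   same k-mer universe.
#' @return list with `table` (columns `kmer`, `z_a`, `z_b`, `z_avg`,
#'   `rank_avg`), `rank_correlation` (Spearman) and `pearson_correlation`
#'   (the scatter-plot correlation of the two Z-score vectors; at realistic
#'   per-k-mer probe coverage this is the sharper concordance measure, since
#'   rank correlation is diluted by the noise-dominated low-affinity bulk).
#' @export
split_half_concordance <- function(tableA, tableB) {
  if (!identical(tableA$kmer, tableB$kmer)) {
    n_diff <- length(union(setdiff(tableA$kmer, tableB$kmer),
                           setdiff(tableB$kmer, tableA$kmer)))
    stop("k-mer universes differ between sets (", n_diff,
         " k-mer(s) not shared or order mismatch)", call. = FALSE)
  }
  tab <- data.frame(kmer = tableA$kmer,
                    z_a = tableA$z_score,
                    z_b = tableB$z_score,
                    stringsAsFactors = FALSE)
  tab$z_avg <- (tab$z_a + tab$z_b) / 2
  ok <- stats::complete.cases(tab$z_a, tab$z_b)
  ord <- order(-tab$z_avg[ok], tab$kmer[ok])
  rk <- rep(NA_integer_, nrow(tab))
  rk[which(ok)[ord]] <- seq_along(ord)
  tab$rank_avg <- rk
  list(table = tab,
       rank_correlation = stats::cor(tab$z_a[ok], tab$z_b[ok],
                                     method = "spearman"),
       pearson_correlation = stats::cor(tab$z_a[ok], tab$z_b[ok]))
}

#' Build a consensus motif from top-scored k-mers
#'
#' Greedy offset alignment: the rank-1 word seeds the alignment at offset 0;
#' each subsequent word is placed at the integer offset (|offset| <= 3)
#' maximising positional identity with the current frequency matrix, ties
#' resolved in favour of offset 0, then smaller |offset|, then the negative
#' offset. Returns the alignment, the position-frequency matrix (columns sum
#' to the number of words covering that column) and an IUPAC consensus where
#' a base enters a column's code if its count is at least 25% of the column
#' total.
#'
#' @param kmers character vector of top-ranked k-mers, best first; all the
#'   same length; at least 2.
#' @param max_shift maximum |offset| explored during alignment.
#' @param iupac_threshold minimum fraction of a column's total for a base to
#'   enter the consensus code.
#' @return an object of class `consensus_motif`: list with `alignment`
#'   (data frame `kmer`, `offset`), `pfm` (4 x width matrix, rows A,C,G,U)
#'   and `consensus` (IUPAC string).
#' @examples
#' consensus_from_top(c("UUUUUUU", "UUUUACA"))
#' @export
consensus_from_top <- function(kmers, max_shift = 3, iupac_threshold = 0.25) {
  if (length(kmers) < 2L) stop("need at least 2 k-mers", call. = FALSE)
  kmers <- rna_normalize(kmers)
  k <- nchar(kmers[1])
  if (any(nchar(kmers) != k)) stop("k-mers must all have the same length",
                                   call. = FALSE)
  # pfm columns indexed over a fixed coordinate frame [-max_shift, k-1+max_shift]
  width <- k + 2L * max_shift
  pfm <- matrix(0L, nrow = 4L, ncol = width,
                dimnames = list(RNA_BASES, NULL))
  place <- function(pfm, word, offset) {
    cols <- (offset + max_shift + 1L):(offset + max_shift + k)
    b <- base_codes(word) + 1L
    for (j in seq_len(k)) pfm[b[j], cols[j]] <- pfm[b[j], cols[j]] + 1L
    pfm
  }
  identity_score <- function(pfm, word, offset) {
    cols <- (offset + max_shift + 1L):(offset + max_shift + k)
    b <- base_codes(word) + 1L
    sum(pfm[cbind(b, cols)])
  }
  offsets <- integer(length(kmers))
  pfm <- place(pfm, kmers[1], 0L)
  if (length(kmers) > 1L) {
    cand <- seq(-max_shift, max_shift)
    # tie order: 0 first, then by |offset|, negative before positive
    cand <- cand[order(abs(cand), cand)]
    for (i in 2:length(kmers)) {
      sc <- vapply(cand, function(o) identity_score(pfm, kmers[i], o), numeric(1))
      best <- cand[which.max(sc)]  # first max in tie order
      offsets[i] <- best
      pfm <- place(pfm, kmers[i], best)
    }
  }
  used <- which(colSums(pfm) > 0)
  pfm <- pfm[, used, drop = FALSE]
  consensus <- paste(vapply(seq_len(ncol(pfm)), function(j) {
    col <- pfm[, j]
    bases <- RNA_BASES[col >= iupac_threshold * sum(col)]
    iupac_code(bases)
  }, character(1)), collapse = "")
  structure(list(alignment = data.frame(kmer = kmers, offset = offsets,
                                        stringsAsFactors = FALSE),
                 pfm = pfm, consensus = consensus),
            class = "consensus_motif")
}

#' @export
print.consensus_motif <- function(x, ...) {
  cat("Consensus motif:", x$consensus, "(", nrow(x$alignment), "words )\n")
  invisible(x)
}

# IUPAC code (RNA flavour: U instead of T) for a set of bases.
iupac_code <- function(bases) {
  key <- paste(sort(bases), collapse = "")
  codes <- c(A = "A", C = "C", G = "G", U = "U",
             AC = "M", AG = "R", AU = "W", CG = "S", CU = "Y", GU = "K",
             ACG = "V", ACU = "H", AGU = "D", CGU = "B", ACGU = "N")
  unname(codes[key])
}

#' Export a consensus motif as a minimal MEME-style text block
#'
#' @param motif a `consensus_motif`.
#' @param path file path.
#' @param name motif name used in the block.
#' @return `path`, invisibly.
#' @export
write_meme_motif <- function(motif, path, name = "consensus") {
  pfm <- motif$pfm
  probs <- sweep(pfm, 2L, pmax(colSums(pfm), 1L), "/")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGU", "",
               sprintf("MOTIF %s", name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d",
                       ncol(pfm), nrow(motif$alignment))), con)
  for (j in seq_len(ncol(probs))) {
    writeLines(paste(sprintf("%.6f", probs[, j]), collapse = " "), con)
  }
  invisible(path)
}

#' Run the full split-half 7-mer scoring analysis
#'
#' Convenience wrapper: aggregates and Z-scores both sets, computes the
#' split-half scatter/concordance, and builds the consensus motif from the
#' top `n_top` 7-mers of the Set A+B average.
#'
#' @param probes probe data frame with both `A` and `B` records.
#' @param n_top number of top-average-Z 7-mers used for the consensus.
#' @inheritParams aggregate_kmer_scores
#' @return list with `tables` (per-set Z-scored tables), `concordance`
#'   (from [split_half_concordance()]), `top_kmers` and `consensus`.
#' @export
rnacompete_analysis <- function(probes, k = 7, trim_fraction = 0.025, n_top = 10) {
  tabs <- aggregate_kmer_scores(probes, k = k, trim_fraction = trim_fraction)
  if (!all(c("A", "B") %in% names(tabs))) {
    stop("both Set A and Set B probes are required", call. = FALSE)
  }
  tabs <- lapply(tabs, zscore_and_rank)
  conc <- split_half_concordance(tabs$A, tabs$B)
  top <- conc$table$kmer[order(conc$table$rank_avg)][seq_len(n_top)]
  list(tables = tabs, concordance = conc, top_kmers = top,
       consensus = consensus_from_top(top))
}
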