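#' Load a genome from FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] keeping only the first
#' word of each FASTA header as the contig name.
#'
#' @param path FASTA file path.
#' @return a `DNAStringSet` keyed by contig name.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Extract the motif-scan window around a crosslink position
#'
#' Returns the sequence `up` nt upstream to `down` nt downstream of the
#' crosslink position in transcript orientation (the minus strand is
#' reverse-complemented), with T mapped to U. The window is truncated at the
#' contig ends; the actual length is the string length of the result, and a
#' `truncated` attribute records whether truncation occurred.
#'
#' @param genome a `DNAStringSet` (see [read_genome()]).
#' @param chrom contig name.
#' @param crosslink_pos 1-based position on the contig.
#' @param strand `"+"` or `"-"`.
#' @param up,down window extent in nt (defaults 30 upstream / 20 downstream,
#'   giving 51-nt windows away from contig ends).
#' @return an RNA string with attribute `truncated`.
#' @export
extract_window <- function(genome, chrom, crosslink_pos, strand, up = 30, down = 20) {
  if (!chrom %in% names(genome)) {
    stop("contig not in genome: ", chrom, call. = FALSE)
  }
  len <- Biostrings::width(genome[chrom])
  if (crosslink_pos < 1 || crosslink_pos > len) {
    stop("position ", crosslink_pos, " outside contig ", chrom,
         " (length ", len, ")", call. = FALSE)
  }
  if (strand == "+") {
    s <- crosslink_pos - up
    e <- crosslink_pos + down
  } else if (strand == "-") {
    s <- crosslink_pos - down
    e <- crosslink_pos + up
  } else {
    stop("invalid strand: ", strand, call. = FALSE)
  }
  s_cl <- max(s, 1L)
  e_cl <- min(e, len)
  seq <- as.character(Biostrings::subseq(genome[[chrom]], s_cl, e_cl))
  if (strand == "-") {
    seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  }
  out <- rna_normalize(seq)
  attr(out, "truncated") <- (s_cl != s) || (e_cl != e)
  out
}

#' Read gene models from a GFF3 file
#'
#' Parses the 9-column GFF3 table and keeps `gene` spans plus the feature
#' intervals `five_prime_UTR`, `CDS`, `three_prime_UTR` and `intron`,
#' grouped per gene via the `ID`/`Parent`-free convention used here: every
#' feature row carries a `gene_id=` attribute. This minimal reader covers
#' the annotation files emitted by [simulate_clip_cohort()] and any GFF3
#' whose features are tagged that way; for richer annotations, import with
#' `rtracklayer` and convert.
#'
#' @param path GFF3 file path.
#' @return named list of gene models; each is a list with `gene_id`,
#'   `chrom`, `strand`, `start`, `end` and `features` (data frame `feature`,
#'   `start`, `end`).
#' @export
read_gene_models <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) return(list())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 9L)) {
    stop("malformed GFF3: expected 9 tab-separated columns", call. = FALSE)
  }
  m <- do.call(rbind, parts)
  gene_id <- sub(".*gene_id=([^;]+).*", "\\1", m[, 9L])
  tab <- data.frame(chrom = m[, 1L], type = m[, 3L],
                    start = as.integer(m[, 4L]), end = as.integer(m[, 5L]),
                    strand = m[, 7L], gene_id = gene_id,
                    stringsAsFactors = FALSE)
  feature_map <- c(five_prime_UTR = "five_prime_utr", CDS = "cds",
                   three_prime_UTR = "three_prime_utr", intron = "intron")
  models <- lapply(split(tab, tab$gene_id), function(g) {
    gene_row <- g[g$type == "gene", , drop = FALSE]
    feats <- g[g$type %in% names(feature_map), , drop = FALSE]
    list(gene_id = g$gene_id[1],
         chrom = g$chrom[1],
         strand = g$strand[1],
         start = if (nrow(gene_row)) gene_row$start[1] else min(g$start),
         end = if (nrow(gene_row)) gene_row$end[1] else max(g$end),
         features = data.frame(feature = unname(feature_map[feats$type]),
                               start = feats$start, end = feats$end,
                               stringsAsFactors = FALSE))
  })
  models
}

#' Assign a cluster to a transcript feature
#'
#' Labels the cluster with the feature (5' UTR, CDS, 3' UTR, intron) of
#' maximal overlap; ties favour `three_prime_utr`, then `five_prime_utr`,
#' then `cds`, then `intron`. A cluster overlapping none of the features is
#' labelled `noncoding` with a warning.
#'
#' @param cluster one-row cluster data frame (or list) with `start`, `end`.
#' @param gene_model a gene model from [read_gene_models()].
#' @return a single feature label.
#' @export
assign_feature <- function(cluster, gene_model) {
  feats <- gene_model$features
  if (nrow(feats) == 0L) {
    warning("gene model has no features; labelling cluster noncoding")
    return("noncoding")
  }
  ov <- pmax(pmin(cluster$end, feats$end) - pmax(cluster$start, feats$start) + 1L, 0L)
  ov_by <- tapply(ov, feats$feature, sum)
  if (all(ov_by == 0)) {
    warning("cluster overlaps no annotated feature; labelling noncoding")
    return("noncoding")
  }
  prec <- c("three_prime_utr", "five_prime_utr", "cds", "intron", "noncoding")
  present <- prec[prec %in% names(ov_by)]
  present[which.max(ov_by[present])]
}

#' Anchor positions of a cluster for window extraction
#'
#' When explicit crosslink positions are available they are the anchors; the
#' fallback anchors a cluster at its strand-aware 5'-most coordinate, or at
#' its midpoint (`anchor = "midpoint"`).
#'
#' @param clusters cluster data frame.
#' @param anchor `"five_prime"` (default) or `"midpoint"`.
#' @return integer vector of anchor positions, one per cluster row.
#' @export
cluster_anchor <- function(clusters, anchor = c("five_prime", "midpoint")) {
  anchor <- match.arg(anchor)
  if (anchor == "midpoint") {
    as.integer(floor((clusters$start + clusters$end) / 2))
  } else {
    ifelse(clusters$strand == "+", clusters$start, clusters$end)
  }
}

#' Classify genes by motif content of their crosslink windows
#'
#' A gene is `bona_fide` if any of its windows contains a bona fide match,
#' else `u_rich` if any window contains a U-rich match, else `none`
#' (class precedence as everywhere in the grammar). The cohort report gives
#' counts and fractions per class and the enrichment of the bona fide
#' fraction over the motif-occurrence null.
#'
#' @param windows_by_gene named list: `gene_id` -> character vector of
#'   window sequences (>= 1 per gene).
#' @param grammar a [motif_grammar()].
#' @param null_window_len fragment length used for the null expectation
#'   (default 50, the conventional random-fragment length).
#' @param null_mode counting convention passed to
#'   [null_window_probability()].
#' @return list with `genes` (data frame `gene_id`, `motif_class`) and
#'   `cohort` (list of counts, fractions, expected null frequency `f` and
#'   `enrichment`).
#' @export
gene_motif_summary <- function(windows_by_gene, grammar = motif_grammar(),
                               null_window_len = 50,
                               null_mode = "summed_pattern_counts") {
  if (length(windows_by_gene) == 0L) stop("no genes supplied", call. = FALSE)
  cls <- vapply(windows_by_gene, function(ws) {
    found <- "none"
    for (w in ws) {
      m <- scan_window(w, grammar)
      if (nrow(m) == 0L) next
      if (any(m$motif_class == "bona_fide")) return("bona_fide")
      found <- "u_rich"
    }
    found
  }, character(1))
  genes <- data.frame(gene_id = names(windows_by_gene), motif_class = unname(cls),
                      stringsAsFactors = FALSE)
  n <- nrow(genes)
  counts <- c(bona_fide = sum(cls == "bona_fide"),
              u_rich = sum(cls == "u_rich"),
              none = sum(cls == "none"))
  null <- null_window_probability(null_window_len, null_mode)
  frac_bona <- counts[["bona_fide"]] / n
  cohort <- list(
    n_genes = n,
    counts = as.list(counts),
    fractions = as.list(counts / n),
    n_motif_positive = n - counts[["none"]],
    fraction_motif_positive = (n - counts[["none"]]) / n,
    expected_f = null$probability,
    null_mode = null_mode,
    enrichment = if (null$probability > 0)
      enrichment_ratio(frac_bona, null$probability) else NA_real_
  )
  list(genes = genes, cohort = cohort)
}

#' End-to-end iCLIP target analysis
#'
#' Chains the cluster post-processing stages: bait overlap and positional
#' equivalence on the (optionally extended) clusters, contaminant filtering,
#' window extraction around cluster anchors, and gene-level motif
#' classification.
#'
#' @param fl,nhl cluster data frames for the two baits.
#' @param genome a `DNAStringSet`.
#' @param rules a [filter_rules()].
#' @param grammar a [motif_grammar()].
#' @param extend_up,extend_down cluster extension applied before distance
#'   computation (set both to 0 if the input clusters are already extended).
#' @param max_gap positional-equivalence threshold (nt).
#' @param up,down motif-window extent around each anchor (nt).
#' @param anchor anchor mode, see [cluster_anchor()].
#' @param null_mode,null_window_len see [gene_motif_summary()].
#' @return list with `overlap` (from [shared_gene_overlap()]), `filtered`
#'   (from [apply_filters()]), `motifs` (from [gene_motif_summary()] on the
#'   retained position-equivalent genes), `windows` (interval data frame)
#'   and `report` (flat list of the headline cohort numbers).
#' @export
clip_target_analysis <- function(fl, nhl, genome, rules = filter_rules(),
                                 grammar = motif_grammar(),
                                 extend_up = 0, extend_down = 0,
                                 max_gap = 50, up = 30, down = 20,
                                 anchor = "five_prime",
                                 null_mode = "summed_pattern_counts",
                                 null_window_len = 50) {
  if (extend_up > 0 || extend_down > 0) {
    fl <- extend_cluster(fl, extend_up, extend_down)
    nhl <- extend_cluster(nhl, extend_up, extend_down)
  }
  ov <- shared_gene_overlap(fl, nhl, max_gap = max_gap)
  shared_genes <- ov$summary$gene_id[ov$summary$shared]
  both <- rbind(fl, nhl)
  both <- both[both$gene_id %in% shared_genes, , drop = FALSE]
  # windows around each cluster anchor of shared genes
  pos <- cluster_anchor(both, anchor)
  win_seq <- character(nrow(both))
  for (i in seq_len(nrow(both))) {
    win_seq[i] <- extract_window(genome, both$chrom[i], pos[i], both$strand[i],
                                 up = up, down = down)
  }
  windows <- data.frame(chrom = both$chrom,
                        start = pmax(ifelse(both$strand == "+", pos - up, pos - down), 1L),
                        end = ifelse(both$strand == "+", pos + down, pos + up),
                        strand = both$strand,
                        gene_id = both$gene_id,
                        sequence = win_seq,
                        stringsAsFactors = FALSE)
  windows_by_gene <- split(windows$sequence, windows$gene_id)
  gene_chrom <- vapply(split(both$chrom, both$gene_id), `[`, character(1), 1L)
  shared_df <- data.frame(gene_id = names(gene_chrom),
                          chrom = unname(gene_chrom),
                          stringsAsFactors = FALSE)
  filtered <- apply_filters(shared_df, rules, windows_by_gene)
  eq <- ov$summary$gene_id[ov$summary$position_equivalent]
  analysed <- intersect(filtered$retained$gene_id, eq)
  motifs <- if (length(analysed)) {
    gene_motif_summary(windows_by_gene[analysed], grammar,
                       null_window_len = null_window_len, null_mode = null_mode)
  } else NULL
  n_retained <- nrow(filtered$retained)
  report <- c(ov$stats,
              list(n_excluded = nrow(filtered$excluded),
                   n_retained = n_retained,
                   n_analysed = length(analysed),
                   pct_position_equivalent_of_retained =
                     if (n_retained > 0)
                       100 * length(analysed) / n_retained else NA_real_),
              if (!is.null(motifs)) motifs$cohort)
  list(overlap = ov, filtered = filtered, motifs = motifs,
       windows = windows, report = report)
}
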