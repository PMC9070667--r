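#' Read / write crosslink-cluster tables
#'
#' Cluster tables are TSV files in the supplementary-table dialect:
#' 1-based inclusive chromosome coordinates with columns `chrom`, `start`,
#' `end`, `gene_id`, `strand`, and optionally `bait` (`FL`, `NHL`,
#' `control`) and `replicate`. Rows are validated (strand token, start <=
#' end, coordinates >= 1) with the offending line number reported.
#'
#' @param path file path.
#' @param bait optional bait label assigned to all rows when the file lacks a
#'   `bait` column.
#' @return `read_cluster_table` returns a data frame of clusters;
#'   `write_cluster_table` returns `path` invisibly and round-trips
#'   losslessly through the reader.
#' @export
read_cluster_table <- function(path, bait = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "gene_id", "strand")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("cluster table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"bait" %in% names(tab)) {
    tab$bait <- if (is.null(bait)) NA_character_ else bait
  }
  if (!"replicate" %in% names(tab)) tab$replicate <- 1L
  validate_clusters(tab)
  tab
}

#' @rdname read_cluster_table
#' @param clusters a cluster data frame.
#' @export
write_cluster_table <- function(clusters, path) {
  utils::write.table(clusters, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_clusters <- function(clusters) {
  # line numbers reported as data rows + header line
  bad_strand <- which(!clusters$strand %in% c("+", "-"))
  if (length(bad_strand)) {
    stop("invalid strand token at line ", bad_strand[1] + 1L,
         ": '", clusters$strand[bad_strand[1]], "'", call. = FALSE)
  }
  bad_coord <- which(clusters$start > clusters$end)
  if (length(bad_coord)) {
    stop("start > end at line ", bad_coord[1] + 1L, call. = FALSE)
  }
  bad_low <- which(clusters$start < 1)
  if (length(bad_low)) {
    stop("coordinate < 1 at line ", bad_low[1] + 1L, call. = FALSE)
  }
  invisible(clusters)
}

#' Extend crosslink clusters strand-awarely
#'
#' Extends each cluster `up` nt upstream and `down` nt downstream in
#' transcript orientation: on the `+` strand the interval becomes
#' `(start - up, end + down)`; on the `-` strand `(start - down, end + up)`.
#' Coordinates are truncated at 1 (truncation is reported via `message()`).
#'
#' @param clusters cluster data frame (see [read_cluster_table()]).
#' @param up,down extension in nt (defaults 20 upstream / 10 downstream, the
#'   convention used when tabulating significant-peak clusters).
#' @return the extended cluster data frame.
#' @export
extend_cluster <- function(clusters, up = 20, down = 10) {
  plus <- clusters$strand == "+"
  new_start <- ifelse(plus, clusters$start - up, clusters$start - down)
  new_end <- ifelse(plus, clusters$end + down, clusters$end + up)
  n_trunc <- sum(new_start < 1)
  if (n_trunc > 0) {
    message(n_trunc, " cluster(s) truncated at coordinate 1 during extension")
    new_start <- pmax(new_start, 1)
  }
  clusters$start <- new_start
  clusters$end <- new_end
  clusters
}

# Gap (nt strictly between two 1-based inclusive intervals); 0 if they
# intersect or abut ... no: abutting intervals (gap formula 0 only when
# overlapping). gap = max(startA,startB) - min(endA,endB) - 1, floored at 0.
interval_gap <- function(s1, e1, s2, e2) {
  pmax(pmax(s1, s2) - pmin(e1, e2) - 1L, 0L)
}

#' Bait-overlap statistics and positional equivalence
#'
#' Intersects the gene sets targeted by two baits (full-length protein and
#' isolated domain), computes the overlap percentage `100 * |A∩B| / |A∪B|`,
#' and, for every shared gene, the minimum gap between any pair of clusters
#' from the two baits (0 when intervals intersect, else the count of
#' nucleotides strictly between them). A shared gene is position-equivalent
#' when that minimum distance is at most `max_gap` nt.
#'
#' @param fl,nhl cluster data frames for the two baits.
#' @param max_gap positional-equivalence threshold in nt (default 50).
#' @return list with `summary` — one row per gene in the union (`gene_id`,
#'   `shared`, `min_distance` (`NA` for unshared), `position_equivalent`) —
#'   and `stats` (`n_fl`, `n_nhl`, `n_shared`, `n_union`, `overlap_pct`,
#'   `n_position_equivalent`, `pct_position_equivalent_of_shared`).
#' @export
shared_gene_overlap <- function(fl, nhl, max_gap = 50) {
  if (nrow(fl) == 0L || nrow(nhl) == 0L) {
    stop("both cluster sets must be non-empty", call. = FALSE)
  }
  genes_fl <- unique(fl$gene_id)
  genes_nhl <- unique(nhl$gene_id)
  shared <- intersect(genes_fl, genes_nhl)
  union_g <- union(genes_fl, genes_nhl)
  min_dist <- rep(NA_real_, length(union_g))
  names(min_dist) <- union_g
  fl_by <- split(fl[c("chrom", "start", "end")], fl$gene_id)
  nhl_by <- split(nhl[c("chrom", "start", "end")], nhl$gene_id)
  for (g in shared) {
    a <- fl_by[[g]]
    b <- nhl_by[[g]]
    pairs <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
    same_chrom <- a$chrom[pairs$i] == b$chrom[pairs$j]
    d <- ifelse(same_chrom,
                interval_gap(a$start[pairs$i], a$end[pairs$i],
                             b$start[pairs$j], b$end[pairs$j]),
                Inf)
    min_dist[g] <- min(d)
  }
  summary <- data.frame(
    gene_id = union_g,
    shared = union_g %in% shared,
    min_distance = unname(min_dist),
    stringsAsFactors = FALSE
  )
  summary$position_equivalent <- !is.na(summary$min_distance) &
    summary$min_distance <= max_gap
  n_shared <- length(shared)
  stats <- list(
    n_fl = length(genes_fl),
    n_nhl = length(genes_nhl),
    n_shared = n_shared,
    n_union = length(union_g),
    overlap_pct = 100 * n_shared / length(union_g),
    n_position_equivalent = sum(summary$position_equivalent),
    pct_position_equivalent_of_shared =
      if (n_shared > 0) 100 * sum(summary$position_equivalent) / n_shared else NA_real_
  )
  list(summary = summary, stats = stats)
}

#' Contaminant / artefact filter rules
#'
#' Bundles the exclusion rules applied to shared target genes before motif
#' analysis: mitochondrial chromosomes, a blocklist of contaminant host
#' genes (snoRNA/scaRNA/snRNA and similar), vector-derived sequence
#' patterns, and a low-complexity rule (poly-A-tail-like windows). All lists
#' may be empty (identity filter).
#'
#' @param mito_chrom_names chromosome names treated as mitochondrial.
#' @param contaminant_gene_blocklist gene ids excluded as known contaminants.
#' @param vector_sequence_patterns character vector of sequences; a gene is
#'   excluded when any of its windows contains one of them (fixed match).
#' @param max_a_run homopolymer-A run length at or above which a window is
#'   low-complexity.
#' @param max_a_fraction A-content above which a window is low-complexity.
#' @return an object of class `filter_rules`.
#' @export
filter_rules <- function(mito_chrom_names = character(0),
                         contaminant_gene_blocklist = character(0),
                         vector_sequence_patterns = character(0),
                         max_a_run = 15, max_a_fraction = 0.8) {
  structure(list(mito_chrom_names = mito_chrom_names,
                 contaminant_gene_blocklist = contaminant_gene_blocklist,
                 vector_sequence_patterns = vector_sequence_patterns,
                 max_a_run = max_a_run,
                 max_a_fraction = max_a_fraction),
            class = "filter_rules")
}

is_low_complexity <- function(windows, max_a_run, max_a_fraction) {
  run <- grepl(strrep("A", max_a_run), windows, fixed = TRUE)
  afrac <- vapply(windows, function(w) {
    mean(strsplit(w, "")[[1]] == "A")
  }, numeric(1))
  run | afrac > max_a_fraction
}

#' Apply contaminant filters to gene summaries
#'
#' Excludes genes by rule, with reason precedence
#' `mitochondrial > contaminant > vector > low_complexity`; every excluded
#' gene carries exactly one primary reason, and retained plus excluded
#' counts always sum to the input count.
#'
#' @param summaries data frame with at least `gene_id` and (for the
#'   mitochondrial rule) `chrom`.
#' @param rules a [filter_rules()] object.
#' @param windows optional named list mapping `gene_id` to the character
#'   vector of its window sequences; required for the vector and
#'   low-complexity rules. A gene is excluded as low-complexity only when
#'   every one of its windows triggers the rule.
#' @return list with `retained` (data frame) and `excluded` (data frame with
#'   `gene_id`, `reason`).
#' @export
apply_filters <- function(summaries, rules = filter_rules(), windows = NULL) {
  stopifnot(inherits(rules, "filter_rules"))
  reason <- rep(NA_character_, nrow(summaries))
  if ("chrom" %in% names(summaries) && length(rules$mito_chrom_names)) {
    reason[is.na(reason) & summaries$chrom %in% rules$mito_chrom_names] <- "mitochondrial"
  }
  if (length(rules$contaminant_gene_blocklist)) {
    reason[is.na(reason) &
             summaries$gene_id %in% rules$contaminant_gene_blocklist] <- "contaminant"
  }
  if (!is.null(windows)) {
    for (i in seq_len(nrow(summaries))) {
      if (!is.na(reason[i])) next
      w <- windows[[summaries$gene_id[i]]]
      if (is.null(w) || length(w) == 0L) next
      if (length(rules$vector_sequence_patterns) &&
          any(vapply(rules$vector_sequence_patterns,
                     function(p) any(grepl(p, w, fixed = TRUE)), logical(1)))) {
        reason[i] <- "vector"
      } else if (all(is_low_complexity(w, rules$max_a_run, rules$max_a_fraction))) {
        reason[i] <- "low_complexity"
      }
    }
  }
  keep <- is.na(reason)
  list(retained = summaries[keep, , drop = FALSE],
       excluded = data.frame(gene_id = summaries$gene_id[!keep],
                             reason = reason[!keep],
                             stringsAsFactors = FALSE))
}

#' Export windows or clusters as a BED track
#'
#' Converts 1-based inclusive coordinates to BED's 0-based half-open
#' convention.
#'
#' @param intervals data frame with `chrom`, `start`, `end`, `strand` and a
#'   name column (`gene_id` used if present).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  name <- if ("gene_id" %in% names(intervals)) intervals$gene_id else "."
  bed <- data.frame(chrom = intervals$chrom,
                    start = intervals$start - 1L,
                    end = intervals$end,
                    name = name,
                    score = 0L,
                    strand = intervals$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
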