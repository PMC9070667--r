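# Seed-reproducible synthetic-data generators. Each generator restores the
# caller's RNG state, so identical (seed, parameters) give byte-identical
# output regardless of surrounding code.

with_seed <- function(seed, expr) {
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  expr
}

random_rna <- function(n, len, background = rep(0.25, 4)) {
  vapply(seq_len(n), function(i) {
    paste(sample(RNA_BASES, len, replace = TRUE, prob = background), collapse = "")
  }, character(1))
}

#' Simulate an RNAcompete-style probe library
#'
#' Generates Set A and Set B probe tables with guaranteed k-mer coverage: in
#' each set, every 7-mer is deliberately placed in `coverage` designed
#' probes (7-mers concatenated into probe-length sequences with random
#' filler), so each 7-mer occurs at least `coverage` times per set. Probe
#' intensity is the maximum relative affinity over the 7-mers the probe
#' contains, times multiplicative lognormal noise.
#'
#' @param affinity_map named numeric vector mapping 7-mers to relative
#'   affinities; unlisted 7-mers get `background_affinity`.
#' @param n_probes total probes over both sets; `NULL` (default) uses the
#'   minimum that achieves the coverage target; smaller values are rejected
#'   with the required minimum.
#' @param probe_len probe length in nt (default 38, within the 30-41 nt
#'   range typical of such libraries).
#' @param noise_sd sdlog of the multiplicative lognormal intensity noise.
#' @param seed integer seed.
#' @param background_affinity affinity of unlisted 7-mers.
#' @param coverage designed occurrences of every 7-mer per set.
#' @return probe data frame (`probe_id`, `set_label`, `sequence`,
#'   `intensity`), Sets A and B.
#' @export
simulate_rnacompete <- function(affinity_map = c(UUUUACA = 10),
                                n_probes = NULL, probe_len = 38,
                                noise_sd = 0.2, seed = 1,
                                background_affinity = 1, coverage = 5) {
  if (length(affinity_map) == 0L || is.null(names(affinity_map))) {
    stop("affinity_map must be a non-empty named vector of 7-mers", call. = FALSE)
  }
  names(affinity_map) <- rna_normalize(names(affinity_map))
  if (any(nchar(names(affinity_map)) != 7L)) {
    stop("affinity_map names must be 7-mers", call. = FALSE)
  }
  k <- 7L
  kpp <- probe_len %/% k  # designed k-mers per probe
  n_design_per_set <- coverage * ceiling(4^k / kpp)
  n_min <- 2L * n_design_per_set
  if (is.null(n_probes)) n_probes <- n_min
  if (n_probes < n_min) {
    stop("n_probes too small for coverage ", coverage,
         " of every 7-mer in both sets; minimum is ", n_min, call. = FALSE)
  }
  aff <- rep(background_affinity, 4^k)
  aff[kmer_codes_of(names(affinity_map)) + 1L] <- unname(affinity_map)
  with_seed(seed, {
    n_extra <- n_probes - n_min
    make_set <- function(label, n_extra_set) {
      seqs <- character(0)
      univ <- all_kmers(k)
      for (pass in seq_len(coverage)) {
        perm <- sample(univ)
        groups <- split(perm, ceiling(seq_along(perm) / kpp))
        seqs <- c(seqs, vapply(groups, function(g) {
          core <- paste(g, collapse = "")
          fill <- probe_len - nchar(core)
          if (fill > 0) {
            core <- paste0(core, paste(sample(RNA_BASES, fill, replace = TRUE),
                                       collapse = ""))
          }
          core
        }, character(1)))
      }
      if (n_extra_set > 0) seqs <- c(seqs, random_rna(n_extra_set, probe_len))
      win <- kmer_window_codes(seqs, k)
      peak <- rep(background_affinity, length(seqs))
      agg <- tapply(aff[win$code + 1L], win$seq_index, max)
      peak[as.integer(names(agg))] <- agg
      intensity <- peak * stats::rlnorm(length(seqs), meanlog = 0, sdlog = noise_sd)
      data.frame(probe_id = sprintf("%s_%06d", label, seq_along(seqs)),
                 set_label = label, sequence = unname(seqs),
                 intensity = intensity, stringsAsFactors = FALSE)
    }
    extra_a <- n_extra %/% 2L
    rbind(make_set("A", extra_a), make_set("B", n_extra - extra_a))
  })
}

#' Audit k-mer coverage of a probe table
#'
#' @param probes probe data frame.
#' @param k k-mer length.
#' @return named integer vector: minimum per-k-mer probe count per set.
#' @export
audit_coverage <- function(probes, k = 7) {
  vapply(split(probes$sequence, probes$set_label), function(seqs) {
    win <- kmer_window_codes(seqs, k)
    key <- as.numeric(win$seq_index) * 4^k + win$code
    keep <- !duplicated(key)
    min(tabulate(win$code[keep] + 1L, nbins = 4^k))
  }, integer(1))
}

#' U-content-graded affinity function over all 7-mers
#'
#' A smooth planted affinity landscape for simulation studies: affinity
#' grows with the longest U-run of the 7-mer, maximal for pure poly-U, with
#' a bonus for an `ACA`-style 3' anchor after a U-run. Used to emulate a
#' binder whose specificity is U-rich rather than a single word, so that
#' split-half concordance is informative.
#'
#' @param max_affinity affinity of the best 7-mer; the worst gets 1.
#' @return named numeric vector over all 4^7 7-mers.
#' @export
u_rich_affinity_map <- function(max_affinity = 10) {
  kmers <- all_kmers(7)
  runs <- vapply(kmers, function(w) {
    r <- rle(strsplit(w, "")[[1]])
    u <- r$lengths[r$values == "U"]
    if (length(u)) max(u) else 0L
  }, integer(1))
  bonus <- as.numeric(grepl("UUUUAC|UUUUA.A|UUUU.CA", kmers))
  score <- runs / 7 + 0.5 * bonus
  1 + (max_affinity - 1) * (score - min(score)) / (max(score) - min(score))
}

u_rich_words <- function() {
  tails <- all_kmers(3)
  tails <- tails[grepl("U", tails)]
  w <- paste0("UUUU", tails)
  g <- motif_grammar()
  setdiff(w, names(g$words))
}

rna_to_dna <- function(x) chartr("U", "T", x)

#' Simulate an iCLIP cohort with a toy genome
#'
#' Builds a toy genome (one main chromosome of protein-coding genes with
#' 5' UTR / CDS / 3' UTR structure on alternating strands, plus a
#' mitochondrial contig), plants motif words in the 3' UTRs of a subset of
#' genes, and places full-length-bait and domain-bait crosslink clusters
#' near the planted motifs (with Gaussian positional jitter), plus bait-
#' specific genes, contaminant loci and random control-bait clusters. The
#' ground truth records every planted role, class and position.
#'
#' @param n_genes number of protein-coding genes on the main chromosome.
#' @param utr_len 3' UTR length in nt (>= 120 so motif and window geometry
#'   fit).
#' @param class_fractions named fractions (`bona_fide`, `u_rich`, `none`)
#'   of the shared genes, summing to 1.
#' @param shared_fraction fraction of genes receiving clusters from both
#'   baits.
#' @param fl_only_fraction,nhl_only_fraction fractions receiving clusters
#'   from one bait only.
#' @param jitter_sd SD (nt) of the crosslink offset around the planted
#'   motif; draws are clipped to `[-10, 10]` so windows keep their planted
#'   motif at realistic jitter.
#' @param cluster_halfwidth clusters span `2*cluster_halfwidth + 1` nt.
#' @param contaminant_fraction fraction (of `n_genes`) of additional
#'   contaminant loci, half mitochondrial, half blocklisted host genes.
#' @param n_control_clusters clusters in the control-bait table.
#' @param background base probabilities of the genome background (A,C,G,U).
#' @param seed integer seed.
#' @param dir if non-`NULL`, also writes `genome.fa`, `annotation.gff3`,
#'   `clusters_FL.tsv`, `clusters_NHL.tsv`, `clusters_control.tsv` and
#'   `truth.tsv` there.
#' @return list with `genome` (`DNAStringSet`), `annotation` (GFF3-shaped
#'   data frame), `clusters` (all baits, one data frame), `truth`, `rules`
#'   (a [filter_rules()]) and, when `dir` is given, `paths`.
#' @export
simulate_clip_cohort <- function(n_genes = 200, utr_len = 400,
                                 class_fractions = c(bona_fide = 0.30,
                                                     u_rich = 0.30,
                                                     none = 0.40),
                                 shared_fraction = 0.25,
                                 fl_only_fraction = 0.30,
                                 nhl_only_fraction = 0.30,
                                 jitter_sd = 3, cluster_halfwidth = 2,
                                 contaminant_fraction = 0.05,
                                 n_control_clusters = 20,
                                 background = rep(0.25, 4),
                                 seed = 1, dir = NULL) {
  if (utr_len < 120) stop("utr_len too short for window geometry (need >= 120)",
                          call. = FALSE)
  if (abs(sum(class_fractions) - 1) > 1e-8) {
    stop("class_fractions must sum to 1", call. = FALSE)
  }
  if (shared_fraction + fl_only_fraction + nhl_only_fraction > 1 + 1e-8) {
    stop("role fractions must sum to at most 1", call. = FALSE)
  }
  utr_len <- as.integer(utr_len)
  n_genes <- as.integer(n_genes)
  cluster_halfwidth <- as.integer(cluster_halfwidth)
  utr5 <- 60L; cds_len <- 210L; gap <- 50L
  gene_len <- utr5 + cds_len + utr_len
  with_seed(seed, {
    chrom_len <- n_genes * (gene_len + gap) + 100L
    chr1 <- sample(RNA_BASES, chrom_len, replace = TRUE, prob = background)
    gene_start <- 50L + (seq_len(n_genes) - 1L) * (gene_len + gap) + 1L
    strand <- rep(c("+", "-"), length.out = n_genes)
    gene_id <- sprintf("SIMG%04d", seq_len(n_genes))

    n_shared <- round(shared_fraction * n_genes)
    n_fl <- round(fl_only_fraction * n_genes)
    n_nhl <- round(nhl_only_fraction * n_genes)
    role <- rep("silent", n_genes)
    perm <- sample(n_genes)
    role[perm[seq_len(n_shared)]] <- "shared"
    role[perm[n_shared + seq_len(n_fl)]] <- "fl_only"
    role[perm[n_shared + n_fl + seq_len(n_nhl)]] <- "nhl_only"

    cls <- rep(NA_character_, n_genes)
    shared_idx <- which(role == "shared")
    n_bona <- round(class_fractions[["bona_fide"]] * length(shared_idx))
    n_ur <- round(class_fractions[["u_rich"]] * length(shared_idx))
    labs <- c(rep("bona_fide", n_bona), rep("u_rich", n_ur),
              rep("none", length(shared_idx) - n_bona - n_ur))
    cls[shared_idx] <- sample(labs)

    bona_words <- names(motif_grammar()$words)
    ur_words <- u_rich_words()
    motif_word <- rep(NA_character_, n_genes)
    motif_start <- rep(NA_integer_, n_genes)  # genomic start of motif
    margin <- 45L
    clusters <- list()
    truth_fl_pos <- rep(NA_integer_, n_genes)
    truth_nhl_pos <- rep(NA_integer_, n_genes)

    utr3_bounds <- function(i) {
      g0 <- gene_start[i]
      if (strand[i] == "+") c(g0 + utr5 + cds_len, g0 + gene_len - 1L)
      else c(g0, g0 + utr_len - 1L)
    }
    jit <- function() as.integer(max(-10, min(10, round(stats::rnorm(1, 0, jitter_sd)))))
    add_cluster <- function(chrom, pos, strand, gid, bait) {
      data.frame(chrom = chrom, start = pos - cluster_halfwidth,
                 end = pos + cluster_halfwidth, gene_id = gid,
                 strand = strand, bait = bait, replicate = 1L,
                 stringsAsFactors = FALSE)
    }

    for (i in seq_len(n_genes)) {
      if (role[i] == "silent") next
      b <- utr3_bounds(i)
      if (role[i] == "shared" && cls[i] != "none") {
        w <- if (cls[i] == "bona_fide") sample(bona_words, 1) else sample(ur_words, 1)
        m0 <- sample((b[1] + margin):(b[2] - margin - 6L), 1)
        ins <- if (strand[i] == "+") strsplit(w, "")[[1]]
               else rev(chartr("ACGU", "UGCA", strsplit(w, "")[[1]]))
        chr1[m0:(m0 + 6L)] <- ins
        motif_word[i] <- w
        motif_start[i] <- m0
        anchor0 <- if (strand[i] == "+") m0 else m0 + 6L
        p_fl <- anchor0 + if (strand[i] == "+") jit() else -jit()
        p_nhl <- anchor0 + if (strand[i] == "+") jit() else -jit()
      } else {
        p0 <- sample((b[1] + margin):(b[2] - margin), 1)
        p_fl <- p0 + jit()
        p_nhl <- p0 + jit()
      }
      if (role[i] %in% c("shared", "fl_only")) {
        clusters[[length(clusters) + 1L]] <-
          add_cluster("chr1", p_fl, strand[i], gene_id[i], "FL")
        truth_fl_pos[i] <- p_fl
      }
      if (role[i] %in% c("shared", "nhl_only")) {
        clusters[[length(clusters) + 1L]] <-
          add_cluster("chr1", p_nhl, strand[i], gene_id[i], "NHL")
        truth_nhl_pos[i] <- p_nhl
      }
    }

    # contaminant loci: half on the mitochondrial contig, half blocklisted
    n_cont <- round(contaminant_fraction * n_genes)
    n_mito <- ceiling(n_cont / 2)
    n_block <- n_cont - n_mito
    mito_len <- max(1000L, n_mito * 300L + 200L)
    mito <- sample(RNA_BASES, mito_len, replace = TRUE, prob = background)
    cont_rows <- list()
    cont_truth <- list()
    if (n_mito > 0) {
      for (j in seq_len(n_mito)) {
        gid <- sprintf("MITOG%03d", j)
        g0 <- 100L + (j - 1L) * 300L
        pos <- g0 + 150L
        cont_rows[[length(cont_rows) + 1L]] <-
          rbind(add_cluster("mitochondrion_genome", pos, "+", gid, "FL"),
                add_cluster("mitochondrion_genome", pos + jit(), "+", gid, "NHL"))
        cont_truth[[length(cont_truth) + 1L]] <-
          data.frame(gene_id = gid, chrom = "mitochondrion_genome", strand = "+",
                     role = "contaminant", planted_class = NA_character_,
                     motif_word = NA_character_, motif_start = NA_integer_,
                     fl_pos = pos, nhl_pos = pos, stringsAsFactors = FALSE)
      }
    }
    blocklist <- character(0)
    if (n_block > 0) {
      silent_idx <- which(role == "silent")
      pick <- silent_idx[seq_len(min(n_block, length(silent_idx)))]
      blocklist <- gene_id[pick]
      for (i in pick) {
        b <- utr3_bounds(i)
        pos <- as.integer(floor(mean(b)))
        role[i] <- "contaminant"
        cont_rows[[length(cont_rows) + 1L]] <-
          rbind(add_cluster("chr1", pos, strand[i], gene_id[i], "FL"),
                add_cluster("chr1", pos + jit(), strand[i], gene_id[i], "NHL"))
        truth_fl_pos[i] <- pos
        truth_nhl_pos[i] <- pos
      }
    }

    # control bait: random clusters on random genes
    ctrl <- lapply(seq_len(n_control_clusters), function(j) {
      i <- sample(n_genes, 1)
      b <- utr3_bounds(i)
      add_cluster("chr1", sample(b[1]:b[2], 1), strand[i], gene_id[i], "control")
    })

    clusters_df <- do.call(rbind, c(clusters, cont_rows, ctrl))
    rownames(clusters_df) <- NULL

    genome <- Biostrings::DNAStringSet(c(
      chr1 = rna_to_dna(paste(chr1, collapse = "")),
      mitochondrion_genome = rna_to_dna(paste(mito, collapse = ""))))

    annotation <- make_annotation(gene_id, gene_start, strand,
                                  utr5, cds_len, utr_len)
    truth <- data.frame(gene_id = gene_id, chrom = "chr1", strand = strand,
                        role = role, planted_class = cls,
                        motif_word = motif_word, motif_start = motif_start,
                        fl_pos = truth_fl_pos, nhl_pos = truth_nhl_pos,
                        stringsAsFactors = FALSE)
    if (length(cont_truth)) truth <- rbind(truth, do.call(rbind, cont_truth))
    rules <- filter_rules(mito_chrom_names = "mitochondrion_genome",
                          contaminant_gene_blocklist = blocklist)
    out <- list(genome = genome, annotation = annotation,
                clusters = clusters_df, truth = truth, rules = rules)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      paths <- list(
        genome = file.path(dir, "genome.fa"),
        annotation = file.path(dir, "annotation.gff3"),
        fl = file.path(dir, "clusters_FL.tsv"),
        nhl = file.path(dir, "clusters_NHL.tsv"),
        control = file.path(dir, "clusters_control.tsv"),
        truth = file.path(dir, "truth.tsv"))
      Biostrings::writeXStringSet(genome, paths$genome)
      write_gff3(annotation, paths$annotation)
      for (b in c(FL = "FL", NHL = "NHL", control = "control")) {
        write_cluster_table(clusters_df[clusters_df$bait == b, , drop = FALSE],
                            paths[[c(FL = "fl", NHL = "nhl",
                                     control = "control")[[b]]]])
      }
      utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      out$paths <- paths
    }
    out
  })
}

make_annotation <- function(gene_id, gene_start, strand, utr5, cds_len, utr_len) {
  rows <- lapply(seq_along(gene_id), function(i) {
    g0 <- gene_start[i]
    gene_len <- utr5 + cds_len + utr_len
    if (strand[i] == "+") {
      segs <- data.frame(
        type = c("gene", "five_prime_UTR", "CDS", "three_prime_UTR"),
        start = c(g0, g0, g0 + utr5, g0 + utr5 + cds_len),
        end = c(g0 + gene_len - 1L, g0 + utr5 - 1L, g0 + utr5 + cds_len - 1L,
                g0 + gene_len - 1L))
    } else {
      segs <- data.frame(
        type = c("gene", "three_prime_UTR", "CDS", "five_prime_UTR"),
        start = c(g0, g0, g0 + utr_len, g0 + utr_len + cds_len),
        end = c(g0 + gene_len - 1L, g0 + utr_len - 1L,
                g0 + utr_len + cds_len - 1L, g0 + gene_len - 1L))
    }
    segs$chrom <- "chr1"
    segs$strand <- strand[i]
    segs$gene_id <- gene_id[i]
    segs
  })
  do.call(rbind, rows)
}

#' Write a GFF3-shaped annotation data frame
#'
#' @param annotation data frame with `chrom`, `type`, `start`, `end`,
#'   `strand`, `gene_id`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  lines <- sprintf("%s\tclipmotif_sim\t%s\t%d\t%d\t.\t%s\t.\tgene_id=%s",
                   annotation$chrom, annotation$type, annotation$start,
                   annotation$end, annotation$strand, annotation$gene_id)
  writeLines(lines, con)
  invisible(path)
}

#' Simulate a noisy titration series
#'
#' Fraction bound from [hill_model()] plus additive Gaussian noise, one or
#' more replicates on a serial-dilution design.
#'
#' @param Kd,hill_n,f_low,f_high Hill parameters (see [hill_model()]).
#' @param noise_sd SD of the additive Gaussian noise on fraction bound.
#' @param design concentration vector, e.g. from [dilution_series()].
#' @param n_replicates number of replicate series.
#' @param seed integer seed.
#' @param clip clip reported fractions to `[0, 1]`?
#' @return data frame (`replicate_id`, `concentration`, `fraction_bound`).
#' @export
simulate_titration <- function(Kd, hill_n = 1, noise_sd = 0.05,
                               design = dilution_series(), seed = 1,
                               f_low = 0, f_high = 1, n_replicates = 1,
                               clip = FALSE) {
  truth <- hill_model(design, Kd, hill_n, f_low, f_high)
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      fb <- truth + stats::rnorm(length(design), 0, noise_sd)
      if (clip) fb <- pmin(pmax(fb, 0), 1)
      data.frame(replicate_id = r, concentration = design, fraction_bound = fb)
    }))
    rownames(out) <- NULL
    out
  })
}
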