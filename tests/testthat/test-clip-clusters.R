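make_clusters <- function(gene_id, start, end, strand = "+", chrom = "chr1",
                          bait = "FL") {
  data.frame(chrom = chrom, start = start, end = end, gene_id = gene_id,
             strand = strand, bait = bait, replicate = 1L,
             stringsAsFactors = FALSE)
}

test_that("cluster tables round-trip and reject malformed rows with line numbers", {
  cl <- make_clusters(c("g1", "g2", "g3"), c(100, 200, 300), c(110, 210, 330),
                      strand = c("+", "-", "+"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cluster_table(cl, path)
  back <- read_cluster_table(path)
  expect_equal(back, cl)

  bad_strand <- cl
  bad_strand$strand[2] <- "."
  write_cluster_table(bad_strand, path)
  expect_error(read_cluster_table(path), "strand token at line 3")

  bad_coord <- cl
  bad_coord$start[3] <- 400
  write_cluster_table(bad_coord, path)
  expect_error(read_cluster_table(path), "start > end at line 4")

  incomplete <- cl[, setdiff(names(cl), "gene_id")]
  write.table(incomplete, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_cluster_table(path), "gene_id")
})

test_that("cluster extension is strand-aware and truncates at coordinate 1", {
  plus <- make_clusters("g1", 100, 110, "+")
  expect_equal(extend_cluster(plus)[, c("start", "end")],
               data.frame(start = 80, end = 120))
  minus <- make_clusters("g1", 100, 110, "-")
  expect_equal(extend_cluster(minus)[, c("start", "end")],
               data.frame(start = 90, end = 130))
  near_edge <- make_clusters("g1", 5, 10, "+")
  expect_message(ext <- extend_cluster(near_edge), "truncated")
  expect_equal(ext$start, 1)
  expect_equal(ext$end, 20)
})

test_that("shared-gene overlap computes union percentage and the 50-nt rule", {
  fl <- make_clusters(c("g1", "g2", "g3"), c(1, 1, 1), c(10, 10, 10))
  nhl <- make_clusters(c("g2", "g3", "g4"), c(5, 100, 1), c(15, 110, 10),
                       bait = "NHL")
  ov <- shared_gene_overlap(fl, nhl)
  expect_identical(ov$stats$n_shared, 2L)
  expect_equal(ov$stats$overlap_pct, 50)
  # boundary of the <=50 rule: gap of exactly 50 is equivalent, 51 is not
  fl2 <- make_clusters("g", 1, 10)
  nhl_50 <- make_clusters("g", 61, 70, bait = "NHL")
  nhl_51 <- make_clusters("g", 62, 70, bait = "NHL")
  expect_true(shared_gene_overlap(fl2, nhl_50)$summary$position_equivalent)
  s51 <- shared_gene_overlap(fl2, nhl_51)$summary
  expect_equal(s51$min_distance, 51)
  expect_false(s51$position_equivalent)
  # intersecting clusters are at distance 0
  both <- shared_gene_overlap(fl2, make_clusters("g", 5, 20, bait = "NHL"))
  expect_equal(both$summary$min_distance, 0)
  expect_error(shared_gene_overlap(fl[0, ], nhl), "non-empty")
})

test_that("overlap percentage matches a brute-force set oracle", {
  set.seed(17)
  for (i in 1:25) {
    a_genes <- sample(sprintf("g%02d", 1:30), sample(3:20, 1))
    b_genes <- sample(sprintf("g%02d", 1:30), sample(3:20, 1))
    fl <- make_clusters(a_genes, seq_along(a_genes) * 100,
                        seq_along(a_genes) * 100 + 10)
    nhl <- make_clusters(b_genes, seq_along(b_genes) * 100,
                         seq_along(b_genes) * 100 + 10, bait = "NHL")
    ov <- shared_gene_overlap(fl, nhl)
    expect_equal(ov$stats$overlap_pct,
                 100 * length(intersect(a_genes, b_genes)) /
                   length(union(a_genes, b_genes)))
  }
})

test_that("distances are invariant under coordinate mirroring", {
  set.seed(29)
  M <- 100000L
  fl <- make_clusters(rep("g", 5), sample(1000:5000, 5), numeric(5))
  fl$end <- fl$start + sample(5:50, 5)
  nhl <- make_clusters(rep("g", 5), sample(1000:5000, 5), numeric(5),
                       bait = "NHL")
  nhl$end <- nhl$start + sample(5:50, 5)
  mirror <- function(cl) {
    out <- cl
    out$start <- M - cl$end
    out$end <- M - cl$start
    out$strand <- ifelse(cl$strand == "+", "-", "+")
    out
  }
  d1 <- shared_gene_overlap(fl, nhl)$summary$min_distance
  d2 <- shared_gene_overlap(mirror(fl), mirror(nhl))$summary$min_distance
  expect_equal(d1, d2)
})

test_that("filters assign one reason with precedence and conserve counts", {
  summaries <- data.frame(
    gene_id = c("ok", "mito", "sno_host", "vec", "polya"),
    chrom = c("chr1", "mitochondrion_genome", "chr1", "chr1", "chr1"),
    stringsAsFactors = FALSE)
  windows <- list(
    ok = "ACGUACGUACGUACGUACGU",
    mito = "ACGUACGUACGUACGUACGU",
    sno_host = "ACGUACGUACGUACGUACGU",
    vec = "GGGACUAGUCCCGGGACGUA",
    polya = strrep("A", 40))
  rules <- filter_rules(mito_chrom_names = "mitochondrion_genome",
                        contaminant_gene_blocklist = "sno_host",
                        vector_sequence_patterns = "ACUAGUCCCGGG")
  res <- apply_filters(summaries, rules, windows)
  expect_identical(nrow(res$retained) + nrow(res$excluded), nrow(summaries))
  expect_identical(res$retained$gene_id, "ok")
  got <- setNames(res$excluded$reason, res$excluded$gene_id)
  expect_identical(got[["mito"]], "mitochondrial")
  expect_identical(got[["sno_host"]], "contaminant")
  expect_identical(got[["vec"]], "vector")
  expect_identical(got[["polya"]], "low_complexity")
  # precedence: a mitochondrial gene that is also blocklisted stays mitochondrial
  rules2 <- filter_rules(mito_chrom_names = "mitochondrion_genome",
                         contaminant_gene_blocklist = "mito")
  res2 <- apply_filters(summaries, rules2, windows)
  expect_identical(res2$excluded$reason[res2$excluded$gene_id == "mito"],
                   "mitochondrial")
  # empty blocklists are the identity filter (only the always-on
  # low-complexity thresholds remain, which ordinary windows never trigger)
  ordinary <- summaries[summaries$gene_id != "polya", ]
  res0 <- apply_filters(ordinary, filter_rules(), windows[ordinary$gene_id])
  expect_identical(nrow(res0$excluded), 0L)
})

test_that("low-complexity rule triggers on A-runs and high A fraction", {
  expect_true(is_low_complexity(strrep("A", 15), 15, 0.8))
  expect_false(is_low_complexity(paste0(strrep("A", 14), "CGCGCG"), 15, 0.8))
  expect_true(is_low_complexity("AAAAAAAAACAAAAAAAAGA", 15, 0.8))  # 90% A, run 9
})

test_that("BED export converts to 0-based half-open coordinates", {
  cl <- make_clusters("g1", 100, 110)
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(cl, path)
  bed <- read.table(path, sep = "\t")
  expect_identical(bed$V2, 99L)
  expect_identical(bed$V3, 110L)
  expect_identical(bed$V4, "g1")
})
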