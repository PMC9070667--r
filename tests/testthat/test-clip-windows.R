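toy_genome <- function(seq = NULL, len = 100, seed = 13) {
  if (is.null(seq)) {
    set.seed(seed)
    seq <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
  }
  Biostrings::DNAStringSet(c(contig = seq))
}

test_that("window extraction matches direct indexing on a toy contig", {
  g <- toy_genome()
  s <- as.character(g[["contig"]])
  w <- extract_window(g, "contig", 50, "+")
  expect_identical(nchar(w), 51L)
  expect_identical(as.character(w), chartr("T", "U", substr(s, 20, 70)))
  expect_false(attr(w, "truncated"))
  # minus strand: reverse complement of bases 30..80
  wm <- extract_window(g, "contig", 50, "-")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(s, 30, 80))))
  expect_identical(as.character(wm), chartr("T", "U", rc))
  # truncation at the contig start: positions 1..30 only
  wt <- extract_window(g, "contig", 10, "+")
  expect_identical(nchar(wt), 30L)
  expect_true(attr(wt, "truncated"))
  expect_error(extract_window(g, "contig", 500, "+"), "outside contig")
  expect_error(extract_window(g, "nope", 10, "+"), "not in genome")
  expect_error(extract_window(g, "contig", 10, "."), "strand")
})

test_that("gene models round-trip through GFF3 and match rtracklayer", {
  sim <- simulate_clip_cohort(n_genes = 6, utr_len = 150, seed = 3,
                              contaminant_fraction = 0, n_control_clusters = 0)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(sim$annotation, path)
  models <- read_gene_models(path)
  expect_identical(length(models), 6L)
  m1 <- models[["SIMG0001"]]
  expect_setequal(m1$features$feature,
                  c("five_prime_utr", "cds", "three_prime_utr"))
  ann1 <- sim$annotation[sim$annotation$gene_id == "SIMG0001", ]
  expect_identical(m1$start, min(ann1$start))
  expect_identical(m1$end, max(ann1$end))
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path)
    expect_identical(length(gr), nrow(sim$annotation))
    expect_identical(sum(gr$type == "gene"), 6L)
  }
})

test_that("feature assignment picks maximal overlap with documented tie-breaks", {
  gm <- list(gene_id = "g", chrom = "chr1", strand = "+",
             start = 1, end = 300,
             features = data.frame(
               feature = c("five_prime_utr", "cds", "three_prime_utr"),
               start = c(1, 61, 201), end = c(60, 200, 300)))
  expect_identical(assign_feature(list(start = 210, end = 250), gm),
                   "three_prime_utr")
  # 10 nt in CDS (191..200), 30 nt in 3' UTR (201..230)
  expect_identical(assign_feature(list(start = 191, end = 230), gm),
                   "three_prime_utr")
  expect_identical(assign_feature(list(start = 61, end = 100), gm), "cds")
  # exact tie CDS vs 3' UTR resolved in favour of the 3' UTR
  expect_identical(assign_feature(list(start = 196, end = 205), gm),
                   "three_prime_utr")
  expect_warning(lab <- assign_feature(list(start = 400, end = 420), gm),
                 "noncoding")
  expect_identical(lab, "noncoding")
})

test_that("clusters planted in 3' UTRs are assigned to the modal 3' UTR category", {
  sim <- simulate_clip_cohort(n_genes = 40, utr_len = 200, seed = 11,
                              contaminant_fraction = 0, n_control_clusters = 0)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(sim$annotation, path)
  models <- read_gene_models(path)
  cl <- sim$clusters[sim$clusters$bait == "FL", ]
  labels <- vapply(seq_len(nrow(cl)), function(i) {
    assign_feature(cl[i, ], models[[cl$gene_id[i]]])
  }, character(1))
  tab <- table(labels)
  expect_identical(names(tab)[which.max(tab)], "three_prime_utr")
})

test_that("gene motif classes follow precedence and cohort report is coherent", {
  res <- gene_motif_summary(list(
    g_bona = c("GGGGGGGGGG", "ACAUUUUACAACA"),
    g_urich = "ACAUUUUCUGACA",
    g_none = "ACGUACGUACGUACG"))
  cls <- setNames(res$genes$motif_class, res$genes$gene_id)
  expect_identical(cls[["g_bona"]], "bona_fide")
  expect_identical(cls[["g_urich"]], "u_rich")
  expect_identical(cls[["g_none"]], "none")
  expect_identical(res$cohort$n_motif_positive, 2L)
  expect_equal(res$cohort$expected_f,
               null_window_probability(50)$probability)
  expect_equal(res$cohort$enrichment,
               (1 / 3) / res$cohort$expected_f)
  expect_error(gene_motif_summary(list()), "no genes")
})

test_that("end-to-end synthetic cohort recovers planted structure", {
  sim <- simulate_clip_cohort(seed = 19)
  fl <- sim$clusters[sim$clusters$bait == "FL", ]
  nhl <- sim$clusters[sim$clusters$bait == "NHL", ]
  res <- clip_target_analysis(fl, nhl, sim$genome, rules = sim$rules)
  truth_shared <- sum(!is.na(sim$truth$fl_pos) & !is.na(sim$truth$nhl_pos))
  expect_lte(abs(res$report$n_shared - truth_shared), 1)
  # contaminants are the excluded loci
  n_cont <- sum(sim$truth$role == "contaminant")
  expect_identical(res$report$n_excluded, n_cont)
  expect_identical(res$report$n_retained, res$report$n_shared - n_cont)
  # planted motif genes detected at >= 95% sensitivity; planted bona fide
  # genes keep their exact class, while a planted u_rich gene may be
  # upgraded to bona_fide when background U residues flank the planted word
  # (class precedence) — it still counts as motif-positive
  truth <- sim$truth
  got <- setNames(res$motifs$genes$motif_class, res$motifs$genes$gene_id)
  motif_genes <- truth$gene_id[!is.na(truth$planted_class) &
                                 truth$planted_class != "none"]
  motif_genes <- intersect(motif_genes, names(got))
  expect_gte(mean(got[motif_genes] != "none"), 0.95)
  bona <- intersect(truth$gene_id[!is.na(truth$planted_class) &
                                    truth$planted_class == "bona_fide"],
                    names(got))
  expect_gte(mean(got[bona] == "bona_fide"), 0.95)
  none_genes <- intersect(
    truth$gene_id[!is.na(truth$planted_class) & truth$planted_class == "none"],
    names(got))
  expect_lte(mean(got[none_genes] == "bona_fide"), 0.05)
})

test_that("zero jitter places every planted motif inside its window", {
  sim <- simulate_clip_cohort(n_genes = 60, seed = 23, jitter_sd = 0,
                              contaminant_fraction = 0)
  fl <- sim$clusters[sim$clusters$bait == "FL", ]
  nhl <- sim$clusters[sim$clusters$bait == "NHL", ]
  res <- clip_target_analysis(fl, nhl, sim$genome, rules = sim$rules)
  truth <- sim$truth
  got <- setNames(res$motifs$genes$motif_class, res$motifs$genes$gene_id)
  planted <- truth[!is.na(truth$planted_class) & truth$planted_class != "none", ]
  # every planted gene is motif-positive (bona fide may upgrade a planted
  # u_rich gene only if the background adds a bona fide word nearby)
  expect_true(all(got[planted$gene_id] != "none"))
  bona <- planted$gene_id[planted$planted_class == "bona_fide"]
  expect_true(all(got[bona] == "bona_fide"))
})
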