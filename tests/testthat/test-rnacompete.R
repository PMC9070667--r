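make_probes <- function(seqs, intensity, set_label = "A") {
  data.frame(probe_id = sprintf("%s_%03d", set_label, seq_along(seqs)),
             set_label = set_label, sequence = seqs, intensity = intensity,
             stringsAsFactors = FALSE)
}

test_that("aggregate scores are trimmed means over containing probes", {
  probes <- make_probes(c("AAAAAAAC", "CAAAAAAA", "GGGGGGGG"), c(2, 4, 6))
  tab <- aggregate_kmer_scores(probes)$A
  expect_equal(tab$aggregate_score[tab$kmer == "AAAAAAA"], 3)  # probes 1 and 2
  expect_equal(tab$aggregate_score[tab$kmer == "GGGGGGG"], 6)
  # absent 7-mer flagged missing, not scored
  expect_true(tab$missing[tab$kmer == "UUUUUUU"])
  expect_identical(tab$n_probes[tab$kmer == "UUUUUUU"], 0L)
  # constant intensities give every scored 7-mer the same score
  const <- aggregate_kmer_scores(make_probes(c("ACGUACGUA", "CCCCCCCC"), c(5, 5)))$A
  expect_true(all(const$aggregate_score[!const$missing] == 5))
  expect_error(aggregate_kmer_scores(probes[0, ]), "empty")
  expect_error(aggregate_kmer_scores(probes, trim_fraction = 0.5), "trim_fraction")
})

test_that("aggregation is invariant to probe order and counts probes once", {
  set.seed(3)
  seqs <- vapply(1:40, function(i) rand_rna(20), character(1))
  probes <- make_probes(seqs, runif(40, 1, 10))
  t1 <- aggregate_kmer_scores(probes)$A
  t2 <- aggregate_kmer_scores(probes[sample(40), ])$A
  expect_equal(t1, t2)
  # a 7-mer occurring twice in one probe contributes that probe once
  dup <- make_probes(c("UUUUUUUUUU", "UUUUUUUC"), c(8, 2))
  td <- aggregate_kmer_scores(dup)$A
  expect_equal(td$aggregate_score[td$kmer == "UUUUUUU"], 5)
  expect_identical(td$n_probes[td$kmer == "UUUUUUU"], 2L)
})

test_that("z-scoring has the closed form with population SD and ranks deterministically", {
  tab <- data.frame(kmer = c("AAAAAAA", "AAAAAAC", "AAAAAAG"),
                    aggregate_score = c(2, 4, 6), n_probes = 1L,
                    missing = FALSE, stringsAsFactors = FALSE)
  z <- zscore_and_rank(tab)
  expect_equal(z$z_score, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_identical(z$rank, c(3L, 2L, 1L))
  # tie broken lexicographically
  tie <- tab
  tie$aggregate_score <- c(6, 6, 2)
  zt <- zscore_and_rank(tie)
  expect_identical(zt$rank, c(1L, 2L, 3L))
  all_equal <- tab
  all_equal$aggregate_score <- 5
  expect_error(zscore_and_rank(all_equal), "degenerate score distribution")
})

test_that("z tables are standardised and scale-invariant", {
  probes <- simulate_rnacompete(seed = 21, noise_sd = 0.2)
  tabs <- lapply(aggregate_kmer_scores(probes), zscore_and_rank)
  for (tab in tabs) {
    z <- tab$z_score[!tab$missing]
    expect_lt(abs(mean(z)), 1e-12)
    expect_lt(abs(sqrt(mean(z^2)) - 1), 1e-12)
  }
  # doubling intensities doubles scores, leaves Z and ranks unchanged
  probes2 <- probes
  probes2$intensity <- probes2$intensity * 2
  t1 <- zscore_and_rank(aggregate_kmer_scores(probes)$A)
  t2 <- zscore_and_rank(aggregate_kmer_scores(probes2)$A)
  expect_equal(t2$aggregate_score, t1$aggregate_score * 2)
  expect_equal(t2$z_score, t1$z_score)
  expect_identical(t2$rank, t1$rank)
})

test_that("planted word ranks first and ranking is trim-insensitive without noise", {
  probes <- simulate_rnacompete(c(UUUUACA = 10), noise_sd = 0, seed = 9)
  ranks <- lapply(c(0, 0.1, 0.25), function(tr) {
    tabs <- lapply(aggregate_kmer_scores(probes, trim_fraction = tr),
                   zscore_and_rank)
    vapply(tabs, function(t) t$rank[t$kmer == "UUUUACA"], integer(1))
  })
  for (r in ranks) expect_true(all(r == 1L))
})

test_that("split-half concordance has the expected limiting behaviour", {
  probes <- simulate_rnacompete(seed = 33)
  tabs <- lapply(aggregate_kmer_scores(probes), zscore_and_rank)
  same <- split_half_concordance(tabs$A, tabs$A)
  expect_equal(same$rank_correlation, 1)
  expect_equal(same$pearson_correlation, 1)
  neg <- tabs$A
  neg$z_score <- -neg$z_score
  expect_equal(split_half_concordance(tabs$A, neg)$rank_correlation, -1)
  expect_equal(same$table$z_avg, tabs$A$z_score)
  # mismatched universes rejected with the difference count
  truncated <- tabs$B[-(1:3), ]
  expect_error(split_half_concordance(tabs$A, truncated), "universes differ")
})

test_that("split halves of a graded affinity landscape agree strongly", {
  # per-k-mer coverage 15 per set, as in dense designed libraries; the
  # Z-score scatter between halves then correlates > 0.9, while rank
  # correlation stays lower because the low-affinity bulk is noise-ranked
  probes <- simulate_rnacompete(u_rich_affinity_map(), noise_sd = 0.2,
                                seed = 41, coverage = 15)
  tabs <- lapply(aggregate_kmer_scores(probes), zscore_and_rank)
  conc <- split_half_concordance(tabs$A, tabs$B)
  expect_gt(conc$pearson_correlation, 0.9)
  expect_gt(conc$rank_correlation, 0.4)
})

test_that("consensus construction aligns and degenerates only where words disagree", {
  same <- consensus_from_top(rep("UUUUACA", 10))
  expect_identical(same$consensus, "UUUUACA")
  expect_true(all(colSums(same$pfm) == 10))
  expect_true(all(apply(same$pfm, 2, max) == 10))
  two <- consensus_from_top(c("UUUUUUU", "UUUUACA"))
  expect_identical(substr(two$consensus, 1, 4), "UUUU")
  # positions 5-7 disagree (U vs A, U vs C, U vs A) -> degenerate codes
  expect_identical(substr(two$consensus, 5, 7), "WYW")
  expect_error(consensus_from_top(c("UUUUACA", "UUUUAC")), "same length")
  expect_error(consensus_from_top("UUUUACA"), "at least 2")
})

test_that("top-10 consensus from a U-rich landscape keeps a poly-U core", {
  probes <- simulate_rnacompete(u_rich_affinity_map(), noise_sd = 0.2, seed = 55)
  res <- rnacompete_analysis(probes)
  expect_true(grepl("UUU", res$consensus$consensus))
  # PFM column sums never exceed the word count and total to 7 per word
  expect_true(all(colSums(res$consensus$pfm) <= nrow(res$consensus$alignment)))
  expect_identical(sum(res$consensus$pfm), 7L * nrow(res$consensus$alignment))
})

test_that("probe tables round-trip through TSV", {
  probes <- make_probes(c("ACGUACGUA", "UUUUACAGG"), c(1.5, 2.5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_probe_table(probes, path)
  back <- read_probe_table(path)
  expect_equal(back, probes)
})
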