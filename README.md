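# clipmotif

Characterising the sequence specificity and cellular targets of a
single-stranded-RNA-binding protein — the kind of analysis needed for
TRIM-NHL proteins whose NHL β-propeller domain binds short U-rich RNA
motifs. The package is aimed at computational biologists who have (a)
RNAcompete-style probe-intensity tables, (b) iCLIP crosslink-cluster tables
for two immunoprecipitation baits (full-length protein vs isolated
domain), and/or (c) fraction-bound titration series, and who want the
whole chain — motif scoring, target classification, null models,
enrichment, binding constants — reproducible from the command line or from
R.

## What it computes

**Motif grammar.** Bona fide binding sites are exact matches to the four
degenerate heptamers `UUUUACN`, `UUUUANA`, `UUUUNCA`, `UUUUUUU` (11
distinct words, 13 counted per pattern); U-rich sites are `UUUU` followed
by 3 nt containing at least one more U, minus the bona fide set. Windows
are scanned exhaustively with bona fide > U-rich precedence.

**Null models and enrichment.** The chance frequency *f* of a bona fide
site in a random *L*-mer is available in the conventional summed-count
independence form, `1 − (1 − 13/4⁷)^(L−6)` (3.4% at L = 50), and as an
exact transfer-matrix computation over the deduplicated word set (2.8% at
L = 50), with a seed-deterministic Monte-Carlo cross-check. Enrichment is
the observed/expected ratio.

**Split-half 7-mer scoring.** Probe intensities → per-7-mer trimmed-mean
aggregate scores → Z-scores (population SD, mean 0 / SD 1 by construction)
→ ranks, separately for probe Sets A and B, with a Z-score scatter table,
split-half concordance, and an IUPAC consensus motif built from the top-10
average-Z 7-mers by greedy offset alignment (MEME-style export).

**iCLIP target analysis.** Cluster extension (20/10 nt, strand-aware),
bait-overlap percentage `100·|A∩B|/|A∪B|`, the ≤ 50 nt positional
equivalence rule, contaminant filters (mitochondrial / blocklist / vector /
low-complexity, one reason each), −30/+20 nt windows around crosslink
anchors, gene-level motif classification, transcript-feature assignment,
and a JSON cohort report.

**Hill fits.** `f = f_low + (f_high − f_low)·c^n/(K_d^n + c^n)` by bounded
Levenberg–Marquardt with a deterministic initializer and multi-start,
per-replicate fits aggregated as mean ± SD of K_d, and honest flags for
unidentifiable or boundary-pinned fits.

**Synthetic data.** Seed-reproducible generators for probe libraries with
guaranteed 7-mer coverage, toy genomes with planted motifs and crosslink
clusters (plus contaminants and decoys), and noisy titration curves — so
every stage of the pipeline is testable without downloads.

## Worked example

```r
library(clipmotif)

null_window_probability(50)
#> Null model (summed_pattern_counts, independence): P(>=1 match in 50 nt) = 0.0343231
null_window_probability(50, "distinct_words")
#> Null model (distinct_words, exact): P(>=1 match in 50 nt) = 0.0280762

# synthetic iCLIP cohort -> target analysis
sim <- simulate_clip_cohort(seed = 1)
fl  <- subset(sim$clusters, bait == "FL")
nhl <- subset(sim$clusters, bait == "NHL")
res <- clip_target_analysis(fl, nhl, sim$genome, rules = sim$rules)
res$report[c("n_shared", "overlap_pct", "n_retained")]
#> $n_shared    [1] 60
#> $overlap_pct [1] 33.33333
#> $n_retained  [1] 50
res$motifs$cohort$counts
#> $bona_fide [1] 17   $u_rich [1] 13   $none [1] 20
res$motifs$cohort$enrichment
#> [1] 9.906648

# Hill fit on a 3-replicate titration
titr <- simulate_titration(Kd = 1.7, noise_sd = 0.03, seed = 1, n_replicates = 3)
fit_hill(titr)
#> Hill fits over 3 replicate(s) (3 converged): Kd = 1.73 +/- 0.167
```

Reading the numbers: of 60 genes bound by both baits, 50 survive the
contaminant filters; 17 carry a bona fide motif within −30/+20 nt of a
crosslink anchor — about 9.9-fold more than the 3.4% expected in random
50-mers — and the fitted dissociation constant recovers the planted
1.7 µM within its replicate scatter. The first two lines show the two null
conventions side by side: the summed-count independence approximation
(the 3.4% convention) and the exact deduplicated probability (2.8%).

The same stages run from the shell via the thin wrapper:

```sh
Rscript inst/cli/clipmotif.R simulate --out runs/sim --seed 1
Rscript inst/cli/clipmotif.R clip --fl runs/sim/clusters_FL.tsv \
    --nhl runs/sim/clusters_NHL.tsv --genome runs/sim/genome.fa --out runs/clip
Rscript inst/cli/clipmotif.R motifs --null-window-len 50 --out runs/null
```

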