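---
title: "Models and methods behind clipmotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind clipmotif}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clipmotif)
```

`clipmotif` characterises the sequence specificity and cellular targets of a
single-stranded-RNA-binding protein — the use case is a TRIM-NHL family
protein whose β-propeller NHL domain recognises short U-rich motifs — from
two complementary kinds of evidence: in vitro probe-binding intensities
(RNAcompete-style) and in-cell crosslink clusters (iCLIP-style). This
vignette explains each model, the tunable parameters and their defaults,
what the synthetic-data generators do and do not emulate, and the numerical
choices made where the design was genuinely open.

## The motif grammar

Two disjoint motif classes are defined over 7-nt windows:

* **bona fide** sites: exact matches to `UUUUACN`, `UUUUANA`, `UUUUNCA` or
  `UUUUUUU`. Expanded, these four degenerate patterns contain 13 words
  counted per pattern and 11 distinct words (`UUUUACA` satisfies all three
  degenerate patterns).
* **U-rich** sites: four consecutive uridines followed by three nucleotides
  containing at least one additional U, *excluding* anything that is already
  bona fide.

Bona fide takes precedence at every level — word, window and gene — so the
two classes partition motif-positive material. This matters because a word
such as `UUUUUCA` satisfies both definitions, and downstream per-class
counts would otherwise double-count. Overlapping matches are all reported
(`scan_window()` classifies every 7-nt window); gene-level presence is
"at least one match in any window".

`T` is silently normalised to `U` and lowercase is upper-cased throughout,
so DNA-alphabet genomes and RNA-alphabet motifs mix freely.

## Occurrence null models

The headline enrichment statistic compares the observed fraction of
motif-positive targets with the chance frequency *f* of at least one bona
fide word in a random fragment. `null_window_probability()` exposes two
counting conventions:

* `summed_pattern_counts` (default): per-pattern word counts are summed
  *without* deduplication (13 words), and the per-position probability
  `p = 13/4^7` is turned into a window probability with the
  positional-independence approximation `1 - (1 - p)^(L - 6)`. For `L = 50`
  this gives 0.0343, i.e. the conventional "3.4% of random 50-mers" figure.
* `distinct_words`: the deduplicated 11-word set. Here the default method is
  an **exact** transfer-matrix computation: dynamic programming over the
  4096 possible 6-mer suffix states, which correctly accounts for the
  clumping of matches caused by self-overlapping words (poly-U runs
  especially). The exact value for `L = 50` is 0.02808 — measurably below
  the independence approximation of 0.02912. A 10^7-sample Monte-Carlo check
  during development agreed with the exact value to within sampling error
  and sat about 6 standard errors (at n = 10^6) away from the approximation,
  which is why the approximation is *not* used as the reference for the
  deduplicated mode; it remains available as `method = "independence"`.

`null_monte_carlo()` draws i.i.d. windows from the background and scans
them, as an empirical cross-check of either analytic mode; it is
seed-deterministic and reports the binomial standard error.

The background composition defaults to uniform (0.25 per base). The
background behind the printed 3.4% convention is not knowable from the
figure itself; the summed-counts/uniform/independence combination
reproduces it exactly, so that combination is the default, and both modes
are always reported by the pipeline's `motifs` stage so the reader can see
the gap. User-supplied compositions (e.g. U-enriched 3' UTR backgrounds)
are accepted for sensitivity analysis.

## RNAcompete-style split-half scoring

Probe intensities are aggregated per 7-mer as a symmetric trimmed mean
(default `trim_fraction = 0.025`) of the intensities of probes containing
the 7-mer, each probe counted once. The trimmed mean is the conventional
robust statistic for this assay family; the fraction is configurable and,
on noise-free data, the ranking is invariant to it. Z-scores use the
population standard deviation (the sample/population distinction is
negligible at 16,384 7-mers but is stated for exactness), and ranks break
ties lexicographically so results are deterministic. No inter-array
normalisation is applied — this is a single-protein analysis — though a
per-set median-scaling switch would be trivial to add upstream.

Split-half concordance reports both the Spearman rank correlation and the
Pearson correlation of the two Z-score vectors. At realistic per-7-mer
coverage the Pearson scatter correlation is the sharper measure: the bulk
of 7-mers are low-affinity and their ranks are noise-dominated, which
dilutes Spearman without saying anything about the top of the table.

The consensus motif is built from the top-N (default 10) average-Z 7-mers
by greedy offset alignment: the rank-1 word seeds the alignment, each
subsequent word is placed at the integer offset within ±3 maximising
positional identity with the current frequency matrix, with ties resolved
towards offset 0, then smaller |offset|, then the negative offset. The
IUPAC consensus letter for a column includes every base with at least 25%
of the column total. The alignment algorithm is a design choice (the
underlying assay convention does not prescribe one); it is deterministic
and exposed so alternatives can be compared.

## iCLIP cluster post-processing

Cluster tables use 1-based inclusive coordinates in the supplementary-table
dialect (`chrom`, `start`, `end`, `gene_id`, `strand`); BED export converts
to 0-based half-open. The stages are:

1. **Extension**: clusters are extended 20 nt upstream and 10 nt downstream
   in transcript orientation (strand-aware, truncated at coordinate 1).
2. **Bait overlap**: the gene sets targeted by the full-length protein and
   the isolated domain are intersected; the overlap percentage is
   `100·|A∩B|/|A∪B|`. For each shared gene the minimum gap between any
   FL×NHL cluster pair is computed — intersecting intervals count as
   distance 0, otherwise the gap is the number of nucleotides strictly
   between them — and genes with gap ≤ 50 nt are "position-equivalent".
   The positional-equivalence fraction is reported both over all shared
   loci and over the retained (post-filter) loci, since either denominator
   is defensible.
3. **Filtering**: mitochondrial chromosomes, blocklisted contaminant host
   genes (snoRNA/scaRNA/snRNA and similar), vector-derived sequence
   patterns, and low-complexity windows, applied in that precedence order
   so each excluded gene carries exactly one primary reason. Blocklists
   ship empty (identity filter) because the curation is dataset-specific.
   The low-complexity rule — homopolymer-A run ≥ 15 nt or > 80% A, both
   configurable — excludes a gene only when *every* window triggers it.
4. **Windows**: around each crosslink anchor, the window spans 30 nt
   upstream to 20 nt downstream in transcript orientation (51 nt away from
   contig ends; minus-strand windows are reverse-complemented). When
   explicit crosslink positions are not provided, the anchor defaults to
   the cluster's strand-aware 5'-most coordinate, with a midpoint mode as
   an alternative — which nucleotide of a cluster is "the" crosslink is an
   upstream-pipeline detail this package does not re-derive.
5. **Gene classification**: bona fide if any window has a bona fide match,
   else U-rich if any window has a U-rich match, else none. A gene counts
   once regardless of cluster or replicate multiplicity. The cohort report
   includes the enrichment of the bona fide fraction over the null *f*
   (by default the summed-counts 50-mer convention, so the enrichment is
   comparable with the published ninefold figure).
6. **Feature assignment**: a cluster is labelled with the transcript
   feature of maximal overlap, ties resolved 3' UTR > 5' UTR > CDS >
   intron, and `noncoding` (with a warning) when nothing overlaps.

## Hill binding fits

`fit_hill()` fits `f = f_low + (f_high − f_low)·c^n/(Kd^n + c^n)` to
fraction-bound titrations by bounded Levenberg–Marquardt. The baseline and
plateau are *fitted* by default (bounds [−0.2, 1.2]) because fraction-bound
normalisation of real thermophoresis data is imperfect; the Hill
coefficient is bounded to [0.3, 4] and boundary-pinned parameters are
flagged rather than silently accepted. The initializer is deterministic
(Kd₀ = concentration nearest half-maximal response, n₀ = 1, extremes for
the baselines) and a three-point multi-start over Hill-coefficient starting
values (1, 0.5, 2) guards against boundary-pinned local minima of the
box-constrained objective; the converged fit never has a larger residual
sum of squares than the initializer's curve. Replicates are fitted
separately and the dissociation constant aggregated as mean ± SD, matching
the convention of reporting K_d from at least three independent
experiments. Any of n, f_low, f_high can be held fixed (`fix_n`,
`fix_f_low`, `fix_f_high`); whether the Hill coefficient should be fitted
or pinned at 1 is left to the user because the underlying convention is
ambiguous.

A caution on identifiability that the package's own tests respect: with the
standard 16-point 3:1 dilution from 5 µM and additive noise of 0.05 on the
fraction bound, the dissociation constant is *not* identifiable to 15%
relative error when all four parameters are free — the Cramér–Rao bound on
SD(K̂d)/Kd ranges from 0.12 to above 1 across Kd ∈ {0.5, 1.7, 5} µM and
n ∈ {1, 2}, because the plateau is barely observed when Kd approaches the
top concentration. The package's recovery study therefore holds the
generator-known nuisance parameters (n, f_low = 0, f_high = 1) at their
true values, where the empirical RMSE is 8–14% (matching the
one-free-parameter Cramér–Rao bound), while the noise-free check exercises
the fully free fit and recovers all parameters to well under 1%. Users
fitting real data at similar noise should expect correspondingly wide Kd
intervals unless replicates are pooled or the plateau is constrained.

## Synthetic data: what it emulates and what it does not

All generators are seed-deterministic (they restore the caller's RNG state)
and emit files that parse through the package's own readers. Defaults were
fixed once, before the test suite was finalised:

* `simulate_rnacompete()`: probes of 38 nt; every 7-mer deliberately placed
  in 5 designed probes per set (16,385 probes per set at the default), so
  coverage is guaranteed rather than probabilistic; probe intensity is the
  maximum affinity over contained 7-mers times lognormal noise
  (`sdlog = 0.2`); planted single-word landscapes use affinity 10 against
  background 1, and `u_rich_affinity_map()` provides a graded U-run-driven
  landscape for concordance studies. Not emulated: microarray image
  processing, spatial artefacts, cross-experiment normalisation — so
  passing tests say nothing about those stages.
* `simulate_clip_cohort()`: 200 genes of 5' UTR (60 nt) / CDS (210 nt) /
  3' UTR (400 nt) on alternating strands of one chromosome plus a
  mitochondrial contig; 25% of genes receive clusters from both baits, 30%
  from each single bait; shared genes carry planted classes in proportions
  0.30/0.30/0.40 (bona fide / U-rich / none); crosslink positions jitter
  around the planted motif with SD 3 nt (clipped at ±10 so the planted
  motif stays within reach of the window at realistic jitter); clusters
  span 5 nt; 5% contaminant loci (half mitochondrial, half blocklisted) and
  20 random control-bait clusters. Background composition is uniform; real
  3' UTRs are U/A-enriched, which would *raise* the background motif rate,
  so the false-positive rates measured here are optimistic for real data —
  a U-enriched background can be passed for sensitivity analysis. Note one
  behaviour that is correct rather than a defect: a gene planted with a
  U-rich word can be classified bona fide when background uridines flank
  the planted word, because class precedence is applied to the realised
  sequence, not to the generator's intent. Not emulated: read-level
  structure (FASTQ, UMIs, truncation positions), peak calling, alignment.
* `simulate_titration()`: Hill curve plus additive Gaussian noise
  (default SD 0.05) on the 16-point 3:1 design from 5 µM.

## Problem sizes in the shipped tests

The suite verifies the scanner against a naive regex oracle on 10^4 random
sequences of lengths 7–200, the Monte-Carlo null at 10^6 samples for the
acceptance check (10^5 for the per-module invariant), planted-word
top-ranking across 100 generator seeds, Hill recovery on 50 seeds per grid
point, and one full 200-gene cohort end-to-end per acceptance run. These
sizes give comfortable statistical margins for every asserted tolerance
while keeping a full run in the minutes range on one CPU.

## Known limitations

* The motif grammar is exact-match/rule-based by design; there is no
  position-weight-matrix scoring and no secondary-structure awareness
  (hairpin-recognising proteins need a different model).
* The cluster reader expects the supplementary-table dialect; richer GFF3
  annotations than the emitted five feature types must be reduced to a
  representative transcript upstream.
* Differential binding statistics, peak calling and read processing are
  out of scope; the pipeline starts from called clusters.
* The published target-accounting figures (751/623 genes per bait, 249
  shared, 214 retained, 128/65/63 motif split) can be recomputed by the
  package only when the corresponding supplementary tables are supplied by
  the user; they are third-party data and are not shipped.
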