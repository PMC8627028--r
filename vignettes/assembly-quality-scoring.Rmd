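---
title: "Scoring genome assemblies without a reference: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring genome assemblies without a reference: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmqual)
```

## The problem

De novo genome assemblies usually cannot be validated by comparison with a
trusted reference, because for most organisms no trusted reference exists.
Contiguity statistics (N50, scaffold counts, gap percent) are cheap but say
nothing about accuracy; a misjoin *raises* N50. `asmqual` scores an assembly
on continuity, completeness **and** accuracy using only the assembly itself
plus a paired-end short-read library, by (1) computing a fixed suite of 13
quality metrics, several of which are derived base-by-base from read
mapping, and (2) collapsing them into a single score with a regression
model trained against reference-based quality scores. Because the score is
learned against an absolute reference-based target, scores from the same
model are comparable across assemblies and across organisms — the property
that distinguishes this approach from likelihood rankings (ALE) or feature
response curves (FRCbam), which only order assemblies of the same genome.

## The metric suite

One metric row describes one scored unit (a whole assembly, or one
sequence scored alone). The 13 model-facing metrics, in the package's
canonical column order (`METRIC_NAMES`):

| metric | source | meaning |
|---|---|---|
| `normN50` | sequence | scaffold N50 as % of total length (100 = single piece) |
| `gap_perc` | sequence | % of bases that are N |
| `prop_pair_perc` | mapping | reads in proper pairs / mapped reads × 100 |
| `FCD_err_in_contig`, `FCD_err_over_gap` | mapping | % bases where the fragment-coverage profile deviates from a local flat fit |
| `low_fc_in_contig`, `low_fc_over_gap` | mapping | % bases with fragment depth < 25% of the global mean |
| `links` | mapping | % bases covered by ≥2 pairs whose mates map elsewhere |
| `clip` | mapping | % bases inside clustered soft-clip anchor windows |
| `coll_repeat` | mapping | % bases in sustained >2× fragment-depth runs |
| `low_read_cov` | mapping | % bases with read depth < 25% of the global mean |
| `error_free_bases` | mapping | % bases with ≥5× perfectly matching, unclipped coverage and no error flag |
| `norm_contig_number` | sequence | contigs per Mbp |

All mapping metrics are percents of total bases, so chromosomes of
different lengths are directly comparable. Every depth threshold is
*relative to the run's global mean depth*, so 10× and 30× libraries behave
alike; the recommended minimum is 10× coverage with an insert of roughly
350–550 bp, matching the conditions the bundled-model approach was
designed for.

The per-base flag engine re-derives, natively and deterministically, the
evidence classes that reference-free validators extract from alignments:
clip clusters at breakpoints, physical (fragment) coverage dropouts,
fragment-coverage-distribution (FCD) anomalies, distant/cross-sequence
mate links, collapsed repeats, and the complementary "error-free base"
certificate. The FCD statistic here is a windowed mean absolute deviation
between the fragment-depth profile and its running median (window = one
insert mean), flagged where it exceeds 0.3× the mean fragment depth; the
original tooling's exact statistic is treated as a black box, and only the
monotone behaviour of the metric matters because models are retrained
against metrics produced by *this* engine. The first and last insert-mean
bases of each sequence are excluded from FCD/low-fragment flagging:
fragments cannot fully cover sequence ends, so physical coverage is
depressed there by construction, not by misassembly.

## The read mapper

Reads are placed by a deterministic k-mer seed-and-extend mapper (Rcpp):
exact 17-mer seeds every 8 bp vote for (target, diagonal) candidates; the
best candidates get an ungapped extension (match +1, mismatch −3) whose
maximal-scoring segment defines the alignment, with the unaligned read
ends recorded as soft clips. Alignments with fewer matching bases than
`min_identity` × read length are dropped — 0.5 by default for
chromosome-scale scoring, 0.75 recommended for scaffolds, where spurious
mapping is more likely. Ties break by (matches, mismatches, target order,
position, strand), so output is reproducible bit-for-bit. A
coordinate-level SAM/BAM import (`read_alignments()`) can replace the
built-in mapper; a SAM written by `write_sam()` round-trips to identical
metric rows, which is the tested hand-off contract.

Proper pairs are defined here as: same target, opposite strands, FR
orientation, insert within mean ± 3 sd. Insert statistics are estimated
robustly (median / MAD) from the data unless supplied; supplying them is
necessary when scoring heavily damaged assemblies, where too few clean
pairs remain to estimate the library geometry.

## Reference-based training targets

Where a trusted reference exists (for model building), quality is anchored
in the **percent of matching bases**:

$$\mathrm{PMB} = \frac{L_\mathrm{ref} - \mathrm{differences}}{L_\mathrm{ref}} \times 100$$

`count_differences()` defines `differences` as the number of reference
bases that a match-maximising 1-to-1 alignment cannot pair with an
identical query base — substitutions, deleted blocks and unaligned
reference sequence all count, and a self-comparison gives exactly 0. The
aligner chains unique 21-mer anchors with a weighted
longest-increasing-subsequence DP and closes inter-anchor regions with an
exact match-maximising dynamic program (banded only above 4×10⁷ cells).
One consequence of match maximisation worth knowing: an isolated
substitution can occasionally be "rescued" through a compensating gap
pair, so the difference count can undershoot an injected-SNP truth count
by ~1%; the count always agrees exactly with a quadratic-time alignment
oracle computing the same quantity.

Raw PMB values are not directly comparable across chromosomes or
organisms, so two scaling rounds follow, both driven by the Euclidean
distance between a chromosome's metric vector and the *ideal* vector
(`normN50` 100, `gap_perc` 0, `prop_pair_perc` 100, `error_free_bases`
100, every error flag 0). Within an organism, the chromosome closest to
ideal keeps its PMB and every other is multiplied by
$1 - (d_i - d_\mathrm{best})/D$; across organisms the same factor is
applied per organism using best-chromosome distances. The normaliser $D$
is fixed: the distance from the ideal vector to the all-worst vector
(every metric at its worst 0–100 bound), $D = 100\sqrt{12}$. This linear
factor is this package's design choice — it is the simplest map that keeps
the best instance fixed, decreases in distance, and is scale-free across
organisms; any alternative satisfying those constraints could be swapped
in at `internal_scale()`/`external_scale()`. `norm_contig_number` is
excluded from the distance set because it has no finite worst bound, which
would leave $D$ undefined; the 12 retained metrics all live on a 0–100
scale.

Scores above 100 are legal and meaningful at prediction time: they mark
sequences whose metrics beat the best training instance.

## Feature selection

The cascade mirrors standard practice for small, collinear feature sets:

1. **Pearson filter** — drop metrics with |r| < 0.1 against the target
   (only a very weak linear relationship).
2. **Pairwise correlations** — reported, with |r| > 0.8 pairs flagged, to
   expose multicollinearity.
3. **JMIM** — greedy joint-mutual-information maximisation (first pick
   maximises I(X;Y); later picks maximise the minimum joint information
   with any already-selected feature). Continuous metrics are discretised
   by equal-frequency binning, 10 bins (configurable); ties break by
   column order, making the ranking deterministic. The lowest-ranked
   features (default: 2) are dropped as redundant.
4. **Permutation importance** — %IncMSE from a 500-tree random forest's
   out-of-bag permutation test; the smallest (default: 2) are dropped.
5. **Exhaustive subset regression** — OLS on every subset of the surviving
   candidates up to size 6; the winning subset is the lowest-RSS one that
   contains no feature whose fitted coefficient sign contradicts its
   marginal correlation sign. This *sign-contradiction rule* formalises
   the exclusion of metrics whose regression weight is a collinearity
   artefact; exclusions are reported, never silent.

## Model training and selection

Six regression families are compared on one shared seeded 80/20 split,
each tuned by minimising cross-validated RMSE (all via caret): a general
linear model (10-fold CV, 10 repeats), elastic net (10-fold CV, α ∈
{0,…,1}, λ log-spaced 10⁻⁴–10), k-nearest neighbours (10-fold CV, 5
repeats, odd k 3–21, standardised inputs), random forest (10-fold CV, 500
trees, mtry ∈ {2,4,6}), and linear/polynomial SVMs (5-fold CV, cost ∈
{0.25,…,4}, degree 2–3, standardised inputs). Test-set performance is
reported as RMSE and R²; R² is primarily the squared Pearson correlation
between predicted and observed scores, with the 1 − SS_res/SS_tot variant
also reported since the two diverge for biased predictions. The family
with the lowest test RMSE wins (ties: higher R², then fixed family order)
and is refit on the full table. Every random draw — split, folds,
bootstraps, permutations — flows from one integer seed recorded in the
model's provenance metadata, and a saved model (metadata JSON + estimator)
round-trips to identical predictions.

## The simulators and what they do (not) show

The package tests and examples run entirely on simulated data:

- `random_genome()` draws i.i.d. bases (GC 0.41) — deliberately
  structure-free.
- `mutate_assembly()` injects SNPs, geometric(0.5)-sized indels (cap 50
  bp), tandem duplications/deletions, and N-gap conversions, never inside
  existing gaps, with a coordinate truth log.
- `fragment_assembly()` and `translocate_assembly()` vary contiguity and
  create breakpoint junctions with known coordinates.
- `simulate_reads()` draws normal(450, 50) fragments at uniform positions,
  20× coverage and 150 bp reads by default, FR orientation, Bernoulli base
  errors (0.001 default).
- `generate_training_set()` wires everything together: reads are simulated
  from the *pristine* source and mapped to the *degraded* copy, so mapping
  evidence reflects the injected damage exactly as real reads reveal real
  misassemblies; reference scoring then supplies the training target.

Its default degradation gradient mixes all error classes at five
increasing severities (SNPs up to 15%, indels, CNVs, gaps, fragmentation
to 20 pieces) so a trained model sees variation in every feature. For
studying score-versus-error-rate response, a pure SNP ladder (0–20% or
0–30% in 5% steps) is the standard configuration; under it the score
response is sigmoid — nearly flat at low rates, steepest between the 10%
and 15% levels, flattening as the mapping signal saturates — which the
acceptance suite asserts as an ordering of consecutive score drops.

What passing these tests does **not** show: real genomes have repeats, GC
bias, heterozygosity and sequencer-specific error profiles that i.i.d.
simulation cannot produce, so absolute metric levels (especially
`coll_repeat`, `links` and clip backgrounds) will differ on real data.
The simulation results validate the machinery — flag localisation,
monotone degradation response, model recovery — not any particular
real-data operating point. Models intended for real assemblies must be
trained on metric tables from real (or realistically simulated) genomes.

## Numerical choices and degenerate inputs

- Coordinates are 0-based half-open internally; BED convention on disk.
- Lowercase (soft-masked) bases count as their uppercase equivalents; N
  matches nothing, including N.
- Contigs split at N-runs ≥ 1 by default (`min_gap` configurable); both
  scaffold- and contig-level N50 are emitted, scaffold `normN50` feeds the
  model.
- `norm_contig_number` is contigs per Mbp — the simplest length
  normalisation; it is dropped by the Pearson filter in practice.
- Zero mapped reads, zero mean depth, zero target variance, empty tables
  and missing features are hard errors with the offending name in the
  message; zero-variance features and constant predictions degrade with a
  warning (feature removed; R² reported as 0).
- Mean read depth below 2× is a hard stop; below 10× warns, citing the
  recommended minimum.

Problem sizes used by the test and acceptance suites — 20–200 kb genomes,
15–20× coverage, 6–20 genomes × 3–5 degradation levels, 10 split seeds —
were chosen so that coverage statistics concentrate well clear of the
asserted thresholds while the whole suite stays desk-scale.

## Known limitations

- The mapper is ungapped within an alignment; an indel inside a read
  surfaces as a clip, not an I/D operation. Breakpoint *localisation* is
  unaffected (and is what the flags consume), but per-read identity near
  small indels is conservative.
- Difference counting is match-maximising (see above): a strict
  substitution-only count can differ by ~1% at high SNP densities.
- The external-scaling anchor is only as good as the best assembly in the
  training cohort; scores from models trained on different cohorts (or
  different feature sets, such as an N50-free variant) are not comparable
  with each other.
- Scoring scaffolds shorter than a few Mb is unreliable at default
  stringency; raise `min_identity` to 0.75 and interpret with care.
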