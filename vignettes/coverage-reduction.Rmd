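---
title: "Evaluating coverage reduction in shotgun metagenomics profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating coverage reduction in shotgun metagenomics profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shallowmeta)
```

## The question

Shotgun metagenomics sequencing classifies every read in a library
against a reference database, yielding a species-level abundance
profile of a complex sample. Sequencing depth is the dominant cost, so
a practical question is how shallow an experiment can be before its
taxonomic summaries — which species are present, how abundant they
are, how diverse the community is, how samples relate to each other —
stop being trustworthy. shallowmeta implements the evaluation pipeline
for that question: calibrate a detection rule on a community of known
composition, then subsample reads to a ladder of depths with
replication and measure how each summary statistic degrades.

## Detection-threshold calibration

The reference is a *staggered mock community*: 20 bacterial species
mixed at deliberately unequal abundances, five species at each of
0.02%, 0.18%, 1.8% and 18% (`mock_spec()`). Scoring an observed
profile against the declared list gives confusion counts: a declared
species observed at or above a candidate abundance threshold is a true
positive, below it a false negative, and any non-declared species above
the threshold a false positive. Because the universe of absent species
is unbounded, performance is summarised by the F1 score

$$F_1 = \frac{2\,TP}{2\,TP + FP + FN},$$

the harmonic mean of precision and recall. Sweeping the threshold over
a grid (`threshold_sweep()`, 0.001–0.5% by default) and taking the F1
maximiser (`best_threshold()`, ties toward the smaller threshold)
yields the operating rule used everywhere else in the package: **a
species is present when supported by at least 10 reads and at least
0.1% relative abundance**, both comparisons inclusive. The inclusive
boundary matters: a species observed at exactly 0.1% is detected, one
at 0.096% is not.

Two subtleties are worth recording. First, the packaged benchmark
abundance table censors values below 0.1%, so thresholds under 0.1%
cannot be re-scored from it; the pipeline scores the full grid from
the packaged confusion counts (recomputing F1 from the printed
TP/FP/FN) and cross-checks the recomputable rows against the abundance
column. Second, the detection threshold is applied to the fraction of
*classified* species-level reads (`basis = "classified"`); the
`"total"` basis (including unclassified reads) is available because
classifier reports express their fraction column that way.

## Subsampling model

Reduced coverage is emulated by drawing a fixed number of reads from a
profile (`subsample_profile()`). The default draw is **multivariate
hypergeometric** — without replacement over the finite set of observed
reads, with the unclassified pool as one category — which is exactly
what subsampling the raw read files would do. Sampling is implemented
by sequential conditional hypergeometric draws, so cost is linear in
the number of species regardless of depth, and a draw at the full
depth returns the profile unchanged. A multinomial (infinite-pool)
variant serves when the source is a declared composition rather than a
finite read set. Upsampling is refused: depth reduction only.

`depth_series()` runs the replicated experiment: by default depths of
10,000 / 25,000 / 50,000 / 100,000 / 250,000 / 500,000 / 1,000,000
reads, five replicates per depth, and a two-sided 99% confidence
interval on the replicate mean. The interval is Student-t with
`n_reps - 1` degrees of freedom — the minimal defensible choice at five
replicates — with an empirical-percentile alternative; the confidence
level is an explicit parameter because conventions differ between 95%
and 99% in this literature. Replicate seeds derive deterministically
from one master seed and the (depth, replicate) cell, so a whole grid
is reproducible from a single integer.

## Diversity statistics

Alpha diversity uses the classical quantities, computed (by
convention, configurable) on the species passing the detection rule
with abundances renormalised over that set:

* observed taxa $S$: the number of detected species;
* Shannon index $H = -\sum_i p_i \ln p_i$ (nats), via vegan;
* Pielou evenness $J = H / \ln S$, with $\ln S$ the maximum $H$
  attainable at richness $S$.

For the declared staggered mock these evaluate to $H = 1.9703$ and
$J = 0.6577$; the test suite freezes both against an independent
direct-summation oracle. Agreement between a full and a reduced
profile is measured by `abundance_correlation()` — Spearman for
full-versus-reduced comparisons, Pearson (percent scale) for
expected-versus-observed — over the union of the species sets with
absent species at zero, since a reduced sample legitimately loses rare
species.

## Beta diversity under subsampling

Sample relationships are summarised by Bray–Curtis dissimilarity on
detected-species relative abundances (Hellinger/Euclidean available),
ordinated either by principal coordinates (deterministic; the default
for testability) or by non-metric multidimensional scaling with seeded
multi-start (20 random starts, best Kruskal stress-1 kept), which is
the conventional choice for community data. The stability of the
ordination under depth reduction is quantified by Procrustes
superimposition: both configurations are centred and, in the symmetric
convention, scaled to unit sum of squares; the optimal rotation
(reflections permitted) comes from the singular decomposition of the
cross-product, and the agreement statistic is
$r = \sqrt{1 - m^2}$ with $m^2$ the standardised residual sum of
squares. `protest()` attaches a permutation p-value by shuffling row
order, $p = (1 + \#\{r_{perm} \ge r\})/(n_{perm}+1)$, so 999
permutations give a floor of 0.001; with very few samples the
permutation engine enumerates all row orders and the p-value is exact
instead. Dissimilarity measure and NMDS dimensionality are stated
defaults (Bray–Curtis, 2-D), not forced choices.

## Synthetic classifier output

No sequencing data ships with the package; a simulator provides
classifier-style inputs.

* `simulate_profile()` draws reads multinomially from a declared
  composition and passes each through a **misclassification kernel**:
  per true species, a set of emitted labels with probabilities plus an
  unclassified rate (probabilities summing to one). The default model
  is the identity kernel with a single sister-species leak —
  *Escherichia coli* reads emitted as *Shigella flexneri* with
  probability 0.007 — the minimal mechanism that reproduces the
  characteristic lone false positive of real mock-community profiles
  (expected frequency $18\% \times 0.007 = 0.126\%$, just above the
  0.1% rule). Abundances are read fractions; genome-size weighting is
  deliberately omitted because declared compositions and classifier
  tables are both expressed as read fractions.
* `simulate_study()` builds a heterogeneous multi-sample panel.
  Species weights come from a log-normal species-abundance
  distribution (σ = 1 by default; log-series available), and the
  candidate pool size is searched so that the number of species at or
  above 0.1% of the normalised composition matches the richness
  target; reads are then drawn multinomially at the design depth. The
  packaged panel reproduces the richness (4–138 species) and depth
  (1.3–12.5 million reads) ranges of a real ten-sample
  coverage-reduction panel. Samples draw their species from a shared
  300-name pool so that cross-sample dissimilarities have structure.

What the simulator does **not** emulate: sequence content and
sequencing error (reads are abstract labels, so read-length and
trimming effects are out of scope), database incompleteness,
strain-level ambiguity beyond the single configured leak, and
compositional correlations between species. Tests passing on these
synthetics therefore demonstrate the statistical machinery —
subsampling laws, estimator behaviour, threshold logic — not classifier
accuracy on real communities.

## Gene recovery

The assembly-completeness stage is summarised, not re-run: a
`gene_recovery_table()` holds per-species fractions of conserved
single-copy genes found complete, fragmented, or missing; the
*reconstructed* proportion is complete + fragmented, and the
per-sample figure is its unweighted mean over detected species
(`mean_recovery()`), with a detected-but-unassessed species an error
rather than a silent zero. `simulate_recovery()` provides the
depth-dependence: per species, mean coverage
$c = \text{depth} \times \text{fraction} \times L / G$, genes
discretised into read-length bins, each bin covered with the
Lander–Waterman probability $1 - e^{-c}$; a gene is complete when all
bins are covered, fragmented when some are. Reusing one seed across
depths couples the uniform draws, making recovery monotone
non-decreasing in depth seed-for-seed. The model ignores assembly
contiguity, so it is optimistic about *fragmented* recovery at low
coverage — at one million reads nearly every gene of a 1.8%-abundance
species has at least one covered bin, while the *complete* fraction
separates the 18% and 1.8% tiers sharply. Comparisons between
abundance tiers are therefore made on the complete fraction; the
qualitative claims the simulator supports are the depth monotonicity
and the tier ordering, not literal completeness values.

## Numerical and design choices

* Threshold comparisons are inclusive (≥) at both the read and the
  fraction rule; sweep ties break toward the smaller threshold.
* F1 is carried at full precision; published-table comparisons round
  to two decimals.
* The hypergeometric subsampler is exact (sequential `rhyper()`), not
  an approximation; the test suite checks it against the closed-form
  multivariate hypergeometric pmf by exhaustive enumeration on totals
  ≤ 8.
* Seeded functions restore the caller's RNG state, and all grids
  derive per-cell seeds from one master integer below $2^{31}$.
* Degenerate inputs fail loudly: empty profiles cannot be normalised,
  single-species vectors have no evenness, configurations with
  mismatched sample ids cannot be superimposed, and a requested depth
  above the available total names the offending depth.
* Percent-to-count fixture conversion uses half-up rounding at the
  declared full-sample total and warns if rounding would flip any
  species across the 0.1% boundary.

## Problem sizes

The shipped defaults run the full study in well under a minute on one
core: a mock community simulated at its full depth of 4,969,245 reads,
the seven-depth × five-replicate subsampling grid, a ten-sample panel
at 1.3–12.5 million reads each, 999-permutation Procrustes tests per
depth, and 100-gene recovery tables for 20 species. The test suite
uses the same machinery at reduced sizes (e.g. 200 simulated draws for
the leakage expectation, 20 seeds for monotonicity checks, 200 trials
for permutation-test calibration), chosen so each Monte-Carlo
assertion retains a ≥3σ margin.

## Worked sketch

```{r example, eval = FALSE}
# calibrate: the packaged benchmark column vs the declared mock
obs <- abundance_vector(fixture_column("nt"), basis = "classified")
sw <- threshold_sweep(obs, mock_spec(), c(0.1, 0.5))
best_threshold(sw)

# simulate and subsample
p <- simulate_profile(mock_spec(), depth = 1e6, seed = 1)
ds <- depth_series(p, metric = observed_taxa, seed = 1,
                   depths = c(1e4, 1e5, 5e5))
ds

# or run every stage at once
run_pipeline(list(seed = 1), out_dir = tempfile("covrun"))
```

## Known limitations

Species identity is an exact string match on binomial names (no
taxonomy-ID resolution); genus/phylum aggregation is out of scope. The
simulator's misclassification kernel is first-order (one read, one
label) and cannot express database-conditional behaviour. Procrustes
p-values with fewer than about seven samples are exact-enumeration
values rather than the 0.001-floor convention. The gene-recovery model
is a coverage model, not an assembler, and should be read
qualitatively.
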