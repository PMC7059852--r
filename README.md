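# shallowmeta

How shallow can a shotgun metagenomics experiment be before its
taxonomic summaries degrade? `shallowmeta` is an R package for
answering that question with a reproducible evaluation pipeline, aimed
at researchers planning sequencing budgets for complex samples (gut,
food, environmental, defined mixtures) and at anyone benchmarking a
taxonomic classifier against a mock community.

The package implements:

* **Detection-threshold calibration** on a staggered mock community
  (20 species at 0.02/0.18/1.8/18% declared abundance): confusion
  counts against the declared composition and the F1 score
  `F1 = 2·TP / (2·TP + FP + FN)`, swept over a threshold grid to pick
  the operating rule (≥ 10 reads and ≥ 0.1% relative abundance, both
  inclusive).
* **Replicated depth subsampling**: exact multivariate hypergeometric
  draws (without replacement, unclassified reads as one category) over
  a 10,000–1,000,000-read ladder, five replicates per depth, Student-t
  confidence bands (99% by default).
* **Alpha-diversity depth curves**: observed taxa `S`, Shannon
  `H = −Σ pᵢ ln pᵢ` (nats), Pielou evenness `J = H / ln S`, computed on
  detection-filtered, renormalised abundances.
* **Abundance agreement**: Spearman/Pearson correlation between full
  and depth-reduced profiles over the species union (absent = 0).
* **Beta-diversity stability**: Bray–Curtis dissimilarity, PCoA/NMDS
  ordination, Procrustes superimposition (`r = sqrt(1 − m²)`) with the
  PROTEST permutation test.
* **Gene-recovery summaries**: completeness tables (complete /
  fragmented / missing gene fractions), the mean reconstructed
  proportion over detected species, and a Lander–Waterman coverage
  simulator (`P(base covered) = 1 − e^{−c}`) for the depth dependence.
* **A synthetic community/classifier simulator** — staggered
  compositions, a configurable misclassification kernel
  (sister-species leakage, unclassified rate), and multi-sample study
  panels spanning 4–138 species — so every stage runs with no
  sequencing data and no network.

Profiles are exchanged as Bracken-style species-report TSVs
(`read_bracken_tsv()` / `write_bracken_tsv()`), and small transcriptions
of the published benchmark tables ship with the package
(`load_fixture()`).

## Worked example

```r
library(shallowmeta)

# 1. Calibrate the detection threshold on the packaged benchmark:
#    the mock community profiled against the nt database, scored
#    against its declared composition.
obs <- abundance_vector(fixture_column("nt"), basis = "classified")
threshold_sweep(obs, mock_spec(), c(0.1, 0.5))
#>   threshold tp fp fn        f1
#> 1       0.1 14  1  6 0.8000000
#> 2       0.5 10  0 10 0.6666667
```

At a 0.1% threshold, 14 of 20 declared species are recovered, the six
misses are dominated by the 0.02% tier (undetectable by construction),
and the lone false positive is *Shigella flexneri* — read leakage from
its sister species *E. coli*. F1 = 0.8 beats the stricter 0.5%
threshold (F1 = 0.67), so 0.1% is the operating rule.

```r
# 2. Simulate classifier output for the mock and check the declared
#    alpha diversity.
p <- simulate_profile(mock_spec(), depth = 1e6, seed = 1)
p
#> <taxon_profile> sample: sim
#>   species: 20  classified reads: 1e+06  unclassified: 0
#>   Escherichia coli                    180,653
#>   Staphylococcus epidermidis          180,396
#>   ...
shannon(declared_abundances(mock_spec()))  # 1.97028 nats
pielou(declared_abundances(mock_spec()))   # 0.6576956

# 3. Depth curve of observed richness on a rich synthetic sample
#    (138 species, steep log-normal abundance distribution).
d <- study_design("M2_like", richness = 138, depth = 1.5e6, sigma = 2)
prof <- simulate_study(d, seed = 1)[[1]]
depth_series(prof, depths = c(1e4, 1e5, 1e6),
             metric = observed_taxa, seed = 1)
#> <depth_series> metric: observed_taxa  ( 5 replicates, 99% CI )
#>  depth  mean ci_low ci_high
#>  1e+04 115.0 112.48  117.52
#>  1e+05 112.4 107.89  116.91
#>  1e+06 113.4 112.27  114.53
```

The richness estimate is depth-sensitive for species near the 0.1%
boundary — the confidence band at 10,000 reads is wider and its centre
biased relative to the million-read subsample, the behaviour that makes
shallow sequencing risky for very complex samples.

The whole study (calibration, mock and panel simulation, subsampling
grid, diversity and correlation tables, Procrustes stability,
gene recovery) runs end-to-end with

```r
run_pipeline(list(seed = 1), out_dir = "covrun")
report_tables("covrun")
```

writing one TSV per stage plus a manifest sufficient to reproduce every
output byte-for-byte. A thin command-line wrapper lives at
`inst/scripts/run_pipeline.R`.

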