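# detoxshift

Comparative RNA-Seq analysis of detoxification-gene expression across a
cryptic species complex feeding on multiple host plants.

Cryptic species complexes of generalist herbivores (the motivating system is
the whitefly *Bemisia tabaci*, six species on four host plants) pose a
recurring analytical question: are expression differences in the
detoxification system — P450 monooxygenases, glutathione S-transferases,
carboxylesterases, UDP-glucosyltransferases, sulfotransferases and ABC
transporters — shaped by phylogeny, or by the species' ability to perform on
many hosts? `detoxshift` packages the full computational chain of that
comparison for reuse: host-range survey clustering, ancestral host-state
reconstruction, negative-binomial differential expression with
fold-change/FDR thresholds, rule-based gene classification, a
clustering-by-performance-group permutation null, and survival-assay
statistics — together with a synthetic-data generator with known ground
truth, so every stage is testable without any sequencing data.

## What it computes

* **Host-range survey** (`binary_euclidean_distance`,
  `hierarchical_cluster`, `cut_into_k`, `shared_taxa`): species-groups are
  clustered from a binary presence/absence matrix over host taxa using
  Euclidean distance, d(i,j) = sqrt(#columns where i and j differ), with
  complete linkage (UPGMA by flag) and a deterministic lexicographic
  tie-break.
* **Ancestral host states** (`mk_likelihood`, `estimate_rate_ml`,
  `marginal_ancestral`, `mp_reconstruct`, `ancestral_host_report`): each
  host taxon is a binary character evolving under the equal-rates Mk model;
  over a branch of length *t* at rate *q*, P(change) = (1 − e^(−2qt))/2.
  The likelihood is computed by Felsenstein pruning with a stationary
  (1/2, 1/2) root prior, the rate by bounded 1-D maximum likelihood,
  node probabilities by marginal (all-tips) reconstruction, and
  most-parsimonious state sets by unit-cost Sankoff passes. Multifurcating
  nodes are handled natively.
* **Differential expression** (`filter_low_counts`,
  `size_factors_median_ratio`, `estimate_dispersion`, `nb_wald_test`,
  `adjust_bh`, `regularized_log`): genes need ≥ 10 reads in ≥ 4 % of
  samples; normalization is median-of-ratios; the test is a self-contained
  NB Wald statistic on log2 fold changes (Var = μ + αμ²; delta-method SE)
  with Benjamini–Hochberg correction across all retained genes. Thresholds
  follow the study design: |log2FC| ≥ 1 for constitutive between-species
  contrasts on the common host, ≥ 0.58 (1.5-fold) for plastic
  within-species contrasts, both at padj ≤ 0.05.
* **Gene classification** (`constitutive_unique`, `plastic_sets`,
  `shared_machinery`, `family_enrichment`, `classification_report`):
  constitutively unique genes must beat *every* other species in the same
  direction; plastic genes respond within a species after transfer off the
  common host; the shared "essential detoxification machinery" keeps genes
  plastic in more than one species with a consistent direction in at least
  two. Family enrichment is a 6-category chi-squared (df = 5) against the
  catalog's family proportions.
* **Clustering null** (`mean_profiles`, `standardize_per_gene`,
  `pearson_dissimilarity`, `bipartition_success`, `random_subset_null`,
  `pca_correlation`, `variance_partition`): species × plant mean profiles
  are standardized per gene, clustered with Pearson dissimilarity
  (1 − r) and complete linkage, and a trial succeeds only if every
  species' profiles are contiguous and the top split equals the
  high/low performance grouping; 500 random gene subsets of 266 give the
  permutation null with empirical p = (successes + 1)/(trials + 1).
* **Survival statistics** (`arcsine_sqrt`, `two_way_anova`,
  `dunn_sidak_pairwise`, `performance_letters`): arcsine-square-root
  transformed proportions, two-way ANOVA, and step-down sequential
  Bonferroni pairwise comparisons at Dunn–Šidák levels
  α′ᵢ = 1 − (1 − α)^(1/(m − i + 1)) with compact letter displays.
* **Synthetic data** (`simulate_counts`, `simulate_mk_history`,
  `simulate_survival`, `default_scenario`): NB counts over the 6 × 4 × 3
  factorial with a 298-gene catalog embedded in 25,000 background genes and
  planted constitutive/plastic/machinery classes; Mk-evolved binary
  characters; binomial or beta-binomial survival.

## Worked example

```r
library(detoxshift)

sim  <- simulate_counts(default_design(), default_scenario(), seed = 1)
filt <- filter_low_counts(sim$counts)           # keeps 24,347 of 25,298 genes
sf   <- size_factors_median_ratio(filt)
disp <- estimate_dispersion(filt, sf, sim$design)
rld  <- regularized_log(filt, sf)

between <- de_between_species(filt, sf, disp, sim$design)  # 15 pairs on eggplant
within  <- de_within_species(filt, sf, disp, sim$design)   # 18 plant shifts
rep_ <- classification_report(between, within, sim$catalog)

length(rep_$shared$machinery)
#> [1] 86
rep_$enrichment_machinery$chi_square   # chi2(5) against catalog proportions
#> [1] 5.915012

bg <- setdiff(rownames(rld), sim$catalog$gene_id)
random_subset_null(rld, sim$design, default_grouping(),
                   subset_size = 266, n_trials = 500, seed = 1, pool = bg)$n_success
#> [1] 0
```

The 86 genes recovered as shared machinery are the planted group-structured
responders (80 true, 6 false at these thresholds), the catalog-wide
clustering splits the six species exactly into the high/low performance
groups, and none of 500 random 266-gene background subsets reproduces that
split — the background carries only species and plant signal, so the
grouping is a property of the detoxification catalog, not of expression
data per se.

Survival statistics from the same scenario:

```r
surv <- simulate_survival(default_survival_means(), seed = 1)
two_way_anova(surv)
#>             df     ss        f  p
#> species      5 1.8287  77.2968  0
#> plant        3 2.2378 157.6458  0
#> interaction 15 0.5697   8.0273  0
#> residual    48 0.2271       NA NA
performance_letters(surv)$cassava$letters
#>   AsiaII-1      MEAM1     MED-Q1        NW2   SSA1-SG3 Uganda-ASL
#>        "a"        "a"        "c"        "c"       "ab"       "bc"
```

Species sharing a letter do not differ significantly on that plant after
the sequential Dunn–Šidák correction.

A config-driven run of the whole chain:

```r
run_pipeline(list(outdir = "out", seed = 1))   # or run_pipeline("cfg.yaml")
```

writes per-stage TSV/JSON outputs plus a `run.log`; rerunning with the same
config and seed reproduces every output byte-identically. A thin CLI wrapper
lives at `inst/cli/detoxshift.R`.

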