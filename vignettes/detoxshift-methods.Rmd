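---
title: "detoxshift: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{detoxshift: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`detoxshift` implements the computational chain of a comparative
detoxification-transcriptomics study design: six cryptic herbivore species
are reared on a common host (eggplant), shifted for 24 h onto three
chemically defended noncommon hosts (cassava, kale, pepper), and profiled by
RNA-Seq in three replicates per cell. The package asks, with tested code,
the study's central question — whether detoxification-gene expression tracks
phylogeny or host-performance ability — and provides a synthetic generator
with known ground truth so that every claim the pipeline makes can be
checked end to end. This vignette is the package's own account of the
models, the tunable parameters, and the choices made where the design was
genuinely open.

## Host-range survey clustering

Species groups are described by binary presence/absence profiles over host
taxa (orders, families or genera). For 0/1 rows, Euclidean distance is
`sqrt(k)` where `k` is the number of taxa in which two groups differ, so the
dendrogram is driven purely by host-range overlap. Agglomeration uses
complete linkage by default; UPGMA is available by flag because both
conventions are common for such matrices and they can disagree — rather than
silently choosing, both are exposed (`hierarchical_cluster(d, "upgma")`).

Merges at tied heights are resolved deterministically: among all pairs
within `1e-12` of the minimum, the pair whose (lexicographically smallest
member label, then largest) is smallest merges first. Ties are the rule, not
the exception, with binary data, and this rule makes results identical
across platforms and input orderings (a property the test suite checks by
permuting rows).

"Commonly shared" host taxa are operationalized as column prevalence
strictly above `min_fraction` (default 0.5, i.e. used by a majority of
species groups). The threshold is a free parameter because no canonical
value exists; it only affects the descriptive `shared_taxa` report.

## Ancestral host-state reconstruction

Each host taxon is treated as an independent binary character on a rooted,
branch-length-bearing phylogeny, evolving under the symmetric two-state
Markov (Mk, equal-rates) model. Over a branch of length $t$ at rate $q$,

$$P(\text{stay}) = \tfrac{1}{2}(1 + e^{-2qt}), \qquad
  P(\text{change}) = \tfrac{1}{2}(1 - e^{-2qt}).$$

* **Likelihood** — Felsenstein pruning with per-node rescaling of partial
  likelihoods (log scale accumulates the constants), so 64-tip trees are
  handled without underflow. Multifurcating nodes are products over all
  children; no arbitrary binary resolution is introduced. Zero-length
  branches use the exact identity transition matrix.
* **Root prior** — stationary uniform (1/2, 1/2), the equal-rates model's
  stationary distribution and the convention of the standard tools for this
  analysis. Because the prior is a choice, reproduction of published root
  probabilities from external data can shift by a few hundredths under a
  different prior; results on constant characters are prior-independent
  (probability 1 for the shared state, rate at the zero boundary).
* **Rate estimation** — 1-D bounded maximum likelihood on $[10^{-9}, 100]$
  (Brent-type `optimize`, tolerance $10^{-8}$). The bounds cover plausible
  per-tree scales while avoiding overflow; all-constant characters return
  the 0 boundary directly. Multiple characters can be pooled into one rate
  by summing log-likelihoods.
* **Marginal reconstruction** — for every node, the probability of each
  state given *all* tips, computed by combining upward partials with a
  downward pass; vectors sum to 1 within $10^{-12}$, and tips are
  degenerate. The test suite verifies exact agreement (to $10^{-10}$) with
  brute-force enumeration over all internal-state assignments on trees of
  up to 7 tips, and agreement with `ape::ace` marginals on larger trees.
* **Parsimony** — most-parsimonious-reconstruction state sets from unit-cost
  Sankoff dynamic programming up and down the tree: a state belongs to a
  node's set iff some minimum-change labelling uses it. This is checked
  against enumeration of all labellings.

Rate identifiability depends on the tree scale: on near-saturated trees
(many expected changes per character) the likelihood flattens and the MLE
can run to a bound. The recovery checks therefore use trees scaled to a
moderate regime (64 tips, branch lengths ~U(0, 0.5), 200 pooled characters),
where the pooled MLE lands within 20 % of the generating rate.

## Differential expression

The DE engine is a deliberately self-contained negative-binomial stand-in:
the analysis logic around it (filtering rule, thresholds, contrast
structure, classifications) is the scientific content here, not the engine.
Numerical parity with any external DE package is explicitly not claimed.

* **Filter** — a gene is kept when it has ≥ `min_reads` (10) reads in at
  least `ceiling(sample_fraction × n)` samples (4 % of 72 samples → 3).
  The ceiling is the conservative reading of "at least 10 reads in 4 % of
  samples"; retained counts are logged.
* **Normalization** — median-of-ratios size factors (per sample, the median
  over all-positive genes of count / gene geometric mean), rescaled to
  geometric mean 1. The rescale changes nothing downstream (only ratios
  matter) and gives the factors a fixed convention.
* **Dispersion** — per-gene method of moments on normalized counts,
  $\alpha = (s^2 - \bar\mu)/\bar\mu^2$ pooled across design cells weighted
  by within-cell df, floored at $10^{-8}$, then moderated toward the
  across-gene median with `prior_df = 50` pseudo-df. The moderation is the
  usual empirical-Bayes stabilization: with three replicates per cell the
  raw estimates are noisy, and plugging underestimated dispersions into a
  Wald statistic visibly inflates false calls.
* **Test** — log2 fold change on cell means of normalized counts with a
  pseudo-mean of 0.5 inside the ratio (avoids division by zero and tames
  low-count fold changes), delta-method SE from the NB variance
  $\mathrm{Var}(k/s) = \mu/s + \alpha\mu^2$, two-sided normal-reference
  Wald p. Under a pure NB null (10,000 genes, 3 vs 3, known $\alpha = 0.1$)
  the empirical type-I error at nominal 0.05 sits inside [0.03, 0.08]
  (acceptance suite). No fold-change shrinkage is applied, because the
  calling thresholds are defined on raw fold changes.
* **Multiplicity** — Benjamini–Hochberg across all retained genes within
  each contrast (`stats::p.adjust`; the test suite holds it against the
  textbook $O(n^2)$ step-up definition on fuzzed vectors).
* **Calling** — constitutive contrasts (between species on eggplant):
  |log2FC| ≥ 1 and padj ≤ 0.05; plastic contrasts (within species, plant vs
  eggplant): |log2FC| ≥ 0.58 (1.5-fold) and padj ≤ 0.05.
* **Expression scale** — `regularized_log` is a shifted log2 of normalized
  counts, a monotone log2-scale transform used for clustering, PCA and
  ANOVA. It deliberately does not reimplement any shrinkage-based
  regularization; this is the package's main fidelity gap relative to
  variance-stabilized transforms, and it matters most for low-count genes
  (mitigated by the count filter upstream).

## Gene classification rules

Restricted to the catalog universe (the 298 detox genes; family composition
104 P450, 25 GST, 24 COE, 71 UDPGT, 20 SULT, 54 ABC):

* **Constitutively unique** (per species, on the common host): significant
  in *all five* pairwise contrasts against the other species, with a
  consistent direction. This is the strictest reading of "over/under
  expressed in one species compared to all others" and makes the sets
  well-defined (a gene can be unique to at most one species per direction).
* **Plastic** (per species × noncommon plant): called at the plastic
  thresholds. Species-level response patterns are assigned by a configurable
  rule: "multi-host-high" with ≥ `high_cut` (default 20) called genes on
  ≥ 2 plants, "single-host-high" on exactly one, "low" otherwise. The
  cut is an operationalization of patterns that the motivating study
  described qualitatively; it only labels species, never genes.
* **Shared machinery**: genes plastic in ≥ 2 species (`shared_multi`),
  filtered to those where ≥ 2 species share the same direction on any of
  their called plants — one consistent species pair suffices. Direction
  consistency is evaluated across (species, plant) calls per gene.
* **Family enrichment**: 6-category goodness-of-fit chi-squared of a gene
  set's family counts against catalog proportions, df = 5, no continuity
  correction, expected counts = catalog proportion × set size.

## Expression structure and the clustering null

Mean profiles per species × plant cell (24 columns) are standardized per
gene (mean 0, sd 1 across cells; flat genes become zero rows and are
flagged), and columns are clustered with Pearson dissimilarity $1 - r$ and
complete linkage. A clustering "recovers the performance grouping" only if
(i) each species' four plant profiles form a contiguous subtree and (ii)
cutting the top split partitions the species exactly into the high/low
performance groups. The two-condition criterion reflects the observed
structure being tested: species cluster first, performance groups above
them. A 6-species-mean mode is available through the same functions by
passing species-level profiles.

The permutation null redraws `subset_size = 266` genes without replacement
`n_trials = 500` times from a pool and repeats the whole
profile–standardize–cluster–test chain. The default pool excludes the
catalog (background genes only), which is the cleanest null for the claim
"the grouping is carried by the detox catalog"; a full-pool mode is a flag,
since the wording of the original subsampling pool is ambiguous. Cell means
and per-gene standardization are invariant to which genes are subsampled,
so they are computed once — the per-trial work is exactly the correlation,
clustering and bipartition test. The empirical p-value uses the
$(k+1)/(n+1)$ convention, avoiding zero from finite trials. Trial seeds are
derived from the master seed (`sub_seed`), making every trial independently
reproducible.

Per-gene two-factor variance partition uses the balanced-design identity
(species, plant, interaction, residual sums of squares are orthogonal and
add to the total within $10^{-9}$ relative); the test suite pins the
decomposition to `aov` on random fixtures. PCA uses the correlation method:
genes scaled to unit variance, eigenvectors unit norm, explained-variance
fractions summing to 1.

## Survival statistics

Proportions are arcsine-square-root transformed (radians), analysed by
two-way ANOVA (Type-I sums of squares on the balanced assay), and compared
pairwise by Welch t-tests under a step-down sequential Bonferroni procedure
at Dunn–Šidák levels: at step $i$ of $m$, $\alpha'_i = 1 - (1 -
\alpha)^{1/(m - i + 1)}$, stopping at the first non-rejection. The Welch
statistic is a choice — the procedure's correction, not its pairwise
statistic, is what the design fixes. Letters are assigned from maximal
cliques of the non-significance graph (brute force; group counts are tiny),
ordered by group means, so species sharing a letter are statistically
inseparable. Comparisons default to within-plant panels, with a pooled
cells mode by flag, since either reading of "pairwise comparisons" is
defensible.

## The synthetic generator: what it emulates, and what it does not

`default_scenario()` *is* the package's statement of study conditions:
6 species × 4 plants × 3 replicates (72 samples), a 298-gene catalog with
the canonical family composition inside 25,000 background genes, NB counts
with $\mathrm{Var} = \mu + \alpha\mu^2$, and library-size factors
~U(0.5, 1.5) (echoing widely varying mapping rates). Counts for gene $g$ in
sample $j$ are NB with mean $s_j \cdot 2^{\eta_{gj}}$, where $\eta$ sums a
base level, species effects, plant effects and species × plant responses,
all on the log2 scale.

Parameter defaults and their rationale:

* **Base expression**: background log2 means ~N(5, 2); catalog genes
  ~N(7, 1.2). Detoxification enzymes are moderately-to-well expressed;
  keeping the catalog off the low-count floor matters because fold-change
  thresholds (0.58) are unreliable where Poisson noise dominates.
* **Dispersion**: $\alpha$ ~ lognormal(log 0.015, 0.5). Each replicate is a
  pool of ~50 adults, which averages away most individual biological
  variation; between-replicate dispersion is accordingly modest.
* **Background structure**: plant effects sd 1.0 shared across species,
  species effects sd 0.5, no interaction. Host-plant association therefore
  dominates background profiles — the structure reported for genome-wide
  expression in this design — and it is why random background subsets fail
  the species-contiguity condition of the null test.
* **Catalog structure**: species effects sd 0.3; a per-gene constitutive
  group signature ~N(0, 0.4) polarized between the high- and
  low-performance groups (low performers tend to lower detox expression);
  and planted classes — 10 constitutively unique genes per species
  (6 over, 4 under, effect ±3), 40 single-species plastic genes
  (effect ±2 on 1–3 noncommon plants), 50 machinery genes induced (+2)
  across the high group and 30 suppressed (−2) across the low group on 2–3
  noncommon plants. Planted effects sit at ≥ 2× the calling thresholds by
  design, so recovery failures indicate pipeline defects rather than power
  limits. All group-structured signal is confined to the catalog.
* **Survival**: binomial replicates of 50 adults around cell means 0.9 on
  eggplant, 0.75 (high group) and 0.40 (low group) on noncommon hosts;
  a beta-binomial option (`kappa`) adds replicate heterogeneity.

These values were fixed once, by exploratory calibration during package
design, and the acceptance suite then pins the scenario's qualitative
behavior across seeds: the catalog clustering recovers the grouping, the
background null yields 0/500, and planted classes are recovered with
sensitivity ≥ 0.9 at FDR ≤ 0.1.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: read-level artifacts (mapping bias, positional
effects), mean–dispersion trends, correlated gene modules beyond the
planted structure, unbalanced designs, or dropout. Two known divergences
from the motivating study's reported statistics are deliberate: the
generator's survival means encode a genuine group × plant interaction, so
its ANOVA interaction term is detectable (the field assay's was not,
presumably due to replicate heterogeneity); and because machinery responses
span whole performance groups, every species shows a sizable plastic
response, so the species-level pattern classes are less varied than in the
study.

## Numerical conventions

* One master seed governs everything; each stochastic stage derives a
  sub-seed (`sub_seed(seed, stage, index)`), and pipeline outputs are
  byte-identical across reruns with the same config and seed.
* Clustering tie-break: lexicographic on cluster labels (above); cutting
  `k` clusters removes the `k − 1` highest merges.
* Pruning partials are rescaled per node; marginals normalize per node, so
  scaling constants cancel exactly.
* The Wald p is set to 1 exactly when the fold change is 0; p-values are
  capped at 1.
* Zero-variance rows standardize to zero vectors (flagged); zero-variance
  columns are an error in correlation distances (undefined) and a warning
  (dropped) in PCA.
* Problem sizes in the shipped tests: enumeration oracles run on 1,000
  random trees of ≤ 7 tips; calibration simulations use 10,000 null genes;
  the end-to-end scenario runs at its full default size (25,298 genes ×
  72 samples), once per suite, with the 500-trial null.

## Known limitations

* The shifted-log2 transform is not a variance-stabilizing regularization;
  clustering of very-low-count genes is noisier than under shrinkage-based
  transforms.
* The NB Wald stand-in does not reproduce any specific external DE engine's
  dispersion shrinkage, outlier filtering or exact p-values; only the
  analysis logic downstream of the engine is portable.
* Ancestral-state root probabilities depend on the root prior and on how
  outgroups are scored for host characters; external-data reproductions
  should expect shifts of a few hundredths.
* The mapping-rate covariate question ("normalization taking mapping
  percentage into account") is not modelled beyond median-of-ratios.
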