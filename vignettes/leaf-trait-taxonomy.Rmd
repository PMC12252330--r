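---
title: "Numerical taxonomy of leaf phenotypic traits: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Numerical taxonomy of leaf phenotypic traits: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenotax)
library(dplyr)
```

phenotax implements a phenetic (numerical-taxonomy) workflow for leaf
macrostructure traits measured across a germplasm collection — the kind of
survey where each accession (a wild species or a bred cultivar) is scored
on tens of qualitative characters encoded as ordinals and a handful of
quantitative measurements, over dozens of replicate leaves. The workflow has
four stages: trait screening, dimensionality reduction, hierarchical
clustering, and pedigree-based validation of the clusters. This vignette
explains the statistical model behind each stage, the tunable parameters
and their defaults, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the design was genuinely
open.

## Data model

Three tables describe a study:

* a **codebook** (`as_codebook()`): each trait is *qualitative*, with an
  ordered set of level labels mapped to consecutive integer codes starting
  at 0 (binary characters conventionally 0 = absent, 1 = present), or
  *quantitative*, with measurement units;
* an **observation table**: one row per germplasm × replicate leaf ×
  trait;
* a **register** (`as_register()`): accession id, rank (`species` or
  `cultivar`), the infrageneric section for species, and known parents for
  cultivars.

`aggregate_observations()` reduces replicates to one germplasm-level value
per trait: the **mean** for quantitative traits and the **mode** (smallest
code on ties) for qualitative traits. Field protocols rarely state the
aggregation rule; the mean/mode pair was chosen because it is
deterministic, invariant to replicate order, and keeps qualitative cells
valid integer codes. Missing cells are errors rather than imputation
targets: the protocol assumes complete scoring, and silent imputation
would distort the diversity indices below.

Qualitative codes are treated as numeric ordinals throughout — they enter
standardization, PCA and Euclidean distances exactly like measurements.
This mirrors ordinal numerical coding practice in germplasm phenetics; a
Gower dissimilarity option exists (`trait_distances(..., method =
"gower")`) for users uncomfortable with that assumption, but it is off by
default because the reference methodology is Euclidean.

## Stage 1 — trait screening

Qualitative traits are screened by three indices over the $n$ germplasms,
with $n_i$ the count carrying level $i$ of $k$ declared levels:

$$D = 1 - \sum_{i=1}^{k} \frac{n_i (n_i - 1)}{n (n - 1)}, \qquad
H = -\sum_{i=1}^{k} \frac{n_i}{n} \ln \frac{n_i}{n}, \qquad
E = H / H_k .$$

$D$ is the unbiased Simpson diversity — the probability that two distinct
germplasms differ in the trait (the package's implementation is tested
against exhaustive pair enumeration). $H$ is Shannon–Wiener information in
nats, and $E$ is evenness. A trait is retained when $D \ge 0.50$,
$H \ge 0.80$ and $E \ge 0.60$, all inclusive.

Two readings of $H_k$ are defensible; the package uses $H_k = \ln k$ with
$k$ the number of levels **declared in the codebook**, not the number
observed. Declared-$k$ is deterministic (it does not change when a rare
level drops out of a subsample) and penalises traits whose declared states
are not realised in the collection; `trait_diversity()` reports
`k_observed` alongside so the difference is auditable. For the degenerate
single-level trait, $E$ is defined as 0 (the trait carries no information
and will fail the $D$ gate anyway).

Quantitative traits are screened for *intraspecific uniformity* and
*interspecific distinctness*:

$$\overline{CV} = \frac{1}{n} \sum_{i=1}^{n} \frac{S_i}{\bar X_i} \times 100\%,
\qquad CV = \frac{S'}{\bar X'} \times 100\%,$$

where $S_i, \bar X_i$ are the replicate sd and mean within germplasm $i$,
and $S', \bar X'$ the sd and mean of the germplasm-level values. Retention
requires $\overline{CV} \le 10\%$ (the trait is stable within an
accession, hence robust to environment) and $CV \ge 15\%$ (it
discriminates between accessions). Both use the sample standard deviation
(denominator $n-1$), the small-sample convention appropriate to ~30
replicate leaves, and both are invariant to positive rescaling, so unit
choices never affect screening.

## Stage 2 — dimensionality reduction

The germplasm-level matrix is standardized column-wise to mean 0, sd 1
(`standardize_traits()`; constant columns are an error naming the
offenders). `pca_retain()` eigen-decomposes the trait **correlation**
matrix: eigenvalues $\lambda_1 \ge \dots \ge \lambda_p$ sum to $p$, and
components with $\lambda \ge 0.90$ are retained. Loadings follow the
component-matrix convention of mainstream statistical software —
eigenvector entries scaled by $\sqrt{\lambda}$, i.e. the correlation
between trait and component, so one column's squared loadings sum to its
eigenvalue and individual entries can approach $\pm 1$. This is the scale
on which the $|loading| \ge 0.60$ significance rule of
`low_contribution_filter()` operates: a trait is kept when it correlates
at 0.60 or better with at least one retained component. The threshold is
applied inclusively with a $10^{-9}$ tolerance; eigenvector signs are
fixed so each vector's largest-magnitude entry is positive, a pure
determinism convention that the absolute-value filter cannot see.

`correlation_prune()` then removes residual redundancy: trait pairs with
$|r| > 0.80$ form a conflict graph, and vertices are deleted until no edge
remains. Which member of a correlated pair survives is, in practice, an
observational-convenience judgement that no algorithm should make silently
— so the analyst supplies an ordered `prefer` list of protected traits;
among unprotected traits the highest-degree vertex is removed first, ties
broken alphabetically, making the output deterministic. If two protected
traits conflict, the earlier-listed one survives and a warning reports the
clash. The result is guaranteed (and asserted in tests) to contain no
retained pair above the threshold.

## Stage 3 — clustering

`trait_distances()` computes Euclidean distances on the standardized final
traits; `cluster_germplasm()` performs Ward's minimum-variance
agglomeration on squared distances (Ward.D2). Merge heights are reported
on the distance scale, $\sqrt{2\,\Delta ESS}$, so two singletons merge at
exactly their Euclidean distance and heights are monotone nondecreasing.
The merge sequence is verified in the test suite against an exhaustive
oracle that, at every step, evaluates every cluster pair's increase in
total within-cluster sum of squares.

Partitions are produced by cutting at a **cluster count** `k`
(`cut_dendrogram()`), not at a printed height: heights depend on the data
set and on each implementation's height convention, whereas counts are
reproducible across software. Typical use cuts at `k = 2` (major groups)
and `k = 5` (subgroups). `summarize_groups()` reports per-cluster counts
by rank, quantitative means ± sd (singleton clusters have no sample sd;
it is reported as 0 with `sd_defined = FALSE`), and modal qualitative
levels. `species_proportions()` gives each cluster's within-cluster
species percentage and its share of all species; percentages are rounded
half-up to one decimal, matching the reporting convention of the
literature.

## Stage 4 — ancestry

For cultivars with known (full or partial) pedigrees, co-clustering with a
parent is evidence that the cluster structure tracks descent:

* `ancestor_inclined_probability()` — the percentage of pedigreed
  cultivars sharing a cluster with ≥ 1 known parent. A cultivar counts
  once however many parents match; parents absent from the partition drop
  from that cultivar's check, and a cultivar with no parent present leaves
  the denominator (with a warning). The statistic is monotone under
  cluster merging and equals 100 on a single cluster — so it is only
  meaningful relative to the chance level implied by cluster sizes, which
  the simulation tools let you estimate.
* `breeding_frequency()` — every cultivar contributes two parental slots;
  known parents occupy slots and the remainder is tracked explicitly as
  `"(unknown)"`, keeping frequencies comparable between full and partial
  pedigrees.
* `section_distribution()` — per taxonomic section, the percentage of its
  species in each cluster (rows sum to 100%).
* `order_correlation()` — given ordinal codes for an assumed evolutionary
  order of sections and of clusters, each species contributes one
  (section code, cluster code) pair; the Pearson correlation with the
  exact t-transform p-value ($t = r\sqrt{(n-2)/(1-r^2)}$, two-sided,
  unadjusted — it is a single test) measures concordance. How such
  concordance statistics are constructed varies between studies (per
  species, per section, proportion-weighted); this package implements the
  per-species pairing because it is the only construction fully
  determined by the data tables, and reports `n` and `n_excluded` so the
  basis of the statistic is always visible.

## The synthetic-data generator

Published germplasm trait matrices are rarely deposited, so validation
needs data with known truth. `simulate_population()` emulates the
essential structure of a leaf-macrostructure survey:

* species fall into `n_groups` latent phenetic groups (default 5),
  assigned round-robin; each group owns a preferred level per qualitative
  trait (probability mass `group_concentration`, default 0.8, on the
  preferred level) and a quantitative mean (multiplicative offsets with sd
  `group_separation`, default 0.25, around trait base means drawn from
  5–50);
* species scatter around their group (`species_jitter_cv`, default 3%) —
  small enough that con-group species stay similar, nonzero so they stay
  distinct;
* each cultivar draws one **donor parent** (uniformly among its 1–2
  parents, two with probability 0.8) and copies each germplasm-level trait
  from the donor with probability `inheritance_fidelity` (default 0.9),
  otherwise drawing from the pooled species distribution. Drawing the
  donor once per cultivar (rather than per trait) makes the
  full-fidelity limit exact — the cultivar's trait vector *is* one
  parent's — which is the property the recovery tests rely on; per-trait
  donor mixing would blur that limit whenever the two parents differ;
* replicate leaves add multiplicative Gaussian noise at the
  `within_cv` target (default 8%, comfortably inside the ≤ 10%
  uniformity gate; draws clipped at a small positive floor to keep
  measurements physical) for quantitative traits, and uniform level flips
  at `level_flip_prob` (default 5%) for qualitative traits.

Defaults mirror a collection of 34 species and 39 cultivars scored for 39
qualitative and 11 quantitative candidates over 30 leaves. One integer
seed drives all randomness; identical configurations are byte-identical.

What the generator does **not** emulate: trait–trait correlation beyond
what shared group membership induces (real leaf dimensions co-vary
allometrically), polygenic inheritance (donor copying is a caricature of
heritability — fidelity is a free parameter, not calibrated to any
measured heritability), environment-by-year effects, and realistic
venation geometry. Tests passing on synthetic data therefore demonstrate
that the pipeline recovers structure *of the kind it assumes*; they do not
certify performance on collections whose structure violates those
assumptions (e.g. heavily admixed cultivars blurring group boundaries).

## Numerical choices and degenerate inputs

* Ties in qualitative aggregation and in conflict-graph pruning break
  deterministically (smallest code; alphabetical trait name).
* Gate comparisons are inclusive at the printed thresholds, with a
  $10^{-9}$ tolerance only on the PCA loading gate where scaled loadings
  are computed quantities.
* Eigenvalues of the correlation matrix below $-10^{-10}$ are an error;
  small negative round-off is clamped to 0.
* `evenness_e()` rejects $H > \ln k$ as inconsistent; `simpson_d()`
  requires $n \ge 2$; CV functions reject zero means and singleton
  replicate sets rather than returning infinities.
* Reported percentages round half away from zero to one decimal
  (`round_half_up()`); base R's round-half-even would disagree with the
  conventional reporting of values such as 92.3%.

## Problem sizes used in validation

The test suite and the acceptance script validate on deliberately compact
instances: oracle comparisons run the Simpson pair-enumeration check on
every level-count vector with $n \le 12$ and the exhaustive Ward check on
100 random instances of up to 8 points (the exhaustive search is
factorial in n); cluster-recovery runs use 25 species + 10 cultivars in 5
groups; the zero-fidelity chance-level estimate averages 200 simulated
collections of 25 accessions. These sizes give exact oracle coverage and
Monte-Carlo standard errors well below the tolerances asserted, while a
full default-size simulation (73 accessions × 50 traits × 30 replicates)
is exercised once to validate shapes and file round-trips.

## Known limitations

* Ordinal coding imposes equal spacing between adjacent qualitative
  levels; the Gower option relaxes scaling but not ordinality.
* The ancestor-inclined probability treats both parents symmetrically and
  ignores pedigree depth (grandparents never enter).
* Greedy conflict-graph pruning is not guaranteed minimal when the
  conflict graph is dense and no preference list is given (minimum vertex
  cover is NP-hard); on the sparse graphs typical after a PCA filter it
  coincides with the minimum, and the preference list overrides it
  wherever the analyst cares.
* `order_correlation()` on a handful of species has low power; its
  p-value is exact under bivariate normality that ordinal codes only
  approximate. Treat it as a descriptive concordance measure.
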