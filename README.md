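# phenotax

Numerical taxonomy of leaf phenotypic traits in germplasm collections.

Botanical collections of difficult genera — *Malus* (crabapples) being the
classic case — hold dozens of wild species and bred cultivars whose
morphological boundaries blur through hybridisation. phenotax implements
the phenetic workflow used to classify such collections from leaf
macrostructure: traits observable directly or under a dissecting scope
(shape, pubescence, colour, venation architecture), scored on replicate
leaves, encoded as ordinals, and analysed in four stages. It is written
for curators and taxonomists who have a trait codebook, a replicate-level
observation table and an accession register, and want a reproducible path
from raw scores to clusters and pedigree-based validation.

## The method

1. **Screening.** Qualitative traits are kept when they are diverse,
   informative and even across the *n* germplasms:

   D = 1 − Σ nᵢ(nᵢ−1)/n(n−1) ≥ 0.50,  H = −Σ (nᵢ/n) ln(nᵢ/n) ≥ 0.80,
   E = H/ln k ≥ 0.60.

   Quantitative traits are kept when stable within accessions but
   discriminating between them: mean within-germplasm CV ≤ 10% and
   among-germplasm CV ≥ 15% (sample sd throughout).
2. **Reduction.** Correlation-matrix PCA retains components with
   eigenvalue λ ≥ 0.90; traits whose component loadings (eigenvector ×
   √λ) never reach |0.60| are dropped; remaining pairs with Pearson
   |r| > 0.80 are pruned greedily under a user-supplied preference list.
3. **Clustering.** Euclidean distances on the standardized final traits,
   Ward.D2 agglomeration (heights = √(2·ΔESS), verified against an
   exhaustive minimal-variance oracle), cuts by cluster count
   (typically k = 2 major groups, k = 5 subgroups), per-cluster
   summaries and species proportions.
4. **Ancestry.** For cultivars with known parents: the ancestor-inclined
   distribution probability (share of pedigreed cultivars co-clustering
   with ≥ 1 parent), breeding frequencies over two parental slots per
   cultivar, section-by-cluster distributions, and the ordinal
   correlation between an assumed evolutionary order of sections and of
   clusters.

A synthetic germplasm generator (`simulate_population()`) with known
latent groups, pedigrees and tunable trait-inheritance fidelity provides
ground truth for every stage. See the methods vignette
(`vignettes/leaf-trait-taxonomy.Rmd`) for models, assumptions and design
choices.

## Worked example

```r
library(phenotax)

sim <- simulate_population(sim_config(seed = 20))   # 73 accessions, 50 traits
run <- run_pipeline(sim$observations, sim$codebook, sim$register,
                    config = pipeline_config(k = c(2L, 5L)))
run
#> Leaf-trait numerical taxonomy pipeline
#>   traits: candidates=50 -> after_screen=34 -> after_pca=20 -> after_prune=20
#>   cuts: k2, k5
#>   ancestor-inclined probability (k2): 100.0% (n=39)
#>   ancestor-inclined probability (k5): 100.0% (n=39)
```

Fifty candidate traits shrink to 34 after the diversity/CV screen, to 20
after the PCA loading gate, with no residual |r| > 0.80 pair to prune.
All 39 simulated cultivars (generated at inheritance fidelity 0.9) land
in the same cluster as a parent — on real collections this percentage is
the evidence that clusters track descent.

```r
species_proportions(run$partitions$k5, sim$register)
#> # A tibble: 5 × 6
#>   cluster     n n_species n_cultivars pct_species pct_of_species
#>   <chr>   <int>     <int>       <int>       <dbl>          <dbl>
#> 1 C1         14         6           8        42.9           17.6
#> 2 C2         14         7           7        50             20.6
#> 3 C3         16         7           9        43.8           20.6
#> 4 C4         13         7           6        53.8           20.6
#> 5 C5         16         7           9        43.8           20.6

head(breeding_frequency(pedigree_set(sim$register)), 3)
#> # A tibble: 3 × 3
#>   parent slots frequency
#>   <chr>  <int>     <dbl>
#> 1 SP17       6       7.7
#> 2 SP13       5       6.4
#> 3 SP20       5       6.4
```

`pct_species` is the within-cluster species percentage; `pct_of_species`
is each cluster's share of all species in the collection. Results carry
`autoplot()`/`plot_*()` methods (screen bars with gate lines, scree plot,
dendrogram, section heatmap) and broom-style `tidy()`/`glance()`.

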