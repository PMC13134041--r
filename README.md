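# microterroir

Spatially explicit analysis of grapevine-associated microbial communities
("microbial terroir") from 16S rRNA gene and fungal ITS amplicon surveys.

Microbial communities on wine grapes vary not just between regions and
cultivars but *within* single vineyard blocks, and that spatial
heterogeneity — dispersal limitation, microclimate gradients, edge effects
from neighbouring fields — shapes both diversity estimates and the pool of
organisms entering fermentation. `microterroir` provides the desk-side
toolkit for quantifying this: it consumes a denoised ASV count table,
sequences, taxonomy and georeferenced sample metadata, and answers how
similar communities are at the vine / vineyard / region scales, whether
dissimilarity grows with distance, what site and cultivar explain, how
gamma diversity accumulates with sampling density, and what the diversity
surface of a vineyard looks like.

## What it computes

* **Import & QC** — TSV/BIOM feature tables, FASTA sequences, taxonomy
  and metadata readers; standard amplicon filtering (unassigned at class,
  < 2 total reads, chloroplast/mitochondria/host lineages, Eukaryota in
  16S mode).
* **Bootstrapped diversity** — even subsampling at 500 reads with 10
  with-replacement bootstraps; alpha (richness, Shannon in bits) as the
  bootstrap median, beta (Jaccard, Bray–Curtis) as the bootstrap
  **medoid**; k-mer decomposition of ASVs (default k = 16) as a
  pseudo-phylogenetic feature space; classical PCoA.
* **Spatial statistics** — haversine geodesic distances; Mantel
  distance-decay tests (Spearman, two-sided, 999 permutations, exhaustive
  enumeration at small n); pair classification by vine / vineyard / site;
  per-taxon latitude/longitude screens with BH correction.
* **Group inference** — PERMANOVA with pseudo-F
  `(SS_A/(a−1))/(SS_W/(n−a))` and effect size `R² = SS_A/SS_T`; pairwise
  PERMANOVA with compact letter display; stratified (two-way) PERMANOVA
  permuting within sites; ANOVA (type II for unbalanced two-way designs);
  Spearman trend tests.
* **Gamma diversity** — pooled richness/entropy and sample-accumulation
  curves with Monte-Carlo confidence bands.
* **Kriging** — Matérn Gaussian-process interpolation (ν = 1.5 default,
  10 optimizer restarts, multi-start marginal-likelihood maximisation) of
  any per-vine quantity, on a local equirectangular projection.
* **Synthetic vineyards** — a generator of georeferenced, spatially
  autocorrelated multinomial communities with site/cultivar effects,
  localized rare taxa, an edge-gradient taxon and contaminant features,
  used to validate and power-test every stage.

## Worked example

Simulate a two-site vineyard pair with the default study conditions,
filter, estimate bootstrapped Bray–Curtis, and test site separation and
distance decay:

```r
library(microterroir)

ds <- simulateDataset(simulationConfig(seed = 42))
ft <- filterFeatures(ds$table, ds$taxonomy)   # class rule, <2 reads, organelles
ft
#> FeatureTable: 76 features x 120 samples, 598,169 total reads

beta <- bootstrapBeta(ft, "bray_curtis", depth = 500, nBoot = 10, seed = 42)
md <- ds$metadata
permanova(beta, setNames(md$vineyard, rownames(md)),
          permutations = 999, seed = 42)
#> PERMANOVA: pseudo-F = 55.4681, R2 = 0.3198, p = 0.001 (999 permutations)
#>   groups: V1 (n=60), V2 (n=60)

v1 <- rownames(md)[md$vineyard == "V1"]
distanceDecay(as.matrix(beta)[v1, v1], geodesicMatrix(md[v1, ]),
              permutations = 999, seed = 42)
#> Mantel test: rho = 0.2437, p = 0.001 (999 permutations, 1770 pairs)
#>   OLS (descriptive): community = 0.3232 + 0.004189 * metres; slope 95% CI [0.003402, 0.004976]
```

Read: the two sites are cleanly separated (R² ≈ 0.32 of compositional
variance explained by site, p = 0.001), and within site V1 community
dissimilarity increases significantly with geodesic distance between
vines (rho = 0.24) — the distance-decay signature of dispersal
limitation. Gamma accumulation shows richness still climbing at high
sampling density:

```r
curve <- accumulationCurve(
  rarefyTable(ft, 500, withReplacement = TRUE, seed = 42),
  setNames(md$vineyard, rownames(md)),
  densities = c(1, 5, 10, 20, 40), nIter = 10, seed = 42)
head(as.data.frame(curve), 5)
#>   site density mean    lower    upper            metric n_iterations
#> 1   V1       1 38.4 36.28865 40.51135 observed_features           10
#> 2   V1       5 57.1 55.86326 58.33674 observed_features           10
#> 3   V1      10 61.2 59.94727 62.45273 observed_features           10
#> 4   V1      20 64.3 63.62135 64.97865 observed_features           10
#> 5   V1      40 66.6 65.83101 67.36899 observed_features           10
```

A thin command-line wrapper over the same functions is installed at
`exec/microterroir.R` (subcommands `simulate`, `filter`, `diversity`,
`mantel`, `permanova`, `gamma`); every stochastic subcommand takes
`--seed` and reruns bit-identically.

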