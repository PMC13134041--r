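---
title: "Methods: spatial analysis of vineyard microbiome diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial analysis of vineyard microbiome diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microterroir)
```

# Scope and model of the data

`microterroir` analyses georeferenced marker-gene surveys of grapevine
microbiota: a sample-by-ASV count table (16S rRNA gene or fungal ITS),
the ASV sequences, taxonomy annotations, and per-sample metadata carrying
vineyard, cultivar and WGS84 coordinates for every sampled vine. The
scientific questions it targets are spatial: how heterogeneous are
communities within a vine, within a vineyard, and between vineyards; does
community dissimilarity increase with geodesic distance (distance decay,
the classic signature of dispersal limitation); do site or cultivar
explain compositional variance; how does cumulative (gamma) diversity
grow with sampling density; and can diversity or individual taxa be
interpolated across a vineyard surface.

Everything upstream of the count table — demultiplexing, denoising,
chimera removal, taxonomic classification — is out of scope; the package
consumes the outputs of those standard tools.

# Feature filtering

`filterFeatures()` applies the conventional QC rules for amplicon
surveys: features unassigned at the class level are removed, features
with fewer than 2 total reads across all samples are removed, and
lineages matching organelle/host terms (chloroplast, mitochondria,
Viridiplantae, Metazoa) are excluded by case-insensitive substring match;
in 16S mode, features whose domain is Eukaryota are also dropped.
Whether ITS features unclassified at the domain level should also be
removed is left as configuration (off by default): reference databases
differ in how they mark such sequences, and the conservative choice is to
keep them. Filtering never drops samples; samples left empty are
reported and dealt with at rarefaction, keeping the two decisions
orthogonal. Filtering is idempotent because each rule depends only on a
feature's own lineage and total count.

# Bootstrapped rarefaction and diversity

Sampling depth varies by orders of magnitude between samples, so all
diversity estimation is performed at an even depth of 500 reads per
sample — a depth suited to low-biomass, low-diversity berry surfaces —
using 10 bootstrap resamples drawn *with replacement* from each sample's
relative abundances (a multinomial draw at fixed depth). Alpha diversity
(observed richness and Shannon entropy) is summarised per sample as the
median over bootstraps; beta diversity (Jaccard on presence/absence,
Bray–Curtis on counts) as the **medoid** matrix — the bootstrap matrix
minimising the summed Frobenius distance to the others, ties broken by
lowest bootstrap index — so the summary is always an actually observed
distance matrix and remains a valid metric input for downstream
permutation tests. Plain without-replacement rarefaction is also
provided; it drops samples below the target depth.

Two conventions are fixed and stated everywhere they matter:

* **Shannon entropy is in bits** (log base 2), the convention of common
  amplicon toolchains; `alphaDiversity(c(2, 1, 1), "shannon")` is
  exactly 1.5.
* **Pairs of all-zero samples get distance 0**, loudly, so permutation
  tests never receive NaN.

`kmerizeTable()` re-expresses the table in k-mer space: the count of
k-mer *m* in sample *s* is the read-weighted number of occurrences of
*m* across the ASV sequences. This acts as a pseudo-phylogenetic feature
representation — communities sharing sequence content look similar even
when their exact ASVs differ. The default k = 16 follows common k-mer
tooling; reverse complements are not collapsed. Both choices are
configurable since neither is canonical.

`ordinatePCoA()` implements classical metric multidimensional scaling:
double-centre \(-D^2/2\), eigendecompose, scale eigenvectors by the
square roots of the positive eigenvalues. Negative eigenvalues (from
non-Euclidean dissimilarities such as Bray–Curtis) are reported but
excluded from coordinates, and proportions explained are relative to the
sum of positive eigenvalues.

# Spatial statistics

Geodesic distances are haversine great-circle distances on a sphere of
mean radius 6 371 008.8 m. At vineyard extents (tens to thousands of
metres) the spherical error is far below half a percent, and the choice
of metres as the unit is immaterial to rank-based tests within one plot.
For anything requiring planar geometry (kriging, the synthetic layout)
coordinates are projected to local metres by an equirectangular
projection about the centroid — adequate because vineyard extents are
vanishingly small relative to the Earth radius.

`mantelTest()` correlates the upper triangles of two distance matrices
with Spearman's rho (average ranks for ties) and permutes the sample
labels of the second matrix, rows and columns simultaneously. The test
is two-sided on |rho| and uses the \((1 + x)/(1 + N)\) estimator, so a
p-value can never be zero and equals the exhaustive-enumeration value
when all \(n!\) orderings are requested (`permutations = "exhaustive"`,
n ≤ 7). `distanceDecay()` couples the Mantel test with an ordinary
least-squares fit of community distance on geodesic distance across
pairs. The regression is *descriptive only* — pairs sharing a sample are
not independent — and all inference comes from the Mantel permutation;
the pair list is returned for plotting. When community distances are
constant the Mantel rho is undefined and only the (zero-slope) fit is
reported, with a warning.

`taxonCoordinateScreen()` is the exploratory screen for spatially
structured taxa: per-taxon Spearman correlations of relative abundance
against latitude and against longitude, restricted to taxa above a
prevalence floor (default 10 % of samples). Benjamini–Hochberg
adjustment across all tests in the screen is the default; `"none"`
reproduces the uncorrected exploratory behaviour. It is a screen, not a
spatial model: it will flag edge gradients (e.g. a powdery-mildew front
entering from a neighbouring field) but says nothing about mechanism.

# Kriging

`fitKrige()` fits a Gaussian process with a Matérn kernel plus white
noise by maximising the log marginal likelihood over length scale,
amplitude and noise, from 10 random log-uniform starts plus one
heuristic start at the median inter-point distance. Values are
standardised internally. Smoothness defaults to ν = 1.5 — Matérn is the
family of choice for environmental surfaces, and ν = 1.5 (once
differentiable) is the customary compromise between the roughness of
ν = 0.5 and the oversmoothness of the squared exponential; ν ∈
{0.5, 1.5, 2.5} is configurable. Search bounds are length scale in
[0.1 × min, 10 × max inter-point distance] and amplitude/noise sd in
[1e-8, 10] on the standardised scale; the bounds keep the optimiser away
from degenerate ridges (zero-length-scale interpolation, pure-noise
fits) while covering every physically meaningful solution. Pinning
`noiseBounds` near zero turns the fit into an exact interpolator, which
is how the training-point recovery checks operate. Predictions report
the posterior mean and the *latent* (noise-free) standard deviation,
de-standardised; far from all data the mean reverts to the training mean
and the sd to the prior amplitude.

# Group inference

`permanova()` uses the among/within squared-distance decomposition:
\(SS_{total} = \sum_{i<j} d_{ij}^2 / n\), within-group analogues summed
per group, pseudo-F = \((SS_A/(a-1)) / (SS_W/(n-a))\), significance by
label permutation with the same never-zero estimator as the Mantel test.
The reported effect size is \(R^2 = SS_A / SS_{total}\). On Euclidean
distances of 1-D data the pseudo-F is identical to the classical one-way
ANOVA F, a cross-method identity the tests verify to 1e-9.

Pairwise PERMANOVA adjusts pairwise p-values (Benjamini–Hochberg by
default; no correction is also available) and renders them as a compact
letter display via insert-and-absorb, so that two groups share a letter
exactly when their adjusted p exceeds alpha.

The two-way analysis — "does cultivar matter after accounting for
site?" — is realised as a *stratified* PERMANOVA: sums of squares are
decomposed within each site and pooled, and permutations shuffle
cultivar labels only within sites. Restricted permutations make the
null distribution conditional on the site structure with minimal
modelling assumptions; a factor constant within every stratum is
unresolvable confounding and raises an error. This is one defensible
reading of a two-way design on distance matrices; sequential
multi-factor partitioning is deliberately not implemented.

ANOVA on alpha diversity uses the classical one-way F-test or, for two
factors, type II sums of squares without interaction — appropriate for
the unbalanced cultivar-within-site designs these surveys produce
(e.g. 93 vs 41 samples). `spearmanTrend()` handles ordered covariates
such as row number, with exact p-values for n ≤ 9 without ties.

# Gamma diversity

`pooledGamma()` sums counts across a sample set and computes the alpha
metric on the pooled vector: gamma richness is the total observed
richness of the set, and gamma Shannon is the entropy *of the pooled
counts* — "cumulative diversity" read as pooling, not as averaging
per-sample entropies, because the pooled community is what an aggregate
sample (e.g. a must) would measure. `accumulationCurve()` draws x
samples per site (with replacement by default, matching
sample-rarefaction practice; without replacement as an option), repeats
10 times per density, and reports the mean with a t-based 95 % CI — with
10 iterations that interval is wide, and the iteration count is
configurable. Per-draw richness can never exceed the pooled richness of
the site, an exact bound the tests assert on every draw.

# The synthetic vineyard generator

Real surveys from the archives cannot be regenerated at desk scale (the
upstream denoising/classification pipeline is version-sensitive), so
validation rests on a generator that produces data with the statistical
structure the analyses assume — not a mechanistic dispersal model.

The layout places a regular grid of vines (default 5 rows × 12 vines at
3 m × 2 m, the shape of a densely sampled block) per site, rotated by an
orientation angle, with sites offset by kilometres (default two sites
3 km apart, matching nearby-vineyard comparisons); planar metres are
converted to lat/lon by the inverse of the same equirectangular
projection the analysis uses. Cultivars are monoclonal or randomly
interplanted (default 60/40, the typical dominance of a field blend).

For core taxon *t* on vine *v* the log-propensity is

\[
\eta(t, v) = b_t + \beta_{site}(t, s(v)) + \beta_{cv}(t, c(v)) +
  w_t\, G_t(v) + \varepsilon(t, v)
\]

with taxon baselines \(b_t \sim N(0, 1)\) giving realistic community
unevenness, site effects \(N(0, \sigma_{site}^2)\) (default 1), cultivar
effects \(N(0, \sigma_{cv}^2)\) (default 0.5, i.e. secondary to site),
independent zero-mean Gaussian random fields \(G_t\) with exponential
covariance \(\exp(-d/30\,\mathrm{m})\) and log-normal loadings \(w_t\)
scaled by \(\sigma_{spatial}\) (default 1), and residual noise (default
0.3). Relative abundances are the softmax across taxa within each vine —
guaranteeing a valid simplex and making every effect compositional, as
amplicon counts are — and counts are one multinomial draw at fixed depth
(default 5000), so sample totals are exact. Rare taxa occur only within
a 5 m radius of a random focal vine, giving the non-saturating richness
tail; one gradient taxon increases log-linearly along a coordinate axis
*within each site*, emulating a phytopathogen front at a vineyard edge;
and configurable contaminant features carry organelle/unassigned
lineages so the filter rules can be exercised.

Two deliberate choices keep the validation honest. Generation uses the
exponential covariance (Matérn ν = 0.5) while kriging fits ν = 1.5, so
parameter-recovery tests run under mild misspecification rather than in
a self-confirming loop — recovered length scales are accordingly judged
only to within a factor of two of the generating 30 m. And the
generator's defaults are fixed study conditions, not tuning knobs: the
power targets (significant positive distance decay in ≥ 80 % of
replicates with spatial structure only; site R² above cultivar R² in
≥ 90 % when site effects dominate) are design targets evaluated at these
defaults.

What the generator does *not* emulate: sequence errors and chimeras,
taxon-taxon interactions, temporal succession, anisotropic or
non-stationary spatial structure, and depth variation between samples
(an optional negative-binomial depth mode is the obvious extension).
Passing tests therefore demonstrate correctness of the statistical
machinery under the stated generative assumptions, not that real
vineyards satisfy those assumptions.

# Numerical and degenerate-input conventions

* Permutation p-values use \((1 + x)/(1 + N)\) and tie comparisons use a
  1e-12 slack so floating-point noise cannot flip a count.
* Distance matrices are validated to be symmetric within 1e-12, hollow
  and non-negative on entry to every consumer.
* GRF covariances get a 1e-10 diagonal jitter before Cholesky; GP
  likelihood evaluations that still fail return a large penalty so
  multi-start optimisation can continue.
* All-zero samples: richness 0; Shannon 0 with a warning; distance 0 by
  convention with a message.
* Every stochastic operation takes an explicit seed and restores the
  caller's RNG state; the CLI defaults to seed 42 and prints it.

# Problem sizes used in validation

The shipped checks run at deliberately small scale chosen to exercise
every code path with tight Monte-Carlo tolerances: exhaustive
permutation oracles at n ≤ 6; 300-replicate null calibrations for each
permutation test at n = 10–12 with 999 permutations; 50-replicate power
runs on 60-vine single-site communities at depth 500; 20 replicate GP
fits on 100-point grids; and a 2 000-replicate binomial check of the
bootstrap resampler. The same quantities at larger n behave identically
by construction; the sizes are a choice about statistical resolution,
with Monte-Carlo standard errors stated next to each tolerance in the
tests.
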