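---
title: "Methods: from LC-MS feature tables to tritrophic path models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from LC-MS feature tables to tritrophic path models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytocommune)
```

## The problem

A community chemical-ecology study of this kind couples three layers of
observation: an untargeted LC-MS profile of foliar tissue (hundreds of
aligned retention-time x m/z "peak bins" per plant), the lepidopteran
herbivore community collected from the same plants, and the parasitoid
outcomes of rearing those larvae. The scientific questions are hierarchical:
at which spatiotemporal scale does phytochemistry vary, which groups of
covarying compounds carry that variation, and how do those groups mediate
the effects of elevation and plant size on herbivores and parasitoids?

`phytocommune` implements that analysis chain as a reusable, fully seeded
pipeline: pseudospectrum quality control, compound-class annotation,
internal-standard normalization, chemodiversity and dispersion statistics,
weighted-correlation-network composite variables, and observed-variable path
models. A synthetic-data generator with complete ground truth makes every
stage testable without any field data.

## Feature quality control

Aligned feature tables over-count compounds: one molecule yields adducts,
isotopes, and in-source fragments. Lacking raw chromatograms (peak-shape
correlation needs extracted-ion traces, which a feature table does not
carry), the pseudospectrum grouping uses the two signals a table does carry:
co-elution within `rt_window` (default 5 s, roughly twice a chromatographic
peak width at a 0.4 mL/min gradient) and cross-sample Pearson correlation at
least `corr_min` (default 0.7). Components of the resulting pair graph
(single linkage, deterministic) are pseudospectra; the member with the
highest mean abundance represents the group's peak area.

Ammonium adducts matter specifically because the downstream nitrogen rule
reads mass parity: an [M+NH4]+ ion sits 17.026549 Da above its [M+H]+
partner and would masquerade as a nitrogenous compound. Any feature sitting
at that spacing (tolerance 0.005 Da, about 18 ppm at m/z 273) above a member
of its own pseudospectrum is removed.

Batch effects are filtered by per-feature one-way ANOVA on extraction batch
with the permissive alpha = 0.10 (removing a real compound costs less than
keeping an artifact when hundreds of features remain). Zero-variance
features get p = 1: no variance, no evidence. By construction the stage
order is grouping, representative selection, adduct removal, batch filter;
feature count never increases and the sample set never changes.

## Annotation: nitrogen rule, RMD, mixtures, class windows

For protonated ions the nitrogen rule flips: an even nominal (rounded) ion
m/z implies an odd nitrogen count in the neutral molecule. The parity
partition is deliberately coarse - even-nitrogen compounds land on the
"wrong" side - but it is exactly what a TOF feature table supports.

Relative mass defect, `(m/z - nominal) / (m/z) * 1e6` ppm, proxies hydrogen
saturation: flavonoids (aglycones and glycosides) sit near 200-400 ppm,
lipids and phospholipids near 600-800 ppm. When the fractional mass exceeds
0.5 the defect is computed against `floor(m/z)` so RMD stays positive (a
defect of 0.585 at m/z 760 still means a hydrogen-rich ion).

Within each parity partition, features are clustered by Gaussian mixtures
over standardized (rt, m/z, RMD) - standardization is essential since the
three axes differ by orders of magnitude. Six covariance families
(spherical/diagonal/full, shared or per-component) are fit by EM from
seeded k-means starts for k = 1..12, and BIC (`-2 logLik + npar log n`,
smaller better) picks the model. Clusters are then labeled by the first
matching rule in a fixed order: phospholipid (nitrogenous in the lipid
windows), peptide (the nitrogenous catch-all, reflecting the wide rt/m-z/RMD
spread of oligopeptides), flavonoid glycoside (rt 350-450 s, RMD
200-400 ppm), flavonoid aglycone (rt 600-800 s, same RMD band), lipid
(rt 750-1050 s, m/z 400-900, RMD 600-800 ppm), other (early, low-RMD small
molecules), else unknown.

One consequence is worth stating plainly: any nitrogenous cluster outside
the phospholipid windows is called "peptide". Nitrogenous minor compounds
(alkaloids, amino acids) and nitrogenous unknowns are therefore
*structurally* mislabeled - in the default synthetic world this caps
all-feature class recovery near 88-89% even when clustering is perfect,
which is why the recovery tests report both the unconditional rate and the
rate over features whose planted class the rule vocabulary can express
(>= 90%).

Features of classes served by a co-injected internal standard (naringenin
100 uM for aglycones, naringin 101 uM for glycosides, cholecystokinin
fragment 30-33 amide 52 uM for peptides) are divided by the standard's area
in the same sample, cancelling injection and ionization nuisance; everything
is then divided by dry extracted mass (g). The normalization is exactly
multiplicative, so a per-sample global factor with proportional standard
response cancels to machine precision.

## Diversity, dispersion, composition

Chemodiversity is the Shannon effective number (Hill number at q = 1),
`exp(-sum p log p)`: the number of equally abundant peaks with the same
entropy, bounded by 1 and the richness. It is computed per individual per
collection month, then aggregated (plot, subsite, site) with one-way ANOVAs
across groups.

Dispersion and composition use distance matrices: Manhattan distances
between normalized chemical profiles, binary Jaccard between plot-level
herbivore communities (the quantitative-vs-binary choice is undocumented in
this analysis tradition's sources; binary is the common default for
community turnover). Dispersion embeds the distance matrix in
principal-coordinate space, keeps negative-eigenvalue axes, and measures
each sample's distance to its group centroid as
`sqrt(max(0, d2_real - d2_imag))` - for any Euclidean-embeddable metric this
reproduces direct centroid geometry exactly, which the tests pin at 1e-8.
A spatial-median center is offered as an option (the reference
implementation's default); the acceptance tests pin only the centroid
variant, and for Euclidean embeddings the Weiszfeld median is exact.

PERMANOVA partitions the squared interpoint distances (`SS_total =
sum d2 / n`, within-group analogues per group) into a pseudo-F. The p-value
comes from label permutations: complete enumeration whenever the number of
distinct relabelings is at most 1e5 (then `p = #{F >= F_obs} / #perms`,
exact), otherwise 9999 seeded random permutations with the add-one
convention. Because PERMANOVA conflates location and dispersion effects,
composition tests are gated: if the dispersion ANOVA rejects homogeneity at
alpha = 0.05 the PERMANOVA is not run and only the gate record is reported
(boundary convention: p equal to alpha proceeds).

## Covariance-network modules

The composite-variable engine builds an unsigned weighted correlation
network over features of the log-scale, mean-centered data: adjacency
`|cor|^beta` with beta = 8 (chosen in the field by scale-free topology fit;
`pick_soft_power()` implements that index as the signed R^2 of
`log10 p(k) ~ log10 k` over binned connectivity). The topological overlap
matrix smooths adjacency through shared neighbors; modules are
average-linkage clusters of `1 - TOM` under a static cut.

Two deliberate deviations from the reference tooling, both documented
design choices: the dynamic hybrid tree cut is replaced by a deterministic
static cut at absolute height 0.99 on the [0,1] TOM dissimilarity (clusters
below `min_size` = 5 join the grey pseudo-module), and module labels use the
conventional size-ordered color vocabulary (turquoise, blue, brown, ...).
A cut at a *quantile* of the merge heights was considered and rejected: with
planted blocks plus noise, more than 1% of joins are top-level, so the 0.99
quantile sits above the inter-module joins and collapses everything into
one module.

Each module's eigenvalue is the first principal component of its
standardized member submatrix, unit variance, oriented to correlate
non-negatively with the module's mean profile; kME is each feature's
correlation with its own eigenvalue (hubs = highest |kME|). Modules whose
eigenvalues correlate above 0.75 (dissimilarity below the 0.25 merge
height) are merged iteratively until stable; merging is idempotent. Ranking
modules by the F statistic of plot-level dispersion of their member features
identifies the module carrying the most spatial structure.

## Path models

The plot-level models are observed-variable path analyses (no latent
constructs): linear structural equations among z-scored columns, so
estimates are standardized coefficients. The implied covariance is
`(I - B)^-1 Psi (I - B)^-T`; the ML discrepancy
`log|Sigma| - log|S| + tr(S Sigma^-1) - p` is minimized by BFGS from
equation-wise OLS starts (for recursive models with free exogenous
covariances that start is already the ML optimum, which is why saturated
models hit zero discrepancy to 1e-6). `chi2 = (n - 1) F_min` (Wishart
convention, S with the n-1 denominator), df = moments minus free
parameters, and AIC is reported both as `chi2 - 2 df` and `-2 logLik + 2k`:
the two differ by a data-only constant, so model *comparisons* agree, and
absolute AIC values are not comparable across likelihood conventions.

The model-building procedure mirrors the field practice: an ecological
backbone (elevation -> leaves per plant -> herbivore abundance ->
herbivore diversity; elevation -> parasitoid success) is protected, all
module eigenvalues enter as predictors of the herbivore/parasitoid
variables and as responses to elevation and plant size, and the least
significant chemistry edge (largest p above alpha = 0.05) is removed and
the model refit until all remaining chemistry edges are significant.
Direct effects are the B entries; total effects are `(I - B)^-1 - I` (the
geometric series over routes, requiring spectral radius below 1); indirect
is their difference.

## The synthetic world

The generator states one world and the tests measure the pipeline against
it:

* **Design**: 2 sites x 3 elevation-band subsites x 3 plots x 3 monthly
  collections (18 plots), elevation 1600-2600 m a.s.l. with plot jitter
  +/-50 m, about 3 tagged individuals per plot (negative binomial, minimum
  1), dry mass ~ N(0.020 g, 0.002), 4 extraction batches assigned by
  *randomized* run order - the real protocol randomizes samples before
  analysis, and without this the batch filter would confound batch with
  plot structure.
* **Classes**: 175 features in 7 classes (peptide 40, flavonoid glycoside
  35, phospholipid 33, lipid 31, flavonoid aglycone 11, other 7, unknown
  18; the literature source lists the 33-peak phospholipid class twice, and
  one class of 33 is used). Each feature draws rt and RMD from truncated
  normals centred in its class window (sd = width/6, clamped), and its m/z
  is constructed so that the nominal mass parity matches its nitrogen flag
  and the realized RMD matches the draw under the floor/round convention.
  "Other" is fully nitrogenous (alkaloids, amino acids); unknowns are 25%
  nitrogenous late eluters.
* **Modules**: the three largest classes (peptides, flavonoid glycosides,
  phospholipids) each load on one latent factor (loadings U(1.0, 1.4),
  log-scale noise sd 0.8). That puts within-module correlations at
  ~0.55-0.68: *below* the 0.7 pseudospectrum threshold - distinct
  co-eluting compounds must not be mistaken for one compound - yet strong
  enough that beta = 8 topological overlap separates the blocks. Factors
  have intraclass correlation 0.5 at plot level plus planted
  elevation/plant-size effects.
* **Ecology**: plot-level herbivore counts are negative binomial
  (mean 10 per plot-collection at baseline, size 5) with log-mean linear in
  the planted predictors; morphotype identities (19 by default) follow a
  geometric-decay multinomial whose decay shrinks - evenness grows - with
  the planted diversity signal; rearing outcomes are died (20% background)
  or adult/parasitoid with parasitoid logit linear in the planted
  predictors (baseline 30%).
* **Planted coefficients** carry the sign pattern of the motivating system
  (peptides boost herbivore abundance; flavonoid glycosides suppress
  herbivores and parasitoid success and respond negatively to elevation and
  plant size) at moderate magnitudes (0.16-0.60) chosen once so every
  endogenous variable keeps positive residual variance; published
  coefficients near 1 arise under strong predictor collinearity and would
  make a standardized generative system ill-conditioned.

What a green test does **not** establish: the generator draws classes from
clean, stationary windows (no retention drift, no isotope patterns, no
baseline noise bins, no missing values), batch effects are additive on the
log scale, and module structure is exactly block-diagonal. Real data violate
all of these; the tests certify the statistical machinery, not instrument
physics.

## Numerical choices and degenerate inputs

* Constant-abundance features: singleton pseudospectra (correlation
  undefined), p = 1 in the batch filter, excluded from networks with a
  warning.
* Mixture EM: ridge 1e-6 on covariances; candidates that empty a component
  are skipped and logged; all-candidate failure is an error.
* Parity ambiguity: fractional masses within 0.3 of the half-integer
  boundary are logged but still assigned (the convention is deterministic).
* PCoA eigenvalues below 1e-8 (relative) are dropped; negative-axis
  corrections are clamped at zero before the square root.
* Ties: soft-power ties go to the smallest power; hub ties break by feature
  id; two empty communities have Jaccard distance 0 (flagged).
* Seeds: one global seed expands to per-stage seeds by fixed offsets, so a
  stage can be re-run in isolation; every stochastic routine takes an
  explicit seed and the whole pipeline is byte-reproducible.

## Known limitations

* No raw-spectrum operations: no peak picking, rt warping, gap filling,
  isotope grouping, or peak-shape correlation; no spectral-library or
  accurate-mass database matching.
* The nitrogen-rule partition misplaces even-nitrogen compounds by
  construction, and the peptide catch-all absorbs nitrogenous minor
  classes (quantified above).
* The plot-level path models at the default 18-plot design are
  deliberately small-n; they run, but sign/effect recovery is certified at
  ~100-300 plots in the tests.
* Module count on synthetic data is a function of planted structure; no
  fixed module count is asserted anywhere.
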