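---
title: "Methods: integrated metabolomics-flavoromics analysis"
author: "flavoromics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated metabolomics-flavoromics analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flavoromics)
```

# Scope and data model

`flavoromics` analyses paired intensity tables from a multi-group food
profiling study: non-volatile metabolites (LC-MS) and volatile organic
compounds (VOCs, GCxGC-TOF MS), measured on the same biological samples.
Both tables are held as `SummarizedExperiment` objects (features x
samples) with group labels in `colData` and an optional internal-standard
feature recorded in the metadata. Missing measurements are `NA`; zero is a
legal intensity and is never conflated with absence, because the
missingness filter must count true absences.

The pipeline runs in a fixed order: peak quality control, retention-index
identity confirmation, internal-standard normalization, missingness
filtering, imputation, multivariate modeling, differential screening,
aroma scoring, network and correlation analyses, pathway
over-representation. Each stage is an exported function; `runPipeline()`
chains them and writes a manifest with checksums, so reruns are
byte-identical.

# Preprocessing chain

**Peak QC.** A peak is retained iff its signal-to-noise ratio is at least
`min_sn` (default 50) and its spectral library similarity (0-999 scale) is
at least `min_similarity` (default 700). Both bounds are inclusive, the
convention of chromatography QC reports.

**Retention-index confirmation.** The retention index of an analyte is
computed from an n-alkane ladder by the van den Dool-Kratz linear form for
temperature-programmed GC,

$$ RI = 100\,n + 100\,(n'-n)\,\frac{t - t_n}{t_{n'} - t_n}, $$

with $t_n \le t \le t_{n'}$ the bracketing alkane retention times
($n' = n+1$ for a complete ladder; the factor scales with the gap
otherwise). An alkane maps exactly to 100 times its carbon number, and no
extrapolation beyond the ladder is allowed. An identification is confirmed
when the absolute difference between calculated and theoretical RI is
*strictly* below `ri_tolerance` (default 20).

**Internal-standard semi-quantification.** Every intensity is divided by
the sample's internal-standard intensity, giving *relative content*; the
IS channel (identically 1 afterwards) is dropped. Dividing by the IS only
— with no analyte-specific response factors — is what makes the result a
relative, not absolute, concentration; the ROAV analysis downstream is
scale-invariant, so this suffices.

**Missingness filter.** A feature is removed iff its missing fraction
*strictly exceeds* `max_missing_frac` (default 0.5): a feature missing in
exactly half the samples is kept. The strict/inclusive boundary semantics
across the three thresholds (QC inclusive, missingness strict, RI strict)
are deliberate and covered by boundary tests.

**Imputation.** Remaining gaps are filled with half the feature's minimum
observed value — the standard stand-in for values censored below the
detection limit in MS data. Imputation runs after the missingness filter,
so every imputed feature has at least half its values observed. The filter
order is fixed and logged, and the chain is idempotent: run on its own
output it changes nothing.

# Multivariate models

Both PCA and OPLS-DA operate on log-transformed, mean-centered and (by
default) unit-variance-scaled intensities — standard metabolomics
autoscaling. The log transform is applied inside the model functions, not
stored in the tables.

**PCA** is the singular value decomposition of the scaled matrix;
explained-variance fractions are the normalized squared singular values.

**OPLS-DA** follows the orthogonal-projection scheme for a single
two-class response: the predictive weight vector $w \propto X^\top y$ is
fixed from the original scaled matrix; each of `nOrtho` orthogonal
components removes from $X$ the part of its loading orthogonal to $w$
(scores $t_o$ carry zero covariance with $y$ by construction); the final
predictive score is $t = X_{\mathrm{filtered}}\,w$ with inner regression
$c = y^\top t / t^\top t$. With `nOrtho = 0` the model reduces exactly to
one-component PLS1, which the tests exploit as an oracle equivalence.
`nOrtho` defaults to 1, the usual one-predictive-plus-one-orthogonal
layout for a two-class comparison.

**VIP** is computed over the predictive component,
$\mathrm{VIP}_j = \sqrt{p}\,|w_j| / \lVert w \rVert$ for $p$ features,
which forces $\mathrm{mean}(\mathrm{VIP}^2) = 1$; this normalization is
asserted on every fit. Restricting VIP to the predictive part keeps marker
ranking tied to class-predictive variation.

**R²Y and Q².** R²Y is the fraction of centered class-indicator variance
explained by the fitted response. Q² is cross-validated:
$Q^2 = 1 - \mathrm{PRESS}/\mathrm{SSY}$, where each fold's samples are
predicted from a model completely refit on the remaining samples
(centering, scaling, orthogonal filtering and the inner regression are all
re-estimated per fold). Leave-one-out is used up to 12 samples — covering
the three-replicate pairwise designs this package targets — and seeded
stratified 7-fold otherwise. Q² can be negative; values above ~0.4-0.5 are
conventionally read as acceptable predictive ability.

**Sign convention.** Every component (PCA loadings, OPLS-DA predictive
and orthogonal loadings) is flipped so its largest-magnitude loading
element is positive, making outputs byte-reproducible.

# Differential screening

For each ordered group pair, features are screened by the combined rule
**VIP > 1 and p < 0.05** (both strict on their boundaries). The p-value is
a per-feature Welch t-test on log intensities; a one-way ANOVA across all
groups is available for the omnibus question. Benjamini-Hochberg
adjustment is always computed and reported; whether the *screen* uses raw
or adjusted p is a flag (`use_adjusted`). The raw-p default mirrors common
OPLS-DA screening practice, but raw-p selection cannot bound the false
discovery rate: with 10% true effects, the VIP and p criteria largely
coincide for a pairwise model, so the empirical FDR approaches the null
rate divided by prevalence. The package's own recovery experiment (see the
acceptance suite) therefore screens with `use_adjusted = TRUE`, the
appropriate choice whenever an FDR guarantee is the goal; both routes are
exposed and the discrepancy is documented rather than hidden.

Fold changes are computed on the un-logged, normalized group means and
reported as log2; direction is `up` when the first group of the pair is
higher. Degenerate features (zero variance everywhere with equal means)
take p = 1 by declared convention.

Heatmap ordering uses per-feature z-scores (zero-variance rows become
all-zero, with a message), Euclidean distances and complete-linkage
agglomeration; merge structure is verified against a from-scratch
agglomeration oracle in the tests.

# Aroma contribution (OAV / ROAV)

For one group with mean relative contents $C_i$ and odor thresholds in
water $OT_i$:

$$ OAV_i = C_i / OT_i, \qquad ROAV_i = 100 \cdot OAV_i / OAV_{\max}. $$

ROAV is a 0-100 scale; the group's strongest compound scores exactly 100.
Contribution classes are read literally from the conventional wording: a
compound is a *key* contributor iff ROAV strictly exceeds 1, *moderate*
on the closed interval [0.1, 1], *minor* below. Compounds without an odor
threshold are listed unscored and never determine $OAV_{\max}$ — an
unscorable compound cannot be the reference. $C_i$ is the group **mean**
of IS-normalized content (median available as an option), and each group
is scored against its own $OAV_{\max}$, so per-group contributions are
comparable within, not across, groups. ROAV is invariant to any global
rescaling of contents, which is why semi-quantification is sufficient.

Class composition sums mean relative contents per chemical class
(hydrocarbons, alcohols, aldehydes, esters, ketones, others) and
normalizes to percentages per group. Venn partitioning counts the seven
exclusive regions of three per-group detection sets, where "detected"
means observed before imputation in at least one of the group's samples.

The VOC-sensory network links each selected VOC to its sensory
descriptors and keeps the `top_k = 10` attributes by degree, ties broken
lexicographically so retention is order-invariant.

# Association analyses

**Correlation.** Spearman's rho between every metabolite and every VOC is
the Pearson correlation of mid-ranks (average ranks under ties); p-values
use the t approximation on $n-2$ degrees of freedom, with an exact option
for $n \le 10$. Significance flags default to raw p < 0.05 — the marking
convention of clustered double-matrix correlation heatmaps — while
BH-adjusted p-values are emitted alongside for stricter readings.

**Pathway over-representation.** With $N$ universe features, $K$ pathway
members, $n$ selected and $k$ selected members, the enrichment p-value is
the upper-tail hypergeometric probability $P(X \ge k)$, BH-adjusted
across pathways. The universe is an explicit, required input: whether it
is "all detected" or "all annotated" features materially changes the
test, so the package refuses to guess. Topology or impact scoring of
external pathway tools is out of scope.

# The synthetic-study generator

`generateStudy()` emulates the statistical structure the analysis
assumes, with three groups (GL, SN, XZ) of `n_per_group = 3` replicates
by default — the scale of a three-breed, three-bulls-per-breed design.
Choices, in brief:

- **Log-normal intensities.** Log-intensity = latent feature mean +
  $N(0, \sigma)$ with $\sigma = \sqrt{\log(1 + \mathrm{cv}^2)}$; baseline
  latent means are drawn around $\log(10^5)$. Multiplicative noise
  matches MS intensity behavior and makes fold planting exact on the log
  scale: a planted feature's affected-group latent mean is shifted by
  exactly $\pm\log(\mathrm{effect\_size})$, recorded in the truth record.
- **Per-sample loading factors** multiply whole samples (including the
  spiked internal standard at fixed nominal amount), so IS normalization
  has something real to remove.
- **Missingness** is below-LOD censoring (lowest `lod_quantile` of
  intensities) followed by missing-at-random masking at `missing_rate`,
  in that order, so half-minimum imputation faces detection-limit
  structure; the internal standard is never masked.
- **Annotations** draw chemical classes from the closed six-class
  taxonomy, odor thresholds log-uniform over $10^{-3}$–$10^{1}$ (odor
  thresholds in water genuinely span orders of magnitude), theoretical
  RIs consistent with the ladder up to a small perturbation, and 1-4
  descriptors from a fixed 14-term sensory vocabulary that includes the
  canonical attributes (sweet, fruity, green, waxy, ethereal, floral, …).
  The vocabulary is a packaged static table standing in for an external
  flavor database, so no network access is needed.
- **The alkane ladder** is affine in carbon number (C7-C30, 1.5 min
  spacing) with optional jitter bounded at 1% of the spacing; at the
  default jitter of 0 the RI interpolation is exactly affine, which the
  closed-form tests exploit.
- **Peak records** give most features comfortable S/N and similarity
  margins with a realistic failing tail, so the QC filters have work to
  do without destroying the study.
- **Pathways**: eight synthetic pathways, with planted differential
  metabolites concentrated in two designated "enriched" ones.

Defaults for what the emulated design does not pin down (effect size 4,
10% differential features, CV 0.2, 5% missingness, 2% LOD quantile) were
chosen once as representative of a clear but not trivial metabolomics
effect; all are exposed in `synthConfig()`.

What the generator does **not** emulate: chromatographic peak shapes,
co-elution and deconvolution errors, batch drift, feature-feature
correlation beyond the planted group structure, non-random (intensity
dependent) missingness beyond the LOD mechanism, and annotation errors.
Tests passing on this generator therefore validate the statistical
machinery and its contracts, not robustness to those instrument-level
artifacts.

# Numerical and validation choices

Randomness is always taken from an explicit seed, and the generator
restores the caller's RNG state. Determinism of the full pipeline is
asserted byte-for-byte on the manifest checksums.

The validation suite sizes its simulations for tightness per unit time:
oracle equivalences use 9x30 and 8-item instances where exhaustive or
closed-form checks are exact; the null-behavior study uses 50 seeded
runs of 100-metabolite tables; the recovery study uses 20 seeds of
200-metabolite tables at n = 20 per group; hypergeometric enumeration
covers every configuration up to a 12-feature universe. Degenerate-input
conventions (constant features, all-identical groups, zero-variance
z-scores, empty descriptor sets) are all explicit code paths with tests,
not accidents of floating point.

# Known limitations

- OPLS-DA here is single-response (two classes); multi-class comparisons
  are handled pairwise, and the three-group overview is left to PCA.
- ROAV ignores perceptual interactions (masking, synergy); it ranks
  candidate contributors, it does not predict the percept.
- The exact Spearman option delegates to `stats::cor.test` and requires
  untied data, as usual.
- Q² folds are stratified but not repeated; for very small n the LOO
  estimate is the only one offered.
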