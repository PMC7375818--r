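---
title: "Quantifying 3D synaptic organization: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3D synaptic organization: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synaptostats3d)
```

## What this package computes

Volume electron microscopy (FIB/SEM) studies of cortical neuropil reconstruct
every synaptic junction inside a stack of serial sections and then quantify
the population along a fixed sequence of steps. This package implements that
quantitative pipeline for the human hippocampal CA1 field and makes every
stage testable against synthetic data with known ground truth:

1. **Stereology.** Volume fractions (V~v~) of tissue classes by Cavalieri
   point counting on semithin sections, and per-stack fixation-artifact
   fractions by the same point counting on every 20th FIB/SEM section.
2. **Correction arithmetic.** Tissue shrinks during osmication and plastic
   embedding. With an area shrinkage factor $p^2$ (processed/fresh area),
   in-plane linear factor $p = \sqrt{p^2}$, and z-axis factor $p_z$, measured
   lengths are divided by $p$, areas by $p^2$, and counting-frame volumes are
   first discounted by the artifact fraction and then divided by
   $p^2 p_z$. Densities are recomputed against the corrected volume.
3. **Counting.** An unbiased 3D counting frame (brick rule) filters the
   reconstructed synapses; synaptic density is the included count divided by
   the (optionally corrected) frame volume.
4. **Spatial statistics.** Synapse centroids are tested against complete
   spatial randomness (CSR) with the F (empty space), G (nearest neighbour)
   and K (Ripley) functions and Monte-Carlo envelopes from 99 conditional CSR
   simulations; nearest-neighbour distances double as intersynaptic
   distances.
5. **SAS morphometry.** The synaptic apposition surface (SAS) — the surface
   of apposition between active zone and postsynaptic density — is measured
   from its triangulated mesh: area, boundary perimeter, curvature
   ($1 - \text{projected area}/\text{area}$), and a four-way shape
   classification (macular, horseshoe, perforated, fragmented).
6. **Statistical battery.** $\chi^2$ association tests with expected
   frequencies $E_{ij} = T_i T_j / T$, two-sample Kolmogorov-Smirnov,
   Mann-Whitney, one-way ANOVA with Tukey HSD, log-normal and log-logistic
   size-distribution fits, and $R^2$ correlations, under the dual
   significance convention ($p < 0.05$ when $n$ = subjects, $p < 0.001$ when
   $n$ = synapses).

## The synthetic generator and what it emulates

`generate_population()` draws one stack's synapse table from a
`layer_profile`: centroids are a homogeneous Poisson process at the layer's
synaptic density; polarity (asymmetric AS vs symmetric SS) is Bernoulli;
postsynaptic target and junction shape are conditional multinomials; SAS
area is log-normal; SAS perimeter is the equal-area-circle perimeter scaled
by a polarity-specific shape factor with multiplicative log-normal noise; and
SAS curvature is Beta-distributed with mean near 0.05.

The packaged calibration (`ca1_layer_profiles()`) transcribes the published
human CA1 per-layer table: densities 0.45 (SO) to 0.99 (sSP) synapses/µm³,
AS fractions near 95% (89% in SLM), pooled target and shape frequencies, and
per-layer SAS-area moments. The published material gives per-layer means and
SEMs but not the log-scale parameters, so the log-normal models are
calibrated by method of moments with SD recovered as SEM·√n — an
approximation, flagged as such. The pooled split of horseshoe vs fragmented
AS (and perforated vs fragmented SS) is likewise not printed; the shipped
values respect the printed macular and second-ranked shares and the printed
ordering.

Fixation artifacts are emulated as blob regions (unions of balls, thresholded
on a distance field to hit the target fraction exactly) carved out of the
point process: synapses falling inside the blobs are removed, which is what
makes artifact-corrected density recover the true intensity. Coordinates are
generated directly in corrected (tissue) space, so the default study
configuration uses identity shrinkage factors; the factors are exercised as
pure arithmetic wherever measured values are supplied.

**What the generator does not emulate.** Real stacks show between-stack
density variance beyond Poisson (the published table reports SDs like
0.45 ± 0.19 across stacks); the generator is homogeneous at the layer mean,
so passing recovery tests demonstrate correctness of the estimators, not
robustness to biological overdispersion. Shapes, targets and sizes are drawn
independently, whereas in tissue they are correlated (complex-shaped
junctions are larger); no dendritic geometry, no mark correlations, no
inhomogeneous intensity.

## Numerical and design choices

* **Coordinates** are nm, 0-based, in the half-open box $[0, \text{extent})$.
  Synapse location is the junction centroid.
* **Counting frame**: exclusion faces fixed at minimum-x/y/z (open),
  inclusion at the maxima (closed). The brick rule's orientation is a
  convention; with centroid-only records the rule degrades to
  centroid-in-box, flagged in the output attributes.
* **Border correction** for F/G/K is reduced sampling (minus sampling): at
  radius $r$ only points (or empty-space test locations) farther than $r$
  from every face contribute. It is simple and unbiased, which matters more
  than efficiency in small EM stacks. The r grid defaults to 50 values from
  0 to a quarter of the shortest window edge; the F-function test lattice has
  $\lceil n^{1/3}\rceil^3$ locations.
* **Envelope verdict**: the default envelope is a global (sup-deviation)
  band — a constant-width band around the theoretical CSR curve whose
  half-width is the largest supremum deviation among the 99 simulated
  curves — giving an exact Monte-Carlo level of 1/(99+1) = 1% over the whole
  r grid. The classic pointwise min/max envelope is also available
  (`type = "pointwise"`), but over a 50-point r grid its multiplicity
  inflates the global type-I rate to roughly 20%, which would make a
  calibrated verdict impossible; it is kept for display. The calibration
  tests require the CSR verdict to be positive in at least 93 of 100
  replicates and the hard-core and clustered alternatives to be rejected in
  at least 95.
* **Curvature projection plane** is the orthogonal-regression best-fit plane
  to the mesh vertices. Projected area is the outline-filled region: per
  component, the projected outer boundary polygon minus projected hole
  polygons. For strongly folded sheets (beyond a hemisphere) the outline
  area is an approximation; the parametric validation families stay within
  the regime where it is exact.
* **Shape classifier cascade**: ≥2 components → fragmented; ≥1 interior hole
  → perforated; projected-outline solidity (polygon area / convex hull area)
  < 0.85 → horseshoe; else macular. The published taxonomy was assigned
  visually, so 0.85 is a declared convention; the classifier is exact on all
  five parametric families across random sizes and poses.
* **Rounding**: reported values round half-up (table style, 2 decimals for
  percentages and densities, integers for thickness shares); internal math is
  full precision. Correction arithmetic reproduces published
  corrected/uncorrected pairs when the factors are applied at their printed
  3-decimal precision (`as_shrinkage_factors(p2 = 0.933, pz = 0.901,
  p = 0.966)`), matching how the published tables were produced.
* **Artifact-volume convention**: the artifact discount applies to the
  measured (processed) volume first, then the shrinkage division — artifacts
  are measured in processed tissue. Published corrected/uncorrected
  counting-frame volume pairs cannot be reproduced from the printed factors
  alone because per-stack artifact fractions were not printed; both volume
  conventions are exposed and none of the package's checks depend on that
  row.
* **Mann-Whitney**: exact permutation distribution for small untied samples,
  normal approximation with tie correction otherwise — the exact branch is
  verified against exhaustive rank-permutation enumeration.
* **ANOVA** is classical (equal variance); the source analyses do not state
  Welch, and with 5 subjects per group the classical form is the
  conventional choice.
* **Log-logistic** is parameterized by CDF$(x) = 1/(1+(x/\alpha)^{-\beta})$
  and fitted by Nelder-Mead on log-parameters from a logistic
  method-of-moments start.

## Problem sizes used by the tests

The test suite exercises the pipeline at desk scale, chosen to keep the
Monte-Carlo calibration sharp while remaining quick: CSR calibration uses
patterns of n = 1000 in a 10 × 10 × 10 µm window with 99-simulation
envelopes over 100 replicates per scenario (CSR, hard-core at 500 nm,
Thomas-like clustering); the shape classifier is checked on 200 randomized
fixtures; type-I calibration uses 1000 null simulations per test; and the
end-to-end recovery run uses the full 5-layer × 5-case × 3-stack design with
10 × 8 × 5 µm stacks (≈ 20,000 synapses), mirroring the real study's scale.

## Known limitations

* SAS meshes are taken as given (or generated parametrically); extracting a
  SAS from a voxel segmentation of real EM data is out of scope.
* Only marginal CSR is tested — no inhomogeneous intensity, no
  pair-correlation function, no cross-type (AS vs SS) mark correlation.
* The counting frame's treatment of junctions that touch an inclusion face
  while extending outside the stack cannot be resolved with centroid-only
  records; the centroid rule is flagged in output metadata.
* Profiles are calibrated to published summary statistics, not raw data;
  moment-matched log-normal parameters are approximations to the real
  per-layer size distributions.
* The CSR envelope tests use the full stack box as the window. A synthetic
  stack whose artifact fraction is near the top of the 0–20% range is
  genuinely non-CSR over that window (a fifth of the box holds no synapses),
  so its verdict can honestly fail even though the underlying process is
  CSR; real-data workflows that segment artifact regions could instead test
  within the artifact-free domain, which this package does not model.
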