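---
title: "Methods: test-retest repeatability screening of mpMRI radiomic features"
author: "radrepeat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: test-retest repeatability screening of mpMRI radiomic features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radrepeat)
```

# The problem

A quantitative imaging feature is only a biomarker candidate if two scans
of the same patient, taken days apart with no interim treatment, give
essentially the same value. `radrepeat` implements a repeatability screen
for paired test–retest prostate multiparametric MRI: a T2-weighted volume
and an ADC (apparent diffusion coefficient) map per timepoint, a 3D
prostate gland mask, and one or more radiologist-delineated lesion masks,
each delineated independently at the two timepoints. Both modalities are
assumed pre-coregistered and resampled to a single grid per patient; the
package validates grid compatibility (spacing within 1e-3 mm, origin
within 1e-2 mm) but performs no registration itself.

The analysis asks three nested questions about each of 307 radiomic
features, per region variant and modality:

1. **Concordance.** Lin's concordance correlation coefficient between the
   test and retest values across the cohort,
   $CCC = 2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)$,
   with population ($1/n$) moments. CCC penalises both poor correlation
   and deviation from the identity line.
2. **Dynamic range.** $DR = 1 - \overline{|Test - Retest|} / (Max - Min)$,
   where the range is taken over the pooled test and retest values. A
   feature can repeat perfectly yet carry no information if its repeat
   error is as large as its biological spread; DR near 1 means the repeat
   error is small relative to the interpatient range.
3. **Non-redundancy.** Among the features that survive the joint screen
   ($CCC \ge c$ and $DR \ge c$ at the same cutoff $c$), features are
   grouped by the coefficient of determination $R^2$ (squared Pearson
   correlation) of their subject-wise $(Test + Retest)/2$ averages, and
   each group keeps one representative — the feature with the highest DR.

# Region variants

Four region variants are analysed by default, with two more opt-in:

* `RADIOLOGIST_RAW` / `RADIOLOGIST_Z` — the radiologist lesion mask, on
  native or gland-standardised intensities;
* `HABITAT_SPHERE_RAW` / `HABITAT_SPHERE_Z` — an automatically converged
  restricted-diffusion habitat: a 15 mm-diameter sphere centred at the
  lesion centroid (world mm) is intersected with the gland, the ADC values
  in that search region are thresholded at $\mu - k\sigma$ (default
  $k = 1$), and the largest 26-connected component is kept. The habitat
  may extend beyond the lesion but never beyond the gland;
* `HABITAT_MEDIAN_RAW` / `HABITAT_MEDIAN_Z` (opt-in) — the largest
  26-connected component of the at-or-below-median ADC voxels inside the
  lesion; always a subset of the lesion.

Habitats are converged independently per timepoint from that timepoint's
lesion mask and raw ADC map, and the converged mask is then applied to
both modalities. Habitat thresholds always operate on raw ADC: the z-score
is a monotone map, so thresholding standardised ADC would select the same
voxels; computing on raw ADC makes that explicit.

The literature source for the sphere threshold names only a
"distributional deviation", so the multiplier $k$ is exposed in
`habitatConfig()` and $k = 1$ is this package's documented convention, not
a verified constant.

## Standardisation

`zscoreStandardize()` subtracts the gland mean and divides by the gland
population standard deviation (divide by $N$; at gland voxel counts the
difference from $N-1$ is immaterial but a fixed convention keeps runs
reproducible). Standardisation is per patient, per timepoint and per
modality; voxels outside the gland are mapped with the same parameters, so
lesion intensities become relative to the whole gland. A constant gland is
rejected rather than silently producing infinities.

# The 307-feature catalog

`buildCatalog()` returns the ordered catalog: C1 — 45 size/shape features;
C2 — 107 intensity, histogram, local-intensity and texture-matrix features
(19 first-order statistics, 23 intensity-histogram, 5 local-intensity,
23 co-occurrence, 16 run-length, 16 size-zone, 5 grey-tone difference);
C3 — 155 filter-bank features (125 Laws kernel triples, 30 wavelet
subband statistics). Roughly fifty (index, name) pairs are fixed by the
published feature lists the catalog mirrors (for example
`F148:NGTDM_Coarseness`, `F228:3D-LawsF-R5-L5-L5`,
`F54:Surface-area-(mm^2)`); the remaining membership is this package's
published convention. Histogram features that are constants by
construction under min–max discretisation (minimum/maximum level, level
range) are deliberately excluded — they would carry zero dynamic range on
any cohort.

Numerical conventions that the source material leaves open, fixed here:

* **Discretisation**: fixed bin *number* (default `Ng = 32`) over the
  in-ROI min–max range, `level = max(1, ceiling(Ng * (x - min)/range))`
  (left-open bins, minimum attached to bin 1); a constant ROI maps to
  level 1. Fixed-bin-number makes raw and z-scored texture features
  directly comparable because the binning is invariant to positive affine
  intensity maps.
* **Direction aggregation**: co-occurrence and run-length matrices are
  computed per direction over the 13 unique 3D lattice directions and the
  *feature values* are averaged (the `avgCooc_3D`/`avg_3D` naming), not
  the matrices merged. Size-zone uses a single matrix with 26-connected
  zones; the grey-tone difference matrix uses the in-ROI 26-neighbourhood
  with the IBSI $\varepsilon = 10^{-12}$ coarseness guard.
* **Texture vs shape and spacing**: texture families operate on the voxel
  lattice ignoring spacing anisotropy; shape features are spacing-aware
  (mm, mm², mm³), with surface area by exposed-face counting, in-plane
  border length per slice, and principal-axis geometry from the
  voxel-centre covariance (axis length $4\sqrt\lambda$).
* **Laws reduction**: mean absolute filter response over ROI voxels, with
  symmetric (edge-inclusive) boundary padding; kernels L5/E5/S5/R5/W5
  applied separably along x/y/z.
* **Wavelets**: two-level *undecimated* (à trous) Haar decomposition;
  subbands C1–C7 are the level-1 details (LLH, LHL, LHH, HLL, HLH, HHL,
  HHH with letters meaning the x/y/z filters), C8–C14 the level-2 details
  in the same order, C15 the level-2 approximation; per subband the mean
  absolute coefficient and the coefficient energy over ROI voxels. The
  original basis is not recoverable from the source; Haar keeps the
  "details vanish on constants" identity exact.
* **Degenerate ROIs**: features that are genuinely undefined on a
  degenerate ROI (co-occurrence correlation and the first information
  correlation measure of a constant region, coefficient of variation at
  exactly zero mean) are emitted as `NaN`, excluded pairwise downstream
  and flagged.
* **Weighted centroid weights** are intensities shifted to be
  non-negative ($w = I - \min I$), so the centre-of-mass shift of a
  uniform ROI is exactly zero and z-scored (signed) volumes cannot produce
  sign-cancelling weights.

# Screening and redundancy reduction

`screenFeatures()` aligns patient-lesions across timepoints
(complete-pairs analysis: any pair containing `NaN` is dropped; fewer
than 3 complete pairs makes the feature's statistics `NaN` and it never
passes), computes CCC and DR, and flags the joint rule
`pass(c) <=> ccc >= c & dr >= c` at cutoffs 0.65–0.95. Degenerate-vector
conventions: constant-and-equal pairs give CCC 1, constant-and-unequal
give 0; a degenerate pooled range gives DR 0.

`reduceFeatures()` runs the recursive grouping greedily: pick the
surviving feature with the highest DR (ties broken to the lowest catalog
index, which makes selection deterministic), remove every feature with
$R^2 \ge$ cutoff against it, recurse on the remainder. The iteration
order of the original procedure is not specified; greedy DR-descending
elimination honours both stated rules (group by $R^2$, representative =
highest DR) and guarantees that every removed feature is redundant with
at least one selected representative. It does *not* certify pairwise
independence of the survivors — redundancy elimination, not independence.
A constant feature vector has $R^2 = 0$ against everything and survives
on its own merits.

**Summary tabulation.** The summary count table applies redundancy
reduction once per variant × modality × $R^2$ cutoff to the *base*
(lowest, 0.65) passing set, then each row $\ge c$ counts the survivors
whose CCC and DR both reach $c$. Applying the greedy reduction
independently per row cannot guarantee the nesting such tables exhibit (a
high-DR hub feature can eliminate two features in a superset that both
survive in a subset), whereas counting one survivor set at increasing
cutoffs is monotone by construction and matches the convention of listing
selected features at the 0.65 row.

# What the synthetic data emulate — and what they do not

`generatePhantomCohort()` builds, per patient: an ellipsoidal gland
(semi-axes ~(24, 20, 14) mm ± 10 %) on a 48 × 48 × 16 grid at
(2, 2, 4) mm spacing; one ellipsoidal lesion (nominal radius 7 mm,
per-axis ± 40 %, placed wholly inside the gland) with a planted
low-ADC core occupying half the lesion volume (radius fraction
$0.5^{1/3}$), shell ADC midway between core and gland; per-patient
intensity means (± 8 %) and noise scale (± 40 %) emulating cohort
diversity; a frozen per-patient Gaussian texture shared by both
timepoints (ADC SD 100 × 10⁻⁶ mm²/s, T2w SD 40 a.u.); fresh Gaussian
voxel noise per timepoint (`retestNoiseSD`, a multiplier of the texture
SD, applied to both timepoints so that 0 makes test ≡ retest bitwise);
and independent re-delineation of the RETEST lesion emulated by a random
dilation/erosion with a world-radius ball up to `boundaryJitterMM`
(default 2 mm). Everything is deterministic given the seed.

The wide per-patient size spread is deliberate: on a 4 mm slice grid,
discrete size-coupled features (slice counts, bounding-box extents,
histogram bin counts) only acquire a genuine between-patient range if
lesion geometry varies substantially, and a feature with zero cohort
range has zero dynamic range by convention.

The core-at-half-volume choice makes the within-lesion sub-median habitat
coincide with the planted core, which is what lets core recovery be
scored with a Dice coefficient against known ground truth (the planted
core is carried in the cohort object as synthetic ground truth, never as
a pipeline input).

What the phantom does **not** model: MR physics (bias fields, Rician
noise at low SNR — noise is Gaussian by design so the designed-CCC
algebra stays exact), endorectal-coil artifacts, zonal anatomy (PZ/TZ),
reader-specific delineation bias, or inter-scanner effects. Passing tests
on the phantom therefore demonstrate the *pipeline's* correctness and
operating characteristics under controlled concordance, not the clinical
repeatability of any specific feature on patient data.

`generateDesignedFeatures()` bypasses imaging entirely: feature $j$ for
subject $i$ is $Test = \mu_{ij} + e_1$, $Retest = \mu_{ij} + e_2$ with
$\mu_{ij} \sim N(0, b_j^2)$ and the measurement SD set so the population
CCC $b_j^2/(b_j^2 + w_j^2)$ equals the requested target (target 0 uses
$b = 0$; target 1 uses $w = 0$). Duplicate blocks are exact affine copies
(population $R^2 = 1$), used to validate redundancy collapse.

# Problem sizes and validation design

The validation suite works at sizes chosen to exercise every code path
while keeping a full run in minutes: texture engines are checked against
independent brute-force enumeration oracles (explicit pair/run/zone/
neighbourhood loops) on fifty random 4×4×4 ROIs at `Ng = 4` to 1e-9;
the repeatability statistics against naive direct-formula implementations
on a thousand random vector pairs to 1e-12; concordance recovery on 100
designed replicates of 60 features at n = 200 (20 replicate features per
target in {0.3, 0.65, 0.9}; the per-target estimate is the mean sample
CCC over its replicate features, whose sampling SD ≈ 0.014 makes the
± 0.05 recovery band meaningful — a single feature's sample CCC at
target 0.3 has SD ≈ 0.064 and could not be held to that band);
perfect-repeatability and end-to-end checks on 5- and 10-patient
phantoms. The noiseless phantom limit (retest ≡ test bitwise) must give
CCC = 1 and DR = 1 for every feature and identical survivor counts on
every cutoff row.

# Known limitations

* Feature values are conventions wherever the source material is silent
  (discretisation, aggregation, wavelet basis, Laws statistic); numeric
  equality with other extractors is not expected, IBSI-aligned
  definitions are.
* The greedy redundancy representative set depends on the DR ordering;
  other valid orderings of the recursive procedure would select different
  (equally justified) representatives.
* DICOM / DICOM-SEG ingestion is out of scope; inputs are NIfTI volumes
  already coregistered and resampled to a common grid per patient.
* With very small cohorts (n = 3–5 pairs) CCC and $R^2$ are extremely
  noisy; the package computes them for any n ≥ 3 but inference at such
  sizes characterises the pipeline, not the features.
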