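---
title: "Methods: enthesis histomorphometry and the cohort correlation layer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enthesis histomorphometry and the cohort correlation layer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enthesomorph)
```

## What the package models

The quadriceps tendon inserts on the proximal patella through a
fibrocartilaginous enthesis whose three parts (lateral, central, medial)
receive load from different muscles: vastus lateralis laterally, rectus
femoris and vastus intermedialis centrally, vastus medialis medially. Load
imbalance between these muscles is thought to remodel both the enthesis
fibrocartilage and the trabecular bone beneath it, and to relate to
patellofemoral cartilage degeneration as scored on the ICRS 0–4 scale.

`enthesomorph` implements the quantitative chain needed to study this on
sectioned material:

1. **Trabecular segmentation** of scanned bone sections by
   Laplacian-of-Gaussian (LoG) zero-crossing detection, with automatic
   exclusion of the cortical shell.
2. **Two-dimensional histomorphometry**: apparent bone area (BA, the 2-D
   analogue of BV/TV), trabecular separation by mean intercept length, and
   derived trabecular thickness indices.
3. **Enthesis morphometry**: calcified (CF) and uncalcified (UF)
   fibrocartilage thickness, five perpendicular measurements per section
   across the attachment width, pooled over a 1-mm slide series.
4. **Cohort statistics**: muscle-volume contributions, the VL/VM volume
   ratio, ICRS consensus grading, lateral/medial ratios, a
   Kolmogorov–Smirnov normality gate, Wilcoxon comparisons, and Spearman
   correlation with categorical strength labels.

Because the raw material is cadaveric and not deposited, a synthetic-data
module generates every input with known ground truth; all accuracy claims
in the test suite are claims about recovery of that ground truth.

## Segmentation

The LoG filter at scale $\sigma$ is the composition of Gaussian smoothing
and the Laplacian; its response is negative inside locally bright regions,
positive inside dark ones, and crosses zero on intensity edges. The kernel
is sampled from the analytic factorization
$L(x,y) = g''(x)g(y) + g(x)g''(y)$, truncated at $4\sigma$, with the
second-derivative samples recentred to sum to zero so a constant image maps
to an exactly zero response; the 2-D convolution is applied as two
separable passes with edge replication.

`zero_crossing_binarize()` colours the partition induced by the
zero-crossing contours: every connected sign region is classified from its
mean source intensity against an Otsu threshold (bright regions are
trabeculae under the scanner convention; `polarity = "dark"` inverts
this). Classifying whole regions rather than pixels is what makes the
binarization robust to noise deep inside homogeneous marrow pools, where
the response hovers around zero and per-pixel signs are essentially
random.

Parameter defaults:

* `sigma_mm`: 3 pixels. Trabeculae in this tissue are roughly 0.07–0.19 mm
  thick; at typical flatbed-scanner resolutions (pixels of 0.02–0.05 mm) a
  3-px kernel resolves them while still suppressing noise.
* `shell_threshold = 0.85`, `band_mm = 1`: the cortical shell is peeled
  from each image edge while a sliding band of width 1 mm keeps a bone
  fraction above 0.85. If no side qualifies, the full image becomes the
  ROI and the result is flagged.

A known property of Marr–Hildreth edges is a small outward displacement on
curved boundaries (zero crossings of a smoothed disk sit slightly outside
it). For minority bone fractions this inflates recovered BA by about +0.02
when struts are only ~2.7$\sigma$ wide; at strut widths of $4\sigma$ and
above the bias falls below ~0.01. The accuracy tests therefore use struts
of at least $4\sigma$, which is also the regime the estimator is intended
for.

## Morphometry

* **BA** is the bone-pixel fraction of the ROI, exact integer arithmetic.
* **Trabecular separation (Tb.Sp)** is the mean marrow intercept length
  along horizontal and vertical scan lines. Runs truncated by the ROI
  border are excluded (censored runs bias the mean downward); if exclusion
  empties the run set — e.g. an all-bone ROI — the censored runs are used
  with a warning rather than failing.
* **TH (printed form)** is reported as $2/(\mathrm{Tb.Sp}/\mathrm{BA}) =
  2\,\mathrm{BA}/\mathrm{Tb.Sp}$. Note this expression has units of 1/mm,
  not mm; it is kept as the headline index for comparability with the
  literature that uses it, and two dimensionally consistent companions are
  reported alongside: the parallel-plate thickness
  $\mathrm{Tb.Sp}\cdot\mathrm{BA}/(1-\mathrm{BA})$ (mm; exact for ideal
  plates, where it equals the strut width) and the directly measured mean
  bone intercept `TH_intercept` (mm).

## Enthesis thickness measurement

The tidemark (mineralization front) is an annotated polyline. CF thickness
is measured at five stations placed at the midpoints of five equal
intervals across the attachment width — the midpoint choice keeps stations
away from the cut ends, where normals are one-sided. At each station a ray
is cast along the local inward tidemark normal (tangent by central
differences) to its intersection with the calcified-zone outer boundary.
For a flat tidemark this reduces exactly to the vertical distance.

UF thickness follows the "furthest recognizable chondrocyte" rule: each
chondrocyte is assigned to the band containing its projection onto the
tidemark, and each band reports the maximum perpendicular distance among
its cells. Empty bands yield `NA` with a warning; a section with fewer
than three valid bands is flagged.

`profile_region()` pools the five-measurement sets over the 1-mm slide
series. The SD is taken over all $5 \times n_\mathrm{slides}$ measurements
by default; "SD of slide means" is available via `sd_of = "slide_means"`
because the pooling level is genuinely ambiguous in practice and the two
differ whenever between-slide variance is appreciable.

## ICRS grading data model

Each grader scores every cartilage defect; a grader's knee grade is the
maximum over defects. Two graders agreeing fix the consensus; on
disagreement a third grade decides by majority, falling back to the median
if all three differ (the adjudication protocol is otherwise unspecified,
and majority-then-median is the minimal total rule consistent with it).
With two graders and no adjudicator the median (possibly half-integral) is
returned.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated; its defaults are fixed at the published cohort values and are
not tuning knobs.

**Trabecular textures.** Five families (stripes, checkerboard, disk,
plate lattice, thresholded Gaussian random field) with controllable bone
fraction and strut thickness. The random field — white noise smoothed at
half the strut width and thresholded at the empirical $(1-\mathrm{BA})$
quantile — is the histology-like family used for round-trip tests. Masks
are rendered at gray levels 200 (bone) and 50 (marrow) with additive
Gaussian noise; the levels are arbitrary but fixed, and segmentation must
not depend on them (it sees only an Otsu split).

**Enthesis sections.** Flat or sinusoidal tidemarks (amplitude 0.1 mm,
wavelength 3 mm: the offset curve stays simple because the offset is below
the minimum radius of curvature, $\lambda^2/4\pi^2 A \approx 2.3$ mm).
The calcified boundary is the exact offset curve at `cf_mm`, and each band
contains one chondrocyte at exactly `uf_mm`, so the construction is its
own oracle.

**Cohort.** A 12-donor, 24-knee cohort by default. Dependence among the
ratio-level variables {VL/VM, UF ratio, CF ratio, BA ratio, TH ratio,
ICRS} is a latent Gaussian copula. For continuous pairs the latent
correlation is $2\sin(\pi r_s/6)$, which maps latent normals exactly to
the target Spearman. The ICRS margin is an ordinal discretization and its
ties attenuate Spearman computed with average ranks, so for ICRS pairs the
attenuated population Spearman is computed by 1-D Gaussian integration and
inverted with `uniroot`; targets above the tie-capped maximum (~0.84 for
the default grade distribution) are rejected with the offending pair
named, as is any non-positive-semidefinite latent matrix.

Marginals are log-normal, matched to the published means and SDs:
muscle volumes sex-specific, medial and central facet values direct, and
**lateral values derived as medial × ratio** so the ratio-level dependence
holds by construction. A consequence worth knowing: the dispersion of the
derived lateral values is implied, not matched, and the ratio dispersions
themselves are delta-method propagations of the facet means/SDs (the
source tables print no ratio SDs).

The ICRS grade distribution is the closed-form solution of
mean $=2.35$, SD $=0.55$ on support $\{1,2,3,4\}$ with symmetric extreme
mass: $p_1=p_4=0.01875$, $p_2=0.63125$, $p_3=0.33125$.

Two knees per donor share a latent donor component with weight
$\sqrt{0.8}$ (leg-to-leg correlation 0.8, exposed as a parameter). No
within-donor correlation is published; 0.8 reflects that muscle volumes
and joint degeneration are strongly but not perfectly bilateral, and the
cross-variable dependence structure is unaffected by its value.

What the generator does **not** emulate: spatial heterogeneity within a
section beyond the texture statistics, staining artefacts, grader bias
(the two graders are symmetric-noise copies of the consensus), any
age or sex dependence of the enthesis variables, and measurement error in
the annotations. Passing round-trip tests therefore demonstrate that the
estimators are correct and well-calibrated under these idealized
conditions — not that they are robust to every artefact of real scanned
histology.

## Statistical layer

* **KS gate**: one-sample Kolmogorov–Smirnov against a normal with the
  sample mean and SD. The plug-in form is anticonservative as a strict
  test (Lilliefors correction would be needed) but it is used here as a
  routing gate to the nonparametric path, matching common practice.
* **Wilcoxon**: signed-rank for paired within-knee comparisons (exact null
  for ≤ 25 untied non-zero differences, normal approximation with
  continuity correction otherwise); rank-sum for independent groups such
  as male vs female totals.
* **Spearman**: Pearson correlation of average ranks; p exact (AS 89) for
  n ≤ 10 without ties, t approximation otherwise. Strength labels use
  half-open intervals on $|r|$ — [0.8, 1] very strong, [0.60, 0.80)
  moderate, [0.30, 0.60) fair, [0, 0.30) weak — making the printed
  category bounds a total, order-consistent map (the printed bounds leave
  gaps at 0.59–0.60 and 0.29–0.30).
* **Unit of analysis**: correlations default to knee level (n up to 24);
  `unit = "donor"` averages the two knees first (n = 12). The published
  analysis does not state which was used; knee level is the default
  because it matches the printed n for the paired comparisons.

## Problem sizes and numerical choices

The test suite and the acceptance script run on deliberately modest sizes
chosen as the package's own validation budget: 192-px sections (4.8 mm at
0.025 mm/px) for segmentation round-trips, 20 seeds for the BA recovery
check, 12 slides for the CF recovery check, 500 knees for the
correlation-recovery check and 8 000 independent knees for the entrywise
copula convergence check. Kernel truncation is $4\sigma$ with a zero-DC
correction; the copula inversion tolerance is $10^{-8}$; all generators
take explicit integer seeds and are bit-reproducible.

## Known limitations

* The printed TH index is dimensionally inconsistent (1/mm); it is
  reproduced verbatim by design, with consistent companions alongside.
* Marr–Hildreth curvature bias (+~0.02 BA) at strut widths below
  $3\sigma$; choose `sigma_mm` (or resolution) so struts are ≥ $4\sigma$.
* The cortical boundary is a rectangle after per-side peeling, adequate
  for sections whose shell hugs the image margin; strongly oblique or
  interior shells would need a contour-following boundary.
* The copula reproduces rank dependence only; joint tail behaviour and
  any real nonmonotone relations are out of scope.
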