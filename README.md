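# enthesomorph

Quantitative histomorphometry of the quadriceps tendon enthesis and the
proximal patella, with the cohort-level correlation analysis that relates
enthesis structure to quadriceps muscle balance and patellofemoral
cartilage status.

## The problem

The quadriceps inserts on the patella through a fibrocartilaginous
enthesis whose lateral, central and medial parts receive load from
different muscles (VL; RF + VI; VM). Imbalance between the vastus
lateralis and vastus medialis — summarized by the **VL/VM volume ratio** —
is suspected to remodel the enthesis and the trabecular bone beneath it
and to track patellofemoral osteoarthritis severity (ICRS grade 0–4).
Testing this requires a chain of measurements on sectioned material:

* **Trabecular segmentation.** Scanned bone sections are filtered with a
  Laplacian-of-Gaussian (Marr–Hildreth) kernel; the zero crossings of the
  response trace the trabecular edges, and the induced sign regions are
  two-coloured into trabeculae (bright) and marrow (dark). The cortical
  shell is detected and excluded automatically.
* **Histomorphometry.** On the binary image: apparent bone area
  `BA = bone pixels / tissue pixels` (the 2-D analogue of BV/TV),
  trabecular separation `Tb.Sp` as the mean marrow intercept length, and
  the trabecular thickness index `TH = 2/(Tb.Sp/BA)` with a plate-model
  companion `Tb.Sp·BA/(1−BA)` in mm.
* **Enthesis morphometry.** Calcified fibrocartilage (CF) thickness:
  perpendicular distance from the tidemark to the outer calcified
  boundary; uncalcified (UF): distance from the tidemark to the furthest
  chondrocyte. Five stations per section, pooled across a 1-mm slide
  series.
* **Cohort statistics.** Muscle contributions (% of total quadriceps
  volume), ICRS consensus grading (max over defects, third-grader
  adjudication), lateral/medial ratios per knee, Wilcoxon comparisons,
  and Spearman correlations labelled very strong (|r| ≥ 0.8), moderate
  [0.60, 0.80), fair [0.30, 0.60), weak (< 0.30).

No raw cadaveric material is distributable, so the package ships a
synthetic-data module that generates every input with known ground truth:
trabecular textures with controllable bone fraction and strut thickness,
annotated enthesis sections with exact CF/UF construction, and a
donor cohort whose ratio-level variables carry a user-specified Spearman
dependence via a latent Gaussian copula (tie-corrected for the ordinal
ICRS margin).

## Worked example

```r
library(enthesomorph)

# segment a synthetic trabecular section at bone fraction 0.49 and measure it
sp  <- texture_spec("gaussian_random_field", target_ba = 0.49, noise_sd = 15, seed = 42)
g   <- gen_trabecular_image(sp)
morphometry(segment_trabeculae(g$image))
#> <morphometry_result> region central: BA 0.490, Tb.Sp 0.419 mm, TH 2.339 (printed),
#>   0.403 mm (plate), 0.415 mm (intercept), ROI 65536 px
```

Recovered BA (0.490) matches the generator's ground truth (0.49); the
plate-model and intercept thickness agree (~0.41 mm), while the printed
`TH` index is on its own 1/mm scale.

```r
# CF/UF thickness on a 4-slide series of annotated central sections
secs <- lapply(1:4, function(i)
  gen_enthesis_section("central", cf_mm = 1.21, uf_mm = 0.62,
                       tidemark_shape = "sinusoid", seed = i, slide_index = i))
profile_region(secs)
#> <thickness_profile> region central (4 slides): CF 1.21 +/- 0.00 mm, UF 0.62 +/- 0.00 mm

# muscle contributions from cohort-average volumes (cm^3), published total
ct <- muscle_contributions(152, 78, 204, 247, total = 682)
#> VM 22.3%  RF 11.4%  VI 29.9%  VL 36.2%

# a 12-donor cohort with the published ratio dependence, correlated ratios
coh <- gen_cohort(cohort_spec(n_donors = 12, seed = 1))
build_table2(knee_ratios(coh))
#> Spearman correlations of lateral/medial ratios (24 knees)
#>          vl_vm uf_ratio cf_ratio ba_ratio th_ratio icrs
#> vl_vm    1     0.76+    0.69+    0.92*    0.78+    0.66+
#> ...
#>   * very strong (|r| >= 0.8), + moderate (0.60 <= |r| < 0.80)
```

At n = 24 knees the sample correlations scatter widely around their
population targets (the `vl_vm`–`ba_ratio` entry is 0.92 here against a
population value of 0.81); at n = 500 they land within ±0.05.

A full pipeline run (images → masks → morphometry, sections → thickness
profiles, cohort → summary + correlation tables, plus a JSON manifest):

```r
run_pipeline(pipeline_config("out/run1", seed = 1))
```

A thin command-line wrapper is installed at `inst/cli/enthesomorph`
(`simulate images|sections|cohort`, `report`).

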