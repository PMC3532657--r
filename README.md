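# residuoscope

Quantitative analysis for wide-field intraoperative fluorescence imaging of
microscopic residual tumor.

After gross resection of a soft-tissue sarcoma, microscopic clusters of tumor
cells left in the tumor bed drive local recurrence. A wide-field epi-
illumination imager viewing a protease-activated near-infrared probe can make
those clusters visible during surgery: the excised tumor is imaged first, a
per-subject intensity threshold is derived from it, and the tumor bed is then
called **positive** or **negative** for residual fluorescence — a call that
risk-stratifies subjects for recurrence and can guide further resection until
the bed is clear. `residuoscope` implements that analysis chain as a tested R
package, together with a synthetic-phantom and cohort generator so every stage
can be exercised end to end without instrument data.

## What it computes

- **Emission rates.** Raw CCD counts are exposure-normalized to the
  time-independent emission rate `(counts − background) / t` in counts/s
  (`normalize_by_exposure()`), with device linearity checked against
  microsphere series over 1–250 ms and a 250-fold (0.4%–100%) intensity range
  (`fit_exposure_linearity()`, `fit_intensity_linearity()`).
- **Resolution.** Bar-target analysis via the contrast transfer function
  `CTF(f) = (I_max − I_min) / (I_max + I_min)` at spatial frequency `f`
  (cycles/mm); the resolution limit is the first downward crossing of a
  configurable cutoff, converted to micrometres as one full line cycle,
  `1000 / f` (`measure_ctf_curve()`, `frequency_to_resolution()` — 62.8
  cycles/mm ↦ ≈ 16 μm).
- **Quantification.** ROI means and the tumor-to-muscle signal ratio
  (`tumor_to_muscle_ratio()`); the per-subject threshold
  `0.8 × min(tumor emission rate)` (`calibrate_threshold()`); and
  connected-component bed classification (`classify_bed()`).
- **Guided resection.** An iterative remove-reimage loop on phantom beds with
  optional revelation of deeper cluster layers (`run_guided_resection()`),
  scored against ground truth (`score_detection()`).
- **Survival.** Kaplan–Meier product-limit curves with Greenwood variance,
  the two-group log-rank test, and two-arm proportional-hazards estimation
  (Breslow ties, Wald CIs) linking classification to recurrence
  (`km_estimator()`, `logrank_test()`, `hazard_ratio()`).
- **Synthesis.** Seeded generators for blurred bar targets, microsphere
  calibration series, tumor/muscle/bed phantom triples with truth masks, and
  two-arm recurrence cohorts under exponential (optionally Weibull)
  proportional hazards (`make_bar_target()`, `make_microsphere_series()`,
  `make_tumor_bed_pair()`, `simulate_cohort()`).

## Worked example

```r
library(residuoscope)

spec <- acquisition_spec(frame_shape = c(120L, 160L), exposure_time = 100)
pair <- make_tumor_bed_pair(spec, tumor_rate = 2400, muscle_rate = 200,
  residual_clusters = data.frame(diameter_um = 16, rate = 2400,
                                 center_row_um = 400, center_col_um = 500),
  heterogeneity_cv = 0.2, noise = "on", seed = 42L)

tumor <- normalize_by_exposure(pair$tumor)
bed   <- normalize_by_exposure(pair$bed)
roi   <- segment_tumor(tumor)

tumor_to_muscle_ratio(tumor, roi, normalize_by_exposure(pair$muscle),
                      matrix(TRUE, 120, 160))
#> [1] 12.01   # constructed at 12, recovered under shot noise

model <- calibrate_threshold(tumor, roi, fraction = 0.8, subject_id = "m01")
#> threshold_model [m01]: 880 counts/s = 0.80 x tumor min 1100 (literal-min)
classify_bed(bed, model)
#> bed_classification: positive (max rate 2620 vs threshold 880; 6 supra px)
```

The bed carries a single 16-μm residual cluster (6 truth pixels at 6.5
μm/pixel); the 80%-of-tumor-minimum threshold finds it. Cohort-level
inference recovers a generative hazard ratio:

```r
co <- simulate_cohort(cohort_spec(25, baseline_hazard = 0.03,
                                  true_hazard_ratio = 4.7, seed = 7L))
hazard_ratio(co[co$arm == "residual_negative", ],
             co[co$arm == "residual_positive", ])
#> hr_result: HR 4.77 (95% CI 2.08-10.9), Wald P = 0.000219, log-rank P = 5.95e-05
```

## Command line

`inst/cli/residuoscope` exposes subcommands `simulate`, `calibrate`, `ctf`,
`quantify`, `classify`, `resect`, `survival`, `experiment` with common
`--seed`, `--config`, `--out` flags, e.g.

```sh
inst/cli/residuoscope classify --tumor t.tif --bed b.tif --fraction 0.8 --out report/
inst/cli/residuoscope survival --cohort cohort.csv --out report/
```

Images are uncompressed grayscale TIFFs with acquisition metadata in the
ImageDescription tag; plain TIFFs from other tools work with
`--exposure-ms`. Cohort CSVs use the header
`subject_id,arm,time_months,event`.

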