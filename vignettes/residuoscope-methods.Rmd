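---
title: "residuoscope: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{residuoscope: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`residuoscope` reimplements the quantitative core of intraoperative
wide-field fluorescence imaging for residual-tumor detection: device
calibration, resolution characterization, per-subject thresholding, bed
classification, a guided-resection loop, and recurrence survival analysis,
all exercised on synthetic phantoms and simulated cohorts. This vignette
records the models behind each stage, why the defaults are what they are,
and where the design was genuinely open.

## The forward imaging model

A scene is a map of emission rates $\lambda(x,y)$ in counts/s/pixel. The
camera converts it to counts at exposure time $t$ (ms):

$$ C = \mathrm{Poisson}(\lambda\, t) + \mathcal{N}(0, \sigma_r^2) + o, $$

rounded and clipped to $[0, 2^{b}-1]$, with read noise $\sigma_r$ (default 5
counts), dark offset $o$ (default 100 counts), and bit depth $b = 16$. The
instrument this emulates was only ever described as linear in exposure and
intensity; shot + read noise with a constant offset is the standard CCD
contract and is the package's own modeling choice, not a published one.

With noise `"off"` the counts are kept as the *real-valued* expectation
$\lambda t + o$, deliberately skipping integer quantization: at a 1 ms
exposure, rounding alone would inject up to 500 counts/s of error into the
normalized rate, which would contradict the exact exposure-invariance
contract the noise-free mode exists to verify.

Geometry defaults place 6.5 μm pixels at 1:1 magnification, so a full
1015 × 1385 frame spans the instrument's 9.0 × 6.6 mm field of view. Tests
and the virtual experiment use reduced frames (e.g. 120 × 160 px); frame
shape is a free parameter and nothing in the analysis depends on it beyond
pixel count.

## Exposure normalization

`normalize_by_exposure()` computes $(C - \hat{o})/t$, floored at zero. The
background estimate $\hat{o}$ defaults to the metadata dark offset when
present and otherwise the 1st percentile of the frame; whether the original
workflow subtracted any background at all is undocumented, so the method is
recorded in the provenance and can be forced to `"none"` or a constant.
Pixels at ≥ 98% of full scale are flagged; above 1% saturated pixels the
provenance carries a warning. Note one physical consequence of the zero
floor: when a region's signal is within a few noise standard deviations of
zero, clipping biases its mean upward. The test suite measures dim regions
at 250 ms for this reason rather than papering over the bias.

## Resolution analysis

Bar targets follow the three-bar convention of the USAF-1951 chart. Groups
are rendered analytically: a square wave of period $P = 1000/f$ μm
(frequency $f$ in line cycles/mm) convolved with a Gaussian PSF of width
$\sigma$ has the closed form of differenced normal CDFs, evaluated at pixel
centres, with bar and gap centres aligned to pixel centres so that sampled
extrema coincide with continuum extrema.

Contrast is measured as the modulus

$$ \mathrm{CTF}(f) = \frac{I_{max} - I_{min}}{I_{max} + I_{min}}, $$

where $I_{max}$ is the mean of the per-bar profile maxima and $I_{min}$ the
mean of the per-gap minima, on the profile averaged along the bar direction.
The source text names $I_{max}$ and $I_{min}$ but its equation is an
unrecoverable figure; the standard square-wave modulus above is the only
form consistent with the named variables, and it is adopted here. Under deep
blur, pixel sampling can invert a vanishing modulation by a hair; the
measurement clamps that case to zero contrast rather than erroring.

The *resolution limit* is the first downward crossing of a cutoff,
linearly interpolated between measured frequencies. No cutoff was published;
the default is CTF = 0.1 and it is always reported alongside the limit.
Spatial resolution is one full line cycle, $1000/f$ μm — the only convention
under which the published 62.8 and 63.0 cycles/mm limits round to the
published "approximately 16 μm".

The CTF pipeline is validated against an independent brute-force oracle: a
1-D numerical convolution of the bar pattern with the Gaussian kernel on a
0.05 μm grid, summarized with the same per-bar/per-gap rule. Agreement is
enforced to 2% wherever the oracle contrast is at least 0.05; below that a
relative criterion stops being meaningful against 6.5 μm sampling.

## Microsphere calibration

`make_microsphere_series()` renders non-overlapping flat-top spheres at
nominal brightness fractions (the instrument was characterized over
0.4%–100%) and exposures (1–250 ms), reusing placements across the grid so
ratios are exact by construction. Truth rates are capped at
$\mathrm{full\ well}/t_{max}$ so no configuration can exceed saturation.

Sphere intensity is the mean over the sphere footprint (pixel-centre disc of
the sphere's own radius; `margin_px = 0`). An earlier convention of radius
+ 1 px was considered and rejected: with flat-top spheres the extra annulus
only admits background pixels and dilutes the mean by $(r/(r+1))^2$ — about
36% for a 3-pixel radius — which would defeat the requirement that the
intensity-linearity slope estimate the brightest sphere's emission rate
(to 5%). The margin remains available as a parameter for blurred or real
data, where spilled flux makes it meaningful.

## Thresholding and classification

The subject-specific threshold is
$\theta = \mathrm{fraction} \times \min(\text{tumor emission rate})$, with
fraction 0.8 — the published rule. Two open details are resolved as
follows:

- **"Minimum":** by default the literal minimum over the tumor ROI *after a
  3 × 3 median filter*, which rejects isolated dead pixels that would
  otherwise send the threshold to zero; a percentile statistic (e.g.
  `percentile(1)`) is exposed as the robust alternative, and on noisy
  phantoms it stays within 5% of the noiseless literal minimum.
- **Positive call extent:** a bed is positive when some 8-connected
  supra-threshold component reaches `min_cluster_px` = 4 pixels (≈ 13 μm
  across at default pitch) — small enough to honor the instrument's 16 μm
  sensitivity claim, large enough that a single noisy pixel cannot flip a
  bed. It is configurable down to 1. No minimal extent was ever published.

Classification operates on emission rates on both sides, so it is invariant
to the exposure time of the raw bed frame — verified exactly for noiseless
scenes from 1 to 250 ms. Coordinates are 0-based (row, col) in reports;
areas are reported in μm² via pixel pitch squared.

Display transfer for publication maps the tumor image's own [min, max]
linearly to [0, 255] with clipping and applies the identical map to all
images of the same subject; rounding is round-half-to-even (base R). The map
is intentionally not idempotent — its output is a display scale.

## Guided resection

`run_guided_resection()` repeats classify → remove → re-image. Removal takes
each supra-threshold component dilated by `margin_px` (default 2 px; no
removal geometry was published, so the margin is a free parameter), reverts
the removed tissue to the muscle background rate, and clears its truth
pixels. Serially positive beds are emulated by a *reveal model*: pre-placed
deeper cluster layers are exposed with a per-step Bernoulli probability.
This is a simulation construct for generating multi-step traces, not a
biological claim. The loop always terminates within `max_steps`; persistent
positivity is flagged, not raised.

## Survival analysis

Kaplan–Meier estimation uses the product-limit form with Greenwood variance
(set to 0 at the terminal point where $\hat S = 0$, where the formula
degenerates). The two-group log-rank test uses hypergeometric variances with
the standard tie correction. The hazard ratio maximizes the partial
likelihood of a single binary covariate with Breslow tie handling by
safeguarded Newton–Raphson; the published analyses never name their HR
method, so this conventional choice is recorded, a Mantel–Haenszel O/E ratio
is included as a cross-check, and both Wald and log-rank p-values are
reported because it is equally unstated which was printed. When one arm has
no events the likelihood is monotone: the estimate is reported as 0 or ∞,
flagged non-estimable, with a one-sided 95% profile-likelihood bound.
Everything is verified against brute-force risk-set enumeration on small
datasets and against `survival::survfit` / `survdiff` / `coxph` as an
independent oracle on random censored data.

Three-arm comparisons (single-negative, single-positive,
multi-resection-cleared) are expressed as declared pairwise contrasts; no
global trend test is attempted, matching how such results are reported.

## The synthetic cohort

`simulate_cohort()` draws event times with cumulative hazard $h\,t^a$
(shape $a = 1$, i.e. exponential, by default; the Weibull shape is exposed
for robustness checks) with the positive arm's hazard a clean proportional
multiple of the baseline at every shape. Administrative censoring applies at
12 months, the stated follow-up horizon. Default baseline hazard 0.03
events/month puts the negative arm at ≈ 30% cumulative recurrence over
follow-up — a scientist's-choice calibration (no per-arm event rates were
published), fixed once and not revisited.

## What the generator does and does not emulate

Emulated: exposure/intensity linearity with shot + read noise; Gaussian-blur
resolution loss on bar targets; tumor/muscle contrast at probe-specific
ratios; microscopic residual clusters down to 16 μm with exact pixel-level
ground truth (the stand-in for reporter-gene histology); lognormal
multiplicative tissue texture (CV 0.2 by default, chosen to look like real
heterogeneity — qualitative only, never asserted quantitatively);
proportional-hazards recurrence with censoring.

Not emulated: optical PSF physics beyond a Gaussian; spectral properties of
the reporter or probes; tissue depth attenuation (signal from below the bed
surface is simply invisible here, as it largely is to epi-illumination);
3-D tissue mechanics; surgeon behavior. A green test therefore establishes
the *analysis chain* — not instrument physics, and not biology. In
particular, published animal endpoints (specific hazard ratios,
tumor-to-muscle means) are validated only by parameter-recovery simulation
at matching generative values, because the underlying images and event
times were never deposited.

## Numerical and interface choices

- Seeds are explicit everywhere; generators restore the caller's RNG state.
  Derived child seeds stay below $2^{31}$.
- Background Otsu thresholding (256 bins) with largest-component selection
  segments phantom tumors; constant images are rejected as degenerate.
- Linear fits are ordinary least squares; noise-free fixtures fit exactly
  and the perfect-fit warning from `summary.lm` is silenced at the source.
- Images travel as uncompressed grayscale baseline TIFF (8/16-bit, single
  strip, little-endian) with acquisition metadata as JSON in the
  ImageDescription tag. No R TIFF bindings exist in the target environment,
  so the package carries a minimal codec for exactly this dialect;
  round-trips are tested, and plain TIFFs from other tools are accepted
  with an explicit `--exposure-ms`.
- Configuration files are JSON (read by `jsonlite`) rather than YAML — the
  deployment environment guarantees no YAML parser — with hand validation
  and an MD5 config hash stamped into experiment outputs for provenance.

## Known limitations

- The pure-R connected-components and median-filter passes are adequate for
  the frame sizes used here but would want compiled support for full-frame
  (1.4 Mpx) batch studies.
- The non-estimable HR bound is a profile-likelihood approximation; exact
  conditional inference (as in rare-event epidemiology) is out of scope.
- Sphere detection assumes well-separated flat-top spheres; clumped or
  blurred spheres would need matched-filter detection.
- The guided-resection margin and reveal probability shape the step-count
  distribution directly; conclusions about "number of resections needed"
  are conditional on those two knobs.
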