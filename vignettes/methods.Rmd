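---
title: "Methods: image-quality evaluation for dose-reduced chest CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-quality evaluation for dose-reduced chest CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ctiq` implements the quantitative and observer-based methodology used to
compare chest-CT reconstructions acquired at different dose levels: noise
texture via anatomical power spectra, contrast via aorta/fat CNR with paired
statistics, resolution via vessel line profiles, dose via DLP-to-effective-dose
conversion, and subjective quality via visual grading characteristics (VGC)
analysis with bootstrap uncertainty. Because clinical DICOM series and reader
panels are rarely shareable, the package pairs every analysis stage with a
synthetic counterpart — phantom stacks with controllable noise spectra and a
latent-threshold rating simulator — so the whole pipeline can be validated
end to end against known ground truth.

## Power-spectrum estimation

For each axial slice, four non-overlapping 64 × 64-pixel ROIs tile the central
128 × 128-pixel window ([extract_central_rois()]). Each ROI is mirrored about
its right and bottom edges into an even-symmetric 128 × 128 block
([mirror_roi()]), which suppresses the edge/leakage artefacts of transforming
patches of strongly correlated images; the block mean is subtracted and the
spectrum is `(Δx² / N) |DFT|²` in HU² mm² ([roi_power_spectrum()]). The
examination spectrum is the mean over all ROIs of all slices
([examination_ps()]); radial averaging into bins one frequency-grid step wide
(DC excluded, empty bins dropped) yields the 1-D curve ([radial_average()]);
cohort curves attach the per-bin relative standard error
`100 · (SD/√n) / mean` across patients ([cohort_ps()]).

Design choices where the method leaves room:

* **Mean subtraction only.** Only the per-ROI mean is removed before the DFT;
  no background detrending is applied. This removes the dependence on absolute
  HU offset while retaining anatomy-driven low-frequency power — the curves are
  power spectra of anatomical images, not pure noise power spectra.
* **Mirroring convention.** The 2N × 2N even-symmetric reflection; the
  frequency spacing therefore uses the mirrored side, `1/(128 · Δx)` at the
  defaults. The DFT of a mirrored block is real up to grid phase factors (a
  cosine transform), which the suite verifies numerically.
* **Parseval as an invariant.** Summing the 2-D spectrum times the bin area
  equals the mean per-ROI pixel variance (population divisor) *exactly*; the
  suite asserts this to float tolerance on every examination, and recovery of a
  known generating noise variance to within 2%.
* **Estimator limits.** With 64-pixel ROIs the estimator has an effective
  spectral resolution of a few hundredths of mm⁻¹ and leaks power from spectral
  peaks into neighbouring bins. For smooth (low-pass) spectra the radially
  averaged estimate recovers the generating filter to ~3% RMS over
  0.05–0.8 · Nyquist (40 slices); for a strongly band-pass "sharp kernel"
  spectrum the lowest-frequency bins — where the target is ~15× below the
  peak — are biased upward by 30–100%, and recovery to 5% holds only above
  ~0.15 mm⁻¹. This is a property of small-ROI spectrum estimation, not of the
  implementation; tests assert both behaviours explicitly.
* The Nyquist-corner bin of a mirrored block is structurally zero; its
  relative SE is reported as 0 rather than 0/0.

## CNR and line profiles

`CNR = (HU₁ − HU₂) / √(SD₁² + SD₂²)` over two 15-mm circular ROIs (aorta and
mediastinal fat by convention). Pixels belong to an ROI iff their centre lies
inside the circle (orientation-independent and reproducible); SDs use the
n − 1 divisor — with ~300 pixels per ROI the divisor choice is numerically
negligible but must be fixed for bit-stability. Per-patient differences
between two reconstructions, `CNR₁ − CNR₂`, are summarised by their mean and
SEM and tested with a two-sided paired Student t-test (df = n − 1, α = 0.05)
via `stats::t.test`; the difference is the plain arithmetic difference, with
no normalisation. Zero-variance differences are flagged degenerate rather
than fed to the t-test.

Line profiles sample the segment between two mm-coordinate endpoints at
uniform steps (default half the pixel spacing; the requested step is rounded
so the endpoints are always sampled) with bilinear interpolation between
pixel centres; a nearest-neighbour mode reads exact pixel values. Identical
endpoints can be applied across reconstructions of the same anatomy, which is
how resolution differences over small vessels are visualised.

## VGC analysis

Paired ordinal ratings (two conditions per case × reader × question) are first
oriented so that larger always means better: reading-form
("questionnaire"-coded) scales, where 1 is the best answer, are reversed
(`oriented = k + 1 − raw`); synthetic sets are generated in `higher_better`
coding and pass through unchanged. The rating container carries this coding
explicitly because the two conventions are irreconcilable from the numbers
alone.

The VGC curve plots, for each threshold t from k down to 1, the fraction of
reference ratings ≥ t against the fraction of test ratings ≥ t. The area under
it, `AUC_VGC`, is computed through the rank-sum form of the equivalent
pairwise statistic `P(test > ref) + ½ P(test = ref)` over all pooled
test × reference pairs — algebraically identical to the trapezoid area (the
suite asserts the identity) but exact in floating point, so identical rating
multisets give 0.5 *exactly*. The statistic is rank-invariant: any strictly
monotone relabelling of the categories leaves it unchanged. A parametric
alternative fits the binormal model (shared cut-points, reference latent
N(0,1), test latent N(μ, σ²)) by maximum likelihood with `stats::optim`;
`AUC = Φ(μ / √(1 + σ²))`.

Bootstrap uncertainty uses percentile intervals (default 2000 replicates, a
mandatory seed):

* **fixed-reader** — cases are resampled with replacement; every original
  reader's paired ratings for each drawn case are kept, so conclusions apply
  to the participating readers;
* **random-reader** — readers are resampled with replacement first, then
  cases, so conclusions generalise to a reader population at the price of
  wider intervals (the suite verifies the widening on average).

Pairing is preserved throughout: a drawn case contributes both its test and
reference ratings. Significance is reported as the 95% CI excluding 0.5.
AUCs are pooled over readers and cases per question (the curve construction
forces pooled empirical distributions); per-reader AUCs are reported as
diagnostics. Under the null (no condition difference, 25 cases × 5 readers),
the fixed-reader interval covers 0.5 in ~93–95% of simulated studies.

## The synthetic data generators

**Phantom stacks.** A deterministic chest-like phantom (body ellipse, two lung
fields at −850 HU, a 45-HU aorta disk, a −100-HU fat disk, 1–4-mm vessels at
50 HU) is rasterised by pixel centre at 512 × 512 px and 0.75 mm spacing.
Noise is stationary Gaussian, shaped by multiplying the DFT of white noise
with a radial amplitude filter — the square root of the target power
spectrum — which gives exact stationary control of the spectrum. Two named
filters emulate the kernel contrast of CT reconstructions: a band-pass
`(f/f_p) exp((1 − (f/f_p)²)/2)` peaked at 0.35 mm⁻¹ (sharp/lung kernel:
higher resolution, more noise) and a Gaussian low-pass `exp(−(f/f₀)²)` with
f₀ = 0.30 mm⁻¹ (smooth/standard kernel). The whole-stack noise SD is scaled
to `σ_ref · dose^(−1/2)` exactly (quantum-noise dose scaling). Edge
enhancement is unsharp masking, `x + gain · (x − blur(x, σ))`: the simplest
surrogate with the observable consequences of a vendor edge filter (raised
high-frequency spectrum, sharper profiles, amplified noise and hence slightly
lower CNR); its gain and radius are free parameters, not calibrated to any
proprietary filter.

**Ratings.** A cumulative-threshold (ordered-categories) latent model: latent
value = condition mean (0 or δ) + case effect + reader effect + residual, with
case and reader effects shared between conditions (the paired design), and the
category is 1 + the number of cut-points below the latent value. With zero
case/reader effects the population AUC has the closed form `Φ(δ/(σ√2))`,
enabling parameter-recovery tests.

**Discretisation bias.** The empirical AUC of k-category data converges to the
*categorical* exceedance probability, which is strictly below the latent
closed form: at δ = 1, σ = 1 the best 5-category value is ≈ 0.7487 against
Φ(1/√2) ≈ 0.7602, for *any* cut-point placement. Recovery experiments
therefore use cut-points centred between the condition means
(δ/2 + {−1, −⅓, ⅓, 1}), the placement that loses least information, and
compare the median over five simulated studies of 2000 cases with the
closed form at a 3-SE tolerance (SE ≈ 0.0075): the residual ~0.012 bias is an
inherent property of rank statistics on coarsely discretised data, and a
single-study check sits close enough to the tolerance edge to fail for
unlucky draws. The binormal estimator, which models the discretisation, is
consistent for the latent AUC and recovers it without this bias.

## The six-arm study replica

`run_study()` crosses two protocols (full dose; ultra-low dose) with three
reconstruction styles (sharp kernel + high noise; smooth kernel + low noise;
the latter plus edge enhancement) and runs every stage on each arm. Defaults
mirror a 25-patient, 5-reader, 10-question study (six 5-step criterion
questions, four 3-step acceptability questions) and were chosen once, on
physical grounds:

* full-dose noise SDs 35 HU (sharp) and 12 HU (smooth); ULD arms share the
  shapes with relative dose `(31/85)² ≈ 0.13`, i.e. noise ×2.7 — the ratio of
  typical noise-index settings, not the 2% effective-dose ratio, because tube
  current floors keep ULD noise from scaling with dose all the way;
* reconstruction PSF (Gaussian SD) 0.6 mm for the sharp kernel and 1.0 mm for
  the smooth kernel: real reconstructions have finite resolution, and without
  this blur the rasterised phantom's step edges carry so much high-frequency
  anatomy power that the edge-enhanced arm would overtake the sharp-kernel arm
  in the spectrum — an artefact of perfect edges, not a property of the
  methods;
* unsharp-mask gain 0.6, radius 1.0 mm for the edge-enhanced arm;
* a per-patient log-normal noise multiplier (CV 0.15), shared across a
  patient's arms because one acquisition feeds all reconstructions of a
  protocol; this habitus surrogate gives cohort PS relative standard errors of
  a few percent at n = 25, the order observed in patient cohorts;
* latent rating shifts 0.6 (full dose) and 1.0 (ULD) for the smooth-kernel
  arm over the sharp-kernel arm — denoising helps most where noise is worst;
* dose records drawn around mean DLPs equivalent to 2.5 mSv and 0.05 mSv
  through the chest coefficient 0.015 mSv/(mGy·cm), with the cohort means
  pinned so the 2% ratio is exact;
* six slices per examination at 512 px (tests use smaller stacks): the
  spectra average 24 ROI spectra per examination, enough for stable cohort
  curves while keeping a full 25-patient, six-arm run within a couple of
  minutes.

Every stage seed derives from the global seed by hashing a stage label
(`derive_seed()`), so adding a stage never perturbs existing streams; the
derived integers are used only to seed R's RNG, never as random numbers
themselves. Two runs with the same configuration are bit-identical.

## What the synthetic validation does and does not show

The generators emulate *paired reconstructions of identical anatomy differing
in noise magnitude, noise texture and edge sharpness*, and *paired ordinal
ratings with known ground-truth separation*. Passing tests therefore show
that the estimators recover known spectra, CNR orderings, dose arithmetic and
rating separations correctly, and that the bootstrap attains nominal
coverage — on data satisfying the generators' assumptions (stationary
Gaussian noise, slice-identical anatomy, a correctly specified latent rating
model, no reader drift or learning effects). They do not show anything about
vendor reconstruction algorithms, non-stationary or non-linear noise in real
iterative/deep-learning reconstructions, reader behaviour beyond the latent
model, or patient-specific CNR magnitudes. Directional results on the six-arm
replica (which arm's spectrum dominates at high frequency, which arm wins on
CNR, fixed vs random reader interval widths) are forced by construction and
serve as end-to-end plumbing checks, not as clinical findings.

## Degenerate inputs and numerical conventions

Validation errors name the offending entity (ROI outside the image, unpaired
(case, reader) cell, out-of-range rating with its row). Zero-variance CNR
differences short-circuit the t-test (t = 0, p = 1 when the mean difference is
also zero). The binormal fit refuses single-category data. Bootstrap
quantiles use `stats::quantile` defaults (type 7). ROI pixel inclusion,
profile step rounding and the SD divisor are fixed as described above so that
all generators and estimators are bit-reproducible under a fixed seed.
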