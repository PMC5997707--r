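---
title: "Models and methods: energy-transfer analytics for hybrid BRET-FRET biosensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: energy-transfer analytics for hybrid BRET-FRET biosensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybret)
```

## The system being modelled

A hybrid BRET-FRET (hyBRET) biosensor is a single-chain kinase-activity
reporter carrying three emitters: a YFP acceptor, a CFP donor, and the
luciferase RLuc8 fused to the CFP. The same molecule can be read out in
two modes. Under 440 nm excitation it behaves as a conventional FRET
biosensor: phosphorylation changes the intramolecular CFP-to-YFP transfer
efficiency `E_CY`, read as the yellow/cyan emission ratio. With the
substrate coelenterazine-h it becomes a BRET reporter: the luciferase
excites the CFP (efficiency `E_RC`), which relays energy onward to YFP,
so the same yellow/cyan ratio reports activity with no excitation light
at all. This package implements the computational side of that design:
forward emission-spectrum models, transfer-rate estimation, ratiometric
image analysis, and microplate screening analytics, together with a
seeded synthetic-data generator that stands in for the undeposited raw
data.

## Forward emission models

The models are steady-state branch-ratio bookkeeping. Each excitation (or
catalytic) event either stays on its emitter or transfers, and each
branch contributes that emitter's area-normalized emission shape `f(λ)`
weighted by its quantum efficiency `φ`:

* Fluorescence mode:
  `F(λ) = ε_C [(1−E_CY) φ_C f_C(λ) + E_CY φ_Y f_Y(λ)] + ε_Y φ_Y f_Y(λ)`
* Bioluminescence mode:
  `B(λ) = E_RC (1−E_CY) φ_C f_C(λ) + (E_RY + E_RC E_CY) φ_Y f_Y(λ) + (1−E_RC−E_RY) φ_R f_R(λ)`

with NanoLuc analogues obtained by substituting `E_NC`, `E_NY`, `φ_N`,
`f_N`. The three bioluminescence branch weights always sum to one — that
partition-of-unity is asserted in the test suite at machine precision and
is the invariant the whole estimation scheme rests on.

Design choices worth stating explicitly:

* **Amplitude.** The published equations describe shapes, not counts. A
  single free positive amplitude multiplies every model spectrum so that
  raw-count spectra can be fitted directly; area-normalized comparisons
  recover it from the area constraint. No other scale parameter exists.
* **Excitation coefficients.** Only relative excitation survives the free
  amplitude, so `ε_C` is fixed at 1 and the YFP cross-excitation term is
  `cross_excitation_fraction × eps_ratio`, where the fraction (default
  0.029) is the YFP extinction at the donor-excitation line relative to
  its maximum, and `eps_ratio` is the extinction ratio of the two
  fluorophores at their respective wavelengths.
* **Wavelength grid.** The canonical grid is 400-700 nm at 2 nm, the
  resolution of the photonic multichannel analyzer the spectra emulate.
  Other grids are linearly interpolated; extrapolation outside a
  reference shape's support is a hard error rather than a silent zero.
* **Instrument response.** Detector spectral sensitivity is assumed to be
  folded into the measured reference shapes. An optional per-wavelength
  weight vector is exposed on both forward models for cases where a
  separate correction is available; the default is uniform.

### The photophysics profile

`solve_E_RC()` inverts the mixture
`φ_CNL = φ_C E_RC + φ_R (1−E_RC)` for the luciferase-to-CFP efficiency.
The measured quantum-efficiency table of the original characterization is
not publicly deposited, so the packaged default profile
(`inst/extdata/synthetic-photophysics.yml`) is a synthetic transcription:
literature-typical values for the emitter classes involved
(Turquoise-family CFP 0.84, YPet-family YFP 0.77, RLuc8 0.053), with the
fusion efficiency `φ_CNL = 0.15531` consistent with the published
`E_RC = 0.13`. Every result that depends on these constants is therefore
conditional on the profile; users with measured values supply their own
key-value file to `read_photophysics()`. A result of `solve_E_RC` outside
`[0, 1]` raises an error — clipping would hide inconsistent photophysics.

## Transfer-rate estimation

`fit_E_CY()` and `fit_E_RY()` minimize unweighted sums of squared
residuals between a measured spectrum and the forward model, over one
free transfer rate plus the amplitude. Choices:

* **Optimizer.** Bounded Levenberg-Marquardt (`minpack.lm`), multi-started
  from rates {0.1, 0.3, 0.5, 0.7, 0.9}; the best objective wins and ties
  break toward the smaller rate, so the estimate is a deterministic
  function of the data. The test suite checks that disjoint starting
  grids reach the same minimum to 1e-8 RMS — the optimum, not the solver
  path, carries the result.
* **Weights.** Unweighted SSE by default; optional inverse-variance
  weights accommodate Poisson counting noise. At the count levels the
  generator emulates (peak 1e4) the difference is negligible next to the
  parameter's sampling error.
* **Order of estimation.** `E_RC` comes from quantum efficiencies alone
  and is held fixed (the luciferase-CFP linker is engineered to be
  rigid); `E_CY` is fitted from the fluorescence spectrum and then fixed
  in the bioluminescence fit (the FRET and BRET modes share one
  conformation distribution). `E_RY` is bounded to `[0, 1−E_RC]` so the
  residual luciferase branch stays nonnegative. The two rates are never
  re-fitted jointly; that assumption is part of the model, not a
  numerical convenience.
* **Baseline.** No additive baseline is floated: the synthetic spectra
  are background-free and measured inputs are expected
  background-subtracted. (The fitter operates on raw vectors, so a user
  can subtract a constant beforehand without touching the machinery.)
* **Uncertainty.** The 95% intervals and pointwise curve envelopes come
  from a seeded residual-resampling bootstrap (default 300-500
  replicates, refitted from the point estimate). Spectrum residuals are
  heteroscedastic under photon noise, which the resampling handles
  without a variance model; the delta-method band
  (`delta_method_band()`) is kept as a linearized cross-check and the two
  agree to ~10% under homoscedastic noise in the tests. Fewer than 50
  replicates draws a warning but still computes.

## Ratiometric imaging

`preprocess_stack()` runs, per channel and frame: cosmic-ray removal
(single-frame spatial test: a pixel is replaced by its 3×3 median when
its robust z-score against that median exceeds `spike_z`; a temporal test
would be natural for video but luminescence exposures run 6-30 s and
frames are few), a spatial median filter (an exact windowed median —
documented stand-in for the proprietary denoising software used on the
original images; ratio statistics, not pixel-exact images, are the
quantity of record), and background subtraction. The default background
estimate is the histogram mode of the darkest 25% of pixels, per channel
per frame; a measured value can be supplied instead and is echoed into
the run manifest.

`compute_ratio()` is deliberately the same operation in both modes —
yellow over cyan on the mask of pixels whose denominator clears
`min_denominator` — because in BRET mode the cyan bandpass physically
collects CFP and luciferase emission together, which is exactly the
denominator the BRET ratio is defined over. Two invariances matter and
are tested: the ratio is unchanged by any gain common to both channels
(in particular by substrate decay, which multiplies both channels by the
same per-frame factor — the computational reason BRET time courses are
robust to the minutes-scale decay of coelenterazine), and it scales
linearly under a gain applied to one channel only.

The intensity-modulated display (`render_imd()`) uses exactly eight hue
bins from blue (low ratio) to red (high) over a user range
`[r_min, r_max]`, values clipped to the end bins, with brightness set by
the mean of the two channels rescaled over a 1-99% percentile window;
masked-out pixels are black. Linear unmixing of two co-expressed
luminophores (`unmix_two_luminophores()`) solves the per-pixel 2×2 system
given the channel signatures, clips negative abundances to zero, and
reports the residual map so saturated or mis-modelled pixels are visible.

Cell segmentation is out of scope by design: labels are either supplied
or come from the generator's ground truth. Per-cell traces use the median
ratio over the labelled pixels and `normalize_timecourse()` divides by
the pre-stimulus mean, making baselines exactly 1.

## Plate analytics

`zprime()` implements `1 − 3(SD₀+SD₁)/(Ave₀−Ave₁)` with sample (n−1)
standard deviations (the screening-statistics convention) and the
denominator oriented untreated-minus-treated.

`hill_fit()` fits the decreasing Hill form
`r(X) = min + amp·IC50^nH/(X^nH + IC50^nH)`. IC50 is parameterized on the
log scale for conditioning (reported in linear µM), `min`/`amp`
initialize from the data extremes and may be fixed, and the fit is
multi-started over `nH` ∈ {0.5, 1, 2, 4} with ties toward the smallest —
Hill fits on sparse designs are multimodal and the grid makes the choice
reproducible. Replicate wells enter as individual rows (well-level
fitting), not as per-dose averages. Zero-amplitude data leave IC50
unidentifiable; the fit returns with `converged = FALSE` rather than
erroring.

### The coupled ERK / live-cell model

The multiplexed assay reads two Hill curves off one plate: the BRET ratio
(ERK activity) and the total luminescence (live-cell proxy), both
decreasing in dose. The coupled model predicts live cells from the
*observed* ERK value by inverting the ERK Hill curve to an implied dose
and evaluating the live-cell Hill there; when the two curves share IC50
and nH the predicted live-vs-ERK relation is exactly linear, which is the
model's explanation of the observed correlation between ERK activity and
viability.

One point the implementation had to settle: from (ERK, live) pairs alone
the composition only identifies the ratio `IC50_ERK/IC50_L` and the
exponent ratio `nH_L/nH_ERK` — the dose scale cancels. `coupled_fit()`
therefore requires the dose column and estimates in two stages:
`(IC50_ERK, nH_ERK)` from the ERK-vs-dose curve with `min`/`amp` fixed,
then each well's implied dose from its ERK value via the inverse Hill,
then `(IC50_L, nH_L)` by least squares of the live counts at those
implied doses. Wells whose ERK value falls outside the open interval
`(min_ERK, min_ERK + amp_ERK)` — where the inverse is undefined — are
excluded with a reported count, using a relative guard of
`1e-9 × amp_ERK` at both ends. Zero-dose wells of a noise-free plate sit
exactly on the upper bound and are therefore excluded; with realistic
noise roughly half of the near-plateau wells are. This loses little
information because those wells constrain only the plateaus, which are
fixed.

## The synthetic-data generator

The generator defines the study conditions under which every guarantee in
the test suite is stated:

* **Spectra** (`gen_biosensor_spectrum()`): forward model scaled to a
  peak of 1e4 counts, Poisson photon noise (Gaussian optional). Reference
  shapes (`gen_reference_basis()`) are two-Gaussian mixtures per emitter
  — CFP peaked at 475 nm with a ~503 nm shoulder, YFP at 527 nm, RLuc8
  broad around 480 nm — smooth, unit-area, deterministic; measured
  reference tables drop in through `read_spectrum()`.
* **Image stacks** (`gen_ratio_stack()`): elliptical cells (default 5 in
  a 96×96 field, 10 frames at 1 min), per-cell true ratios uniform on
  0.35-0.65 (the in vivo BRET-ratio spread), peak cell intensity 2000
  counts over a 100-count background, substrate decay with 9 min
  half-life applied identically to both channels, Poisson noise, and
  single-pixel spikes at rate 1e-4 standing in for cosmic rays on a
  cooled camera. Spike coordinates and per-cell ratios go into the truth
  manifest.
* **Plates** (`gen_plate()`): the coupled model at ERK
  (min 0.30, amp 0.30, IC50 0.015 µM, nH 1) and live-cell
  (min 1000, amp 9000 counts, IC50 0.028 µM, nH 1.5) parameters — the
  IC50 scale of an EGFR-inhibitor response in a sensitive line — at ten
  doses spanning 0 and 1e-3 to ~3.2 µM, with independent multiplicative
  log-normal noise at 2% CV per readout. `gen_zprime_plate()` draws
  3 + 3 wells at ratio means 1.0/0.6 with SD 0.0047, the regime of a
  high-quality luminescence screen.

Everything is reproducible from the seed, and every generator returns its
truth, so round-trip tests never invent expected values.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: no optical PSF or pixel cross-talk, no EM-gain
excess noise, no flat-field or vignetting structure, no chromatic
registration error between channels, no tissue absorption or scattering
(the dominant confounders of in vivo BRET), no plate edge effects, and
cells are uniform ellipses rather than textured objects. The pipeline's
statistical behaviour under those effects must be established against
measured data.

## Problem sizes and numerical conventions

The test suite and the acceptance script run at the sizes the analyses
are designed around: 151-point spectra, 100-seed Monte-Carlo for the
noisy `E_CY` recovery, 300-replicate bootstraps for the `E_RY` interval,
96×96×10 image stacks, 40-well plates and 50-seed plate recovery runs.
Tolerances follow the quantity: algebraic identities at machine precision
(1e-12 to 1e-15), noiseless optimizer round-trips at 1e-5, Monte-Carlo
statements at the level their sampling error supports. Ratios are
undefined (NA, masked) rather than clipped when denominators fail the
threshold; transfer budgets that would make a branch weight negative are
errors, not clamps.

## Known limitations

* The forward models are steady-state: no excited-state kinetics,
  lifetimes, or anisotropy, and no spectral shift of the emitters with
  environment.
* `E_CY` is assumed identical in FRET and BRET modes and `E_RC`
  conformation-independent; violations bias `E_RY` directly and are not
  detectable from a single spectrum pair.
* The default photophysics profile is synthetic (see above); absolute
  transfer rates inherit its uncertainty even though ratio-based
  readouts largely cancel it.
* The background-mode estimator assumes at least a quarter of each frame
  is background; dense fields need a supplied background.
* The coupled-model exclusion rule drops plateau wells; designs with
  very few interior doses can leave the live-cell stage under-determined
  (guarded by an explicit minimum-well check).
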