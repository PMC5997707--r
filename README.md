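# hybret

Analytics for hybrid BRET-FRET (hyBRET) kinase biosensors — single-chain
reporters carrying a YFP acceptor, a CFP donor and the luciferase RLuc8,
which read out kinase activity as a yellow/cyan emission ratio either
under excitation light (FRET mode) or on the substrate coelenterazine-h
with no excitation at all (BRET mode). The package is for people who
build or use such sensors and need the downstream numbers: how much
energy moves between the emitters, what a ratio image time course really
shows, and whether a luminescence plate assay is tight enough to screen
with.

## What it computes

**Emission-spectrum models and transfer rates.** The forward models are
steady-state branch mixtures of area-normalized emission shapes
`f_C, f_Y, f_R` weighted by quantum efficiencies `φ`:

    F(λ) = ε_C[(1−E_CY) φ_C f_C(λ) + E_CY φ_Y f_Y(λ)] + ε_Y φ_Y f_Y(λ)
    B(λ) = E_RC(1−E_CY) φ_C f_C(λ) + (E_RY + E_RC·E_CY) φ_Y f_Y(λ)
           + (1−E_RC−E_RY) φ_R f_R(λ)

`E_CY` (CFP→YFP FRET), `E_RC` (RLuc8→CFP BRET) and `E_RY` (direct
RLuc8→YFP) are fractional transfer rates. `solve_E_RC()` gets `E_RC`
from quantum efficiencies via `φ_CNL = φ_C E_RC + φ_R(1−E_RC)`;
`fit_E_CY()`/`fit_E_RY()` estimate the others by bounded
Levenberg–Marquardt with multi-start and seeded bootstrap confidence
envelopes; `pathway_decomposition()` splits the yellow emission into the
direct and CFP-mediated routes.

**Ratio imaging.** `preprocess_stack()` (cosmic-ray removal, median
denoising, background subtraction), `compute_ratio()` (yellow/cyan over
a denominator-thresholded mask — the same operation in FRET and BRET
modes), `render_imd()` (eight-hue intensity-modulated display),
`unmix_two_luminophores()` (per-pixel 2×2 linear unmixing) and per-cell
baseline-normalized traces. The ratio is provably invariant to substrate
decay common to both channels.

**Plate analytics.** `zprime()` (Z′ = 1 − 3(SD₀+SD₁)/(Ave₀−Ave₁)),
`hill_fit()` (decreasing Hill equation, log-scale IC50, multi-start nH),
and `coupled_fit()` — the coupled ERK-activity / live-cell model in
which the observed BRET ratio is inverted to an implied dose that
predicts total luminescence, yielding both IC50s and Hill coefficients
and the live-vs-ERK correlation line.

**Synthetic data.** `gen_reference_basis()`, `gen_biosensor_spectrum()`,
`gen_ratio_stack()`, `gen_plate()`, `gen_zprime_plate()` generate every
input class with Poisson/log-normal noise and a recorded ground truth,
so the whole pipeline is testable without any measured data.

## Worked example

The `analysis/` directory is a four-step workflow (simulate inputs,
transfer rates, imaging, plate). Running

```sh
Rscript analysis/01_simulate_inputs.R
Rscript analysis/02_transfer_rates.R
```

prints:

```
E_RC from quantum efficiencies: 0.130
  pre  E_CY = 0.288 [0.286, 0.289]; E_RY = 0.00058 [0.00031, 0.0009]; CFP-mediated R->Y = 0.037
  post E_CY = 0.441 [0.439, 0.442]; E_RY = 1.8e-05 [0, 0.00028]; CFP-mediated R->Y = 0.057
CFP-mediated transfer dominates the direct route in both states (direct E_RY upper CI 0.0009)
```

Read: the luciferase transfers 13% of its energy to the CFP; the
CFP-to-YFP FRET efficiency rises from 0.29 to 0.44 on stimulation
(brackets are bootstrap 95% CIs, recovered here from spectra simulated
at those truths); direct RLuc8→YFP transfer is consistent with zero, so
essentially all yellow emission in BRET mode arrives through the CFP —
the design premise of the hybrid sensor. Steps 3 and 4 continue with the
image stack (per-cell ratio recovery to ~0.2%, decay robustness at
machine precision) and the plate (Z′ ≈ 0.96 on the validation plate,
coupled-model IC50s 0.0146/0.0287 µM against truths 0.015/0.028 µM).

## Layout

```
R/                  package code (models, fitting, imaging, plate, simulate, io)
analysis/           numbered workflow drivers writing under results/
scripts/acceptance.R  headline-quantity recomputation (JSON out)
tests/testthat/     unit, property and acceptance tests
vignettes/          methods vignette: models, assumptions, design choices
inst/extdata/       synthetic photophysics profile (key-value YAML)
```
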