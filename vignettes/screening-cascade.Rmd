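---
title: "The screening cascade: models, parameters, and design choices"
author: "screenCascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The screening cascade: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenCascade)
```

# The problem

High-throughput reporter screens read one luminescence value per well of a
96- or 384-well plate; a compound that lowers the tagged protein's
abundance lowers the signal. Three nuisance structures stand between the
raw reads and a hit list: plate-to-plate scale differences, smooth
positional (row/column) artifacts, and well-level noise. On top of that, a
compound can lower luminescence simply by killing cells, so a viability
counter-screen is required, and the therapeutic question — does the
compound sensitize cells to a PARP inhibitor? — needs dose-combination
analysis. This package implements that full cascade as reusable,
individually tested stages.

# Stage models

## Percent activity and the Z-factor gate

Every well is scaled to the plate's negative-control (vehicle) median:
$\%A = 100\,s/\mathrm{med}(s_{neg})$. The median over the negative
controls is exactly 100 by construction, and background (lytic-buffer)
wells never enter the control median. Plate screenability is gated on
$Z' = 1 - 3(\sigma_{+}+\sigma_{-})/|\mu_{+}-\mu_{-}|$ computed from the raw
control arms with sample moments; plates below 0.7 are excluded and
logged. $Z'$ is undefined when the arms' means coincide, and that is an
error rather than a sentinel value.

## B-scores

The B-score removes additive row and column effects by Tukey's two-way
median polish and studentizes the residual with a robust scale:
$$B_{ij} = \frac{r_{ij}}{1.4826 \cdot \mathrm{MAD}(r_{\text{sample}})}.$$

Three choices here were genuinely open and are fixed as follows:

* **Polish on log10 signal** (default; `logScale = FALSE` gives the raw
  alternative). Luminescence artifacts scale with signal, so positional
  effects are multiplicative; on the log scale the additive two-way model
  is exactly matched. This also makes B-scores invariant to global signal
  rescaling, which is tested.
* **Control wells are masked out of the medians.** Rows and columns that
  contain controls still contribute their sample wells, but the control
  wells themselves cannot bias the effects; whole control columns (whose
  effect is inestimable from sample wells) are assigned a zero column
  effect, and the control wells still receive scores. The plate scale is
  the MAD over sample-well residuals only.
* **Hit threshold relative to controls, boundary inclusive.** A well is a
  down-hit when $B \le \bar B_{neg} - k\,\mathrm{SD}(B_{neg})$ with
  $k = 3$; the screen seeks decreased signal, so `direction = "down"` is
  the default, with "up" and "both" exposed.

`medianPolish()` is implemented in the package (row sweep, column sweep,
effect re-centering) because the fit must report iteration count and a
convergence flag, tolerate fully masked columns, and guarantee the exact
reconstruction identity `overall + row + col + residual = input`; it is
cross-checked against `stats::medpolish` in the tests. Convergence is
declared when every residual row and column median is below `tol`
(default 1e-6) in absolute value, within `maxIter` (default 20) sweeps.
A median polish is not unique — implementations can settle on different
but equally valid decompositions — which is why the cross-check compares
residual mass rather than cell-wise values.

## The counter-screen ratio

$\mathrm{ratio} = \%V / \max(\%A, 0.1)$, pass iff ratio ≥ 2 (inclusive:
"meeting" a 2:1 requirement includes attaining it exactly). The 0.1% floor
keeps compounds that abolish the signal nearly completely — which produce
deliberately extreme ratios — finite without materially changing any
realistic value. Compounds observed in only one channel are reported in an
`unmatched` table, never dropped silently.

## Dose-response, AUC and the combination call

The four-parameter logistic is parameterized in viability orientation,
$r(d) = e_{min} + (e_{max}-e_{min})/(1+(d/ec_{50})^{h})$, fitted by
bounded Levenberg–Marquardt least squares (`minpack.lm::nlsLM`) with a
multi-start grid (ec50 at each observed positive dose × hill ∈
{0.5, 1, 2}); ec50 and hill are fitted on the log scale within bounds
(responses in [−10, 120], ec50 within 1e-4–1e4× the observed dose range,
hill in [0.1, 10]). Flat data yields a flagged degenerate curve rather
than an error. With only 4 doses a full 4PL is under-determined, so the
combination sub-screen works on observed points: the normalized AUC is the
trapezoidal integral of response/100 over log10 dose divided by the
log-dose span (flat 100% viability ⇒ exactly 1, and the value is invariant
to the dose unit). ΔAUC = AUC(mono) − AUC(combo) is reported, and the
combination *flag* uses the per-dose rule — more than 10 viability
percentage points lost relative to monotherapy at ≥1 dose — with the sign
convention that positive ΔAUC means the combination is more effective.

## ZIP synergy

On the fractional-inhibition scale $y = \mathrm{clamp}((100-V)/100, 0, 1)$
the zero-interaction expectation is $y_1 + y_2 - y_1 y_2$. The fitted δ
surface follows the potency-shift logic of the ZIP family:

1. fit 4PLs to both monotherapy axes;
2. for each fixed positive dose of drug 1, fit a conditional 4PL across
   drug-2 doses with its zero-dose asymptote pinned to drug 1's fitted
   monotherapy inhibition at that dose;
3. the symmetric fits with roles swapped;
4. average the two conditional fits per cell;
5. $\delta_{ij} = 100\,(\hat y_c - \mathrm{zip}(\hat y_1, \hat y_2))$ for
   cells with both doses positive.

Degenerate (flat) conditional fits fall back to the observed cell value
and are counted in the report. The overall score averages only cells with
both doses positive — the monotherapy axes are δ ≡ 0 by construction and
would dilute it; published overall scores from web tools may average
differently, so printed scores are treated as classification examples, not
bit-reproducible targets. The most-synergistic-area score is the maximum
window mean over contiguous 3×3 submatrices (window exposed as a
parameter), and classification is inclusive at threshold 5.
`blissExcessMatrix()` computes the fit-free excess directly from observed monotherapy
cells; it is exactly symmetric under drug swap and serves as the internal
oracle for the fitted surface in the tests (fitted scores agree with it to
within fit tolerance, ~0.5 on the δ scale).

# The synthetic generator

`simulatePrimaryScreen()` draws, per plate, a plate multiplier and one
multiplier per row and column (log10-normal with SDs `plateEffectSd`,
`rowEffectSd`, `colEffectSd`), and per well a mean-1 lognormal noise
factor with CV `noiseCv`. A sample well's expected signal is
`baseline × positional × trueActivity/100`; a fraction `hitFraction` of
compounds receives a true activity drawn from `hitActivityRange`, the rest
sit at 100%. The viability channel shares the same compound truth
(`toxicFraction` of compounds at `toxicityRange`% viability, others at
100%) with fresh positional draws — it is an independent assay read.
Controls follow a fixed layout (384: columns 1–2 negative, 23 positive,
24 background); the positive control multiplies the baseline by
`positiveControlActivity`/100.

Default magnitudes are free parameters of the simulation, not estimates of
any real plate set; they were chosen once to describe a well-run screen:
2.5% well noise, ~2% row/column effects and ~12% plate scale spread
(log10 SDs 0.008/0.008/0.05), and a 4-fold positive control. Together
these put simulated Z-factors around 0.8 — the "highly screenable" regime
a facility would demand of a production screen — comfortably above the
0.7 gate, with hits at 5–40% activity separated from the null by tens of
control SDs. Dose-combination surfaces are built from two 4PL curves: the
independence surface `100·zip(y1, y2)` plus an injected δ landscape on
interior cells, clamped to [0, 100] (assay readouts are bounded; a warning
fires if δ pushes pre-clamp inhibition outside [−20, 120]), then converted
back to viability with mean-1 lognormal replicate noise.

What the generator deliberately does **not** emulate: edge evaporation
beyond row/column effects, liquid-handler carryover, cell-growth kinetics,
signal loss in the luminescence channel from cytotoxicity (the coupling
lives entirely in the shared truth and the viability channel), and the
time offset between the luminescence and viability reads. Tests passing on
simulated screens therefore demonstrate the statistical machinery under
the stated noise model, not robustness to every artifact of real plates.

# Calibration and test design

* **Null B-score calibration** pools the sample wells of 10 seeded
  hit-free plates (~3,200 wells): mean within ±0.1 and SD within
  (0.8, 1.2). Pooling is used because a per-plate SD on ~320 wells is too
  noisy to be a meaningful calibration check. The pooled SD sits near
  1.12, slightly above 1 because median-polish residuals are mildly
  heavy-tailed relative to the MAD scale — a known property of the
  estimator, not a defect.
* **Hit recovery** is run at the stress setting `noiseCv = 0.1` with true
  hits at 5–50% activity across 10 plates; sensitivity ≥ 0.9 and
  specificity ≥ 0.99 against the generator's truth.
* **δ recovery** (δ ∈ {5, 10, 20}, noise-free within ±1.5, ±3 at 5%
  replicate CV) uses monotherapy curves whose independence surface peaks
  near 77% inhibition, leaving headroom so that injected δ up to 20 is not
  truncated by the [0, 100] clamp; with strongly inhibiting curves the
  clamp, not the estimator, caps what is recoverable.
* **Null ZIP calibration** draws 50 random 4PL pairs (plateaus 10–60%,
  ec50 0.3–5 µM, hill 0.7–2.5) on the 7-dose anchor grid
  0–10 µM; every overall score falls in (−1, 1), below the threshold 5.
* **The end-to-end demo** (2 × 384 plates, 4% hits, 8% toxic, half the
  eligible hits designed synergistic at δ = 15, anchor at its lowest
  positive dose, 3 replicates at 2% CV) must recover exactly the designed
  hit ∧ non-toxic ∧ synergistic set, with each stage's compound set a
  subset of the previous stage's. These problem sizes keep the whole suite
  under a minute while leaving decisive margins at every threshold.

# Other conventions and degenerate inputs

Wells are 0-based (row, column) internally, displayed as "A01"-style
labels; display/parse is a tested bijection. Missing signal is distinct
from zero signal — zero is a legal measurement. Doses are µM throughout;
unit conversion happens at the boundary. Replicate wells are **not**
aggregated: one record per well, aggregation is left to the caller.
MAD = 0 plates, all-missing polish rows/columns, equal control means, and
sub-4-dose 4PL requests are errors with named causes; flat dose-response
data and sub-window δ regions degrade gracefully with flags/warnings. The
knock-in design utilities do pure arithmetic (amplicon = wild-type +
insert; in-frame iff length ≡ 0 mod 3; stop-codon scan by frame) and flag
— rather than resolve — donor designs whose printed arm/insert accounting
does not add up, like the bundled 140-nt example oligo (40 + 39 + 40 ≠
140).

# Known limitations

* Per-plate polishing only: plate-to-plate adjustment is per-plate
  normalization plus per-plate MAD scaling, not a joint cross-plate model.
* No spatial smoothing beyond row/column effects (no 2-D loess polish).
* ZIP confidence intervals, Loewe and HSA models are out of scope; Bliss
  excess is the only alternative surface.
* The conditional-fit average is one concrete reconstruction of the ZIP
  family; other implementations may average monotherapy axes into the
  overall score or weight replicates differently, so cross-tool score
  comparisons should use classifications, not raw values.
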