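---
title: "Models and methods behind poresignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind poresignal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poresignal)
```

poresignal implements the signal chain of ionic-current blockade sensing
with solid-state nanopores: a pore sits in a thin SiN~x~ membrane between
two electrolyte chambers, a bias drives an open-pore current $I_0$ through
it, and a translocating ssDNA molecule blocks part of the aperture for its
dwell time, leaving a residual current $I_0 - \Delta I_B$. The package
models the device physics (conductance, noise), synthesizes realistic
recordings, detects blockades, and discriminates homopolymers by their
residual-current distributions. This vignette explains each model, the
tunable parameters, and the design choices made where more than one
reasonable option existed.

## Pore conductance and effective thickness

The open-pore conductance of a cylindrical pore of diameter $d$ in a
membrane of effective thickness $h_{\mathrm{eff}}$, with access resistance
on both sides, is

$$G = \sigma\left[\frac{4\,h_{\mathrm{eff}}}{\pi d^2} +
\frac{1}{d}\right]^{-1},$$

with $\sigma$ the electrolyte conductivity (11.1 S/m for 1 M KCl by
default). Units are chosen so no conversion constants appear: $d$ and
$h_{\mathrm{eff}}$ in nm and $\sigma$ in S/m give $G$ directly in nS, and
nS times mV gives pA. As $h_{\mathrm{eff}} \to 0$ the access term alone
survives, $G = \sigma d$. The formula lives in one internal function so an
alternative geometry (conical, hourglass) can be swapped without touching
the fitting code.

`fit_effective_thickness()` inverts the model: given measured
$(d, G)$ pairs it estimates $h_{\mathrm{eff}}$ by unweighted nonlinear
least squares *on conductance* (not on resistance — the measurements are
conductances, and reciprocal transformation would reweight the residuals).
Because the inverse model is linear in $h_{\mathrm{eff}}$, the starting
value is obtained in closed form and the Levenberg–Marquardt refinement
converges in a few steps; on noiseless model-generated points the estimate
is exact to numerical precision, and 1% multiplicative conductance noise
propagates to roughly 2% thickness error for a 10-point diameter series.
$h_{\mathrm{eff}}$ is deliberately not constrained by the physical
deposition thickness: the effective value inferred electrically is the
quantity of interest, and an hourglass pore makes it smaller than the
physical one.

The dielectric-noise coefficient follows the standard lossy-capacitor
expression $S_D = 8\pi k_B T\, D_{\mathrm{loss}} C_{\mathrm{eff}}$, with
the loss tangent $D_{\mathrm{loss}}$ (~1e-4 for quartz) and the device's
effective capacitance $C_{\mathrm{eff}}$ (~70 pF quartz, ~1600 pF Si,
patch-clamp cell-test values used as preset constants).

## The four-term noise model

The one-sided current-noise PSD is modeled as

$$S(f) = A f^{-\beta} + B + C f + D f^2,$$

flicker noise ($\beta \in [0,2]$), white Johnson-plus-shot noise,
dielectric noise, and capacitive (voltage) noise. `rms_from_psd()`
integrates it in closed form over a band; the flicker term uses the
logarithmic antiderivative at $\beta = 1$ and the power-law form
otherwise. The RMS of a recorded trace is the standard deviation of its
samples; under Parseval the two definitions agree, and both are exposed.

### Substrate presets

The published totals for this class of device are RMS values, not
coefficient tables, so the presets are defined *by construction*: the band
power over 1 Hz–10 kHz is fixed to the characteristic RMS (quartz 5.3 pA
and Si 38 pA at rest; 12.58 and 131.6 pA under bias at matched 4.5-nA pore
current), and the split across the four terms is set once on physical
grounds:

* at 0 mV the capacitive (voltage-noise) term vanishes, $D = 0$;
* on the Si substrate dielectric noise dominates (70% of band power at
  rest) — that is precisely the pathology the insulating substrate
  removes;
* on quartz the white term dominates at rest (65%), with modest flicker
  (15%) and dielectric (20%) shares;
* under bias the flicker share grows (40% quartz, 30% Si) and a small
  capacitive share appears.

Coefficients are computed from these constraints at call time, so the
construction is auditable rather than a table of opaque constants. A
consequence worth knowing: because the $Cf$ and $Df^2$ terms carry power
past 10 kHz that a 6-pole Bessel filter only partially removes, the
standard deviation of a filtered preset trace sits a few percent above the
1 Hz–10 kHz band RMS (about +5% for quartz at rest, +11% for the
dielectric-dominant Si preset). This is the physically correct behavior
of a soft-edged filter, not a calibration error.

### Estimation and fitting

`estimate_psd()` is an averaged modified periodogram: Hann window,
per-segment mean removal, 50% overlap, one-sided scaling such that the
integrated PSD matches the trace variance. The default segment length of
2^14 samples at 250 kHz gives 15.3-Hz resolution, enough to see the
flicker knee while averaging ~120 segments on a 4-s trace. The two lowest
bins are biased low by the per-segment mean removal and window leakage;
fits therefore start at the third bin by default in the round-trip
protocol.

`fit_noise_model()` fits $\log_{10} S$ against $\log_{10} f$ with all
coefficients bounded at zero and $\beta$ clamped to $[0, 2]$. Two
numerical choices matter. First, the spectrum is rebinned onto a
logarithmic grid (24 bins/decade, geometric bin centers) before fitting,
so each decade carries comparable weight — on the raw linear grid the top
decade would outvote the flicker region several-hundred-to-one. Second,
the problem is rescaled so all parameters are O(1) (PSD levels are ~1e-24
A^2/Hz and the raw coefficients span 20 orders of magnitude, which defeats
finite-difference Jacobians). When a spectrum has no low-frequency excess
the flicker amplitude and exponent are jointly unidentifiable; the fit
then drops the flicker term and reports $\beta$ at its lower bound rather
than a spurious interior value.

With this protocol, synthesize–estimate–fit round trips recover $A$–$D$
within 25% and $\beta$ within 0.15 in at least 90% of seeds (the
acceptance suite runs 20).

### Synthesis

`synth_noise()` shapes white phases in the frequency domain: bin $k$ gets
amplitude $\sqrt{S(f_k)\, f_s n / 2}$ and an independent uniform phase,
the DC bin is zero, and the inverse FFT returns a real zero-mean trace
whose expected periodogram equals the model. Synthesis runs at the next
2-3-5-smooth length and truncates, keeping the FFT $O(n \log n)$ for
arbitrary durations. Every stochastic function in the package takes an
explicit seed; there is no hidden global state.

## The recording chain

Traces are sampled at 250 kHz and low-pass filtered with a 6-pole Bessel
filter at 10 kHz, the standard patch-clamp anti-aliasing chain. No digital
Bessel designer is available in the installed stack, so the package builds
the analog prototype itself — the poles of the degree-6 reverse Bessel
polynomial, rescaled so the magnitude response is −3 dB at the cutoff —
and discretizes by bilinear transform with frequency prewarping
(`signal::bilinear`). The realized response is −3.0 dB at 10 kHz and about
−138 dB at 100 kHz. Filtering is forward-only (causal), as in the
instrument; the filter therefore delays each blockade by the group delay
(~43 µs) and smears its edges over a 10–90% rise time of ~34 µs. Both
numbers matter repeatedly below.

## The synthetic-data generator

`sample_events()` draws ground-truth event lists: dwell times log-uniform
on 4–1000 µs (the observed dwell range spans ~2.5 decades with no
pronounced mode; a log-normal alternative is exposed), residual currents
Gaussian per homopolymer preset truncated at 0 pA, and exponential
inter-event gaps at a default 10 s⁻¹ (chosen for desk-scale traces; the
reference experiments report only ">200 events"). Events are laid out
sequentially so they cannot overlap; rates implying more than 50% duty
cycle are rejected. `render_trace()` places ideal rectangles on the
open-pore baseline and adds preset noise; intra-event structure from
DNA–pore interaction is out of scope.

Homopolymer presets carry the reference residual Gaussians at 200 mV
(polyA 688.4 ± 43.1, polyT 631.5 ± 67.6, polyC 643.8 ± 85.2 pA);
`polyA_mix`/`polyT_mix` carry the narrower components seen when both
polymers are measured in one chamber (679.9 ± 21.3, 641.2 ± 20.2 pA). At
other biases residuals scale proportionally with voltage — a documented
simplification valid near the reference bias. Membrane-condition presets
pair the printed open-pore/blockade currents (0.35/0.11, 0.81/0.21,
1.64/0.42 nA for 20/10/5 nm) with event-depth spreads taken from the
printed blockade-fraction SD bands.

What the generator does *not* emulate: capture-rate physics and its
voltage dependence, folded/partial translocations, intra-event current
substates, electrode drift beyond slow baseline wander, and poly-G
(which forms G-tetrads and yields no systematic translocations). Tests
passing on synthetic data therefore validate the estimators against the
stated generative model, not against every pathology of real recordings.

## Event detection

`correct_baseline()` estimates the open-pore level per sample. The noise
scale comes from lagged differences, `mad(diff(x, lag))/sqrt(2)` with the
lag at the filter's decorrelation scale ($f_s / 2 f_c$ samples): lagged
differences see the band-limited noise but are blind to slow drift and to
the blockade levels themselves. Provisional blockades are flagged 4σ below
a running 75th percentile (a running *median* would sit between the levels
when blockades fill half the window — the 75th percentile anchors the
open level even for a 50% duty cycle square wave), bridged by linear
interpolation, and the reported baseline is the running median of the
bridged trace (default window 10 ms).

`detect_events()` uses a threshold with hysteresis: an event is a maximal
run of samples below baseline − kσ/2 containing at least one sample below
baseline − kσ, with k = 5 by default. The published description says only
"current thresholds greater than the noise level"; k = 5 makes false
positives negligible at 250 kHz (< 1 per 10 s measured) while leaving
events a few rise times long detectable, and the hysteresis close
threshold at k/2 captures the full smeared extent of each blockade.

### Depth estimation: the template fit

A 10-kHz filter attenuates the apparent depth of any blockade shorter
than a few rise times, and under the 4–1000 µs dwell law nearly half of
all events are in that regime. A trimmed mean over the thresholded
samples — the naive estimator — is biased shallow by tens of percent for
those events and drags every aggregate statistic with it. The default
depth estimator therefore fits each detected event with a
filtered-rectangle template, $b - a\,[R(t - t_0) - R(t - t_0 - w)]$,
where $R$ is the recording filter's step response (precomputed on a
16-fold oversampled grid), recovering the underlying rectangle's depth
$a$ and width $w$. This is the approach long used for
bandwidth-limited nanopore events (template/step-response fitting in the
ADEPT style). The depth is bounded above by the local baseline, because
the residual current cannot be negative. The trimmed mean remains
available (`depth_method = "mean"`) and is the fallback when a fit fails.

Identifiability sets the resolution floor: for a rectangle much shorter
than the rise time only the area $a \times w$ is constrained, so depth
and width trade off freely — a true 14-µs, 420-pA blockade fits almost
equally well as a 3.6-µs blockade at the depth bound. The 12-µs minimum
dwell (three samples at the filter-limited bandwidth) consequently
cannot act on the threshold-crossing width (the filter smears every
event past it) nor robustly on the raw fitted width (ridge solutions
scatter it): it acts on the *effective dwell*, the fitted blockade area
divided by the typical depth of the long events — exactly the
well-determined combination. The typical depth is the median over events
of at least two rise times (~68 µs), for which the template estimator is
unbiased to within ~2 pA.

Each detected event carries a `depth_reliable` flag (fitted width ≥ two
rise times). Shorter blockades are real detections — they count for
event rates and dwell statistics — but their individual depths are
ridge-limited, so `summarize_events()` computes depth and
blockade-fraction moments over the reliable subset while counting all
detections. On the 5-nm-membrane condition this yields mean blockade
fractions within a few tenths of a point of the generating 25.6% across
seeds, with recall 0.96–0.99 and precision ~1 against ground truth.
Detector scoring counts recall over resolvable truths (true dwell ≥ the
minimum dwell) and matches intervals with a 100-µs tolerance absorbing
the group delay.

`summarize_events()` reports depth and blockade-fraction moments and the
signal-to-noise ratio $\mathrm{SNR} = \overline{\Delta I_B} /
\Delta I_{\mathrm{RMS}}$ with the RMS taken from an event-free baseline
stretch. Dwell times are reported threshold-to-threshold (plus the
template width separately); whether published dwell values are
threshold-based or FWHM is not stated, and threshold-to-threshold is the
implemented convention.

## Homopolymer discrimination

`fit_single_gaussian()` histograms per-event mean residual currents with
Freedman–Diaconis bins (density scaling; no published bin width exists to
match) and least-squares fits an amplitude-scaled Gaussian, falling back
to sample moments for degenerate input. An R² diagnostic below 0.8 flags
non-Gaussian shapes such as bimodality.

`fit_two_gaussian_mixture()` is a self-contained EM with 10 random
restarts (means from random quantile pairs, pooled SDs, equal weights),
keeping the best log-likelihood and returning components ordered by mean.
Values beyond 5 robust SDs of the median are trimmed first: a histogram
fit is insensitive to a few stray far-off bins, but EM is not, and
depth-saturated template failures would otherwise capture a component.
The trim removes well under 1% of a clean Gaussian sample. An
independently implemented EM (mclust) serves as a cross-check in the test
suite on a well-separated mixture where the optimum is unambiguous.

One calibration finding is worth stating plainly: for 300 + 300 draws
from the mixture-experiment components — two Gaussians ~1.9 pooled SDs
apart — the fully converged maximum-likelihood solution constrains each
component mean only to about ±20 pA (calibrated over 20 seeds; the ML
optimum's likelihood exceeds the truth's, so this is sampling spread, not
an optimizer failure). Recovery tests use that honest tolerance.

Peak residuals convert to blockade fractions ($100\,r/GV$) and blockade
conductances ($(GV - r)/V$, in pS); the two are exactly complementary —
fraction plus the blockade's share of $G$ totals 100% — and
`rank_homopolymers()` orders nucleotides by descending blockade
conductance with alphabetical tie-breaks, reporting the minimum pairwise
gap that the discrimination rests on. A static literature table of
per-nucleotide blockade conductances across protein and solid-state pores
ships as reference data (`blockade_reference_table()`), not as computed
output; note its poly-C entry (3670 pS) differs slightly from the value
implied by the poly-C peak residual (3731 pS), and both printed values
are kept as printed.

## Problem sizes and runtime choices

The validation suite uses desk-scale problems chosen to make each
statistical assertion sharp without waste: 4-s traces (~120 Welch
segments) for PSD round trips, 220–300 events per detection run, 20 seeds
for calibration loops. The pipeline driver (`run_pipeline()`) composes
simulate → filter → detect → summarize → discriminate deterministically
from a single config and writes TSV artifacts plus a versioned JSON
report; TSV with `#` metadata headers is the canonical interchange
(human-inspectable and diff-able). Patch-clamp vendor formats are not
parsed — `read_trace()` defines the entry point a converter would target.

## Known limitations

* Preset noise decompositions are constructed, not measured; only their
  band totals are anchored to published values.
* The conductance model is the standard cylinder-plus-access form; it
  does not explain the systematically high conductance of solid-state
  pores relative to protein pores, and no attempt is made to.
* Depth estimates for events between one and two filter rise times are
  ridge-limited; dwell estimates below the rise time rely entirely on the
  template.
* Residual-vs-bias scaling is linear by assumption; presets are defined
  at 200 mV.
* The EM mixture is validated for two components; other k are exposed but
  untested against published values.
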