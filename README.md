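# poresignal

Signal analysis for low-noise solid-state nanopore recordings.

A solid-state nanopore reads single molecules electrically: a bias across
a nanometer-scale pore in a thin SiN~x~ membrane drives an open-pore
current *I₀*, and each translocating ssDNA molecule blocks part of the
aperture, leaving a residual current *I₀ − ΔI_B* for its dwell time.
Whether homopolymers can be told apart comes down to noise: the blockade
differences between nucleotides are tens of pS, while conventional
Si-substrate devices carry tens of pA of RMS noise. This package
implements the full analysis chain for such measurements, aimed at anyone
working with (or simulating) patch-clamp-style nanopore current traces:

* **Pore model** — conductance versus geometry,
  `G = σ[4h_eff/(πd²) + 1/d]⁻¹`, with least-squares estimation of the
  effective membrane thickness `h_eff` from (diameter, conductance) data,
  and the dielectric-noise coefficient `S_D = 8πk_B·T·D_loss·C_eff`.
* **Noise model** — the four-term PSD `S(f) = A f^(−β) + B + C f + D f²`
  (flicker, white, dielectric, capacitive), with Welch-style estimation,
  bounded log-log fitting, band-limited RMS in closed form, and synthesis
  of noise traces with a prescribed spectrum.
* **Trace synthesis** — full synthetic recordings: substrate noise
  presets, rectangular blockades from per-homopolymer residual-current
  Gaussians, 250-kHz digitization through a 6-pole 10-kHz Bessel filter.
* **Event detection** — running-median baseline correction with blockade
  exclusion, 5σ threshold detection with hysteresis, and per-event depth
  and width recovered by fitting the filter's step-response template
  (events near the filter rise time are otherwise measured too shallow).
* **Discrimination** — Freedman–Diaconis histogram Gaussian fits,
  two-component EM mixture fitting with restarts, conversion of peak
  residuals to blockade conductances, and nucleotide ranking.

## Worked example

Simulate the 5-nm-membrane condition (open-pore current 1.64 nA, mean
blockade 0.42 nA, quartz-substrate noise), detect the events, and
summarize:

```r
library(poresignal)

cond  <- make_condition_preset("membrane5nm")
pr    <- condition_event_preset(cond)
truth <- sample_events(pr, 220, seed = 910)
dur   <- max(truth$start_s + truth$dwell_us * 1e-6) + 0.05

trace <- render_trace(cond$I0_nA, truth, cond$noise,
                      duration_s = dur, seed = 911)
trace <- bessel_lowpass(trace)            # 6-pole Bessel, 10 kHz
det   <- detect_events(trace, correct_baseline(trace))

st <- summarize_events(det, baseline_rms_pA = 13.9)
c(st$mean_fraction_pct, st$sd_fraction_pct, st$snr)
#> [1] 25.53318  3.310352 30.12950
score_events(det, truth)$recall
#> [1] 0.9717514
```

The mean blockade fraction (25.5 ± 3.3%) lands on the reference values
for this condition (25.3 ± 3.3%), and the detector recovers ≥ 95% of the
resolvable ground-truth events. Depth statistics are computed over the
depth-reliable events — blockades of at least two filter rise times,
whose depth the 10-kHz bandwidth can quantify. Converting the homopolymer peak residuals
measured at a 6.95-nS pore under 200 mV:

```r
blockade_conductance(688.4, 6.95, 200)    # polyA
#> [1] 3508
blockade_conductance(631.5, 6.95, 200)    # polyT
#> [1] 3792.5
rank_homopolymers(data.frame(label = c("A", "T", "C"),
                             dI_block_pS = c(3510, 3800, 3670)))
#> $order
#> [1] "T>C>A"
#> $min_delta_pS
#> [1] 130
```

The `analysis/` directory holds the narrative workflow as numbered
scripts — `01_pore_model.R` (conductance curves and thickness refits),
`02_noise_model.R` (preset spectra, fits, RMS table),
`03_translocation_detection.R` (simulate, detect, score the three
membrane conditions), `04_homopolymer_discrimination.R` (peak fits, the
polyA+polyT mixture EM, ranking) — each writing its tables under
`results/`.

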