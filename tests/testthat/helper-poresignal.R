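# shared fixture builders (everything generated in code, no stored data)

# short filtered recording of a condition preset with known ground truth
make_test_run <- function(condition = "membrane5nm", n_events = 60,
                          seed = 1, rate_per_s = 10) {
  cond <- make_condition_preset(condition)
  pr <- condition_event_preset(cond)
  truth <- sample_events(pr, n_events, rate_per_s, seed = seed)
  dur <- max(truth$start_s + truth$dwell_us * 1e-6) + 0.05
  tr <- render_trace(cond$I0_nA, truth, cond$noise, duration_s = dur,
                     seed = seed + 1)
  trf <- bessel_lowpass(tr)
  list(cond = cond, truth = truth, trace = trf,
       baseline = correct_baseline(trf))
}

# single rectangular event in white noise, filtered
make_single_event_trace <- function(depth_pA, dwell_us, sigma_pA,
                                    I0_pA = 1000, fs = 250e3,
                                    duration_s = 0.2, seed = 5) {
  ev <- data.frame(start_s = duration_s / 2, dwell_us = dwell_us,
                   residual_pA = I0_pA - depth_pA, label = "test")
  np <- noise_params(B = (sigma_pA * 1e-12)^2 / (fs / 2))
  bessel_lowpass(render_trace(I0_pA / 1000, ev, np, fs_Hz = fs,
                              duration_s = duration_s, seed = seed))
}
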