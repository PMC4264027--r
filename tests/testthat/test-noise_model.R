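test_that("noise model evaluates term by term", {
  flat <- eval_noise_model(noise_params(B = 1e-24), c(1, 10, 1e3, 1e5))
  expect_true(all(flat$psd_A2_per_Hz == 1e-24))
  # f = 1 collapses all powers to A + B + C + D
  p <- noise_params(A = 3e-25, beta = 1.3, B = 2e-25, C = 1e-26, D = 5e-27)
  expect_equal(eval_noise_model(p, 1)$psd_A2_per_Hz,
               3e-25 + 2e-25 + 1e-26 + 5e-27)
  # term-by-term hand arithmetic at 1 kHz
  p2 <- noise_params(A = 1e-22, beta = 1, B = 1e-25, C = 1e-29, D = 1e-33)
  expect_equal(eval_noise_model(p2, 1e3)$psd_A2_per_Hz, 2.11e-25,
               tolerance = 1e-12)
  expect_error(eval_noise_model(p2, c(10, 0)), "positive")
})

test_that("noise model is additive coefficient-wise", {
  p1 <- noise_params(A = 1e-24, beta = 1, B = 1e-26, C = 1e-30, D = 1e-35)
  p2 <- noise_params(A = 3e-24, beta = 1, B = 5e-26, C = 2e-30, D = 4e-35)
  ps <- noise_params(A = 4e-24, beta = 1, B = 6e-26, C = 3e-30, D = 5e-35)
  f <- 10^seq(0, 5, by = 0.25)
  expect_equal(eval_noise_model(ps, f)$psd_A2_per_Hz,
               eval_noise_model(p1, f)$psd_A2_per_Hz +
                 eval_noise_model(p2, f)$psd_A2_per_Hz)
})

test_that("band-limited RMS follows the closed-form integrals", {
  expect_equal(rms_from_psd(noise_params(B = 1e-24), c(1, 1e4)),
               sqrt(1e-24 * 9999) * 1e12, tolerance = 1e-12)
  expect_equal(rms_from_psd(noise_params(B = 1e-24), c(1, 1e4)), 100,
               tolerance = 1e-4)
  expect_equal(rms_from_psd(noise_params(), c(1, 1e4)), 0)
  # dielectric and capacitive closed forms
  expect_equal(rms_from_psd(noise_params(C = 1e-30), c(10, 1e3)),
               sqrt(1e-30 * (1e6 - 100) / 2) * 1e12)
  expect_equal(rms_from_psd(noise_params(D = 1e-36), c(10, 1e3)),
               sqrt(1e-36 * (1e9 - 1e3) / 3) * 1e12)
  expect_error(rms_from_psd(noise_params(B = 1e-24), c(1e4, 1)), "band")
})

test_that("RMS is monotone non-decreasing in band width", {
  p <- noise_params(A = 1e-24, beta = 0.8, B = 1e-26, C = 1e-30, D = 1e-35)
  uppers <- 10^seq(1, 5, by = 0.5)
  rms <- vapply(uppers, function(u) rms_from_psd(p, c(1, u)), 1)
  expect_true(all(diff(rms) >= 0))
})

test_that("substrate presets integrate to the characteristic RMS values", {
  expect_equal(rms_from_psd(noise_preset("quartz0mV"), c(1, 1e4)), 5.3,
               tolerance = 1e-9)
  expect_equal(rms_from_psd(noise_preset("si0mV"), c(1, 1e4)), 38,
               tolerance = 1e-9)
  expect_equal(rms_from_psd(noise_preset("quartzBias"), c(1, 1e4)), 12.58,
               tolerance = 1e-9)
  expect_equal(rms_from_psd(noise_preset("siBias"), c(1, 1e4)), 131.6,
               tolerance = 1e-9)
  expect_error(noise_preset("teflon"), "unknown")
})

test_that("synthesized noise has the prescribed variance and is reproducible", {
  z <- synth_noise(noise_params(), 250e3, 1000, seed = 1)
  expect_true(all(z == 0))
  # white-only: variance = B * fs / 2 over a 1-s trace
  x <- synth_noise(noise_params(B = 1e-24), 250e3, 250e3, seed = 2)
  expect_equal(stats::var(x), 1e-24 * 125e3, tolerance = 0.05)
  expect_identical(x, synth_noise(noise_params(B = 1e-24), 250e3, 250e3,
                                  seed = 2))
  expect_false(identical(x, synth_noise(noise_params(B = 1e-24), 250e3,
                                        250e3, seed = 3)))
})

test_that("averaged periodogram is flat for white noise and Parseval-consistent", {
  fs <- 250e3
  x <- synth_noise(noise_params(B = 4e-24), fs, 2 * fs, seed = 4)
  sp <- estimate_psd(x, fs, segment_length = 256)
  expect_gt(attr(sp, "n_segments"), 50)
  # the two lowest bins are biased by per-segment mean removal and window
  # leakage; all other bins sit on the analytic one-sided level
  expect_true(all(abs(sp$psd_A2_per_Hz[-(1:2)] / 4e-24 - 1) < 0.10))
  # Parseval: band-integrated PSD equals the trace variance within 5%
  pw <- (rms_from_psd(sp, range(sp$freqs_Hz)) * 1e-12)^2
  expect_equal(pw, stats::var(x), tolerance = 0.05)
  # DC trace: zero PSD at all f > 0
  spc <- estimate_psd(rep(3e-9, 4096), fs, segment_length = 512)
  expect_true(all(spc$psd_A2_per_Hz == 0))
  expect_error(estimate_psd(rnorm(100), fs, segment_length = 256),
               "insufficient")
})

test_that("synthesized colored noise matches the model per half-decade band", {
  fs <- 250e3
  p <- noise_preset("quartz0mV")
  x <- synth_noise(p, fs, 8 * 2^14 * 3, seed = 9)
  sp <- estimate_psd(x, fs, segment_length = 2^12)
  band_edges <- 10^seq(2, 5, by = 0.5)
  for (i in seq_len(length(band_edges) - 1)) {
    sel <- sp$freqs_Hz >= band_edges[i] & sp$freqs_Hz < band_edges[i + 1]
    est <- mean(sp$psd_A2_per_Hz[sel])
    mod <- mean(eval_noise_model(p, sp$freqs_Hz[sel])$psd_A2_per_Hz)
    expect_equal(est, mod, tolerance = 0.15)
  }
})

test_that("model fit is self-consistent on an exact spectrum", {
  p <- noise_params(A = 4.6e-25, beta = 1, B = 1.7e-27, C = 1.1e-31,
                    D = 4.2e-36)
  f <- 10^seq(0, 5, length.out = 400)
  fit <- fit_noise_model(eval_noise_model(p, f))
  expect_equal(fit$A, p$A, tolerance = 0.01)
  expect_equal(fit$beta, p$beta, tolerance = 0.01)
  expect_equal(fit$B, p$B, tolerance = 0.01)
  expect_equal(fit$C, p$C, tolerance = 0.01)
  expect_equal(fit$D, p$D, tolerance = 0.01)
})

test_that("white spectrum yields negligible colored terms and bounded beta", {
  f <- 10^seq(0, 5, length.out = 300)
  fit <- fit_noise_model(eval_noise_model(noise_params(B = 1e-24), f))
  expect_equal(fit$B, 1e-24, tolerance = 0.01)
  # colored contributions < 1% of the white level anywhere in range
  expect_lt(fit$A * 1^(-fit$beta), 0.01 * fit$B)
  expect_lt(fit$C * 1e5, 0.01 * fit$B)
  expect_lt(fit$D * 1e10, 0.01 * fit$B)
  expect_gte(fit$beta, 0)
  expect_lte(fit$beta, 2)
})

test_that("degenerate spectra are rejected", {
  expect_error(fit_noise_model(noise_spectrum(1:30, rep(0, 30))),
               "degenerate")
  expect_error(fit_noise_model(noise_spectrum(1:10, rep(1e-24, 10))),
               "insufficient")
})

test_that("single-seed PSD round trip recovers the generating parameters", {
  fs <- 250e3
  p <- noise_params(A = 4.57e-25, beta = 1, B = 1.69e-27, C = 1.12e-31,
                    D = 4.21e-36)
  x <- synth_noise(p, fs, 4 * fs, seed = 11)
  sp <- estimate_psd(x, fs)
  fit <- fit_noise_model(sp, fit_range_Hz = c(3 * fs / 2^14, 1e5))
  expect_equal(fit$A, p$A, tolerance = 0.25)
  expect_equal(fit$beta, p$beta, tolerance = 0.15)
  expect_equal(fit$B, p$B, tolerance = 0.25)
  expect_equal(fit$C, p$C, tolerance = 0.25)
  expect_equal(fit$D, p$D, tolerance = 0.25)
})

test_that("spectra round-trip through TSV", {
  sp <- eval_noise_model(noise_preset("si0mV"), 10^seq(0, 5, by = 0.1))
  path <- tempfile(fileext = ".tsv")
  write_spectrum(sp, path)
  sp2 <- read_spectrum(path)
  expect_equal(sp2$freqs_Hz, sp$freqs_Hz, tolerance = 1e-9)
  expect_equal(sp2$psd_A2_per_Hz, sp$psd_A2_per_Hz, tolerance = 1e-9)
})
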