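#' Uniformly sampled current recording
#'
#' The package's trace container: current samples in pA plus acquisition
#' metadata (sampling rate, low-pass filter settings, bias).
#'
#' @param samples_pA Numeric vector of current samples in pA (finite).
#' @param fs_Hz Sampling rate in Hz.
#' @param filter_cutoff_Hz Low-pass cutoff applied to the samples, or `NA`
#'   if unfiltered. Must be below fs/2.
#' @param filter_order Filter order, or `NA`.
#' @param bias_mV Applied voltage in mV.
#' @param meta Free-form provenance list (seed, preset names, ...).
#' @return An object of class `trace_recording`.
#' @export
trace_recording <- function(samples_pA, fs_Hz, filter_cutoff_Hz = NA_real_,
                            filter_order = NA_real_, bias_mV = NA_real_,
                            meta = list()) {
  if (!is.numeric(fs_Hz) || fs_Hz <= 0) stop("fs_Hz must be positive")
  if (any(!is.finite(samples_pA))) stop("samples must be finite")
  if (!is.na(filter_cutoff_Hz) && filter_cutoff_Hz >= fs_Hz / 2)
    stop("filter_cutoff_Hz must be below Nyquist")
  structure(list(samples_pA = as.numeric(samples_pA), fs_Hz = fs_Hz,
                 filter_cutoff_Hz = filter_cutoff_Hz,
                 filter_order = filter_order, bias_mV = bias_mV,
                 meta = meta),
            class = "trace_recording")
}

#' @export
print.trace_recording <- function(x, ...) {
  cat(sprintf(
    "<trace_recording> %d samples @ %g kHz (%.3f s), filter %s, bias %s mV\n",
    length(x$samples_pA), x$fs_Hz / 1e3, length(x$samples_pA) / x$fs_Hz,
    if (is.na(x$filter_cutoff_Hz)) "none"
    else sprintf("%g kHz order %g", x$filter_cutoff_Hz / 1e3, x$filter_order),
    format(x$bias_mV)))
  invisible(x)
}

#' ssDNA homopolymer blockade presets
#'
#' Residual-current Gaussians and dwell-time range for 40-nt homopolymers
#' translocating a 1.4-nm-diameter, 2.4-nm-effective-thickness pore at
#' 200 mV: poly-A 688.4 +/- 43.1 pA, poly-T 631.5 +/- 67.6 pA, poly-C
#' 643.8 +/- 85.2 pA, dwell times spanning 4-1000 us. `"polyA_mix"` and
#' `"polyT_mix"` carry the narrower components observed when both polymers
#' are measured together in one chamber (679.9 +/- 21.3 and
#' 641.2 +/- 20.2 pA). At other biases the residual scales proportionally
#' with voltage (documented simplification).
#'
#' @param label One of `"polyA"`, `"polyT"`, `"polyC"`, `"polyA_mix"`,
#'   `"polyT_mix"`.
#' @param bias_mV Bias the preset is evaluated at (default 200 mV, the
#'   reference bias the residuals are defined at).
#' @return List with `label`, `residual_mean_pA`, `residual_sd_pA`,
#'   `dwell_min_us`, `dwell_max_us`.
#' @export
homopolymer_preset <- function(label, bias_mV = 200) {
  tab <- list(polyA = c(688.4, 43.1),
              polyT = c(631.5, 67.6),
              polyC = c(643.8, 85.2),
              polyA_mix = c(679.9, 21.3),
              polyT_mix = c(641.2, 20.2))
  if (!label %in% names(tab))
    stop("unknown homopolymer preset: ", label)
  scale <- bias_mV / 200
  list(label = label,
       residual_mean_pA = tab[[label]][1] * scale,
       residual_sd_pA = tab[[label]][2] * scale,
       dwell_min_us = 4, dwell_max_us = 1000)
}

#' Draw a ground-truth event list
#'
#' Dwell times are log-uniform on the preset range (blockade dwell spans
#' ~2.5 decades with no pronounced mode); residual currents are Gaussian
#' with the preset mean/SD, truncated at 0 pA; inter-event gaps are
#' exponential with the given mean rate and events are laid out
#' sequentially, so they never overlap; rates implying an expected duty
#' cycle above 50% are rejected as unpackable.
#'
#' @param preset A [homopolymer_preset()]-like list (needs
#'   `residual_mean_pA`, `residual_sd_pA`, `dwell_min_us`, `dwell_max_us`,
#'   `label`).
#' @param n_events Number of events (>= 1).
#' @param rate_per_s Mean event rate in 1/s (default 10).
#' @param seed Integer RNG seed.
#' @param dwell_law `"loguniform"` (default) or `"lognormal"` (median at the
#'   geometric center of the range, spread covering it at 2 SD).
#' @return Data frame with columns `start_s`, `dwell_us`, `residual_pA`,
#'   `label`, sorted and non-overlapping.
#' @export
sample_events <- function(preset, n_events, rate_per_s = 10, seed = 1,
                          dwell_law = c("loguniform", "lognormal")) {
  dwell_law <- match.arg(dwell_law)
  if (n_events < 1) stop("n_events must be >= 1")
  set.seed(seed)
  n <- as.integer(n_events)
  lo <- preset$dwell_min_us; hi <- preset$dwell_max_us
  dwell <- if (lo == hi) rep(lo, n)
    else if (dwell_law == "loguniform")
      exp(stats::runif(n, log(lo), log(hi)))
    else {
      m <- sqrt(lo * hi)
      s <- log(hi / m) / 2
      pmin(pmax(stats::rlnorm(n, log(m), s), lo), hi)
    }
  res <- stats::rnorm(n, preset$residual_mean_pA, preset$residual_sd_pA)
  for (tries in 1:100) {   # truncate at 0: redraw the non-physical tail
    bad <- res < 0
    if (!any(bad)) break
    res[bad] <- stats::rnorm(sum(bad), preset$residual_mean_pA,
                             preset$residual_sd_pA)
  }
  res[res < 0] <- 0
  # events occupy start..start+dwell; a rate whose expected duty cycle
  # exceeds 50% cannot be honored alongside the dwell law
  if (rate_per_s * mean(dwell) * 1e-6 > 0.5)
    stop("event generation failed: rate too high to pack events")
  gaps <- stats::rexp(n, rate_per_s)
  start <- cumsum(gaps) + c(0, cumsum(dwell[-n] * 1e-6))
  data.frame(start_s = start, dwell_us = dwell, residual_pA = res,
             label = preset$label, stringsAsFactors = FALSE)
}

#' Render an idealized noisy current trace
#'
#' Baseline at the open-pore current everywhere, rectangular drops to each
#' event's residual current for its dwell, plus additive colored noise from
#' [synth_noise()]. Unfiltered; pass the result through [bessel_lowpass()]
#' to emulate the recording chain.
#'
#' @param I0_nA Open-pore current in nA.
#' @param events Event data frame as from [sample_events()] (may have 0 rows).
#' @param noise_params A [noise_params()]; use `noise_params()` for zero noise.
#' @param fs_Hz Sampling rate (default 250 kHz).
#' @param duration_s Trace duration in s; all events must fit inside it.
#' @param seed Integer RNG seed for the noise.
#' @param bias_mV Recorded bias metadata (default 200).
#' @return An unfiltered [trace_recording()] (samples in pA).
#' @export
render_trace <- function(I0_nA, events, noise_params, fs_Hz = 250e3,
                         duration_s, seed = 1, bias_mV = 200) {
  n <- as.integer(round(duration_s * fs_Hz))
  if (nrow(events) > 0 &&
      any(events$start_s + events$dwell_us * 1e-6 > duration_s))
    stop("event outside trace duration")
  x <- rep(I0_nA * 1000, n)
  if (nrow(events) > 0) {
    i0 <- as.integer(round(events$start_s * fs_Hz)) + 1L
    len <- pmax(1L, as.integer(round(events$dwell_us * fs_Hz / 1e6)))
    for (k in seq_len(nrow(events))) {
      idx <- i0[k]:min(i0[k] + len[k] - 1L, n)
      x[idx] <- events$residual_pA[k]
    }
  }
  x <- x + synth_noise(noise_params, fs_Hz, n, seed) * 1e12
  trace_recording(x, fs_Hz, bias_mV = bias_mV,
                  meta = list(seed = seed, I0_nA = I0_nA,
                              n_events = nrow(events)))
}

# digital 6-pole Bessel design: poles of the reverse Bessel polynomial,
# frequency-scaled so |H| = -3 dB at the cutoff, then bilinear transform
# with prewarping. Cached per (fs, cutoff, order).
.bessel_filter <- local({
  cache <- list()
  function(fs_Hz, cutoff_Hz, order) {
    key <- paste(fs_Hz, cutoff_Hz, order)
    if (!is.null(cache[[key]])) return(cache[[key]])
    n <- order
    k <- 0:n
    coefs <- factorial(2 * n - k) /
      (2^(n - k) * factorial(k) * factorial(n - k))
    p <- polyroot(coefs)
    g <- Re(prod(-p))
    hmag <- function(w) abs(g / prod(1i * w - p))
    w3 <- stats::uniroot(function(w) hmag(w) - 1 / sqrt(2),
                         c(1e-3, 1e3))$root
    wc <- 2 * fs_Hz * tan(pi * cutoff_Hz / fs_Hz)  # prewarped analog cutoff
    Sp <- p / w3 * wc
    ba <- signal::as.Arma(signal::bilinear(Sz = numeric(0), Sp = Sp,
                                           Sg = Re(prod(-Sp)), T = 1 / fs_Hz))
    cache[[key]] <<- ba
    ba
  }
})

#' Apply a Bessel low-pass filter to a recording
#'
#' Forward (causal) 6-pole Bessel low-pass, the anti-aliasing filter of a
#' patch-clamp amplifier: unity gain at DC, -3 dB at the cutoff, maximally
#' flat group delay. The digital filter is obtained from the analog Bessel
#' prototype by bilinear transform with frequency prewarping.
#'
#' @param trace A [trace_recording()].
#' @param cutoff_Hz -3 dB cutoff in Hz (default 10 kHz); must be < fs/2.
#' @param order Number of poles (default 6).
#' @return The filtered [trace_recording()] with filter metadata set.
#' @export
bessel_lowpass <- function(trace, cutoff_Hz = 1e4, order = 6) {
  stopifnot(inherits(trace, "trace_recording"))
  if (cutoff_Hz >= trace$fs_Hz / 2)
    stop("cutoff must be below the Nyquist frequency")
  ba <- .bessel_filter(trace$fs_Hz, cutoff_Hz, order)
  # pad with the initial level so the filter starts settled, not at 0 pA
  pad <- as.integer(round(10 * trace$fs_Hz / cutoff_Hz))
  y <- as.numeric(signal::filter(ba, c(rep(trace$samples_pA[1], pad),
                                       trace$samples_pA)))
  out <- trace
  out$samples_pA <- y[(pad + 1):length(y)]
  out$filter_cutoff_Hz <- cutoff_Hz
  out$filter_order <- order
  out
}

#' Measurement-condition presets
#'
#' Open-pore and mean blockade currents for the three membrane thicknesses
#' (2.5-nm pore, 200 mV): 20 nm (0.35, 0.11 nA), 10 nm (0.81, 0.21 nA),
#' 5 nm (1.64, 0.42 nA), with the per-condition blockade-fraction SD bands
#' (5.7, 4.5, 3.3 percentage points) setting the event-depth spread. Plain
#' substrate names return only the noise preset. The noise preset attached
#' to membrane conditions is quartz under bias, the configuration those
#' recordings were made in.
#'
#' @param name One of `"membrane20nm"`, `"membrane10nm"`, `"membrane5nm"`,
#'   `"quartz0mV"`, `"quartzBias"`, `"si0mV"`, `"siBias"`.
#' @return List with `I0_nA`, `mean_blockade_nA`, `depth_sd_pA`,
#'   `frac_sd_pct` and `noise` (a [noise_params()]); the current fields are
#'   `NA` for plain substrate names.
#' @examples
#' make_condition_preset("membrane5nm")$I0_nA  # 1.64
#' @export
make_condition_preset <- function(name) {
  mem <- list(membrane20nm = c(I0 = 0.35, dIB = 0.11, fsd = 5.7),
              membrane10nm = c(I0 = 0.81, dIB = 0.21, fsd = 4.5),
              membrane5nm  = c(I0 = 1.64, dIB = 0.42, fsd = 3.3))
  if (name %in% names(mem)) {
    m <- mem[[name]]
    return(list(name = name, I0_nA = m[["I0"]],
                mean_blockade_nA = m[["dIB"]],
                frac_sd_pct = m[["fsd"]],
                depth_sd_pA = m[["fsd"]] / 100 * m[["I0"]] * 1000,
                noise = noise_preset("quartzBias")))
  }
  if (name %in% c("quartz0mV", "quartzBias", "si0mV", "siBias"))
    return(list(name = name, I0_nA = NA_real_, mean_blockade_nA = NA_real_,
                frac_sd_pct = NA_real_, depth_sd_pA = NA_real_,
                noise = noise_preset(name)))
  stop("unknown condition preset: ", name)
}

#' Event preset for a membrane condition
#'
#' Converts a membrane condition into the event-sampling preset used by
#' [sample_events()]: residual mean I0 - mean blockade, residual SD from the
#' printed blockade-fraction SD band, dwell range 4-1000 us.
#'
#' @param condition A [make_condition_preset()] membrane condition.
#' @return Preset list suitable for [sample_events()].
#' @export
condition_event_preset <- function(condition) {
  if (is.na(condition$I0_nA))
    stop("condition has no blockade currents: ", condition$name)
  list(label = condition$name,
       residual_mean_pA = (condition$I0_nA - condition$mean_blockade_nA) * 1000,
       residual_sd_pA = condition$depth_sd_pA,
       dwell_min_us = 4, dwell_max_us = 1000)
}
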