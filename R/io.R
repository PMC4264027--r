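#' Write / read a current trace as TSV
#'
#' Two columns (time_s, current_pA) preceded by `#key=value` metadata lines
#' carrying the sampling rate, filter settings, bias and provenance. The
#' header must declare `fs_Hz`; samples round-trip to 1e-6 pA.
#'
#' @param trace A [trace_recording()].
#' @param path File path.
#' @return `write_trace` returns the path invisibly; `read_trace` returns a
#'   [trace_recording()].
#' @rdname trace_io
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "trace_recording"))
  if (any(!is.finite(trace$samples_pA))) stop("format error: NaN samples")
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(fs_Hz = trace$fs_Hz, filter_cutoff_Hz = trace$filter_cutoff_Hz,
           filter_order = trace$filter_order, bias_mV = trace$bias_mV)
  for (k in names(hdr))
    writeLines(sprintf("#%s=%s", k, format(hdr[[k]], digits = 15)), con)
  for (k in names(trace$meta))
    writeLines(sprintf("#meta.%s=%s", k, format(trace$meta[[k]])), con)
  t_s <- (seq_along(trace$samples_pA) - 1) / trace$fs_Hz
  writeLines(sprintf("%.9f\t%.6f", t_s, trace$samples_pA), con)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  hdr <- sub("^#", "", lines[hdr_idx])
  kv <- strsplit(hdr, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(z) paste(z[-1], collapse = "="), "")
  if (!"fs_Hz" %in% keys) stop("format error: missing #fs_Hz header")
  num <- function(k) {
    if (!k %in% keys) return(NA_real_)
    suppressWarnings(as.numeric(vals[match(k, keys)]))
  }
  body <- lines[setdiff(seq_along(lines), hdr_idx)]
  body <- body[nzchar(body)]
  samples <- vapply(strsplit(body, "\t", fixed = TRUE),
                    function(z) as.numeric(z[2]), numeric(1))
  if (any(!is.finite(samples))) stop("format error: non-finite samples")
  meta_keys <- grep("^meta\\.", keys, value = TRUE)
  meta <- as.list(vals[match(meta_keys, keys)])
  names(meta) <- sub("^meta\\.", "", meta_keys)
  trace_recording(samples, fs_Hz = num("fs_Hz"),
                  filter_cutoff_Hz = num("filter_cutoff_Hz"),
                  filter_order = num("filter_order"),
                  bias_mV = num("bias_mV"), meta = meta)
}

#' Write / read an event table as TSV
#'
#' Tab-separated with a commented header line; works for both ground-truth
#' tables from [sample_events()] and detection tables from
#' [detect_events()].
#'
#' @param events Event data frame.
#' @param path File path.
#' @rdname event_io
#' @export
write_events <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(events), collapse = "\t")), con)
  utils::write.table(events, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname event_io
#' @export
read_events <- function(path) {
  first <- readLines(path, n = 1)
  cols <- strsplit(sub("^#", "", first), "\t", fixed = TRUE)[[1]]
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          comment.char = "#", col.names = cols,
                          stringsAsFactors = FALSE)
  df
}

#' Pipeline run configuration
#'
#' All tunables of the simulate-filter-detect-discriminate chain with
#' defaults equal to the package's documented choices. The configuration
#' round-trips through JSON unchanged.
#'
#' @param condition Condition preset name (see [make_condition_preset()]).
#' @param polymers Character vector of homopolymer presets to simulate
#'   (`NULL` uses the condition's own blockade levels instead).
#' @param n_events Events per polymer (default 300).
#' @param rate_per_s Event rate (default 10).
#' @param seed Master seed.
#' @param fs_Hz Sampling rate (default 250 kHz).
#' @param filter_cutoff_Hz Bessel cutoff (default 10 kHz).
#' @param filter_order Bessel order (default 6).
#' @param k_sigma Detection threshold multiplier (default 5).
#' @param min_dwell_us Detection minimum dwell (default 12).
#' @param baseline_window_s Baseline median window (default 0.01).
#' @param g_open_nS Open conductance used for fraction/blockade conversion
#'   (default 6.95).
#' @param bias_mV Bias (default 200).
#' @return List of class `run_config`.
#' @export
run_config <- function(condition = "membrane5nm", polymers = NULL,
                       n_events = 300, rate_per_s = 10, seed = 1,
                       fs_Hz = 250e3, filter_cutoff_Hz = 1e4,
                       filter_order = 6, k_sigma = 5, min_dwell_us = 12,
                       baseline_window_s = 0.01, g_open_nS = 6.95,
                       bias_mV = 200) {
  structure(list(condition = condition, polymers = polymers,
                 n_events = n_events, rate_per_s = rate_per_s, seed = seed,
                 fs_Hz = fs_Hz, filter_cutoff_Hz = filter_cutoff_Hz,
                 filter_order = filter_order, k_sigma = k_sigma,
                 min_dwell_us = min_dwell_us,
                 baseline_window_s = baseline_window_s,
                 g_open_nS = g_open_nS, bias_mV = bias_mV),
            class = "run_config")
}

# derive a reproducible sub-seed from the master seed, kept within 32-bit
.subseed <- function(seed, offset) (as.integer(seed) * 101L + offset) %% 2000000011L

#' Run the full simulate - filter - detect - discriminate pipeline
#'
#' Simulates a recording for the configured condition (one trace per
#' polymer when `polymers` is set, otherwise the condition's blockade
#' levels), Bessel-filters it, detects and summarizes events, and, for a
#' two-polymer mixture, fits the two-component residual-current mixture.
#' Deterministic for a fixed config; stage failures are reported in the
#' stage status rather than aborting the stages before them.
#'
#' @param config A [run_config()].
#' @param outdir Optional directory; when set, traces, event tables and the
#'   JSON report are written there.
#' @return List of class `pipeline_report`: `schema_version`, `config`,
#'   `stats` (event statistics), `events`, `truth`, `score`, `mixture`
#'   (when >= 2 polymers), `stages` (per-stage status).
#' @export
run_pipeline <- function(config = run_config(), outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  stages <- list()
  report <- list(schema_version = "1.0", config = unclass(config))
  cond <- make_condition_preset(config$condition)
  presets <- if (is.null(config$polymers)) list(condition_event_preset(cond))
    else lapply(config$polymers, homopolymer_preset, bias_mV = config$bias_mV)

  all_truth <- list(); all_det <- list()
  for (i in seq_along(presets)) {
    pr <- presets[[i]]
    truth <- if (config$n_events >= 1)
      sample_events(pr, config$n_events, config$rate_per_s,
                    seed = .subseed(config$seed, 7L * i))
    else data.frame(start_s = numeric(0), dwell_us = numeric(0),
                    residual_pA = numeric(0), label = character(0))
    dur <- if (nrow(truth))
      max(truth$start_s + truth$dwell_us * 1e-6) + 0.05 else 0.5
    I0 <- if (!is.na(cond$I0_nA)) cond$I0_nA
      else config$g_open_nS * config$bias_mV / 1000
    tr <- render_trace(I0, truth, cond$noise, fs_Hz = config$fs_Hz,
                       duration_s = dur, seed = .subseed(config$seed, 13L * i),
                       bias_mV = config$bias_mV)
    tr <- bessel_lowpass(tr, config$filter_cutoff_Hz, config$filter_order)
    bl <- correct_baseline(tr, config$baseline_window_s)
    det <- detect_events(tr, bl, config$k_sigma, config$min_dwell_us)
    det$label <- if (nrow(det)) pr$label else character(0)
    all_truth[[i]] <- truth; all_det[[i]] <- det
    if (!is.null(outdir)) {
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      write_trace(tr, file.path(outdir, paste0("trace_", pr$label, ".tsv")))
      write_events(truth, file.path(outdir, paste0("truth_", pr$label, ".tsv")))
      write_events(det, file.path(outdir, paste0("events_", pr$label, ".tsv")))
    }
  }
  truth <- do.call(rbind, all_truth)
  det <- do.call(rbind, all_det)
  stages$simulate <- "ok"; stages$filter <- "ok"; stages$detect <- "ok"
  report$truth <- truth
  report$events <- det

  # baseline RMS from an event-free synthetic stretch of the same noise
  base_rms <- stats::sd(bessel_lowpass(
    render_trace(1, truth[0, , drop = FALSE], cond$noise,
                 fs_Hz = config$fs_Hz, duration_s = 0.2,
                 seed = .subseed(config$seed, 3L)),
    config$filter_cutoff_Hz, config$filter_order)$samples_pA)
  report$baseline_rms_pA <- base_rms

  report$stats <- tryCatch({
    s <- summarize_events(det, base_rms)
    stages$summarize <- "ok"
    unclass(s)
  }, error = function(e) {
    stages$summarize <<- paste("error:", conditionMessage(e)); NULL
  })
  report$score <- if (nrow(truth) && nrow(det))
    score_events(det, truth, config$min_dwell_us) else NULL

  # discriminate on the depth-reliable events: ridge-limited short
  # blockades carry no usable residual-current information
  resid_rel <- det$residual_mean_pA[det$depth_reliable]
  report$mixture <- tryCatch({
    if (length(presets) >= 2) {
      mx <- fit_two_gaussian_mixture(resid_rel,
                                     seed = .subseed(config$seed, 29L),
                                     k = length(presets))
      stages$discriminate <- "ok"
      as.data.frame(mx)
    } else {
      g <- fit_single_gaussian(resid_rel)
      stages$discriminate <- "ok"
      data.frame(mean_pA = g$mean_pA, sd_pA = g$sd_pA, weight = 1)
    }
  }, error = function(e) {
    stages$discriminate <<- paste("insufficient-data:",
                                  conditionMessage(e)); NULL
  })
  report$stages <- stages
  class(report) <- "pipeline_report"
  if (!is.null(outdir)) {
    json <- report
    json$events <- NULL; json$truth <- NULL
    class(json) <- NULL
    jsonlite::write_json(json, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> condition:", x$config$condition, "\n")
  for (s in names(x$stages)) cat(sprintf("  %-12s %s\n", s, x$stages[[s]]))
  if (!is.null(x$stats))
    cat(sprintf("  %d events, fraction %.1f%%, SNR %.1f\n",
                x$stats$n_events, x$stats$mean_fraction_pct, x$stats$snr))
  invisible(x)
}
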