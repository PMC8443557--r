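#' Construct a current trace
#'
#' @param samples Numeric vector of current samples in pA.
#' @param sampling_hz Sampling rate in Hz.
#' @param polarity Deflection sign of synaptic events: `"negative"` (inward,
#'   mEPSC at -65 mV) or `"positive"` (outward, mIPSC at 0 mV).
#' @param condition Recording condition label.
#' @param age Age label (`"0M"`, `"3M"`, `"6M"`).
#' @return A `trace` object (numeric vector with attributes).
#' @export
trace <- function(samples, sampling_hz, polarity = c("negative", "positive"),
                  condition = c("mEPSC", "mIPSC", "field", "evoked"),
                  age = c("3M", "0M", "6M")) {
  polarity <- match.arg(polarity)
  condition <- match.arg(condition)
  age <- match.arg(age)
  stopifnot(is.numeric(samples), length(samples) >= 1,
            is.numeric(sampling_hz), sampling_hz > 0)
  structure(as.numeric(samples), sampling_hz = sampling_hz,
            polarity = polarity, condition = condition, age = age,
            class = "trace")
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %s %s, %d samples @ %g Hz (%.2f s), polarity %s\n",
              attr(x, "age"), attr(x, "condition"), length(x),
              attr(x, "sampling_hz"), length(x) / attr(x, "sampling_hz"),
              attr(x, "polarity")))
  invisible(x)
}

#' Detection parameters for miniature-event analysis
#'
#' Amplitude and area thresholds are expressed in units of the baseline SD
#' (and SD x ms). When not given explicitly they are taken from the default
#' table keyed by (age, condition): amplitude/area 3/4.5 (0M mEPSC),
#' 3/9 (0M mIPSC), 2/3 (3M and 6M mEPSC), 2/6 (3M and 6M mIPSC).
#'
#' @param age,condition Keys into the default threshold table.
#' @param band_low_hz,band_high_hz Band-pass edges in Hz (default 4-1000).
#' @param baseline_window_ms Length of the event-free baseline segment used
#'   for SD estimation (default 50 ms).
#' @param amp_thresh_sd Amplitude threshold in baseline-SD units.
#' @param area_thresh_sd_ms Area threshold in baseline-SD x ms units.
#' @return A `detection_params` list.
#' @export
detection_params <- function(age = c("3M", "0M", "6M"),
                             condition = c("mEPSC", "mIPSC"),
                             band_low_hz = 4, band_high_hz = 1000,
                             baseline_window_ms = 50,
                             amp_thresh_sd = NULL, area_thresh_sd_ms = NULL) {
  age <- match.arg(age)
  condition <- match.arg(condition)
  defaults <- list(
    `0M.mEPSC` = c(3, 4.5), `0M.mIPSC` = c(3, 9),
    `3M.mEPSC` = c(2, 3),   `3M.mIPSC` = c(2, 6),
    `6M.mEPSC` = c(2, 3),   `6M.mIPSC` = c(2, 6))
  key <- defaults[[paste(age, condition, sep = ".")]]
  amp_thresh_sd <- amp_thresh_sd %||% key[1]
  area_thresh_sd_ms <- area_thresh_sd_ms %||% key[2]
  stopifnot(band_low_hz > 0, band_high_hz > band_low_hz,
            amp_thresh_sd > 0, area_thresh_sd_ms > 0,
            baseline_window_ms > 0)
  structure(list(age = age, condition = condition,
                 band_low_hz = band_low_hz, band_high_hz = band_high_hz,
                 baseline_window_ms = baseline_window_ms,
                 amp_thresh_sd = amp_thresh_sd,
                 area_thresh_sd_ms = area_thresh_sd_ms),
            class = "detection_params")
}

# Zero-phase 2nd-order Butterworth band-pass on a plain numeric vector.
# The mean is removed first and the ends are padded with reflected data
# (one low-cut period) so filter start-up transients do not leak into the
# returned samples; output length equals input length.
bandpass_core <- function(samples, sampling_hz, low_hz, high_hz) {
  nyq <- sampling_hz / 2
  if (high_hz >= nyq) stop("band_high_hz must be below the Nyquist frequency")
  bf <- signal::butter(2, c(low_hz, high_hz) / nyq, type = "pass")
  x <- samples - mean(samples)
  n <- length(x)
  np <- min(n - 1L, ceiling(sampling_hz / low_hz))
  pad_head <- 2 * x[1] - x[(np + 1L):2L]        # odd reflection
  pad_tail <- 2 * x[n] - x[(n - 1L):(n - np)]
  y <- signal::filtfilt(bf, c(pad_head, x, pad_tail))
  y[(np + 1L):(np + n)]
}

#' Zero-phase band-pass filter a trace
#'
#' Second-order Butterworth band-pass applied forward-backward
#' (zero phase, so event timing is preserved). Output length equals input
#' length.
#'
#' @param trace A [trace()].
#' @param params A [detection_params()].
#' @return A filtered `trace`.
#' @export
bandpass_filter <- function(trace, params) {
  fs <- attr(trace, "sampling_hz")
  out <- bandpass_core(as.numeric(trace), fs, params$band_low_hz,
                       params$band_high_hz)
  attributes(out) <- attributes(trace)
  out
}

# Minimum SD over sliding windows (event-free baseline selection), on a
# numeric vector that has already been filtered.
baseline_sd_core <- function(x, sampling_hz, window_ms = 50, step_ms = 10) {
  w <- max(2L, round(window_ms / 1000 * sampling_hz))
  if (length(x) < 2L * w)
    stop("trace shorter than twice the baseline window")
  step <- max(1L, round(step_ms / 1000 * sampling_hz))
  starts <- seq.int(1L, length(x) - w + 1L, by = step)
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  s <- cs[starts + w] - cs[starts]
  s2 <- cs2[starts + w] - cs2[starts]
  v <- (s2 - s^2 / w) / (w - 1)
  sqrt(max(0, min(v)))
}

#' Estimate the baseline noise SD of a trace
#'
#' A window of `baseline_window_ms` is slid in 10 ms steps over the raw
#' trace and the window with minimal SD is taken as the event-free baseline
#' segment; its SD is returned. This automates the manual selection of a
#' quiet segment lacking events. The SD is measured on the raw (unfiltered)
#' trace so that thresholds are expressed in units of the recorded baseline
#' noise; detection itself runs on the band-passed trace, whose in-band
#' noise is no larger, which makes the SD-unit thresholds conservative.
#'
#' @param trace A [trace()] at least twice the baseline window long.
#' @param params A [detection_params()].
#' @return Baseline SD in pA.
#' @export
estimate_baseline_sd <- function(trace, params) {
  baseline_sd_core(as.numeric(trace), attr(trace, "sampling_hz"),
                   params$baseline_window_ms)
}

#' Detect miniature synaptic events
#'
#' The trace is band-pass filtered and rectified according to its polarity.
#' Candidate events are local maxima of the rectified filtered trace that
#' exceed `amp_thresh_sd x baseline SD` (the SD of the quiet raw-trace
#' segment found by [estimate_baseline_sd()]) and whose topographic
#' prominence also reaches the amplitude threshold — a peak riding on a
#' larger event's decay is not a separate event unless the trace dips by at
#' least the threshold between them. Candidates closer than 2 ms keep only
#' the larger peak. Each surviving event's boundaries extend to the
#' crossings of half the amplitude threshold around its peak, and the event
#' is accepted iff its trapezoidal area between the boundaries, expressed
#' in SD x ms units, reaches `area_thresh_sd_ms`. Every criterion tightens
#' as either threshold rises, so the accepted-event count is non-increasing
#' in both thresholds. Peak amplitudes are measured on the rectified
#' filtered trace; overlapping events may share boundary samples, in which
#' case the shared area contributes to each.
#'
#' @param trace A [trace()] of at least 1 s.
#' @param params A [detection_params()].
#' @return Data frame of accepted events (`onset_s`, `peak_s`,
#'   `peak_amplitude_pa`, `area_pa_ms`), with attributes
#'   `trace_duration_s` and `baseline_sd_pa`.
#' @export
detect_minis <- function(trace, params) {
  fs <- attr(trace, "sampling_hz")
  if (length(trace) < fs) stop("trace must be at least 1 s long for detection")
  raw <- as.numeric(trace)
  sd_b <- baseline_sd_core(raw, fs, params$baseline_window_ms)
  empty <- data.frame(onset_s = numeric(0), peak_s = numeric(0),
                      peak_amplitude_pa = numeric(0), area_pa_ms = numeric(0))
  dur <- length(trace) / fs
  if (sd_b == 0) {
    if (diff(range(raw)) > 0)
      stop("degenerate baseline: SD is zero but the trace carries signal")
    return(structure(empty, trace_duration_s = dur, baseline_sd_pa = 0))
  }
  filt <- bandpass_core(raw, fs, params$band_low_hz, params$band_high_hz)
  x <- if (attr(trace, "polarity") == "negative") -filt else filt
  amp_thr <- params$amp_thresh_sd * sd_b
  low_thr <- 0.5 * amp_thr
  n <- length(x)
  # candidate peaks: local maxima exceeding the amplitude threshold
  is_peak <- c(FALSE, x[2:(n - 1)] >= x[1:(n - 2)] &
                      x[2:(n - 1)] > x[3:n], FALSE) & x > amp_thr
  peak_idx <- which(is_peak)
  if (!length(peak_idx))
    return(structure(empty, trace_duration_s = dur, baseline_sd_pa = sd_b))
  # prominence gate: reject a peak if higher terrain is reachable without
  # descending at least amp_thr below the peak (it belongs to that event)
  prominent <- vapply(peak_idx, function(q) {
    level <- x[q] - amp_thr
    i <- q - 1L
    while (i >= 1L) {
      if (x[i] > x[q]) return(FALSE)
      if (x[i] < level) break
      i <- i - 1L
    }
    j <- q + 1L
    while (j <= n) {
      if (x[j] > x[q]) return(FALSE)
      if (x[j] < level) break
      j <- j + 1L
    }
    TRUE
  }, logical(1))
  peak_idx <- peak_idx[prominent]
  if (!length(peak_idx))
    return(structure(empty, trace_duration_s = dur, baseline_sd_pa = sd_b))
  # enforce a 2 ms minimum inter-event separation, keeping the larger peak
  min_sep <- round(0.002 * fs)
  ord <- order(x[peak_idx], decreasing = TRUE)
  taken <- logical(length(peak_idx))
  suppressed <- logical(n)
  for (j in ord) {
    p <- peak_idx[j]
    if (suppressed[p]) next
    taken[j] <- TRUE
    suppressed[max(1L, p - min_sep + 1L):min(n, p + min_sep - 1L)] <- TRUE
  }
  peak_idx <- peak_idx[taken]
  # event boundaries: nearest half-threshold crossings around each peak
  below <- x < low_thr
  prev_below <- cummax(ifelse(below, seq_len(n), 0L))
  next_below <- rev(cummin(rev(ifelse(below, seq_len(n), n + 1L))))
  on_idx <- pmax(prev_below[peak_idx] + 1L, 1L)
  off_idx <- pmin(next_below[peak_idx] - 1L, n)
  dt_ms <- 1000 / fs
  ctrap <- c(0, cumsum((x[-1] + x[-n]) / 2))  # ctrap[i]: integral up to i
  area <- (ctrap[off_idx] - ctrap[on_idx]) * dt_ms
  area[off_idx == on_idx] <- x[peak_idx[off_idx == on_idx]] * dt_ms
  ok <- area / sd_b >= params$area_thresh_sd_ms
  out <- data.frame(onset_s = (on_idx[ok] - 1L) / fs,
                    peak_s = (peak_idx[ok] - 1L) / fs,
                    peak_amplitude_pa = x[peak_idx[ok]],
                    area_pa_ms = area[ok])
  out <- out[order(out$onset_s), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, trace_duration_s = dur, baseline_sd_pa = sd_b)
}

#' Per-cell summary of detected miniature events
#'
#' @param events Event data frame from [detect_minis()] (or with the same
#'   columns plus a `trace_duration_s` attribute, or supply `duration_s`).
#' @param duration_s Trace duration; defaults to the events attribute.
#' @param condition,age,group Metadata carried through to the summary.
#' @return A one-row data frame: `frequency_hz`, `mean_amplitude_pa`
#'   (`NA` when no events), `n_events`, plus metadata.
#' @export
summarize_cells <- function(events, duration_s = NULL, condition = NA,
                            age = NA, group = NA) {
  duration_s <- duration_s %||% attr(events, "trace_duration_s")
  if (is.null(duration_s) || duration_s <= 0)
    stop("positive trace duration required")
  n <- nrow(events)
  data.frame(frequency_hz = n / duration_s,
             mean_amplitude_pa = if (n) mean(events$peak_amplitude_pa)
                                 else NA_real_,
             n_events = n, condition = condition, age = age, group = group)
}

#' Excitation/inhibition ratio
#'
#' Miniature mode divides the mEPSC frequency by the mIPSC frequency of a
#' cell; evoked mode divides the peak EPSC amplitude (at -65 mV) by the peak
#' IPSC amplitude (at 0 mV). A zero denominator yields `NA` (excluded
#' listwise from group statistics).
#'
#' @param excitatory,inhibitory Numeric values (frequencies or amplitudes),
#'   or one-row summaries from [summarize_cells()] in miniature mode.
#' @param mode `"miniature_freq"` or `"evoked_amp"`.
#' @return Numeric ratio(s); `NA` where the denominator is zero.
#' @export
ei_ratio <- function(excitatory, inhibitory,
                     mode = c("miniature_freq", "evoked_amp")) {
  mode <- match.arg(mode)
  pick <- function(x) {
    if (is.data.frame(x)) {
      if (mode == "miniature_freq") x$frequency_hz else x$mean_amplitude_pa
    } else as.numeric(x)
  }
  e <- pick(excitatory); i <- pick(inhibitory)
  out <- ifelse(i > 0, e / i, NA_real_)
  out
}

#' Long-term depression magnitude from a normalized field-EPSP series
#'
#' Amplitudes are renormalized so that the baseline window (-10, 0\] min
#' (relative to low-frequency stimulation onset) has mean 1; the LTD
#' magnitude is the renormalized mean over the post-LFS window
#' \[30, 40\] min. Renormalization makes the result invariant to uniform
#' rescaling of the raw series and idempotent.
#'
#' @param times_min Times in minutes relative to LFS onset.
#' @param amplitudes Field EPSP amplitudes (any consistent units).
#' @return Normalized amplitude over the post-LFS window (1 = no change).
#' @export
ltd_magnitude <- function(times_min, amplitudes) {
  stopifnot(length(times_min) == length(amplitudes))
  base <- amplitudes[times_min > -10 & times_min <= 0]
  post <- amplitudes[times_min >= 30 & times_min <= 40]
  if (!length(base)) stop("series does not cover the baseline window (-10, 0]")
  if (!length(post)) stop("series does not cover the post-LFS window [30, 40]")
  mean(post) / mean(base)
}

#' Paired-pulse ratio
#'
#' @param amp1_pa Amplitude of the first evoked response (> 0).
#' @param amp2_pa Amplitude of the second evoked response.
#' @return `amp2_pa / amp1_pa`.
#' @export
paired_pulse_ratio <- function(amp1_pa, amp2_pa) {
  if (any(amp1_pa <= 0)) stop("first-pulse amplitude must be positive")
  amp2_pa / amp1_pa
}

#' Log2 fold change of a physiological parameter between groups
#'
#' `log2(mean(exposed) / mean(unexposed))`; the same logFC convention used
#' for gene expression, so phenotype and transcript trajectories are
#' directly comparable.
#'
#' @param ue_values,vpa_values Numeric vectors for the unexposed and exposed
#'   groups (positive means).
#' @return logFC (base-2).
#' @export
phenotype_logfc <- function(ue_values, vpa_values) {
  mu_ue <- mean(ue_values); mu_vpa <- mean(vpa_values)
  if (!(mu_ue > 0) || !(mu_vpa > 0))
    stop("group means must be positive for a log fold change")
  log2(mu_vpa / mu_ue)
}

#' Per-age group comparison with Welch's t-test and Holm-Sidak correction
#'
#' Two-sided Welch t-test per age between unexposed and exposed groups, with
#' Holm-Sidak step-down adjustment across the family of ages. Ages with
#' fewer than two values in either group are flagged missing (`NA`) and do
#' not count toward the family size.
#'
#' @param values Numeric vector of per-cell (or per-animal) measurements.
#' @param age Age label per value.
#' @param group Group label per value (`"UE"` / `"VPA"`).
#' @return Data frame with one row per age: `age`, `n_ue`, `n_vpa`,
#'   `p_raw`, `p_adj`.
#' @export
group_compare <- function(values, age, group) {
  stopifnot(length(values) == length(age), length(values) == length(group))
  ages <- unique(age)
  res <- lapply(ages, function(a) {
    ue <- values[age == a & group == "UE"]
    vpa <- values[age == a & group == "VPA"]
    p <- if (length(ue) < 2 || length(vpa) < 2) NA_real_
    else if (stats::sd(ue) > 0 || stats::sd(vpa) > 0)
      stats::t.test(vpa, ue, var.equal = FALSE)$p.value
    else if (mean(ue) == mean(vpa)) 1 else 0  # both groups constant
    data.frame(age = a, n_ue = length(ue), n_vpa = length(vpa), p_raw = p)
  })
  out <- do.call(rbind, res)
  out$p_adj <- p_adjust_holm_sidak(out$p_raw)
  out
}
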