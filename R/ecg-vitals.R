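# ECG vital-sign extraction: baseline filtering, R-peak detection, heart
# rate per 4 s window, and breathing rate per 20 s window via the
# ECG-derived respiration (EDR) tachogram.

#' Remove ECG baseline wander with a second-order IIR notch
#'
#' Designs a narrow-band-reject biquad centered at `f0` Hz with quality
#' factor `Q` and applies it along the stream. With the defaults
#' (`f0 = 0.05` Hz, `Q = 0.005`) the filter behaves as a baseline-wander
#' remover: over any practical record length it suppresses DC and slow
#' drift (the near-unit-circle pole that would restore DC has a time
#' constant of hundreds of seconds) while leaving the upper ECG band
#' essentially untouched.
#'
#' @param ecg A [sensor_stream()] of modality `"ecg"`, length >= 10.
#' @param f0 Notch center frequency in Hz.
#' @param Q Quality factor (dimensionless); bandwidth is `f0 / Q`.
#' @param zero_phase If `TRUE` apply forward-backward (zero phase);
#'   default is a single forward pass.
#' @return The filtered stream (same length, same metadata).
#' @export
baseline_filter <- function(ecg, f0 = 0.05, Q = 0.005, zero_phase = FALSE) {
  stopifnot(inherits(ecg, "sensor_stream"))
  if (ecg$modality != "ecg") stop("`ecg` must be an ECG stream",
                                  call. = FALSE)
  if (nrow(ecg$samples) < 10) stop("ECG stream too short (< 10 samples)",
                                   call. = FALSE)
  coef <- design_notch(f0, Q, ecg$fs)
  x <- as.numeric(ecg$samples[, 1])
  y <- if (zero_phase) signal::filtfilt(coef$b, coef$a, x)
       else as.numeric(signal::filter(coef$b, coef$a, x))
  out <- ecg
  out$samples <- matrix(y, ncol = 1)
  out
}

# Notch biquad design (same formulation as scipy.signal.iirnotch): zeros on
# the unit circle at +-w0, pole radius set from the -3 dB bandwidth f0/Q.
design_notch <- function(f0, Q, fs) {
  if (fs <= 2 * f0)
    stop("sampling rate too low for the notch design", call. = FALSE)
  w0 <- f0 / (fs / 2)                    # normalized (1 = Nyquist)
  bw <- w0 / Q
  if (bw >= 1)
    stop("notch bandwidth exceeds Nyquist; increase Q or fs", call. = FALSE)
  beta <- tan(bw * pi / 2)
  gain <- 1 / (1 + beta)
  b <- gain * c(1, -2 * cos(pi * w0), 1)
  a <- c(1, -2 * gain * cos(pi * w0), 2 * gain - 1)
  list(b = b, a = a)
}

#' Detect R peaks in an ECG window by the rolling-mean method
#'
#' Shifts the window to a nonnegative baseline, computes a centered moving
#' average with half-width `roll_s` seconds (edges padded with the window
#' mean), marks maximal contiguous runs where the signal exceeds the
#' rolling mean -- raised by `ma_perc` percent, the standard guard against
#' spurious regions in flat or noisy segments -- as regions of interest
#' (ROI), and takes one peak per ROI at its maximum (first index on ties).
#' RR intervals are derived from consecutive peaks.
#'
#' At 50 Hz a sample is 20 ms, which is coarse next to the few-percent
#' respiratory modulation of the RR intervals, so each peak is refined to
#' sub-sample resolution by 4x cubic-spline up-sampling around the ROI
#' maximum (`upsample`, default 4); RR intervals are computed from the
#' refined times. Set `upsample = 1` for bare integer-index peaks.
#'
#' @param win A `window` over a filtered ECG stream (see [segment()]),
#'   typically 4 s.
#' @param roll_s Rolling-mean half-width in seconds.
#' @param ma_perc Percentage by which the rolling mean is raised before
#'   thresholding (0 gives the bare rolling mean).
#' @param upsample Up-sampling factor for peak-time refinement.
#' @return List of class `rpeak_set`: `peak_indices` (1-based, relative to
#'   the parent stream), `peak_times_s` (refined), `rr_ms`, `fs`, and
#'   `flagged` (`TRUE` when fewer than 2 peaks were found).
#' @export
detect_r_peaks <- function(win, roll_s = 0.25, ma_perc = 20, upsample = 4) {
  stopifnot(inherits(win, "window"))
  x <- as.numeric(window_data(win))
  x <- x - min(x)
  fs <- win$stream$fs
  hw <- round(roll_s * fs)
  padded <- c(rep(mean(x), hw), x, rep(mean(x), hw))
  roll <- as.numeric(stats::filter(padded, rep(1 / (2 * hw + 1), 2 * hw + 1),
                                   sides = 2))
  roll <- roll[(hw + 1):(hw + length(x))]
  above <- x > roll * (1 + ma_perc / 100)
  peaks <- integer(0)
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      seg <- starts[j]:ends[j]
      peaks <- c(peaks, seg[which.max(x[seg])])
    }
  }
  peaks_abs <- peaks + win$start             # 1-based into parent stream
  frac <- if (upsample > 1)
    vapply(peaks, refine_peak, 0, x = x, upsample = upsample) else
    as.numeric(peaks)
  times <- (frac + win$start - 1) / fs
  rr <- if (length(times) >= 2) diff(times) * 1000 else numeric(0)
  structure(list(peak_indices = peaks_abs, peak_times_s = times,
                 rr_ms = rr, fs = fs,
                 flagged = length(peaks_abs) < 2),
            class = "rpeak_set")
}

# Fractional peak location: cubic-spline up-sample the 5 samples around a
# local maximum and take the argmax on the finer grid.
refine_peak <- function(i, x, upsample = 4) {
  lo <- max(1L, i - 2L); hi <- min(length(x), i + 2L)
  if (hi - lo < 2) return(as.numeric(i))
  grid <- seq(lo, hi, by = 1 / upsample)
  vals <- stats::spline(lo:hi, x[lo:hi], xout = grid, method = "fmm")$y
  grid[which.max(vals)]
}

#' Heart rate from an RR-interval set
#'
#' `HR = round(60000 / mean(rr_ms))` beats per minute. Windows whose HR
#' exceeds `bad_above` bpm are labeled `bad_signal` (a simple signal
#' quality index: rates that high at rest or during daily activity are
#' overwhelmingly motion artifact).
#'
#' @param rpeaks An `rpeak_set` from [detect_r_peaks()], or any list with
#'   a non-empty `rr_ms`.
#' @param window_span `c(start_s, end_s)` recorded on the measurement.
#' @param bad_above Quality threshold in bpm.
#' @return A one-row data frame (kind, value, window_start_s,
#'   window_end_s, quality), or `NULL` when `rr_ms` is empty.
#' @export
compute_hr <- function(rpeaks, window_span = c(NA_real_, NA_real_),
                       bad_above = 190) {
  rr <- rpeaks$rr_ms
  if (!length(rr)) return(NULL)
  hr <- round_int(60000 / mean(rr))
  data.frame(kind = "HR", value = hr,
             window_start_s = window_span[1], window_end_s = window_span[2],
             quality = if (hr > bad_above) "bad_signal" else "ok",
             stringsAsFactors = FALSE)
}

#' ECG-derived respiration (EDR) waveform over a span
#'
#' Places the instantaneous heart rate of each RR interval at the time of
#' the later peak and cubic-spline-interpolates onto a uniform grid
#' (`grid_hz`, default 4 Hz) over the span -- the standard low-rate
#' tachogram resampling used in HRV work. The resampled waveform is then
#' restricted to the respiratory band with a zero-phase second-order
#' low-pass at `lp_hz` (default 0.7 Hz, comfortably above any plausible
#' breathing rate), which removes the beat-quantization ripple that would
#' otherwise masquerade as respiratory peaks; `lp_hz = NULL` skips it.
#'
#' @param rpeaks An `rpeak_set` whose peaks cover the span (>= 4 peaks).
#' @param fs Sampling rate of the source stream in Hz.
#' @param span_s `c(start_s, end_s)` of the analysis span.
#' @param grid_hz EDR grid rate in Hz.
#' @param lp_hz Low-pass corner frequency in Hz, or `NULL`.
#' @return Numeric vector of length `round((end - start) * grid_hz)`, or
#'   `NULL` when fewer than 4 peaks are available.
#' @export
edr_waveform <- function(rpeaks, fs, span_s, grid_hz = 4, lp_hz = 0.7) {
  t_peaks <- rpeaks$peak_times_s %||% ((rpeaks$peak_indices - 1) / fs)
  if (length(t_peaks) < 4) return(NULL)
  rr <- diff(t_peaks) * 1000
  inst_hr <- 60000 / rr                    # bpm per interval
  t_hr <- t_peaks[-1]                      # at the later peak
  n <- round((span_s[2] - span_s[1]) * grid_hz)
  grid <- span_s[1] + (seq_len(n) - 1) / grid_hz
  sf <- stats::splinefun(t_hr, inst_hr, method = "fmm")
  edr <- sf(pmin(pmax(grid, min(t_hr)), max(t_hr)))  # no extrapolation:
  # grid points outside the observed beat times hold the boundary value
  if (!is.null(lp_hz) && lp_hz < grid_hz / 2) {
    bf <- signal::butter(2, lp_hz / (grid_hz / 2), type = "low")
    edr <- as.numeric(signal::filtfilt(bf, edr - mean(edr))) + mean(edr)
  }
  edr
}

#' Breathing rate from an EDR waveform
#'
#' Respiratory peaks are local maxima of the EDR separated by at least
#' `min_sep_s` seconds (which caps the measurable rate at 60 brpm) whose
#' topographic prominence is at least `prom_frac` of the waveform's
#' half peak-to-peak range (a genuine crest's prominence is the full
#' respiratory swing, while residual beat-quantization ripple riding on a
#' crest shoulder has near-zero prominence); the mean respiratory
#' frequency is `n_peaks / window_s` Hz, reported as `round(60 * f)`
#' breaths per minute.
#'
#' @param edr Numeric EDR waveform from [edr_waveform()].
#' @param window_s Span length in seconds (default 20).
#' @param grid_hz Grid rate of `edr` in Hz.
#' @param min_sep_s Minimum separation between respiratory peaks.
#' @param prom_frac Minimum prominence as a fraction of half the
#'   waveform's peak-to-peak range.
#' @param prom_abs Absolute prominence floor in bpm of instantaneous
#'   heart rate. Residual beat-quantization ripple after the band
#'   limiting stays below about `HR^2 / 12000 * 0.5` bpm (~1.2 bpm at
#'   180 bpm), while the weakest genuine respiratory crest carries at
#'   least ~2.5 bpm of prominence, so the default 1.5 separates the two.
#' @param window_span `c(start_s, end_s)` recorded on the measurement.
#' @return One-row data frame as in [compute_hr()]; 0 detected peaks give
#'   value 0 with quality `bad_signal`.
#' @export
#' @param count_span Optional `c(start_s, end_s)`: when the EDR grid
#'   extends beyond the analysis window (`grid_start_s` gives the grid
#'   origin), only maxima whose time falls in the half-open
#'   `[start, end)` are counted, so a crest on a window boundary is
#'   counted in exactly one window.
#' @param grid_start_s Time of the first EDR grid point.
compute_br <- function(edr, window_s = 20, grid_hz = 4, min_sep_s = 1,
                       prom_frac = 0.1, prom_abs = 1.5,
                       window_span = c(NA_real_, NA_real_),
                       count_span = NULL, grid_start_s = 0) {
  pk <- local_maxima(edr, min_sep = round(min_sep_s * grid_hz),
                     min_prom = max(prom_abs,
                                    prom_frac * diff(range(edr)) / 2))
  if (!is.null(count_span)) {
    t_pk <- grid_start_s + (pk - 1) / grid_hz
    pk <- pk[t_pk >= count_span[1] & t_pk < count_span[2]]
  }
  n_peaks <- length(pk)
  br_hz <- n_peaks / window_s
  data.frame(kind = "BR", value = round_int(60 * br_hz),
             window_start_s = window_span[1], window_end_s = window_span[2],
             quality = if (n_peaks == 0) "bad_signal" else "ok",
             stringsAsFactors = FALSE)
}

# Indices of local maxima (strict rise, non-strict fall) with topographic
# prominence >= min_prom, thinned so that retained peaks are >= min_sep
# samples apart, keeping higher peaks first.
local_maxima <- function(x, min_sep = 1L, min_prom = 0) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (min_prom > 0)
    cand <- cand[vapply(cand, prominence, 0, x = x) >= min_prom]
  if (!length(cand)) return(integer(0))
  ord <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord)
    if (!length(kept) || all(abs(kept - i) >= min_sep)) kept <- c(kept, i)
  sort(kept)
}

# Topographic prominence of x[i]: height above the higher of the two key
# saddles, i.e. the minima between i and the nearest strictly higher
# point (or the series end) on each side.
prominence <- function(i, x) {
  side_min <- function(idx) {
    m <- x[i]
    for (j in idx) {
      if (x[j] > x[i]) return(m)
      m <- min(m, x[j])
    }
    m
  }
  left <- if (i > 1) side_min((i - 1):1) else x[i]
  right <- if (i < length(x)) side_min((i + 1):length(x)) else x[i]
  x[i] - max(left, right)
}

#' Extract HR and BR measurements from a filtered ECG stream
#'
#' Heart rate on non-overlapping `hr_window_s` (default 4 s) windows;
#' breathing rate on `br_window_s` (default 20 s) windows with
#' `br_overlap` (default 0.8) overlap, i.e. a measurement every 4 s from
#' the previous 20 s. The BR stage reuses the R peaks detected by the HR
#' stage (a shared peak cache) rather than re-detecting. All values are
#' rounded to the nearest integer. Streams shorter than `br_window_s`
#' yield HR only.
#'
#' @param ecg A baseline-filtered [sensor_stream()] of modality `"ecg"`.
#' @param hr_window_s,br_window_s,br_overlap Window schedule.
#' @param bad_above HR quality threshold in bpm.
#' @return Data frame with columns subject, kind, window_start_s,
#'   window_end_s, value, quality.
#' @export
extract_vitals <- function(ecg, hr_window_s = 4, br_window_s = 20,
                           br_overlap = 0.8, bad_above = 190) {
  stopifnot(inherits(ecg, "sensor_stream"), ecg$modality == "ecg")
  fs <- ecg$fs
  hr_wins <- segment(ecg, hr_window_s, 0)
  rows <- list()
  peak_cache <- numeric(0)                   # refined peak times, seconds
  for (w in hr_wins) {
    rp <- detect_r_peaks(w)
    peak_cache <- c(peak_cache, rp$peak_times_s)
    m <- compute_hr(rp, window_span = window_span(w), bad_above = bad_above)
    if (!is.null(m)) rows[[length(rows) + 1L]] <- m
  }
  # a pulse straddling a window boundary is seen by both windows: merge
  # cache entries closer than a 200 ms refractory period (no true RR can
  # be shorter, since rates above 300 bpm are rejected upstream)
  peak_cache <- sort(unique(peak_cache))
  if (length(peak_cache) > 1)
    peak_cache <- peak_cache[c(TRUE, diff(peak_cache) > 0.2)]
  dur <- stream_duration(ecg)
  if (dur >= br_window_s) {
    # schedule in whole samples so window bounds are exact
    win_n <- round(br_window_s * fs)
    stride_n <- max(1L, round(win_n * (1 - br_overlap)))
    starts <- seq.int(0L, nrow(ecg$samples) - win_n, by = stride_n) / fs
    for (st in starts) {
      span <- c(st, st + br_window_s)
      # beats from a small margin outside the span support the spline at
      # the span edges; crest detection runs on a grid extended 2 s each
      # side, but only crests inside the half-open window are counted
      ext <- c(max(0, span[1] - 2), min(dur, span[2] + 2))
      in_span <- peak_cache[peak_cache >= ext[1] - 2.5 &
                              peak_cache <= ext[2] + 2.5]
      edr <- edr_waveform(list(peak_times_s = in_span), fs, ext)
      if (is.null(edr)) next                # < 4 peaks in span
      rows[[length(rows) + 1L]] <-
        compute_br(edr, window_s = br_window_s, window_span = span,
                   count_span = span, grid_start_s = ext[1])
    }
  } else {
    msg("extract_vitals: stream shorter than BR window; BR skipped")
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(kind = character(0), value = integer(0),
                      window_start_s = numeric(0), window_end_s = numeric(0),
                      quality = character(0))
  cbind(data.frame(subject = ecg$subject_id, stringsAsFactors = FALSE), out)
}
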