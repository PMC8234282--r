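# Frozen oracle coefficients for the notch design at fs = 50 Hz,
# f0 = 0.05 Hz, Q = 0.005, computed independently with
# scipy.signal.iirnotch(0.05, 0.005, fs=50).
scipy_notch <- list(
  b = c(0.57919222, -1.15836157, 0.57919222),
  a = c(1.0, -1.15836157, 0.15838444))

test_that("notch design matches the independent oracle coefficients", {
  coef <- activital:::design_notch(0.05, 0.005, 50)
  expect_equal(coef$b, scipy_notch$b, tolerance = 1e-7)
  expect_equal(coef$a, scipy_notch$a, tolerance = 1e-7)
  expect_error(activital:::design_notch(30, 0.005, 50), "sampling rate")
})

test_that("baseline filter suppresses DC and drift, passes the ECG band", {
  fs <- 50
  n <- 60 * fs
  t <- (seq_len(n) - 1) / fs
  as_ecg <- function(x) sensor_stream("s", "chest", "ecg", fs,
                                      matrix(x, ncol = 1))
  # constant input: near zero once the fast transient has passed
  y <- baseline_filter(as_ecg(rep(1, n)))$samples[, 1]
  expect_lt(max(abs(y[(2 * fs):n])), 0.1)
  # 0.2 Hz drift of amplitude A: residual drift < 0.1 A
  drift <- baseline_filter(as_ecg(sin(2 * pi * 0.2 * t)))$samples[, 1]
  expect_lt(sqrt(2 * mean(drift[(10 * fs):n]^2)), 0.1)
  # upper ECG band essentially preserved
  tone20 <- baseline_filter(as_ecg(sin(2 * pi * 20 * t)))$samples[, 1]
  expect_gt(sqrt(2 * mean(tone20[(10 * fs):n]^2)), 0.9)
  # response is monotone across the band: 10 Hz passes more than 1 Hz
  amp <- function(f) {
    out <- baseline_filter(as_ecg(sin(2 * pi * f * t)))$samples[, 1]
    sqrt(2 * mean(out[(10 * fs):n]^2))
  }
  expect_gt(amp(10), amp(1))
  expect_error(baseline_filter(as_ecg(rep(0, 5))), "short")
})

test_that("drift on a synthetic ECG is removed without losing peaks", {
  e <- gen_ecg(ecg_truth(800, fs = 50), 60, seed = 3,
               drift_amp = 1, drift_hz = 0.2)
  f <- baseline_filter(e)
  # residual slow component, via an independent low-pass oracle
  lp <- signal::butter(2, 0.5 / 25, type = "low")
  resid <- signal::filtfilt(lp, f$samples[, 1])
  expect_lt(max(abs(resid[500:2900])), 0.1)
  v <- extract_vitals(f)
  expect_equal(mean(v$value[v$kind == "HR"]), 75, tolerance = 0.02)
})

test_that("R peaks of a clean ECG are found within 2 samples of truth", {
  e <- gen_ecg(ecg_truth(1000, fs = 50), 60, seed = 1)
  f <- baseline_filter(e)
  wins <- segment(f, 4, 0)
  truth <- attr(e, "true_peaks")
  expect_equal(length(wins), 15L)
  rp1 <- detect_r_peaks(wins[[1]])
  expect_length(rp1$peak_indices, 4L)
  for (w in wins) {
    rp <- detect_r_peaks(w)
    for (p in rp$peak_indices)
      expect_lte(min(abs(truth - p)), 2)
  }
})

test_that("flat windows yield no peaks; adjacent equal maxima take the first", {
  flat <- sensor_stream("s", "chest", "ecg", 50,
                        matrix(0, 200, 1))
  rp <- detect_r_peaks(segment(flat, 4, 0)[[1]])
  expect_length(rp$peak_indices, 0L)
  expect_true(rp$flagged)

  x <- rep(0, 200)
  x[100:101] <- 1                         # one ROI, two equal maxima
  plateau <- sensor_stream("s", "chest", "ecg", 50, matrix(x, ncol = 1))
  rp2 <- detect_r_peaks(segment(plateau, 4, 0)[[1]], upsample = 1)
  expect_equal(rp2$peak_indices, 100L)
})

test_that("heart rate follows round(60000 / mean RR) with the quality rule", {
  expect_equal(compute_hr(list(rr_ms = c(1000, 1000, 1000)))$value, 60L)
  expect_equal(compute_hr(list(rr_ms = c(700, 750, 800)))$value, 80L)
  m <- compute_hr(list(rr_ms = rep(300, 5)))
  expect_equal(m$value, 200L)
  expect_equal(m$quality, "bad_signal")
  expect_equal(compute_hr(list(rr_ms = rep(315, 5)))$quality, "ok")
  expect_null(compute_hr(list(rr_ms = numeric(0))))
})

test_that("uniformly shrinking RR intervals strictly increases HR", {
  rr <- c(850, 900, 950)
  hr <- vapply(seq(1, 0.4, by = -0.05), function(k)
    compute_hr(list(rr_ms = rr * k))$value, 0L)
  expect_true(all(diff(hr) > 0))
})

test_that("EDR waveform is constant for constant RR and tracks modulation", {
  times <- seq(0.5, 19.5, by = 0.8)       # constant 800 ms RR
  edr <- edr_waveform(list(peak_times_s = times), 50, c(0, 20))
  expect_length(edr, 80L)
  expect_lt(diff(range(edr)), 1e-6)

  # RR modulated at 0.30 Hz -> EDR dominant frequency 0.30 +- 0.05
  e <- gen_ecg(ecg_truth(800, br_hz = 0.30, fs = 50), 40, seed = 6)
  tp <- (attr(e, "true_peaks") - 1) / 50
  edr2 <- edr_waveform(list(peak_times_s = tp[tp <= 20]), 50, c(0, 20))
  spec <- Mod(fft(edr2 - mean(edr2)))[2:40]
  fdom <- ((1:39) * 4 / 80)[which.max(spec)]
  expect_equal(fdom, 0.30, tolerance = 0.05)

  expect_null(edr_waveform(list(peak_times_s = c(1, 2, 3)), 50, c(0, 20)))
})

test_that("breathing rate counts respiratory peaks per window", {
  grid <- (0:79) / 4
  edr6 <- 70 + 5 * sin(2 * pi * 0.30 * grid)       # 6 crests in 20 s
  m <- compute_br(edr6, window_s = 20)
  expect_equal(m$value, 18L)                        # 0.30 Hz
  expect_equal(m$quality, "ok")

  m0 <- compute_br(rep(70, 80), window_s = 20)
  expect_equal(m0$value, 0L)
  expect_equal(m0$quality, "bad_signal")
})

test_that("vital schedule: 15 HR and 11 BR measurements from 60 s", {
  e <- gen_ecg(ecg_truth(750, br_hz = 0.25, fs = 50), 60, seed = 9)
  v <- extract_vitals(baseline_filter(e))
  expect_equal(sum(v$kind == "HR"), 15L)
  expect_equal(sum(v$kind == "BR"), 11L)
  hr <- v[v$kind == "HR", ]
  expect_equal(unique(hr$window_end_s - hr$window_start_s), 4)
  br <- v[v$kind == "BR", ]
  expect_equal(unique(br$window_end_s - br$window_start_s), 20)
  expect_equal(unique(diff(br$window_start_s)), 4)
  expect_equal(mean(hr$value), 80, tolerance = 0.02)
  expect_equal(mean(br$value), 15, tolerance = 2 / 15)

  short <- gen_ecg(ecg_truth(750, fs = 50), 12, seed = 2)
  vs <- suppressMessages(extract_vitals(baseline_filter(short)))
  expect_equal(sum(vs$kind == "BR"), 0L)
  expect_equal(sum(vs$kind == "HR"), 3L)
})

test_that("HR and BR recover generator ground truth on random fixtures", {
  set.seed(31)
  for (i in 1:10) {
    par <- draw_hr_br()
    e <- gen_ecg(ecg_truth(60000 / par["hr"], br_hz = par["br"], fs = 50),
                 60, seed = 1000 + i)
    v <- extract_vitals(baseline_filter(e))
    expect_lte(abs(mean(v$value[v$kind == "HR"]) - par["hr"]), 2)
    expect_lte(abs(mean(v$value[v$kind == "BR"]) - round(60 * par["br"])),
               2)
  }
})
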