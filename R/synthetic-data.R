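# Synthetic accelerometer / ECG generator with known ground truth.

#' Activity profile for the synthetic generator
#'
#' An activity profile describes how one activity of daily living appears
#' on a body-worn triaxial accelerometer: postures are a constant gravity
#' component plus sensor noise, locomotion adds a periodic oscillation
#' along the gravity axis.
#'
#' @param label Activity name, one of [activity_labels()].
#' @param met Metabolic equivalent of task (MET) score, > 0.
#' @param gravity_axis Unit 3-vector giving the orientation of gravity in
#'   the sensor frame (normalized internally).
#' @param osc_freq Oscillation frequency in Hz; must be 0 for the three
#'   posture activities (standing, sitting, lying).
#' @param osc_amp Oscillation amplitude in m/s^2, >= 0.
#' @param noise_sd Gaussian sensor-noise standard deviation in m/s^2, >= 0.
#' @return An object of class `activity_profile`.
#' @seealso [default_profiles()], [gen_accel()]
#' @export
activity_profile <- function(label, met, gravity_axis = c(0, 0, 1),
                             osc_freq = 0, osc_amp = 0, noise_sd = 0.1) {
  label <- match.arg(label, activity_labels())
  stopifnot(is.numeric(met), length(met) == 1L)
  if (met <= 0) stop("`met` must be > 0", call. = FALSE)
  if (length(gravity_axis) != 3L || all(gravity_axis == 0))
    stop("`gravity_axis` must be a non-zero 3-vector", call. = FALSE)
  if (osc_amp < 0 || noise_sd < 0)
    stop("`osc_amp` and `noise_sd` must be >= 0", call. = FALSE)
  posture <- label %in% posture_labels()
  if (posture && osc_freq != 0)
    stop("posture profiles must have osc_freq = 0", call. = FALSE)
  if (!posture && osc_freq <= 0)
    stop("locomotion profiles must have osc_freq > 0", call. = FALSE)
  structure(list(label = label, met = met,
                 gravity_axis = gravity_axis / sqrt(sum(gravity_axis^2)),
                 osc_freq = osc_freq, osc_amp = osc_amp,
                 noise_sd = noise_sd),
            class = "activity_profile")
}

#' Canonical activity labels
#'
#' The eight activities of daily living recognized by the package, in the
#' fixed integer-coding order used in sensor logs (label codes 1..8).
#' @return Character vector of length 8.
#' @export
activity_labels <- function() {
  c("standing", "sitting", "lying", "walking", "climbing_stairs",
    "cycling", "jogging", "running")
}

posture_labels <- function() c("standing", "sitting", "lying")

#' MET scores for the default activities
#'
#' MET (metabolic equivalent of task) scores per activity, from the
#' Compendium of Physical Activities: postures 1.0-1.3, walking 3.5,
#' climbing stairs and cycling 4.0, jogging 7.0, running 8.0.
#' @return Named numeric vector over [activity_labels()].
#' @export
met_table <- function() {
  c(standing = 1.3, sitting = 1.3, lying = 1.0, walking = 3.5,
    climbing_stairs = 4.0, cycling = 4.0, jogging = 7.0, running = 8.0)
}

#' Default activity profiles
#'
#' One profile per activity. Postures differ by gravity orientation in the
#' sensor frame; locomotion activities differ by oscillation frequency
#' (ordered walking < stairs < cycling < jogging < running) and amplitude.
#' The exact frequencies/amplitudes are generator configuration, not claims
#' about human gait.
#'
#' @param noise_sd Sensor-noise SD applied to every profile (m/s^2).
#' @return Named list of [activity_profile()] objects.
#' @export
default_profiles <- function(noise_sd = 0.25) {
  met <- met_table()
  lst <- list(
    activity_profile("standing", met[["standing"]], c(0, 0, 1),
                     noise_sd = noise_sd),
    activity_profile("sitting", met[["sitting"]], c(0.5, 0, 0.866),
                     noise_sd = noise_sd),
    activity_profile("lying", met[["lying"]], c(1, 0, 0),
                     noise_sd = noise_sd),
    activity_profile("walking", met[["walking"]], c(0, 0, 1),
                     osc_freq = 1.6, osc_amp = 1.5, noise_sd = noise_sd),
    activity_profile("climbing_stairs", met[["climbing_stairs"]],
                     c(0.2, 0, 0.98),
                     osc_freq = 2.0, osc_amp = 2.2, noise_sd = noise_sd),
    activity_profile("cycling", met[["cycling"]], c(0.7, 0, 0.714),
                     osc_freq = 2.4, osc_amp = 3.0, noise_sd = noise_sd),
    activity_profile("jogging", met[["jogging"]], c(0, 0.2, 0.98),
                     osc_freq = 2.8, osc_amp = 4.5, noise_sd = noise_sd),
    activity_profile("running", met[["running"]], c(0, 0.35, 0.937),
                     osc_freq = 3.2, osc_amp = 6.0, noise_sd = noise_sd)
  )
  names(lst) <- vapply(lst, `[[`, "", "label")
  lst
}

#' Generate a synthetic triaxial accelerometer stream
#'
#' Postures yield a constant gravity component (9.80665 m/s^2 along the
#' profile's gravity axis) plus Gaussian noise; locomotion profiles add a
#' sinusoid at `osc_freq` with amplitude `osc_amp` along the gravity axis
#' plus a half-amplitude quadrature component on a perpendicular axis.
#' Identical `(arguments, seed)` give bitwise-identical streams.
#'
#' @param profile An [activity_profile()].
#' @param duration_s Duration in seconds, > 0.
#' @param fs Sampling rate in Hz, > 0 (default 50).
#' @param seed Integer seed for the private RNG.
#' @param subject_id,placement Stream metadata.
#' @return A [sensor_stream()] of modality `"accel3d"` with per-sample
#'   labels set to the profile's activity code.
#' @export
gen_accel <- function(profile, duration_s, fs = 50, seed = 1L,
                      subject_id = "sim", placement = "chest") {
  stopifnot(inherits(profile, "activity_profile"))
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("`duration_s` must be > 0", call. = FALSE)
  if (!is.numeric(fs) || fs <= 0)
    stop("`fs` must be > 0", call. = FALSE)
  n <- round(duration_s * fs)
  g <- profile$gravity_axis
  t <- (seq_len(n) - 1) / fs
  base <- matrix(rep(9.80665 * g, each = n), ncol = 3)
  samples <- with_seed(seed, {
    out <- base
    if (profile$osc_freq > 0) {
      phase <- runif(1, 0, 2 * pi)
      osc <- profile$osc_amp * sin(2 * pi * profile$osc_freq * t + phase)
      # quadrature component on an axis perpendicular to gravity
      perp <- perp_axis(g)
      osc2 <- 0.5 * profile$osc_amp *
        cos(2 * pi * profile$osc_freq * t + phase)
      out <- out + outer(osc, g) + outer(osc2, perp)
    }
    if (profile$noise_sd > 0)
      out <- out + matrix(rnorm(3 * n, sd = profile$noise_sd), ncol = 3)
    out
  })
  code <- match(profile$label, activity_labels())
  sensor_stream(subject_id = subject_id, placement = placement,
                modality = "accel3d", fs = fs, samples = samples,
                labels = rep.int(code, n))
}

# A unit vector perpendicular to g (deterministic choice).
perp_axis <- function(g) {
  ref <- if (abs(g[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- ref - sum(ref * g) * g
  v / sqrt(sum(v^2))
}

#' ECG ground truth for the synthetic generator
#'
#' @param rr_ms Sequence of RR intervals in ms (all > 0; recycled to cover
#'   the requested duration). Intervals implying a heart rate above 300 bpm
#'   are rejected.
#' @param br_hz Respiratory frequency in Hz, in `[0, 1)`; 0 disables
#'   respiratory modulation.
#' @param fs Sampling rate in Hz, > 0.
#' @return An object of class `ecg_truth`.
#' @export
ecg_truth <- function(rr_ms, br_hz = 0, fs = 50) {
  if (!length(rr_ms) || any(!is.finite(rr_ms)) || any(rr_ms <= 0))
    stop("`rr_ms` must be positive", call. = FALSE)
  if (any(rr_ms < 200))
    stop("rr_ms below 200 ms implies HR > 300 bpm; rejected", call. = FALSE)
  if (br_hz < 0 || br_hz >= 1)
    stop("`br_hz` must be in [0, 1)", call. = FALSE)
  if (fs <= 0) stop("`fs` must be > 0", call. = FALSE)
  structure(list(rr_ms = as.numeric(rr_ms), br_hz = br_hz, fs = fs),
            class = "ecg_truth")
}

#' Generate a synthetic single-lead ECG stream
#'
#' Builds an R-peak train from the ground-truth RR sequence and renders one
#' narrow Gaussian pulse per beat (SD `pulse_sd_s`, i.e. width of a few
#' tens of ms -- enough for a rolling-mean detector; no P/T morphology).
#' When `br_hz > 0`, respiration modulates both the instantaneous RR
#' interval (respiratory sinus arrhythmia, depth `rsa_depth`) and the peak
#' amplitude (depth `pav_depth`) -- the two classic EDR mechanisms; only
#' the RR route is consumed downstream.
#'
#' @param truth An [ecg_truth()].
#' @param duration_s Duration in seconds, > 0.
#' @param seed Integer seed (used for noise and the respiratory phase).
#' @param rsa_depth,pav_depth Relative modulation depths.
#' @param noise_sd Additive Gaussian noise SD (signal units; peak height 1).
#' @param drift_amp,drift_hz Optional sinusoidal baseline drift.
#' @param pulse_sd_s Gaussian pulse SD in seconds.
#' @param subject_id Stream metadata.
#' @return A [sensor_stream()] of modality `"ecg"` with attributes
#'   `true_peaks` (1-based sample indices of the rendered R peaks) and
#'   `true_rr_ms` (the realized RR intervals in ms).
#' @export
gen_ecg <- function(truth, duration_s, seed = 1L, rsa_depth = 0.04,
                    pav_depth = 0.2, noise_sd = 0, drift_amp = 0,
                    drift_hz = 0.2, pulse_sd_s = 0.012,
                    subject_id = "sim") {
  stopifnot(inherits(truth, "ecg_truth"))
  if (duration_s <= 0) stop("`duration_s` must be > 0", call. = FALSE)
  fs <- truth$fs
  n <- round(duration_s * fs)
  with_seed(seed, {
    resp_phase <- if (truth$br_hz > 0) runif(1, 0, 2 * pi) else 0
    # peak times: t_k = t_{k-1} + rr_k (modulated); the train starts half
    # an interval in, so a window of w seconds at constant rate r holds
    # round(w / r) beats
    times <- numeric(0)
    t_cur <- 0
    k <- 0
    repeat {
      k <- k + 1
      rr <- truth$rr_ms[((k - 1) %% length(truth$rr_ms)) + 1] / 1000
      if (truth$br_hz > 0)
        rr <- rr * (1 + rsa_depth * sin(2 * pi * truth$br_hz * t_cur +
                                          resp_phase))
      if (k == 1) rr <- rr / 2
      t_cur <- t_cur + rr
      if (t_cur > duration_s + 1e-9) break
      times <- c(times, t_cur)
    }
    amps <- rep(1, length(times))
    if (truth$br_hz > 0)
      amps <- 1 + pav_depth * sin(2 * pi * truth$br_hz * times + resp_phase)
    tgrid <- (seq_len(n) - 1) / fs
    sig <- numeric(n)
    halfw <- ceiling(4 * pulse_sd_s * fs)
    for (i in seq_along(times)) {
      c_idx <- round(times[i] * fs) + 1
      idx <- max(1, c_idx - halfw):min(n, c_idx + halfw)
      sig[idx] <- sig[idx] +
        amps[i] * exp(-0.5 * ((tgrid[idx] - times[i]) / pulse_sd_s)^2)
    }
    if (drift_amp > 0)
      sig <- sig + drift_amp * sin(2 * pi * drift_hz * tgrid)
    if (noise_sd > 0) sig <- sig + rnorm(n, sd = noise_sd)
    stream <- sensor_stream(subject_id = subject_id, placement = "chest",
                            modality = "ecg", fs = fs,
                            samples = matrix(sig, ncol = 1))
    attr(stream, "true_peaks") <- pmin(n, round(times * fs) + 1)
    attr(stream, "true_rr_ms") <- diff(times) * 1000
    stream
  })
}

#' Generate a labeled multi-sensor cohort
#'
#' Simulates `n_subjects` subjects wearing accelerometers on the chest,
#' wrist and ankle. Each subject receives subject-specific random offsets
#' drawn once (a small gravity-axis tilt and an amplitude scale factor)
#' applied to all placements; each placement applies a fixed frame rotation
#' and an oscillation-amplitude multiplier (wrist and ankle move more than
#' the chest during locomotion). For every profile, `duration_s` seconds
#' are generated per placement and concatenated in profile order with
#' per-sample activity labels.
#'
#' Optionally a chest ECG stream is generated per activity with an
#' MET-dependent mean heart rate (`hr = 55 + 12.5 * met` bpm, per-subject
#' offset SD 4 bpm) and breathing rate (`br = (9 + 2.6 * met) / 60` Hz),
#' so that downstream vital-sign zones are activity-conditional.
#'
#' @param n_subjects Number of simulated subjects, >= 2.
#' @param profiles Non-empty list of [activity_profile()]s.
#' @param seed Integer seed.
#' @param duration_s Seconds generated per (subject, activity).
#' @param fs Sampling rate in Hz.
#' @param include_ecg If `TRUE`, add one ECG stream per subject covering
#'   the same activity schedule.
#' @return An object of class `cohort`: a list of subjects, each a list
#'   with `subject_id`, `streams` (named by placement) and, when requested,
#'   `ecg` plus `vitals_truth` (a data frame of the per-activity true HR
#'   and BR).
#' @export
gen_cohort <- function(n_subjects, profiles = default_profiles(), seed = 1L,
                       duration_s = 60, fs = 50, include_ecg = FALSE) {
  if (!is.numeric(n_subjects) || n_subjects < 2)
    stop("`n_subjects` must be >= 2", call. = FALSE)
  if (!length(profiles))
    stop("`profiles` must be a non-empty list", call. = FALSE)
  placements <- c("chest", "wrist", "ankle")
  amp_mult <- c(chest = 1.0, wrist = 1.35, ankle = 1.7)
  met <- met_table()
  subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("S%02d", s)
    off <- with_seed(sub_seed(seed, s * 13L), {
      list(tilt_axis = {
             v <- rnorm(3); v / sqrt(sum(v^2))
           },
           tilt_angle = rnorm(1, sd = 4 * pi / 180),
           amp_scale = exp(rnorm(1, sd = 0.05)),
           hr_offset = rnorm(1, sd = 4),
           br_offset = rnorm(1, sd = 0.6))
    })
    streams <- list()
    for (p in placements) {
      segs <- vector("list", length(profiles))
      for (a in seq_along(profiles)) {
        pr <- profiles[[a]]
        pr2 <- pr
        pr2$gravity_axis <- rotate_axis(
          placement_frame(pr$gravity_axis, p), off$tilt_axis, off$tilt_angle)
        pr2$osc_amp <- pr$osc_amp * amp_mult[[p]] * off$amp_scale
        segs[[a]] <- gen_accel(
          pr2, duration_s = duration_s, fs = fs,
          seed = sub_seed(seed, s * 1000L + a * 10L + match(p, placements)),
          subject_id = sid, placement = p)
      }
      streams[[p]] <- concat_streams(segs)
    }
    subj <- list(subject_id = sid, streams = streams)
    if (include_ecg) {
      esegs <- vector("list", length(profiles))
      vt <- data.frame(activity = character(0), hr_bpm = numeric(0),
                       br_hz = numeric(0))
      for (a in seq_along(profiles)) {
        pr <- profiles[[a]]
        hr <- max(45, 55 + 12.5 * pr$met + off$hr_offset)
        br <- min(0.75, max(0.12, (9 + 2.6 * pr$met + off$br_offset) / 60))
        tr <- ecg_truth(rr_ms = 60000 / hr, br_hz = br, fs = fs)
        esegs[[a]] <- gen_ecg(tr, duration_s = duration_s,
                              seed = sub_seed(seed, s * 5000L + a),
                              subject_id = sid)
        esegs[[a]]$labels <- rep.int(match(pr$label, activity_labels()),
                                     nrow(esegs[[a]]$samples))
        vt <- rbind(vt, data.frame(activity = pr$label, hr_bpm = hr,
                                   br_hz = br))
      }
      subj$ecg <- concat_streams(esegs)
      subj$vitals_truth <- vt
    }
    subjects[[s]] <- subj
  }
  structure(list(subjects = subjects, fs = fs, duration_s = duration_s,
                 profiles = profiles, seed = seed),
            class = "cohort")
}

# Fixed per-placement frame: cyclic axis permutations (proper rotations).
placement_frame <- function(g, placement) {
  switch(placement,
         chest = g,
         wrist = c(g[3], g[1], g[2]),
         ankle = c(g[2], g[3], g[1]),
         stop("unknown placement: ", placement, call. = FALSE))
}

# Rodrigues rotation of unit vector v about unit axis k by angle theta.
rotate_axis <- function(v, k, theta) {
  v * cos(theta) + cross3(k, v) * sin(theta) +
    k * sum(k * v) * (1 - cos(theta))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

concat_streams <- function(streams) {
  out <- streams[[1]]
  out$samples <- do.call(rbind, lapply(streams, `[[`, "samples"))
  labs <- lapply(streams, `[[`, "labels")
  out$labels <- if (all(!vapply(labs, is.null, TRUE)))
    do.call(c, labs) else NULL
  tp <- lapply(streams, attr, "true_peaks")
  if (all(!vapply(tp, is.null, TRUE))) {
    offs <- cumsum(c(0, head(vapply(streams, function(s) nrow(s$samples),
                                    0), -1)))
    attr(out, "true_peaks") <- unlist(Map(`+`, tp, offs))
  }
  out
}
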