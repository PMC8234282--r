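# Shared fixture builders. Everything is generated in code at test time;
# heavier objects are built once per session and memoized.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- builder()
  fixture_env[[key]]
}

# Small labeled cohort for classifier tests: 3 subjects, all 8 activities.
small_cohort <- function() {
  memo("small_cohort", function()
    gen_cohort(3, default_profiles(), seed = 11, duration_s = 12))
}

small_har_data <- function() {
  memo("small_har_data", function() build_har_dataset(small_cohort()))
}

# A clean constant-rate ECG stream plus its filtered version.
clean_ecg <- function(rr_ms = 1000, br_hz = 0, duration_s = 60, seed = 1) {
  gen_ecg(ecg_truth(rr_ms, br_hz = br_hz, fs = 50), duration_s,
          seed = seed)
}

# Draw a (heart rate, breathing rate) pair inside the EDR validity
# envelope: breathing at most a third of the beat rate (see the methods
# vignette).
draw_hr_br <- function() {
  hr <- runif(1, 50, 180)
  br <- runif(1, 0.1, min(0.5, hr / 180))
  c(hr = hr, br = br)
}

# Independent brute-force re-implementation of the five-bin zoning
# procedure (explicit loops over samples and edges), used as the oracle
# against extract_zones().
oracle_zones <- function(samples) {
  lo <- min(samples); hi <- max(samples)
  stopifnot(hi > lo)
  edges <- numeric(6)
  for (j in 1:6) edges[j] <- lo + (j - 1) * ((hi - lo) / 5)
  counts <- rep(0L, 5)
  for (s in samples) {
    b <- 5L
    for (j in 1:5) {
      if (s >= edges[j] && s < edges[j + 1]) { b <- j; break }
    }
    counts[b] <- counts[b] + 1L
  }
  green <- rep(FALSE, 5)
  for (j in 1:5) if (counts[j] > length(samples) / 5) green[j] <- TRUE
  if (!any(green)) {
    mx <- max(counts)
    for (j in 1:5) if (counts[j] == mx) green[j] <- TRUE
  }
  for (j in 2:4) if (!green[j] && green[j - 1] && green[j + 1])
    green[j] <- TRUE
  # keep the widest contiguous green run (first on ties)
  best_len <- 0L; best_start <- 0L
  j <- 1L
  while (j <= 5L) {
    if (green[j]) {
      k <- j
      while (k < 5L && green[k + 1L]) k <- k + 1L
      if (k - j + 1L > best_len) { best_len <- k - j + 1L; best_start <- j }
      j <- k + 1L
    } else j <- j + 1L
  }
  green <- rep(FALSE, 5)
  green[best_start:(best_start + best_len - 1L)] <- TRUE
  gidx <- which(green)
  list(green_mark = green, counts = counts,
       green = c(as.integer(round(edges[min(gidx)])),
                 as.integer(round(edges[max(gidx) + 1]))),
       yellow_low_present = min(gidx) > 1,
       yellow_high_present = max(gidx) < 5)
}

# Severity rank of a decide_alert() outcome (NULL = no message).
severity_rank <- function(decision) {
  if (is.null(decision)) return(1L)
  match(decision$outcome,
        c("none", "user_warning", "user_alert", "caretaker_alert",
          "emergency_alert"))
}
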