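# Accelerometer feature extraction: the six feature-vector variants over
# 2 s windows, and importance-based backward feature elimination.

#' Per-sample signal magnitude of a triaxial window
#'
#' Euclidean norm `sqrt(x^2 + y^2 + z^2)` per sample.
#'
#' @param win A triaxial `window` (from [segment()]) or an n-by-3 matrix.
#' @return Numeric vector of per-sample magnitudes.
#' @export
signal_magnitude <- function(win) {
  m <- if (inherits(win, "window")) window_data(win) else as.matrix(win)
  if (ncol(m) != 3) stop("signal_magnitude needs 3-component samples",
                         call. = FALSE)
  sqrt(rowSums(m^2))
}

# The twelve per-signal statistics, in fixed documented order. Choices the
# method leaves open: mad is the unscaled median absolute deviation about
# the median; iqr uses linearly interpolated quantiles; zc counts strict
# sign changes of the mean-centered signal; skewness is adjusted
# Fisher-Pearson and kurtosis excess Fisher (both 0 for a constant
# signal); energy is the mean of squares (so energy = rms^2).
stat_names12 <- c("mean", "std", "min", "max", "mad", "iqr", "var", "zc",
                  "rms", "skew", "kurt", "energy")

stats12 <- function(x) {
  s <- sd(x)
  centered <- x - mean(x)
  zc <- sum(centered[-1] * centered[-length(centered)] < 0)
  out <- c(mean(x), s, min(x), max(x),
           stats::mad(x, constant = 1), IQR(x), var(x), zc,
           sqrt(mean(x^2)),
           if (s > 0) e1071::skewness(x, type = 2) else 0,
           if (s > 0) e1071::kurtosis(x, type = 2) else 0,
           mean(x^2))
  names(out) <- stat_names12
  out
}

# Signal magnitude area: mean over the window of the summed axis
# magnitudes. `absolute = FALSE` gives the literal signed sum instead.
sma_feature <- function(m, absolute = TRUE) {
  v <- if (absolute) abs(m) else m
  sum(v) / nrow(as.matrix(v))
}

safe_cor <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(0)   # posture windows can be constant
  stats::cor(a, b)
}

#' Time-domain feature vector
#'
#' For a raw triaxial window: the 12 per-axis statistics (mean, std, min,
#' max, mad, iqr, var, zc, rms, skewness, kurtosis, energy) for each axis
#' (36), plus the signal magnitude area (1) and the three pairwise axis
#' correlations (3) -- 40 attributes. For a magnitude signal: the 12
#' statistics plus sma -- 13 attributes. Correlations with a zero-variance
#' axis are defined as 0.
#'
#' @param win A `window`, an n-by-3 matrix (raw), or a numeric vector
#'   (magnitude signal).
#' @param sma_absolute Use absolute values in the sma sum (the standard
#'   signal magnitude area); `FALSE` gives the literal signed sum.
#' @return Named numeric vector in a fixed order.
#' @export
time_features <- function(win, sma_absolute = TRUE) {
  m <- if (inherits(win, "window")) window_data(win) else win
  if (is.matrix(m) && ncol(m) == 3) {
    if (nrow(m) < 4) stop("window too short (< 4 samples)", call. = FALSE)
    per_axis <- c(vapply(1:3, function(j) stats12(m[, j]), numeric(12)))
    names(per_axis) <- as.vector(outer(stat_names12, c("x", "y", "z"),
                                       function(s, a) paste(a, s,
                                                            sep = "_")))
    c(per_axis,
      sma = sma_feature(m, sma_absolute),
      corr_xy = safe_cor(m[, 1], m[, 2]),
      corr_xz = safe_cor(m[, 1], m[, 3]),
      corr_yz = safe_cor(m[, 2], m[, 3]))
  } else {
    x <- as.numeric(m)
    if (length(x) < 4) stop("window too short (< 4 samples)", call. = FALSE)
    out <- c(stats12(x), sma_feature(matrix(x, ncol = 1), sma_absolute))
    names(out) <- c(paste("mag", stat_names12, sep = "_"), "mag_sma")
    out
  }
}

# One-sided FFT magnitude spectrum with the DC bin removed.
magnitude_spectrum <- function(x) {
  n <- length(x)
  Mod(stats::fft(x))[2:(floor(n / 2) + 1)]
}

# Spectral entropy (natural log) of the power-normalized spectrum, plus the
# 1-based index of the maximum component (lowest index on ties). Spectra
# that are zero up to floating-point fuzz (a constant signal once DC is
# removed) yield entropy 0 and index 1.
spectrum_extras <- function(s, scale = max(s)) {
  s[s <= 1e-10 * scale] <- 0
  p <- s^2
  tot <- sum(p)
  se <- if (tot > 0) {
    p <- p / tot
    p <- p[p > 0]
    -sum(p * log(p))
  } else 0
  c(se = se, im = which.max(s))
}

#' Frequency-domain feature vector
#'
#' Applies the 12 statistics of [time_features()] to the one-sided FFT
#' magnitude spectrum (DC removed) of each axis, and adds the spectral
#' entropy (`se`) of the power-normalized spectrum and the index of the
#' maximum frequency component (`im`, lowest index on ties): 14 per axis
#' for raw input (42 total), 14 for a magnitude signal.
#'
#' @inheritParams time_features
#' @return Named numeric vector (names prefixed `x_f_` / `mag_f_` etc.).
#' @export
freq_features <- function(win) {
  m <- if (inherits(win, "window")) window_data(win) else win
  per_signal <- function(x, prefix) {
    x <- as.numeric(x)
    s <- magnitude_spectrum(x)
    out <- c(stats12(s), spectrum_extras(s, scale = sqrt(sum(x^2))))
    names(out) <- paste(prefix, c(stat_names12, "se", "im"), sep = "_")
    out
  }
  if (is.matrix(m) && ncol(m) == 3) {
    c(per_signal(m[, 1], "x_f"), per_signal(m[, 2], "y_f"),
      per_signal(m[, 3], "z_f"))
  } else {
    per_signal(as.numeric(m), "mag_f")
  }
}

#' Build one of the six feature-vector variants
#'
#' Variants: `xyz_t` (40 time-domain attributes from the raw triaxial
#' signal), `xyz_f` (42 frequency-domain), `xyz_tf` (concatenation),
#' `mag_t` (13 from the magnitude signal), `mag_f` (14), `mag_tf`
#' (concatenation).
#'
#' @param win A triaxial `window` or n-by-3 matrix.
#' @param variant One of `"xyz_t"`, `"xyz_f"`, `"xyz_tf"`, `"mag_t"`,
#'   `"mag_f"`, `"mag_tf"`.
#' @param sma_absolute Passed to [time_features()].
#' @return Named numeric vector.
#' @export
build_vector <- function(win, variant = c("xyz_t", "xyz_f", "xyz_tf",
                                          "mag_t", "mag_f", "mag_tf"),
                         sma_absolute = TRUE) {
  variant <- match.arg(variant)
  m <- if (inherits(win, "window")) window_data(win) else as.matrix(win)
  mag <- signal_magnitude(m)
  switch(variant,
         xyz_t = time_features(m, sma_absolute),
         xyz_f = freq_features(m),
         xyz_tf = c(time_features(m, sma_absolute), freq_features(m)),
         mag_t = time_features(mag, sma_absolute),
         mag_f = freq_features(mag),
         mag_tf = c(time_features(mag, sma_absolute), freq_features(mag)))
}

#' Importance-based backward feature elimination
#'
#' Trains a random forest, scores features by impurity importance, removes
#' the least important *unit* and repeats, recording cross-validated
#' accuracy at each step. On raw triaxial vectors a unit is the per-axis
#' triple of one statistic (`x_*`, `y_*`, `z_*` -- scored by the average
#' importance of the triple and removed together); singleton features
#' (sma, correlations) are their own units. Elimination stops before the
#' set would drop below 2 features.
#'
#' @param x Feature matrix or data frame with named columns.
#' @param y Class labels (factor or coercible).
#' @param num_trees Trees per forest.
#' @param k Cross-validation folds per step.
#' @param seed Integer seed.
#' @return Data frame trace with columns `n_features`, `cv_accuracy`,
#'   `features` (comma-joined); attribute `best` holds the selected subset
#'   (highest accuracy, ties to the smaller subset).
#' @export
backward_eliminate <- function(x, y, num_trees = 100, k = 3, seed = 1L) {
  x <- as.data.frame(x)
  y <- factor(y)
  units <- feature_units(colnames(x))
  trace <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    cols <- unlist(units, use.names = FALSE)
    acc <- cv_accuracy(x[, cols, drop = FALSE], y, k = k,
                       num_trees = num_trees,
                       seed = sub_seed(seed, step))
    trace[[step]] <- data.frame(n_features = length(cols),
                                cv_accuracy = acc,
                                features = paste(cols, collapse = ","),
                                stringsAsFactors = FALSE)
    if (length(units) <= 1L) break
    fit <- with_seed(sub_seed(seed, 10000L + step),
      ranger::ranger(x = x[, cols, drop = FALSE], y = y,
                     num.trees = num_trees, importance = "impurity",
                     num.threads = 1))
    imp <- fit$variable.importance
    unit_imp <- vapply(units, function(u) mean(imp[u]), 0)
    drop_unit <- which.min(unit_imp)
    remaining <- unlist(units[-drop_unit], use.names = FALSE)
    if (length(remaining) < 2L) break
    units <- units[-drop_unit]
  }
  out <- do.call(rbind, trace)
  best_acc <- max(out$cv_accuracy)
  cand <- out[out$cv_accuracy == best_acc, ]
  best <- cand[which.min(cand$n_features), "features"]
  attr(out, "best") <- strsplit(best, ",")[[1]]
  out
}

# Group feature names into elimination units: x_/y_/z_ triples of the same
# statistic when all three axes are present, otherwise singletons.
feature_units <- function(nms) {
  m <- regmatches(nms, regexec("^([xyz])_(.+)$", nms))
  stat <- vapply(m, function(g) if (length(g) == 3) g[3] else NA_character_,
                 "")
  units <- list()
  for (s in unique(stat[!is.na(stat)])) {
    grp <- nms[!is.na(stat) & stat == s]
    if (length(grp) == 3) units[[paste0("triple_", s)]] <- grp
    else for (g in grp) units[[g]] <- g
  }
  for (g in nms[is.na(stat)]) units[[g]] <- g
  units
}

# Stratified k-fold cross-validated accuracy of a random forest.
cv_accuracy <- function(x, y, k = 3, num_trees = 100, seed = 1L) {
  folds <- with_seed(seed, stratified_folds(y, k))
  correct <- 0L
  for (f in seq_len(k)) {
    test <- folds == f
    if (!any(test) || length(unique(y[!test])) < 2) next
    fit <- with_seed(sub_seed(seed, f),
      ranger::ranger(x = x[!test, , drop = FALSE], y = y[!test],
                     num.trees = num_trees, num.threads = 1))
    pred <- predict(fit, data = x[test, , drop = FALSE])$predictions
    correct <- correct + sum(pred == y[test])
  }
  correct / length(y)
}

# Random fold assignment stratified by class (call inside with_seed()).
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}
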