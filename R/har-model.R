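# Two-layer intensity-gated fusion classifier for human activity
# recognition, plus k-fold / leave-one-subject-out evaluation.

#' Intensity class of an activity
#'
#' Activities are banded by MET score: light (< 3), moderate (3-6),
#' vigorous (> 6).
#'
#' @param label An activity label (see [activity_labels()]), or a MET
#'   score via `intensity_of_met()`.
#' @return `"light"`, `"moderate"` or `"vigorous"`.
#' @export
met_intensity <- function(label) {
  met <- met_table()
  if (!all(label %in% names(met)))
    stop("unknown activity label: ",
         paste(setdiff(label, names(met)), collapse = ", "), call. = FALSE)
  intensity_of_met(met[label])
}

#' @rdname met_intensity
#' @param met MET score(s).
#' @export
intensity_of_met <- function(met) {
  unname(ifelse(met < 3, "light", ifelse(met <= 6, "moderate", "vigorous")))
}

intensity_levels <- function() c("light", "moderate", "vigorous")

#' Sensor pair fused for a given intensity
#'
#' The fusion rules: light intensity fuses chest + wrist, moderate fuses
#' wrist + ankle, vigorous fuses chest + ankle -- the pairs that best
#' separate the activities within each intensity band.
#'
#' @param intensity `"light"`, `"moderate"` or `"vigorous"`.
#' @return Character vector of two placements.
#' @export
select_sensor_pair <- function(intensity) {
  switch(match.arg(intensity, intensity_levels()),
         light = c("chest", "wrist"),
         moderate = c("wrist", "ankle"),
         vigorous = c("chest", "ankle"))
}

#' Layer-1 intensity features
#'
#' The four magnitude-signal statistics the intensity gate consumes:
#' mad, var, rms and iqr, computed on a 1 s magnitude window.
#'
#' @param mag Numeric magnitude signal (one 1 s window).
#' @return Named numeric vector of length 4.
#' @export
intensity_features <- function(mag) {
  c(mad = stats::mad(mag, constant = 1), var = var(mag),
    rms = sqrt(mean(mag^2)), iqr = IQR(mag))
}

#' Layer-2 fusion features for one sensor
#'
#' Ten attributes per sensor: mean, std and rms per axis (9) plus the
#' signal magnitude area (1). Two sensors are fused by concatenation
#' (early / feature-level fusion) into a 20-attribute vector.
#'
#' @param m n-by-3 matrix of one 2 s triaxial window.
#' @return Named numeric vector of length 10.
#' @export
fusion_features <- function(m) {
  m <- as.matrix(m)
  out <- c(colMeans(m), apply(m, 2, sd),
           sqrt(colMeans(m^2)), sma_feature(m))
  names(out) <- c(paste0(c("x", "y", "z"), "_mean"),
                  paste0(c("x", "y", "z"), "_std"),
                  paste0(c("x", "y", "z"), "_rms"), "sma")
  out
}

#' Window-level dataset for the two-layer classifier
#'
#' Segments every placement of every subject into synchronized
#' `window_s`-second windows and precomputes, per window: the 10 fusion
#' features for each placement, and the 4 intensity features for each of
#' the two half-windows of each placement's magnitude signal (so any
#' placement can serve as the gating sensor).
#'
#' @param cohort A `cohort` from [gen_cohort()], or a list of subjects
#'   each with `subject_id` and `streams` (named by placement).
#' @param window_s Window length in seconds (default 2).
#' @return A `har_data` list: `meta` (subject, label, intensity per
#'   window), `fusion` (per placement, n-by-10 matrix), `gate` (per
#'   placement, list of two n-by-4 matrices for the two halves).
#' @export
build_har_dataset <- function(cohort, window_s = 2) {
  subjects <- if (inherits(cohort, "cohort")) cohort$subjects else cohort
  placements <- names(subjects[[1]]$streams)
  meta <- list(); fusion <- list(); gate <- list()
  for (p in placements) { fusion[[p]] <- list(); gate[[p]] <- list() }
  for (subj in subjects) {
    wins <- lapply(subj$streams, segment, window_s = window_s,
                   overlap_frac = 0)
    n_win <- min(vapply(wins, length, 0L))
    for (i in seq_len(n_win)) {
      lab_code <- wins[[placements[1]]][[i]]$label
      lab <- activity_labels()[lab_code]
      meta[[length(meta) + 1L]] <-
        data.frame(subject = subj$subject_id, label = lab,
                   intensity = met_intensity(lab), stringsAsFactors = FALSE)
      for (p in placements) {
        m <- window_data(wins[[p]][[i]])
        fusion[[p]][[length(fusion[[p]]) + 1L]] <- fusion_features(m)
        mag <- sqrt(rowSums(m^2))
        half <- floor(length(mag) / 2)
        gate[[p]][[length(gate[[p]]) + 1L]] <-
          c(intensity_features(mag[1:half]),
            intensity_features(mag[(half + 1):(2 * half)]))
      }
    }
  }
  structure(list(
    meta = do.call(rbind, meta),
    fusion = lapply(fusion, function(l) do.call(rbind, l)),
    gate = lapply(gate, function(l) {
      m <- do.call(rbind, l)
      list(h1 = m[, 1:4, drop = FALSE], h2 = m[, 5:8, drop = FALSE])
    }),
    window_s = window_s), class = "har_data")
}

subset_har <- function(data, idx) {
  structure(list(
    meta = data$meta[idx, , drop = FALSE],
    fusion = lapply(data$fusion, function(m) m[idx, , drop = FALSE]),
    gate = lapply(data$gate, function(g)
      list(h1 = g$h1[idx, , drop = FALSE], h2 = g$h2[idx, , drop = FALSE])),
    window_s = data$window_s), class = "har_data")
}

#' Train the layer-1 intensity gate
#'
#' A decision tree (CART) over exactly the four magnitude features of
#' [intensity_features()], trained on 1 s windows labeled with the
#' intensity of the true activity.
#'
#' @param feats n-by-4 matrix of intensity features.
#' @param intensity Character vector of intensity labels.
#' @return An `rpart` model.
#' @export
train_intensity_layer <- function(feats, intensity) {
  if (length(unique(intensity)) < 2)
    stop("need at least 2 intensity classes to train the gate",
         call. = FALSE)
  df <- as.data.frame(feats)
  df$intensity <- factor(intensity, levels = intensity_levels())
  rpart::rpart(intensity ~ ., data = df, method = "class")
}

#' Train the layer-2 fusion models
#'
#' One random forest per intensity band, trained on windows whose true
#' activity has that intensity, over the 20 early-fused attributes of the
#' band's sensor pair ([select_sensor_pair()]). A band with a single
#' activity class yields a constant model.
#'
#' @param data A `har_data` (training rows only).
#' @param num_trees Trees per forest.
#' @param seed Integer seed.
#' @param pairs Optional named list overriding the pair per intensity;
#'   with `all_pairs = TRUE` a model is trained for every placement pair
#'   of each intensity (enables sensor-failure fallback).
#' @param all_pairs Train fallback models for all pairs.
#' @return Named list of submodels keyed `"<intensity>|<p1>+<p2>"`.
#' @export
train_fusion_layer <- function(data, num_trees = 100, seed = 1L,
                               pairs = NULL, all_pairs = FALSE) {
  placements <- names(data$fusion)
  models <- list()
  for (intensity in intensity_levels()) {
    idx <- which(data$meta$intensity == intensity)
    if (!length(idx)) next
    pair_list <- if (all_pairs) utils::combn(placements, 2, simplify = FALSE)
      else list(pairs[[intensity]] %||% select_sensor_pair(intensity))
    for (pair in pair_list) {
      key <- paste0(intensity, "|", paste(sort(pair), collapse = "+"))
      xm <- fuse_pair(data, pair, idx)
      labs <- factor(data$meta$label[idx], levels = activity_labels())
      models[[key]] <- if (length(unique(labs)) < 2) {
        list(type = "constant", label = as.character(labs[1]))
      } else {
        with_seed(sub_seed(seed, length(models) + 1L),
          ranger::ranger(x = xm, y = droplevels(labs),
                         num.trees = num_trees, num.threads = 1))
      }
    }
  }
  models
}

fuse_pair <- function(data, pair, idx) {
  pair <- sort(pair)
  xm <- cbind(data$fusion[[pair[1]]][idx, , drop = FALSE],
              data$fusion[[pair[2]]][idx, , drop = FALSE])
  colnames(xm) <- c(paste(pair[1], colnames(data$fusion[[pair[1]]]),
                          sep = "_"),
                    paste(pair[2], colnames(data$fusion[[pair[2]]]),
                          sep = "_"))
  as.data.frame(xm)
}

#' Train the full two-layer model
#'
#' @param data A `har_data` from [build_har_dataset()].
#' @param gating Placement whose magnitude signal feeds the intensity
#'   gate (default chest; any placement gates well).
#' @param num_trees Trees per fusion forest.
#' @param seed Integer seed.
#' @param all_pairs Also train fallback fusion models for every sensor
#'   pair (used when a sensor drops out at prediction time).
#' @return A `har_model` object.
#' @export
train_har_model <- function(data, gating = "chest", num_trees = 100,
                            seed = 1L, all_pairs = FALSE) {
  stopifnot(inherits(data, "har_data"))
  g <- data$gate[[gating]]
  gate_model <- train_intensity_layer(
    rbind(g$h1, g$h2), rep(data$meta$intensity, 2))
  fusion_models <- train_fusion_layer(data, num_trees = num_trees,
                                      seed = seed, all_pairs = all_pairs)
  structure(list(gate = gate_model, fusion = fusion_models,
                 gating = gating, window_s = data$window_s,
                 placements = names(data$fusion)),
            class = "har_model")
}

#' Classify activities with the two-layer model
#'
#' Layer 1 classifies the intensity on each of the two 1 s halves of the
#' gating sensor's magnitude window and takes the majority (tie broken
#' toward the more vigorous class -- conservative for alerting). Layer 2
#' applies the matching fusion submodel to the band's sensor pair. If a
#' placement of the selected pair is absent, the best available pair with
#' a trained fallback model is used and the fallback is reported.
#'
#' @param model A `har_model`.
#' @param data A `har_data` of windows to classify.
#' @param available Placements currently available (default: all the
#'   model was trained with).
#' @return Data frame with columns `intensity`, `pair`, `label`,
#'   `fallback`.
#' @export
classify_activity <- function(model, data, available = model$placements) {
  stopifnot(inherits(model, "har_model"), inherits(data, "har_data"))
  if (!(model$gating %in% available))
    stop("gating sensor '", model$gating, "' not available", call. = FALSE)
  g <- data$gate[[model$gating]]
  p1 <- predict(model$gate, as.data.frame(g$h1), type = "class")
  p2 <- predict(model$gate, as.data.frame(g$h2), type = "class")
  intensity <- vote_intensity(as.character(p1), as.character(p2))
  n <- nrow(data$meta)
  label <- character(n)
  pair_used <- character(n)
  fallback <- logical(n)
  for (iv in intensity_levels()) {
    idx <- which(intensity == iv)
    if (!length(idx)) next
    sel <- resolve_pair(model, iv, available)
    if (is.null(sel)) {
      label[idx] <- NA_character_
      msg("classify_activity: no usable sensor pair for intensity ", iv)
      next
    }
    if (sel$fallback)
      msg(sprintf(
        "classify_activity: falling back to pair %s for intensity %s",
        paste(sel$pair, collapse = "+"), iv))
    sub <- model$fusion[[sel$key]]
    xm <- fuse_pair(data, sel$pair, idx)
    label[idx] <- if (is.list(sub) && identical(sub$type, "constant"))
      sub$label else as.character(predict(sub, data = xm)$predictions)
    pair_used[idx] <- paste(sel$pair, collapse = "+")
    fallback[idx] <- sel$fallback
  }
  data.frame(intensity = intensity, pair = pair_used, label = label,
             fallback = fallback, stringsAsFactors = FALSE)
}

# Majority vote over the two 1 s half-window intensity calls; a split
# vote resolves to the more vigorous class (conservative for alerting:
# misreading vigorous activity as light would raise false alarms on
# exercise-elevated vitals, the reverse merely widens the normal range).
vote_intensity <- function(a, b) {
  ra <- match(a, intensity_levels())
  rb <- match(b, intensity_levels())
  intensity_levels()[ifelse(ra == rb, ra, pmax(ra, rb))]
}

# Pick the trained pair for an intensity given the available placements.
resolve_pair <- function(model, intensity, available) {
  want <- select_sensor_pair(intensity)
  keys <- names(model$fusion)
  mk <- function(pair) paste0(intensity, "|",
                              paste(sort(pair), collapse = "+"))
  if (all(want %in% available) && mk(want) %in% keys)
    return(list(pair = sort(want), key = mk(want), fallback = FALSE))
  if (length(available) >= 2) {
    for (pair in utils::combn(sort(available), 2, simplify = FALSE))
      if (mk(pair) %in% keys)
        return(list(pair = pair, key = mk(pair), fallback = TRUE))
  }
  NULL
}

#' Classification metrics from a confusion matrix
#'
#' Rows are true classes, columns predicted. Per class:
#' accuracy = TP / N (instances of the class), precision = TP / (TP + FP),
#' recall = TP / (TP + FN), F = 2PR / (P + R). Per-class accuracy equals
#' recall by construction. Overall accuracy is total correct / total.
#'
#' @param conf Square count matrix with matching dimnames.
#' @return List of class `eval_report`: `per_class` data frame,
#'   `confusion`, `overall_accuracy`.
#' @export
metrics_from_confusion <- function(conf) {
  conf <- as.matrix(conf)
  tp <- diag(conf)
  n_true <- rowSums(conf)
  n_pred <- colSums(conf)
  precision <- ifelse(n_pred > 0, tp / n_pred, 0)
  recall <- ifelse(n_true > 0, tp / n_true, 0)
  f <- ifelse(precision + recall > 0,
              2 * precision * recall / (precision + recall), 0)
  structure(list(
    per_class = data.frame(class = rownames(conf),
                           accuracy = unname(recall),
                           precision = unname(precision),
                           recall = unname(recall),
                           f_measure = unname(f),
                           n = unname(n_true), stringsAsFactors = FALSE),
    confusion = conf,
    overall_accuracy = sum(tp) / sum(conf)), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> overall accuracy %.4f\n", x$overall_accuracy))
  print(x$per_class, row.names = FALSE)
  cat("confusion (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

#' Evaluate the two-layer classifier
#'
#' `scheme = "loso"`: leave-one-subject-out -- each fold holds out all
#' windows of one subject (subject-independent evaluation; the held-out
#' subject never contributes to training). `scheme = "kfold"`: stratified
#' k-fold, repeated `runs` times with reshuffling; counts are pooled over
#' folds and runs before computing metrics.
#'
#' @param data A `har_data`.
#' @param scheme `"loso"` or `"kfold"`.
#' @param k Folds for `"kfold"`.
#' @param runs Repetitions for `"kfold"`.
#' @param gating,num_trees,seed Passed to [train_har_model()].
#' @return An `eval_report` (see [metrics_from_confusion()]) with
#'   attribute `predictions` (data frame of subject, truth, predicted).
#' @export
evaluate_har <- function(data, scheme = c("loso", "kfold"), k = 10,
                         runs = 5, gating = "chest", num_trees = 100,
                         seed = 1L) {
  stopifnot(inherits(data, "har_data"))
  scheme <- match.arg(scheme)
  labs <- factor(data$meta$label, levels = activity_labels())
  classes <- levels(droplevels(labs))
  conf <- matrix(0L, length(classes), length(classes),
                 dimnames = list(classes, classes))
  preds <- list()
  run_fold <- function(train_idx, test_idx, run_seed) {
    stopifnot(length(intersect(train_idx, test_idx)) == 0L)
    model <- train_har_model(subset_har(data, train_idx),
                             gating = gating, num_trees = num_trees,
                             seed = run_seed)
    res <- classify_activity(model, subset_har(data, test_idx))
    data.frame(subject = data$meta$subject[test_idx],
               truth = data$meta$label[test_idx],
               predicted = res$label, stringsAsFactors = FALSE)
  }
  if (scheme == "loso") {
    subjects <- unique(data$meta$subject)
    if (length(subjects) < 2)
      stop("LOSO requires at least 2 subjects", call. = FALSE)
    for (s in subjects) {
      test_idx <- which(data$meta$subject == s)
      train_idx <- which(data$meta$subject != s)
      preds[[length(preds) + 1L]] <-
        run_fold(train_idx, test_idx, sub_seed(seed, match(s, subjects)))
    }
  } else {
    for (r in seq_len(runs)) {
      folds <- with_seed(sub_seed(seed, 777L + r),
                         stratified_folds(droplevels(labs), k))
      for (f in seq_len(k)) {
        test_idx <- which(folds == f)
        if (!length(test_idx)) next
        preds[[length(preds) + 1L]] <-
          run_fold(which(folds != f), test_idx,
                   sub_seed(seed, r * 100L + f))
      }
    }
  }
  pd <- do.call(rbind, preds)
  ok <- !is.na(pd$predicted)
  for (i in which(ok))
    conf[pd$truth[i], pd$predicted[i]] <- conf[pd$truth[i],
                                               pd$predicted[i]] + 1L
  rep <- metrics_from_confusion(conf)
  attr(rep, "predictions") <- pd
  rep
}
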