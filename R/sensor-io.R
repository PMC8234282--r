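# Sensor stream container, fixed-rate log IO, and window segmentation.

#' Fixed-rate sensor stream
#'
#' @param subject_id Subject identifier.
#' @param placement One of `"chest"`, `"wrist"`, `"ankle"`.
#' @param modality `"accel3d"` (3 components per sample) or `"ecg"` (1).
#' @param fs Sampling rate in Hz, > 0.
#' @param samples Numeric matrix, one row per sample; 3 columns for
#'   `accel3d`, 1 for `ecg`.
#' @param labels Optional integer per-sample activity labels (length =
#'   number of samples).
#' @return An object of class `sensor_stream`.
#' @export
sensor_stream <- function(subject_id, placement, modality, fs, samples,
                          labels = NULL) {
  placement <- match.arg(placement, c("chest", "wrist", "ankle"))
  modality <- match.arg(modality, c("accel3d", "ecg"))
  if (!is.numeric(fs) || fs <= 0) stop("`fs` must be > 0", call. = FALSE)
  samples <- as.matrix(samples)
  want <- if (modality == "accel3d") 3L else 1L
  if (ncol(samples) != want)
    stop(sprintf("%s samples must have %d component(s)", modality, want),
         call. = FALSE)
  if (!is.null(labels) && length(labels) != nrow(samples))
    stop("`labels` must align 1:1 with samples", call. = FALSE)
  structure(list(subject_id = subject_id, placement = placement,
                 modality = modality, fs = fs, samples = samples,
                 labels = if (is.null(labels)) NULL else as.integer(labels)),
            class = "sensor_stream")
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("<sensor_stream> %s %s/%s: %d samples @ %g Hz (%.1f s)%s\n",
              x$subject_id, x$placement, x$modality, nrow(x$samples), x$fs,
              nrow(x$samples) / x$fs,
              if (is.null(x$labels)) "" else ", labeled"))
  invisible(x)
}

#' Stream duration in seconds
#' @param stream A [sensor_stream()].
#' @export
stream_duration <- function(stream) nrow(stream$samples) / stream$fs

#' Default MHEALTH column map
#'
#' Column indices (1-based) into the 24-column whitespace-separated MHEALTH
#' log layout: chest accelerometer in columns 1-3, ECG lead I in column 4,
#' ankle accelerometer in 6-8, wrist accelerometer in 15-17, activity label
#' in column 24. Only the channels the pipeline consumes are mapped;
#' gyroscope/magnetometer columns are ignored.
#'
#' @return A named list; each stream entry has `cols`, `placement`,
#'   `modality`, plus a `label` column index.
#' @export
default_column_map <- function() {
  list(
    chest_acc = list(cols = 1:3, placement = "chest", modality = "accel3d"),
    ecg = list(cols = 4L, placement = "chest", modality = "ecg"),
    ankle_acc = list(cols = 6:8, placement = "ankle", modality = "accel3d"),
    wrist_acc = list(cols = 15:17, placement = "wrist",
                     modality = "accel3d"),
    label = 24L
  )
}

#' Read a whitespace-separated fixed-rate sensor log
#'
#' One row per sample at a fixed rate. `column_map` declares, for each
#' stream, which columns hold its components, plus the activity-label
#' column. Rows containing non-numeric fields in any mapped column are
#' dropped with a reported count.
#'
#' @param path Path to the log file.
#' @param column_map As [default_column_map()].
#' @param fs Sampling rate in Hz.
#' @param subject_id Subject identifier attached to every stream.
#' @return Named list of [sensor_stream()]s (one per declared stream), each
#'   carrying the label column; attribute `n_dropped` counts dropped rows.
#' @export
read_sensor_log <- function(path, column_map = default_column_map(),
                            fs = 50, subject_id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    utils::read.table(path, header = FALSE, colClasses = "character",
                      blank.lines.skip = TRUE),
    error = function(e) stop("empty sensor log: ", path, call. = FALSE))
  if (!nrow(raw)) stop("empty sensor log: ", path, call. = FALSE)
  streams <- column_map[setdiff(names(column_map), "label")]
  label_col <- column_map$label
  needed <- unique(c(unlist(lapply(streams, `[[`, "cols")), label_col))
  if (max(needed) > ncol(raw))
    stop(sprintf("column %d not present in %s (file has %d columns)",
                 max(needed), path, ncol(raw)), call. = FALSE)
  num <- suppressWarnings(
    vapply(needed, function(j) as.numeric(raw[[j]]), numeric(nrow(raw))))
  num <- matrix(num, nrow = nrow(raw))
  colnames(num) <- as.character(needed)
  keep <- rowSums(is.na(num)) == 0L
  n_dropped <- sum(!keep)
  if (!any(keep)) stop("no numeric rows in ", path, call. = FALSE)
  num <- num[keep, , drop = FALSE]
  labels <- if (!is.null(label_col))
    as.integer(num[, as.character(label_col)]) else NULL
  out <- lapply(streams, function(sp) {
    sensor_stream(subject_id = subject_id, placement = sp$placement,
                  modality = sp$modality, fs = fs,
                  samples = num[, as.character(sp$cols), drop = FALSE],
                  labels = labels)
  })
  if (n_dropped > 0)
    msg(sprintf("read_sensor_log: dropped %d non-numeric row(s) from %s",
                n_dropped, path))
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write streams as an MHEALTH-style whitespace-separated log
#'
#' Inverse of [read_sensor_log()]: lays the given streams out according to
#' `column_map` (unmapped columns are written as 0) with the integer
#' activity label in the label column. Values are written with 6 decimal
#' places, so a write/read round trip reproduces samples to 1e-6.
#'
#' @param streams Named list of [sensor_stream()]s; names must match the
#'   stream entries of `column_map`.
#' @param path Output path.
#' @param column_map As [default_column_map()].
#' @param n_cols Total number of columns in the layout.
#' @export
write_sensor_log <- function(streams, path,
                             column_map = default_column_map(),
                             n_cols = 24) {
  spec <- column_map[setdiff(names(column_map), "label")]
  used <- intersect(names(spec), names(streams))
  if (!length(used)) stop("no streams match the column map", call. = FALSE)
  n <- unique(vapply(streams[used], function(s) nrow(s$samples), 0))
  if (length(n) != 1L)
    stop("streams must have equal length to share one log", call. = FALSE)
  mat <- matrix(0, nrow = n, ncol = n_cols)
  for (nm in used) mat[, spec[[nm]]$cols] <- streams[[nm]]$samples
  lab <- streams[[used[1]]]$labels
  if (!is.null(column_map$label))
    mat[, column_map$label] <- if (is.null(lab)) 0L else lab
  txt <- apply(mat, 1L, function(r) paste(sprintf("%.6f", r),
                                          collapse = "\t"))
  writeLines(txt, path)
  invisible(path)
}

#' Sliding-window segmentation
#'
#' Cuts a stream into windows of `window_s` seconds at stride
#' `window_s * (1 - overlap_frac)`. With `overlap_frac = 0` this is the
#' fixed-size non-overlapping sliding window; the trailing partial window
#' is discarded. Window spans are 0-based half-open sample intervals
#' `[start, start + length)`; windows are index views into the parent
#' stream (the stream must not be mutated afterwards).
#'
#' Mixed-label windows receive the majority per-sample label, ties broken
#' by the label of the first sample in the window.
#'
#' @param stream A [sensor_stream()].
#' @param window_s Window length in seconds; `window_s * fs` must be >= 2.
#' @param overlap_frac Fractional overlap in `[0, 1)`.
#' @return List of `window` objects (fields `stream`, `start`, `length`,
#'   `label`).
#' @export
segment <- function(stream, window_s, overlap_frac = 0) {
  stopifnot(inherits(stream, "sensor_stream"))
  if (overlap_frac < 0 || overlap_frac >= 1)
    stop("`overlap_frac` must be in [0, 1)", call. = FALSE)
  len <- round(window_s * stream$fs)
  if (len < 2) stop("window of < 2 samples; increase `window_s`",
                    call. = FALSE)
  stride <- round(len * (1 - overlap_frac))
  if (stride < 1) stop("stride of 0 samples; reduce `overlap_frac`",
                       call. = FALSE)
  n <- nrow(stream$samples)
  starts <- seq.int(0L, by = stride, length.out = max(0L, (n - len) %/%
                                                        stride + 1L))
  starts <- starts[starts + len <= n]
  lapply(starts, function(st) {
    lab <- NULL
    if (!is.null(stream$labels)) {
      labs <- stream$labels[(st + 1):(st + len)]
      tab <- table(labs)
      winners <- as.integer(names(tab)[tab == max(tab)])
      lab <- if (length(winners) == 1L) winners else
        if (labs[1] %in% winners) labs[1] else winners[1]
    }
    structure(list(stream = stream, start = as.integer(st),
                   length = as.integer(len), label = lab),
              class = "window")
  })
}

#' Extract the sample matrix of a window
#' @param win A window from [segment()].
#' @return Numeric matrix of `win$length` rows.
#' @export
window_data <- function(win) {
  stopifnot(inherits(win, "window"))
  win$stream$samples[(win$start + 1):(win$start + win$length), ,
                     drop = FALSE]
}

#' Window span in seconds
#' @param win A window from [segment()].
#' @return `c(start_s, end_s)`.
#' @export
window_span <- function(win) {
  c(win$start, win$start + win$length) / win$stream$fs
}
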