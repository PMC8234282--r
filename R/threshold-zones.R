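# Per-(vital, activity) green/yellow/red zone learning by the five-bin
# histogram procedure, HR boundary adjustment, and rule emission.

#' Learn the green/yellow zones for one (vital, activity)
#'
#' The sample range `[min, max]` is divided into five equal-width bins
#' (half-open, last bin closed, so every sample falls in exactly one bin).
#' Bins holding strictly more than the mean count (n / 5) are marked
#' green; a bin whose count equals the mean is not green. A single
#' non-green bin strictly between two green bins is promoted to green. If
#' no bin exceeds the mean (a uniform histogram), the bins attaining the
#' maximum count are marked green, which guarantees a non-empty normal
#' range. Should promotion still leave several disjoint green segments,
#' the widest (first on ties) is kept and the others are demoted.
#'
#' The green range runs from the lower edge of the first green bin to the
#' upper edge of the last one (edges, not observed extremes; rounded to
#' integers since measurements are integer-valued). The yellow ranges are
#' `[data_min, green_lo - 1]` when bin 1 is not green and
#' `[green_hi + 1, data_max]` when bin 5 is not green. The red zone is
#' everything outside `[data_min, data_max]`.
#'
#' @param samples Integer-valued measurements (quality-filtered), >= 5
#'   unless all are equal (degenerate entry: green = `[v, v]`, no yellow).
#' @param vital `"HR"` or `"BR"`.
#' @param activity Activity label.
#' @return A `zone_entry` list: `vital`, `activity`, `green = c(lo, hi)`,
#'   `yellow_low`, `yellow_high` (each `c(lo, hi)` or `NULL`),
#'   `data_min`, `data_max`, `n`, and `bins` (counts and green marks).
#' @export
extract_zones <- function(samples, vital = "HR", activity = "unknown") {
  samples <- as.numeric(samples)
  if (any(!is.finite(samples))) stop("non-finite samples", call. = FALSE)
  lo <- min(samples); hi <- max(samples)
  if (lo == hi) {
    return(structure(list(vital = vital, activity = activity,
                          green = c(round_int(lo), round_int(hi)),
                          yellow_low = NULL, yellow_high = NULL,
                          data_min = round_int(lo), data_max = round_int(hi),
                          n = length(samples),
                          bins = NULL), class = "zone_entry"))
  }
  if (length(samples) < 5)
    stop("need >= 5 samples to fit zones", call. = FALSE)
  edges <- lo + (0:5) * ((hi - lo) / 5)
  bin <- pmin(findInterval(samples, edges), 5L)       # last bin closed
  counts <- tabulate(bin, nbins = 5)
  green <- counts > length(samples) / 5
  if (!any(green)) green <- counts == max(counts)     # uniform histogram
  # promote a single yellow bin strictly between two green bins
  for (i in 2:4) if (!green[i] && green[i - 1] && green[i + 1])
    green[i] <- TRUE
  green <- keep_widest_segment(green)
  gidx <- which(green)
  g_lo <- round_int(edges[min(gidx)])
  g_hi <- round_int(edges[max(gidx) + 1])
  d_min <- round_int(lo); d_max <- round_int(hi)
  structure(list(
    vital = vital, activity = activity,
    green = c(g_lo, g_hi),
    yellow_low = if (min(gidx) > 1) c(d_min, g_lo - 1L) else NULL,
    yellow_high = if (max(gidx) < 5) c(g_hi + 1L, d_max) else NULL,
    data_min = d_min, data_max = d_max, n = length(samples),
    bins = list(edges = edges, counts = counts, green = green)),
    class = "zone_entry")
}

# Keep only the widest contiguous run of TRUE (first on ties).
keep_widest_segment <- function(mark) {
  r <- rle(mark)
  runs <- which(r$values)
  if (length(runs) <= 1) return(mark)
  widths <- r$lengths[runs]
  keep <- runs[which.max(widths)]
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- rep(FALSE, length(mark))
  out[starts[keep]:ends[keep]] <- TRUE
  out
}

#' @export
print.zone_entry <- function(x, ...) {
  fmt <- function(r) if (is.null(r)) "-" else sprintf("[%d, %d]", r[1], r[2])
  cat(sprintf(
    "<zone_entry> %s / %s: green %s, yellow_low %s, yellow_high %s, red outside [%d, %d] (n = %d)\n",
    x$vital, x$activity, fmt(x$green), fmt(x$yellow_low),
    fmt(x$yellow_high), x$data_min, x$data_max, x$n))
  invisible(x)
}

#' Snap HR zone boundaries to multiples of five
#'
#' Commercial heart-rate monitors are only accurate to about +-3 bpm, so
#' HR boundaries are rounded to the nearest multiple of 5 (ties away from
#' zero). Green boundaries are rounded first; the yellow ranges are then
#' re-derived so the +-1 adjacency invariants still hold, and the data
#' extremes are rounded as the outer yellow bounds. A yellow range that
#' collapses (rounded green boundary at or past the rounded extreme) is
#' dropped. Applying the adjustment twice equals applying it once. BR
#' entries are returned unchanged.
#'
#' @param entry A `zone_entry`.
#' @return The adjusted `zone_entry`.
#' @export
adjust_hr_bounds <- function(entry) {
  stopifnot(inherits(entry, "zone_entry"))
  if (!identical(entry$vital, "HR")) return(entry)
  g_lo <- round_to_multiple(entry$green[1])
  g_hi <- round_to_multiple(entry$green[2])
  d_min <- min(round_to_multiple(entry$data_min), g_lo)
  d_max <- max(round_to_multiple(entry$data_max), g_hi)
  entry$green <- c(g_lo, g_hi)
  entry$data_min <- d_min
  entry$data_max <- d_max
  entry$yellow_low <- if (!is.null(entry$yellow_low) && g_lo > d_min)
    c(d_min, g_lo - 1L) else NULL
  entry$yellow_high <- if (!is.null(entry$yellow_high) && g_hi < d_max)
    c(g_hi + 1L, d_max) else NULL
  entry
}

#' Zone table over (vital, activity) pairs
#'
#' @param entries List of `zone_entry` objects.
#' @return A `zone_table`, keyed `"<vital>|<activity>"`.
#' @export
zone_table <- function(entries = list()) {
  names(entries) <- vapply(entries, function(e)
    paste(e$vital, e$activity, sep = "|"), "")
  structure(list(entries = entries), class = "zone_table")
}

#' Look up a zone entry
#' @param table A `zone_table`.
#' @param vital,activity Key pair.
#' @return The `zone_entry`, or `NULL` when absent.
#' @export
zone_lookup <- function(table, vital, activity) {
  table$entries[[paste(vital, activity, sep = "|")]]
}

#' Fit a zone table from cohort vital measurements
#'
#' Filters to quality `"ok"` rows, optionally excludes a target subject
#' (so their zones come only from the other cohort members) and applies
#' any demographic row filter, then fits [extract_zones()] per
#' (vital, activity) and snaps HR boundaries via [adjust_hr_bounds()].
#' Pairs with fewer than `min_samples` measurements are skipped with a
#' report.
#'
#' @param vitals Data frame with columns subject, kind, value, quality,
#'   activity (as produced by [extract_vitals()] plus an activity column).
#' @param exclude_subject Optional subject id to leave out.
#' @param filter Optional predicate over rows (takes the data frame,
#'   returns a logical vector), e.g. a demographics filter.
#' @param min_samples Minimum samples per entry (default 5).
#' @param adjust_hr Apply the multiple-of-five HR adjustment.
#' @return A `zone_table`.
#' @export
fit_cohort <- function(vitals, exclude_subject = NULL, filter = NULL,
                       min_samples = 5, adjust_hr = TRUE) {
  stopifnot(all(c("subject", "kind", "value", "quality", "activity")
                %in% names(vitals)))
  keep <- vitals$quality == "ok"
  if (!is.null(exclude_subject))
    keep <- keep & !(vitals$subject %in% exclude_subject)
  if (!is.null(filter)) keep <- keep & filter(vitals)
  v <- vitals[keep, , drop = FALSE]
  entries <- list()
  for (vital in unique(v$kind)) {
    for (act in unique(v$activity)) {
      x <- v$value[v$kind == vital & v$activity == act]
      if (length(x) < min_samples) {
        if (length(x) > 0)
          msg(sprintf("fit_cohort: skipping %s/%s (%d < %d samples)",
                      vital, act, length(x), min_samples))
        next
      }
      e <- extract_zones(x, vital = vital, activity = act)
      if (adjust_hr) e <- adjust_hr_bounds(e)
      entries[[length(entries) + 1L]] <- e
    }
  }
  zone_table(entries)
}

#' Render a zone table as IF-THEN rules
#'
#' One rule per (vital, activity, zone) present, with the normal /
#' altered / emergency wording, e.g.
#' `"IF activity=walking THEN normal HR range is 70–125 bpm"`. The
#' emergency rule renders both open sides
#' (`"<8 or >44 brpm"`).
#'
#' @param table A `zone_table`.
#' @return Data frame with columns vital, activity, zone, lo, hi, text.
#' @export
emit_rules <- function(table) {
  stopifnot(inherits(table, "zone_table"))
  unit <- function(vital) if (vital == "HR") "bpm" else "brpm"
  rows <- list()
  add <- function(e, zone, lo, hi, wording) {
    rng <- if (zone == "red")
      sprintf("<%d or >%d %s", e$data_min, e$data_max, unit(e$vital))
    else sprintf("%d–%d %s", lo, hi, unit(e$vital))
    rows[[length(rows) + 1L]] <<- data.frame(
      vital = e$vital, activity = e$activity, zone = zone,
      lo = if (zone == "red") NA_integer_ else lo,
      hi = if (zone == "red") NA_integer_ else hi,
      text = sprintf("IF activity=%s THEN %s %s range is %s",
                     e$activity, wording, e$vital, rng),
      stringsAsFactors = FALSE)
  }
  for (e in table$entries) {
    add(e, "green", e$green[1], e$green[2], "normal")
    if (!is.null(e$yellow_low))
      add(e, "yellow", e$yellow_low[1], e$yellow_low[2], "altered")
    if (!is.null(e$yellow_high))
      add(e, "yellow", e$yellow_high[1], e$yellow_high[2], "altered")
    add(e, "red", NA, NA, "emergency")
  }
  do.call(rbind, rows)
}

#' Serialize / restore a zone table as JSON
#'
#' @param table A `zone_table`.
#' @param path Output (input) path.
#' @param meta Optional named list stored under `"meta"` (seed, hash).
#' @return `write_zone_table()` returns the path; `read_zone_table()` the
#'   restored `zone_table`.
#' @export
write_zone_table <- function(table, path, meta = NULL) {
  entries <- lapply(table$entries, function(e)
    list(vital = e$vital, activity = e$activity, green = e$green,
         yellow_low = e$yellow_low, yellow_high = e$yellow_high,
         data_min = e$data_min, data_max = e$data_max, n = e$n))
  jsonlite::write_json(list(meta = meta, entries = entries), path,
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_zone_table
#' @export
read_zone_table <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  entries <- lapply(obj$entries, function(e) {
    e$green <- as.integer(unlist(e$green))
    e$yellow_low <- if (length(e$yellow_low))
      as.integer(unlist(e$yellow_low)) else NULL
    e$yellow_high <- if (length(e$yellow_high))
      as.integer(unlist(e$yellow_high)) else NULL
    e$data_min <- as.integer(e$data_min)
    e$data_max <- as.integer(e$data_max)
    structure(e, class = "zone_entry")
  })
  zone_table(unname(entries))
}
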