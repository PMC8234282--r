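# Zone membership, the graded alert protocol, and stream monitoring.

#' Classify a measurement into its zone
#'
#' Membership test against the green / yellow / red partition of a zone
#' entry: green inside the normal range, yellow elsewhere inside
#' `[data_min, data_max]`, red outside.
#'
#' @param value Integer measurement.
#' @param entry A `zone_entry` (see [extract_zones()]).
#' @return `"green"`, `"yellow"` or `"red"`.
#' @export
classify_zone <- function(value, entry) {
  stopifnot(inherits(entry, "zone_entry"))
  if (value >= entry$green[1] && value <= entry$green[2]) return("green")
  if (value >= entry$data_min && value <= entry$data_max) return("yellow")
  "red"
}

# Severity ladder used by the protocol and the monotonicity property.
alert_outcomes <- function() {
  c("none", "user_warning", "user_alert", "caretaker_alert",
    "emergency_alert")
}

#' Decide the alert outcome for one evaluation tick
#'
#' The escalation protocol over the monitored vitals' zones:
#' two (or more) vitals red sends an *alert* to the emergency service;
#' one red an *alert* to the caretaker; two yellow an *alert* to the
#' user; one yellow a *warning* to the user; all green, no message. Red
#' dominates yellow (a red + yellow tick produces the single caretaker
#' alert), and exactly one message is produced per tick.
#'
#' @param zones Named character vector of zones per vital, e.g.
#'   `c(HR = "yellow", BR = "green")`.
#' @return `NULL` when all green, otherwise a list with `recipient`
#'   (`"user"`, `"caretaker"`, `"emergency"`), `level` (`"warning"` or
#'   `"alert"`) and `outcome` (one of `alert_outcomes()`).
#' @export
decide_alert <- function(zones) {
  stopifnot(all(zones %in% c("green", "yellow", "red")))
  n_red <- sum(zones == "red")
  n_yellow <- sum(zones == "yellow")
  if (n_red >= 2)
    list(recipient = "emergency", level = "alert",
         outcome = "emergency_alert")
  else if (n_red == 1)
    list(recipient = "caretaker", level = "alert",
         outcome = "caretaker_alert")
  else if (n_yellow >= 2)
    list(recipient = "user", level = "alert", outcome = "user_alert")
  else if (n_yellow == 1)
    list(recipient = "user", level = "warning", outcome = "user_warning")
  else NULL
}

#' Monitor vital measurements against a zone table
#'
#' Pairs each measurement with the activity label covering its window
#' midpoint, classifies it into a zone, and applies [decide_alert()] once
#' per evaluation tick (a tick is one `window_end_s` instant, every 4 s
#' under the default schedule). `bad_signal` measurements never produce
#' an alert; measurements whose (vital, activity) entry is missing from
#' the table, or whose midpoint no activity covers, are skipped and
#' counted.
#'
#' @param vitals Data frame from [extract_vitals()] (columns subject,
#'   kind, value, window_start_s, window_end_s, quality).
#' @param activities Data frame with columns start_s, end_s, label
#'   (recognized or true activity intervals).
#' @param table A `zone_table`.
#' @return Data frame of messages (tick_s, recipient, level, outcome,
#'   vitals, activity), one row per non-green tick; attribute `skipped`
#'   counts held measurements and `zones` gives the per-measurement zone
#'   classification.
#' @export
monitor <- function(vitals, activities, table) {
  stopifnot(inherits(table, "zone_table"))
  v <- vitals[vitals$quality == "ok", , drop = FALSE]
  act_of <- function(t_mid) {
    hit <- which(activities$start_s <= t_mid & t_mid < activities$end_s)
    if (length(hit)) activities$label[hit[1]] else NA_character_
  }
  n <- nrow(v)
  zone <- character(n); act <- character(n)
  skipped <- 0L
  for (i in seq_len(n)) {
    mid <- (v$window_start_s[i] + v$window_end_s[i]) / 2
    a <- act_of(mid)
    entry <- if (!is.na(a)) zone_lookup(table, v$kind[i], a) else NULL
    if (is.null(entry)) {
      zone[i] <- NA_character_; act[i] <- a
      skipped <- skipped + 1L
      next
    }
    zone[i] <- classify_zone(v$value[i], entry)
    act[i] <- a
  }
  zones_df <- cbind(v, data.frame(activity = act, zone = zone,
                                  stringsAsFactors = FALSE))
  msgs <- list()
  for (tick in sort(unique(v$window_end_s))) {
    idx <- which(v$window_end_s == tick & !is.na(zone))
    if (!length(idx)) next
    z <- zone[idx]; names(z) <- v$kind[idx]
    decision <- decide_alert(z)
    if (is.null(decision)) next
    out_idx <- idx[z != "green"]
    msgs[[length(msgs) + 1L]] <- data.frame(
      tick_s = tick, recipient = decision$recipient,
      level = decision$level, outcome = decision$outcome,
      vitals = paste(sprintf("%s=%d", v$kind[out_idx], v$value[out_idx]),
                     collapse = ";"),
      activity = act[out_idx[1]], stringsAsFactors = FALSE)
  }
  out <- if (length(msgs)) do.call(rbind, msgs) else
    data.frame(tick_s = numeric(0), recipient = character(0),
               level = character(0), outcome = character(0),
               vitals = character(0), activity = character(0))
  attr(out, "skipped") <- skipped
  attr(out, "zones") <- zones_df
  out
}

#' Append alert messages to a JSON-lines log
#'
#' @param messages Data frame from [monitor()].
#' @param path Output path (appended).
#' @export
write_alert_log <- function(messages, path) {
  con <- file(path, open = "a")
  on.exit(close(con))
  for (i in seq_len(nrow(messages)))
    writeLines(jsonlite::toJSON(as.list(messages[i, ]),
                                auto_unbox = TRUE), con)
  invisible(path)
}
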