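test_that("all-equal samples give a degenerate green entry", {
  e <- extract_zones(rep(60, 7), "HR", "sitting")
  expect_equal(e$green, c(60L, 60L))
  expect_null(e$yellow_low)
  expect_null(e$yellow_high)
  expect_equal(classify_zone(60, e), "green")
  expect_equal(classify_zone(59, e), "red")
  expect_error(extract_zones(c(1, 2, 3)), "5 samples")
})

test_that("a dense first bin with a sparse tail yields only a high yellow", {
  x <- c(rep(10, 7), 30, 40, 50)
  e <- extract_zones(x, "BR", "lying")
  o <- oracle_zones(x)
  expect_equal(e$bins$green, o$green_mark)
  expect_equal(e$green, o$green)
  expect_null(e$yellow_low)
  expect_equal(e$yellow_high, c(e$green[2] + 1L, 50L))
})

test_that("a single sparse bin between green bins is promoted", {
  x <- c(1, 3, 5, 7, 15, 21, 23, 25, 27, 50)
  # bins over [1, 50]: counts 4, 1, 4, 0, 1 -> bins 1 and 3 green,
  # bin 2 promoted, single contiguous green run over bins 1-3
  e <- extract_zones(x, "BR", "walking")
  expect_equal(e$bins$counts, c(4L, 1L, 4L, 0L, 1L))
  expect_equal(e$bins$green, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  o <- oracle_zones(x)
  expect_equal(e$bins$green, o$green_mark)
  expect_equal(e$green, o$green)
  expect_null(e$yellow_low)
  expect_equal(e$yellow_high[2], 50L)
})

test_that("bin counts exactly at the mean are not green", {
  x <- c(1, 1, 1, 1, 3, 3, 5, 5, 7, 9)     # counts 4,2,2,1,1; mean 2
  e <- extract_zones(x, "HR", "standing")
  expect_equal(e$bins$counts, c(4L, 2L, 2L, 1L, 1L))
  expect_equal(e$bins$green, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  # uniform histogram: maximum-count bins become green
  u <- c(1, 2, 3, 4, 5)
  eu <- extract_zones(u, "HR", "standing")
  expect_true(all(eu$bins$green))
  expect_equal(eu$green, c(1L, 5L))
})

test_that("brute-force oracle reproduces zoning on random samples", {
  set.seed(21)
  for (i in 1:200) {
    n <- sample(5:200, 1)
    x <- sample(40:180, n, replace = TRUE)
    if (min(x) == max(x)) next
    e <- extract_zones(x, "HR", "test")
    o <- oracle_zones(x)
    expect_equal(e$bins$green, o$green_mark)
    expect_equal(e$green, o$green)
    expect_equal(is.null(e$yellow_low), !o$yellow_low_present)
    expect_equal(is.null(e$yellow_high), !o$yellow_high_present)
    # fitted samples never fall in the red zone
    expect_true(all(vapply(x, classify_zone, "", entry = e) != "red"))
  }
})

test_that("zones partition the integers with exact adjacency", {
  set.seed(22)
  for (i in 1:50) {
    x <- sample(40:180, sample(10:100, 1), replace = TRUE)
    if (min(x) == max(x)) next
    e <- extract_zones(x, "HR", "test")
    vals <- (e$data_min - 5L):(e$data_max + 5L)
    zones <- vapply(vals, classify_zone, "", entry = e)
    in_green <- vals >= e$green[1] & vals <= e$green[2]
    in_yellow <- (!in_green) & vals >= e$data_min & vals <= e$data_max
    expect_equal(zones == "green", in_green)
    expect_equal(zones == "yellow", in_yellow)
    expect_equal(zones == "red", !(in_green | in_yellow))
    if (!is.null(e$yellow_low))
      expect_equal(e$yellow_low[2], e$green[1] - 1L)
    if (!is.null(e$yellow_high))
      expect_equal(e$yellow_high[1], e$green[2] + 1L)
  }
})

test_that("HR bounds snap to multiples of five and the map is idempotent", {
  mk <- function(g_lo, g_hi, d_min, d_max, vital = "HR")
    structure(list(vital = vital, activity = "walking",
                   green = c(g_lo, g_hi),
                   yellow_low = if (g_lo > d_min) c(d_min, g_lo - 1L),
                   yellow_high = if (g_hi < d_max) c(g_hi + 1L, d_max),
                   data_min = d_min, data_max = d_max, n = 50L,
                   bins = NULL), class = "zone_entry")
  a <- adjust_hr_bounds(mk(72L, 123L, 61L, 148L))
  expect_equal(a$green, c(70L, 125L))
  expect_equal(a$yellow_low, c(60L, 69L))
  expect_equal(a$yellow_high, c(126L, 150L))
  expect_equal(adjust_hr_bounds(mk(73L, 127L, 70L, 140L))$green,
               c(75L, 125L))
  expect_equal(adjust_hr_bounds(mk(67L, 68L, 60L, 80L))$green,
               c(65L, 70L))
  # BR entries pass through untouched
  b <- mk(11L, 27L, 8L, 33L, vital = "BR")
  expect_identical(adjust_hr_bounds(b), b)
  # idempotence over random entries
  set.seed(23)
  for (i in 1:100) {
    d_min <- sample(40:80, 1); d_max <- d_min + sample(20:80, 1)
    g_lo <- d_min + sample(0:10, 1); g_hi <- d_max - sample(0:10, 1)
    if (g_lo > g_hi) next
    e1 <- adjust_hr_bounds(mk(g_lo, g_hi, d_min, d_max))
    expect_identical(adjust_hr_bounds(e1), e1)
  }
})

test_that("rules render in the IF-THEN wording per zone", {
  e <- structure(list(vital = "HR", activity = "walking",
                      green = c(70L, 125L), yellow_low = c(60L, 69L),
                      yellow_high = c(126L, 150L), data_min = 60L,
                      data_max = 150L, n = 90L, bins = NULL),
                 class = "zone_entry")
  rules <- emit_rules(zone_table(list(e)))
  expect_equal(nrow(rules), 4L)            # green, two yellows, red
  expect_equal(rules$text[rules$zone == "green"],
               "IF activity=walking THEN normal HR range is 70–125 bpm")
  expect_true(all(grepl("altered", rules$text[rules$zone == "yellow"])))
  red <- rules$text[rules$zone == "red"]
  expect_match(red, "emergency")
  expect_match(red, "<60")
  expect_match(red, ">150")

  e_br <- extract_zones(c(rep(18, 6), 8, 30), "BR", "sitting")
  r_br <- emit_rules(zone_table(list(e_br)))
  expect_true(all(grepl("brpm", r_br$text)))
})

test_that("cohort fitting filters quality, excludes the target subject", {
  set.seed(24)
  vitals <- data.frame(
    subject = rep(c("A", "B", "C"), each = 40),
    kind = "HR",
    value = round(c(rnorm(40, 80, 5), rnorm(40, 85, 5), rnorm(40, 150, 5))),
    quality = "ok",
    activity = "walking", stringsAsFactors = FALSE)
  # bad-signal outliers must not widen any range
  vitals <- rbind(vitals,
                  data.frame(subject = "A", kind = "HR", value = 250L,
                             quality = "bad_signal", activity = "walking"))
  tab <- fit_cohort(vitals, exclude_subject = "C")
  e <- zone_lookup(tab, "HR", "walking")
  expect_false(is.null(e))
  expect_lt(e$data_max, 150)               # C's and the artifact excluded
  expect_equal(e$green[1] %% 5, 0)         # HR adjustment applied

  # a pair with too few samples is skipped
  few <- data.frame(subject = "A", kind = "BR", value = c(12L, 14L, 15L),
                    quality = "ok", activity = "lying")
  tab2 <- suppressMessages(fit_cohort(rbind(vitals, few)))
  expect_null(zone_lookup(tab2, "BR", "lying"))
  expect_false(is.null(zone_lookup(tab2, "HR", "walking")))
})

test_that("green range covers most of a Gaussian cohort", {
  set.seed(25)
  x <- round(rnorm(400, 95, 10))
  e <- extract_zones(x, "HR", "walking")
  coverage <- mean(x >= e$green[1] & x <= e$green[2])
  expect_gte(coverage, 0.6)
})

test_that("zone tables survive a JSON round trip", {
  set.seed(26)
  entries <- list(
    adjust_hr_bounds(extract_zones(round(rnorm(60, 90, 12)), "HR",
                                   "walking")),
    extract_zones(round(rnorm(60, 18, 4)), "BR", "walking"),
    extract_zones(rep(60, 8), "HR", "lying"))
  tab <- zone_table(entries)
  path <- withr::local_tempfile(fileext = ".json")
  write_zone_table(tab, path, meta = list(seed = 1))
  back <- read_zone_table(path)
  for (key in names(tab$entries)) {
    a <- tab$entries[[key]]; b <- back$entries[[key]]
    expect_equal(a$green, b$green)
    expect_equal(a$yellow_low, b$yellow_low)
    expect_equal(a$yellow_high, b$yellow_high)
    expect_equal(a$data_min, b$data_min)
    expect_equal(a$data_max, b$data_max)
  }
})
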