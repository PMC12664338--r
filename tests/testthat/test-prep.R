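minute_series <- function(counts, person = "a",
                          start = as.POSIXct("2022-01-03 00:00:00", tz = "UTC")) {
  tibble::tibble(
    person_id = person,
    timestamp = start + 60 * (seq_along(counts) - 1),
    counts = as.integer(counts)
  )
}

epoch_series <- function(counts, person = "a",
                         start = as.POSIXct("2022-01-03 00:00:00", tz = "UTC")) {
  tibble::tibble(
    person_id = person,
    timestamp = start + 10 * (seq_along(counts) - 1),
    counts = as.integer(counts)
  )
}

test_that("collapse_epochs sums six 10 s epochs per minute", {
  expect_equal(collapse_epochs(epoch_series(c(10, 0, 5, 0, 0, 5)))$counts, 20L)
  expect_equal(collapse_epochs(epoch_series(rep(1, 12)))$counts, c(6L, 6L))
  expect_warning(
    out <- collapse_epochs(epoch_series(rep(1, 7))),
    "Dropped 1 trailing epoch"
  )
  expect_equal(out$counts, 6L)
  # leading truncation to a minute boundary
  expect_warning(
    out2 <- collapse_epochs(epoch_series(
      rep(2, 16),
      start = as.POSIXct("2022-01-03 00:00:20", tz = "UTC")
    )),
    "leading epoch"
  )
  expect_equal(out2$counts, c(12L, 12L))
  expect_true(all(as.numeric(out2$timestamp) %% 60 == 0))
  # unsupported resolution
  expect_error(collapse_epochs(minute_series(c(1, 2))), "unsupported resolution")
})

test_that("detect_nonwear implements the 60-min zero rule with 2-min allowance", {
  wear_of <- function(counts) detect_nonwear(minute_series(counts))$wear
  # 120 zeros: all non-wear
  expect_equal(wear_of(rep(0, 120)), rep(FALSE, 120))
  # 59 zeros then high counts: zeros stay wear
  expect_equal(
    wear_of(c(rep(0, 59), rep(500, 100))),
    rep(TRUE, 159)
  )
  # allowance absorbs a 2-min low interruption
  expect_equal(
    wear_of(c(rep(0, 30), rep(50, 2), rep(0, 30))),
    rep(FALSE, 62)
  )
  # 3-min interruption splits into two sub-60 runs: all wear
  expect_equal(
    wear_of(c(rep(0, 30), rep(50, 3), rep(0, 30))),
    rep(TRUE, 63)
  )
  # empty series
  expect_equal(nrow(detect_nonwear(minute_series(integer()))), 0L)
})

test_that("detect_nonwear equals the brute-force window scanner", {
  set.seed(42)
  for (rep in 1:30) {
    n <- sample(200:3000, 1)
    counts <- sample(
      c(0L, 0L, 0L, sample(1:100, 5), sample(101:2000, 5)),
      n, replace = TRUE
    )
    got <- !detect_nonwear(minute_series(counts))$wear
    want <- brute_nonwear(counts)
    expect_identical(got, want)
  }
  # boundary case the greedy maximal-run reading would get wrong
  tricky <- c(rep(0L, 59), rep(50L, 3), rep(0L, 59))
  expect_identical(
    !detect_nonwear(minute_series(tricky))$wear,
    brute_nonwear(tricky)
  )
})

test_that("ground-truth wear is recovered for separated long bouts", {
  spec <- epoch_sim_spec(
    n_days = 3,
    wear_bouts = data.frame(
      day = rep(1:3, each = 2),
      start = rep(c(420, 800), 3),
      end = rep(c(700, 1200), 3),
      level = 300
    ),
    seed = 21
  )
  sim <- simulate_epoch_stream(spec)
  minutes <- collapse_epochs(sim$epochs)
  got_wear <- detect_nonwear(minutes)$wear
  expect_identical(got_wear, sim$truth$wear)
})

test_that("classify_minutes applies the 100 cpm cut-point on worn minutes", {
  m <- minute_series(c(99, 100, 0, 250))
  m$wear <- c(TRUE, TRUE, FALSE, TRUE)
  lab <- classify_minutes(m)
  expect_equal(as.character(lab$label), c("sb", "pa", "nonwear", "pa"))
  expect_error(classify_minutes(m, wear = c(TRUE, FALSE)), "not aligned")
  expect_error(classify_minutes(minute_series(1:3)), "wear")
})

test_that("summarize_days counts minutes and applies the 500-min validity rule", {
  counts <- c(rep(50, 400), rep(300, 300), rep(0, 740))
  m <- minute_series(counts)
  m$wear <- c(rep(TRUE, 700), rep(FALSE, 740))
  d <- summarize_days(classify_minutes(m))
  expect_equal(d$sb_min, 400)
  expect_equal(d$pa_min, 300)
  expect_equal(d$wear_min, 700)
  expect_true(d$valid_day)
  # conservation: labels partition the recorded minutes
  lab <- classify_minutes(m)
  expect_equal(sum(table(lab$label)), nrow(m))
  # 499 wear minutes -> invalid
  m2 <- minute_series(rep(150, 499))
  m2$wear <- TRUE
  expect_false(summarize_days(classify_minutes(m2))$valid_day)
  # all non-wear -> zero everything, invalid
  m3 <- minute_series(rep(0, 1440))
  m3$wear <- FALSE
  d3 <- summarize_days(classify_minutes(m3))
  expect_equal(c(d3$wear_min, d3$sb_min, d3$pa_min), c(0, 0, 0))
  expect_false(d3$valid_day)
  # duplicate minutes -> error
  expect_error(
    summarize_days(classify_minutes(dplyr::bind_rows(m2, m2), wear = rep(TRUE, 998))),
    "Duplicate"
  )
})

test_that("raising the wear threshold never increases valid days", {
  set.seed(8)
  sim <- simulate_demo_epochs(n_persons = 3, n_days = 7, seed = 8)
  minutes <- collapse_epochs(sim$epochs)
  lab <- classify_minutes(detect_nonwear(minutes))
  prev <- Inf
  for (thr in c(300, 500, 700, 900)) {
    nv <- sum(summarize_days(lab, min_wear = thr)$valid_day)
    expect_lte(nv, prev)
    prev <- nv
  }
})

day_record <- function(person, dates, valid) {
  tibble::tibble(
    person_id = person, date = as.Date(dates),
    is_weekend = format(as.Date(dates), "%u") %in% c("6", "7"),
    wear_min = ifelse(valid, 700, 400),
    sb_min = ifelse(valid, 450, 250), pa_min = ifelse(valid, 250, 150),
    valid_day = valid
  )
}

test_that("apply_protocol needs >= 4 valid days including a weekend day", {
  mon_sun <- as.Date("2022-01-03") + 0:6 # Mon..Sun
  # 7 valid days -> included
  expect_true(apply_protocol(day_record("a", mon_sun, rep(TRUE, 7)))$included)
  # 5 valid weekdays, no weekend -> excluded
  expect_false(
    apply_protocol(day_record("b", mon_sun, c(rep(TRUE, 5), FALSE, FALSE)))$included
  )
  # 3 valid days incl. Saturday -> excluded
  expect_false(
    apply_protocol(
      day_record("c", mon_sun, c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE))
    )$included
  )
})

test_that("build_panel indexes days, masks invalid days, centers predictors", {
  mon_sun <- as.Date("2022-01-03") + 0:6
  days <- dplyr::bind_rows(
    day_record("a", mon_sun, rep(TRUE, 7)),
    day_record("b", mon_sun, c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  )
  preds <- tibble::tibble(person_id = c("a", "b"), pain = c(2, 4),
                          fatigue = c(1, 1), wellbeing = c(5, 7))
  panel <- build_panel(days, preds)
  expect_equal(nrow(panel), 14)
  expect_equal(panel$day_index[panel$person_id == "a"], 1:7)
  expect_true(is.na(panel$sb_min[panel$person_id == "b" & panel$day_index == 4]))
  expect_equal(unique(panel$pain_c[panel$person_id == "a"]), -1)
  expect_equal(unique(panel$pain_c[panel$person_id == "b"]), 1)
  # person without predictor dropped with warning
  preds2 <- preds[1, ]
  expect_warning(p2 <- build_panel(days, preds2), "without predictor")
  expect_equal(unique(p2$person_id), "a")
})

test_that("full-size protocol pass yields the expected panel shape", {
  mon_sun <- as.Date("2022-01-03") + 0:6
  days <- dplyr::bind_rows(lapply(sprintf("s%02d", 1:41), function(p) {
    day_record(p, mon_sun, rep(TRUE, 7))
  }))
  preds <- tibble::tibble(
    person_id = sprintf("s%02d", 1:41), pain = rep(c(0, 2, 4), length.out = 41),
    fatigue = 3, wellbeing = 6
  )
  panel <- build_panel(days, preds)
  expect_equal(nrow(panel), 287)
  expect_equal(sum(is.na(panel$sb_min)), 0)
})
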