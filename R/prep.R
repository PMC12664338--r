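#' Collapse 10 s epochs to 60 s counts-per-minute
#'
#' Each minute's count is the sum of its six 10 s counts. The series must
#' start on a minute boundary; leading epochs before the first boundary are
#' truncated, and a trailing incomplete minute is dropped, both with a
#' warning (counts are never fabricated by zero padding).
#'
#' @param epochs Tibble `person_id`, `timestamp` (POSIXct, equally spaced
#'   10 s apart per person), `counts` (non-negative).
#' @returns Tibble `person_id`, `timestamp` (minute boundaries), `counts`
#'   (cpm).
#' @export
collapse_epochs <- function(epochs) {
  check_epoch_frame(epochs)
  epochs |>
    dplyr::group_by(.data$person_id) |>
    dplyr::group_modify(~ collapse_one(.x)) |>
    dplyr::ungroup()
}

check_epoch_frame <- function(epochs, expect_len = 10) {
  stopifnot(
    is.data.frame(epochs),
    all(c("person_id", "timestamp", "counts") %in% names(epochs))
  )
  if (any(epochs$counts < 0, na.rm = TRUE)) abort("Epoch counts must be >= 0.")
  by_p <- split(as.numeric(epochs$timestamp), epochs$person_id)
  for (pid in names(by_p)) {
    ts <- by_p[[pid]]
    if (is.unsorted(ts, strictly = TRUE)) {
      bad <- which(diff(ts) <= 0)[1] + 1L
      abort(sprintf(
        "Timestamps for person %s are not strictly increasing (row %d of that person).",
        pid, bad
      ))
    }
    d <- unique(diff(ts))
    if (length(ts) > 1 && (length(d) != 1 || d != expect_len)) {
      abort(sprintf(
        "Person %s: epochs are not equally spaced at %d s (unsupported resolution).",
        pid, as.integer(expect_len)
      ))
    }
  }
  invisible(epochs)
}

collapse_one <- function(x) {
  sec <- as.numeric(x$timestamp) %% 60
  first <- which(sec == 0)[1]
  if (is.na(first)) {
    warn("No minute boundary in series; nothing to collapse.")
    return(tibble(timestamp = x$timestamp[0], counts = integer()))
  }
  if (first > 1) {
    warn(sprintf("Truncated %d leading epoch(s) before the first minute boundary.", first - 1L))
    x <- x[first:nrow(x), , drop = FALSE]
  }
  n_min <- nrow(x) %/% 6L
  dropped <- nrow(x) - n_min * 6L
  if (dropped > 0) {
    warn(sprintf("Dropped %d trailing epoch(s) forming an incomplete minute.", dropped))
  }
  if (n_min == 0) {
    return(tibble(timestamp = x$timestamp[0], counts = integer()))
  }
  idx <- seq_len(n_min * 6L)
  tibble(
    timestamp = x$timestamp[seq(1, n_min * 6L, by = 6L)],
    counts = as.integer(tapply(x$counts[idx], rep(seq_len(n_min), each = 6L), sum))
  )
}

#' Detect non-wear time in a 60 s count series
#'
#' A minute is non-wear iff it lies inside at least one window of
#' `min_window_min` or more consecutive minutes in which every count is
#' `<= low_count_max` and at most `allowance_min` minutes have counts
#' strictly between 0 and `low_count_max` (inclusive upper end). Any minute
#' with a count above `low_count_max` terminates every window through it.
#' Allowance minutes count toward window length and are non-wear when inside
#' a detected window. Detection runs over each person's whole series, so
#' windows may span midnight.
#'
#' @param minutes Tibble `person_id`, `timestamp` (60 s spacing), `counts`.
#' @param min_window_min Minimum window length in minutes (default 60).
#' @param allowance_min Allowed low-but-nonzero minutes per window (default 2).
#' @param low_count_max Upper cpm bound for "low" counts (default 100).
#' @returns Input tibble plus logical column `wear`.
#' @export
detect_nonwear <- function(minutes, min_window_min = 60, allowance_min = 2,
                           low_count_max = 100) {
  check_epoch_frame(minutes, expect_len = 60)
  minutes |>
    dplyr::group_by(.data$person_id) |>
    dplyr::mutate(wear = !nonwear_mask(
      .data$counts, min_window_min, allowance_min, low_count_max
    )) |>
    dplyr::ungroup()
}

# Two-pointer sweep. For each window end `r`, `l` is the smallest start such
# that [l, r] contains no blocker (count > low) and <= allowance interruption
# minutes; the maximal valid window ending at r is [l, r], and every valid
# window is contained in one of these, so marking them marks the union.
nonwear_mask <- function(counts, min_window_min, allowance_min, low_count_max) {
  n <- length(counts)
  mask <- logical(n)
  if (n == 0) return(mask)
  interrupt <- counts > 0 & counts <= low_count_max
  blocker <- counts > low_count_max
  l <- 1L
  n_int <- 0L
  for (r in seq_len(n)) {
    if (blocker[r]) {
      l <- r + 1L
      n_int <- 0L
      next
    }
    if (interrupt[r]) n_int <- n_int + 1L
    while (n_int > allowance_min) {
      if (interrupt[l]) n_int <- n_int - 1L
      l <- l + 1L
    }
    if (r - l + 1L >= min_window_min) {
      mask[l:r] <- TRUE
    }
  }
  mask
}

#' Classify worn minutes into sedentary behavior and physical activity
#'
#' Non-wear minutes are labelled `nonwear` regardless of count; wear minutes
#' with counts below the cut-point are `sb`, the rest `pa` (default cut-point
#' 100 cpm: `< 100` sedentary, `>= 100` active).
#'
#' @param minutes Tibble as returned by [detect_nonwear()] (needs a `wear`
#'   column), or supply `wear` explicitly.
#' @param cutpoint_cpm Intensity cut-point (default 100).
#' @param wear Optional logical vector overriding `minutes$wear`; must align
#'   with the rows of `minutes`.
#' @returns Input tibble plus factor column `label` with levels
#'   `nonwear`, `sb`, `pa`.
#' @export
classify_minutes <- function(minutes, cutpoint_cpm = 100, wear = NULL) {
  stopifnot(is.data.frame(minutes))
  if (is.null(wear)) {
    if (!"wear" %in% names(minutes)) {
      abort("`minutes` has no `wear` column; run detect_nonwear() first or pass `wear`.")
    }
    wear <- minutes$wear
  }
  if (length(wear) != nrow(minutes) || anyNA(wear)) {
    abort("Wear mask is not aligned with the minute series.")
  }
  minutes |>
    dplyr::mutate(label = factor(
      dplyr::case_when(
        !wear ~ "nonwear",
        minutes$counts < cutpoint_cpm ~ "sb",
        TRUE ~ "pa"
      ),
      levels = c("nonwear", "sb", "pa")
    ))
}

#' Summarize labelled minutes into day records
#'
#' Counts SB, PA and wear minutes per person-day: `wear_min = sb_min +
#' pa_min`, and marks a day valid when wear time reaches `min_wear` minutes
#' (default 500). Partial first/last days are summarized as-is; the validity
#' rule handles shortness. Weekend = Saturday or Sunday.
#'
#' @param labelled Tibble from [classify_minutes()] (`person_id`, `timestamp`,
#'   `label`).
#' @param min_wear Minimum daily wear minutes for a valid day (default 500).
#' @returns Tibble `person_id`, `date`, `is_weekend`, `wear_min`, `sb_min`,
#'   `pa_min`, `valid_day`.
#' @export
summarize_days <- function(labelled, min_wear = 500) {
  stopifnot(all(c("person_id", "timestamp", "label") %in% names(labelled)))
  if (anyDuplicated(labelled[c("person_id", "timestamp")]) > 0) {
    abort("Duplicate minutes for a person-day.")
  }
  labelled |>
    dplyr::mutate(date = as.Date(.data$timestamp, tz = "UTC")) |>
    dplyr::group_by(.data$person_id, .data$date) |>
    dplyr::summarise(
      sb_min = sum(.data$label == "sb"),
      pa_min = sum(.data$label == "pa"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      is_weekend = format(.data$date, "%u") %in% c("6", "7"),
      wear_min = .data$sb_min + .data$pa_min,
      valid_day = .data$wear_min >= min_wear
    ) |>
    dplyr::select(
      "person_id", "date", "is_weekend", "wear_min", "sb_min", "pa_min",
      "valid_day"
    )
}

#' Apply the wear-protocol inclusion rule
#'
#' A person is included when they have at least `min_valid_days` valid days
#' of which at least `require_weekend_days` fall on a weekend (valid day =
#' wear time at/above the daily threshold, as set in [summarize_days()]).
#'
#' @param days Day-record tibble from [summarize_days()].
#' @param min_valid_days Minimum number of valid days (default 4).
#' @param require_weekend_days Minimum valid weekend days (default 1).
#' @returns Tibble `person_id`, `n_valid_days`, `n_valid_weekend_days`,
#'   `has_valid_weekend_day`, `included`.
#' @export
apply_protocol <- function(days, min_valid_days = 4, require_weekend_days = 1) {
  stopifnot(all(c("person_id", "is_weekend", "valid_day") %in% names(days)))
  days |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(
      n_valid_days = sum(.data$valid_day),
      n_valid_weekend_days = sum(.data$valid_day & .data$is_weekend),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      has_valid_weekend_day = .data$n_valid_weekend_days >= 1,
      included = .data$n_valid_days >= min_valid_days &
        .data$n_valid_weekend_days >= require_weekend_days
    )
}

#' Join day records with person-level predictors into an analysis panel
#'
#' Keeps persons passing the wear protocol, assigns day index 1..7 by
#' calendar order from each person's first recorded day, re-expresses invalid
#' or unrecorded days as missing, attaches the person-level numeric-rating
#' predictors, and stores grand-mean-centered copies (`*_c` columns, centered
#' over included persons).
#'
#' @param days Day records from [summarize_days()].
#' @param predictors Tibble `person_id` plus numeric predictor columns (e.g.
#'   `pain`, `fatigue`, `wellbeing` on the 0-10 NRS).
#' @param validity Optional inclusion table from [apply_protocol()]; computed
#'   with default thresholds when omitted.
#' @param max_days Panel length per person (default 7); later days dropped
#'   with a warning.
#' @returns Panel tibble: `person_id`, `day_index`, `date`, `is_weekend`,
#'   `wear_min`, `sb_min`, `pa_min`, `valid_day`, predictor and `*_c`
#'   columns. Invalid/unrecorded days have `NA` minutes.
#' @export
build_panel <- function(days, predictors, validity = NULL, max_days = 7L) {
  stopifnot(is.data.frame(predictors), "person_id" %in% names(predictors))
  if (is.null(validity)) validity <- apply_protocol(days)
  included <- validity$person_id[validity$included]
  no_pred <- setdiff(included, predictors$person_id)
  if (length(no_pred) > 0) {
    warn(paste0(
      "Dropping person(s) without predictor values: ",
      paste(no_pred, collapse = ", ")
    ))
    included <- setdiff(included, no_pred)
  }
  if (length(included) == 0) abort("No included persons with predictors.")
  pred_cols <- setdiff(names(predictors), "person_id")
  grid <- days |>
    dplyr::filter(.data$person_id %in% included) |>
    dplyr::group_by(.data$person_id) |>
    dplyr::mutate(day_index = as.integer(.data$date - min(.data$date)) + 1L) |>
    dplyr::ungroup()
  if (any(grid$day_index > max_days)) {
    warn(sprintf("Dropping day records beyond day %d.", max_days))
    grid <- dplyr::filter(grid, .data$day_index <= max_days)
  }
  first_dates <- grid |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(first_date = min(.data$date), .groups = "drop")
  full <- tidyr::expand_grid(
    person_id = sort(included), day_index = seq_len(max_days)
  ) |>
    dplyr::left_join(first_dates, by = "person_id") |>
    dplyr::mutate(date = .data$first_date + .data$day_index - 1L) |>
    dplyr::select(-"first_date") |>
    dplyr::mutate(is_weekend = format(.data$date, "%u") %in% c("6", "7")) |>
    dplyr::left_join(
      dplyr::select(grid, "person_id", "day_index", "wear_min", "sb_min",
                    "pa_min", "valid_day"),
      by = c("person_id", "day_index")
    ) |>
    dplyr::mutate(
      valid_day = !is.na(.data$valid_day) & .data$valid_day,
      wear_min = ifelse(.data$valid_day, .data$wear_min, NA_real_),
      sb_min = ifelse(.data$valid_day, .data$sb_min, NA_real_),
      pa_min = ifelse(.data$valid_day, .data$pa_min, NA_real_)
    ) |>
    dplyr::left_join(
      predictors[predictors$person_id %in% included, , drop = FALSE],
      by = "person_id"
    )
  for (pc in pred_cols) {
    person_vals <- full |>
      dplyr::distinct(.data$person_id, .keep_all = TRUE) |>
      dplyr::pull(pc)
    full[[paste0(pc, "_c")]] <- full[[pc]] - mean(person_vals)
  }
  full
}
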