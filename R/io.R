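PANEL_COLS <- c(
  "person_id", "day_index", "date", "is_weekend", "wear_min", "sb_min",
  "pa_min", "valid_day", "pain", "fatigue", "wellbeing"
)

#' Read / write epoch-level count streams
#'
#' Epoch CSV dialect: `person_id`, `timestamp` (ISO-8601, UTC), `counts`.
#' ActiGraph-style exports with header banners can be read by skipping the
#' banner lines. Timestamps must be strictly increasing within person.
#'
#' @param path File path.
#' @param skip Number of banner lines to skip before the header (default 0).
#' @returns Tibble `person_id`, `timestamp` (POSIXct UTC), `counts`.
#' @export
read_epochs <- function(path, skip = 0) {
  x <- readr::read_csv(
    path, skip = skip,
    col_types = readr::cols(
      person_id = readr::col_character(),
      timestamp = readr::col_datetime(),
      counts = readr::col_integer()
    ),
    na = "", progress = FALSE
  )
  if (anyNA(x$timestamp) || anyNA(x$counts)) {
    bad <- which(is.na(x$timestamp) | is.na(x$counts))[1]
    abort(sprintf("Malformed epoch CSV: unparseable value at data row %d.", bad))
  }
  if (any(x$counts < 0)) {
    abort(sprintf("Negative count at data row %d.", which(x$counts < 0)[1]))
  }
  for (pid in unique(x$person_id)) {
    idx <- which(x$person_id == pid)
    ts <- as.numeric(x$timestamp[idx])
    if (is.unsorted(ts, strictly = TRUE)) {
      bad <- idx[which(diff(ts) <= 0)[1] + 1L]
      abort(sprintf(
        "Non-monotone timestamp for person %s at data row %d.", pid, bad
      ))
    }
  }
  x
}

#' @rdname read_epochs
#' @param epochs Epoch tibble to write.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(all(c("person_id", "timestamp", "counts") %in% names(epochs)))
  readr::write_csv(epochs[c("person_id", "timestamp", "counts")], path, na = "")
  invisible(path)
}

#' Read / write person-day panels
#'
#' Panel CSV dialect: `person_id`, `day_index` (1-7), `date`, `is_weekend`,
#' `wear_min`, `sb_min`, `pa_min`, `valid_day`, `pain`, `fatigue`,
#' `wellbeing`; missing values are empty fields. `read_panel(write_panel(x))`
#' returns `x` (dialect columns).
#'
#' @param path File path.
#' @returns Panel tibble.
#' @export
read_panel <- function(path) {
  x <- readr::read_csv(
    path,
    col_types = readr::cols(
      person_id = readr::col_character(),
      day_index = readr::col_integer(),
      date = readr::col_date(),
      is_weekend = readr::col_logical(),
      wear_min = readr::col_double(),
      sb_min = readr::col_double(),
      pa_min = readr::col_double(),
      valid_day = readr::col_logical(),
      pain = readr::col_double(),
      fatigue = readr::col_double(),
      wellbeing = readr::col_double()
    ),
    na = "", progress = FALSE
  )
  validate_panel(x)
  x
}

validate_panel <- function(x) {
  missing_cols <- setdiff(PANEL_COLS, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("Panel is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (any(x$day_index < 1 | x$day_index > 7)) {
    abort("Panel validation: day_index must be in 1..7.")
  }
  if (anyDuplicated(x[c("person_id", "day_index")]) > 0) {
    abort("Panel validation: duplicate (person_id, day_index).")
  }
  invisible(x)
}

#' @rdname read_panel
#' @param panel Panel tibble to write (extra columns such as the centered
#'   `*_c` copies are dropped; the dialect is fixed).
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  readr::write_csv(panel[PANEL_COLS], path, na = "")
  invisible(path)
}

#' Write posterior draws as long-format CSV
#'
#' Columns `chain`, `draw`, `parameter`, `value`. Parameters are the
#' between-level quantities (`gamma0[...]`, `gamma1[...]`, `tau[...]`,
#' `sigma_mu`), all person effects (`u[<person>,<effect>]`), imputed states
#' on missing days (`w[<person>,<day>,<series>]`), and the conditional
#' deviance (`deviance`).
#'
#' @param fit A [dsem_fit()] object.
#' @param path File path.
#' @export
write_draws <- function(fit, path) {
  stopifnot(inherits(fit, "dsem_fit"))
  parts <- purrr::map_dfr(seq_along(fit$chains), function(k) {
    ch <- fit$chains[[k]]
    n <- ch$n_keep
    fx <- as_tibble(ch$fixed) |>
      dplyr::mutate(draw = seq_len(n)) |>
      tidyr::pivot_longer(-"draw", names_to = "parameter", values_to = "value")
    eff <- purrr::map_dfr(seq_along(fit$persons), function(i) {
      m <- ch$effects[, i, , drop = TRUE]
      m <- matrix(m, nrow = n, ncol = 8)
      colnames(m) <- sprintf("u[%s,%s]", fit$persons[i], EFFECTS)
      as_tibble(m) |>
        dplyr::mutate(draw = seq_len(n)) |>
        tidyr::pivot_longer(-"draw", names_to = "parameter", values_to = "value")
    })
    miss <- which(!fit$obs, arr.ind = TRUE)
    st <- NULL
    if (nrow(miss) > 0) {
      st <- purrr::map_dfr(seq_len(nrow(miss)), function(j) {
        i <- miss[j, 1]; t <- miss[j, 2]
        tibble(
          draw = rep(seq_len(n), 2),
          parameter = rep(sprintf(
            "w[%s,%d,%s]", fit$persons[i], t, c("sb", "pa")
          ), each = n),
          value = c(ch$states[, i, t], ch$states[, i, fit$t_days + t])
        )
      })
    }
    dev <- tibble(
      draw = seq_len(n), parameter = "deviance", value = as.vector(ch$deviance)
    )
    dplyr::bind_rows(fx, eff, st, dev) |>
      dplyr::mutate(chain = k, .before = 1)
  })
  readr::write_csv(parts, path, na = "")
  invisible(path)
}

#' Read a long-format draws CSV
#'
#' @param path File path.
#' @returns Tibble `chain`, `draw`, `parameter`, `value`.
#' @export
read_draws <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      chain = readr::col_integer(), draw = readr::col_integer(),
      parameter = readr::col_character(), value = readr::col_double()
    ),
    na = "", progress = FALSE
  )
}

#' Write a results or descriptives table as CSV
#'
#' @param x Tibble (e.g. from [dsem_table()] or [descriptives()]).
#' @param path File path.
#' @export
write_summary <- function(x, path) {
  readr::write_csv(x, path, na = "")
  invisible(path)
}

# Deterministic JSON manifest (sorted keys, no wall-clock values).
write_manifest <- function(x, path) {
  x <- x[order(names(x))]
  jsonlite::write_json(
    x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  invisible(path)
}
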