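#' Specification for a synthetic epoch-level accelerometer stream
#'
#' Describes, per simulated day, where the device was worn (bouts with a mean
#' counts-per-minute level) and where it was off (forced-zero intervals).
#' Minutes covered by no wear bout are non-wear (zero counts). Counts are
#' drawn per 10 s epoch as Poisson around `level / 6`, giving non-negative
#' integers with realistic dispersion.
#'
#' @param n_days Number of simulated days.
#' @param wear_bouts Data frame with columns `day`, `start`, `end`, `level`:
#'   half-open minute intervals `[start, end)` within `[0, 1440)` and a mean
#'   cpm level `>= 0`.
#' @param nonwear_bouts Optional data frame `day`, `start`, `end` of intervals
#'   forced to zero counts (must not overlap wear bouts).
#' @param noise One of `"poisson"` (default) or `"constant"` (each epoch gets
#'   exactly `level / 6`, useful for exact fixtures).
#' @param seed Integer seed; the stream is a deterministic function of it.
#' @param person_id Identifier written into the stream.
#' @param start_date First calendar day of the stream.
#' @returns An object of class `epoch_sim_spec`.
#' @export
epoch_sim_spec <- function(n_days,
                           wear_bouts,
                           nonwear_bouts = NULL,
                           noise = c("poisson", "constant"),
                           seed = 1L,
                           person_id = "sim-01",
                           start_date = as.Date("2022-01-03")) {
  noise <- match.arg(noise)
  stopifnot(n_days >= 1, is.data.frame(wear_bouts))
  wear_bouts <- as_tibble(wear_bouts)
  if (nrow(wear_bouts) > 0) {
    stopifnot(all(c("day", "start", "end", "level") %in% names(wear_bouts)))
    check_bouts(wear_bouts, n_days)
    if (any(wear_bouts$level < 0)) abort("Bout levels must be >= 0.")
  }
  if (!is.null(nonwear_bouts) && nrow(nonwear_bouts) > 0) {
    nonwear_bouts <- as_tibble(nonwear_bouts)
    stopifnot(all(c("day", "start", "end") %in% names(nonwear_bouts)))
    check_bouts(dplyr::bind_rows(
      wear_bouts[c("day", "start", "end")],
      nonwear_bouts[c("day", "start", "end")]
    ), n_days)
  }
  structure(
    list(
      n_days = as.integer(n_days), wear_bouts = wear_bouts,
      nonwear_bouts = nonwear_bouts, noise = noise, seed = as.integer(seed),
      person_id = person_id, start_date = as.Date(start_date)
    ),
    class = "epoch_sim_spec"
  )
}

check_bouts <- function(bouts, n_days) {
  if (any(bouts$start < 0 | bouts$end > 1440 | bouts$start >= bouts$end)) {
    abort("Bout minute indices must satisfy 0 <= start < end <= 1440.")
  }
  if (any(bouts$day < 1 | bouts$day > n_days)) {
    abort("Bout `day` outside 1..n_days.")
  }
  by_day <- split(bouts, bouts$day)
  for (b in by_day) {
    b <- b[order(b$start), , drop = FALSE]
    if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)])) {
      i <- which(b$start[-1] < b$end[-nrow(b)])[1]
      abort(sprintf(
        "Overlapping bouts on day %d: [%d, %d) and [%d, %d).",
        b$day[1], b$start[i], b$end[i], b$start[i + 1], b$end[i + 1]
      ))
    }
  }
  invisible(bouts)
}

#' Simulate a 10 s epoch count stream with known wear ground truth
#'
#' Emulates a hip-worn accelerometer recording vertical-axis activity counts
#' in 10 s epochs: six epochs per minute, 1440 minutes per day. Counts inside
#' wear bouts are drawn around the bout's cpm level; all other minutes are
#' exactly zero.
#'
#' @param spec An [epoch_sim_spec()].
#' @returns A list with `epochs` — tibble `person_id`, `timestamp` (POSIXct,
#'   UTC, 10 s grid), `counts` (integer) — and `truth` — tibble `person_id`,
#'   `date`, `minute` (0-based minute of day), `wear` (logical ground truth).
#' @examples
#' spec <- epoch_sim_spec(1, data.frame(day = 1, start = 480, end = 500, level = 300))
#' str(simulate_epoch_stream(spec)$epochs)
#' @export
simulate_epoch_stream <- function(spec) {
  stopifnot(inherits(spec, "epoch_sim_spec"))
  set.seed(spec$seed)
  n_min_day <- 1440L
  out <- vector("list", spec$n_days)
  truth <- vector("list", spec$n_days)
  for (d in seq_len(spec$n_days)) {
    level <- numeric(n_min_day) # cpm level per minute; 0 = non-wear
    wear <- logical(n_min_day)
    wb <- spec$wear_bouts[spec$wear_bouts$day == d, , drop = FALSE]
    for (j in seq_len(nrow(wb))) {
      idx <- (wb$start[j] + 1L):wb$end[j]
      level[idx] <- wb$level[j]
      wear[idx] <- TRUE
    }
    lev_epoch <- rep(level / 6, each = 6L)
    counts <- if (spec$noise == "poisson") {
      rpois(length(lev_epoch), lev_epoch)
    } else {
      as.integer(round(lev_epoch))
    }
    counts[rep(!wear, each = 6L)] <- 0L
    date <- spec$start_date + (d - 1L)
    ts0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
    out[[d]] <- tibble(
      person_id = spec$person_id,
      timestamp = ts0 + seq(0, by = 10, length.out = length(counts)),
      counts = as.integer(counts)
    )
    truth[[d]] <- tibble(
      person_id = spec$person_id, date = date,
      minute = 0:(n_min_day - 1L), wear = wear
    )
  }
  list(epochs = dplyr::bind_rows(out), truth = dplyr::bind_rows(truth))
}

#' Default between-level truth for panel simulation
#'
#' The stated world of the generator: intercepts and random-effect variances
#' at the magnitudes reported for hip-worn accelerometry in adults with a
#' sedentary-dominant day (latent means ~460/245 min/d of SB/PA, weak positive
#' autoregression, near-zero cross-lags, log innovation variances ~9.1/8.1,
#' strongly negative latent-mean covariance), with predictor slopes zero.
#'
#' @returns A [dsem_params()] object.
#' @export
default_truth <- function() {
  dsem_params(
    gamma0 = c(
      mu_sb = 460, mu_pa = 245, phi_sb = 0.18, phi_pa = 0.05,
      beta_sb = -0.01, beta_pa = -0.02, logpsi_sb = 9.10, logpsi_pa = 8.12
    ),
    gamma1 = 0,
    tau = c(
      mu_sb = 13876, mu_pa = 10851, phi_sb = 0.07, phi_pa = 0.06,
      beta_sb = 0.22, beta_pa = 0.01, logpsi_sb = 0.19, logpsi_pa = 1.03
    ),
    sigma_mu = -6871
  )
}

#' Specification for a synthetic person-day movement-behavior panel
#'
#' @param n_persons Number of persons (`>= 2` for hierarchical use; `1`
#'   allowed for single-subject checks). Default 41.
#' @param t_days Days per person. Default 7.
#' @param truth A [dsem_params()] object; defaults to [default_truth()].
#' @param predictor_mean,predictor_sd Person-level predictor distribution on
#'   the 0-10 numeric rating scale; defaults 1.9 and 2.4 (pain-like). Draws
#'   are truncated to `[0, 10]` by resampling.
#' @param missing_day_prob Probability a person-day is missing. Default 0.
#' @param seed Integer seed.
#' @param clamp If `TRUE`, clamp simulated minutes into `[0, 1440]`. Off by
#'   default: the fitted model is Gaussian and truncation would bias recovery.
#' @returns An object of class `panel_sim_spec`.
#' @export
panel_sim_spec <- function(n_persons = 41L, t_days = 7L,
                           truth = default_truth(),
                           predictor_mean = 1.9, predictor_sd = 2.4,
                           missing_day_prob = 0, seed = 1L,
                           clamp = FALSE) {
  stopifnot(
    n_persons >= 1, t_days >= 2,
    missing_day_prob >= 0, missing_day_prob < 1,
    predictor_sd >= 0
  )
  validate_dsem_params(truth)
  structure(
    list(
      n_persons = as.integer(n_persons), t_days = as.integer(t_days),
      truth = truth, predictor_mean = predictor_mean,
      predictor_sd = predictor_sd, missing_day_prob = missing_day_prob,
      seed = as.integer(seed), clamp = isTRUE(clamp)
    ),
    class = "panel_sim_spec"
  )
}

rmvnorm2 <- function(mean, V) {
  L <- chol(V + diag(1e-12 * max(1, diag(V)), nrow = 2))
  drop(mean + t(L) %*% rnorm(2))
}

#' Simulate a person-day SB/PA panel from the DSEM generative model
#'
#' For each person: draws the predictor, draws the eight random effects from
#' the between-level model (rejection-sampling until the implied VAR(1) is
#' stationary), draws the day-1 deviations from the person's stationary
#' distribution, iterates the within equations, and emits
#' `SB_it = mu_sb_i + w_sb_it`, `PA_it = mu_pa_i + w_pa_it`. Days are then
#' masked missing at `missing_day_prob`.
#'
#' @param spec A [panel_sim_spec()].
#' @returns List with `panel` — tibble in the panel dialect (`person_id`,
#'   `day_index`, `date`, `is_weekend`, `wear_min`, `sb_min`, `pa_min`,
#'   `valid_day`, `pain`, `fatigue`, `wellbeing`; simulated days carry the
#'   predictor in all three symptom columns' chosen one, see Details) — and
#'   `effects` — tibble of realized person effects (ground truth) plus
#'   `predictor` and `rejections` (count of non-stationary redraws).
#'
#' @details The single simulated person-level predictor is stored in the
#'   `pain` column; `fatigue` and `wellbeing` are filled with independent
#'   NRS-like draws so the panel dialect is complete. `wear_min` is emitted as
#'   `sb_min + pa_min` and `valid_day` as `TRUE` for observed days.
#' @export
simulate_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_sim_spec"))
  set.seed(spec$seed)
  tr <- spec$truth
  N <- spec$n_persons
  T <- spec$t_days
  ids <- sprintf("p%02d", seq_len(N))
  draw_nrs <- function(n, m, s) {
    x <- rnorm(n, m, s)
    bad <- which(x < 0 | x > 10)
    k <- 0
    while (length(bad) > 0 && k < 1000) {
      x[bad] <- rnorm(length(bad), m, s)
      bad <- which(x < 0 | x > 10)
      k <- k + 1
    }
    pmin(pmax(x, 0), 10)
  }
  P <- draw_nrs(N, spec$predictor_mean, spec$predictor_sd)
  Pc <- P - mean(P)
  eff <- matrix(NA_real_, N, 8, dimnames = list(ids, EFFECTS))
  rejections <- integer(N)
  panel <- vector("list", N)
  dates <- as.Date("2022-01-03") + seq_len(T) - 1L
  for (i in seq_len(N)) {
    be <- between_equations(tr, Pc[i])
    repeat {
      u <- be$mean
      u[c("mu_sb", "mu_pa")] <- rmvnorm2(
        be$mean[c("mu_sb", "mu_pa")],
        be$cov[c("mu_sb", "mu_pa"), c("mu_sb", "mu_pa")]
      )
      rest <- setdiff(EFFECTS, c("mu_sb", "mu_pa"))
      u[rest] <- rnorm(length(rest), be$mean[rest], sqrt(tr$tau[rest]))
      if (spectral_radius(lag_matrix(u)) < 1 - 1e-8) break
      rejections[i] <- rejections[i] + 1L
      if (rejections[i] > 10000L) {
        abort("Could not draw stationary person dynamics after 10000 tries.")
      }
    }
    eff[i, ] <- u
    V0 <- stationary_covariance(u)
    w <- matrix(NA_real_, T, 2)
    w[1, ] <- rmvnorm2(c(0, 0), V0)
    A <- lag_matrix(u)
    sds <- sqrt(exp(c(u[["logpsi_sb"]], u[["logpsi_pa"]])))
    for (t in seq_len(T)[-1]) {
      w[t, ] <- drop(A %*% w[t - 1, ]) + rnorm(2) * sds
    }
    sb <- u[["mu_sb"]] + w[, 1]
    pa <- u[["mu_pa"]] + w[, 2]
    if (spec$clamp) {
      sb <- pmin(pmax(sb, 0), 1440)
      pa <- pmin(pmax(pa, 0), 1440)
    }
    panel[[i]] <- tibble(
      person_id = ids[i], day_index = seq_len(T), date = dates,
      is_weekend = format(dates, "%u") %in% c("6", "7"),
      sb_min = sb, pa_min = pa
    )
  }
  panel <- dplyr::bind_rows(panel)
  miss <- runif(nrow(panel)) < spec$missing_day_prob
  panel$sb_min[miss] <- NA_real_
  panel$pa_min[miss] <- NA_real_
  fatigue <- round(draw_nrs(N, 3.5, 3.4), 0)
  wellbeing <- round(draw_nrs(N, 6.4, 2.4), 0)
  panel <- panel |>
    dplyr::mutate(
      wear_min = .data$sb_min + .data$pa_min,
      valid_day = !is.na(.data$sb_min)
    ) |>
    dplyr::left_join(
      tibble(
        person_id = ids, pain = P,
        fatigue = fatigue, wellbeing = wellbeing
      ),
      by = "person_id"
    ) |>
    dplyr::select(
      "person_id", "day_index", "date", "is_weekend", "wear_min",
      "sb_min", "pa_min", "valid_day", "pain", "fatigue", "wellbeing"
    )
  effects <- as_tibble(eff) |>
    dplyr::mutate(
      person_id = ids, predictor = P, predictor_centered = Pc,
      rejections = rejections, .before = 1
    )
  list(panel = panel, effects = effects)
}
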