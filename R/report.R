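#' Standardized within-person estimates, averaged across clusters
#'
#' For every posterior draw and person the model-implied stationary
#' covariance \eqn{V_i} of the within deviations is computed (discrete
#' Lyapunov); standardized coefficients follow the model-implied convention:
#' the autoregressions are already standardized (same variable at both lags
#' under stationarity), the cross-lags are rescaled by the ratio of
#' stationary SDs, the standardized residual is the innovation share
#' \eqn{\psi_u / V_u}, and the within R-squared is its complement. Per-draw
#' values are averaged across persons ("clusters"), then summarized over
#' draws. Non-stationary draw/person combinations are excluded from that
#' draw's average and the exclusion rate is reported.
#'
#' @param fit A [dsem_fit()] object.
#' @param level Credibility level (default 0.95).
#' @returns A list of class `dsem_std_within` with
#'   \describe{
#'     \item{summary}{tibble of across-cluster averages (`phi_sb`, `phi_pa`,
#'       `beta_sb`, `beta_pa`, `zeta_sb`, `zeta_pa`, `r2_sb`, `r2_pa`)
#'       summarized over draws;}
#'     \item{person}{tibble of person-level posterior-mean standardized
#'       coefficients;}
#'     \item{antipersistence}{tibble with the share of persons whose
#'       posterior-mean standardized autoregression is negative, per series;}
#'     \item{exclusion_rate}{fraction of draw-person combinations excluded as
#'       non-stationary.}
#'   }
#' @export
standardize_within <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "dsem_fit"))
  arr <- posterior_draws(fit, "effects")
  n_draw <- dim(arr)[1]
  N <- dim(arr)[2]
  flat <- function(k) as.vector(arr[, , k]) # draw-major within person blocks
  phi_sb <- flat(3); phi_pa <- flat(4)
  beta_sb <- flat(5); beta_pa <- flat(6)
  psi_sb <- exp(flat(7)); psi_pa <- exp(flat(8))
  V <- stat_cov_batch_cpp(phi_sb, beta_sb, beta_pa, phi_pa, psi_sb, psi_pa)
  stable <- V[, 1] == 1
  v_sb <- V[, 2]; v_pa <- V[, 3]
  std <- tibble(
    draw = rep(seq_len(n_draw), times = N),
    person = rep(seq_len(N), each = n_draw),
    stable = stable,
    phi_sb = ifelse(stable, phi_sb, NA_real_),
    phi_pa = ifelse(stable, phi_pa, NA_real_),
    beta_sb = ifelse(stable, beta_sb * sqrt(v_pa / v_sb), NA_real_),
    beta_pa = ifelse(stable, beta_pa * sqrt(v_sb / v_pa), NA_real_),
    zeta_sb = ifelse(stable, psi_sb / v_sb, NA_real_),
    zeta_pa = ifelse(stable, psi_pa / v_pa, NA_real_)
  ) |>
    dplyr::mutate(r2_sb = 1 - .data$zeta_sb, r2_pa = 1 - .data$zeta_pa)
  quantities <- c("phi_sb", "phi_pa", "beta_sb", "beta_pa",
                  "zeta_sb", "zeta_pa", "r2_sb", "r2_pa")
  per_draw <- std |>
    dplyr::group_by(.data$draw) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(quantities), ~ mean(.x, na.rm = TRUE)),
      .groups = "drop"
    )
  summary <- purrr::map_dfr(
    quantities,
    ~ summarize_posterior(per_draw[[.x]], parameter = .x, level = level)
  )
  person <- std |>
    dplyr::group_by(.data$person) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(quantities[1:4]), ~ mean(.x, na.rm = TRUE)),
      prop_stable = mean(.data$stable),
      .groups = "drop"
    ) |>
    dplyr::mutate(person_id = fit$persons[.data$person], .before = 1) |>
    dplyr::select(-"person")
  anti <- tibble(
    series = c("sb", "pa"),
    share_negative = c(
      mean(person$phi_sb < 0, na.rm = TRUE),
      mean(person$phi_pa < 0, na.rm = TRUE)
    )
  )
  structure(
    list(
      summary = summary, person = person, antipersistence = anti,
      exclusion_rate = mean(!stable)
    ),
    class = "dsem_std_within"
  )
}

#' @export
print.dsem_std_within <- function(x, ...) {
  cat("Standardized within-person estimates (averaged across clusters)\n")
  print(x$summary)
  cat(sprintf(
    "Antipersistence: %.1f%% (SB), %.1f%% (PA) of persons; %.2f%% of draws non-stationary\n",
    100 * x$antipersistence$share_negative[1],
    100 * x$antipersistence$share_negative[2],
    100 * x$exclusion_rate
  ))
  invisible(x)
}

#' Standardized between-person estimates
#'
#' Standardizes, per posterior draw, the predictor effects on each random
#' effect by \eqn{\gamma_1 \cdot SD(P) / SD(u)} with
#' \eqn{SD(u)^2 = \gamma_1^2 Var(P) + \tau_u}, the latent-mean covariance by
#' the corresponding total between-level SDs, and reports the between-level
#' R-squared \eqn{\gamma_1^2 Var(P) / SD(u)^2}; summaries over draws.
#'
#' @param fit A [dsem_fit()] object (hierarchical).
#' @param level Credibility level.
#' @returns Tibble: one summary row per `u ON predictor` effect, plus
#'   `sigma_mu (std)` and per-effect `r2[u]` rows.
#' @export
standardize_between <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "dsem_fit"))
  if (!fit$config$hierarchical) abort("Between-level standardization needs a hierarchical fit.")
  var_p <- var(fit$pc)
  if (!is.finite(var_p) || var_p <= 0) abort("Predictor variance must be > 0.")
  m <- posterior_draws(fit, "fixed")
  out <- list()
  sd_u <- matrix(NA_real_, nrow(m), 8, dimnames = list(NULL, EFFECTS))
  for (k in seq_along(EFFECTS)) {
    g1 <- m[, paste0("gamma1[", EFFECTS[k], "]")]
    tau <- m[, paste0("tau[", EFFECTS[k], "]")]
    sd_u[, k] <- sqrt(g1^2 * var_p + tau)
    std <- g1 * sqrt(var_p) / sd_u[, k]
    r2 <- g1^2 * var_p / (g1^2 * var_p + tau)
    out[[paste0(EFFECTS[k], " ON predictor")]] <- std
    out[[paste0("r2[", EFFECTS[k], "]")]] <- r2
  }
  out[["sigma_mu (std)"]] <-
    m[, "sigma_mu"] / (sd_u[, "mu_sb"] * sd_u[, "mu_pa"])
  purrr::map_dfr(
    names(out), ~ summarize_posterior(out[[.x]], parameter = .x, level = level)
  )
}

# Spearman rank correlation with average ranks for ties; two-sided p via the
# t approximation.
spearman_rho <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) return(c(rho = NA_real_, p = NA_real_, n = n))
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(c(rho = NA_real_, p = NA_real_, n = n)) # constant input: undefined
  }
  r <- cor(rx, ry)
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  c(rho = r, p = p, n = n)
}

#' Day-wise descriptive statistics of the movement-behavior panel
#'
#' Across-person mean and SD of wear, SB and PA minutes per day index, the SB
#' share of wear time (reported both as the mean of person-level daily ratios
#' and as the ratio of the day's means), and the Spearman correlation between
#' SB and PA minutes across persons with its two-sided p value (average-rank
#' ties, t approximation). Days on which SB or PA is constant across persons
#' get `NA` correlation and are flagged.
#'
#' @param panel Panel tibble (see [build_panel()] / [simulate_panel()]).
#' @returns Tibble with one row per `day_index`.
#' @export
descriptives <- function(panel) {
  stopifnot(all(c("person_id", "day_index", "sb_min", "pa_min") %in% names(panel)))
  if (!"wear_min" %in% names(panel)) {
    panel$wear_min <- panel$sb_min + panel$pa_min
  }
  panel |>
    dplyr::group_by(.data$day_index) |>
    dplyr::group_modify(function(d, key) {
      sp <- spearman_rho(d$sb_min, d$pa_min)
      nan2na <- function(x) if (is.nan(x)) NA_real_ else x
      tibble(
        n = sum(!is.na(d$sb_min)),
        wear_mean = nan2na(mean(d$wear_min, na.rm = TRUE)),
        wear_sd = nan2na(sd(d$wear_min, na.rm = TRUE)),
        sb_mean = nan2na(mean(d$sb_min, na.rm = TRUE)),
        sb_sd = nan2na(sd(d$sb_min, na.rm = TRUE)),
        pa_mean = nan2na(mean(d$pa_min, na.rm = TRUE)),
        pa_sd = nan2na(sd(d$pa_min, na.rm = TRUE)),
        sb_share_mean_ratio = nan2na(mean(d$sb_min / d$wear_min, na.rm = TRUE)),
        sb_share_ratio_means = nan2na(
          mean(d$sb_min, na.rm = TRUE) / mean(d$wear_min, na.rm = TRUE)
        ),
        spearman_r = sp[["rho"]],
        spearman_p = sp[["p"]],
        correlation_defined = !is.na(sp[["rho"]])
      )
    }) |>
    dplyr::ungroup()
}

#' Results table of a fitted DSEM
#'
#' Assembles the standard reporting table for this model class:
#' unstandardized fixed effects, random-effect variances, standardized
#' within-person estimates averaged across clusters, standardized
#' between-level predictor effects with the latent-mean covariance, and
#' within/between R-squared.
#'
#' @param fit A [dsem_fit()] object.
#' @param level Credibility level.
#' @returns Tibble with columns `block`, `parameter`, `estimate`, `mean`,
#'   `conf.low`, `conf.high`, `p`, `significant`.
#' @export
dsem_table <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "dsem_fit"))
  fx <- tidy(fit, level = level)
  g0 <- fx[grepl("^gamma0", fx$parameter), ]
  g0$block <- "fixed effects"
  tau <- fx[grepl("^tau", fx$parameter), ]
  tau$block <- "random-effect variances"
  sw <- standardize_within(fit, level = level)
  within <- sw$summary
  within$block <- "standardized within (averaged across clusters)"
  names(within)[names(within) == "parameter"] <- "parameter"
  sb <- standardize_between(fit, level = level)
  on_pred <- sb[grepl(" ON predictor$", sb$parameter), ]
  on_pred$block <- "standardized between"
  smu <- sb[sb$parameter == "sigma_mu (std)", ]
  smu$block <- "standardized between"
  r2b <- sb[grepl("^r2\\[mu_", sb$parameter) | grepl("^r2\\[", sb$parameter), ]
  r2b$block <- "between R2"
  dplyr::bind_rows(g0, tau, within, on_pred, smu, r2b) |>
    dplyr::select(
      "block", "parameter", "estimate", "mean", "conf.low", "conf.high",
      "p", "significant"
    )
}
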