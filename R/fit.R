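#' Sampler configuration for the movement-behavior DSEM
#'
#' @param iterations Total MCMC iterations per chain (default 50000).
#' @param thin Keep every `thin`-th post-burn-in draw (default 10).
#' @param chains Number of independent chains (default 2).
#' @param burn_in_fraction Fraction of iterations discarded as burn-in
#'   (default 0.5). The adaptive Metropolis step for the log innovation
#'   variances is tuned during burn-in (target acceptance 0.3-0.5) and frozen
#'   afterwards to preserve detailed balance.
#' @param seed Integer seed; chain `k` uses `seed + k - 1`.
#' @param hierarchical If `FALSE`, the between level is dropped and the
#'   person effects get fixed diffuse priors (single-subject mode).
#' @param initial Treatment of the day-1 deviations: `"stationary"`
#'   (default) the person-specific stationary distribution, with a diffuse
#'   fallback for non-stationary draws; `"diffuse"` a near-flat Gaussian,
#'   effectively conditioning on the first observation, as in the standard
#'   commercial DSEM implementation.
#' @param prior_gamma_var,prior_mu_intercept_var Gaussian prior variances for
#'   the between-level regression coefficients; the min/day-scaled latent-mean
#'   intercepts get the larger variance. Diffuse by default.
#' @param prior_tau_shape,prior_tau_rate Inverse-gamma prior for the
#'   random-effect residual variances. The defaults `(-1, 0)` are the flat
#'   (uniform-on-variance) prior used by the standard commercial DSEM
#'   implementation; conjugate-diffuse pairs such as `(0.001, 0.001)` are
#'   accepted but collapse the latent-mean spread on the min/day scale (see
#'   the methods vignette on hyperprior scaling).
#' @param prior_wishart_df,prior_wishart_scale Inverse-Wishart prior for the
#'   2x2 latent-mean covariance block. The defaults `(-3, 0)` give the flat
#'   improper prior (density constant in the covariance); an identity-scale
#'   proper prior would be strongly informative on the min^2/day^2 scale.
#' @param nonhier_mu_var,nonhier_dyn_var Diffuse prior variances used when
#'   `hierarchical = FALSE`.
#' @param step_init Initial random-walk step for the log-variance updates.
#' @param adapt_interval Iterations per step-size adaptation batch.
#' @param psr_threshold Convergence flag threshold for the potential scale
#'   reduction (default 1.1).
#' @returns A list of class `fit_config`.
#' @export
fit_config <- function(iterations = 50000L, thin = 10L, chains = 2L,
                       burn_in_fraction = 0.5, seed = 1L,
                       hierarchical = TRUE,
                       initial = c("stationary", "diffuse"),
                       prior_gamma_var = 1e6, prior_mu_intercept_var = 1e8,
                       prior_tau_shape = -1, prior_tau_rate = 0,
                       prior_wishart_df = -3, prior_wishart_scale = 0,
                       nonhier_mu_var = 1e8, nonhier_dyn_var = 1e6,
                       step_init = 0.4, adapt_interval = 50L,
                       psr_threshold = 1.1) {
  stopifnot(
    iterations >= thin, thin >= 1, chains >= 1,
    burn_in_fraction > 0, burn_in_fraction < 1
  )
  initial <- match.arg(initial)
  structure(
    list(
      iterations = as.integer(iterations), thin = as.integer(thin),
      chains = as.integer(chains), burn_in_fraction = burn_in_fraction,
      seed = as.integer(seed), hierarchical = isTRUE(hierarchical),
      initial = initial,
      prior = list(
        gamma_var = prior_gamma_var, mu_intercept_var = prior_mu_intercept_var,
        tau_shape = prior_tau_shape, tau_rate = prior_tau_rate,
        wishart_df = prior_wishart_df, wishart_scale = prior_wishart_scale,
        nonhier_mu_var = nonhier_mu_var, nonhier_dyn_var = nonhier_dyn_var
      ),
      step_init = step_init, adapt_interval = as.integer(adapt_interval),
      psr_threshold = psr_threshold
    ),
    class = "fit_config"
  )
}

# Reshape a panel tibble into the person x day matrices the sampler needs.
panel_model_frame <- function(panel, predictor) {
  stopifnot(
    is.data.frame(panel),
    all(c("person_id", "day_index", "sb_min", "pa_min") %in% names(panel))
  )
  if (!predictor %in% names(panel)) {
    abort(paste0("Predictor column `", predictor, "` not found in panel."))
  }
  if (anyDuplicated(panel[c("person_id", "day_index")]) > 0) {
    abort("Duplicate (person_id, day_index) rows in panel.")
  }
  persons <- sort(unique(panel$person_id))
  t_max <- max(panel$day_index)
  if (t_max < 2) abort("Panel needs at least 2 days per person.")
  N <- length(persons)
  y_sb <- y_pa <- matrix(NA_real_, N, t_max)
  pvals <- numeric(N)
  for (i in seq_len(N)) {
    rows <- panel[panel$person_id == persons[i], , drop = FALSE]
    y_sb[i, rows$day_index] <- rows$sb_min
    y_pa[i, rows$day_index] <- rows$pa_min
    pv <- unique(rows[[predictor]])
    if (length(pv) != 1 || is.na(pv)) {
      abort(paste0("Predictor must be constant and non-missing within person ",
                   persons[i], "."))
    }
    pvals[i] <- pv
  }
  obs <- !is.na(y_sb) & !is.na(y_pa)
  if (any(rowSums(obs) == 0)) {
    abort("Every person needs at least one observed day.")
  }
  if (!any(rowSums(obs) >= 2)) {
    abort("Identifiability: no person has 2 or more observed days.")
  }
  y_sb[!obs] <- NaN
  y_pa[!obs] <- NaN
  list(
    persons = persons, t_days = t_max, y_sb = y_sb, y_pa = y_pa,
    obs = obs, predictor_raw = pvals, pc = pvals - mean(pvals)
  )
}

#' Fit the bivariate multilevel DSEM by Metropolis-within-Gibbs MCMC
#'
#' Estimates the within-person VAR(1) with person-specific means,
#' autoregressive and cross-lagged slopes and log innovation variances as
#' random effects, regressed at the between level on one grand-mean centered
#' person-level predictor. Diffuse priors throughout; missing person-days are
#' sampled as latent states (missing at random).
#'
#' @param panel Panel tibble with `person_id`, `day_index`, `sb_min`,
#'   `pa_min` and the predictor column (e.g. from [build_panel()] or
#'   [simulate_panel()]). `NA` minutes mark missing days.
#' @param predictor Name of the person-level predictor column
#'   (default `"pain"`).
#' @param config A [fit_config()].
#' @returns An object of class `dsem_fit` with thinned post-burn-in draws per
#'   chain of the between-level parameters, all person effects, the latent
#'   within states, and the conditional deviance. Use [tidy()] /
#'   [glance()] / [standardize_within()] / [standardize_between()] /
#'   [dic()] / [psr()] on it.
#' @export
dsem_fit <- function(panel, predictor = "pain", config = fit_config()) {
  stopifnot(inherits(config, "fit_config"))
  mf <- panel_model_frame(panel, predictor)
  if (config$hierarchical && length(mf$persons) < 2) {
    abort("Hierarchical fit needs at least 2 persons; see fit_config(hierarchical = FALSE).")
  }
  if (config$hierarchical) {
    n <- length(mf$persons)
    if (config$prior$wishart_df + n < 2 || config$prior$tau_shape + n / 2 <= 0) {
      abort(paste0(
        "The flat default variance priors need more persons (n = ", n, ") ",
        "for a proper posterior; supply proper hyperpriors via fit_config ",
        "(e.g. prior_wishart_df = 4, prior_wishart_scale = 1, ",
        "prior_tau_shape = 0.001, prior_tau_rate = 0.001) or use ",
        "hierarchical = FALSE."
      ))
    }
  }
  burn <- as.integer(floor(config$iterations * config$burn_in_fraction))
  chains <- vector("list", config$chains)
  for (k in seq_len(config$chains)) {
    set.seed(config$seed + k - 1L)
    res <- dsem_mcmc_cpp(
      mf$y_sb, mf$y_pa, mf$obs * 1L, mf$pc,
      n_iter = config$iterations, burn = burn, thin = config$thin,
      hierarchical = config$hierarchical, prior = config$prior,
      step_init = config$step_init, adapt_interval = config$adapt_interval,
      stat_init = config$initial == "stationary"
    )
    colnames(res$fixed) <- fixed_param_names()
    chains[[k]] <- res
  }
  structure(
    list(
      chains = chains, config = config, predictor = predictor,
      persons = mf$persons, pc = mf$pc, predictor_raw = mf$predictor_raw,
      t_days = mf$t_days, y_sb = mf$y_sb, y_pa = mf$y_pa, obs = mf$obs,
      n_keep = chains[[1]]$n_keep
    ),
    class = "dsem_fit"
  )
}

fixed_param_names <- function() {
  c(
    paste0("gamma0[", EFFECTS, "]"),
    paste0("gamma1[", EFFECTS, "]"),
    paste0("tau[", EFFECTS, "]"),
    "sigma_mu"
  )
}

#' Extract posterior draws from a fitted DSEM
#'
#' @param fit A [dsem_fit()] object.
#' @param type `"fixed"` for between-level parameters (matrix, draws x
#'   parameters, chains stacked), `"effects"` for person effects (array
#'   draws x persons x 8), `"states"` for latent deviations (array draws x
#'   persons x 2T), `"deviance"` for the conditional deviance vector.
#' @param chain Optional single chain index; default stacks all chains.
#' @returns Matrix, array or vector as described.
#' @export
posterior_draws <- function(fit, type = c("fixed", "effects", "states", "deviance"),
                            chain = NULL) {
  stopifnot(inherits(fit, "dsem_fit"))
  type <- match.arg(type)
  ch <- if (is.null(chain)) seq_along(fit$chains) else chain
  pick <- function(res) switch(type,
    fixed = res$fixed, effects = res$effects,
    states = res$states, deviance = res$deviance
  )
  parts <- lapply(fit$chains[ch], pick)
  if (type %in% c("fixed")) {
    return(do.call(rbind, parts))
  }
  if (type == "deviance") {
    return(unlist(parts, use.names = FALSE))
  }
  out <- parts[[1]]
  if (length(parts) > 1) {
    for (j in 2:length(parts)) {
      tmp <- array(NA_real_, dim = dim(out) + c(dim(parts[[j]])[1], 0, 0))
      tmp[seq_len(dim(out)[1]), , ] <- out
      tmp[dim(out)[1] + seq_len(dim(parts[[j]])[1]), , ] <- parts[[j]]
      out <- tmp
    }
  }
  out
}

#' @export
print.dsem_fit <- function(x, ...) {
  cat("<dsem_fit> bivariate multilevel VAR(1) DSEM\n")
  cat(sprintf(
    "  %d persons x %d days, predictor `%s`\n",
    length(x$persons), x$t_days, x$predictor
  ))
  cat(sprintf(
    "  %d chain(s) x %d kept draws (%d iterations, thin %d)\n",
    length(x$chains), x$n_keep, x$config$iterations, x$config$thin
  ))
  if (x$config$hierarchical) {
    print(tidy(x), n = 8)
  }
  invisible(x)
}

#' Potential scale reduction (Gelman-Rubin) per between-level parameter
#'
#' Computed as `sqrt((W + B) / W)` with `W` the mean within-chain variance
#' and `B` the variance of the chain means, the convention under which two
#' identical chains give exactly 1. With a single chain the chain is split in
#' half (with a warning).
#'
#' @param fit A [dsem_fit()] object.
#' @param threshold Flagging threshold; defaults to the fitted config's.
#' @returns Tibble `parameter`, `psr`, `converged`.
#' @export
psr <- function(fit, threshold = NULL) {
  stopifnot(inherits(fit, "dsem_fit"))
  threshold <- threshold %||% fit$config$psr_threshold
  mats <- lapply(fit$chains, function(ch) ch$fixed)
  if (length(mats) == 1) {
    warn("Single chain: computing split-chain PSR.")
    m <- mats[[1]]
    h <- nrow(m) %/% 2
    mats <- list(m[seq_len(h), , drop = FALSE],
                 m[(h + 1):(2 * h), , drop = FALSE])
  }
  vals <- vapply(colnames(mats[[1]]), function(p) {
    draws <- lapply(mats, function(m) m[, p])
    W <- mean(vapply(draws, var, 0))
    B <- var(vapply(draws, mean, 0))
    if (W <= 0) return(if (B <= 1e-300) 1 else Inf)
    sqrt((W + B) / W)
  }, 0)
  tibble(
    parameter = colnames(mats[[1]]), psr = unname(vals),
    converged = unname(vals) < threshold
  )
}

# Conditional deviance: -2 * within-level observed-data log density given
# person effects and states. R implementation used at the posterior means.
conditional_deviance <- function(u, states, fit) {
  N <- length(fit$persons)
  T <- fit$t_days
  dev <- 0
  for (i in seq_len(N)) {
    ui <- u[i, ]
    names(ui) <- EFFECTS
    A <- lag_matrix(ui)
    psi <- exp(c(ui[["logpsi_sb"]], ui[["logpsi_pa"]]))
    w <- rbind(states[i, seq_len(T)], states[i, T + seq_len(T)])
    for (t in 2:T) {
      if (!fit$obs[i, t]) next
      m <- A %*% w[, t - 1]
      dev <- dev + stats::dnorm(w[1, t], m[1], sqrt(psi[1]), log = TRUE) +
        stats::dnorm(w[2, t], m[2], sqrt(psi[2]), log = TRUE)
    }
    if (fit$obs[i, 1]) {
      V1 <- if (fit$config$initial == "stationary") {
        initial_state_cov(ui)
      } else {
        diag(DIFFUSE_INIT_VAR, 2)
      }
      dev <- dev + log_dmvnorm2(w[, 1], c(0, 0), V1)
    }
  }
  -2 * dev
}

#' Deviance information criterion of a fitted DSEM
#'
#' Conditional-deviance definition: `D(theta)` is minus twice the
#' within-level observed-data log density given the person effects and latent
#' states; `pD = mean(D) - D(posterior means)` and `DIC = mean(D) + pD`.
#' (Conditional, i.e. person effects are treated as parameters; this matches
#' the effective-parameter counts reported for this model class.)
#'
#' @param fit A [dsem_fit()] object.
#' @returns Tibble with `dic`, `pd`, `mean_deviance`, `deviance_at_means`.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "dsem_fit"))
  dev <- posterior_draws(fit, "deviance")
  eff <- posterior_draws(fit, "effects")
  states <- posterior_draws(fit, "states")
  u_hat <- apply(eff, c(2, 3), mean)
  s_hat <- apply(states, c(2, 3), mean)
  d_hat <- conditional_deviance(u_hat, s_hat, fit)
  d_bar <- mean(dev)
  tibble(
    dic = d_bar + (d_bar - d_hat), pd = d_bar - d_hat,
    mean_deviance = d_bar, deviance_at_means = d_hat
  )
}

#' Posterior summary of a vector of draws
#'
#' Point estimate is the posterior median (mean also reported); the interval
#' is the equal-tail 95% credibility interval; the one-tailed posterior p is
#' `min(Pr(draw < 0), Pr(draw > 0))`; significance means the interval
#' excludes zero.
#'
#' @param draws Numeric vector of posterior draws (length >= 2).
#' @param parameter Optional parameter label.
#' @param level Credibility level (default 0.95).
#' @returns One-row tibble: `parameter`, `estimate` (median), `mean`,
#'   `conf.low`, `conf.high`, `p`, `significant`.
#' @export
summarize_posterior <- function(draws, parameter = NA_character_, level = 0.95) {
  stopifnot(is.numeric(draws), length(draws) >= 2)
  a <- (1 - level) / 2
  qs <- unname(quantile(draws, c(a, 1 - a), na.rm = TRUE, type = 7))
  tibble(
    parameter = parameter,
    estimate = median(draws, na.rm = TRUE),
    mean = mean(draws, na.rm = TRUE),
    conf.low = qs[1], conf.high = qs[2],
    p = min(mean(draws < 0, na.rm = TRUE), mean(draws > 0, na.rm = TRUE)),
    significant = qs[1] > 0 | qs[2] < 0
  )
}

#' Tidy posterior summaries of a fitted DSEM
#'
#' @param x A [dsem_fit()] object.
#' @param effects `"fixed"` (between-level parameters; default) or
#'   `"person"` (per-person random-effect summaries).
#' @param level Credibility level.
#' @param ... Unused.
#' @returns A tibble with one row per parameter (see
#'   [summarize_posterior()]); for `"person"`, columns `person_id`, `effect`
#'   and the summary columns.
#' @method tidy dsem_fit
#' @export
tidy.dsem_fit <- function(x, effects = c("fixed", "person"), level = 0.95, ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") {
    m <- posterior_draws(x, "fixed")
    return(purrr::map_dfr(
      colnames(m), ~ summarize_posterior(m[, .x], parameter = .x, level = level)
    ))
  }
  arr <- posterior_draws(x, "effects")
  purrr::map_dfr(seq_along(x$persons), function(i) {
    purrr::map_dfr(seq_along(EFFECTS), function(k) {
      s <- summarize_posterior(arr[, i, k], parameter = EFFECTS[k], level = level)
      dplyr::mutate(s, person_id = x$persons[i], .before = 1) |>
        dplyr::rename(effect = "parameter")
    })
  })
}

#' One-row model summary of a fitted DSEM
#'
#' @param x A [dsem_fit()] object.
#' @param ... Unused.
#' @returns Tibble with sample sizes, draw counts, DIC, pD, the maximum
#'   potential scale reduction over between-level parameters, and a
#'   convergence flag.
#' @method glance dsem_fit
#' @export
glance.dsem_fit <- function(x, ...) {
  d <- dic(x)
  p <- if (x$config$hierarchical) psr(x) else NULL
  tibble(
    n_persons = length(x$persons), n_days = x$t_days,
    n_obs = sum(x$obs), n_chains = length(x$chains),
    n_draws = x$n_keep * length(x$chains),
    dic = d$dic, pd = d$pd,
    max_psr = if (is.null(p)) NA_real_ else max(p$psr),
    converged = if (is.null(p)) NA else all(p$converged)
  )
}
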