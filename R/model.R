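#' Between-level parameter set for the bivariate movement-behavior DSEM
#'
#' Bundles every between-person parameter of the model: for each of the eight
#' person-level random effects \eqn{u \in \{\mu_{SB}, \mu_{PA}, \phi_{SB},
#' \phi_{PA}, \beta_{SB}, \beta_{PA}, \log\psi_{SB}, \log\psi_{PA}\}} an
#' intercept \eqn{\gamma_{0u}}, a slope \eqn{\gamma_{1u}} on the grand-mean
#' centered person-level predictor, and a random-effect residual variance
#' \eqn{\tau_u}; plus the single between-level covariance \eqn{\sigma_\mu}
#' between the \eqn{\mu_{SB}} and \eqn{\mu_{PA}} residuals. All other random
#' effects are mutually independent at the between level.
#'
#' @param gamma0 Named numeric vector of intercepts over the eight effects
#'   (names as in [dsem_effect_names()]); unnamed scalars are recycled.
#' @param gamma1 Predictor slopes, same shape as `gamma0`. Default 0.
#' @param tau Random-effect residual variances, same shape; must be `>= 0`.
#' @param sigma_mu Covariance between the latent-mean residuals (min^2/day^2).
#' @returns An object of class `dsem_params`: a list with elements `gamma0`,
#'   `gamma1`, `tau` (each a named length-8 numeric) and `sigma_mu` (scalar).
#' @examples
#' dsem_params(gamma0 = c(mu_sb = 460, mu_pa = 245, phi_sb = 0.18))
#' @export
dsem_params <- function(gamma0 = 0, gamma1 = 0, tau = 0, sigma_mu = 0) {
  expand <- function(x, what) {
    if (is.null(names(x)) && length(x) == 1L) {
      out <- rep(as.numeric(x), 8L)
      names(out) <- EFFECTS
      return(out)
    }
    if (is.null(names(x)) && length(x) == 8L) {
      out <- as.numeric(x)
      names(out) <- EFFECTS
      return(out)
    }
    if (!all(names(x) %in% EFFECTS)) {
      abort(paste0(
        "Unknown effect name(s) in `", what, "`: ",
        paste(setdiff(names(x), EFFECTS), collapse = ", ")
      ))
    }
    out <- rep(0, 8L)
    names(out) <- EFFECTS
    out[names(x)] <- as.numeric(x)
    out
  }
  p <- structure(
    list(
      gamma0 = expand(gamma0, "gamma0"),
      gamma1 = expand(gamma1, "gamma1"),
      tau = expand(tau, "tau"),
      sigma_mu = as.numeric(sigma_mu)
    ),
    class = "dsem_params"
  )
  validate_dsem_params(p)
  p
}

validate_dsem_params <- function(p) {
  vals <- c(p$gamma0, p$gamma1, p$tau, p$sigma_mu)
  if (any(!is.finite(vals))) abort("dsem_params values must be finite.")
  if (any(p$tau < 0)) abort("Random-effect variances `tau` must be >= 0.")
  blk <- mu_block(p)
  if (min(eigen(blk, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    abort("The (mu_sb, mu_pa) covariance block is not positive semi-definite.")
  }
  invisible(p)
}

mu_block <- function(p) {
  matrix(c(p$tau[["mu_sb"]], p$sigma_mu, p$sigma_mu, p$tau[["mu_pa"]]), 2, 2)
}

#' Names of the eight person-level random effects
#'
#' @returns Character vector in the canonical order: `mu_sb`, `mu_pa`,
#'   `phi_sb`, `phi_pa`, `beta_sb`, `beta_pa`, `logpsi_sb`, `logpsi_pa`.
#' @export
dsem_effect_names <- function() EFFECTS

#' @export
print.dsem_params <- function(x, ...) {
  cat("<dsem_params>\n")
  m <- rbind(gamma0 = x$gamma0, gamma1 = x$gamma1, tau = x$tau)
  print(round(m, 4))
  cat("sigma_mu (mu_sb, mu_pa covariance):", format(x$sigma_mu), "\n")
  invisible(x)
}

# Lag matrix of the person-level VAR(1):
#   w_sb,t = phi_sb w_sb,t-1 + beta_sb w_pa,t-1 + zeta_sb,t
#   w_pa,t = phi_pa w_pa,t-1 + beta_pa w_sb,t-1 + zeta_pa,t
lag_matrix <- function(u) {
  matrix(
    c(u[["phi_sb"]], u[["beta_pa"]], u[["beta_sb"]], u[["phi_pa"]]),
    2, 2
  )
}

spectral_radius <- function(A) max(Mod(eigen(A, only.values = TRUE)$values))

#' Conditional mean and covariance of today's within-person deviations
#'
#' The within-person (level-1) model is a person-specific bivariate VAR(1):
#' \deqn{w_{SB,t} = \phi_{SB} w_{SB,t-1} + \beta_{SB} w_{PA,t-1} + \zeta_{SB,t}}
#' \deqn{w_{PA,t} = \phi_{PA} w_{PA,t-1} + \beta_{PA} w_{SB,t-1} + \zeta_{PA,t}}
#' with independent Gaussian innovations of variances
#' \eqn{\psi_{SB} = e^{\lambda_{SB}}}, \eqn{\psi_{PA} = e^{\lambda_{PA}}}.
#'
#' @param effects Named numeric vector (or one-row data frame) holding at
#'   least `phi_sb`, `phi_pa`, `beta_sb`, `beta_pa`, `logpsi_sb`, `logpsi_pa`.
#' @param w_prev Length-2 numeric: yesterday's deviations `(w_sb, w_pa)`.
#' @returns List with `mean` (length-2) and `cov` (2x2 diagonal), both with
#'   dimnames `c("sb", "pa")`.
#' @export
within_equations <- function(effects, w_prev) {
  u <- as_effect_vector(effects)
  w_prev <- as.numeric(w_prev)
  stopifnot(length(w_prev) == 2L, all(is.finite(w_prev)))
  A <- lag_matrix(u)
  m <- drop(A %*% w_prev)
  V <- diag(exp(c(u[["logpsi_sb"]], u[["logpsi_pa"]])))
  dimnames(V) <- list(c("sb", "pa"), c("sb", "pa"))
  names(m) <- c("sb", "pa")
  list(mean = m, cov = V)
}

as_effect_vector <- function(effects) {
  if (is.data.frame(effects)) {
    stopifnot(nrow(effects) == 1L)
    effects <- unlist(effects[intersect(names(effects), EFFECTS)])
  }
  stopifnot(is.numeric(effects), !is.null(names(effects)))
  if (!all(is.finite(effects))) abort("Person effects must be finite.")
  effects
}

#' Between-level distribution of the person random effects
#'
#' Each random effect is regressed on the grand-mean centered person-level
#' predictor: \eqn{u_i \sim N(\gamma_0 + \gamma_1 (P_i - \bar P), \tau)}.
#' Effects are independent except for the \eqn{(\mu_{SB}, \mu_{PA})} pair,
#' which shares the covariance \eqn{\sigma_\mu}.
#'
#' @param params A [dsem_params()] object.
#' @param p_centered Scalar centered predictor value for one person.
#' @returns List with `mean` (named length-8) and `cov` (8x8).
#' @export
between_equations <- function(params, p_centered) {
  validate_dsem_params(params)
  stopifnot(is.finite(p_centered), length(p_centered) == 1L)
  m <- params$gamma0 + params$gamma1 * p_centered
  V <- diag(params$tau)
  dimnames(V) <- list(EFFECTS, EFFECTS)
  V["mu_sb", "mu_pa"] <- V["mu_pa", "mu_sb"] <- params$sigma_mu
  list(mean = m, cov = V)
}

#' Stationary within-person covariance of the deviations
#'
#' Solves the discrete Lyapunov equation \eqn{V = A V A^\top + \Psi} for the
#' person's lag matrix \eqn{A} and diagonal innovation covariance
#' \eqn{\Psi = \mathrm{diag}(e^{\lambda_{SB}}, e^{\lambda_{PA}})}. This is the
#' model-implied long-run covariance of the within-person deviations, used for
#' standardization and for the latent initial state at day 1.
#'
#' @inheritParams within_equations
#' @returns 2x2 matrix with dimnames `c("sb","pa")`, or `NULL` (with attribute
#'   handling left to the caller) when the dynamics are non-stationary
#'   (spectral radius of `A` not `< 1`), in which case standardization is
#'   undefined for that draw/person.
#' @examples
#' stationary_covariance(c(
#'   phi_sb = 0.5, phi_pa = 0, beta_sb = 0, beta_pa = 0,
#'   logpsi_sb = log(3), logpsi_pa = 0
#' ))["sb", "sb"] # 3 / (1 - 0.25) = 4
#' @export
stationary_covariance <- function(effects) {
  u <- as_effect_vector(effects)
  A <- lag_matrix(u)
  if (spectral_radius(A) >= 1 - 1e-12) {
    return(NULL)
  }
  Psi <- diag(exp(c(u[["logpsi_sb"]], u[["logpsi_pa"]])))
  vecV <- solve(diag(4) - (A %x% A), as.vector(Psi))
  V <- matrix(vecV, 2, 2)
  V <- (V + t(V)) / 2
  dimnames(V) <- list(c("sb", "pa"), c("sb", "pa"))
  V
}

# Initial-state variance: stationary when stable, else a diffuse fallback.
DIFFUSE_INIT_VAR <- 1e6

initial_state_cov <- function(u) {
  V <- stationary_covariance(u)
  if (is.null(V) || min(eigen(V, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    V <- diag(DIFFUSE_INIT_VAR, 2)
    dimnames(V) <- list(c("sb", "pa"), c("sb", "pa"))
    attr(V, "diffuse") <- TRUE
  }
  V
}

log_dmvnorm2 <- function(x, mean, V) {
  d <- x - mean
  det <- V[1, 1] * V[2, 2] - V[1, 2] * V[2, 1]
  Q <- (d[1]^2 * V[2, 2] - 2 * d[1] * d[2] * V[1, 2] + d[2]^2 * V[1, 1]) / det
  -log(2 * pi) - 0.5 * log(det) - 0.5 * Q
}

#' Joint log density of the full hierarchical model
#'
#' Evaluates, for a complete configuration of parameters, person effects and
#' within states, the sum of (a) the within-level Gaussian transition
#' densities for days `t >= 2`, (b) the initial-state density at `t = 1` under
#' the person's stationary distribution (diffuse fallback when the person's
#' dynamics are non-stationary), and (c) the between-level Gaussian density of
#' each person's effects given the centered predictor. Used by the sampler's
#' tests and by information criteria.
#'
#' @param params A [dsem_params()] object.
#' @param effects Data frame of person effects: `person_id` plus the eight
#'   effect columns (see [dsem_effect_names()]).
#' @param states Data frame of within states: `person_id`, `day`, `w_sb`,
#'   `w_pa`, complete for days `1..T` per person (missing days imputed).
#' @param panel Data frame with `person_id`, `day`, observed `sb`, `pa`
#'   (`NA` = missing) and a person-constant centered predictor `p_c`.
#' @returns Scalar log density.
#' @export
joint_log_density <- function(params, effects, states, panel) {
  validate_dsem_params(params)
  persons <- unique(panel$person_id)
  total <- 0
  for (pid in persons) {
    u <- as_effect_vector(effects[effects$person_id == pid, , drop = FALSE][, EFFECTS])
    st <- states[states$person_id == pid, , drop = FALSE]
    st <- st[order(st$day), , drop = FALSE]
    pan <- panel[panel$person_id == pid, , drop = FALSE]
    pan <- pan[order(pan$day), , drop = FALSE]
    if (!all(st$day == seq_len(nrow(st)))) {
      abort(paste0("States for person ", pid, " must cover days 1..T."))
    }
    # observed-day identity: y = mu + w must hold exactly where observed
    obs <- !is.na(pan$sb)
    if (any(obs)) {
      idx <- match(pan$day[obs], st$day)
      mism <- which(
        abs(pan$sb[obs] - (u[["mu_sb"]] + st$w_sb[idx])) > 1e-6 |
          abs(pan$pa[obs] - (u[["mu_pa"]] + st$w_pa[idx])) > 1e-6
      )
      if (length(mism) > 0) {
        abort(paste0(
          "Observed-day identity violated for person ", pid,
          ", day ", pan$day[obs][mism[1]]
        ))
      }
    }
    w <- cbind(st$w_sb, st$w_pa)
    if (any(!is.finite(w))) {
      abort(paste0("Non-finite state for person ", pid,
                   ", day ", st$day[which(!is.finite(rowSums(w)))[1]]))
    }
    A <- lag_matrix(u)
    psi <- exp(c(u[["logpsi_sb"]], u[["logpsi_pa"]]))
    # (a) transitions
    if (nrow(w) >= 2) {
      for (t in 2:nrow(w)) {
        m <- drop(A %*% w[t - 1, ])
        total <- total +
          stats::dnorm(w[t, 1], m[1], sqrt(psi[1]), log = TRUE) +
          stats::dnorm(w[t, 2], m[2], sqrt(psi[2]), log = TRUE)
      }
    }
    # (b) initial state
    V1 <- initial_state_cov(u)
    total <- total + log_dmvnorm2(w[1, ], c(0, 0), V1)
    # (c) between level
    be <- between_equations(params, pan$p_c[1])
    mu_pair <- c(u[["mu_sb"]], u[["mu_pa"]])
    total <- total + log_dmvnorm2(
      mu_pair, be$mean[c("mu_sb", "mu_pa")],
      be$cov[c("mu_sb", "mu_pa"), c("mu_sb", "mu_pa")]
    )
    rest <- setdiff(EFFECTS, c("mu_sb", "mu_pa"))
    total <- total + sum(stats::dnorm(
      u[rest], be$mean[rest], sqrt(diag(be$cov)[rest]), log = TRUE
    ))
  }
  if (!is.finite(total)) abort("Joint log density is non-finite.")
  unname(total)
}
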