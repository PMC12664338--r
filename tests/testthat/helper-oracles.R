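# Independent oracles used across the suite. These deliberately use naive,
# brute-force formulations so they share no code path with the package.

# Non-wear scanner: a minute is non-wear iff it lies in SOME window [a, b]
# of length >= min_window whose counts are all <= low_max with at most
# `allowance` minutes strictly above 0. Direct enumeration over starts with
# a growing end pointer.
brute_nonwear <- function(counts, min_window = 60, allowance = 2, low_max = 100) {
  n <- length(counts)
  mask <- logical(n)
  for (a in seq_len(n)) {
    if (counts[a] > low_max) next
    n_int <- 0L
    b <- a
    while (b <= n && counts[b] <= low_max) {
      if (counts[b] > 0) n_int <- n_int + 1L
      if (n_int > allowance) break
      if (b - a + 1L >= min_window) mask[a:b] <- TRUE
      b <- b + 1L
    }
  }
  mask
}

# Spearman correlation from first principles: ranks by counting, Pearson by
# explicit sums, p from the t approximation.
brute_spearman <- function(x, y) {
  n <- length(x)
  rank_count <- function(v) {
    vapply(seq_len(n), function(i) {
      sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }, 0)
  }
  rx <- rank_count(x)
  ry <- rank_count(y)
  mx <- sum(rx) / n
  my <- sum(ry) / n
  num <- sum((rx - mx) * (ry - my))
  den <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  if (den == 0) return(c(rho = NA_real_, p = NA_real_))
  r <- num / den
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  c(rho = r, p = p)
}

# Random stable 2x2 VAR system for Lyapunov checks: rejection-sample lag
# matrices to spectral radius < `radius_max`.
random_stable_system <- function(radius_max = 0.95, scale = 0.6) {
  repeat {
    A <- matrix(stats::rnorm(4, 0, scale), 2, 2)
    if (max(Mod(eigen(A, only.values = TRUE)$values)) < radius_max) break
  }
  list(
    A = A,
    effects = c(
      phi_sb = A[1, 1], beta_sb = A[1, 2], beta_pa = A[2, 1], phi_pa = A[2, 2],
      logpsi_sb = stats::rnorm(1, 0, 1), logpsi_pa = stats::rnorm(1, 0, 1)
    )
  )
}

# Simulate a bivariate VAR(1) path of length n from deviations 0.
simulate_var_path <- function(A, psi_sb, psi_pa, n, w0 = c(0, 0)) {
  w <- matrix(NA_real_, n, 2)
  cur <- w0
  for (t in seq_len(n)) {
    cur <- drop(A %*% cur) + c(
      stats::rnorm(1, 0, sqrt(psi_sb)), stats::rnorm(1, 0, sqrt(psi_pa))
    )
    w[t, ] <- cur
  }
  w
}

# Naive evaluation of the hierarchical joint density: every factor written
# out with dnorm / explicit 2x2 Gaussian algebra, looping over everything.
naive_joint_density <- function(params, effects, states, panel) {
  dmvn2 <- function(x, m, V) {
    di <- x - m
    Vi <- solve(V)
    as.numeric(-log(2 * pi) - 0.5 * determinant(V)$modulus -
      0.5 * t(di) %*% Vi %*% di)
  }
  total <- 0
  for (pid in unique(panel$person_id)) {
    u <- effects[effects$person_id == pid, ]
    st <- states[states$person_id == pid, ]
    st <- st[order(st$day), ]
    A <- matrix(c(u$phi_sb, u$beta_pa, u$beta_sb, u$phi_pa), 2, 2)
    psi <- c(exp(u$logpsi_sb), exp(u$logpsi_pa))
    for (t in 2:nrow(st)) {
      m <- A %*% c(st$w_sb[t - 1], st$w_pa[t - 1])
      total <- total + dnorm(st$w_sb[t], m[1], sqrt(psi[1]), log = TRUE)
      total <- total + dnorm(st$w_pa[t], m[2], sqrt(psi[2]), log = TRUE)
    }
    V1 <- stationary_covariance(c(
      phi_sb = u$phi_sb, phi_pa = u$phi_pa, beta_sb = u$beta_sb,
      beta_pa = u$beta_pa, logpsi_sb = u$logpsi_sb, logpsi_pa = u$logpsi_pa
    ))
    if (is.null(V1)) V1 <- diag(1e6, 2)
    total <- total + dmvn2(c(st$w_sb[1], st$w_pa[1]), c(0, 0), V1)
    pc <- panel$p_c[panel$person_id == pid][1]
    mean_u <- params$gamma0 + params$gamma1 * pc
    Vmu <- matrix(c(
      params$tau[["mu_sb"]], params$sigma_mu,
      params$sigma_mu, params$tau[["mu_pa"]]
    ), 2, 2)
    total <- total + dmvn2(c(u$mu_sb, u$mu_pa), mean_u[c("mu_sb", "mu_pa")], Vmu)
    for (nm in c("phi_sb", "phi_pa", "beta_sb", "beta_pa", "logpsi_sb", "logpsi_pa")) {
      total <- total + dnorm(u[[nm]], mean_u[[nm]], sqrt(params$tau[[nm]]), log = TRUE)
    }
  }
  total
}

# Small complete panel in model-frame form plus matching effects/states, for
# joint-density and DIC checks.
make_tiny_instance <- function(seed = 1, n_persons = 3, t_days = 4) {
  set.seed(seed)
  params <- dsem_params(
    gamma0 = c(
      mu_sb = 5, mu_pa = 3, phi_sb = 0.3, phi_pa = 0.1,
      beta_sb = -0.1, beta_pa = 0.05, logpsi_sb = 0.2, logpsi_pa = -0.1
    ),
    gamma1 = c(mu_sb = 0.5, phi_sb = 0.1),
    tau = c(
      mu_sb = 2, mu_pa = 1.5, phi_sb = 0.02, phi_pa = 0.02,
      beta_sb = 0.02, beta_pa = 0.02, logpsi_sb = 0.1, logpsi_pa = 0.1
    ),
    sigma_mu = -0.8
  )
  ids <- paste0("q", seq_len(n_persons))
  effects <- NULL
  states <- NULL
  panel <- NULL
  for (i in seq_len(n_persons)) {
    pc <- rnorm(1)
    u <- c(
      mu_sb = 5 + rnorm(1), mu_pa = 3 + rnorm(1),
      phi_sb = runif(1, -0.3, 0.4), phi_pa = runif(1, -0.3, 0.4),
      beta_sb = runif(1, -0.2, 0.2), beta_pa = runif(1, -0.2, 0.2),
      logpsi_sb = rnorm(1, 0, 0.3), logpsi_pa = rnorm(1, 0, 0.3)
    )
    w <- matrix(rnorm(2 * t_days), t_days, 2)
    effects <- rbind(effects, data.frame(person_id = ids[i], t(u)))
    states <- rbind(states, data.frame(
      person_id = ids[i], day = seq_len(t_days), w_sb = w[, 1], w_pa = w[, 2]
    ))
    panel <- rbind(panel, data.frame(
      person_id = ids[i], day = seq_len(t_days),
      sb = u[["mu_sb"]] + w[, 1], pa = u[["mu_pa"]] + w[, 2], p_c = pc
    ))
  }
  list(params = params, effects = effects, states = states, panel = panel)
}
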