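small_fit <- function(seed = 1, n_persons = 8, iterations = 800, chains = 2,
                      t_days = 7, missing = 0, ...) {
  sim <- simulate_panel(panel_sim_spec(
    n_persons = n_persons, t_days = t_days, missing_day_prob = missing,
    seed = seed
  ))
  dsem_fit(sim$panel, "pain", fit_config(
    iterations = iterations, thin = 2, chains = chains, seed = seed + 500, ...
  ))
}

test_that("same seed and config give identical draws", {
  f1 <- small_fit(seed = 3, iterations = 400)
  f2 <- small_fit(seed = 3, iterations = 400)
  expect_identical(f1$chains[[1]]$fixed, f2$chains[[1]]$fixed)
  expect_identical(f1$chains[[2]]$effects, f2$chains[[2]]$effects)
  f3 <- small_fit(seed = 4, iterations = 400)
  expect_false(identical(f1$chains[[1]]$fixed, f3$chains[[1]]$fixed))
})

test_that("fit validates its inputs", {
  sim <- simulate_panel(panel_sim_spec(n_persons = 4, seed = 1))
  expect_error(dsem_fit(sim$panel, "bogus"), "not found")
  one <- sim$panel[sim$panel$person_id == "p01", ]
  expect_error(dsem_fit(one, "pain"), "at least 2 persons")
  varying <- sim$panel
  varying$pain[2] <- varying$pain[2] + 1
  expect_error(dsem_fit(varying, "pain"), "constant")
  dup <- dplyr::bind_rows(sim$panel, sim$panel[1, ])
  expect_error(dsem_fit(dup, "pain"), "Duplicate")
  # no person with 2+ observed days -> identifiability error
  sparse <- sim$panel
  sparse$sb_min[sparse$day_index > 1] <- NA
  sparse$pa_min[sparse$day_index > 1] <- NA
  expect_error(dsem_fit(sparse, "pain"), "Identifiability")
})

test_that("missing days are imputed as latent states", {
  f <- small_fit(seed = 9, n_persons = 6, iterations = 600, missing = 0.25)
  st <- posterior_draws(f, "states")
  miss <- which(!f$obs, arr.ind = TRUE)
  expect_gt(nrow(miss), 0)
  i <- miss[1, 1]; t <- miss[1, 2]
  draws <- st[, i, t]
  expect_gt(sd(draws), 0) # sampled, not frozen
  # observed states are pinned to y - mu exactly
  obs_idx <- which(f$obs[1, ])[1]
  eff <- posterior_draws(f, "effects")
  expect_equal(
    st[, 1, obs_idx], f$y_sb[1, obs_idx] - eff[, 1, 1],
    tolerance = 1e-12
  )
})

test_that("psr is exactly 1 for identical chains and large for split ones", {
  f <- small_fit(seed = 5, iterations = 400)
  # identical chains
  f2 <- f
  f2$chains[[2]] <- f2$chains[[1]]
  p <- psr(f2)
  expect_true(all(abs(p$psr - 1) < 1e-12))
  # chains centred at different constants
  f3 <- f
  f3$chains[[1]]$fixed[] <- 0
  f3$chains[[2]]$fixed[] <- 5
  f3$chains[[1]]$fixed[, 1] <- rnorm(nrow(f3$chains[[1]]$fixed), 0, 0.1)
  f3$chains[[2]]$fixed[, 1] <- rnorm(nrow(f3$chains[[2]]$fixed), 5, 0.1)
  expect_gt(psr(f3)$psr[1], 10)
  # single chain falls back to split-chain with a warning
  f4 <- f
  f4$chains <- f4$chains[1]
  expect_warning(p4 <- psr(f4), "split-chain")
  expect_equal(nrow(p4), 25)
})

test_that("a well-mixed sampler passes its own convergence check", {
  f <- small_fit(seed = 21, n_persons = 10, iterations = 3000)
  p <- psr(f)
  expect_lt(max(p$psr), 1.2)
})

test_that("dic has the stated degenerate and non-degenerate behaviour", {
  f <- small_fit(seed = 7, iterations = 600)
  d <- dic(f)
  expect_gt(d$pd, 0) # Jensen: non-degenerate posterior
  expect_equal(d$dic, d$mean_deviance + d$pd, tolerance = 1e-10)
  # degenerate posterior: every draw identical -> pd = 0, dic = D(theta-hat)
  fd <- f
  ch <- fd$chains[[1]]
  n <- ch$n_keep
  ch$fixed <- ch$fixed[rep(1, n), , drop = FALSE]
  ch$effects <- ch$effects[rep(1, n), , , drop = FALSE]
  ch$states <- ch$states[rep(1, n), , , drop = FALSE]
  ch$deviance <- rep(ch$deviance[1], n)
  for (k in seq_along(fd$chains)) fd$chains[[k]] <- ch
  dd <- dic(fd)
  expect_equal(dd$pd, 0, tolerance = 1e-6)
  expect_equal(dd$dic, dd$deviance_at_means, tolerance = 1e-6)
})

test_that("the C++ deviance matches an independent R evaluation", {
  f <- small_fit(seed = 13, n_persons = 5, iterations = 400, chains = 1)
  ch <- f$chains[[1]]
  k <- ch$n_keep
  # recompute the conditional deviance of the final draw naively
  dev <- 0
  T <- f$t_days
  for (i in seq_along(f$persons)) {
    u <- ch$effects[k, i, ]
    A <- matrix(c(u[3], u[6], u[5], u[4]), 2, 2)
    sds <- exp(u[7:8] / 2)
    w <- rbind(ch$states[k, i, 1:T], ch$states[k, i, T + 1:T])
    for (t in 2:T) {
      if (!f$obs[i, t]) next
      m <- A %*% w[, t - 1]
      dev <- dev + dnorm(w[1, t], m[1], sds[1], log = TRUE) +
        dnorm(w[2, t], m[2], sds[2], log = TRUE)
    }
    V1 <- stationary_covariance(stats::setNames(u, dsem_effect_names()))
    if (is.null(V1)) V1 <- diag(1e6, 2)
    x <- w[, 1]
    dev <- dev - log(2 * pi) - 0.5 * log(det(V1)) -
      0.5 * drop(t(x) %*% solve(V1) %*% x)
  }
  expect_equal(ch$deviance[k], -2 * dev, tolerance = 1e-8)
})

test_that("posterior mode agrees with a numerical maximiser (single subject)", {
  tr <- dsem_params(
    gamma0 = c(mu_sb = 10, mu_pa = 5, phi_sb = 0.4, phi_pa = 0.1,
               beta_sb = -0.2, beta_pa = 0.1, logpsi_sb = 1, logpsi_pa = 0.5),
    tau = 0, sigma_mu = 0
  )
  sim <- simulate_panel(panel_sim_spec(n_persons = 1, t_days = 400, truth = tr, seed = 6))
  pan <- sim$panel
  pan$day_index <- seq_len(nrow(pan))
  f <- dsem_fit(pan, "pain", fit_config(
    iterations = 3000, thin = 3, chains = 1, seed = 2, hierarchical = FALSE
  ))
  eff <- posterior_draws(f, "effects")
  pm <- apply(eff, 3, mean)
  # independent route: maximise the exact single-subject log posterior
  y <- cbind(pan$sb_min, pan$pa_min)
  negll <- function(th) {
    mu <- th[1:2]; A <- matrix(c(th[3], th[6], th[5], th[4]), 2, 2)
    lam <- th[7:8]
    w <- sweep(y, 2, mu)
    n <- nrow(w)
    r <- w[-1, ] - w[-n, ] %*% t(A)
    ll <- sum(dnorm(r[, 1], 0, exp(lam[1] / 2), log = TRUE)) +
      sum(dnorm(r[, 2], 0, exp(lam[2] / 2), log = TRUE))
    V1 <- stationary_covariance(c(
      phi_sb = th[3], phi_pa = th[4], beta_sb = th[5], beta_pa = th[6],
      logpsi_sb = lam[1], logpsi_pa = lam[2]
    ))
    if (is.null(V1)) return(1e10)
    ll <- ll - log(2 * pi) - 0.5 * log(det(V1)) -
      0.5 * drop(t(w[1, ]) %*% solve(V1) %*% w[1, ])
    -ll
  }
  opt <- optim(c(mean(y[, 1]), mean(y[, 2]), 0, 0, 0, 0,
                 log(var(y[, 1])), log(var(y[, 2]))),
               negll, method = "BFGS", control = list(maxit = 500))
  # at T = 400 posterior mean and mode coincide to sampling error
  expect_lt(max(abs(pm[3:6] - opt$par[3:6])), 0.04)
  expect_lt(max(abs(pm[1:2] - opt$par[1:2])), 1.5)
  expect_lt(max(abs(pm[7:8] - opt$par[7:8])), 0.1)
})

test_that("tau posterior is smaller when the truth has no effect spread", {
  tr0 <- default_truth()
  tr0$tau[["phi_sb"]] <- 0
  sim0 <- simulate_panel(panel_sim_spec(n_persons = 30, truth = tr0, seed = 44))
  simv <- simulate_panel(panel_sim_spec(n_persons = 30, seed = 44))
  cfg <- fit_config(iterations = 2000, thin = 4, chains = 1, seed = 10)
  f0 <- dsem_fit(sim0$panel, "pain", cfg)
  fv <- dsem_fit(simv$panel, "pain", cfg)
  m0 <- median(posterior_draws(f0, "fixed")[, "tau[phi_sb]"])
  mv <- median(posterior_draws(fv, "fixed")[, "tau[phi_sb]"])
  expect_lt(m0, mv)
})

test_that("tidy and glance summarise the fit", {
  f <- small_fit(seed = 15, iterations = 600)
  td <- tidy(f)
  expect_equal(nrow(td), 25)
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  expect_true(all(td$p >= 0 & td$p <= 0.5))
  tp <- tidy(f, effects = "person")
  expect_equal(nrow(tp), 8 * 8)
  g <- glance(f)
  expect_equal(g$n_persons, 8)
  expect_equal(g$n_draws, f$n_keep * 2)
  expect_true(is.finite(g$dic))
})
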