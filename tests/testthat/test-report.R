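# A minimal hand-built dsem_fit-shaped object lets the standardization and
# summary machinery be tested deterministically, without MCMC noise.
fake_fit <- function(effects_array, fixed = NULL, pc = NULL, persons = NULL,
                     t_days = 7, hierarchical = TRUE) {
  n_draw <- dim(effects_array)[1]
  N <- dim(effects_array)[2]
  persons <- persons %||% sprintf("f%02d", seq_len(N))
  if (is.null(fixed)) {
    fixed <- matrix(0, n_draw, 25)
    colnames(fixed) <- actidsem:::fixed_param_names()
  }
  obs <- matrix(TRUE, N, t_days)
  structure(
    list(
      chains = list(list(
        fixed = fixed, effects = effects_array,
        states = array(0, dim = c(n_draw, N, 2 * t_days)),
        deviance = rep(0, n_draw), n_keep = n_draw,
        lambda_accept = matrix(0.4, N, 2)
      )),
      config = fit_config(iterations = 10, thin = 1, chains = 1,
                          hierarchical = hierarchical),
      predictor = "pain", persons = persons,
      pc = pc %||% (seq_len(N) - mean(seq_len(N))),
      predictor_raw = pc %||% seq_len(N),
      t_days = t_days, obs = obs,
      y_sb = matrix(0, N, t_days), y_pa = matrix(0, N, t_days),
      n_keep = n_draw
    ),
    class = "dsem_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

effects_cube <- function(draws_list) {
  # draws_list: list over draws of N x 8 matrices (columns in effect order)
  n_draw <- length(draws_list)
  N <- nrow(draws_list[[1]])
  arr <- array(NA_real_, dim = c(n_draw, N, 8))
  for (d in seq_len(n_draw)) arr[d, , ] <- draws_list[[d]]
  arr
}

u_row <- function(mu_sb = 0, mu_pa = 0, phi_sb = 0, phi_pa = 0,
                  beta_sb = 0, beta_pa = 0, logpsi_sb = 0, logpsi_pa = 0) {
  c(mu_sb, mu_pa, phi_sb, phi_pa, beta_sb, beta_pa, logpsi_sb, logpsi_pa)
}

test_that("standardization of a no-dynamics model gives residual 1, R2 0", {
  m <- rbind(u_row(), u_row(logpsi_sb = 2))
  arr <- effects_cube(list(m, m))
  fit <- fake_fit(arr)
  sw <- standardize_within(fit)
  expect_equal(sw$summary$estimate[sw$summary$parameter == "zeta_sb"], 1)
  expect_equal(sw$summary$estimate[sw$summary$parameter == "r2_sb"], 0)
  expect_equal(sw$exclusion_rate, 0)
})

test_that("standardized cross-lags follow the stationary-SD rescaling", {
  u <- u_row(phi_sb = 0.4, phi_pa = 0.2, beta_sb = 0.3, beta_pa = -0.1,
             logpsi_sb = 1.2, logpsi_pa = 0.4)
  arr <- effects_cube(list(matrix(u, 1, 8), matrix(u, 1, 8)))
  fit <- fake_fit(arr)
  sw <- standardize_within(fit)
  V <- stationary_covariance(c(
    phi_sb = 0.4, phi_pa = 0.2, beta_sb = 0.3, beta_pa = -0.1,
    logpsi_sb = 1.2, logpsi_pa = 0.4
  ))
  want_beta_sb <- 0.3 * sqrt(V["pa", "pa"] / V["sb", "sb"])
  want_beta_pa <- -0.1 * sqrt(V["sb", "sb"] / V["pa", "pa"])
  expect_equal(sw$summary$estimate[sw$summary$parameter == "beta_sb"], want_beta_sb)
  expect_equal(sw$summary$estimate[sw$summary$parameter == "beta_pa"], want_beta_pa)
  # identity: R2 = 1 - standardized residual, and phi passes through
  expect_equal(
    sw$summary$estimate[sw$summary$parameter == "r2_sb"],
    1 - sw$summary$estimate[sw$summary$parameter == "zeta_sb"]
  )
  expect_equal(sw$summary$estimate[sw$summary$parameter == "phi_sb"], 0.4)
  # cross-check against simulation-estimated stationary SDs
  set.seed(31)
  A <- matrix(c(0.4, -0.1, 0.3, 0.2), 2, 2)
  w <- simulate_var_path(A, exp(1.2), exp(0.4), 2e5)
  sim_beta_sb <- 0.3 * sd(w[, 2]) / sd(w[, 1])
  expect_equal(want_beta_sb, sim_beta_sb, tolerance = 0.02)
})

test_that("standardized within quantities are scale invariant", {
  set.seed(40)
  draws <- lapply(1:20, function(d) {
    rbind(
      u_row(phi_sb = rnorm(1, 0.2, 0.1), phi_pa = rnorm(1, 0.1, 0.1),
            beta_sb = rnorm(1, 0, 0.2), beta_pa = rnorm(1, 0, 0.05),
            logpsi_sb = rnorm(1, 9, 0.3), logpsi_pa = rnorm(1, 8, 0.3),
            mu_sb = 460, mu_pa = 245),
      u_row(phi_sb = rnorm(1, 0.2, 0.1), phi_pa = rnorm(1, 0.1, 0.1),
            beta_sb = rnorm(1, 0, 0.2), beta_pa = rnorm(1, 0, 0.05),
            logpsi_sb = rnorm(1, 9, 0.3), logpsi_pa = rnorm(1, 8, 0.3),
            mu_sb = 400, mu_pa = 300)
    )
  })
  fit <- fake_fit(effects_cube(draws))
  sw1 <- standardize_within(fit)
  # SB x 2, PA x 0.5 transforms the effect draws deterministically:
  # mu_sb x2, beta_sb x4 (PA -> SB), beta_pa x 1/4, logpsi_sb + 2 log 2,
  # logpsi_pa - 2 log 2; phi unchanged.
  draws2 <- lapply(draws, function(m) {
    m2 <- m
    m2[, 1] <- m[, 1] * 2
    m2[, 2] <- m[, 2] * 0.5
    m2[, 5] <- m[, 5] * 4
    m2[, 6] <- m[, 6] / 4
    m2[, 7] <- m[, 7] + 2 * log(2)
    m2[, 8] <- m[, 8] - 2 * log(2)
    m2
  })
  fit2 <- fake_fit(effects_cube(draws2))
  sw2 <- standardize_within(fit2)
  for (col in c("estimate", "conf.low", "conf.high")) {
    expect_equal(sw2$summary[[col]], sw1$summary[[col]], tolerance = 1e-8)
  }
  expect_equal(sw2$person$phi_sb, sw1$person$phi_sb, tolerance = 1e-8)
})

test_that("antipersistence shares and exclusions are reported", {
  m <- rbind(
    u_row(phi_sb = -0.2, phi_pa = 0.3),
    u_row(phi_sb = 0.1, phi_pa = -0.1),
    u_row(phi_sb = 0.2, phi_pa = 0.2),
    u_row(phi_sb = 1.2, phi_pa = 0.2) # non-stationary: excluded
  )
  fit <- fake_fit(effects_cube(list(m, m)))
  sw <- standardize_within(fit)
  expect_equal(sw$exclusion_rate, 0.25)
  expect_equal(
    sw$antipersistence$share_negative[sw$antipersistence$series == "sb"],
    1 / 3
  )
})

test_that("standardize_between matches its closed forms", {
  n_draw <- 3
  fixed <- matrix(0, n_draw, 25)
  colnames(fixed) <- actidsem:::fixed_param_names()
  fixed[, "gamma1[phi_sb]"] <- 0.1
  fixed[, "tau[phi_sb]"] <- 0.05
  fixed[, "gamma1[mu_sb]"] <- 0
  fixed[, "tau[mu_sb]"] <- 10000
  fixed[, "tau[mu_pa]"] <- 8100
  fixed[, "sigma_mu"] <- -4500
  arr <- effects_cube(rep(list(rbind(u_row(), u_row())), n_draw))
  pc <- c(-1, 1)
  fit <- fake_fit(arr, fixed = fixed, pc = pc)
  sb <- standardize_between(fit)
  var_p <- var(pc)
  want <- 0.1 * sqrt(var_p) / sqrt(0.1^2 * var_p + 0.05)
  expect_equal(sb$estimate[sb$parameter == "phi_sb ON predictor"], want)
  expect_equal(
    sb$estimate[sb$parameter == "r2[phi_sb]"],
    0.1^2 * var_p / (0.1^2 * var_p + 0.05)
  )
  # with all gamma1 = 0 the mu covariance standardizes to a plain correlation
  expect_equal(
    sb$estimate[sb$parameter == "sigma_mu (std)"],
    -4500 / sqrt(10000 * 8100)
  )
  expect_equal(sb$estimate[sb$parameter == "mu_sb ON predictor"], 0)
  expect_equal(sb$estimate[sb$parameter == "r2[mu_sb]"], 0)
})

test_that("standardize_between approaches +/-1 as tau vanishes", {
  n_draw <- 2
  fixed <- matrix(0, n_draw, 25)
  colnames(fixed) <- actidsem:::fixed_param_names()
  fixed[, "gamma1[beta_sb]"] <- -0.3
  fixed[, "tau[beta_sb]"] <- 1e-12
  fixed[, "tau[mu_sb]"] <- 1
  fixed[, "tau[mu_pa]"] <- 1
  arr <- effects_cube(rep(list(rbind(u_row(), u_row())), n_draw))
  fit <- fake_fit(arr, fixed = fixed, pc = c(-2, 2))
  sb <- standardize_between(fit)
  expect_equal(sb$estimate[sb$parameter == "beta_sb ON predictor"], -1,
    tolerance = 1e-6
  )
})

test_that("summarize_posterior follows the credibility-interval conventions", {
  s <- summarize_posterior(rep(c(-1, 1), 50))
  expect_equal(s$p, 0.5)
  expect_false(s$significant)
  s2 <- summarize_posterior(runif(200) + 0.5)
  expect_lt(s2$p, 1 / 200 + 1e-12)
  expect_true(s2$significant)
  set.seed(99)
  s3 <- summarize_posterior(rnorm(1e5))
  expect_equal(s3$conf.low, -1.96, tolerance = 0.03)
  expect_equal(s3$conf.high, 1.96, tolerance = 0.03)
  expect_equal(s3$estimate, 0, tolerance = 0.02)
  expect_true(s3$conf.low <= s3$estimate && s3$estimate <= s3$conf.high)
})

test_that("descriptives reproduce day-wise summaries and Spearman oracle", {
  set.seed(17)
  sim <- simulate_panel(panel_sim_spec(n_persons = 15, seed = 17))
  d <- descriptives(sim$panel)
  expect_equal(nrow(d), 7)
  day1 <- sim$panel[sim$panel$day_index == 1, ]
  expect_equal(d$sb_mean[1], mean(day1$sb_min))
  expect_equal(d$sb_sd[1], sd(day1$sb_min))
  expect_equal(d$wear_mean[1], mean(day1$wear_min))
  want <- brute_spearman(day1$sb_min, day1$pa_min)
  expect_equal(d$spearman_r[1], unname(want["rho"]), tolerance = 1e-12)
  expect_equal(d$spearman_p[1], unname(want["p"]), tolerance = 1e-12)
  # SB share conventions both reported, both in [0, 1]
  expect_true(all(d$sb_share_mean_ratio > 0 & d$sb_share_mean_ratio < 1))
  expect_true(all(d$sb_share_ratio_means > 0 & d$sb_share_ratio_means < 1))
})

test_that("descriptives handle perfect, constant and missing inputs", {
  pan <- tibble::tibble(
    person_id = rep(c("a", "b", "c", "d"), 2),
    day_index = rep(1:2, each = 4),
    sb_min = c(400, 300, 200, 100, 5, 5, 5, 5),
    pa_min = c(100, 200, 300, 400, 1, 2, 3, 4),
    wear_min = sb_min + pa_min
  )
  d <- descriptives(pan)
  expect_equal(d$spearman_r[1], -1) # strictly decreasing
  expect_equal(d$spearman_p[1], 0)
  expect_false(d$correlation_defined[2]) # constant SB: undefined, flagged
  pan2 <- pan
  pan2$sb_min[pan2$day_index == 2] <- NA
  pan2$pa_min[pan2$day_index == 2] <- NA
  pan2$wear_min[pan2$day_index == 2] <- NA
  d2 <- descriptives(pan2)
  expect_equal(d2$n[2], 0)
  expect_true(is.na(d2$sb_mean[2]))
})

test_that("descriptives match the rank oracle on tied integer vectors", {
  set.seed(55)
  for (k in 1:25) {
    n <- sample(5:12, 1)
    x <- sample(0:5, n, replace = TRUE)
    y <- sample(0:5, n, replace = TRUE)
    want <- brute_spearman(x, y)
    got <- actidsem:::spearman_rho(x, y)
    if (is.na(want["rho"])) {
      expect_true(is.na(got[["rho"]]))
    } else {
      expect_equal(got[["rho"]], unname(want["rho"]), tolerance = 1e-12)
      expect_equal(got[["p"]], unname(want["p"]), tolerance = 1e-12)
    }
  }
})

test_that("reported tables are invariant to person order", {
  sim <- simulate_panel(panel_sim_spec(n_persons = 8, seed = 29))
  shuffled <- sim$panel[sample(nrow(sim$panel)), ]
  expect_equal(descriptives(shuffled), descriptives(sim$panel))
})
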