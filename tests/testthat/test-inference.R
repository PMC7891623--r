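test_that("log_posterior equals the sum of its component operations", {
  set.seed(20)
  model <- tiny_model()
  d <- flat_data(60)
  pen <- model$penalty
  pr_w <- weakly_informative_prior(pen, ig_a = 0.01, ig_b = 0.01)
  P <- diag(model$basis$n_basis) * 2
  pr_f <- fixed_effects_prior(rnorm(model$basis$n_basis, 100), P)
  st <- list(beta_mu = rnorm(model$basis$n_basis, 100),
             beta_sigma = rnorm(model$basis$n_basis, log(15), 0.1),
             tau2_mu = 1, tau2_sigma = 3)
  B <- bspline_design(d$age, model$basis)
  expected <- gaussian_loglik(d$score, drop(B %*% st$beta_mu),
                              exp(drop(B %*% st$beta_sigma))) +
    prior_log_density(pr_w, st$beta_mu, st$tau2_mu) +
    ig_log_density(st$tau2_mu, 0.01, 0.01) +
    prior_log_density(pr_f, st$beta_sigma, st$tau2_sigma) +
    ig_log_density(st$tau2_sigma, pr_f$ig_a, pr_f$ig_b)
  expect_equal(log_posterior(st, d, model, pr_w, pr_f), expected,
               tolerance = 1e-10)

  # null-space beta: changing tau moves only the IG + normalization terms
  p <- model$basis$n_basis
  st0 <- st; st0$beta_mu <- rep(3, p)
  for (t2 in c(0.5, 2, 8)) {
    st1 <- st0; st1$tau2_mu <- t2
    diff_lp <- log_posterior(st1, d, model, pr_w, pr_f) -
      log_posterior(st0, d, model, pr_w, pr_f)
    diff_expected <- (ig_log_density(t2, 0.01, 0.01) -
                        ig_log_density(1, 0.01, 0.01)) +
      (-0.5 * pr_w$rank * log(t2))  # normalization; penalty term is zero
    expect_equal(diff_lp, diff_expected, tolerance = 1e-10)
  }

  # flat-prior limit: posterior differences converge to likelihood differences
  st_a <- st; st_b <- st
  st_b$beta_mu <- st$beta_mu + rnorm(p, 0, 0.5)
  st_a$tau2_mu <- st_b$tau2_mu <- 1e12
  lp_diff <- log_posterior(st_b, d, model, pr_w, pr_f) -
    log_posterior(st_a, d, model, pr_w, pr_f)
  ll_diff <- gaussian_loglik(d$score, drop(B %*% st_b$beta_mu),
                             exp(drop(B %*% st_b$beta_sigma))) -
    gaussian_loglik(d$score, drop(B %*% st_a$beta_mu),
                    exp(drop(B %*% st_a$beta_sigma)))
  expect_equal(lp_diff, ll_diff, tolerance = 1e-6)
})

test_that("tau full conditional follows conjugacy algebra", {
  K <- difference_penalty(6, 2)
  fc <- tau_full_conditional(rep(0, 6), K$matrix, a = 0.3, b = 0.7,
                             rank = K$rank)
  expect_equal(fc$shape, 0.3 + K$rank / 2)
  expect_equal(fc$rate, 0.7)
  # constants live in the order-2 null space
  K4 <- difference_penalty(4, 2)
  fc2 <- tau_full_conditional(rep(1, 4), K4$matrix, 1, 2)
  expect_equal(fc2$rate, 2)
  expect_equal(fc2$shape, 1 + K4$rank / 2)

  # grid-search oracle: the analytic conditional density of tau^2 is
  # maximized at rate/(shape + 1)
  set.seed(21)
  beta <- rnorm(5)
  core <- crossprod(matrix(rnorm(25), 5))
  fc3 <- tau_full_conditional(beta, core, a = 2, b = 1)
  log_cond <- function(t2) {
    quad <- drop(t(beta) %*% core %*% beta)
    rk <- qr(core)$rank
    -(2 + rk / 2 + 1) * log(t2) - (1 + quad / 2) / t2
  }
  grid <- exp(seq(log(0.01), log(100), length.out = 4000))
  argmax <- grid[which.max(vapply(grid, log_cond, 0))]
  expect_equal(argmax, fc3$rate / (fc3$shape + 1), tolerance = 0.01)
})

test_that("fit_mcmc enforces its contracts", {
  model <- tiny_model()
  d <- flat_data(40)
  p <- model$basis$n_basis
  pm <- posterior_mode_prior(rep(0, p), diag(p))
  weak <- weakly_informative_prior(model$penalty)
  expect_error(fit_mcmc(d, model, pm, pm), "posterior_mode")
  expect_error(fit_mcmc(d, model, weak, weak, n_iter = 100, n_burnin = 100),
               "exceed")
  d_bad <- d; d_bad$age[1] <- 30
  expect_error(fit_mcmc(d_bad, model, weak, weak), "clamp")
})

test_that("equal seeds give bitwise-identical draws; different seeds differ", {
  model <- tiny_model()
  d <- flat_data(60)
  weak <- weakly_informative_prior(model$penalty)
  f1 <- fit_mcmc(d, model, weak, weak, n_iter = 120, n_burnin = 40, seed = 99)
  f2 <- fit_mcmc(d, model, weak, weak, n_iter = 120, n_burnin = 40, seed = 99)
  expect_identical(f1$chains[[1]]$beta_mu, f2$chains[[1]]$beta_mu)
  expect_identical(f1$chains[[2]]$beta_sigma, f2$chains[[2]]$beta_sigma)
  expect_identical(f1$chains[[1]]$tau2_mu, f2$chains[[1]]$tau2_mu)
  f3 <- fit_mcmc(d, model, weak, weak, n_iter = 120, n_burnin = 40, seed = 100)
  expect_false(identical(f1$chains[[1]]$beta_mu, f3$chains[[1]]$beta_mu))
})

test_that("a near-degenerate fixed-effects prior pins the posterior", {
  model <- tiny_model()
  p <- model$basis$n_basis
  d <- flat_data(50)
  m_mu <- rep(100, p); m_sg <- rep(log(15), p)
  f <- fit_mcmc(d, model,
                fixed_effects_prior(m_mu, 1e8 * diag(p)),
                fixed_effects_prior(m_sg, 1e8 * diag(p)),
                n_iter = 300, n_burnin = 100, seed = 5)
  cm <- coef_means(f)
  expect_lt(max(abs(cm$beta_mu - m_mu)), 1e-2)
  expect_lt(max(abs(cm$beta_sigma - m_sg)), 1e-2)
})

test_that("MCMC recovers constant truth within posterior uncertainty", {
  model <- bdr_model(make_knots(5, 21, 24))
  d <- flat_data(500, mu = 100, sigma = 15, seed = 31)
  weak <- weakly_informative_prior(model$penalty)
  fit <- fit_mcmc(d, model, weak, weak, n_iter = 800, n_burnin = 200, seed = 6)
  B <- bspline_design(seq(5.8, 20.2, length.out = 10), model$basis)
  bm <- do.call(rbind, lapply(fit$chains, `[[`, "beta_mu"))
  bs <- do.call(rbind, lapply(fit$chains, `[[`, "beta_sigma"))
  mu_draws <- bm %*% t(B)
  sg_draws <- exp(bs %*% t(B))
  for (j in 1:10) {
    expect_lt(abs(mean(mu_draws[, j]) - 100), 3 * sd(mu_draws[, j]) + 1e-9)
    expect_lt(abs(mean(sg_draws[, j]) - 15), 3 * sd(sg_draws[, j]) + 1e-9)
  }
  expect_true(all(fit$acceptance_sigma > 0.05))
})

test_that("conjugate toy: mu-block sampling matches the closed-form posterior", {
  # known sigma, fixed tau: the exact posterior of beta_mu is Gaussian
  model <- tiny_model()
  p <- model$basis$n_basis
  sigma <- 10; tau2 <- 4
  d <- flat_data(80, mu = 50, sigma = sigma, seed = 77)
  weak <- weakly_informative_prior(model$penalty)
  fit <- fit_mcmc(d, model, weak, weak, n_iter = 2500, n_burnin = 500,
                  seed = 3, fixed_sigma = sigma,
                  fixed_tau = list(mu = tau2, sigma = 1))
  B <- bspline_design(d$age, model$basis)
  Q <- crossprod(B) / sigma^2 + weak$core / tau2
  Sig <- solve(Q)
  m_post <- drop(Sig %*% crossprod(B, d$score) / sigma^2)
  draws <- do.call(rbind, lapply(fit$chains, `[[`, "beta_mu"))
  n_eff <- nrow(draws)  # draws are iid here (exact Gibbs, no dependence)
  mc_se <- sqrt(diag(Sig) / n_eff)
  expect_true(all(abs(colMeans(draws) - m_post) < 3.5 * mc_se))
  expect_equal(cov(draws), Sig, tolerance = 0.15)
})

test_that("posterior-mode fit matches the ridge closed form and ascends", {
  model <- tiny_model()
  p <- model$basis$n_basis
  sigma <- 8; tau2 <- 2
  d <- flat_data(70, mu = 30, sigma = sigma, seed = 41)
  weak <- weakly_informative_prior(model$penalty)
  fit <- fit_posterior_mode(d, model, weak, weak, fixed_sigma = sigma,
                            fixed_tau = list(mu = tau2, sigma = 1))
  B <- bspline_design(d$age, model$basis)
  ridge <- solve(crossprod(B) / sigma^2 + weak$core / tau2,
                 crossprod(B, d$score) / sigma^2)
  expect_equal(fit$state$beta_mu, drop(ridge), tolerance = 1e-6)

  # full fit: objective trace is non-decreasing
  fit2 <- fit_posterior_mode(d, model, weak, weak)
  expect_true(all(diff(fit2$trace) > -1e-8))
})

test_that("posterior_mode prior at tau = 1 matches the fixed-effects mode", {
  set.seed(42)
  model <- tiny_model()
  p <- model$basis$n_basis
  d <- flat_data(90, mu = 60, sigma = 5, seed = 43)
  P <- crossprod(matrix(rnorm(p * p), p)) / p + diag(p) * 0.3
  m_mu <- rep(60, p); m_sg <- rep(log(5), p)
  f_pm <- fit_posterior_mode(d, model, posterior_mode_prior(m_mu, P),
                             posterior_mode_prior(m_sg, P),
                             fixed_tau = list(mu = 1, sigma = 1))
  f_fe <- fit_posterior_mode(d, model, fixed_effects_prior(m_mu, P),
                             fixed_effects_prior(m_sg, P))
  expect_equal(f_pm$state$beta_mu, f_fe$state$beta_mu, tolerance = 1e-4)
  expect_equal(f_pm$state$beta_sigma, f_fe$state$beta_sigma, tolerance = 1e-4)
})

test_that("gelman_rubin implements the scale-reduction formula", {
  expect_equal(gelman_rubin(list(c(1, 2, 3), c(1, 2, 3))), sqrt(2 / 3))
  # non-overlapping near-constant chains diverge
  expect_gt(gelman_rubin(list(c(0, 1e-6, -1e-6), c(10, 10 + 1e-6, 10 - 1e-6))),
            100)
  expect_equal(gelman_rubin(list(c(0, 0, 0), c(10, 10, 10))), Inf)
  # iid chains from one distribution concentrate near 1
  set.seed(50)
  expect_lt(abs(gelman_rubin(list(rnorm(1e4), rnorm(1e4))) - 1), 0.01)
  expect_error(gelman_rubin(list(1:3)), "two chains")
  expect_error(gelman_rubin(list(1:3, 1:4)), "share a length")
})

test_that("AICc formula and knot selection behave", {
  expect_equal(aicc(-100, 5, 100), 210 + 60 / 94)
  expect_equal(aicc(-100, 5, 100), 210.638, tolerance = 1e-3)
  expect_error(aicc(-10, 10, 11), "undefined")

  # equal fit quality: the penalty is monotone in p, so smaller p wins
  expect_lt(aicc(-50, 4, 80), aicc(-50, 9, 80))

  # data truly linear in age: the penalty shrinks both candidates to a
  # near-linear fit, so the small candidate never loses to the much larger
  # one by more than the AICc complexity penalty allows
  set.seed(51)
  age <- seq(5, 21, length.out = 300)
  d <- data.frame(age = age, score = 2 * age + rnorm(300, 0, 2))
  pick <- select_knots_aicc(d, c(5, 20))
  tab <- attr(pick, "table")
  expect_equal(nrow(tab), 2L)
  expect_true(all(is.finite(tab$aicc)))
  edf_gap <- abs(diff(tab$edf))
  expect_lt(tab$aicc[tab$n_knots == 5] - tab$aicc[tab$n_knots == 20],
            2 * edf_gap + 2)
})
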