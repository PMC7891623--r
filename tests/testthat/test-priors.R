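test_that("weakly informative prior has zero mean and penalty core", {
  pen <- difference_penalty(8, 2)
  pr <- weakly_informative_prior(pen)
  expect_equal(pr$mean, rep(0, 8))
  expect_true(pr$scaled_by_tau)
  expect_equal(pr$core, pen$matrix, ignore_attr = TRUE)

  # null-space invariance: affine beta has the same density as 0
  beta0 <- rep(0, 8)
  aff <- 2 + 0.5 * seq_len(8)
  expect_equal(prior_log_density(pr, aff, 1.3),
               prior_log_density(pr, beta0, 1.3), tolerance = 1e-10)

  # kernel algebra: log-density difference is -beta' K beta / (2 tau^2)
  set.seed(4)
  for (tau2 in c(0.5, 1, 7)) {
    beta <- rnorm(8)
    expect_equal(prior_log_density(pr, beta, tau2) -
                   prior_log_density(pr, beta0, tau2),
                 -drop(t(beta) %*% pen$matrix %*% beta) / (2 * tau2),
                 tolerance = 1e-10)
  }
})

test_that("fixed-effects prior is tau-free with mode at its mean", {
  set.seed(5)
  p <- 5
  A <- matrix(rnorm(p * p), p); P <- crossprod(A) + diag(p)
  m <- rnorm(p)
  pr <- fixed_effects_prior(m, P)
  expect_false(pr$scaled_by_tau)
  # density at the mean beats random points; tau has no effect
  at_m <- prior_log_density(pr, m)
  for (r in 1:5) {
    beta <- m + rnorm(p)
    expect_lt(prior_log_density(pr, beta), at_m)
    expect_equal(prior_log_density(pr, beta, tau_sq = 9),
                 prior_log_density(pr, beta, tau_sq = 0.1))
    expect_equal(prior_log_density(pr, beta) - at_m,
                 -drop(t(beta - m) %*% P %*% (beta - m)) / 2,
                 tolerance = 1e-10)
  }
  # scaling the precision by 4 halves every prior SD: quadratic term x4
  pr4 <- fixed_effects_prior(m, 4 * P)
  beta <- m + rnorm(p)
  expect_equal(prior_log_density(pr4, beta) - prior_log_density(pr4, m),
               4 * (prior_log_density(pr, beta) - at_m), tolerance = 1e-10)
  expect_error(fixed_effects_prior(m, -P), "positive definite")
})

test_that("posterior-mode prior collapses to fixed-effects at tau = 1", {
  set.seed(6)
  p <- 4
  P <- crossprod(matrix(rnorm(p * p), p)) + diag(p)
  m <- rnorm(p)
  pm <- posterior_mode_prior(m, P)
  fe <- fixed_effects_prior(m, P)
  beta <- rnorm(p)
  expect_equal(prior_log_density(pm, beta, tau_sq = 1),
               prior_log_density(fe, beta))
  expect_equal(prior_log_density(pm, beta, 2.5) - prior_log_density(pm, m, 2.5),
               -drop(t(beta - m) %*% P %*% (beta - m)) / (2 * 2.5),
               tolerance = 1e-10)
  # vanishing influence as tau -> infinity: kernel difference goes to 0
  expect_lt(abs(prior_log_density(pm, beta, 1e12) -
                  prior_log_density(pm, m, 1e12)), 1e-9)
})

test_that("every prior kind has concave (quadratic, PSD-curvature) log density", {
  set.seed(7)
  pen <- difference_penalty(6, 2)
  P <- crossprod(matrix(rnorm(36), 6)) + diag(6)
  priors <- list(weakly_informative_prior(pen),
                 fixed_effects_prior(rnorm(6), P),
                 posterior_mode_prior(rnorm(6), P))
  for (pr in priors) {
    b1 <- rnorm(6); b2 <- rnorm(6)
    mid <- prior_log_density(pr, (b1 + b2) / 2, 1.2)
    ends <- (prior_log_density(pr, b1, 1.2) + prior_log_density(pr, b2, 1.2)) / 2
    expect_gte(mid, ends - 1e-10)
  }
})

test_that("inverse-gamma density: closed form, mode, and normalization", {
  expect_equal(ig_log_density(1, 1, 1), -1)
  # mode at b/(a+1)
  for (ab in list(c(2, 3), c(0.5, 0.5), c(4, 1))) {
    a <- ab[1]; b <- ab[2]
    mode <- b / (a + 1)
    grid <- seq(mode * 0.25, mode * 4, length.out = 400)
    expect_equal(grid[which.max(ig_log_density(grid, a, b))], mode,
                 tolerance = 0.05)
    total <- integrate(function(t) exp(ig_log_density(t, a, b)), 0, Inf,
                       rel.tol = 1e-8)$value
    expect_equal(total, 1, tolerance = 1e-5)
  }
  expect_error(ig_log_density(-1, 1, 1), "> 0")
})

test_that("ig_log_density matches the histogram of inverse-gamma draws", {
  set.seed(8)
  a <- 3; b <- 2
  draws <- 1 / rgamma(2e4, shape = a, rate = b)
  brks <- quantile(draws, seq(0, 1, 0.125))
  h <- hist(draws, breaks = brks, plot = FALSE)
  dens_pred <- vapply(seq_len(length(brks) - 1), function(i) {
    integrate(function(t) exp(ig_log_density(t, a, b)), brks[i],
              brks[i + 1])$value / diff(brks[i + 0:1])
  }, 0)
  expect_equal(h$density, dens_pred, tolerance = 0.08)
})

test_that("prior extraction recovers a known Gaussian from synthetic draws", {
  set.seed(9)
  p <- 4
  S0 <- crossprod(matrix(rnorm(p * p), p)) / p + diag(p) * 0.5
  m0 <- rnorm(p, 10)
  R0 <- chol(S0)
  ndr <- 1e5
  draws <- matrix(rnorm(ndr * p), ndr) %*% R0 + rep(m0, each = ndr)
  # package a synthetic fit so the extraction path is the real one
  fit <- structure(list(
    method = "mcmc",
    chains = list(list(beta_mu = draws[1:(ndr / 2), ],
                       beta_sigma = draws[1:(ndr / 2), ]),
                  list(beta_mu = draws[(ndr / 2 + 1):ndr, ],
                       beta_sigma = draws[(ndr / 2 + 1):ndr, ])),
    model = bdr_model(make_knots(5, 21, n_knots = 3, degree = 0,
                                 penalty_order = 1)),
    n_chains = 2L), class = "bdr_fit")
  fit$method <- "mcmc"
  info <- extract_prior_from_fit(fit)
  expect_equal(info$m_mu, m0, tolerance = 0.02)
  expect_equal(info$P_mu, solve(S0), tolerance = 0.1)
  # knots copied verbatim
  expect_identical(info$basis$inner_knots, fit$model$basis$inner_knots)
})

test_that("degenerate (zero-variance) draws are rejected", {
  v <- c(1, 2, 3)
  fit <- structure(list(
    method = "mcmc",
    chains = list(list(beta_mu = matrix(v, 10, 3, byrow = TRUE),
                       beta_sigma = matrix(v, 10, 3, byrow = TRUE)),
                  list(beta_mu = matrix(v, 10, 3, byrow = TRUE),
                       beta_sigma = matrix(v, 10, 3, byrow = TRUE))),
    model = bdr_model(make_knots(5, 21, n_knots = 3, degree = 0,
                                 penalty_order = 1))), class = "bdr_fit")
  expect_error(extract_prior_from_fit(fit), "singular")
  # too few draws relative to dimension
  fit2 <- fit
  fit2$chains <- list(list(beta_mu = matrix(rnorm(3), 1, 3),
                           beta_sigma = matrix(rnorm(3), 1, 3)),
                      list(beta_mu = matrix(rnorm(3), 1, 3),
                           beta_sigma = matrix(rnorm(3), 1, 3)))
  expect_error(extract_prior_from_fit(fit2), "too few retained draws")
})

test_that("prior info serializes through JSON losslessly enough to rebuild", {
  set.seed(10)
  p <- 3
  info <- structure(list(
    m_mu = rnorm(p), P_mu = diag(p) + 0.1,
    m_sigma = rnorm(p), P_sigma = diag(p) * 2,
    basis = basis_to_list(make_knots(5, 21, n_knots = 3, degree = 0,
                                     penalty_order = 1)),
    n_draws = 100L), class = "bdr_prior_info")
  path <- tempfile(fileext = ".json")
  write_prior_info(info, path)
  back <- read_prior_info(path)
  expect_identical(back$m_mu, info$m_mu)
  expect_identical(back$P_mu, unname(info$P_mu))
  expect_identical(as.numeric(back$basis$inner_knots),
                   as.numeric(info$basis$inner_knots))
})
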