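#' Joint log-posterior of the location-scale model
#'
#' Log-likelihood plus, for each of the two terms, the coefficient log-prior
#' given its smoothing variance and the inverse-gamma log-density of the
#' smoothing variance itself. For `fixed_effects` terms the smoothing
#' variance keeps its inverse-gamma prior but does not enter the coefficient
#' prior.
#'
#' @param state List with `beta_mu`, `beta_sigma`, `tau2_mu`, `tau2_sigma`
#'   (smoothing variances, `> 0`).
#' @param data List or data frame with numeric `age` and `score`.
#' @param model A [bdr_model()].
#' @param prior_mu,prior_sigma `term_prior` objects for the two terms.
#' @return Scalar log-posterior (up to the constant of proportionality of
#'   the posterior, i.e. the marginal likelihood).
#' @export
log_posterior <- function(state, data, model, prior_mu, prior_sigma) {
  B <- bspline_design(data$age, model$basis)
  eta_mu <- additive_predictor(state$beta_mu, B)
  eta_sg <- additive_predictor(state$beta_sigma, B)
  par <- invert_links(eta_mu, pmin(pmax(eta_sg, -ETA_SIGMA_BOUND), ETA_SIGMA_BOUND))
  gaussian_loglik(data$score, par$mu, par$sigma) +
    prior_log_density(prior_mu, state$beta_mu, state$tau2_mu) +
    ig_log_density(state$tau2_mu, prior_mu$ig_a, prior_mu$ig_b) +
    prior_log_density(prior_sigma, state$beta_sigma, state$tau2_sigma) +
    ig_log_density(state$tau2_sigma, prior_sigma$ig_a, prior_sigma$ig_b)
}

#' Full conditional of a smoothing variance
#'
#' Under the Gaussian term prior \eqn{N(m, \tau^2 C^{-})} and the
#' inverse-gamma hyperprior IG(a, b), the full conditional of \eqn{\tau^2}
#' is inverse-gamma with shape `a + rank(C)/2` and rate
#' `b + beta' C beta / 2` (pass `beta - m` for a non-zero prior mean).
#'
#' @param beta Coefficient vector (already centred at the prior mean).
#' @param core PSD precision core matrix `C`.
#' @param a,b Inverse-gamma hyperparameters.
#' @param rank Rank of `core`; computed from its eigenvalues if omitted.
#' @return List with `shape` and `rate`.
#' @export
tau_full_conditional <- function(beta, core, a, b, rank = NULL) {
  core <- as.matrix(core)
  if (is.null(rank)) {
    ev <- eigen((core + t(core)) / 2, symmetric = TRUE, only.values = TRUE)$values
    rank <- sum(ev > max(ev) * 1e-8)
  }
  quad <- drop(crossprod(beta, core %*% beta))
  list(shape = a + rank / 2, rate = b + quad / 2)
}

validate_norm_data <- function(data, basis) {
  if (is.null(data$age) || is.null(data$score)) {
    stop("data must have 'age' and 'score' components")
  }
  age <- as.numeric(data$age); score <- as.numeric(data$score)
  if (length(age) != length(score)) stop("age and score lengths differ")
  if (anyNA(age) || anyNA(score)) stop("data contain missing values")
  lo <- basis$inner_range[1]; hi <- basis$inner_range[2]
  eps <- 1e-8 * (hi - lo)
  if (any(age < lo - eps | age > hi + eps)) {
    stop("ages outside the basis inner range [", lo, ", ", hi,
         "]; clamp them first (clamp_ages)")
  }
  list(age = age, score = score)
}

# deterministic initialization: beta_mu from (barely ridged) least squares;
# beta_sigma from a moving-window SD of the residuals projected on the basis
initial_state <- function(B, y, age) {
  p <- ncol(B); n <- nrow(B)
  ridge <- diag(1e-8 * sum(B^2) / p, p)
  beta_mu <- drop(solve(crossprod(B) + ridge, crossprod(B, y)))
  r <- y - drop(B %*% beta_mu)
  ord <- order(age)
  w <- max(5L, min(50L, n %/% 10L))
  sd_run <- numeric(n)
  r_sorted <- r[ord]
  for (i in seq_len(n)) {
    lo <- max(1L, i - w); hi <- min(n, i + w)
    sd_run[i] <- stats::sd(r_sorted[lo:hi])
  }
  sd_run[!is.finite(sd_run) | sd_run <= 0] <- max(stats::sd(r), 1e-3)
  log_sd <- numeric(n); log_sd[ord] <- log(sd_run)
  beta_sg <- drop(solve(crossprod(B) + ridge, crossprod(B, log_sd)))
  list(beta_mu = beta_mu, beta_sigma = beta_sg, tau2_mu = 10, tau2_sigma = 10)
}

prior_precision_at <- function(prior, tau2) {
  if (prior$scaled_by_tau) prior$core / tau2 else prior$core
}

#' Fit by Metropolis-within-Gibbs MCMC
#'
#' Runs `n_chains` sequential Markov chains (seeded `seed`, `seed + 1`, ...)
#' of a Metropolis-within-Gibbs sampler: the mu coefficients are drawn from
#' their exact Gaussian full conditional, the sigma coefficients by an MH
#' step with an iteratively weighted least squares proposal, and the
#' smoothing variances from their conjugate inverse-gamma full conditionals.
#' Only `weakly_informative` and `fixed_effects` priors admit MCMC; the
#' `posterior_mode` prior (penalty constraints on top of a transferred
#' precision) must be fitted with [fit_posterior_mode()].
#'
#' @param data List or data frame with `age` and `score`; ages must lie in
#'   the basis inner range (see [clamp_ages()]).
#' @param model A [bdr_model()].
#' @param prior_mu,prior_sigma `term_prior` objects.
#' @param n_chains,n_iter,n_burnin MCMC settings. Defaults follow the
#'   convention of two chains of 2000 iterations with 500 burn-in.
#' @param seed Integer seed; chain `c` uses `seed + c - 1`.
#' @param step_scale Multiplier on the sigma-block proposal spread. The
#'   sampler halves it automatically if mid-burn-in acceptance drops below
#'   5%; a run that accepts nothing during burn-in errors and advises
#'   setting this below 1.
#' @param fixed_sigma Optional known residual SD (scalar or length-n vector);
#'   fixes the scale part of the model and samples only the mu term.
#'   Intended for validation against closed-form posteriors.
#' @param fixed_tau Optional list with `mu` and/or `sigma`: fixes the
#'   smoothing variances instead of sampling them (validation use).
#' @return A `bdr_fit` with per-chain retained draws, acceptance rates, and
#'   split-free Gelman-Rubin `rhat` per spline coefficient.
#' @export
fit_mcmc <- function(data, model, prior_mu, prior_sigma,
                     n_chains = 2L, n_iter = 2000L, n_burnin = 500L,
                     seed = 1L, step_scale = 1, fixed_sigma = NULL,
                     fixed_tau = NULL) {
  stopifnot(inherits(model, "bdr_model"), inherits(prior_mu, "term_prior"),
            inherits(prior_sigma, "term_prior"))
  if (prior_mu$kind == "posterior_mode" || prior_sigma$kind == "posterior_mode") {
    stop("MCMC sampling is not available for the posterior_mode prior ",
         "(transferred precision combined with additional penalty ",
         "constraints); use fit_posterior_mode()")
  }
  if (n_iter <= n_burnin) stop("n_iter must exceed n_burnin")
  d <- validate_norm_data(data, model$basis)
  B <- bspline_design(d$age, model$basis)
  n <- nrow(B)

  init <- initial_state(B, d$score, d$age)
  fixed_eta <- numeric(0)
  if (!is.null(fixed_sigma)) {
    fs <- rep_len(as.numeric(fixed_sigma), n)
    if (any(fs <= 0)) stop("fixed_sigma must be positive")
    fixed_eta <- log(fs)
    init$beta_sigma <- rep(0, ncol(B))
  }
  sample_tau <- is.null(fixed_tau)
  if (!is.null(fixed_tau)) {
    if (!is.null(fixed_tau$mu)) init$tau2_mu <- fixed_tau$mu
    if (!is.null(fixed_tau$sigma)) init$tau2_sigma <- fixed_tau$sigma
  }

  lp0 <- tryCatch(
    log_posterior(init, d, model, prior_mu, prior_sigma),
    error = function(e) NaN)
  if (!is.finite(lp0) && is.null(fixed_sigma)) {
    stop("non-finite log-posterior at the initial state (", lp0,
         "); check data scaling and prior hyperparameters")
  }

  chains <- vector("list", n_chains)
  accept <- numeric(n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(as.integer((seed + ch - 1L) %% .Machine$integer.max))
    res <- .mcmc_chain_cpp(
      B, d$score,
      prior_mu$mean, prior_mu$core, prior_mu$scaled_by_tau, prior_mu$rank,
      prior_sigma$mean, prior_sigma$core, prior_sigma$scaled_by_tau,
      prior_sigma$rank,
      prior_mu$ig_a, prior_mu$ig_b,
      as.integer(n_iter), as.integer(n_burnin),
      init$beta_mu, init$beta_sigma, init$tau2_mu, init$tau2_sigma,
      step_scale, TRUE, is.null(fixed_sigma), sample_tau, fixed_eta)
    if (is.null(fixed_sigma) && n_burnin > 0 &&
        isTRUE(res$accept_sigma_burnin == 0)) {
      stop("sigma block accepted no proposals during burn-in; ",
           "override the proposal spread with a smaller step_scale")
    }
    chains[[ch]] <- res
    accept[ch] <- res$accept_sigma
  }

  p <- ncol(B)
  rhat <- rep(NA_real_, 2L * p)
  names(rhat) <- c(paste0("beta_mu[", seq_len(p), "]"),
                   paste0("beta_sigma[", seq_len(p), "]"))
  if (n_chains >= 2L) {
    for (j in seq_len(p)) {
      rhat[j] <- gelman_rubin(lapply(chains, function(c) c$beta_mu[, j]))
      if (is.null(fixed_sigma)) {
        rhat[p + j] <- gelman_rubin(lapply(chains, function(c) c$beta_sigma[, j]))
      }
    }
  }

  structure(
    list(method = "mcmc", chains = chains, model = model,
         prior_kinds = c(mu = prior_mu$kind, sigma = prior_sigma$kind),
         n_chains = n_chains, n_iter = n_iter, n_burnin = n_burnin,
         seed = seed, acceptance_sigma = accept, rhat = rhat,
         fixed_sigma = fixed_sigma, n_obs = n),
    class = "bdr_fit"
  )
}

#' Fit by maximizing the log-posterior
#'
#' Alternating block maximization: the mu coefficients have an exact
#' penalized weighted least squares update, the sigma coefficients are
#' updated by Fisher-scoring steps with step-halving to guarantee ascent,
#' and each smoothing variance is set to the mode of its inverse-gamma full
#' conditional, `rate / (shape + 1)`. Iteration stops when the log-posterior
#' gain falls below `tol`. Works with all three prior kinds (it is the only
#' estimator available for the `posterior_mode` prior).
#'
#' @inheritParams fit_mcmc
#' @param tol Convergence tolerance on the log-posterior gain.
#' @param max_iter Maximum outer iterations.
#' @return A `bdr_fit` with `method = "mode"`, the maximizing `state`, and
#'   the trace of log-posterior values.
#' @export
fit_posterior_mode <- function(data, model, prior_mu, prior_sigma,
                               tol = 1e-6, max_iter = 200L,
                               fixed_sigma = NULL, fixed_tau = NULL) {
  stopifnot(inherits(model, "bdr_model"))
  d <- validate_norm_data(data, model$basis)
  B <- bspline_design(d$age, model$basis)
  n <- nrow(B); p <- ncol(B)
  BtB <- crossprod(B)
  jitter <- diag(1e-10 * sum(diag(BtB)) / p, p)

  st <- initial_state(B, d$score, d$age)
  if (!is.null(fixed_tau)) {
    if (!is.null(fixed_tau$mu)) st$tau2_mu <- fixed_tau$mu
    if (!is.null(fixed_tau$sigma)) st$tau2_sigma <- fixed_tau$sigma
  }
  fs <- if (!is.null(fixed_sigma)) rep_len(as.numeric(fixed_sigma), n) else NULL

  eta_sigma <- function(state) {
    if (!is.null(fs)) log(fs)
    else pmin(pmax(drop(B %*% state$beta_sigma), -ETA_SIGMA_BOUND),
              ETA_SIGMA_BOUND)
  }
  lp <- function(state) {
    sg <- exp(eta_sigma(state))
    val <- gaussian_loglik(d$score, drop(B %*% state$beta_mu), sg) +
      prior_log_density(prior_mu, state$beta_mu, state$tau2_mu) +
      ig_log_density(state$tau2_mu, prior_mu$ig_a, prior_mu$ig_b)
    if (is.null(fs)) {
      val <- val +
        prior_log_density(prior_sigma, state$beta_sigma, state$tau2_sigma) +
        ig_log_density(state$tau2_sigma, prior_sigma$ig_a, prior_sigma$ig_b)
    }
    val
  }

  trace <- lp(st)
  for (it in seq_len(max_iter)) {
    # mu block: exact maximizer of the conditional (quadratic) objective
    sig2 <- exp(2 * eta_sigma(st))
    P <- prior_precision_at(prior_mu, st$tau2_mu)
    Q <- crossprod(B, B / sig2) + P + jitter
    st$beta_mu <- drop(solve(Q, crossprod(B, d$score / sig2) + P %*% prior_mu$mean))

    # sigma block: Fisher scoring with step-halving (ascent guaranteed)
    if (is.null(fs)) {
      r <- d$score - drop(B %*% st$beta_mu)
      Ps <- prior_precision_at(prior_sigma, st$tau2_sigma)
      for (inner in 1:10) {
        cur <- st$beta_sigma
        eta <- eta_sigma(st)
        z <- eta + 0.5 * (r^2 * exp(-2 * eta) - 1)
        cand <- drop(solve(2 * BtB + Ps + jitter,
                           2 * crossprod(B, z) + Ps %*% prior_sigma$mean))
        f_cur <- lp(st)
        step <- 1
        repeat {
          st$beta_sigma <- cur + step * (cand - cur)
          if (lp(st) >= f_cur - 1e-12 || step < 1e-4) break
          step <- step / 2
        }
        if (lp(st) < f_cur) { st$beta_sigma <- cur; break }
        if (sqrt(sum((st$beta_sigma - cur)^2)) < 1e-10) break
      }
    }

    # smoothing variances: mode of the IG full conditional
    if (is.null(fixed_tau) || is.null(fixed_tau$mu)) {
      if (prior_mu$scaled_by_tau) {
        fc <- tau_full_conditional(st$beta_mu - prior_mu$mean, prior_mu$core,
                                   prior_mu$ig_a, prior_mu$ig_b,
                                   rank = prior_mu$rank)
        st$tau2_mu <- fc$rate / (fc$shape + 1)
      } else {
        st$tau2_mu <- prior_mu$ig_b / (prior_mu$ig_a + 1)
      }
    }
    if ((is.null(fixed_tau) || is.null(fixed_tau$sigma)) && is.null(fs)) {
      if (prior_sigma$scaled_by_tau) {
        fc <- tau_full_conditional(st$beta_sigma - prior_sigma$mean,
                                   prior_sigma$core, prior_sigma$ig_a,
                                   prior_sigma$ig_b, rank = prior_sigma$rank)
        st$tau2_sigma <- fc$rate / (fc$shape + 1)
      } else {
        st$tau2_sigma <- prior_sigma$ig_b / (prior_sigma$ig_a + 1)
      }
    }

    trace <- c(trace, lp(st))
    k <- length(trace)
    if (abs(trace[k] - trace[k - 1]) < tol) {
      return(structure(
        list(method = "mode", state = st, model = model,
             prior_kinds = c(mu = prior_mu$kind, sigma = prior_sigma$kind),
             log_posterior = trace[k], trace = trace, n_iter = it,
             fixed_sigma = fixed_sigma, n_obs = n),
        class = "bdr_fit"))
    }
  }
  stop("posterior-mode optimization did not converge in ", max_iter,
       " iterations; objective trace: ",
       paste(utils::tail(round(trace, 4), 8), collapse = ", "))
}

#' @export
print.bdr_fit <- function(x, ...) {
  cat("bdrnorm fit (", x$method, "), n =", x$n_obs,
      "| priors:", x$prior_kinds["mu"], "/", x$prior_kinds["sigma"], "\n")
  if (x$method == "mcmc") {
    cat("  chains:", x$n_chains, "x", x$n_iter, "iterations (",
        x$n_burnin, "burn-in ) | sigma-block acceptance:",
        paste(round(x$acceptance_sigma, 3), collapse = ", "), "\n")
    cat("  max Rhat:", round(max(x$rhat, na.rm = TRUE), 4), "\n")
  } else {
    cat("  log-posterior:", round(x$log_posterior, 4), "after", x$n_iter,
        "outer iterations\n")
  }
  invisible(x)
}

#' Posterior-mean (or modal) coefficients of a fit
#'
#' @param fit A `bdr_fit`.
#' @return List with `beta_mu` and `beta_sigma`.
#' @export
coef_means <- function(fit) {
  stopifnot(inherits(fit, "bdr_fit"))
  if (fit$method == "mcmc") {
    list(beta_mu = colMeans(do.call(rbind, lapply(fit$chains, `[[`, "beta_mu"))),
         beta_sigma = colMeans(do.call(rbind, lapply(fit$chains, `[[`, "beta_sigma"))))
  } else {
    list(beta_mu = fit$state$beta_mu, beta_sigma = fit$state$beta_sigma)
  }
}

#' Plug-in mu and sigma curves from a fit
#'
#' Returns vectorized functions `mu_fn(age)` and `sigma_fn(age)` evaluated
#' at the posterior-mean (MCMC) or modal coefficients. Ages are clamped to
#' the basis inner range before evaluation.
#'
#' @param fit A `bdr_fit`.
#' @return List with functions `mu_fn` and `sigma_fn`.
#' @export
fitted_curves <- function(fit) {
  cm <- coef_means(fit)
  basis <- fit$model$basis
  fixed <- fit$fixed_sigma
  mu_fn <- function(age) {
    B <- bspline_design(clamp_ages(age, basis$inner_range), basis)
    drop(B %*% cm$beta_mu)
  }
  sigma_fn <- function(age) {
    if (!is.null(fixed)) return(rep_len(as.numeric(fixed), length(age)))
    B <- bspline_design(clamp_ages(age, basis$inner_range), basis)
    exp(pmin(pmax(drop(B %*% cm$beta_sigma), -ETA_SIGMA_BOUND), ETA_SIGMA_BOUND))
  }
  list(mu_fn = mu_fn, sigma_fn = sigma_fn)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' \eqn{\hat R = \sqrt{((n-1)/n \cdot W + B/n) / W}} with `W` the mean
#' within-chain variance and `B` the between-chain variance of chain means
#' times `n`. Identical chains give \eqn{\sqrt{(n-1)/n}}; non-overlapping
#' constant chains give `Inf`. Values below 1.1 are conventionally taken as
#' converged.
#'
#' @param chains List of at least two numeric vectors of equal length
#'   `n >= 2` (retained, unpooled traces).
#' @return Scalar \eqn{\hat R}.
#' @export
gelman_rubin <- function(chains) {
  if (!is.list(chains) || length(chains) < 2L) {
    stop("need at least two chains")
  }
  n <- unique(vapply(chains, length, 1L))
  if (length(n) != 1L || n < 2L) stop("chains must share a length >= 2")
  W <- mean(vapply(chains, stats::var, 1))
  Bv <- n * stats::var(vapply(chains, mean, 1))
  if (W == 0) {
    if (Bv > 0) return(Inf)
    return(1)
  }
  sqrt(((n - 1) / n * W + Bv / n) / W)
}

#' Corrected Akaike information criterion
#'
#' `AICc = -2 loglik + 2p + 2p(p+1)/(n - p - 1)`.
#'
#' @param loglik Maximized log-likelihood.
#' @param p Effective number of parameters.
#' @param n Number of observations; requires `n - p - 1 > 0`.
#' @return Scalar AICc.
#' @export
aicc <- function(loglik, p, n) {
  if (n - p - 1 <= 0) stop("AICc undefined: n - p - 1 <= 0")
  -2 * loglik + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

#' Select the number of inner knots by AICc
#'
#' Fits each candidate knot count by posterior mode with weakly informative
#' priors and picks the AICc-minimizing count. The effective number of
#' parameters is the sum of the trace of the smoother matrix of each term
#' plus one per smoothing variance; ties break toward the smaller count.
#'
#' @param data List or data frame with `age` and `score`.
#' @param candidate_knot_counts Integer vector of inner-knot counts.
#' @param degree,penalty_order Basis settings (defaults: cubic, order 2).
#' @param ig_a,ig_b Smoothing-variance hyperparameters.
#' @return The selected knot count (integer), with the AICc table in
#'   attribute `"table"`.
#' @export
select_knots_aicc <- function(data, candidate_knot_counts, degree = 3L,
                              penalty_order = 2L, ig_a = 1e-4, ig_b = 1e-4) {
  age <- as.numeric(data$age)
  n <- length(age)
  rows <- lapply(sort(unique(as.integer(candidate_knot_counts))), function(k) {
    basis <- make_knots(min(age), max(age), n_knots = k, degree = degree,
                        penalty_order = penalty_order)
    model <- bdr_model(basis)
    prior <- weakly_informative_prior(model$penalty, ig_a, ig_b)
    fit <- fit_posterior_mode(data, model, prior, prior)
    st <- fit$state
    B <- bspline_design(age, basis)
    sig2 <- exp(2 * pmin(pmax(drop(B %*% st$beta_sigma), -ETA_SIGMA_BOUND),
                         ETA_SIGMA_BOUND))
    Xw_mu <- crossprod(B, B / sig2)
    edf_mu <- sum(diag(solve(Xw_mu + prior_precision_at(prior, st$tau2_mu),
                             Xw_mu)))
    Xw_sg <- 2 * crossprod(B)
    edf_sg <- sum(diag(solve(Xw_sg + prior_precision_at(prior, st$tau2_sigma),
                             Xw_sg)))
    p <- edf_mu + edf_sg + 2
    if (n - p - 1 <= 0) {
      warning("knot count ", k, " skipped: n - p - 1 <= 0")
      return(data.frame(n_knots = k, edf = p, aicc = NA_real_))
    }
    ll <- gaussian_loglik(data$score, drop(B %*% st$beta_mu), sqrt(sig2))
    data.frame(n_knots = k, edf = p, aicc = aicc(ll, p, n))
  })
  tab <- do.call(rbind, rows)
  ok <- tab[!is.na(tab$aicc), , drop = FALSE]
  if (nrow(ok) == 0) stop("no admissible knot count among the candidates")
  best <- ok$n_knots[which.min(ok$aicc)]   # sorted input => ties pick smallest
  structure(as.integer(best), table = tab)
}
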