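#' Coefficient priors for one P-spline term
#'
#' Three Gaussian prior laws on a term's coefficient vector are supported:
#'
#' * **weakly informative** — \eqn{N(0, \tau^2 K^{-})}, with `K` the
#'   difference-penalty matrix. Encodes only smoothness; partially improper
#'   (rank of `K` is `n_basis - order`).
#' * **fixed effects** — \eqn{N(m, \hat P^{-1})}: mean and precision taken
#'   from a stage-one posterior, with *no* scaling by the smoothing variance.
#'   The stage-one fit was already penalized, so smoothness is baked into
#'   \eqn{\hat P}; MCMC remains possible in stage two.
#' * **posterior mode** — \eqn{N(m, \tau^2 \hat P^{-1})}: as above but with a
#'   free scale \eqn{\tau^2}. Combined with the stage-two penalty structure,
#'   MCMC is not available for this construction; fits using it must use the
#'   posterior-mode optimiser.
#'
#' Every prior carries the inverse-gamma hyperparameters `(a, b)` of the
#' smoothing-variance prior. Defaults are the vague `a = b = 1e-4`.
#'
#' @name term_priors
NULL

new_term_prior <- function(kind, mean, core, scaled_by_tau, ig_a, ig_b,
                           rank = NULL) {
  stopifnot(ig_a > 0, ig_b > 0)
  core <- as.matrix(core)
  if (!isTRUE(all.equal(core, t(core), tolerance = 1e-10))) {
    stop("precision core must be symmetric")
  }
  core <- (core + t(core)) / 2
  if (length(mean) != nrow(core)) {
    stop("prior mean length (", length(mean),
         ") does not match precision dimension (", nrow(core), ")")
  }
  ev <- eigen(core, symmetric = TRUE, only.values = TRUE)$values
  tol <- max(ev) * 1e-8
  est_rank <- sum(ev > tol)
  if (is.null(rank)) rank <- est_rank
  if (min(ev) < -tol) stop("precision core is not positive semi-definite")
  structure(
    list(kind = kind, mean = as.numeric(mean), core = core,
         scaled_by_tau = scaled_by_tau, ig_a = ig_a, ig_b = ig_b,
         rank = rank, logdet_core = sum(log(ev[ev > tol]))),
    class = "term_prior"
  )
}

#' @rdname term_priors
#' @param penalty A `penalty_matrix` from [difference_penalty()].
#' @param ig_a,ig_b Inverse-gamma hyperparameters for the smoothing
#'   variance, both `> 0`.
#' @return A `term_prior` object.
#' @export
weakly_informative_prior <- function(penalty, ig_a = 1e-4, ig_b = 1e-4) {
  stopifnot(inherits(penalty, "penalty_matrix"))
  new_term_prior("weakly_informative",
                 mean = rep(0, nrow(penalty$matrix)),
                 core = penalty$matrix, scaled_by_tau = TRUE,
                 ig_a = ig_a, ig_b = ig_b, rank = penalty$rank)
}

#' @rdname term_priors
#' @param m Prior mean vector (stage-one posterior mean).
#' @param P_hat Prior precision matrix (stage-one posterior precision);
#'   must be strictly positive definite.
#' @export
fixed_effects_prior <- function(m, P_hat, ig_a = 1e-4, ig_b = 1e-4) {
  ch <- tryCatch(chol(P_hat), error = function(e) NULL)
  if (is.null(ch)) stop("P_hat is not positive definite (Cholesky failed)")
  new_term_prior("fixed_effects", mean = m, core = P_hat,
                 scaled_by_tau = FALSE, ig_a = ig_a, ig_b = ig_b,
                 rank = nrow(as.matrix(P_hat)))
}

#' @rdname term_priors
#' @export
posterior_mode_prior <- function(m, P_hat, ig_a = 1e-4, ig_b = 1e-4) {
  ch <- tryCatch(chol(P_hat), error = function(e) NULL)
  if (is.null(ch)) stop("P_hat is not positive definite (Cholesky failed)")
  new_term_prior("posterior_mode", mean = m, core = P_hat,
                 scaled_by_tau = TRUE, ig_a = ig_a, ig_b = ig_b,
                 rank = nrow(as.matrix(P_hat)))
}

#' @export
print.term_prior <- function(x, ...) {
  cat("term prior:", x$kind, "| dim", length(x$mean),
      "| rank", x$rank,
      if (x$scaled_by_tau) "| scaled by tau^2" else "| tau-free",
      "| IG(", x$ig_a, ",", x$ig_b, ")\n")
  invisible(x)
}

#' Log density of a coefficient prior
#'
#' Evaluates the (log) Gaussian prior density of a coefficient vector given
#' the smoothing variance. For rank-deficient cores (the weakly informative
#' prior) the partially improper convention is used: the density is taken on
#' the row space of the penalty, with \eqn{\tau^2} entering through
#' \eqn{-\mathrm{rank}/2 \cdot \log\tau^2}.
#'
#' @param prior A `term_prior`.
#' @param beta Coefficient vector.
#' @param tau_sq Smoothing variance; ignored for `fixed_effects` priors.
#' @return Scalar log density.
#' @export
prior_log_density <- function(prior, beta, tau_sq = 1) {
  stopifnot(inherits(prior, "term_prior"))
  d <- beta - prior$mean
  quad <- drop(crossprod(d, prior$core %*% d))
  if (prior$scaled_by_tau) {
    if (tau_sq <= 0) stop("tau_sq must be positive")
    -0.5 * prior$rank * (log(2 * pi) + log(tau_sq)) +
      0.5 * prior$logdet_core - quad / (2 * tau_sq)
  } else {
    -0.5 * prior$rank * log(2 * pi) + 0.5 * prior$logdet_core - quad / 2
  }
}

#' Inverse-gamma log density
#'
#' Density \eqn{b^a/\Gamma(a) \cdot x^{-(a+1)} e^{-b/x}} of the smoothing
#' variance prior, evaluated on the log scale (normalizing constant
#' included). Its mode is at `b / (a + 1)`.
#'
#' @param tau_sq Evaluation point, `> 0`.
#' @param a,b Shape and rate hyperparameters, both `> 0`.
#' @return Scalar log density.
#' @export
ig_log_density <- function(tau_sq, a, b) {
  if (any(tau_sq <= 0) || a <= 0 || b <= 0) {
    stop("ig_log_density requires tau_sq, a, b > 0")
  }
  a * log(b) - lgamma(a) - (a + 1) * log(tau_sq) - b / tau_sq
}

#' Extract informative-prior ingredients from a stage-one fit
#'
#' Computes, for each distributional parameter, the posterior mean of the
#' spline coefficients and the posterior precision matrix (inverse of the
#' sample covariance of the pooled post-burn-in draws), together with the
#' knot locations. These are the three ingredients a stage-two fit needs to
#' build an informative prior. A small diagonal ridge
#' (`1e-8 * trace / n_basis`) is added to each covariance before inversion
#' to tolerate near-singular draw covariances.
#'
#' @param fit A `bdr_fit` from [fit_mcmc()] (draws required).
#' @return An object of class `bdr_prior_info`: list with `m_mu`, `P_mu`,
#'   `m_sigma`, `P_sigma`, `basis` (serialized basis spec), `n_draws`.
#' @export
extract_prior_from_fit <- function(fit) {
  stopifnot(inherits(fit, "bdr_fit"))
  if (fit$method != "mcmc") {
    stop("informative priors are extracted from MCMC fits; this is a ",
         fit$method, " fit")
  }
  pool_mu <- do.call(rbind, lapply(fit$chains, `[[`, "beta_mu"))
  pool_sg <- do.call(rbind, lapply(fit$chains, `[[`, "beta_sigma"))
  p <- ncol(pool_mu)
  if (nrow(pool_mu) < p + 2L) {
    stop("too few retained draws (", nrow(pool_mu),
         ") to estimate a posterior precision; need at least ", p + 2L)
  }
  prec <- function(draws, label) {
    S <- stats::cov(draws)
    ridge <- 1e-8 * sum(diag(S)) / ncol(S)
    P <- tryCatch(solve(S + diag(ridge, ncol(S))), error = function(e) NULL)
    if (is.null(P)) {
      stop("posterior covariance of ", label, " draws is singular; ",
           "more draws are needed (have ", nrow(draws), ", basis dim ",
           ncol(draws), ")")
    }
    (P + t(P)) / 2
  }
  structure(
    list(m_mu = colMeans(pool_mu), P_mu = prec(pool_mu, "mu"),
         m_sigma = colMeans(pool_sg), P_sigma = prec(pool_sg, "sigma"),
         basis = basis_to_list(fit$model$basis),
         n_draws = nrow(pool_mu)),
    class = "bdr_prior_info"
  )
}

#' Read / write informative-prior objects
#'
#' The `bdr_prior_info` object is the hand-off artifact between the
#' stage-one fit (e.g. old norms, norms from another country) and the
#' stage-two fit. It serializes to JSON with full double precision so knots
#' round-trip bit-exactly.
#'
#' @param info A `bdr_prior_info`.
#' @param path File path for the JSON artifact.
#' @export
write_prior_info <- function(info, path) {
  stopifnot(inherits(info, "bdr_prior_info"))
  obj <- list(m_mu = info$m_mu, P_mu = info$P_mu,
              m_sigma = info$m_sigma, P_sigma = info$P_sigma,
              basis = info$basis, n_draws = info$n_draws)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_prior_info
#' @export
read_prior_info <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(m_mu = as.numeric(obj$m_mu), P_mu = as.matrix(obj$P_mu),
         m_sigma = as.numeric(obj$m_sigma), P_sigma = as.matrix(obj$P_sigma),
         basis = obj$basis, n_draws = obj$n_draws),
    class = "bdr_prior_info"
  )
}
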