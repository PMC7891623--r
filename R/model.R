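#' Gaussian location-scale model specification
#'
#' The response is modelled as \eqn{y_i \sim N(\mu(x_i), \sigma(x_i)^2)} with
#' \eqn{\mu = B \beta_\mu} (identity link) and
#' \eqn{\log \sigma = B \beta_\sigma} (log link, guaranteeing
#' \eqn{\sigma > 0}). Both distributional parameters use one P-spline term in
#' the single predictor (age) and share the same knot locations, so that
#' stage-one coefficients can be transferred into stage-two priors
#' one-for-one. The penalty null space contains constants, so each term
#' absorbs its own intercept.
#'
#' @param basis A `spline_basis_spec` shared by both parameters.
#' @return An object of class `bdr_model` with fields `basis`, `penalty`
#'   (the shared `penalty_matrix`), and link labels.
#' @export
bdr_model <- function(basis) {
  stopifnot(inherits(basis, "spline_basis_spec"))
  structure(
    list(basis = basis,
         penalty = difference_penalty(basis$n_basis, basis$penalty_order),
         link_mu = "identity", link_sigma = "log"),
    class = "bdr_model"
  )
}

#' @export
print.bdr_model <- function(x, ...) {
  cat("Gaussian location-scale model; identity link for mu, log link for sigma\n")
  print(x$basis)
  invisible(x)
}

#' Additive predictor
#'
#' \eqn{\eta = B\beta} for one distributional parameter.
#'
#' @param beta Coefficient vector.
#' @param design Design matrix with `length(beta)` columns.
#' @return Numeric vector of linear predictor values.
#' @export
additive_predictor <- function(beta, design) {
  if (!is.matrix(design)) stop("design must be a matrix")
  if (length(beta) != ncol(design)) {
    stop("dimension mismatch: length(beta) = ", length(beta),
         " but design has ", ncol(design), " columns")
  }
  drop(design %*% beta)
}

# eta^sigma is bounded to +/- 20 before exponentiation inside the fitting
# routines to avoid numeric collapse of the scale; exp(20) ~ 4.9e8.
ETA_SIGMA_BOUND <- 20

#' Invert the link functions
#'
#' Maps the additive predictors back to the distributional parameters:
#' `mu = eta_mu` (identity) and `sigma = exp(eta_sigma)` (log link).
#'
#' @param eta_mu,eta_sigma Numeric vectors of linear predictor values.
#' @return A list with components `mu` and `sigma` (strictly positive).
#' @export
invert_links <- function(eta_mu, eta_sigma) {
  sigma <- exp(eta_sigma)
  if (any(!is.finite(sigma))) {
    bad <- which(!is.finite(sigma))
    stop("overflow in exp(eta_sigma) at index ", bad[1],
         " (eta_sigma = ", eta_sigma[bad[1]], ")")
  }
  list(mu = eta_mu, sigma = sigma)
}

#' Gaussian log-likelihood
#'
#' \eqn{\sum_i [-\log\sigma_i - \tfrac12\log 2\pi - (y_i-\mu_i)^2 /
#' (2\sigma_i^2)]}.
#'
#' @param y,mu Numeric vectors of equal length (recycling of scalar `mu`
#'   and `sigma` is allowed).
#' @param sigma Strictly positive numeric vector.
#' @return The scalar log-likelihood.
#' @export
gaussian_loglik <- function(y, mu, sigma) {
  if (any(sigma <= 0)) stop("sigma must be strictly positive")
  sum(stats::dnorm(y, mean = mu, sd = sigma, log = TRUE))
}
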