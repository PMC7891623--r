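#' Clamp ages to the knot range
#'
#' The spline basis is undefined outside its inner knot range, so testees
#' slightly outside the normative age range are forced to the nearest bound
#' before norms are looked up. The number of clamped values is attached as
#' attribute `"n_clamped"`.
#'
#' @param ages Numeric vector.
#' @param inner_range Length-2 numeric `(low, high)`.
#' @return `ages` with out-of-range values replaced by the bounds.
#' @export
clamp_ages <- function(ages, inner_range) {
  stopifnot(length(inner_range) == 2L, inner_range[1] < inner_range[2])
  out <- pmin(pmax(ages, inner_range[1]), inner_range[2])
  attr(out, "n_clamped") <- sum(ages < inner_range[1] | ages > inner_range[2])
  out
}

#' Percentile of a raw score given age
#'
#' \eqn{\Phi((y - \mu(age)) / \sigma(age))} on the probability scale.
#'
#' @param y Raw score(s).
#' @param age Age(s), inside the model's inner knot range (clamp first).
#' @param mu_fn,sigma_fn Curve functions, e.g. from [fitted_curves()] or a
#'   [population_model()].
#' @return Percentile(s) in (0, 1).
#' @export
percentile_of_score <- function(y, age, mu_fn, sigma_fn) {
  s <- sigma_fn(age)
  if (any(s <= 0)) stop("sigma_fn returned non-positive values")
  stats::pnorm((y - mu_fn(age)) / s)
}

#' Centile curve
#'
#' The score reaching a fixed percentile as a function of age:
#' \eqn{\mu(age) + \sigma(age)\,\Phi^{-1}(level)}. Under the Gaussian
#' location-scale model centile curves of different levels never intersect.
#'
#' @param level Probability in (0, 1).
#' @param ages Numeric vector of ages.
#' @inheritParams percentile_of_score
#' @return Numeric vector of scores, one per age.
#' @export
centile_curve <- function(level, ages, mu_fn, sigma_fn) {
  if (length(level) != 1L || level <= 0 || level >= 1) {
    stop("level must be a single probability strictly inside (0, 1)")
  }
  mu_fn(ages) + sigma_fn(ages) * stats::qnorm(level)
}

# default reporting levels for centile plots/tables
DEFAULT_CENTILE_LEVELS <- c(0.004, 0.02, 0.10, 0.25, 0.50, 0.75, 0.90, 0.98, 0.996)

#' Pointwise posterior credible band of a centile curve
#'
#' For `n_draws` retained posterior draws of the coefficients, the centile
#' curve is evaluated draw-wise and summarized by its pointwise posterior
#' mean and equal-tailed 95% interval. If more retained draws are available
#' than `n_draws`, a seeded subsample is used; if fewer, a seeded resample
#' with replacement.
#'
#' @param fit A `bdr_fit` from [fit_mcmc()] (mode-only fits carry no
#'   posterior spread and are rejected).
#' @param level Centile level in (0, 1).
#' @param ages Ages at which to evaluate the band.
#' @param n_draws Number of posterior draws used (default 1001).
#' @param seed Seed for the draw subsample.
#' @return Data frame with `age`, `lower`, `mean`, `upper`.
#' @export
credible_band <- function(fit, level, ages, n_draws = 1001L, seed = 1L) {
  stopifnot(inherits(fit, "bdr_fit"))
  if (fit$method != "mcmc") {
    stop("credible bands need posterior draws; this is a mode-only fit")
  }
  if (level <= 0 || level >= 1) stop("level must be inside (0, 1)")
  bm <- do.call(rbind, lapply(fit$chains, `[[`, "beta_mu"))
  bs <- do.call(rbind, lapply(fit$chains, `[[`, "beta_sigma"))
  total <- nrow(bm)
  set.seed(as.integer(seed %% .Machine$integer.max))
  idx <- sample.int(total, size = n_draws, replace = total < n_draws)
  basis <- fit$model$basis
  B <- bspline_design(clamp_ages(ages, basis$inner_range), basis)
  z <- stats::qnorm(level)
  # draws x ages matrix of draw-wise centile curves
  eta_sg <- bs[idx, , drop = FALSE] %*% t(B)
  eta_sg <- pmin(pmax(eta_sg, -ETA_SIGMA_BOUND), ETA_SIGMA_BOUND)
  curves <- bm[idx, , drop = FALSE] %*% t(B) + z * exp(eta_sg)
  qs <- apply(curves, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  data.frame(age = ages, lower = qs[1, ], mean = colMeans(curves),
             upper = qs[2, ])
}

#' Normed-score transforms
#'
#' Re-expresses a percentile as a normalized z-score and an IQ-type score
#' (`100 + 15 z`).
#'
#' @param percentile Probability strictly inside (0, 1).
#' @return List with `z` and `iq`.
#' @export
normed_transforms <- function(percentile) {
  if (any(percentile <= 0) || any(percentile >= 1)) {
    stop("percentile must be strictly inside (0, 1)")
  }
  z <- stats::qnorm(percentile)
  list(z = z, iq = 100 + 15 * z)
}

#' Long-format norm table
#'
#' @param fit A `bdr_fit`.
#' @param ages Ages at which to tabulate.
#' @param levels Centile levels (default the conventional nine levels
#'   0.4th to 99.6th).
#' @return Data frame with columns `age`, `level`, `score`.
#' @export
norm_table <- function(fit, ages, levels = DEFAULT_CENTILE_LEVELS) {
  fc <- fitted_curves(fit)
  do.call(rbind, lapply(levels, function(p) {
    data.frame(age = ages, level = p,
               score = centile_curve(p, ages, fc$mu_fn, fc$sigma_fn))
  }))
}

#' Compact "norm card" round trip
#'
#' A norm card is the minimal JSON artifact for score-to-percentile lookup:
#' basis specification plus posterior-mean (or modal) coefficients. It does
#' not carry posterior uncertainty.
#'
#' @param fit A `bdr_fit`.
#' @param path JSON file path.
#' @export
write_norm_card <- function(fit, path) {
  cm <- coef_means(fit)
  jsonlite::write_json(
    list(basis = basis_to_list(fit$model$basis),
         beta_mu = cm$beta_mu, beta_sigma = cm$beta_sigma),
    path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_norm_card
#' @return `read_norm_card()` returns a list with `mu_fn`, `sigma_fn`, and
#'   the `basis` spec; the functions clamp ages to the knot range.
#' @export
read_norm_card <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  basis <- basis_from_list(obj$basis)
  beta_mu <- as.numeric(obj$beta_mu)
  beta_sg <- as.numeric(obj$beta_sigma)
  list(
    basis = basis,
    mu_fn = function(age) {
      drop(bspline_design(clamp_ages(age, basis$inner_range), basis) %*% beta_mu)
    },
    sigma_fn = function(age) {
      eta <- drop(bspline_design(clamp_ages(age, basis$inner_range), basis) %*% beta_sg)
      exp(pmin(pmax(eta, -ETA_SIGMA_BOUND), ETA_SIGMA_BOUND))
    })
}
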