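#' Population models for the synthetic norming world
#'
#' A population model is a pair of smooth functions `mu_fn(age)` and
#' `sigma_fn(age) > 0` on the normative age range, defining the true
#' conditional Gaussian score distribution (and hence the true percentile
#' surface) used both to generate normative samples and to score fitted
#' models.
#'
#' @param mu_fn,sigma_fn Vectorized functions of age.
#' @param label Short text label.
#' @param age_range Length-2 numeric support (default `c(5, 21)`).
#' @return An object of class `population_model`.
#' @export
population_model <- function(mu_fn, sigma_fn, label = "population",
                             age_range = c(5, 21)) {
  grid <- seq(age_range[1], age_range[2], length.out = 1000L)
  s <- sigma_fn(grid)
  m <- mu_fn(grid)
  if (any(!is.finite(m)) || any(!is.finite(s))) {
    stop("population curves must be finite on the age range")
  }
  if (any(s <= 0)) stop("sigma_fn must be strictly positive on the age range")
  structure(list(mu_fn = mu_fn, sigma_fn = sigma_fn, label = label,
                 age_range = age_range),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat("population model '", x$label, "' on ages [", x$age_range[1], ",",
      x$age_range[2], "]\n", sep = "")
  invisible(x)
}

# One config block holding every constant of the synthetic world: the
# stand-in prior population (an intelligence-scale-like score: mean raw
# score rising steeply in childhood and flattening toward adulthood, with a
# mildly U-shaped SD), and the default misspecification magnitudes
# (expressed relative to the mean SD; chosen as documented stand-ins since
# the fitted parameters of the licensed normative data are not public).
SYNTH_CONFIG <- list(
  age_range = c(5, 21),
  mu_scale = 100, mu_onset = 4, mu_rate = 6,       # mu(a) = 100(1-exp(-(a-4)/6))
  sigma_base = 8, sigma_amp = 2,                   # sigma(a) = 8+2((a-13)/8)^2
  sigma_center = 13, sigma_halfwidth = 8,
  delta_mu_factor = 0.3,                           # shift in mu: 0.3 * mean SD
  sigma_inflation = 1.2,                           # multiplicative shift in SD
  mu_age_ramp_factor = 0.6                         # ramp 0 -> 0.6 * mean SD
)

#' Canonical stand-in prior population
#'
#' The package's stand-in for a Gaussian norming model estimated on
#' intelligence-test normative data for ages 5-21: the mean raw score rises
#' steeply in childhood and plateaus toward adulthood,
#' \eqn{\mu(a) = 100\,(1 - e^{-(a-4)/6})}, and the SD is mildly U-shaped,
#' \eqn{\sigma(a) = 8 + 2((a-13)/8)^2}. All constants live in one config
#' block; this is a synthetic population, not fitted to any licensed data.
#'
#' @return A `population_model` labelled `"prior_population"`.
#' @export
default_prior_population <- function() {
  cf <- SYNTH_CONFIG
  population_model(
    mu_fn = function(a) cf$mu_scale * (1 - exp(-(a - cf$mu_onset) / cf$mu_rate)),
    sigma_fn = function(a) cf$sigma_base +
      cf$sigma_amp * ((a - cf$sigma_center) / cf$sigma_halfwidth)^2,
    label = "prior_population", age_range = cf$age_range)
}

mean_sigma <- function(pop) {
  grid <- seq(pop$age_range[1], pop$age_range[2], length.out = 1001L)
  mean(pop$sigma_fn(grid))
}

#' Prior-misspecification specification
#'
#' Describes how the population generating the new normative data
#' (`M_norm`) deviates from the population behind the prior (`M_prior`).
#' Five levels: `zero` (none), `mu` (constant shift in the mean), `sigma`
#' (multiplicative shift in the SD), `mu_sigma` (both), and `mu_age` (an
#' age-dependent shift in the mean, by default a linear ramp growing toward
#' the oldest ages).
#'
#' @param level One of `"zero"`, `"mu"`, `"sigma"`, `"mu_sigma"`, `"mu_age"`.
#' @param delta_mu Constant mean shift in score units; default
#'   `0.3 * mean sigma` of the reference population.
#' @param factor_sigma Multiplicative SD factor (`> 0`); default 1.2.
#' @param delta_mu_age_fn Age-dependent mean shift; default a linear ramp
#'   from 0 at the youngest age to `0.6 * mean sigma` at the oldest.
#' @param reference `population_model` from which the defaults are scaled.
#' @return An object of class `misspec_spec`.
#' @export
misspecification_spec <- function(level = c("zero", "mu", "sigma", "mu_sigma",
                                            "mu_age"),
                                  delta_mu = NULL, factor_sigma = NULL,
                                  delta_mu_age_fn = NULL,
                                  reference = default_prior_population()) {
  level <- match.arg(level)
  cf <- SYNTH_CONFIG
  ms <- mean_sigma(reference)
  lo <- reference$age_range[1]; hi <- reference$age_range[2]
  if (is.null(delta_mu)) delta_mu <- cf$delta_mu_factor * ms
  if (is.null(factor_sigma)) factor_sigma <- cf$sigma_inflation
  if (is.null(delta_mu_age_fn)) {
    ramp_top <- cf$mu_age_ramp_factor * ms
    delta_mu_age_fn <- function(a) ramp_top * (a - lo) / (hi - lo)
  }
  if (factor_sigma <= 0) stop("factor_sigma must be positive")
  if (level == "mu_age") {
    probe <- delta_mu_age_fn(seq(lo, hi, length.out = 11L))
    if (diff(range(probe)) == 0) {
      stop("mu_age misspecification requires a non-constant delta_mu_age_fn")
    }
  }
  structure(list(level = level, delta_mu = delta_mu,
                 factor_sigma = factor_sigma,
                 delta_mu_age_fn = delta_mu_age_fn),
            class = "misspec_spec")
}

#' Apply a misspecification to a population model
#'
#' @param pop A `population_model` (the prior population).
#' @param spec A `misspec_spec`.
#' @return The deviated `population_model` (`M_norm`).
#' @export
apply_misspecification <- function(pop, spec) {
  stopifnot(inherits(pop, "population_model"), inherits(spec, "misspec_spec"))
  mu0 <- pop$mu_fn; sg0 <- pop$sigma_fn
  mu1 <- switch(spec$level,
    zero = mu0,
    mu = function(a) mu0(a) + spec$delta_mu,
    sigma = mu0,
    mu_sigma = function(a) mu0(a) + spec$delta_mu,
    mu_age = function(a) mu0(a) + spec$delta_mu_age_fn(a))
  sg1 <- switch(spec$level,
    zero = sg0,
    mu = sg0,
    sigma = function(a) sg0(a) * spec$factor_sigma,
    mu_sigma = function(a) sg0(a) * spec$factor_sigma,
    mu_age = sg0)
  population_model(mu1, sg1, label = paste0(pop$label, "+", spec$level),
                   age_range = pop$age_range)
}

#' Generate a normative sample
#'
#' Ages are `n` noiseless, equally spaced design points spanning the
#' population age range (endpoints included); scores are independent
#' Gaussian draws from the population's conditional distribution.
#'
#' @param pop A `population_model`.
#' @param n Sample size (`>= 2`).
#' @param seed Integer seed; the draw is a pure function of `(pop, n, seed)`.
#' @return Data frame with columns `age` and `score`.
#' @export
generate_sample <- function(pop, n, seed = 1L) {
  stopifnot(inherits(pop, "population_model"))
  if (n < 2) stop("need n >= 2 observations")
  set.seed(as.integer(seed %% .Machine$integer.max))
  age <- seq(pop$age_range[1], pop$age_range[2], length.out = n)
  data.frame(age = age,
             score = stats::rnorm(n, mean = pop$mu_fn(age),
                                  sd = pop$sigma_fn(age)))
}
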