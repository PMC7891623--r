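#' Percentile RMSE between a fitted and a true norming model
#'
#' The outcome measure of the simulation study: estimated and true
#' percentiles are compared on a grid of `n_age` equally spaced ages across
#' the full age range and, per age, `n_score` scores corresponding to true
#' z-scores equally spaced on \eqn{[-3, 3]} (scores further than 3 SD from
#' the conditional mean are not reported in norming practice). The true
#' percentile of grid point `(x, y)` is \eqn{\Phi(z)}; the estimated one is
#' \eqn{\Phi((y - \hat\mu(x))/\hat\sigma(x))}. Returns the root mean square
#' of their difference on the probability scale.
#'
#' @param fit_mu_fn,fit_sigma_fn Fitted curves (e.g. from
#'   [fitted_curves()]); must be defined (after clamping) on the age range.
#' @param true_pop A `population_model` defining the true percentiles.
#' @param n_age,n_score Grid resolution (defaults 1000 x 1000).
#' @return Scalar RMSE on the probability scale.
#' @export
rmse_percentiles <- function(fit_mu_fn, fit_sigma_fn, true_pop,
                             n_age = 1000L, n_score = 1000L) {
  stopifnot(inherits(true_pop, "population_model"))
  ages <- seq(true_pop$age_range[1], true_pop$age_range[2],
              length.out = n_age)
  z <- seq(-3, 3, length.out = n_score)
  theta <- stats::pnorm(z)
  mu_t <- true_pop$mu_fn(ages); sg_t <- true_pop$sigma_fn(ages)
  mu_h <- fit_mu_fn(ages); sg_h <- fit_sigma_fn(ages)
  if (any(sg_h <= 0)) stop("fitted sigma curve non-positive on the grid")
  # theta_hat[i, j] = pnorm(a_i + b_i z_j): score y_ij = mu_t + z_j sg_t
  a <- (mu_t - mu_h) / sg_h
  b <- sg_t / sg_h
  sq <- 0
  for (j in seq_len(n_score)) {
    sq <- sq + sum((stats::pnorm(a + b * z[j]) - theta[j])^2)
  }
  sqrt(sq / (n_age * n_score))
}

#' Simulation condition
#'
#' One cell of the factorial design: prior type (3) x prior
#' misspecification (5) x `n_prior` (500/1000/2000) x `n_norm`
#' (250/500/1000). Factor levels outside these sets are rejected unless
#' `strict = FALSE`.
#'
#' @param prior_type `"weakly_informative"`, `"fixed_effects"`, or
#'   `"posterior_mode"`.
#' @param misspec_level `"zero"`, `"mu"`, `"sigma"`, `"mu_sigma"`, `"mu_age"`.
#' @param n_prior,n_norm Stage-one and stage-two sample sizes.
#' @param strict Enforce the canonical factor levels for the sample sizes.
#' @return A `simulation_condition` list.
#' @export
simulation_condition <- function(prior_type, misspec_level, n_prior, n_norm,
                                 strict = TRUE) {
  prior_type <- match.arg(prior_type, c("weakly_informative", "fixed_effects",
                                        "posterior_mode"))
  misspec_level <- match.arg(misspec_level,
                             c("zero", "mu", "sigma", "mu_sigma", "mu_age"))
  if (strict) {
    if (!n_prior %in% c(500, 1000, 2000)) {
      stop("n_prior must be one of 500, 1000, 2000 (use strict = FALSE to override)")
    }
    if (!n_norm %in% c(250, 500, 1000)) {
      stop("n_norm must be one of 250, 500, 1000 (use strict = FALSE to override)")
    }
  }
  structure(list(prior_type = prior_type, misspec_level = misspec_level,
                 n_prior = as.integer(n_prior), n_norm = as.integer(n_norm)),
            class = "simulation_condition")
}

# Deterministic 31-bit seed stream. Stage-one seeds depend only on
# (n_prior, replicate) so stage-one fits are shared across prior types and
# misspecification levels; stage-two data seeds depend on (misspec, n_norm,
# replicate) but NOT the prior type, pairing the noise across prior types
# within a replicate.
derive_seed <- function(base_seed, ...) {
  parts <- c(...)
  h <- as.double(base_seed) %% 2147483647
  for (p in parts) {
    v <- if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) else as.double(p)
    h <- (h * 69069 + v + 1) %% 2147483647
  }
  as.integer(h) + 1L
}

#' Run one replicate of a simulation condition
#'
#' Two-stage design: a stage-one sample of size `n_prior` is drawn from the
#' prior population and fitted by MCMC with the weakly informative prior;
#' its posterior mean and precision become the informative prior. The
#' stage-two sample of size `n_norm` is drawn from the misspecified
#' population and fitted with the condition's prior (MCMC for the weakly
#' informative and fixed-effects priors, posterior-mode optimisation for
#' the posterior-mode prior). The replicate's outcome is the percentile
#' RMSE of the stage-two fit against the stage-two population.
#' Weakly-informative conditions skip stage one entirely, so their outcome
#' cannot depend on `n_prior`.
#'
#' @param condition A [simulation_condition()].
#' @param replicate_index Replicate number (1-based).
#' @param base_seed Study-level seed.
#' @param n_iter,n_burnin MCMC settings per chain (reduced-scale defaults).
#' @param n_knots Inner knots for both stages (default 24).
#' @param rmse_grid Grid resolution for the outcome, `c(n_age, n_score)`.
#' @param stage1_cache Optional environment used to memoize stage-one fits
#'   across conditions within a replicate (key: `n_prior:replicate`).
#' @param pop Prior population (default [default_prior_population()]).
#' @return List with `rmse`, `rhat` (stage-two, MCMC only), and the seeds
#'   used.
#' @export
run_replicate <- function(condition, replicate_index, base_seed = 1L,
                          n_iter = 1000L, n_burnin = 250L, n_knots = 24L,
                          rmse_grid = c(1000L, 1000L), stage1_cache = NULL,
                          pop = default_prior_population()) {
  stopifnot(inherits(condition, "simulation_condition"))
  lo <- pop$age_range[1]; hi <- pop$age_range[2]
  basis <- make_knots(lo, hi, n_knots = n_knots)
  model <- bdr_model(basis)
  weak <- weakly_informative_prior(model$penalty)

  informative <- condition$prior_type != "weakly_informative"
  info <- NULL
  if (informative) {
    key <- paste0("np", condition$n_prior, ":r", replicate_index)
    if (!is.null(stage1_cache) && !is.null(stage1_cache[[key]])) {
      info <- stage1_cache[[key]]
    } else {
      seed_s1 <- derive_seed(base_seed, "stage1", condition$n_prior,
                             replicate_index)
      y_prior <- generate_sample(pop, condition$n_prior, seed = seed_s1)
      fit1 <- fit_mcmc(y_prior, model, weak, weak, n_chains = 2L,
                       n_iter = n_iter, n_burnin = n_burnin,
                       seed = derive_seed(base_seed, "fit1", condition$n_prior,
                                          replicate_index))
      info <- extract_prior_from_fit(fit1)
      if (!is.null(stage1_cache)) stage1_cache[[key]] <- info
    }
  }

  mspec <- misspecification_spec(condition$misspec_level, reference = pop)
  pop_norm <- apply_misspecification(pop, mspec)
  seed_norm <- derive_seed(base_seed, "ynorm", condition$misspec_level,
                           condition$n_norm, replicate_index)
  y_norm <- generate_sample(pop_norm, condition$n_norm, seed = seed_norm)

  # the weakly informative path must be structurally independent of n_prior
  np_eff <- if (informative) condition$n_prior else 0L
  seed_fit <- derive_seed(base_seed, "fit2", condition$prior_type,
                          condition$misspec_level, np_eff,
                          condition$n_norm, replicate_index)
  fit2 <- switch(condition$prior_type,
    weakly_informative = fit_mcmc(y_norm, model, weak, weak, n_chains = 2L,
                                  n_iter = n_iter, n_burnin = n_burnin,
                                  seed = seed_fit),
    fixed_effects = fit_mcmc(
      y_norm, model,
      fixed_effects_prior(info$m_mu, info$P_mu),
      fixed_effects_prior(info$m_sigma, info$P_sigma),
      n_chains = 2L, n_iter = n_iter, n_burnin = n_burnin, seed = seed_fit),
    posterior_mode = fit_posterior_mode(
      y_norm, model,
      posterior_mode_prior(info$m_mu, info$P_mu),
      posterior_mode_prior(info$m_sigma, info$P_sigma)))

  fc <- fitted_curves(fit2)
  rmse <- rmse_percentiles(fc$mu_fn, fc$sigma_fn, pop_norm,
                           n_age = rmse_grid[1], n_score = rmse_grid[2])
  list(rmse = rmse,
       rhat = if (fit2$method == "mcmc") fit2$rhat else NULL,
       seed_norm = seed_norm, seed_fit = seed_fit)
}

#' Run the factorial simulation study
#'
#' Runs `n_replicates` replicates of every condition, streaming one row per
#' completed replicate to `out_file` (if given) so an interrupted study can
#' resume: existing `(condition, replicate)` rows are not recomputed.
#' Replicate failures are recorded (with `NA` RMSE), not silently dropped;
#' a condition with more than 10% failures is flagged in the summary.
#'
#' @param conditions List of [simulation_condition()] objects.
#' @param n_replicates Replicates per condition (`>= 2`).
#' @param base_seed Study seed.
#' @param n_iter,n_burnin,n_knots,rmse_grid Passed to [run_replicate()].
#' @param out_file Optional CSV path for streaming results.
#' @param progress Print one line per replicate batch.
#' @return List with `results` (long data frame: condition columns,
#'   `replicate`, `rmse`, `error`), `summary` (per-condition mean, SD, SE
#'   of RMSE, failure flag), and `rhat_violation_fraction` (share of spline
#'   coefficients with \eqn{\hat R \ge 1.1} across all stage-two MCMC fits).
#' @export
run_study <- function(conditions, n_replicates, base_seed = 1L,
                      n_iter = 1000L, n_burnin = 250L, n_knots = 24L,
                      rmse_grid = c(1000L, 1000L), out_file = NULL,
                      progress = FALSE) {
  if (inherits(conditions, "simulation_condition")) conditions <- list(conditions)
  stopifnot(n_replicates >= 2)
  done <- NULL
  if (!is.null(out_file) && file.exists(out_file)) {
    done <- utils::read.csv(out_file, stringsAsFactors = FALSE)
  }
  rows <- list()
  n_rhat_total <- 0; n_rhat_bad <- 0

  for (rep_i in seq_len(n_replicates)) {
    cache <- new.env(parent = emptyenv())
    for (cond in conditions) {
      key <- data.frame(prior_type = cond$prior_type,
                        misspec_level = cond$misspec_level,
                        n_prior = cond$n_prior, n_norm = cond$n_norm,
                        replicate = rep_i, stringsAsFactors = FALSE)
      if (!is.null(done) && nrow(merge(done[, names(key)], key)) > 0) {
        prev <- merge(done, key)
        rows[[length(rows) + 1L]] <- prev[, c(names(key), "rmse", "error")]
        next
      }
      res <- tryCatch(
        run_replicate(cond, rep_i, base_seed = base_seed, n_iter = n_iter,
                      n_burnin = n_burnin, n_knots = n_knots,
                      rmse_grid = rmse_grid, stage1_cache = cache),
        error = function(e) e)
      if (inherits(res, "error")) {
        row <- cbind(key, rmse = NA_real_, error = conditionMessage(res))
      } else {
        row <- cbind(key, rmse = res$rmse, error = "")
        if (!is.null(res$rhat)) {
          rh <- res$rhat[is.finite(res$rhat)]
          n_rhat_total <- n_rhat_total + length(rh)
          n_rhat_bad <- n_rhat_bad + sum(rh >= 1.1)
        }
      }
      rows[[length(rows) + 1L]] <- row
      if (!is.null(out_file)) {
        utils::write.table(row, out_file, sep = ",", append = file.exists(out_file),
                           col.names = !file.exists(out_file),
                           row.names = FALSE, qmethod = "double")
      }
    }
    if (progress) {
      message("replicate ", rep_i, "/", n_replicates, " done")
    }
  }

  results <- do.call(rbind, rows)
  summary <- summarize_study(results)
  list(results = results, summary = summary,
       rhat_violation_fraction =
         if (n_rhat_total > 0) n_rhat_bad / n_rhat_total else NA_real_)
}

#' Summarize a study results table
#'
#' @param results Long results data frame from [run_study()].
#' @return Per-condition data frame with `mean_rmse`, `sd_rmse`,
#'   `se_mean_rmse`, replicate counts, and a `flagged` column marking
#'   conditions with more than 10% failed replicates.
#' @export
summarize_study <- function(results) {
  key <- c("prior_type", "misspec_level", "n_prior", "n_norm")
  split_idx <- interaction(results[key], drop = TRUE)
  out <- do.call(rbind, lapply(split(results, split_idx), function(g) {
    ok <- g$rmse[!is.na(g$rmse)]
    data.frame(g[1, key, drop = FALSE],
               n_replicates = nrow(g), n_failed = sum(is.na(g$rmse)),
               mean_rmse = mean(ok), sd_rmse = stats::sd(ok),
               se_mean_rmse = stats::sd(ok) / sqrt(length(ok)),
               flagged = sum(is.na(g$rmse)) > 0.1 * nrow(g))
  }))
  rownames(out) <- NULL
  out[order(out$prior_type, out$misspec_level, out$n_prior, out$n_norm), ]
}
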