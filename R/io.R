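#' Read a normative dataset from delimited text
#'
#' Comma-separated, header required, decimal point. Rows with a missing age
#' or score are dropped with a warning giving the count; if `inner_range`
#' is supplied, out-of-range ages are clamped to its bounds (the standard
#' treatment for testees slightly outside the normative age range) and the
#' clamp count reported.
#'
#' @param path CSV file path.
#' @param age_column,score_column Column names (defaults `"age"`,
#'   `"score"`).
#' @param inner_range Optional length-2 range for age clamping.
#' @return An object of class `normative_dataset`: list with `age`,
#'   `score`, `n`, `n_dropped`, `n_clamped`, `source_label`.
#' @export
read_normative_csv <- function(path, age_column = "age",
                               score_column = "score", inner_range = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c(age_column, score_column)) {
    if (!col %in% names(df)) {
      stop("column '", col, "' not found in ", path,
           " (columns: ", paste(names(df), collapse = ", "), ")")
    }
  }
  age_raw <- df[[age_column]]; score_raw <- df[[score_column]]
  suppressWarnings({
    age <- as.numeric(age_raw); score <- as.numeric(score_raw)
  })
  bad_parse <- which((!is.na(age_raw) & age_raw != "" & is.na(age)) |
                     (!is.na(score_raw) & score_raw != "" & is.na(score)))
  if (length(bad_parse) > 0) {
    stop("unparseable numeric values in ", path, " at data row(s) ",
         paste(utils::head(bad_parse, 5), collapse = ", "))
  }
  keep <- !is.na(age) & !is.na(score) & is.finite(age) & is.finite(score)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    warning(n_dropped, " row(s) with missing age or score dropped from ",
            path)
  }
  age <- age[keep]; score <- score[keep]
  n_clamped <- 0L
  if (!is.null(inner_range)) {
    clamped <- clamp_ages(age, inner_range)
    n_clamped <- attr(clamped, "n_clamped")
    if (n_clamped > 0) {
      message(n_clamped, " age value(s) outside [", inner_range[1], ", ",
              inner_range[2], "] clamped to the bounds")
    }
    age <- as.numeric(clamped)
  }
  structure(list(age = age, score = score, n = length(age),
                 n_dropped = n_dropped, n_clamped = n_clamped,
                 source_label = path),
            class = c("normative_dataset", "list"))
}

#' Serialize a fit to a directory
#'
#' MCMC fits write one CSV per chain and coefficient block plus a
#' `meta.json` (settings, seed, acceptance rates, Rhat per coefficient, and
#' the basis needed to predict); mode fits write the state into the JSON.
#' A convergence report (`convergence.txt`) lists coefficients with
#' \eqn{\hat R \ge 1.1}.
#'
#' @param fit A `bdr_fit`.
#' @param dir Output directory (created if needed).
#' @export
write_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "bdr_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(method = fit$method, prior_kinds = as.list(fit$prior_kinds),
               basis = basis_to_list(fit$model$basis), n_obs = fit$n_obs)
  if (fit$method == "mcmc") {
    meta <- c(meta, list(n_chains = fit$n_chains, n_iter = fit$n_iter,
                         n_burnin = fit$n_burnin, seed = fit$seed,
                         acceptance_sigma = fit$acceptance_sigma,
                         rhat = as.list(fit$rhat)))
    # %.17g so doubles survive the text round trip bit-exactly
    write_num_csv <- function(m, path) {
      m <- as.matrix(m)
      chr <- matrix(sprintf("%.17g", m), nrow(m),
                    dimnames = list(NULL, colnames(m)))
      utils::write.table(chr, path, sep = ",", quote = FALSE,
                         row.names = FALSE)
    }
    for (ch in seq_len(fit$n_chains)) {
      for (blk in c("beta_mu", "beta_sigma")) {
        m <- fit$chains[[ch]][[blk]]
        colnames(m) <- paste0("b", seq_len(ncol(m)))
        write_num_csv(m, file.path(dir, sprintf("chain%d-%s.csv", ch, blk)))
      }
      write_num_csv(
        cbind(tau2_mu = fit$chains[[ch]]$tau2_mu,
              tau2_sigma = fit$chains[[ch]]$tau2_sigma),
        file.path(dir, sprintf("chain%d-tau2.csv", ch)))
    }
    bad <- names(fit$rhat)[is.finite(fit$rhat) & fit$rhat >= 1.1]
    writeLines(c(sprintf("coefficients with Rhat >= 1.1: %d of %d",
                         length(bad), sum(is.finite(fit$rhat))), bad),
               file.path(dir, "convergence.txt"))
  } else {
    meta <- c(meta, list(state = fit$state, log_posterior = fit$log_posterior,
                         trace = fit$trace, n_iter = fit$n_iter))
  }
  jsonlite::write_json(meta, file.path(dir, "meta.json"), digits = I(17),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_fit
#' @return `read_fit()` rebuilds the `bdr_fit` (centile predictions from
#'   the restored fit are bit-identical to the original's).
#' @export
read_fit <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  model <- bdr_model(basis_from_list(meta$basis))
  if (meta$method == "mcmc") {
    chains <- lapply(seq_len(meta$n_chains), function(ch) {
      t2 <- utils::read.csv(file.path(dir, sprintf("chain%d-tau2.csv", ch)))
      list(
        beta_mu = unname(as.matrix(utils::read.csv(
          file.path(dir, sprintf("chain%d-beta_mu.csv", ch))))),
        beta_sigma = unname(as.matrix(utils::read.csv(
          file.path(dir, sprintf("chain%d-beta_sigma.csv", ch))))),
        tau2_mu = t2$tau2_mu, tau2_sigma = t2$tau2_sigma)
    })
    rhat <- unlist(meta$rhat)
    structure(list(method = "mcmc", chains = chains, model = model,
                   prior_kinds = unlist(meta$prior_kinds),
                   n_chains = meta$n_chains, n_iter = meta$n_iter,
                   n_burnin = meta$n_burnin, seed = meta$seed,
                   acceptance_sigma = meta$acceptance_sigma, rhat = rhat,
                   fixed_sigma = NULL, n_obs = meta$n_obs),
              class = "bdr_fit")
  } else {
    structure(list(method = "mode",
                   state = lapply(meta$state, unlist), model = model,
                   prior_kinds = unlist(meta$prior_kinds),
                   log_posterior = meta$log_posterior, trace = meta$trace,
                   n_iter = meta$n_iter, fixed_sigma = NULL,
                   n_obs = meta$n_obs),
              class = "bdr_fit")
  }
}

# append ISO-timestamped lines to a run log
log_lines <- function(log_path, ...) {
  if (is.null(log_path)) return(invisible())
  stamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  cat(paste0(stamp, " ", c(...), "\n"), file = log_path, append = TRUE,
      sep = "")
  invisible()
}
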