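# Independent oracles used across the suite. These deliberately do not call
# package internals: the de Boor recursion is written from the textbook
# definition, matrix products as explicit loops, etc.

# Cox-de Boor recursion, one basis function N_{i,p} at scalar x
deboor_basis <- function(i, p, x, knots) {
  if (p == 0) {
    return(as.numeric(knots[i] <= x && x < knots[i + 1]))
  }
  left <- 0
  if (knots[i + p] > knots[i]) {
    left <- (x - knots[i]) / (knots[i + p] - knots[i]) *
      deboor_basis(i, p - 1, x, knots)
  }
  right <- 0
  if (knots[i + p + 1] > knots[i + 1]) {
    right <- (knots[i + p + 1] - x) / (knots[i + p + 1] - knots[i + 1]) *
      deboor_basis(i + 1, p - 1, x, knots)
  }
  left + right
}

# full design row at scalar x by the recursion
deboor_row <- function(x, knots, degree) {
  n_basis <- length(knots) - degree - 1
  vapply(seq_len(n_basis), deboor_basis, 0, p = degree, x = x, knots = knots)
}

# explicit double-loop matrix product
loop_matmul <- function(A, b) {
  out <- numeric(nrow(A))
  for (i in seq_len(nrow(A))) {
    acc <- 0
    for (j in seq_len(ncol(A))) acc <- acc + A[i, j] * b[j]
    out[i] <- acc
  }
  out
}

# brute-force percentile RMSE with explicit loops over the grid
rmse_bruteforce <- function(mu_hat, sigma_hat, pop, n_age, n_score) {
  ages <- seq(pop$age_range[1], pop$age_range[2], length.out = n_age)
  z <- seq(-3, 3, length.out = n_score)
  total <- 0
  for (i in seq_len(n_age)) {
    for (j in seq_len(n_score)) {
      y <- pop$mu_fn(ages[i]) + z[j] * pop$sigma_fn(ages[i])
      th <- pnorm(z[j])
      th_hat <- pnorm((y - mu_hat(ages[i])) / sigma_hat(ages[i]))
      total <- total + (th_hat - th)^2
    }
  }
  sqrt(total / (n_age * n_score))
}

# small shared fixtures
tiny_basis <- function() make_knots(5, 21, n_knots = 8)
tiny_model <- function() bdr_model(tiny_basis())

# flat-population data for conjugate / recovery checks
flat_data <- function(n, mu = 100, sigma = 15, seed = 1) {
  pop <- population_model(function(a) rep(mu, length(a)),
                          function(a) rep(sigma, length(a)), "flat")
  generate_sample(pop, n, seed = seed)
}
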