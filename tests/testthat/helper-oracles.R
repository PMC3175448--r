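# Independent oracles used to cross-check the implementation.

# B-spline basis via the truncated-power construction for uniform knots:
# B_i(x) = (1 / (p! h^p)) * sum_k (-1)^k C(p+1, k) (x - t_i - k h)_+^p.
# Entirely independent of the Cox-de Boor recursion in evaluate_basis().
tp_basis <- function(x, design) {
  p <- design$degree
  h <- design$h
  kn <- design$knots
  out <- sapply(seq_len(design$n_basis), function(i) {
    v <- 0
    for (k in 0:(p + 1))
      v <- v + (-1)^k * choose(p + 1, k) * pmax(x - (kn[i] + k * h), 0)^p
    v / (factorial(p) * h^p)
  })
  matrix(out, length(x), design$n_basis)
}

# Brute-force maximization of the exact (unpenalized) multinomial
# log-likelihood over the stacked coefficient vector, via general-purpose
# numerical optimization. Used as the lambda = 0 oracle.
brute_multinom <- function(age, status, design, start = NULL) {
  B <- evaluate_basis(age, design)
  K <- design$n_basis
  Ym <- t(sapply(status, function(s) as.numeric(0:3 == s)))
  negll <- function(theta) {
    eta <- cbind(0, B %*% matrix(theta, K, 3))
    mx <- apply(eta, 1, max)
    -sum(Ym * (eta - mx - log(rowSums(exp(eta - mx)))))
  }
  th0 <- if (is.null(start)) rep(0, 3 * K) else as.vector(start)
  opt <- optim(th0, negll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-15))
  opt <- optim(opt$par, negll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-15))
  list(coefficients = matrix(opt$par, K, 3), loglik = -opt$value)
}

# Finite-difference Hessian of the unpenalized multinomial log-likelihood.
fd_hessian <- function(age, status, design, theta, eps = 1e-4) {
  B <- evaluate_basis(age, design)
  K <- design$n_basis
  Ym <- t(sapply(status, function(s) as.numeric(0:3 == s)))
  ll <- function(th) {
    eta <- cbind(0, B %*% matrix(th, K, 3))
    mx <- apply(eta, 1, max)
    sum(Ym * (eta - mx - log(rowSums(exp(eta - mx)))))
  }
  p <- length(theta)
  H <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in i:p) {
    ei <- ej <- rep(0, p); ei[i] <- eps; ej[j] <- eps
    H[i, j] <- H[j, i] <-
      (ll(theta + ei + ej) - ll(theta + ei - ej) -
       ll(theta - ei + ej) + ll(theta - ei - ej)) / (4 * eps^2)
  }
  H
}

# Small status sample drawn from fixed category probabilities.
draw_status <- function(n, probs, ages = 20:90, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(age = sample(ages, n, replace = TRUE),
             status = sample(0:3, n, replace = TRUE, prob = probs))
}

# Two-disease survey config with the pooled-survey marginal calibration,
# used by recovery and calibration tests.
two_disease_config <- function(n, seed, log_or_intercept = 3.2,
                               log_or_slope = -0.025) {
  cfg0 <- pols_like_config()
  survey_config(n, 20L, 90L,
                marginals = cfg0$marginals[c("diabetes", "stroke")],
                dependences = list(
                  dependence_curve("diabetes", "stroke",
                                   log_or_intercept, log_or_slope)),
                seed = seed)
}
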