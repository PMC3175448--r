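test_that("pair status encoding matches the 4-level convention", {
  expect_identical(encode_pair_status(0, 0), 0L) # no disease
  expect_identical(encode_pair_status(1, 0), 1L) # only disease A
  expect_identical(encode_pair_status(0, 1), 2L) # only disease B
  expect_identical(encode_pair_status(1, 1), 3L) # both diseases
  expect_identical(encode_pair_status(c(0, 1, 0, 1), c(0, 0, 1, 1)), 0:3)
  expect_error(encode_pair_status(2, 0), "0/1")
  expect_error(encode_pair_status(0.5, 0), "0/1")
})

test_that("unpenalized fit reproduces the exact maximum likelihood", {
  # identifiable design (3 distinct ages, 3 basis functions), lambda = 0:
  # the MLE probabilities are the saturated per-age proportions, and the
  # coefficients match a brute-force numerical maximizer
  set.seed(1)
  ages <- rep(c(30, 50, 70), each = 20)
  probs <- rbind(c(.7, .1, .1, .1), c(.5, .2, .2, .1), c(.3, .3, .2, .2))
  status <- unlist(lapply(1:3, function(j) sample(0:3, 20, TRUE, probs[j, ])))
  des <- spline_design(30, 70, n_segments = 2, degree = 1)
  pen <- difference_penalty(des$n_basis, 1)
  fit <- fit_pair_pspline(ages, status, des, pen, lambda = 0)
  expect_true(fit$converged)

  emp <- unclass(prop.table(table(ages, factor(status, 0:3)), 1))
  pred <- predict(fit, c(30, 50, 70))
  expect_lt(max(abs(pred - emp)), 1e-6)

  oracle <- brute_multinom(ages, status, des, start = fit$coefficients * 0.9)
  expect_lt(max(abs(fit$coefficients - oracle$coefficients)), 1e-4)
  expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-9)
})

test_that("a huge order-2 penalty collapses to the linear multinomial logit", {
  skip_if_not_installed("nnet")
  set.seed(2)
  n <- 400
  age <- sample(20:90, n, TRUE)
  status <- sapply(age, function(a)
    sample(0:3, 1, prob = c(20, exp(0.03 * a), exp(0.025 * a),
                            exp(0.04 * a - 1))))
  des <- spline_design(20, 90, 20, 3)
  fit <- fit_pair_pspline(age, status, des, difference_penalty(23, 2),
                          lambda = 1e8)
  expect_true(fit$converged)
  m <- nnet::multinom(factor(status, 0:3) ~ age, trace = FALSE,
                      reltol = 1e-14, maxit = 1000)
  pm <- stats::predict(m, newdata = data.frame(age = 20:90), type = "probs")
  expect_lt(max(abs(predict(fit, 20:90) - pm)), 1e-4)
})

test_that("effective dimension interpolates between its limits", {
  set.seed(3)
  d <- draw_status(1500, c(.7, .12, .1, .08))
  des <- spline_design(20, 90, 20, 3)
  pen <- difference_penalty(des$n_basis, 2)
  f0 <- suppressWarnings(fit_pair_pspline(d$age, d$status, des, pen, 0))
  expect_equal(effective_dimension(f0), 3 * des$n_basis, tolerance = 1e-6)
  fI <- fit_pair_pspline(d$age, d$status, des, pen, 1e10)
  expect_equal(effective_dimension(fI), 3 * 2, tolerance = 1e-3)
  # strictly decreasing in lambda on a grid
  eds <- sapply(10^seq(-1, 5), function(l)
    effective_dimension(fit_pair_pspline(d$age, d$status, des, pen, l)))
  expect_true(all(diff(eds) < 0))
  for (f in list(fI)) {
    expect_equal(f$aic, -2 * f$loglik + 2 * f$effective_dimension)
    expect_equal(f$bic, -2 * f$loglik + log(f$n) * f$effective_dimension)
  }
})

test_that("coefficient covariance matches its definition and shrinks with lambda", {
  set.seed(4)
  ages <- rep(c(30, 50, 70), each = 40)
  status <- unlist(lapply(1:3, function(j)
    sample(0:3, 40, TRUE, rbind(c(.6, .15, .15, .1), c(.5, .2, .2, .1),
                                c(.4, .25, .2, .15))[j, ])))
  des <- spline_design(30, 70, 2, 1)
  pen <- difference_penalty(des$n_basis, 1)
  fit <- fit_pair_pspline(ages, status, des, pen, 0)
  V <- coefficient_covariance(fit)
  expect_lt(max(abs(V - t(V))), 1e-10)
  # lambda = 0: inverse of the observed information (finite differences)
  Hfd <- fd_hessian(ages, status, des, as.vector(fit$coefficients))
  Vfd <- solve(-Hfd)
  expect_lt(max(abs(V - Vfd)) / max(abs(Vfd)), 0.05)
  # generalized variance non-increasing in lambda
  ld <- sapply(c(0, 1, 10, 100, 1000), function(l) {
    f <- fit_pair_pspline(ages, status, des, pen, l)
    determinant(coefficient_covariance(f))$modulus
  })
  expect_true(all(diff(ld) < 1e-8))
})

test_that("lambda selection minimizes the requested criterion", {
  set.seed(5)
  d <- draw_status(1200, c(.8, .08, .07, .05))
  des <- spline_design(20, 90, 20, 3)
  # single-value grid returns that fit
  f1 <- suppressWarnings(
    select_lambda(d$age, d$status, des, grid = 10, refine = FALSE))
  expect_equal(f1$lambda, 10)
  # selected criterion value is the profile minimum
  fa <- suppressWarnings(select_lambda(d$age, d$status, des))
  expect_equal(fa$aic, min(fa$profile$aic))
  expect_true(all(fa$profile$aic >= fa$aic - 1e-9))
  # ties break towards the larger (smoother) lambda
  expect_equal(fa$lambda, max(fa$profile$lambda[fa$profile$aic <= fa$aic + 1e-9]))
  expect_error(select_lambda(d$age, d$status, des, grid = numeric(0)),
               "nonempty")
})

test_that("BIC selects at least as much smoothing as AIC on flat truth", {
  set.seed(6)
  wins <- 0
  for (r in 1:50) {
    d <- draw_status(800, c(.8, .09, .06, .05))
    des <- spline_design(20, 90, 10, 3)
    fa <- suppressWarnings(select_lambda(d$age, d$status, des,
                                         criterion = "aic", refine = FALSE))
    fb <- suppressWarnings(select_lambda(d$age, d$status, des,
                                         criterion = "bic", refine = FALSE))
    wins <- wins + (fb$lambda >= fa$lambda)
  }
  expect_gte(wins / 50, 0.9)
})

test_that("predictions are simplex-valued and shift-invariant", {
  set.seed(7)
  d <- draw_status(1000, c(.7, .1, .1, .1))
  des <- spline_design(20, 90, 20, 3)
  pen <- difference_penalty(des$n_basis, 2)
  fit <- fit_pair_pspline(d$age, d$status, des, pen, 100)
  ages <- runif(1000, 20, 90)
  p <- predict(fit, ages)
  expect_true(all(p >= 0))
  expect_lt(max(abs(rowSums(p) - 1)), 1e-12)
  expect_error(predict(fit, 95), "design range")
  # all-zero coefficients: uniform probabilities
  fit0 <- fit
  fit0$coefficients[] <- 0
  expect_equal(unname(predict(fit0, c(25, 60))),
               matrix(0.25, 2, 4), tolerance = 1e-15)
  # shifting ages and the design leaves fitted probabilities unchanged
  des_s <- spline_design(120, 190, 20, 3)
  fit_s <- fit_pair_pspline(d$age + 100, d$status, des_s, pen, 100)
  expect_lt(max(abs(predict(fit_s, ages + 100) - p)), 1e-8)
})

test_that("fitting on near-constant truth recovers flat curves", {
  probs <- c(.75, .1, .09, .06)
  set.seed(8)
  d <- draw_status(40000, probs)
  des <- spline_design(20, 90, 20, 3)
  fit <- suppressWarnings(select_lambda(d$age, d$status, des))
  p <- predict(fit, 25:85)
  for (k in 1:4) {
    se <- sqrt(probs[k] * (1 - probs[k]) / 40000)
    expect_lt(max(abs(p[, k] - probs[k])), max(6 * se, 0.01))
  }
})

test_that("degenerate inputs are rejected with informative errors", {
  des <- spline_design(20, 90, 20, 3)
  pen <- difference_penalty(des$n_basis, 2)
  expect_error(fit_pair_pspline(c(30, 40), c(0, 0), des, pen, 1),
               "two status categories")
  expect_error(fit_pair_pspline(c(30, 40), c(0, 4), des, pen, 1), "status")
  expect_error(fit_pair_pspline(c(30, 40, 50), c(0, 1, 2), des, pen, -1))
})

test_that("fits round-trip through JSON with identical predictions", {
  set.seed(9)
  d <- draw_status(2000, c(.7, .12, .1, .08))
  des <- spline_design(20, 90, 15, 3)
  fit <- suppressWarnings(select_lambda(d$age, d$status, des))
  path <- withr::local_tempfile(fileext = ".json")
  pair_fit_to_json(fit, path, pair = c("x", "y"))
  back <- pair_fit_from_json(path)
  expect_equal(back$pair, c("x", "y"))
  expect_equal(back$lambda, fit$lambda)
  expect_equal(predict(back, 20:90), predict(fit, 20:90))
  expect_equal(coefficient_covariance(back), coefficient_covariance(fit),
               tolerance = 1e-12)
  # restored fits give deterministic intervals, and intervals statistically
  # indistinguishable from the original (the decimal round trip perturbs the
  # covariance factorization by an ulp, so draws are not bit-identical)
  cu1 <- monte_carlo_intervals(fit, n_draws = 2000, seed = 5)
  cu2 <- monte_carlo_intervals(back, n_draws = 2000, seed = 5)
  cu3 <- monte_carlo_intervals(back, n_draws = 2000, seed = 5)
  expect_identical(cu2$lower, cu3$lower)
  expect_equal(cu1$lower, cu2$lower, tolerance = 0.1)
  expect_equal(cu1$upper, cu2$upper, tolerance = 0.1)
})
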