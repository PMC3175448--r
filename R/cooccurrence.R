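#' Observed-minus-expected and observed/expected co-occurrence
#'
#' From the probabilities of the three non-reference pair-status categories
#' (`p_only_a` = P(A, no B), `p_only_b` = P(no A, B), `p_both` = P(A, B)),
#' the marginal prevalences are `P(A) = p_only_a + p_both` and
#' `P(B) = p_only_b + p_both`, and the two deviation-from-independence
#' measures are
#' \deqn{Obs - Exp = P(A,B) - P(A) P(B), \qquad
#'       Obs/Exp = P(A,B) / \{P(A) P(B)\}.}
#' Both equal their independence values (0 and 1) when the joint prevalence
#' is exactly the product of the margins; the ratio exceeds 1 exactly when
#' the difference is positive.
#'
#' @param p_only_a,p_only_b,p_both Category probabilities (vectorized),
#'   nonnegative with sum at most 1.
#' @return Numeric vector of the measure. `observed_over_expected()` returns
#'   `NA` with a warning where a margin is zero (the ratio is undefined
#'   there); `observed_minus_expected()` is always defined.
#' @examples
#' observed_minus_expected(0.16, 0.16, 0.04) # 0: the independence case
#' observed_over_expected(0.16, 0.16, 0.04)  # 1
#' @export
observed_minus_expected <- function(p_only_a, p_only_b, p_both) {
  check_simplex(p_only_a, p_only_b, p_both)
  p_both - (p_only_a + p_both) * (p_only_b + p_both)
}

#' @rdname observed_minus_expected
#' @export
observed_over_expected <- function(p_only_a, p_only_b, p_both) {
  check_simplex(p_only_a, p_only_b, p_both)
  expected <- (p_only_a + p_both) * (p_only_b + p_both)
  out <- ifelse(expected > 0, p_both / expected, NA_real_)
  if (anyNA(out))
    warning("zero marginal prevalence: observed/expected undefined, returned as NA")
  out
}

check_simplex <- function(p1, p2, p3, tol = 1e-9) {
  if (any(p1 < -tol | p2 < -tol | p3 < -tol) || any(p1 + p2 + p3 > 1 + tol))
    stop("category probabilities must be nonnegative and sum to at most 1")
  invisible(TRUE)
}

#' Monte Carlo confidence intervals for the co-occurrence curves
#'
#' Propagates coefficient uncertainty of a fitted pair model into the three
#' outcome measures. Coefficients are repeatedly drawn from a multivariate
#' normal distribution centred at the estimate with the penalized-information
#' covariance; for each draw the category probabilities are predicted on
#' the age grid and joint prevalence, obs-exp and obs/exp computed; the
#' pointwise interval at each age is the pair of empirical `(1-level)/2`
#' and `1-(1-level)/2` percentiles (nearest-rank definition) across draws.
#' Point estimates are the plug-in values at the coefficient estimate, not
#' Monte Carlo medians, so in edge cases a percentile interval of the
#' nonlinear ratio may not bracket the plug-in point; such ages are flagged.
#'
#' @param fit A converged `pair_fit` (from [fit_pair_pspline()] /
#'   [select_lambda()] or restored via [pair_fit_from_json()]).
#' @param ages Age grid; defaults to all integer ages in the design range.
#'   Ages outside the range are dropped with a warning (no extrapolation).
#' @param n_draws Number of coefficient draws (default 10000).
#' @param level Interval level (default 0.95).
#' @param seed Integer seed for the draws.
#' @param pair Optional label `c(disease_a, disease_b)` carried in the
#'   output.
#' @return An object of class `cooccurrence_curve`: list with `pair`,
#'   `ages`, `estimates` (data frame with `p_joint`, `p_a`, `p_b`,
#'   `obs_minus_exp`, `obs_over_exp`), `lower`/`upper` (matrices, one
#'   column per measure), `n_valid_draws` (per age, for the ratio),
#'   `n_draws`, `level`, `seed`, `point_outside_ci` flags.
#' @export
monte_carlo_intervals <- function(fit, ages = NULL, n_draws = 10000L,
                                  level = 0.95, seed = 1L,
                                  pair = c("A", "B")) {
  stopifnot(inherits(fit, "pair_fit"), n_draws >= 1L,
            level > 0, level < 1)
  if (!fit$converged) stop("fit did not converge")
  design <- fit$design
  if (is.null(ages))
    ages <- seq(ceiling(design$age_min), floor(design$age_max))
  outside <- ages < design$age_min | ages > design$age_max
  if (any(outside)) {
    warning("dropping ", sum(outside), " ages outside the design range (no extrapolation)")
    ages <- ages[!outside]
  }
  if (length(ages) == 0L) stop("no ages inside the design range")
  V <- coefficient_covariance(fit)
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop("coefficient covariance is not positive semidefinite")
  K <- design$n_basis
  B <- evaluate_basis(ages, design)
  mu <- as.vector(fit$coefficients)

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  draws <- MASS::mvrnorm(n_draws, mu = mu, Sigma = V) # n_draws x 3K
  if (n_draws == 1L) draws <- matrix(draws, nrow = 1L)

  # per-draw linear predictors by category: n_draws x n_ages
  e1 <- exp(draws[, seq_len(K), drop = FALSE] %*% t(B))
  e2 <- exp(draws[, K + seq_len(K), drop = FALSE] %*% t(B))
  e3 <- exp(draws[, 2L * K + seq_len(K), drop = FALSE] %*% t(B))
  denom <- 1 + e1 + e2 + e3
  P1 <- e1 / denom; P2 <- e2 / denom; P3 <- e3 / denom
  ome <- P3 - (P1 + P3) * (P2 + P3)
  expd <- (P1 + P3) * (P2 + P3)
  oe <- P3 / expd
  oe[expd == 0] <- NA_real_

  lo_p <- (1 - level) / 2
  hi_p <- 1 - lo_p
  qr2 <- function(M) apply(M, 2L, stats::quantile, probs = c(lo_p, hi_p),
                           type = 1, na.rm = TRUE)
  q_joint <- qr2(P3); q_ome <- qr2(ome); q_oe <- qr2(oe)

  pt <- predict(fit, ages)
  est <- data.frame(
    age = ages,
    p_joint = pt[, "P3"],
    p_a = pt[, "P1"] + pt[, "P3"],
    p_b = pt[, "P2"] + pt[, "P3"],
    obs_minus_exp = observed_minus_expected(pt[, "P1"], pt[, "P2"], pt[, "P3"]),
    obs_over_exp = observed_over_expected(pt[, "P1"], pt[, "P2"], pt[, "P3"]),
    row.names = NULL)
  lower <- cbind(p_joint = q_joint[1L, ], obs_minus_exp = q_ome[1L, ],
                 obs_over_exp = q_oe[1L, ])
  upper <- cbind(p_joint = q_joint[2L, ], obs_minus_exp = q_ome[2L, ],
                 obs_over_exp = q_oe[2L, ])
  point <- cbind(p_joint = est$p_joint, obs_minus_exp = est$obs_minus_exp,
                 obs_over_exp = est$obs_over_exp)
  structure(
    list(pair = pair, ages = ages, estimates = est, lower = lower,
         upper = upper, n_valid_draws = colSums(!is.na(oe)),
         n_draws = n_draws, level = level, seed = seed,
         point_outside_ci = point < lower - 1e-12 | point > upper + 1e-12),
    class = "cooccurrence_curve")
}

#' @export
print.cooccurrence_curve <- function(x, ...) {
  cat(sprintf("Co-occurrence curve %s:%s over ages %g-%g (%d draws, %g%% pointwise intervals)\n",
              x$pair[[1L]], x$pair[[2L]], min(x$ages), max(x$ages),
              x$n_draws, 100 * x$level))
  invisible(x)
}

#' Tidy a co-occurrence curve into a long data frame
#'
#' @param x A `cooccurrence_curve`.
#' @param ... Unused.
#' @return Data frame with columns `pair`, `age`, `measure`, `estimate`,
#'   `ci_lower`, `ci_upper`, `n_valid_draws`.
#' @export
as.data.frame.cooccurrence_curve <- function(x, ...) {
  measures <- c("p_joint", "obs_minus_exp", "obs_over_exp")
  do.call(rbind, lapply(measures, function(m) {
    data.frame(pair = paste(x$pair, collapse = ":"), age = x$ages,
               measure = m, estimate = x$estimates[[m]],
               ci_lower = x$lower[, m], ci_upper = x$upper[, m],
               n_valid_draws = if (m == "obs_over_exp") x$n_valid_draws
                               else x$n_draws,
               row.names = NULL)
  }))
}

#' Fit and analyse every disease pair in a survey
#'
#' For each of the `choose(k, 2)` unordered pairs of the named disease
#' columns, encodes pair status, selects the smoothing parameter
#' independently by the chosen criterion, and computes the co-occurrence
#' curves with Monte Carlo intervals. Per-pair failures are collected and
#' reported; the run continues over the remaining pairs.
#'
#' @param data Data frame with an `age` column and one 0/1 column per
#'   disease.
#' @param diseases Character vector (>= 2) of disease column names.
#' @param design A [spline_design()]; default spans the observed ages with
#'   20 segments, cubic.
#' @param penalty_order Difference-penalty order (default 2).
#' @param grid Lambda grid for [select_lambda()].
#' @param criterion `"aic"` or `"bic"`.
#' @param ages Prediction grid (default integer ages over the design range).
#' @param n_draws,level Monte Carlo settings.
#' @param seed Base seed; pair `i` uses `seed + 1000 * i`.
#' @return An object of class `cooccurrence_set`: list with `curves` (named
#'   list of `cooccurrence_curve`), `fits` (named list of `pair_fit`),
#'   `failures` (named character vector of error messages), and `table`
#'   (the row-bound tidy data frame of all curves).
#' @export
run_all_pairs <- function(data, diseases, design = NULL, penalty_order = 2L,
                          grid = default_lambda_grid(),
                          criterion = c("aic", "bic"), ages = NULL,
                          n_draws = 10000L, level = 0.95, seed = 1L) {
  criterion <- match.arg(criterion)
  if (length(diseases) < 2L) stop("need at least 2 diseases")
  missing_cols <- setdiff(c("age", diseases), names(data))
  if (length(missing_cols))
    stop("missing columns in `data`: ", paste(missing_cols, collapse = ", "))
  if (is.null(design))
    design <- spline_design(min(data$age), max(data$age))
  penalty <- difference_penalty(design$n_basis, penalty_order)
  pairs <- utils::combn(diseases, 2L)
  curves <- list(); fits <- list(); failures <- character(0)
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    key <- paste(a, b, sep = ":")
    res <- tryCatch({
      status <- encode_pair_status(data[[a]], data[[b]])
      fit <- select_lambda(data$age, status, design, penalty, grid, criterion)
      curve <- monte_carlo_intervals(
        fit, ages = ages, n_draws = n_draws, level = level,
        seed = (seed + 1000L * k) %% .Machine$integer.max, pair = c(a, b))
      list(fit = fit, curve = curve)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[key]] <- conditionMessage(res)
    } else {
      fits[[key]] <- res$fit
      curves[[key]] <- res$curve
    }
  }
  if (length(failures))
    warning(length(failures), " pair(s) failed: ",
            paste(names(failures), collapse = ", "))
  structure(list(curves = curves, fits = fits, failures = failures,
                 table = if (length(curves))
                   do.call(rbind, c(lapply(curves, as.data.frame),
                                    make.row.names = FALSE))
                 else NULL),
            class = "cooccurrence_set")
}

#' @export
print.cooccurrence_set <- function(x, ...) {
  cat(sprintf("Co-occurrence analysis of %d pair(s)%s\n", length(x$curves),
              if (length(x$failures))
                sprintf(" (%d failed)", length(x$failures)) else ""))
  for (key in names(x$curves)) {
    f <- x$fits[[key]]
    cat(sprintf("  %-20s lambda = %-8.3g ED = %-6.2f %s = %.1f\n", key,
                f$lambda, f$effective_dimension,
                toupper(f$criterion %||% "aic"),
                f[[f$criterion %||% "aic"]]))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
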