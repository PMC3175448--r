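#' Encode disease-pair status
#'
#' Maps two binary disease indicators to the 4-level pair status used as
#' the multinomial outcome: 0 = neither disease, 1 = only disease A,
#' 2 = only disease B, 3 = both diseases.
#'
#' @param indicator_a,indicator_b Vectors of 0/1 indicators (recycled).
#' @return Integer vector of statuses in `{0, 1, 2, 3}`.
#' @examples
#' encode_pair_status(c(0, 1, 0, 1), c(0, 0, 1, 1)) # 0 1 2 3
#' @export
encode_pair_status <- function(indicator_a, indicator_b) {
  ok <- function(x) is.numeric(x) && all(x %in% c(0, 1))
  if (!ok(indicator_a) || !ok(indicator_b))
    stop("disease indicators must be 0/1")
  as.integer(indicator_a + 2L * indicator_b)
}

# Aggregate (age, status) microdata into per-unique-age count rows.
# Returns list(ages, Y [J x 4 counts], m [row totals]).
aggregate_status <- function(age, status) {
  if (length(age) != length(status)) stop("`age` and `status` lengths differ")
  if (!all(status %in% 0:3)) stop("`status` must be in {0, 1, 2, 3}")
  f <- factor(status, levels = 0:3)
  tab <- table(age = age, status = f)
  ages <- as.numeric(rownames(tab))
  Y <- unclass(tab)[, , drop = FALSE]
  storage.mode(Y) <- "double"
  list(ages = ages, Y = Y, m = rowSums(Y))
}

# Multinomial log-likelihood pieces at linear predictors eta (J x 3,
# reference category 0 has eta = 0). Returns list(p [J x 4], loglik).
multinom_probs <- function(eta, Y) {
  full <- cbind(0, eta)
  mx <- apply(full, 1L, max)
  ex <- exp(full - mx)
  denom <- rowSums(ex)
  p <- ex / denom
  list(p = p, loglik = sum(Y * (full - mx - log(denom))))
}

#' Fit a penalized multinomial P-spline of pair status on age
#'
#' Maximizes the penalized multinomial log-likelihood
#' \deqn{\ell(\beta) - \tfrac{\lambda}{2} \sum_{c=1}^{3}
#'       \beta_c^\top P \beta_c}
#' where the three category logits (only A, only B, both; reference: no
#' disease) are B-spline expansions of age sharing one smoothing parameter.
#' Fitting is full Newton on the stacked coefficient vector with
#' step-halving; observations are aggregated by unique age first, so cost is
#' driven by the number of distinct ages, not respondents.
#'
#' @param age Ages (years), one per respondent.
#' @param status Pair status per respondent, from [encode_pair_status()].
#' @param design A [spline_design()] covering the observed ages.
#' @param penalty A [difference_penalty()] of matching size (default order 2).
#' @param lambda Nonnegative smoothing parameter.
#' @param start Optional `n_basis x 3` starting coefficient matrix.
#' @param max_iter,grad_tol,obj_tol Newton controls: iteration cap, max-norm
#'   gradient tolerance of the penalized objective, and relative
#'   objective-change tolerance.
#' @return An object of class `pair_fit`: coefficients (`n_basis x 3`),
#'   `loglik`, `effective_dimension`, `aic`, `bic`, `lambda`, `n`,
#'   `converged`, `n_iter`, `sparse_categories` (status levels with < 5
#'   observations, flagged because rare categories make fits unstable at
#'   extreme ages), plus the Hessian pieces needed for the covariance.
#' @export
fit_pair_pspline <- function(age, status, design,
                             penalty = difference_penalty(design$n_basis),
                             lambda, start = NULL, max_iter = 100L,
                             grad_tol = 1e-6, obj_tol = 1e-9) {
  stopifnot(inherits(design, "spline_design"),
            inherits(penalty, "penalty_matrix"),
            penalty$n_basis == design$n_basis,
            is.numeric(lambda), length(lambda) == 1L, lambda >= 0)
  agg <- aggregate_status(age, status)
  counts <- colSums(agg$Y)
  if (sum(counts > 0) < 2L)
    stop("need observations in at least two status categories")
  K <- design$n_basis
  B <- evaluate_basis(agg$ages, design)
  P <- penalty$matrix
  n <- sum(agg$m)
  beta <- if (is.null(start)) matrix(0, K, 3L) else start
  stopifnot(identical(dim(beta), c(K, 3L)))

  pen_obj <- function(beta) {
    mp <- multinom_probs(B %*% beta, agg$Y)
    mp$loglik - (lambda / 2) * sum(beta * (P %*% beta))
  }
  obj <- pen_obj(beta)
  converged <- FALSE
  iter <- 0L
  grad_max <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    mp <- multinom_probs(B %*% beta, agg$Y)
    p <- mp$p
    # penalized gradient, stacked over categories 1..3
    G <- crossprod(B, agg$Y[, 2:4] - agg$m * p[, 2:4]) - lambda * (P %*% beta)
    grad_max <- max(abs(G))
    if (grad_max < grad_tol) { converged <- TRUE; break }
    # negative Hessian of the unpenalized log-likelihood, block (c, d)
    H <- matrix(0, 3L * K, 3L * K)
    for (cc in 1:3) for (dd in cc:3) {
      w <- agg$m * (p[, cc + 1L] * (cc == dd) - p[, cc + 1L] * p[, dd + 1L])
      blk <- crossprod(B, B * w)
      ri <- (cc - 1L) * K + seq_len(K); ci <- (dd - 1L) * K + seq_len(K)
      H[ri, ci] <- blk
      if (dd > cc) H[ci, ri] <- t(blk)
    }
    A <- H
    for (cc in 1:3) {
      idx <- (cc - 1L) * K + seq_len(K)
      A[idx, idx] <- A[idx, idx] + lambda * P
    }
    step <- tryCatch(solve(A, as.vector(G)), error = function(e)
      stop("Newton system singular (rank-deficient penalized information): ",
           conditionMessage(e)))
    step <- matrix(step, K, 3L)
    # step-halving: require the penalized objective not to decrease
    s <- 1
    repeat {
      cand <- beta + s * step
      obj_new <- pen_obj(cand)
      if (is.finite(obj_new) && obj_new >= obj - 1e-12 * abs(obj)) break
      s <- s / 2
      if (s < 1e-10) { obj_new <- obj; cand <- beta; break }
    }
    rel_change <- abs(obj_new - obj) / (abs(obj) + 1e-10)
    beta <- cand
    obj <- obj_new
    if (rel_change < obj_tol && grad_max < sqrt(grad_tol)) {
      converged <- TRUE
      break
    }
  }
  if (max(abs(beta)) > 50)
    warning("very large coefficients: possible complete separation")

  # Hessian pieces at the optimum
  mp <- multinom_probs(B %*% beta, agg$Y)
  p <- mp$p
  H <- matrix(0, 3L * K, 3L * K)
  for (cc in 1:3) for (dd in cc:3) {
    w <- agg$m * (p[, cc + 1L] * (cc == dd) - p[, cc + 1L] * p[, dd + 1L])
    blk <- crossprod(B, B * w)
    ri <- (cc - 1L) * K + seq_len(K); ci <- (dd - 1L) * K + seq_len(K)
    H[ri, ci] <- blk
    if (dd > cc) H[ci, ri] <- t(blk)
  }
  A <- H
  for (cc in 1:3) {
    idx <- (cc - 1L) * K + seq_len(K)
    A[idx, idx] <- A[idx, idx] + lambda * P
  }
  ed <- sum(diag(solve(A, H)))
  ll <- mp$loglik
  structure(
    list(design = design, penalty = penalty, lambda = lambda,
         coefficients = beta, loglik = ll, effective_dimension = ed,
         aic = -2 * ll + 2 * ed, bic = -2 * ll + log(n) * ed,
         n = n, hessian = H, penalized_information = A,
         converged = converged, n_iter = iter, grad_max = grad_max,
         sparse_categories = which(counts < 5) - 1L),
    class = "pair_fit")
}

#' @export
print.pair_fit <- function(x, ...) {
  cat(sprintf(paste0("Penalized multinomial P-spline fit: n = %d, lambda = %g\n",
                     "  loglik = %.3f, ED = %.2f, AIC = %.2f, BIC = %.2f (%s, %d iter)\n"),
              x$n, x$lambda, x$loglik, x$effective_dimension, x$aic, x$bic,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  if (length(x$sparse_categories))
    cat("  sparse status categories (< 5 obs):",
        paste(x$sparse_categories, collapse = ", "), "\n")
  invisible(x)
}

#' Effective dimension of a penalized fit
#'
#' The trace \eqn{\mathrm{tr}\{(H + \lambda P_{block})^{-1} H\}} with `H`
#' the negative Hessian of the unpenalized log-likelihood at the optimum
#' and the penalty repeated block-diagonally over the three category
#' coefficient vectors. Equals `3 * n_basis` at `lambda = 0` and shrinks to
#' three times the penalty null-space dimension as `lambda` grows.
#'
#' @param fit A converged [fit_pair_pspline()] result.
#' @return Effective dimension (scalar).
#' @export
effective_dimension <- function(fit) {
  stopifnot(inherits(fit, "pair_fit"))
  fit$effective_dimension
}

#' Covariance of the penalized coefficient estimate
#'
#' The penalized-information (Bayesian posterior) covariance
#' \eqn{(H + \lambda P_{block})^{-1}} of the stacked coefficient vector
#' (category 1 coefficients first, then 2, then 3). This is the covariance
#' from which Monte Carlo coefficient draws are taken.
#'
#' @param fit A converged [fit_pair_pspline()] result.
#' @return Symmetric positive definite `3 n_basis x 3 n_basis` matrix.
#' @export
coefficient_covariance <- function(fit) {
  stopifnot(inherits(fit, "pair_fit"))
  if (!fit$converged)
    stop("fit did not converge; covariance would be unreliable")
  if (!is.null(fit$covariance)) return(fit$covariance) # restored from JSON
  V <- tryCatch(solve(fit$penalized_information), error = function(e)
    stop("penalized information is singular: ", conditionMessage(e)))
  (V + t(V)) / 2
}

#' Predicted status probabilities on an age grid
#'
#' Softmax of the three fitted logits against the reference category; each
#' row is (P0, P1, P2, P3) = P(neither), P(only A), P(only B), P(both) and
#' sums to one. Ages outside the design range are an error (penalized
#' spline extrapolation is polynomial and misleading for prevalence).
#'
#' @param object A `pair_fit`.
#' @param ages Age grid within the design range.
#' @param ... Unused.
#' @return `length(ages) x 4` matrix with columns `P0`..`P3`.
#' @export
predict.pair_fit <- function(object, ages, ...) {
  B <- evaluate_basis(ages, object$design)
  full <- cbind(0, B %*% object$coefficients)
  mx <- apply(full, 1L, max)
  ex <- exp(full - mx)
  p <- ex / rowSums(ex)
  colnames(p) <- paste0("P", 0:3)
  rownames(p) <- ages
  p
}

#' Default smoothing-parameter grid
#'
#' 17 points equally spaced in log10 lambda from -2 to 6.
#' @return Numeric vector of lambda values.
#' @export
default_lambda_grid <- function() 10^seq(-2, 6, by = 0.5)

#' Select the smoothing parameter by AIC or BIC over a grid
#'
#' Fits the penalized multinomial model at every grid value (warm-starting
#' each fit from the previous one), picks the value minimizing the chosen
#' information criterion with ties broken towards larger lambda (the
#' smoother fit), then refines once with 5 extra points between the grid
#' neighbours of the minimizer. The criterion uses the effective dimension:
#' AIC = -2 loglik + 2 ED, BIC = -2 loglik + log(n) ED.
#'
#' @inheritParams fit_pair_pspline
#' @param grid Nonempty vector of nonnegative lambda values.
#' @param criterion `"aic"` (default) or `"bic"`.
#' @param refine Add the 5-point zoom around the grid minimizer (default
#'   TRUE).
#' @return The selected `pair_fit`, with the full criterion profile attached
#'   as `$profile` (data frame: lambda, loglik, ed, aic, bic, converged).
#' @export
select_lambda <- function(age, status, design,
                          penalty = difference_penalty(design$n_basis),
                          grid = default_lambda_grid(), criterion = c("aic", "bic"),
                          refine = TRUE) {
  criterion <- match.arg(criterion)
  if (length(grid) == 0L || any(grid < 0)) stop("lambda grid must be nonempty, >= 0")
  grid <- sort(unique(grid))
  fits <- vector("list", length(grid))
  errors <- character(0)
  start <- NULL
  for (i in seq_along(grid)) {
    fits[[i]] <- tryCatch(
      fit_pair_pspline(age, status, design, penalty, grid[[i]], start = start),
      error = function(e) e)
    if (inherits(fits[[i]], "pair_fit")) start <- fits[[i]]$coefficients
    else errors <- c(errors, sprintf("lambda=%g: %s", grid[[i]],
                                     conditionMessage(fits[[i]])))
  }
  ok <- vapply(fits, inherits, TRUE, "pair_fit")
  if (!any(ok))
    stop("all smoothing-parameter fits failed:\n  ",
         paste(errors, collapse = "\n  "))
  fits <- fits[ok]; grid <- grid[ok]
  if (refine && length(grid) > 1L) {
    crit <- vapply(fits, `[[`, 0, criterion)
    imin <- max(which(crit <= min(crit) + 1e-9))
    lo <- if (imin > 1L) grid[[imin - 1L]] else grid[[imin]] / 10
    hi <- if (imin < length(grid)) grid[[imin + 1L]] else grid[[imin]] * 10
    extra <- setdiff(10^seq(log10(max(lo, 1e-12)), log10(hi), length.out = 7L)[2:6],
                     grid)
    start <- fits[[imin]]$coefficients
    for (lam in extra) {
      f <- tryCatch(
        fit_pair_pspline(age, status, design, penalty, lam, start = start),
        error = function(e) NULL)
      if (!is.null(f)) { fits <- c(fits, list(f)); grid <- c(grid, lam) }
    }
    o <- order(grid)
    fits <- fits[o]; grid <- grid[o]
  }
  profile <- data.frame(
    lambda = grid,
    loglik = vapply(fits, `[[`, 0, "loglik"),
    ed = vapply(fits, `[[`, 0, "effective_dimension"),
    aic = vapply(fits, `[[`, 0, "aic"),
    bic = vapply(fits, `[[`, 0, "bic"),
    converged = vapply(fits, `[[`, TRUE, "converged"))
  crit <- profile[[criterion]]
  best <- max(which(crit <= min(crit) + 1e-9)) # ties -> larger lambda
  fit <- fits[[best]]
  fit$profile <- profile
  fit$criterion <- criterion
  fit
}

#' Serialize a pair fit to JSON (and back)
#'
#' Stores everything needed to reproduce predictions and Monte Carlo
#' intervals: the design, penalty order, selected lambda, coefficients,
#' the coefficient covariance (row-major), log-likelihood, effective
#' dimension, AIC/BIC and, when present, the lambda profile.
#'
#' @param fit A converged `pair_fit`.
#' @param path Output path; if `NULL` the JSON string is returned.
#' @param pair Optional `c(disease_a, disease_b)` label stored with the fit.
#' @export
pair_fit_to_json <- function(fit, path = NULL, pair = fit$pair) {
  stopifnot(inherits(fit, "pair_fit"))
  V <- coefficient_covariance(fit)
  x <- list(
    pair = pair,
    design = list(age_min = fit$design$age_min, age_max = fit$design$age_max,
                  n_segments = fit$design$n_segments, degree = fit$design$degree),
    penalty_order = fit$penalty$order,
    lambda = fit$lambda,
    coefficients = fit$coefficients,
    covariance = as.vector(t(V)),
    loglik = fit$loglik, effective_dimension = fit$effective_dimension,
    aic = fit$aic, bic = fit$bic, n = fit$n,
    converged = fit$converged, n_iter = fit$n_iter,
    sparse_categories = fit$sparse_categories,
    criterion = fit$criterion,
    profile = fit$profile)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname pair_fit_to_json
#' @param json JSON string or file path produced by `pair_fit_to_json()`.
#' @return `pair_fit_from_json()` returns a `pair_fit` usable with
#'   [predict.pair_fit()] and [monte_carlo_intervals()] (the covariance is
#'   restored directly; the raw Hessian is not serialized).
#' @export
pair_fit_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  design <- spline_design(x$design$age_min, x$design$age_max,
                          x$design$n_segments, x$design$degree)
  K <- design$n_basis
  V <- matrix(x$covariance, 3L * K, 3L * K, byrow = TRUE)
  fit <- list(design = design,
              penalty = difference_penalty(K, x$penalty_order),
              lambda = x$lambda,
              coefficients = matrix(unlist(x$coefficients), K, 3L),
              loglik = x$loglik, effective_dimension = x$effective_dimension,
              aic = x$aic, bic = x$bic, n = x$n,
              covariance = (V + t(V)) / 2,
              converged = x$converged, n_iter = x$n_iter,
              sparse_categories = x$sparse_categories,
              criterion = x$criterion,
              pair = unlist(x$pair))
  if (!is.null(x$profile)) fit$profile <- as.data.frame(x$profile)
  structure(fit, class = "pair_fit")
}
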