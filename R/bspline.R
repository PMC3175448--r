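#' Equally spaced B-spline design over an age range
#'
#' Constructs the knot vector and bookkeeping for a basis of `n_segments +
#' degree` B-splines of the given degree on `n_segments` equal subintervals
#' of `[age_min, age_max]`, with `degree` extra knots extending each side so
#' that the basis is complete over the whole range. This is the standard
#' rich, equally spaced basis used for P-spline smoothing: the number of
#' segments is chosen generously and the effective smoothness is controlled
#' by a difference penalty, not by knot placement.
#'
#' @param age_min,age_max Numeric range covered by the basis (years).
#' @param n_segments Number of equal interior intervals (default 20).
#' @param degree Polynomial degree of the basis functions (default 3, cubic).
#' @return An object of class `spline_design` with elements `age_min`,
#'   `age_max`, `n_segments`, `degree`, `knots` (length
#'   `n_segments + 2 * degree + 1`) and `n_basis = n_segments + degree`.
#' @examples
#' sd <- spline_design(20, 90, n_segments = 20)
#' sd$n_basis # 23
#' @export
spline_design <- function(age_min, age_max, n_segments = 20L, degree = 3L) {
  stopifnot(is.numeric(age_min), is.numeric(age_max), length(age_min) == 1L,
            length(age_max) == 1L)
  if (!(age_min < age_max)) stop("`age_min` must be strictly less than `age_max`")
  n_segments <- as.integer(n_segments)
  degree <- as.integer(degree)
  if (degree < 0L) stop("`degree` must be >= 0")
  if (n_segments < 1L) stop("`n_segments` must be >= 1")
  if (n_segments < degree + 1L)
    stop("`n_segments` must be at least `degree + 1` to support a difference penalty")
  h <- (age_max - age_min) / n_segments
  knots <- age_min + h * seq.int(-degree, n_segments + degree)
  structure(
    list(age_min = age_min, age_max = age_max, n_segments = n_segments,
         degree = degree, knots = knots, n_basis = n_segments + degree,
         h = h),
    class = "spline_design")
}

#' @export
print.spline_design <- function(x, ...) {
  cat(sprintf("B-spline design: degree %d, %d segments on [%g, %g] (%d basis functions)\n",
              x$degree, x$n_segments, x$age_min, x$age_max, x$n_basis))
  invisible(x)
}

#' Evaluate the B-spline basis at a set of ages
#'
#' Uses the Cox-de Boor recursion in its stable local form: for each
#' evaluation point the `degree + 1` basis functions with support there are
#' computed from the knot differences; all other basis functions are zero.
#' Rows form a partition of unity.
#'
#' @param ages Numeric vector of evaluation points, all within
#'   `[age_min, age_max]`. No extrapolation is performed.
#' @param design A [spline_design()].
#' @return Matrix of dimension `length(ages) x design$n_basis`.
#' @export
evaluate_basis <- function(ages, design) {
  stopifnot(inherits(design, "spline_design"), is.numeric(ages))
  if (length(ages) == 0L)
    return(matrix(0, 0L, design$n_basis))
  eps <- 1e-8 * max(1, abs(design$age_min), abs(design$age_max))
  if (any(ages < design$age_min - eps | ages > design$age_max + eps))
    stop("ages outside the design range [", design$age_min, ", ",
         design$age_max, "]: no extrapolation")
  deg <- design$degree
  kn <- design$knots
  K <- design$n_basis
  h <- design$h
  # index of the knot interval containing x (right-closed at age_max)
  j <- pmin(pmax(1L + as.integer(floor((ages - design$age_min) / h)), 1L),
            design$n_segments) + deg
  out <- matrix(0, length(ages), K)
  for (i in seq_along(ages)) {
    x <- ages[[i]]
    ji <- j[[i]]
    b <- 1
    if (deg > 0L) {
      for (d in seq_len(deg)) {
        saved <- 0
        bb <- numeric(d + 1L)
        for (r in seq_len(d)) {
          term <- b[[r]] / (kn[[ji + r]] - kn[[ji + r - d]])
          bb[[r]] <- saved + (kn[[ji + r]] - x) * term
          saved <- (x - kn[[ji + r - d]]) * term
        }
        bb[[d + 1L]] <- saved
        b <- bb
      }
    }
    out[i, (ji - deg):ji] <- b
  }
  out
}

#' Difference penalty matrix for adjacent B-spline coefficients
#'
#' Returns the quadratic penalty \eqn{P = D^\top D} where `D` is the
#' `order`-th difference operator on coefficient vectors. Its null space is
#' the polynomial coefficient sequences of degree `order - 1`, so with an
#' order-2 penalty a very large smoothing parameter shrinks each fitted
#' logit towards a straight line in age.
#'
#' @param n_basis Number of basis coefficients penalized.
#' @param order Difference order `d` (default 2).
#' @return An object of class `penalty_matrix`: list with `order` and the
#'   `n_basis x n_basis` symmetric positive semidefinite `matrix` of rank
#'   `n_basis - order`.
#' @export
difference_penalty <- function(n_basis, order = 2L) {
  n_basis <- as.integer(n_basis)
  order <- as.integer(order)
  if (order < 1L) stop("`order` must be >= 1")
  if (order >= n_basis) stop("`order` must be smaller than `n_basis`")
  D <- diff(diag(n_basis), differences = order)
  structure(list(order = order, n_basis = n_basis, matrix = crossprod(D)),
            class = "penalty_matrix")
}

#' @export
print.penalty_matrix <- function(x, ...) {
  cat(sprintf("Difference penalty: order %d on %d coefficients (rank %d)\n",
              x$order, x$n_basis, x$n_basis - x$order))
  invisible(x)
}

#' Serialize / restore a spline design
#'
#' The design (range, segment count, degree, knots) round-trips through
#' JSON so fits are reproducible across sessions.
#'
#' @param design A [spline_design()].
#' @param path File path; if `NULL`, the JSON string is returned.
#' @return `design_to_json()` returns the path (or JSON string) invisibly;
#'   `design_from_json()` returns a `spline_design`.
#' @export
design_to_json <- function(design, path = NULL) {
  stopifnot(inherits(design, "spline_design"))
  x <- design[c("age_min", "age_max", "n_segments", "degree")]
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname design_to_json
#' @param json JSON string or path to a JSON file written by
#'   `design_to_json()`.
#' @export
design_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  spline_design(x$age_min, x$age_max, x$n_segments, x$degree)
}
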