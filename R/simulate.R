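#' Age-specific marginal prevalence curve on the logit scale
#'
#' A marginal prevalence curve for one disease: prevalence at age `a` is
#' `plogis(intercept + slope * a + quadratic * a^2)`. A positive slope with
#' zero quadratic gives prevalence rising monotonically with age, the
#' pattern typical of chronic disease in adult survey data; a small negative
#' quadratic lets the rise level off at high ages.
#'
#' @param disease Disease label (character scalar).
#' @param intercept Intercept on the logit scale.
#' @param slope Logit change per year of age.
#' @param quadratic Logit change per squared year (default 0).
#' @return An object of class `marginal_curve`.
#' @export
marginal_curve <- function(disease, intercept, slope, quadratic = 0) {
  stopifnot(is.character(disease), length(disease) == 1L,
            is.numeric(intercept), is.numeric(slope), is.numeric(quadratic))
  structure(list(disease = disease, intercept = intercept, slope = slope,
                 quadratic = quadratic),
            class = "marginal_curve")
}

#' Evaluate a marginal prevalence curve
#'
#' @param age Vector of ages (years).
#' @param spec A [marginal_curve()].
#' @return Prevalence in (0, 1), one value per age.
#' @export
marginal_prevalence <- function(age, spec) {
  stopifnot(inherits(spec, "marginal_curve"))
  stats::plogis(spec$intercept + spec$slope * age + spec$quadratic * age^2)
}

#' Age-varying pairwise dependence as an odds-ratio curve
#'
#' Dependence between two diseases is specified by the 2x2 cell odds ratio
#' as a log-linear function of age:
#' `theta(age) = exp(log_or_intercept + log_or_slope * age)`. A negative
#' slope makes clustering relatively strongest at young ages, so that
#' observed/expected co-occurrence decreases with age even while absolute
#' joint prevalence rises.
#'
#' @param disease_a,disease_b Labels of the two diseases in the pair.
#' @param log_or_intercept Intercept of log theta.
#' @param log_or_slope Change in log theta per year of age.
#' @return An object of class `dependence_curve`.
#' @export
dependence_curve <- function(disease_a, disease_b, log_or_intercept,
                             log_or_slope = 0) {
  stopifnot(is.character(disease_a), is.character(disease_b),
            disease_a != disease_b)
  structure(list(disease_a = disease_a, disease_b = disease_b,
                 log_or_intercept = log_or_intercept,
                 log_or_slope = log_or_slope),
            class = "dependence_curve")
}

#' Odds ratio of a dependence curve at given ages
#' @param age Vector of ages.
#' @param spec A [dependence_curve()].
#' @return Odds ratio theta(age) > 0.
#' @export
pair_odds_ratio <- function(age, spec) {
  stopifnot(inherits(spec, "dependence_curve"))
  exp(spec$log_or_intercept + spec$log_or_slope * age)
}

#' Bivariate binary cell probabilities with given margins and odds ratio
#'
#' The Plackett construction: the unique 2x2 distribution with marginal
#' success probabilities `p_a`, `p_b` and cell odds ratio `theta`. For
#' `theta != 1` the joint probability `p11` is the admissible root of
#' \deqn{(\theta - 1) p_{11}^2 - S p_{11} + \theta p_A p_B = 0,\quad
#'       S = 1 + (p_A + p_B)(\theta - 1),}
#' namely the root with the minus sign on the discriminant; for
#' `theta == 1` it is `p_a * p_b`.
#'
#' @param p_a,p_b Marginal probabilities, both in (0, 1). Vectorized;
#'   recycled against `theta`.
#' @param theta Odds ratio(s), > 0.
#' @return Matrix with columns `p00`, `p01`, `p10`, `p11` (the second index
#'   is disease B), rows summing to 1 and reproducing the margins.
#' @export
joint_cell_probs <- function(p_a, p_b, theta) {
  if (any(theta <= 0)) stop("`theta` must be > 0")
  if (any(p_a <= 0 | p_a >= 1) || any(p_b <= 0 | p_b >= 1))
    stop("margins must lie strictly inside (0, 1)")
  n <- max(length(p_a), length(p_b), length(theta))
  p_a <- rep_len(p_a, n); p_b <- rep_len(p_b, n); theta <- rep_len(theta, n)
  p11 <- numeric(n)
  ind <- abs(theta - 1) < 1e-12
  p11[ind] <- p_a[ind] * p_b[ind]
  if (any(!ind)) {
    tm1 <- theta[!ind] - 1
    S <- 1 + (p_a[!ind] + p_b[!ind]) * tm1
    disc <- S^2 - 4 * theta[!ind] * tm1 * p_a[!ind] * p_b[!ind]
    p11[!ind] <- (S - sqrt(disc)) / (2 * tm1)
  }
  p11 <- pmin(pmax(p11, 0), pmin(p_a, p_b))
  cbind(p00 = 1 - p_a - p_b + p11, p01 = p_b - p11, p10 = p_a - p11,
        p11 = p11)
}

#' Configuration for a synthetic cross-sectional survey
#'
#' Describes a survey of `n_respondents` with integer ages drawn from a
#' categorical age distribution, per-disease marginal prevalence curves,
#' and pairwise dependence curves for selected disease pairs. Pairs carrying
#' a dependence curve must be disjoint (no disease in two modelled pairs);
#' diseases outside modelled pairs are drawn independently given age.
#'
#' @param n_respondents Number of records to generate.
#' @param age_min,age_max Integer age range (inclusive).
#' @param marginals List of [marginal_curve()], one per disease, uniquely
#'   named diseases.
#' @param dependences List of [dependence_curve()] on disjoint pairs of the
#'   diseases in `marginals` (may be empty: full independence).
#' @param age_weights Nonnegative weights over the integer ages
#'   `age_min:age_max` (normalized internally). Default: flat to age 50,
#'   then declining linearly to 20% of the plateau at age 90 and beyond —
#'   a stylized adult population pyramid.
#' @param seed Integer seed making generation reproducible.
#' @param year Survey year label written with the records (default 2001).
#' @return An object of class `survey_config`.
#' @export
survey_config <- function(n_respondents, age_min = 20L, age_max = 90L,
                          marginals, dependences = list(),
                          age_weights = NULL, seed = 1L, year = 2001L) {
  age_min <- as.integer(age_min); age_max <- as.integer(age_max)
  if (!(age_min < age_max)) stop("`age_min` must be < `age_max`")
  n_respondents <- as.integer(n_respondents)
  if (n_respondents < 0L) stop("`n_respondents` must be >= 0")
  stopifnot(all(vapply(marginals, inherits, TRUE, "marginal_curve")))
  diseases <- vapply(marginals, `[[`, "", "disease")
  if (anyDuplicated(diseases)) stop("duplicate disease names in `marginals`")
  names(marginals) <- diseases
  stopifnot(all(vapply(dependences, inherits, TRUE, "dependence_curve")))
  dep_members <- unlist(lapply(dependences,
                               function(d) c(d$disease_a, d$disease_b)))
  if (!all(dep_members %in% diseases))
    stop("dependence curves name diseases absent from `marginals`")
  if (anyDuplicated(dep_members))
    stop("modelled pairs must be disjoint: a disease appears in two dependence curves")
  ages <- age_min:age_max
  if (is.null(age_weights)) {
    age_weights <- ifelse(ages <= 50, 1, pmax(1 - 0.02 * (ages - 50), 0.2))
  }
  if (length(age_weights) != length(ages) || any(age_weights < 0) ||
      sum(age_weights) <= 0)
    stop("`age_weights` must be nonnegative over age_min:age_max with positive sum")
  # marginal curves must stay inside (0, 1) over the range
  for (m in marginals) {
    p <- marginal_prevalence(ages, m)
    if (any(p <= 0 | p >= 1))
      stop("marginal curve for '", m$disease, "' leaves (0, 1) in the age range")
  }
  structure(list(n_respondents = n_respondents, age_min = age_min,
                 age_max = age_max, marginals = marginals,
                 dependences = dependences,
                 age_weights = age_weights / sum(age_weights),
                 seed = as.integer(seed), year = as.integer(year)),
            class = "survey_config")
}

#' Yearly characteristics of the source health survey
#'
#' The transcribed per-year characteristics (2001-2007) of the Dutch
#' cross-sectional health survey that the synthetic generator emulates:
#' sample size, percent men, and self-reported prevalence (percent) of
#' diabetes, stroke, AMI and cancer. The pooled 2001-2007 sample size is
#' the sum of the yearly `n` (69,140), and the pooled prevalences are the
#' calibration targets of [pols_like_config()].
#'
#' @return Data frame with columns `year`, `n`, `pct_men`, `pct_diabetes`,
#'   `pct_stroke`, `pct_ami`, `pct_cancer`.
#' @export
pols_survey_table <- function() {
  utils::read.csv(system.file("extdata", "pols_table1.csv",
                              package = "multimorb"))
}

#' A survey configuration emulating a pooled Dutch-style health survey
#'
#' Four self-reported diseases (diabetes, stroke, AMI, cancer) with
#' prevalence rising on the logit scale with age, calibrated so that the
#' population-averaged prevalences match the pooled levels reported by the
#' source survey (4.0%, 2.2%, 2.9%, 5.1%) under the default age
#' distribution. Two disjoint pairs carry age-decreasing odds-ratio
#' dependence (diabetes-stroke strong, AMI-cancer mild); the remaining
#' pairs are conditionally independent given age, so their true
#' observed/expected ratio is identically 1.
#'
#' @param n_respondents Number of records (default 69140, the pooled size
#'   of seven survey years of roughly 10,000 respondents each).
#' @param seed Integer seed.
#' @param dependences Optional replacement list of [dependence_curve()].
#' @return A [survey_config()].
#' @export
pols_like_config <- function(n_respondents = 69140L, seed = 1L,
                             dependences = NULL) {
  targets <- c(diabetes = 0.040, stroke = 0.022, ami = 0.029, cancer = 0.051)
  slopes <- c(diabetes = 0.080, stroke = 0.085, ami = 0.085, cancer = 0.060)
  ages <- 20:90
  w <- ifelse(ages <= 50, 1, pmax(1 - 0.02 * (ages - 50), 0.2))
  w <- w / sum(w)
  marginals <- lapply(names(targets), function(d) {
    b <- stats::uniroot(
      function(b) sum(w * stats::plogis(b + slopes[[d]] * ages)) - targets[[d]],
      c(-30, 10), tol = 1e-12)$root
    marginal_curve(d, intercept = b, slope = slopes[[d]])
  })
  if (is.null(dependences)) {
    dependences <- list(
      dependence_curve("diabetes", "stroke", log_or_intercept = 3.2,
                       log_or_slope = -0.025),
      dependence_curve("ami", "cancer", log_or_intercept = 1.4,
                       log_or_slope = -0.012))
  }
  survey_config(n_respondents, 20L, 90L, marginals, dependences, seed = seed)
}

#' Generate a synthetic cross-sectional survey
#'
#' Draws ages from the configured age distribution, then disease indicators:
#' for each modelled pair, the 2x2 cell at the respondent's age from
#' [joint_cell_probs()]; for every other disease an independent Bernoulli
#' with its marginal prevalence at that age. Fully reproducible given the
#' config seed.
#'
#' @param config A [survey_config()].
#' @return A `data.frame` with columns `age`, `year` and one 0/1 column per
#'   disease, in the order of `config$marginals`.
#' @export
generate_survey <- function(config) {
  stopifnot(inherits(config, "survey_config"))
  diseases <- names(config$marginals)
  n <- config$n_respondents
  out <- data.frame(age = integer(n), year = rep(config$year, n))
  for (d in diseases) out[[d]] <- integer(n)
  if (n == 0L) return(out)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  ages <- config$age_min:config$age_max
  age <- sample(ages, n, replace = TRUE, prob = config$age_weights)
  out$age <- age
  in_pair <- character(0)
  for (dep in config$dependences) {
    a <- dep$disease_a; b <- dep$disease_b
    in_pair <- c(in_pair, a, b)
    pa <- marginal_prevalence(age, config$marginals[[a]])
    pb <- marginal_prevalence(age, config$marginals[[b]])
    cells <- joint_cell_probs(pa, pb, pair_odds_ratio(age, dep))
    u <- stats::runif(n)
    # cumulative cells: p00 | p01 | p10 | p11
    c1 <- cells[, "p00"]; c2 <- c1 + cells[, "p01"]; c3 <- c2 + cells[, "p10"]
    out[[a]] <- as.integer(u >= c2)           # disease A present in p10, p11
    out[[b]] <- as.integer(u < c2 & u >= c1 | u >= c3)  # B present in p01, p11
  }
  for (d in setdiff(diseases, in_pair)) {
    p <- marginal_prevalence(age, config$marginals[[d]])
    out[[d]] <- as.integer(stats::runif(n) < p)
  }
  out
}

#' Exact age-specific co-occurrence truth implied by a survey configuration
#'
#' Evaluates, for every unordered disease pair in the configuration, the
#' exact joint prevalence and the observed-minus-expected and
#' observed/expected co-occurrence measures at each requested age, using the
#' generator's own cell probabilities (pairs without a dependence curve have
#' odds ratio 1, hence obs/exp identically 1). These curves are the ground
#' truth that model-based estimates should recover.
#'
#' @param config A [survey_config()].
#' @param ages Age grid (default all integer ages in the configured range).
#' @return A `data.frame` with columns `pair`, `disease_a`, `disease_b`,
#'   `age`, `p_a`, `p_b`, `theta`, `p_joint`, `obs_minus_exp`,
#'   `obs_over_exp`.
#' @export
true_curves <- function(config, ages = NULL) {
  stopifnot(inherits(config, "survey_config"))
  if (is.null(ages)) ages <- config$age_min:config$age_max
  if (any(ages < config$age_min | ages > config$age_max))
    stop("ages outside the configured range")
  diseases <- names(config$marginals)
  dep_key <- vapply(config$dependences,
                    function(d) paste(sort(c(d$disease_a, d$disease_b)),
                                      collapse = "|"), "")
  pairs <- utils::combn(diseases, 2L)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    key <- paste(sort(c(a, b)), collapse = "|")
    theta <- if (key %in% dep_key)
      pair_odds_ratio(ages, config$dependences[[match(key, dep_key)]])
    else rep(1, length(ages))
    pa <- marginal_prevalence(ages, config$marginals[[a]])
    pb <- marginal_prevalence(ages, config$marginals[[b]])
    p11 <- joint_cell_probs(pa, pb, theta)[, "p11"]
    data.frame(pair = paste(a, b, sep = ":"), disease_a = a, disease_b = b,
               age = ages, p_a = pa, p_b = pb, theta = theta, p_joint = p11,
               obs_minus_exp = p11 - pa * pb,
               obs_over_exp = p11 / (pa * pb))
  })
  do.call(rbind, res)
}

#' Write / read survey microdata as CSV
#'
#' Plain CSV with header `age,year,<disease columns>` and 0/1 indicators.
#'
#' @param survey Data frame from [generate_survey()] (or same shape).
#' @param path Output file path.
#' @return `write_survey()` returns `path` invisibly; `read_survey()` the
#'   data frame.
#' @export
write_survey <- function(survey, path) {
  utils::write.csv(survey, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_survey
#' @export
read_survey <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
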