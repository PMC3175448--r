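#' Write / read a survey configuration as YAML
#'
#' The YAML mirrors the [survey_config()] fields (marginal curves on the
#' logit scale, dependence curves on the log-odds-ratio scale, optional
#' age weights) so a simulation is fully reproducible from its config file.
#'
#' @param config A [survey_config()].
#' @param path Output path.
#' @return `config_to_yaml()` returns `path` invisibly;
#'   `config_from_yaml()` a `survey_config`.
#' @export
config_to_yaml <- function(config, path) {
  stopifnot(inherits(config, "survey_config"))
  x <- list(
    n_respondents = config$n_respondents,
    age_min = config$age_min, age_max = config$age_max,
    seed = config$seed, year = config$year,
    age_weights = as.numeric(config$age_weights),
    marginals = lapply(unname(config$marginals), function(m)
      list(disease = m$disease, intercept = m$intercept, slope = m$slope,
           quadratic = m$quadratic)),
    dependences = lapply(config$dependences, function(d)
      list(pair = c(d$disease_a, d$disease_b),
           log_or_intercept = d$log_or_intercept,
           log_or_slope = d$log_or_slope)))
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname config_to_yaml
#' @export
config_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  req <- c("n_respondents", "age_min", "age_max", "marginals")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop("config is missing required field(s): ", paste(miss, collapse = ", "))
  marginals <- lapply(x$marginals, function(m)
    marginal_curve(m$disease, m$intercept, m$slope, m$quadratic %||% 0))
  dependences <- lapply(x$dependences %||% list(), function(d)
    dependence_curve(d$pair[[1L]], d$pair[[2L]], d$log_or_intercept,
                     d$log_or_slope %||% 0))
  survey_config(x$n_respondents, x$age_min, x$age_max, marginals,
                dependences, age_weights = x$age_weights,
                seed = x$seed %||% 1L, year = x$year %||% 2001L)
}

write_manifest <- function(out_dir, stage, extra = list()) {
  manifest <- c(list(stage = stage,
                     package = "multimorb",
                     version = as.character(utils::packageVersion("multimorb")),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
                extra)
  path <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  writeLines(as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                           digits = NA)), path)
  invisible(path)
}

#' Pipeline stage 1: simulate a survey to disk
#'
#' Writes the generated microdata (`survey.csv`), the generator's exact
#' co-occurrence truth on the integer age grid (`truth.csv`), the config
#' (`config.yaml`) and a manifest recording the seed.
#'
#' @param config A [survey_config()] or path to a YAML config file.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the named vector of files written.
#' @export
cmd_simulate <- function(config, out_dir) {
  if (is.character(config)) config <- config_from_yaml(config)
  stopifnot(inherits(config, "survey_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  survey_path <- file.path(out_dir, "survey.csv")
  truth_path <- file.path(out_dir, "truth.csv")
  cfg_path <- file.path(out_dir, "config.yaml")
  write_survey(generate_survey(config), survey_path)
  utils::write.csv(true_curves(config), truth_path, row.names = FALSE,
                   quote = FALSE)
  config_to_yaml(config, cfg_path)
  message("simulate: wrote ", config$n_respondents, " records to ", survey_path)
  write_manifest(out_dir, "simulate",
                 list(seed = config$seed, n_respondents = config$n_respondents,
                      files = c("survey.csv", "truth.csv", "config.yaml")))
  invisible(c(survey = survey_path, truth = truth_path, config = cfg_path))
}

#' Pipeline stage 2: fit all pair models to a survey CSV
#'
#' Reads survey microdata, fits one penalized multinomial P-spline per
#' unordered disease pair with independent smoothing-parameter selection,
#' and writes one JSON fit file per pair plus a manifest with the selected
#' lambda and criterion profile summary.
#'
#' @param data_path CSV with an `age` column and the 0/1 disease columns.
#' @param diseases Character vector (>= 2) of disease column names.
#' @param out_dir Output directory.
#' @param criterion `"aic"` (default) or `"bic"`.
#' @param n_segments,degree,penalty_order Spline design settings.
#' @param grid Lambda grid.
#' @return Invisibly, the named vector of fit files written.
#' @export
cmd_fit <- function(data_path, diseases, out_dir, criterion = c("aic", "bic"),
                    n_segments = 20L, degree = 3L, penalty_order = 2L,
                    grid = default_lambda_grid()) {
  criterion <- match.arg(criterion)
  data <- read_survey(data_path)
  if (nrow(data) == 0L) stop("empty input: ", data_path)
  miss <- setdiff(c("age", diseases), names(data))
  if (length(miss)) stop("missing column(s) in ", data_path, ": ",
                         paste(miss, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  design <- spline_design(min(data$age), max(data$age), n_segments, degree)
  penalty <- difference_penalty(design$n_basis, penalty_order)
  pairs <- utils::combn(diseases, 2L)
  files <- character(0)
  lambdas <- list()
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    status <- encode_pair_status(data[[a]], data[[b]])
    fit <- select_lambda(data$age, status, design, penalty, grid, criterion)
    path <- file.path(out_dir, sprintf("fit_%s_%s.json", a, b))
    pair_fit_to_json(fit, path, pair = c(a, b))
    message(sprintf("fit: %s:%s lambda = %g (ED %.2f, %s %.1f) -> %s",
                    a, b, fit$lambda, fit$effective_dimension,
                    toupper(criterion), fit[[criterion]], basename(path)))
    files[[paste(a, b, sep = ":")]] <- path
    lambdas[[paste(a, b, sep = ":")]] <- fit$lambda
  }
  write_manifest(out_dir, "fit",
                 list(data = data_path, diseases = diseases,
                      criterion = criterion, lambda = lambdas,
                      design = list(age_min = design$age_min,
                                    age_max = design$age_max,
                                    n_segments = n_segments, degree = degree,
                                    penalty_order = penalty_order),
                      files = basename(files)))
  invisible(files)
}

#' Pipeline stage 3: co-occurrence curves with Monte Carlo intervals
#'
#' Reads every `fit_*.json` in a directory, computes the three outcome
#' measures (joint prevalence, obs-exp, obs/exp) on the integer age grid
#' with pointwise Monte Carlo percentile intervals, and writes a tidy
#' `curves.csv` (`pair,age,measure,estimate,ci_lower,ci_upper,n_valid_draws`)
#' plus a manifest.
#'
#' @param fits_dir Directory containing fit files from [cmd_fit()].
#' @param out_dir Output directory (default `fits_dir`).
#' @param n_draws Coefficient draws per pair (default 10000).
#' @param level Interval level (default 0.95).
#' @param seed Base seed; pair `i` uses `seed + 1000 * i`.
#' @return Invisibly, the path of `curves.csv`.
#' @export
cmd_analyze <- function(fits_dir, out_dir = fits_dir, n_draws = 10000L,
                        level = 0.95, seed = 1L) {
  fit_files <- sort(list.files(fits_dir, pattern = "^fit_.*\\.json$",
                               full.names = TRUE))
  if (length(fit_files) == 0L)
    stop("no fit_*.json files found in ", fits_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- list()
  seeds <- list()
  for (k in seq_along(fit_files)) {
    fit <- pair_fit_from_json(fit_files[[k]])
    pair <- fit$pair %||% c("A", "B")
    s <- (seed + 1000L * k) %% .Machine$integer.max
    curve <- monte_carlo_intervals(fit, n_draws = n_draws, level = level,
                                   seed = s, pair = pair)
    tabs[[k]] <- as.data.frame(curve)
    seeds[[paste(pair, collapse = ":")]] <- s
  }
  out <- do.call(rbind, tabs)
  curves_path <- file.path(out_dir, "curves.csv")
  utils::write.csv(out, curves_path, row.names = FALSE, quote = FALSE)
  message("analyze: wrote ", nrow(out), " rows to ", curves_path)
  write_manifest(out_dir, "analyze",
                 list(fits = basename(fit_files), n_draws = n_draws,
                      level = level, seed = seed, pair_seeds = seeds))
  invisible(curves_path)
}
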