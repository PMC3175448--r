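# multimorb

Age-specific multimorbidity from cross-sectional survey data.

`multimorb` quantifies how often pairs of chronic diseases occur together in
one person at each age, and how much of that co-occurrence exceeds what
independent occurrence ("sheer coincidence") would produce. It is aimed at
epidemiologists and biostatisticians working with health-survey microdata:
one record per respondent, an age in years, and a binary self-report
indicator per disease (the bundled defaults emulate a Dutch survey asking
about diabetes, stroke, myocardial infarction, and cancer).

## The model

For each unordered disease pair (A, B), every respondent gets a 4-level
status: 0 = neither, 1 = only A, 2 = only B, 3 = both. Status is related to
age by a multinomial logistic regression whose three logits (against the
reference category 0) are P-splines: rich, equally spaced cubic B-spline
expansions of age with a quadratic penalty λ‖Δ²β‖² on second differences of
adjacent coefficients. The fit maximizes

  ℓ(β) − (λ/2) Σ_c β_cᵀ DᵀD β_c

by Newton iteration; the smoothing parameter λ (shared across the three
logits) is selected by minimizing AIC = −2ℓ + 2·ED (or BIC, with log(n)·ED),
where ED = tr{(H + λP)⁻¹H} is the effective dimension of the penalized fit.

From the fitted category probabilities P₀..P₃(age), the package derives
three age-specific outcome measures per pair, with P(A) = P₁+P₃ and
P(B) = P₂+P₃:

- joint prevalence  P(A,B) = P₃
- observed − expected  P₃ − P(A)·P(B)  (0 under independence)
- observed / expected  P₃ / {P(A)·P(B)}  (1 under independence)

Pointwise 95% confidence intervals come from a Monte Carlo procedure:
coefficients are repeatedly drawn (default 10,000 draws) from a multivariate
normal centred at the estimate with the penalized-information covariance
(H + λP)⁻¹; the measures are recomputed for each draw and the 2.5th/97.5th
empirical percentiles taken per age.

A synthetic survey generator with known ground truth completes the package:
marginal prevalence curves are logistic in age, and pairwise dependence is
injected through an age-varying 2×2 odds ratio via the Plackett
construction, so recovery and interval calibration can be tested against
exact truth curves.

## Worked example

```r
library(multimorb)

cfg    <- pols_like_config(20000, seed = 42)  # pooled-survey-like defaults
survey <- generate_survey(cfg)                # age, year + 0/1 indicators
res    <- run_all_pairs(survey, c("diabetes", "stroke", "ami", "cancer"),
                        n_draws = 2000, seed = 1)
print(res)
#> Co-occurrence analysis of 6 pair(s)
#>   diabetes:stroke      lambda = 3.16e+03 ED = 7.79   AIC = 8832.1
#>   diabetes:ami         lambda = 5.62e+06 ED = 6.00   AIC = 9704.3
#>   diabetes:cancer      lambda = 5.62e+06 ED = 6.00   AIC = 12751.1
#>   stroke:ami           lambda = 1.47e+04 ED = 6.52   AIC = 7787.6
#>   stroke:cancer        lambda = 5.62e+06 ED = 6.00   AIC = 10842.7
#>   ami:cancer           lambda = 5.62e+06 ED = 6.00   AIC = 11553.0

curve <- as.data.frame(res$curves[["diabetes:stroke"]])
subset(curve, measure == "obs_over_exp" & age %in% c(40, 60, 80))
#>             pair age      measure estimate ci_lower ci_upper n_valid_draws
#>  diabetes:stroke  40 obs_over_exp     7.21     3.37    14.06          2000
#>  diabetes:stroke  60 obs_over_exp     4.05     2.94     5.29          2000
#>  diabetes:stroke  80 obs_over_exp     2.38     2.08     2.67          2000
```

Reading the output: each pair's multinomial P-spline selected its own λ by
AIC (ED ≈ 6 means the penalty has shrunk each logit to roughly a straight
line; 7.8 leaves mild curvature). For diabetes–stroke, 40-year-olds carry
both diseases about 7 times more often than coincidence predicts, while
80-year-olds only about 2.4 times — relative clustering weakens with age
even though absolute joint prevalence rises. The generating truth for this
pair has odds ratio exp(3.2 − 0.025·age), so the decreasing pattern and its
magnitude are expected; for the four pairs generated without dependence the
interval for observed/expected covers 1.

The same pipeline runs file-to-file with `cmd_simulate()`, `cmd_fit()` and
`cmd_analyze()` (CSV in, JSON fits and a tidy curves CSV out), or from a
shell via `inst/cli/comorb.R`.

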