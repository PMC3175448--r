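---
title: "Modelling age-specific disease co-occurrence with multinomial P-splines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling age-specific disease co-occurrence with multinomial P-splines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multimorb)
```

## The scientific problem

Chronic diseases accumulate with age, so even if diseases struck people
independently, many older respondents would carry two at once: with 20%
marginal prevalence for each of two diseases, 4% joint prevalence is pure
coincidence. The interesting epidemiological quantity is the *excess* over
that benchmark, as a function of age. `multimorb` estimates, for every
unordered pair of diseases in a cross-sectional survey, the age curves of
joint prevalence, observed − expected co-occurrence, and the
observed/expected ratio, with pointwise Monte Carlo confidence intervals.

The input is survey microdata: one row per respondent with an integer age
and a binary self-report indicator per disease. Respondents are treated as
an i.i.d. sample within age; no survey weights, no covariates other than
age, sexes and years pooled (grouping columns pass through untouched, so
stratified reruns are a matter of subsetting).

## The model

For a pair (A, B) each respondent's status is coded 0 (neither), 1 (only
A), 2 (only B), 3 (both) — `encode_pair_status()`. Status given age follows
a multinomial logistic model with reference category 0. Each of the three
logits is a linear combination of `n_basis` cubic B-splines, equally spaced
over the age range (`spline_design()`, default 20 segments, so 23 basis
functions). The basis is deliberately richer than the data require; a
difference penalty of order 2 on adjacent coefficients
(`difference_penalty()`) controls the effective smoothness. The penalized
log-likelihood

$$\ell(\beta) \;-\; \frac{\lambda}{2}\sum_{c=1}^{3}\beta_c^\top D^\top D\,\beta_c$$

is maximized by full Newton iteration on the stacked coefficient vector
(`fit_pair_pspline()`). Because the penalty's null space is linear
coefficient sequences, $\lambda \to \infty$ collapses each logit to a
straight line in age — the model never degenerates below a linear
multinomial logit.

**Tunable parameters.**

| parameter | default | meaning |
|---|---|---|
| `n_segments` | 20 | interior B-spline intervals over the age range; "large" is the point — results are insensitive above ~15 because the penalty does the smoothing |
| `degree` | 3 | cubic: fitted curves have continuous second derivatives |
| `penalty_order` | 2 | null space = straight-line logits; the standard P-spline choice |
| `grid` | $10^{-2} \ldots 10^{6}$, 17 log-spaced points | λ search grid, refined once with 5 points around the minimizer |
| `criterion` | AIC | BIC available; BIC penalizes ED by log(n) > 2, so selects λ at least as large — smoother, less wiggly curves, mostly visible in the ratio at young ages where data are thin |
| `n_draws` | 10,000 | Monte Carlo coefficient draws per pair |
| `level` | 0.95 | pointwise interval level |

The effective dimension $\mathrm{ED} = \mathrm{tr}\{(H+\lambda
P)^{-1}H\}$ counts equivalent free parameters: $3\,n_\text{basis}$ at
$\lambda = 0$, falling to $3 \times 2$ (three straight lines) as
$\lambda \to \infty$. AIC $= -2\ell + 2\,\mathrm{ED}$ and BIC $= -2\ell +
\log(n)\,\mathrm{ED}$.

One λ is shared by the three category logits. This keeps the selection
one-dimensional and is the parsimonious reading when the three curves are
driven by the same underlying age gradients; the machinery accepts any λ
per call, so a per-category search can be scripted if a pair demands it.

## Outcome measures and Monte Carlo intervals

With $P_1, P_2, P_3$ the fitted category probabilities at an age,
$P(A) = P_1 + P_3$ and $P(B) = P_2 + P_3$:

$$\text{Obs}-\text{Exp} = P_3 - P(A)P(B), \qquad
  \text{Obs}/\text{Exp} = \frac{P_3}{P(A)P(B)}.$$

Both are symmetric in A and B, and the ratio exceeds 1 exactly when the
difference is positive. Intervals (`monte_carlo_intervals()`) draw
coefficient vectors from $\mathcal{N}(\hat\beta, (H+\lambda P)^{-1})$ —
the penalized-information, equivalently Bayesian posterior, covariance —
recompute the measures per draw, and take empirical 2.5th/97.5th
percentiles per age.

Numerical choices worth knowing:

- *Percentile definition*: nearest rank (inverse empirical CDF,
  `type = 1`), so intervals are determinate functions of the draws.
- *Point estimates* are plug-in values at $\hat\beta$, not Monte Carlo
  medians; for the nonlinear ratio a percentile interval can in edge cases
  exclude the plug-in point, which is flagged (`point_outside_ci`), not
  silently repaired.
- *Division by zero*: a draw with a zero margin yields an undefined ratio;
  it is kept for the difference and counted out of the ratio at that age
  (`n_valid_draws`). With softmax probabilities this is a theoretical
  rather than practical concern.
- *No extrapolation*: prediction outside the knot range is refused (in
  `predict()`) or clipped with a warning (in interval construction),
  because a penalized fit extrapolates as a polynomial of degree
  `penalty_order - 1`, which is misleading for prevalence.
- *Convergence*: Newton stops when the penalized-objective gradient
  max-norm falls below 1e-6 (cap 100 iterations, step-halving whenever a
  step would decrease the objective). Non-converged fits are flagged and
  refuse to produce a covariance.
- *Sparse categories*: a status category with fewer than 5 observations is
  flagged on the fit; at young ages "both diseases" is often this rare,
  which is exactly where ratio intervals become very wide.
- *Ties in λ selection* break towards the larger λ (the smoother fit).

## The synthetic generator and what it does (not) emulate

`survey_config()` / `generate_survey()` produce microdata with known
truth. Ages are drawn from a categorical distribution over integer ages
20–90 (default: flat to age 50, declining linearly to 20% of the plateau
by 90 — a stylized adult pyramid; real population pyramids are bumpier).
Each disease has a logistic marginal curve in age; intercepts in
`pols_like_config()` are calibrated by root-finding so the
population-averaged prevalences hit the pooled targets of the emulated
survey (diabetes 4.0%, stroke 2.2%, AMI 2.9%, cancer 5.1%), with logit
slopes of 0.06–0.085 per year, the order of magnitude typical for chronic
disease self-reports. Pairwise dependence is injected through the 2×2 odds
ratio $\theta(\text{age}) = \exp(a + b\cdot\text{age})$ using the Plackett
construction: `joint_cell_probs()` solves
$(\theta-1)p_{11}^2 - S\,p_{11} + \theta p_A p_B = 0$,
$S = 1 + (p_A+p_B)(\theta-1)$, for the admissible root, so margins and
odds ratio are exact by construction. The defaults give diabetes–stroke a
strong, age-decreasing dependence ($\log\theta = 3.2 - 0.025\,$age) and
AMI–cancer a mild one ($1.4 - 0.012\,$age); the remaining pairs are
conditionally independent given age, so their true observed/expected
ratio is exactly 1 — useful null cases.

Dependence is pairwise only, on disjoint pairs: a disease may appear in at
most one modelled pair, and no three- or four-way dependence structure is
generated, matching the pairwise scope of the analysis. `true_curves()`
returns the exact per-age truth for every pair.

What the generator does **not** emulate: nonresponse, underdiagnosis and
reporting error, the institutionalized population, sampling weights,
secular time trends, or sex differences. Passing recovery and calibration
tests therefore demonstrates that the estimator recovers the model it
assumes — not that those survey biases are harmless in real data.

## Validation design and problem sizes

The test suite checks each layer against an independent route:

- B-spline basis vs. a truncated-power-basis construction and the standard
  spline machinery (agreement to 1e-10).
- Unpenalized ($\lambda=0$) fits on an identifiable 3-age design vs. the
  closed-form saturated MLE and a brute-force numerical maximizer. (An
  unidentifiable basis — more basis functions than distinct ages — is the
  one situation where $\lambda = 0$ comparisons are meaningless, so the
  oracle tests use a degree-1, 2-segment design.)
- The $\lambda = 10^8$, order-2 fit vs. an independently fitted linear
  multinomial logit (max probability difference below 1e-4).
- Covariance at $\lambda=0$ vs. a finite-difference Hessian inverse.
- Joint-prevalence recovery on a 200,000-record survey (max error below
  0.01 over the interior 5–95% age quantiles).
- Interval calibration: 200 replicates of n = 20,000 with 2,000 draws
  each; mean pointwise coverage of the true observed/expected over ages
  25–85 is required to land in [91%, 98%] at the nominal 95%, and the
  fitted ratio must decrease from age 30 to 80 in at least 95% of
  replicates when the generating odds ratio decreases.

These sizes keep the full suite under a minute on one core while leaving
Monte Carlo noise well inside the asserted bands.

## Known limitations

- Pointwise, not simultaneous, intervals: no statement about the whole
  curve jointly.
- The penalized-information covariance ignores the uncertainty of λ
  selection and smoothing bias; coverage is near-nominal for smooth truth
  (as in the calibration study) but can dip where the truth has curvature
  the selected λ smooths away. A sandwich covariance would be a natural
  extension.
- Self-report quality, nonresponse and institutionalization biases are out
  of scope; estimates inherit whatever those biases put into the data.
- Cancer-style heterogeneous conditions enter as single indicators; the
  model sees only the binary questions asked.
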