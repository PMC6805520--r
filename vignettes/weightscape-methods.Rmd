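---
title: "Methods: integrated subjective-objective indicator weighting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated subjective-objective indicator weighting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weightscape)
```

weightscape estimates how important each indicator in a multi-criteria
evaluation system is, by combining two independent sources of evidence:
expert judgment (a *subjective* route through pairwise comparisons) and
respondent data (an *objective* route through score dispersion and
redundancy). The bundled case study evaluates eleven social-support
indicators for the self-management of type 2 diabetes, grouped under
emotional (E1–E4), informational (I1–I3) and tangible (T1–T4) support, but
nothing in the machinery is specific to that system.

## The subjective route: network-process priorities

Experts compare elements pairwise on the Saaty 1–9 intensity scale. A
judgment matrix $A = (a_{ij})$ is positive and reciprocal
($a_{ij} a_{ji} = 1$, unit diagonal). The local priority vector $W$ solves

$$A W = \lambda_{\max} W,$$

i.e. it is the normalized principal eigenvector. `principal_priority()`
computes it by power iteration (tolerance $10^{-12}$, cap 10,000
iterations); for a positive matrix Perron–Frobenius guarantees a simple
dominant eigenvalue with a positive eigenvector, so convergence is not a
practical concern, and the iteration cap is a defensive bound. A
`method = "geometric"` cross-check (geometric mean of rows) reproduces the
case study's printed priorities to 4 decimal places; the test suite
additionally checks the power iteration against a dense full-spectrum eigen
decomposition on random reciprocal matrices up to order 7.

Judgment coherence is measured by the consistency index
$CI = (\lambda_{\max} - n)/(n - 1)$ and the consistency ratio $CR = CI/RI$,
with $RI$ the mean random index. The source material never prints its $RI$
table, so we use Saaty's standard values
$(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49, 1.51)$ for
$n = 1..11$; $RI(3) = 0.58$ is confirmed by reproducing the case study's
$CR = 0.0079$. For $n \le 2$ a reciprocal matrix is always consistent and
$CR$ is defined as 0. A matrix with $CR \ge 0.1$ is *recorded* as
unacceptable rather than rejected — re-eliciting judgments is a human step a
library cannot perform — unless `strict = TRUE`.

Interdependence among criteria is expressed by a column-stochastic,
zero-diagonal dependency matrix $D$; the adjusted criterion weights are the
single product $D w$. Global sub-criterion weights multiply each local
priority by its parent's adjusted weight. When interdependence among
*sub-criteria* is available as an (unweighted) supermatrix $S$, the
subjective vector is the single product $S w_p$, optionally renormalized
when $S$ is flagged raw. We deliberately default to one multiplication
rather than powering $S$ to its limit, because that is the synthesis the
case study performs; a `limit = TRUE` mode implements the classical limit
supermatrix for users who want it. Whether the case study's supermatrix was
applied raw or column-normalized is not determinable from the published
account, so both modes are exposed.

The published supermatrix itself is not available. The file
`supermatrix_synthetic.csv` shipped with the package is a rank-1 stand-in
(every column equals the published subjective vector) constructed so that
the raw-mode product with the global weights renormalizes to that vector; it
exists to exercise the plumbing and regression-test the synthesis step, and
is labelled synthetic everywhere. The published subjective vector is
therefore treated as a *fixture input*, never as something the package
claims to recompute.

Printed priority vectors are rounded to 4 decimal places and often sum to
0.9999 or 1.0001; wherever the package ingests printed vectors it
renormalizes them onto the exact simplex, and validation tolerances (1e-6
for user input) are chosen to reject genuinely malformed input while
accepting such rounding.

## The objective route: CRITIC

Given an $n \times m$ respondents-by-indicators score matrix on the 0–10
scale, each column is min–max normalized against its ideal (best observed)
and anti-ideal (worst observed) values:

$$x_{aj} = \frac{f_j(a) - f_{j*}}{f_j^* - f_{j*}}.$$

An indicator is informative when respondents *disagree* on it (contrast
intensity, the standard deviation $\sigma_j$ of the normalized column) and
when it is *not redundant* with other indicators (conflict, via the Pearson
correlation $r_{jk}$). The information content and weights are

$$C_j = \sigma_j \sum_{k=1}^m (1 - r_{jk}), \qquad w_j = C_j / \sum_k C_k.$$

Conventions that the definition leaves open, and our choices:

* **Sample vs population standard deviation.** Not stated in the source
  method description, and the raw cohort that would let the printed
  $\sigma$ adjudicate is unavailable. Default is the sample convention
  ($n-1$), switchable via `sd_method = "population"`. The choice rescales
  every $\sigma_j$ by the same factor and therefore changes weights only
  through the conflict term's additive structure — in practice by far less
  than the rounding of the printed vectors.
* **Identical columns.** Two element-wise identical columns are assigned
  $r = 0$ by explicit convention (the stated rule in the method we
  implement), not the $r = +1$ a correlation routine would return. A
  constant column (undefined correlation) also pairs at 0, gets
  $\sigma = 0$ and hence weight 0, with a warning; only an entirely
  degenerate matrix (all $C_j = 0$) errors.
* **Correlation type.** Pearson, as "linear correlation" prescribes;
  Spearman is available behind a flag for sensitivity analysis only.
* **Direction.** All case-study indicators are benefit-type; a per-indicator
  `direction = -1` swaps ideal and anti-ideal for cost-type indicators.

$\sigma$ and $r$ are computed on the *normalized* matrix, which is what the
stepwise definition operates on; min–max normalization also makes the whole
chain invariant to positive affine rescaling of any raw column
(property-tested).

## Fusing the two routes: constrained least squares

With subjective weights $U$ and objective weights $V$ on the simplex, the
comprehensive weights solve

$$\min_W \sum_j \left[ \alpha (w_j - u_j)^2 + \beta (w_j - v_j)^2 \right]
\quad \text{s.t.} \quad \sum_j w_j = 1,\; w_j \ge 0.$$

Under equal trust ($\alpha = \beta$, the default) the optimum is the plain
average $(U + V)/2$: the derivation of the fused weighting in the source
account is not published, but every published fused value equals that
average to 4 decimal places, which pins the objective down and is encoded as
a regression test. We solve the general equality-constrained quadratic
program via its KKT system rather than hard-coding the average, so unequal
trust coefficients $(\alpha, \beta)$ remain supported; an active-set pass
pins negative components to zero, which provably cannot trigger under equal
trust with simplex inputs (also property-tested). Criterion-level shares sum
the fused weights within each parent criterion.

## Grading: rank-sum-ratio probits

Indicators are sorted ascending by fused weight (the weight itself is the
ranking statistic), tied values receive average ranks, and each indicator
gets a cumulative percentage $P_i = \bar{R}_i / m \times 100$. The top entry
would have $P = 100$, where the inverse normal diverges, so it is replaced
by the standard downward adjustment $P_m = (1 - \frac{1}{4m}) \times 100$
(97.73% for $m = 11$). With ties at the top no entry reaches 100 and no
adjustment is applied. The probit is $Y = \Phi^{-1}(P/100) + 5$, the
classical +5 offset that keeps probits positive; the offset is implied by
the published values and is fixed, not configurable.

Reverse-engineering the published probit column shows it corresponds to
$\Phi^{-1}$ evaluated at the cumulative percentage *truncated to a whole
percent* (9.09% behaves as 9%, 97.73% as 97%) — the behavior of the coarse
printed probit lookup tables historically used with this method. All eleven
published probits match that rule to 4 decimal places and none match the
untruncated transform. Whether the original computation truncated or used
such a table is unknowable and observationally equivalent, so the mode name
`legacy_percent_table` is descriptive, not attributive. The default mode is
`exact` (mathematically clean); the legacy mode exists to reproduce
published tables and is what the fixture tests use.

Grades cut the probit axis at half-open intervals; the default three-grade
scheme uses thresholds 4 and 6 (grade 1: $y < 4$; grade 2: $4 \le y < 6$;
grade 3: $y \ge 6$), with a probit exactly at a threshold taking the upper
grade, matching the published interval notation. Other grade counts are
supported only through a user-supplied threshold vector.

## The synthetic cohort generator

The respondent data behind the case study's objective weights are not
deposited, so the package ships a generator that emulates the instrument:
each of 11 indicators is measured by 3 Likert items; categories Strongly
Agree … Strongly Disagree map to 9/7/5/3/1 points; item points are summed
per indicator and the attainable range (3–27 for three items) is rescaled
linearly onto 0–10. The published account states the 0–10 endpoints but not
the mapping from the 27-point sum; a linear rescale of the attainable range
is the transparent convention adopted here. The physician revision of
scores in the original protocol is human judgment, not an algorithm; it is
represented by an optional bounded-noise hook (`physician_sd`), disabled by
default and excluded from every acceptance-grade check.

Correlated responses come from a Gaussian copula: one latent trait per
indicator with a configurable correlation matrix, plus item-level noise
(`item_noise_sd = 0.65`, giving within-indicator item correlations near
0.7), thresholded at cut-points $\Phi^{-1}(k/5)/c_j$ — equal-probability
quintiles sharpened or flattened by the per-indicator contrast parameter
$c_j$. This gives exactly one interpretable knob for the conflict notion
CRITIC measures (the latent correlation) and one for its contrast notion.
A respondent is incomplete with probability `incomplete_rate`, leaving 1–3
random items blank; `filter_incomplete()` removes such rows exactly and
idempotently.

`calibrate_default_cohort()` freezes the shipped stated world: 3,000
respondents, incomplete rate 31/3000 (the case study filtered 31 of 3,000
questionnaires), latent correlations 0.40 within a parent criterion and
0.25 across, unit contrast. These were chosen once so that the normalized
CRITIC contrast intensities land in the published band (0.26–0.34) and the
objective weights in the published 0.05–0.15 band; the tests assert those
*ranges* over seeds, never equality with the published vectors — the real
cohort is unavailable and the generator does not pretend to reproduce it.
What a green cohort test establishes is that the generator occupies the
same statistical regime (dispersion, mild positive correlation, near-uniform
objective weights) as the real data; it does not establish distributional
realism of individual questionnaires, demographic structure, or the
physician adjustment.

## Numerical choices and degenerate inputs

* Validation failures, computation failures and degenerate data raise
  distinct condition classes, mapped by the CLI to exit codes 2, 3 and 4.
* Fraction cells in CSV matrices ("1/3") are parsed as exact rationals
  before float conversion.
* Ties in ranking use the average-rank (midpoint) convention.
* Constant score columns normalize to zero and are flagged rather than
  erroring, unless every column is constant.
* Weight vectors are validated to the simplex at 1e-6 and renormalized
  exactly; all returned vectors satisfy the simplex to 1e-9.

## Known limitations

* The supermatrix synthesis and the dependency elicitation are taken as
  inputs; the package does not re-derive dependency structure from expert
  questionnaires.
* Group judgment aggregation (multiple experts before consensus), fuzzy
  comparisons, and multiplicative or game-theoretic fusion rules are out of
  scope.
* The generator's Likert marginals are symmetric quintiles by default;
  skewed real-world response styles (acquiescence, extreme responding) are
  representable only through the contrast knob, not modeled explicitly.
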