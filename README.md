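# weightscape

Integrated subjective–objective indicator weighting and grading for
multi-criteria evaluation problems in health outcomes research.

Many evaluation questions — *which kinds of social support matter most for
patients managing a chronic disease?* — come down to assigning importance
weights to a structured system of indicators. Expert panels and patient
data each see half the picture: experts encode domain judgment but carry
subjective bias; respondent data carry empirical signal but no notion of
meaning. weightscape implements the full combined-weighting workflow:

1. **Subjective route (analytic network process).** Pairwise-comparison
   matrices on the Saaty 1–9 scale yield local priorities as the principal
   eigenvector of $AW = \lambda_{\max} W$, checked by the consistency ratio
   $CR = \frac{(\lambda_{\max} - n)/(n-1)}{RI(n)} < 0.1$. Interdependence
   among criteria enters through a column-stochastic dependency matrix, and
   among sub-criteria through a supermatrix product.
2. **Objective route (CRITIC).** Respondent scores are min–max normalized;
   each indicator's information content combines its contrast intensity
   (standard deviation $\sigma_j$) with its conflict with the others:
   $C_j = \sigma_j \sum_k (1 - r_{jk})$, normalized to weights.
3. **Fusion.** The comprehensive weights minimize
   $\sum_j [\alpha(w_j-u_j)^2 + \beta(w_j-v_j)^2]$ subject to
   $\sum w_j = 1,\ w_j \ge 0$ — solved as an equality-constrained quadratic
   program (under equal trust this is the average of the two vectors).
4. **Grading (rank-sum ratio).** Indicators are ranked by fused weight,
   cumulative percentages $P_i = \bar R_i/m$ are mapped to classical probits
   $Y = \Phi^{-1}(P) + 5$ (with the standard $P_m = 1 - \frac{1}{4m}$
   top-entry adjustment), and probit thresholds 4 and 6 cut three
   importance grades.

A correlated Likert-survey cohort simulator (Gaussian copula over indicator
traits, 3 items per indicator, 9/7/5/3/1 point mapping, 0–10 rescaling,
incomplete-questionnaire filtering) makes the objective route fully testable
without access to patient data. The published values of the motivating
social-support case study (3 criteria, 11 sub-criteria, 2,969 valid
questionnaires) ship as a fixture with provenance labels.

## Worked example

```r
library(weightscape)
fx <- case_study_fixture()

# Subjective: criterion priorities from the pairwise-comparison matrix
pr <- principal_priority(fx$table1$matrix)
pr
#> <priority_result> n = 3, lambda_max = 3.009203 (power)
#> <weight_vector> 3 components
#>     ES     IS     TS
#> 0.5396 0.1634 0.2970
consistency(fx$table1$matrix, pr)
#> <consistency_report> CI = 0.0046, CR = 0.0079 (RI = 0.58) -> acceptable

# Fuse the case study's subjective and objective sub-criterion weights,
# aggregate to criterion shares, and grade by rank-sum-ratio probits
wy <- as_weight_vector(unlist(fx$omega_y$values), renormalize = TRUE)
wc <- as_weight_vector(unlist(fx$omega_c$values), renormalize = TRUE)
fused <- least_squares_combine(wy, wc)
round(grouped_shares(fused, fx$hierarchy), 2)
#>    ES    IS    TS
#> 23.16 44.82 32.02
tab <- assign_grades(build_rsr_table(fused, mode = "legacy_percent_table"))
grade_groups(tab)
#> $grade_1
#> [1] "E3"
#> $grade_2
#> [1] "E4" "T2" "T3" "I1" "E1" "E2" "T4" "T1"
#> $grade_3
#> [1] "I3" "I2"
```

Reading: informational support carries ~45% of the fused weight (its
sub-criteria I2 "guidance" and I3 "feedback" alone hold grade 3, the
high-sensitivity tier), tangible support ~32%, emotional support ~23%; the
lone grade-1 indicator (E3, "express respect") contributes under 4%.
`lambda_max = 3.0092` barely exceeds $n = 3$, so the expert judgments are
nearly consistent (CR = 0.0079 « 0.1).

For a fully synthetic run (no fixture vectors):

```r
cfg <- calibrate_default_cohort(n_respondents = 1000)
cohort <- filter_incomplete(generate_responses(cfg, seed = 42))
critic(score_responses(cohort, cfg))$weights
```

## Command line

Every stage is also a subcommand (`weightscape_main()`, or the wrapper
script installed at `system.file("cli", "weightscape", package = "weightscape")`):

```sh
weightscape anp    --hierarchy hierarchy.json --dependency dep.csv --out anp.json
weightscape synth  --n 3000 --seed 1 --out scores.csv
weightscape critic --scores scores.csv --out critic.json
weightscape fuse   --subjective anp.json --objective critic.json --out fused.json
weightscape rsr    --weights fused.json --mode legacy --out rsr.json
weightscape run    --config pipeline_case_study.json --out-dir report/
weightscape fixtures export --out fixtures/
```

Exit codes: 2 validation error, 3 computation error, 4 degenerate data.

## Further reading

`vignettes/weightscape-methods.Rmd` documents the model conventions (random
index table, standard-deviation and correlation conventions, the fusion
objective, the legacy percent-table probit mode, the synthetic cohort's
stated parameters) and their rationale.
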