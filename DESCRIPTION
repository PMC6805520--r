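Package: weightscape
Title: Integrated Subjective-Objective Indicator Weighting and Grading
Version: 0.1.0
Authors@R:
    person("weightscape", "developers", email = "dev@weightscape.invalid",
           role = c("aut", "cre"))
Description: Tools for multi-criteria indicator weighting in health outcomes
    research. Computes subjective weights from Saaty pairwise-comparison
    matrices by the analytic network process (principal-eigenvector
    priorities, consistency ratio, dependency-matrix adjustment, supermatrix
    synthesis), objective weights from respondent score data by the CRITIC
    method (contrast intensity times conflict), fuses the two by constrained
    least squares, and grades indicators with rank-sum-ratio probit
    classification. Includes a correlated Likert-survey cohort simulator, a
    bundled social-support case-study fixture, and a pipeline command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
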