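# Bundled case-study fixture: every published value of the social-support
# weighting case study (criterion comparison matrix, dependency matrix, local
# and global weights, subjective/objective/fused vectors, RSR table, grades),
# with a provenance string attached to each element.

#' Load the bundled case-study fixture
#'
#' Returns the printed values of the type-2-diabetes social-support weighting
#' case study shipped with the package: the 3x3 criterion comparison matrix
#' and its priorities, the criterion dependency matrix, local and global
#' sub-criterion weights, the subjective (`omega_y`), objective (`omega_c`)
#' and fused weight vectors, the contrast-intensity and information-content
#' vectors, the RSR distribution table, the three-grade classification, and
#' the criterion-level percentage shares. Each element carries a
#' `provenance` field naming the table or section it was printed in.
#'
#' The subjective vector `omega_y` and the contrast vector `sigma` are
#' fixture inputs only: the supermatrix and raw cohort behind them are not
#' published, so they cannot be recomputed (a synthetic rank-1 stand-in
#' supermatrix, `supermatrix_synthetic.csv`, is shipped for regression
#' plumbing only).
#'
#' @return nested list of class `case_study_fixture`.
#' @examples
#' fx <- case_study_fixture()
#' fx$table1$weights
#' fx$fig5$es_share
#' @export
case_study_fixture <- function() {
  path <- system.file("extdata", "case_study.json", package = "weightscape")
  if (!nzchar(path)) ws_computation_error("bundled fixture not found")
  fx <- jsonlite::read_json(path, simplifyVector = TRUE)
  fx$table1$matrix <- comparison_matrix(
    apply(fx$table1$matrix, c(1, 2), parse_fraction),
    labels = fx$table1$labels)
  fx$dependency$matrix <- dependency_matrix(fx$dependency$matrix,
                                            labels = fx$dependency$labels)
  fx$hierarchy <- hierarchy_spec(
    children = lapply(fx$table2$locals, names),
    local = lapply(fx$table2$locals, unlist))
  structure(fx, class = "case_study_fixture")
}

#' Path to a bundled fixture file
#'
#' @param file file name under the package's `extdata/` (empty to list).
#' @return full path.
#' @export
fixture_path <- function(file = "") {
  system.file("extdata", file, package = "weightscape")
}

#' Export the bundled fixture files
#'
#' Copies every bundled fixture (case-study JSON, matrix CSVs, hierarchy and
#' pipeline configs, the synthetic stand-in supermatrix) into a directory.
#'
#' @param out_dir destination directory (created if needed).
#' @return invisibly, the copied file names.
#' @export
export_fixtures <- function(out_dir) {
  src <- system.file("extdata", package = "weightscape")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list.files(src, full.names = TRUE)
  ok <- file.copy(files, out_dir, overwrite = TRUE)
  if (!all(ok)) ws_computation_error("failed to copy fixture files")
  invisible(basename(files))
}
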