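# End-to-end orchestration: subjective weighting (comparison matrices ->
# priorities -> dependency adjustment -> global weights -> optional
# supermatrix), objective weighting (scores -> CRITIC), least-squares fusion,
# and RSR probit grading, with JSON/markdown reporting.

#' Run the full weighting pipeline
#'
#' Executes the four stages in order and returns a report bundle. The
#' configuration may be a list or a JSON/YAML file path with fields:
#'
#' * `hierarchy`: hierarchy config (path or list; see
#'   [load_hierarchy_config()]), including the criterion comparison matrix.
#' * `dependency`: CSV path or matrix of the criterion dependency matrix.
#' * `supermatrix` (optional): CSV path of a sub-criterion supermatrix;
#'   `supermatrix_raw = TRUE` flags an unnormalized one.
#' * exactly one of `scores` (CSV path or [score_matrix()]) or `synth`
#'   (a [survey_config()] or its fields) for the objective stage.
#' * `subjective_weights` / `objective_weights` (optional): inject fixed
#'   vectors (or `"case_study"` for the bundled printed values) instead of
#'   computing that stage; injected values are footnoted in the report.
#' * `alpha`, `beta`: fusion trust coefficients (default 1, 1).
#' * `probit_mode`: `"exact"` (default) or `"legacy_percent_table"`.
#' * `grade_thresholds`: probit cut-offs (default `c(4, 6)`).
#' * `strict_cr`: abort when a comparison matrix fails the consistency check.
#' * `seed`: RNG seed for the synthetic cohort.
#' * `out_dir` (optional): write per-stage JSON artifacts and a markdown
#'   report there.
#' * `deterministic`: suppress the timestamp in reports.
#'
#' @param config list or path.
#' @return report list of class `pipeline_report`.
#' @export
run_pipeline <- function(config) {
  base <- "."
  if (is.character(config) && length(config) == 1L) {
    base <- dirname(config)
    config <- read_config(config)
  }
  resolve <- function(p) {
    if (is.character(p) && length(p) == 1L && !file.exists(p) &&
        file.exists(file.path(base, p))) file.path(base, p) else p
  }
  has_scores <- !is.null(config$scores)
  has_synth <- !is.null(config$synth)
  injected_obj <- !is.null(config$objective_weights)
  if (has_scores + has_synth + injected_obj != 1L) {
    ws_validation_error(paste(
      "exactly one of 'scores', 'synth' or 'objective_weights' must be given",
      "for the objective stage"))
  }
  notes <- character(0)
  fx <- NULL
  need_fixture <- identical(config$subjective_weights, "case_study") ||
    identical(config$objective_weights, "case_study")
  if (need_fixture) fx <- case_study_fixture()

  ## --- subjective stage -------------------------------------------------
  hier_cfg <- load_hierarchy_config(resolve(config$hierarchy))
  hierarchy <- hier_cfg$hierarchy
  if (is.null(hier_cfg$criteria_matrix)) {
    ws_validation_error("hierarchy config must include 'criteria_matrix'")
  }
  pr <- principal_priority(hier_cfg$criteria_matrix)
  cons <- consistency(hier_cfg$criteria_matrix, pr,
                      strict = isTRUE(config$strict_cr))
  if (!cons$acceptable) {
    warning(sprintf("criterion matrix CR = %.4f >= 0.1; judgments are inconsistent",
                    cons$cr), call. = FALSE)
  }
  dep_in <- resolve(config$dependency)
  dep <- dependency_matrix(if (is.character(dep_in)) read_matrix_csv(dep_in) else dep_in)
  omega3 <- interdependent_weights(dep, pr$weights)
  omega_p <- global_subcriteria_weights(omega3, hierarchy)
  if (!is.null(config$subjective_weights)) {
    subjective <- if (identical(config$subjective_weights, "case_study")) {
      as_weight_vector(unlist(fx$omega_y$values), renormalize = TRUE)
    } else {
      as_weight_vector(unlist(config$subjective_weights), renormalize = TRUE)
    }
    notes <- c(notes, "subjective weights injected from fixture, not recomputed")
  } else if (!is.null(config$supermatrix)) {
    sm <- supermatrix(read_matrix_csv(resolve(config$supermatrix)),
                      raw = isTRUE(config$supermatrix_raw))
    subjective <- apply_supermatrix(sm, omega_p)
  } else {
    subjective <- omega_p
  }

  ## --- objective stage --------------------------------------------------
  critic_diag <- NULL
  cohort <- NULL
  if (injected_obj) {
    objective <- if (identical(config$objective_weights, "case_study")) {
      as_weight_vector(unlist(fx$omega_c$values), renormalize = TRUE)
    } else {
      as_weight_vector(unlist(config$objective_weights), renormalize = TRUE)
    }
    notes <- c(notes, "objective weights injected from fixture, not recomputed")
  } else {
    if (has_scores) {
      s <- config$scores
      scores <- if (is.character(s)) read_scores_csv(resolve(s)) else score_matrix(s)
    } else {
      cfg <- config$synth
      if (!inherits(cfg, "survey_config")) {
        cfg <- if (isTRUE(cfg$default) || identical(cfg, "default")) {
          calibrate_default_cohort(seed = config$seed %||% 1L)
        } else {
          do.call(survey_config, cfg[setdiff(names(cfg), "default")])
        }
      }
      responses <- generate_responses(cfg, seed = config$seed)
      kept <- filter_incomplete(responses, quiet = TRUE)
      cohort <- list(n_generated = nrow(responses), n_kept = nrow(kept),
                     n_removed = nrow(responses) - nrow(kept))
      scores <- score_responses(kept, cfg)
    }
    critic_diag <- critic(scores)
    objective <- critic_diag$weights
  }

  ## --- fusion -----------------------------------------------------------
  if (length(subjective) != length(objective)) {
    ws_validation_error(sprintf(
      "subjective (%d) and objective (%d) weight lengths differ",
      length(subjective), length(objective)))
  }
  if (is.null(names(objective))) names(objective) <- names(subjective)
  alpha <- config$alpha %||% 1
  beta <- config$beta %||% 1
  fused <- least_squares_combine(subjective, objective, alpha, beta)
  bundle <- weight_bundle(subjective, objective, fused)
  shares <- grouped_shares(fused, hierarchy)

  ## --- grading ----------------------------------------------------------
  mode <- config$probit_mode %||% "exact"
  rsr <- assign_grades(build_rsr_table(fused, mode = mode),
                       grade_scheme(config$grade_thresholds %||% c(4, 6)))

  report <- structure(list(
    consistency = cons,
    criterion_weights = pr$weights,
    interdependent_weights = omega3,
    global_weights = omega_p,
    subjective = subjective,
    objective = objective,
    critic = critic_diag,
    cohort = cohort,
    fused = fused,
    table = bundle,
    shares = shares,
    rsr = rsr,
    grades = grade_groups(rsr),
    notes = notes,
    timestamp = if (isTRUE(config$deterministic)) NULL else format(Sys.time())
  ), class = "pipeline_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write a pipeline report to disk
#'
#' Emits `report.json` (full precision) and `report.md` (weights at 4 dp,
#' percentages and probits at 2 dp) into `out_dir`.
#'
#' @param report a [run_pipeline()] result.
#' @param out_dir destination directory.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  json <- list(
    consistency = report$consistency[c("ci", "cr", "acceptable", "ri_used")],
    criterion_weights = as.list(report$criterion_weights),
    interdependent_weights = as.list(report$interdependent_weights),
    global_weights = as.list(report$global_weights),
    subjective = as.list(report$subjective),
    objective = as.list(report$objective),
    fused = as.list(report$fused),
    shares = as.list(report$shares),
    rsr = unclass(report$rsr),
    grades = report$grades,
    cohort = report$cohort,
    notes = report$notes,
    timestamp = report$timestamp
  )
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(report_markdown(report), file.path(out_dir, "report.md"))
  invisible(out_dir)
}

#' Render a pipeline report as markdown
#'
#' @param report a [run_pipeline()] result.
#' @return character vector of markdown lines.
#' @export
report_markdown <- function(report) {
  fmt_w <- function(x) sprintf("%.4f", x)
  lines <- c("# Indicator weighting report", "")
  if (!is.null(report$timestamp)) lines <- c(lines, paste("Generated:", report$timestamp), "")
  lines <- c(lines,
             sprintf("Criterion consistency: CR = %.4f (%s)",
                     report$consistency$cr,
                     if (report$consistency$acceptable) "acceptable" else "NOT acceptable"),
             "", "## Weights (descending by comprehensive weight)", "",
             "| Indicator | Subjective | Objective | Comprehensive |",
             "|---|---|---|---|")
  b <- report$table
  lines <- c(lines, sprintf("| %s | %s | %s | %s |", b$indicator,
                            fmt_w(b$subjective), fmt_w(b$objective),
                            fmt_w(b$comprehensive)))
  lines <- c(lines, "", "## Criterion shares", "",
             sprintf("- %s: %.2f%%", names(report$shares), report$shares),
             "", "## RSR grading", "",
             "| Indicator | RSR | R-bar | P (%) | Probit | Grade |",
             "|---|---|---|---|---|---|")
  r <- report$rsr
  lines <- c(lines, sprintf("| %s | %s | %.1f | %.2f | %.4f | %d |",
                            r$indicator, fmt_w(r$rsr), r$mean_rank, r$p, r$y,
                            r$grade))
  lines <- c(lines, "",
             sprintf("- Grade %d: %s", seq_along(report$grades),
                     vapply(report$grades, function(g)
                       if (length(g)) paste(g, collapse = ", ") else "(none)",
                       character(1))))
  if (length(report$notes)) {
    lines <- c(lines, "", "## Notes", "", paste0("- ", report$notes))
  }
  lines
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(report_markdown(x), sep = "\n")
  invisible(x)
}
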