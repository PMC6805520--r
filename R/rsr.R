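# Rank-sum-ratio (RSR) probit grading: indicators ranked by their fused
# weight (the weight itself serving as the RSR statistic), cumulative
# percentages converted to classical probits (inverse normal + 5), and
# half-open probit intervals mapped to importance grades.

#' Build the RSR distribution table
#'
#' Sorts indicators ascending by weight, assigns average ranks across ties,
#' converts the mean rank to a cumulative percentage `P_i = Rbar_i / m * 100`,
#' replaces the top entry's `P = 100` by the downward-adjusted
#' `P_m = (1 - 1/(4m)) * 100` (the inverse normal is unbounded at 1), and
#' transforms to the classical probit `Y = qnorm(P/100) + 5`.
#'
#' Two probit modes are exposed. `"exact"` evaluates the inverse normal at the
#' exact cumulative percentage. `"legacy_percent_table"` first truncates the
#' percentage to a whole percent (9.09% behaves as 9%), the behavior of the
#' coarse printed probit lookup tables used historically with this method;
#' published tables computed that way are reproduced bit-for-bit by this mode.
#'
#' @param w indicator weights (the RSR statistic), named.
#' @param mode `"exact"` (default) or `"legacy_percent_table"`.
#' @return `data.frame` of class `rsr_table`, rows in ascending rank order,
#'   with columns `indicator`, `rsr`, `f` (frequency of the value), `f_cum`
#'   (upward cumulative frequency), `rank`, `mean_rank`, `p` (cumulative
#'   percentage, after the top-entry adjustment), `p_adjusted` (logical),
#'   `y` (probit).
#' @examples
#' w <- c(a = 0.1, b = 0.3, c = 0.6)
#' build_rsr_table(w, mode = "legacy_percent_table")
#' @export
build_rsr_table <- function(w, mode = c("exact", "legacy_percent_table")) {
  mode <- match.arg(mode)
  w <- as_weight_vector(w, renormalize = TRUE)
  m <- length(w)
  if (m < 2L) ws_validation_error("RSR grading needs at least 2 indicators")
  labels <- names(w) %||% paste0("V", seq_len(m))
  ord <- order(as.numeric(w))
  vals <- as.numeric(w)[ord]
  labs <- labels[ord]
  f <- as.numeric(ave(vals, match(vals, unique(vals)), FUN = length))
  f_cum <- vapply(vals, function(v) sum(vals <= v), numeric(1))
  mean_rank <- rank(vals, ties.method = "average")
  p <- mean_rank / m * 100
  p_adjusted <- abs(p - 100) < 1e-9
  p[p_adjusted] <- (1 - 1 / (4 * m)) * 100
  if (any(p <= 0 | p >= 100)) {
    ws_computation_error("cumulative percentage outside (0, 100) after adjustment")
  }
  p_eff <- if (mode == "legacy_percent_table") trunc(p) else p
  y <- stats::qnorm(p_eff / 100) + 5
  structure(
    data.frame(indicator = labs, rsr = vals, f = f, f_cum = f_cum,
               rank = seq_len(m), mean_rank = mean_rank, p = p,
               p_adjusted = p_adjusted, y = y, stringsAsFactors = FALSE),
    mode = mode, m = m,
    class = c("rsr_table", "data.frame"))
}

#' Probit grade scheme
#'
#' Increasing probit thresholds defining half-open grade intervals: with
#' thresholds `(t1, ..., tk)`, grade 1 is `y < t1`, grade `g` is
#' `t_{g-1} <= y < t_g`, and grade `k+1` is `y >= tk`. The default
#' three-grade scheme uses thresholds 4 and 6, the standard critical probit
#' values for a three-level classification.
#'
#' @param thresholds strictly increasing numeric vector.
#' @export
grade_scheme <- function(thresholds = c(4, 6)) {
  if (length(thresholds) < 1L || is.unsorted(thresholds, strictly = TRUE)) {
    ws_validation_error("grade thresholds must be strictly increasing")
  }
  structure(list(thresholds = thresholds, n_grades = length(thresholds) + 1L),
            class = "grade_scheme")
}

#' Assign importance grades from probit values
#'
#' Cuts the probit column of an RSR table at the scheme's thresholds
#' (half-open on the right: a probit exactly at a threshold takes the higher
#' grade). Under the default scheme grade 3 marks high-sensitivity
#' indicators, grade 2 moderate, grade 1 low.
#'
#' @param table a [build_rsr_table()] result.
#' @param scheme a [grade_scheme()].
#' @return the `rsr_table` with an integer `grade` column appended.
#' @export
assign_grades <- function(table, scheme = grade_scheme()) {
  if (!inherits(table, "rsr_table")) {
    ws_validation_error("'table' must come from build_rsr_table()")
  }
  if (!inherits(scheme, "grade_scheme")) scheme <- grade_scheme(scheme)
  table$grade <- findInterval(table$y, scheme$thresholds) + 1L
  attr(table, "scheme") <- scheme
  table
}

#' Indicators grouped by grade
#'
#' @param table graded [assign_grades()] result.
#' @return named list `grade_1`, `grade_2`, ... of indicator name vectors
#'   (ascending weight order within each grade).
#' @export
grade_groups <- function(table) {
  if (is.null(table$grade)) ws_validation_error("table has no grades; run assign_grades()")
  scheme <- attr(table, "scheme") %||% grade_scheme()
  out <- lapply(seq_len(scheme$n_grades), function(g) {
    table$indicator[table$grade == g]
  })
  names(out) <- paste0("grade_", seq_len(scheme$n_grades))
  out
}
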