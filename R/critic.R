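# CRITIC objective weighting: min-max normalization to the ideal/anti-ideal,
# contrast intensity (sd of the normalized column), conflict (1 - Pearson r),
# information content C_j = sigma_j * sum_k (1 - r_jk), weights C_j / sum C.

#' Respondents-by-indicators score matrix
#'
#' Validates a numeric matrix of scores on the 0-10 scale: no missing cells
#' (incomplete questionnaires must be filtered upstream, see
#' [filter_incomplete()]), all values in `[0, 10]`, at least two indicators.
#'
#' @param x numeric matrix or data frame (respondents in rows).
#' @param respondent_ids,indicator_labels optional dimnames.
#' @return a numeric matrix of class `score_matrix`.
#' @export
score_matrix <- function(x, respondent_ids = NULL, indicator_labels = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x)) {
    ws_validation_error(paste(
      "score matrix contains missing cells; remove incomplete questionnaires",
      "first (filter_incomplete)"))
  }
  if (ncol(x) < 2L) ws_validation_error("need at least 2 indicators to weight")
  if (nrow(x) < 2L) ws_validation_error("need at least 2 respondents")
  if (any(x < 0) || any(x > 10)) {
    ws_validation_error("scores must lie on the 0-10 scale")
  }
  rownames(x) <- respondent_ids %||% rownames(x) %||% paste0("R", seq_len(nrow(x)))
  colnames(x) <- indicator_labels %||% colnames(x) %||% paste0("V", seq_len(ncol(x)))
  structure(x, class = c("score_matrix", "matrix"))
}

#' Min-max normalize scores against ideal and anti-ideal values
#'
#' Each indicator column is rescaled as
#' `x_aj = (f_j(a) - f_min_j) / (f_max_j - f_min_j)` so 1 marks the best
#' observed performance (the ideal) and 0 the worst (the anti-ideal). All
#' indicators are benefit-type by default; `direction = -1` for an indicator
#' swaps ideal and anti-ideal (cost-type). A constant column carries no
#' contrast: it maps to all zeros and is flagged.
#'
#' @param scores a [score_matrix()] (or coercible).
#' @param direction per-indicator `+1` (benefit) or `-1` (cost); recycled.
#' @return matrix of class `normalized_scores` with attributes `ideal`,
#'   `anti_ideal`, `constant` (logical per column), `direction`.
#' @export
normalize_scores <- function(scores, direction = 1) {
  if (!inherits(scores, "score_matrix")) scores <- score_matrix(scores)
  x <- unclass(scores)
  m <- ncol(x)
  direction <- rep_len(direction, m)
  if (!all(direction %in% c(-1, 1))) {
    ws_validation_error("direction must be +1 (benefit) or -1 (cost) per indicator")
  }
  hi <- apply(x, 2, max)
  lo <- apply(x, 2, min)
  ideal <- ifelse(direction > 0, hi, lo)
  anti <- ifelse(direction > 0, lo, hi)
  constant <- abs(hi - lo) < .Machine$double.eps^0.5
  out <- x
  for (j in seq_len(m)) {
    out[, j] <- if (constant[j]) 0 else (x[, j] - anti[j]) / (ideal[j] - anti[j])
  }
  if (any(constant)) {
    warning(sprintf("constant indicator column(s) mapped to zero: %s",
                    paste(colnames(x)[constant], collapse = ", ")),
            call. = FALSE)
  }
  structure(out, ideal = ideal, anti_ideal = anti, constant = constant,
            direction = direction,
            class = c("normalized_scores", "matrix"))
}

#' Contrast intensity and conflict of normalized indicators
#'
#' Contrast intensity is the standard deviation of each normalized column;
#' conflict between two indicators is measured through their Pearson
#' correlation `r_jk`. Two element-wise identical columns are assigned
#' `r = 0` by convention (identical indicators carry no *mutual* information
#' about disagreement, and the undefined constant-column case folds into the
#' same rule); a constant column paired with anything also yields 0.
#'
#' @param norm a [normalize_scores()] result.
#' @param sd_method `"sample"` (divide by n-1, default) or `"population"`.
#' @param cor_method `"pearson"` (default) or `"spearman"` (sensitivity
#'   analysis only).
#' @return object of class `critic_diagnostics`: list with `sigma`,
#'   `conflict`, `info` (NULL until [information_content()]), `weights`
#'   (NULL until [critic_weights()]), `labels`, `n`.
#' @export
contrast_and_conflict <- function(norm, sd_method = c("sample", "population"),
                                  cor_method = c("pearson", "spearman")) {
  if (!inherits(norm, "normalized_scores")) {
    ws_validation_error("'norm' must come from normalize_scores()")
  }
  sd_method <- match.arg(sd_method)
  cor_method <- match.arg(cor_method)
  x <- unclass(norm)
  n <- nrow(x)
  m <- ncol(x)
  sigma <- apply(x, 2, stats::sd)
  if (sd_method == "population") sigma <- sigma * sqrt((n - 1) / n)
  constant <- apply(x, 2, function(col) abs(max(col) - min(col)) < .Machine$double.eps^0.5)
  r <- suppressWarnings(stats::cor(x, method = cor_method))
  for (j in seq_len(m)) {
    for (k in seq_len(m)) {
      identical_cols <- isTRUE(all.equal(x[, j], x[, k], tolerance = 1e-12,
                                         check.attributes = FALSE))
      if ((j != k && identical_cols) || constant[j] || constant[k]) {
        r[j, k] <- 0
      }
    }
  }
  diag(r)[!constant] <- 1
  structure(list(sigma = stats::setNames(sigma, colnames(x)),
                 conflict = r, info = NULL, weights = NULL,
                 labels = colnames(x), n = n,
                 sd_method = sd_method, cor_method = cor_method),
            class = "critic_diagnostics")
}

#' Information content of each indicator
#'
#' `C_j = sigma_j * sum_k (1 - r_jk)`: an indicator is informative when it has
#' high contrast (spread across respondents) and low redundancy with the other
#' indicators. The `k = j` term contributes 0 for a non-constant column since
#' `r_jj = 1`.
#'
#' @param diag a [contrast_and_conflict()] result.
#' @return the same `critic_diagnostics` with `info` filled.
#' @export
information_content <- function(diag) {
  if (!inherits(diag, "critic_diagnostics") || is.null(diag$sigma)) {
    ws_validation_error("'diag' must come from contrast_and_conflict()")
  }
  diag$info <- stats::setNames(
    diag$sigma * rowSums(1 - diag$conflict), diag$labels)
  diag
}

#' CRITIC weights from information content
#'
#' Normalizes the information-content vector to unity: `w_j = C_j / sum(C)`.
#'
#' @param diag a [information_content()] result.
#' @return the same `critic_diagnostics` with `weights` filled
#'   (a `weight_vector`).
#' @export
critic_weights <- function(diag) {
  if (!inherits(diag, "critic_diagnostics") || is.null(diag$info)) {
    ws_validation_error("'diag' must have information content; run information_content()")
  }
  if (all(diag$info <= 0)) {
    ws_degenerate_error(paste(
      "all information contents are zero (constant or perfectly redundant",
      "indicators); objective weights are undefined"))
  }
  diag$weights <- as_weight_vector(diag$info, labels = diag$labels,
                                   renormalize = TRUE)
  diag
}

#' Full CRITIC pipeline
#'
#' Convenience wrapper: normalize, contrast/conflict, information content,
#' weights.
#'
#' @inheritParams normalize_scores
#' @inheritParams contrast_and_conflict
#' @return a completed `critic_diagnostics`.
#' @examples
#' set.seed(1)
#' s <- score_matrix(matrix(runif(60, 0, 10), 20, 3))
#' critic(s)$weights
#' @export
critic <- function(scores, direction = 1,
                   sd_method = c("sample", "population"),
                   cor_method = c("pearson", "spearman")) {
  norm <- normalize_scores(scores, direction = direction)
  diag <- contrast_and_conflict(norm, sd_method = match.arg(sd_method),
                                cor_method = match.arg(cor_method))
  critic_weights(information_content(diag))
}

#' @export
print.critic_diagnostics <- function(x, digits = 4, ...) {
  cat(sprintf("<critic_diagnostics> %d indicators, n = %d respondents\n",
              length(x$labels), x$n))
  cat("sigma:", round(x$sigma, digits), "\n")
  if (!is.null(x$info)) cat("C:    ", round(x$info, digits), "\n")
  if (!is.null(x$weights)) cat("w:    ", round(x$weights, digits), "\n")
  invisible(x)
}
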