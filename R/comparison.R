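#' Pairwise-comparison matrices on the Saaty scale
#'
#' A comparison matrix holds the relative-importance judgments `a_ij` of a
#' panel comparing every pair of elements: `a_ij` is how many times more
#' important element `i` is than element `j` on the 1-9 intensity scale, the
#' inverse comparison carries the reciprocal value, and the diagonal is 1
#' (each element against itself).
#'
#' @param x square numeric matrix of positive judgments.
#' @param labels optional element names; defaults to `rownames(x)` or
#'   `X1..Xn`.
#' @param tol reciprocity tolerance: `a_ij * a_ji` must equal 1 within `tol`.
#' @return a matrix of class `comparison_matrix` with dimnames set.
#' @examples
#' comparison_matrix(rbind(c(1, 3, 2), c(1/3, 1, 1/2), c(1/2, 2, 1)),
#'                   labels = c("ES", "IS", "TS"))
#' @seealso [principal_priority()], [consistency()]
#' @export
comparison_matrix <- function(x, labels = NULL, tol = 1e-6) {
  x <- as.matrix(x)
  if (!is.numeric(x) || nrow(x) != ncol(x) || nrow(x) < 2L) {
    ws_validation_error("a comparison matrix must be a square numeric matrix with n >= 2")
  }
  labels <- labels %||% rownames(x) %||% paste0("X", seq_len(nrow(x)))
  dimnames(x) <- list(labels, labels)
  validate_comparison_matrix(structure(x, class = c("comparison_matrix", "matrix")),
                             tol = tol)
}

#' Validate a pairwise-comparison matrix
#'
#' Checks positivity, a unit diagonal, and reciprocity (`a_ij * a_ji = 1`).
#' Returns the matrix unchanged when valid; raises a validation error naming
#' the first offending cell otherwise.
#'
#' @param m matrix (coerced to `comparison_matrix` on success).
#' @param tol reciprocity/diagonal tolerance.
#' @export
validate_comparison_matrix <- function(m, tol = 1e-6) {
  x <- unclass(as.matrix(m))
  n <- nrow(x)
  if (anyNA(x)) ws_validation_error("comparison matrix contains missing cells")
  bad <- which(x <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    ws_validation_error(sprintf(
      "comparison matrix entry [%d, %d] = %g is not positive",
      bad[1, 1], bad[1, 2], x[bad[1, 1], bad[1, 2]]))
  }
  if (any(abs(diag(x) - 1) > tol)) {
    i <- which(abs(diag(x) - 1) > tol)[1]
    ws_validation_error(sprintf("diagonal entry [%d, %d] = %g; must be 1", i, i, x[i, i]))
  }
  recip <- x * t(x)
  bad <- which(abs(recip - 1) > tol, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    ws_validation_error(sprintf(
      "reciprocity violated at [%d, %d]: a_ij = %g but a_ji = %g (a_ji should be %g)",
      i, j, x[i, j], x[j, i], 1 / x[i, j]))
  }
  if (!inherits(m, "comparison_matrix")) {
    m <- structure(x, class = c("comparison_matrix", "matrix"))
  }
  m
}

#' Parse matrix cells that may be fractions
#'
#' Saaty-scale judgments are conventionally written as fractions ("1/3"); this
#' parses them exactly as rationals before float conversion, so `"1/3"`
#' becomes `1/3` and not a decimal approximation typed by hand.
#'
#' @param x character or numeric vector.
#' @return numeric vector.
#' @keywords internal
parse_fraction <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(x))
  frac <- is.na(out) & grepl("^-?[0-9.]+\\s*/\\s*[0-9.]+$", x)
  if (any(frac)) {
    parts <- strsplit(x[frac], "/", fixed = TRUE)
    out[frac] <- vapply(parts, function(p) {
      as.numeric(p[1]) / as.numeric(p[2])
    }, numeric(1))
  }
  if (anyNA(out) && !anyNA(x)) {
    ws_validation_error(sprintf("cannot parse matrix cell '%s' as a number or fraction",
                                x[which(is.na(out))[1]]))
  }
  out
}
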