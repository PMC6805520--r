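#' Weight vectors on the unit simplex
#'
#' A weight vector is a named, nonnegative numeric vector summing to one.
#' `as_weight_vector()` validates (and optionally renormalizes) a numeric
#' vector; most weightscape functions accept plain numerics and coerce through
#' this helper.
#'
#' @param x numeric vector, possibly named.
#' @param labels optional character vector of names; overrides `names(x)`.
#' @param renormalize if `TRUE`, divide by the sum instead of insisting the
#'   input already sums to one.
#' @param tol tolerance on the simplex constraint.
#' @return a named numeric vector of class `weight_vector`.
#' @examples
#' as_weight_vector(c(ES = 0.5396, IS = 0.1634, TS = 0.2970))
#' @export
as_weight_vector <- function(x, labels = NULL, renormalize = FALSE,
                             tol = 1e-6) {
  if (!is.numeric(x) || length(x) < 1L) {
    ws_validation_error("a weight vector must be a numeric vector of length >= 1")
  }
  x <- as.numeric(x) |> stats::setNames(labels %||% names(x))
  if (anyNA(x)) ws_validation_error("weight vector contains missing values")
  if (any(x < -tol)) {
    ws_validation_error(sprintf(
      "weight vector has negative component(s): min = %.3g", min(x)))
  }
  x[x < 0] <- 0
  s <- sum(x)
  if (renormalize) {
    if (s <= 0) ws_degenerate_error("weight vector sums to zero; cannot renormalize")
    x <- x / s
  } else if (abs(s - 1) > tol) {
    ws_validation_error(sprintf(
      "weight vector must sum to 1 (got %.8f); pass renormalize = TRUE to rescale", s))
  }
  structure(x, class = c("weight_vector", "numeric"))
}

#' @export
print.weight_vector <- function(x, digits = 4, ...) {
  cat("<weight_vector>", length(x), "components\n")
  print(round(unclass(x), digits), ...)
  invisible(x)
}

is_simplex <- function(x, tol = 1e-9) {
  all(x >= -tol) && abs(sum(x) - 1) <= tol
}

`%||%` <- function(a, b) if (is.null(a)) b else a
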