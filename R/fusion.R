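# Least-squares fusion of a subjective and an objective weight vector, and
# aggregation of fused weights to criterion-level shares.

# Equality-constrained QP: minimize sum_j alpha (w_j - u_j)^2 + beta (w_j - v_j)^2
# subject to sum(w) = 1, via the KKT system. Nonnegativity handled by an
# active-set pass: components forced negative are pinned to zero and the
# reduced system re-solved.
solve_fusion_qp <- function(u, v, alpha, beta) {
  m <- length(u)
  free <- rep(TRUE, m)
  w <- rep(NA_real_, m)
  repeat {
    k <- sum(free)
    if (k == 0L) ws_computation_error("fusion QP has no feasible free components")
    # KKT for the free block: 2(alpha+beta) w_f + lambda 1 = 2(alpha u_f + beta v_f)
    H <- diag(2 * (alpha + beta), k)
    A <- rbind(cbind(H, 1), c(rep(1, k), 0))
    b <- c(2 * (alpha * u[free] + beta * v[free]), 1)
    sol <- solve(A, b)
    w_free <- sol[seq_len(k)]
    if (all(w_free >= -1e-12)) {
      w[free] <- pmax(w_free, 0)
      w[!free] <- 0
      return(w)
    }
    idx <- which(free)
    free[idx[which.min(w_free)]] <- FALSE
  }
}

#' Fuse subjective and objective weights by constrained least squares
#'
#' Finds the comprehensive weight vector `W` minimizing the summed squared
#' deviations from the subjective vector `U` and the objective vector `V`,
#' `sum_j alpha (w_j - u_j)^2 + beta (w_j - v_j)^2`, subject to `sum(W) = 1`
#' and `W >= 0`. Under equal trust (`alpha = beta`) with simplex inputs the
#' optimum is the plain average `(U + V) / 2`, which already satisfies both
#' constraints; unequal trust coefficients generalize to the convex
#' combination `(alpha U + beta V) / (alpha + beta)`. The solver is the
#' general equality-constrained quadratic program (KKT solve), so the closed
#' form is recovered rather than assumed.
#'
#' @param u subjective weights (e.g. network-process output).
#' @param v objective weights (e.g. CRITIC output), same length and labels.
#' @param alpha,beta nonnegative trust coefficients (default equal trust).
#' @return a `weight_vector` of comprehensive weights.
#' @examples
#' least_squares_combine(c(a = 0.7, b = 0.3), c(a = 0.5, b = 0.5))
#' @export
least_squares_combine <- function(u, v, alpha = 1, beta = 1) {
  u <- as_weight_vector(u)
  v <- as_weight_vector(v)
  if (length(u) != length(v)) {
    ws_validation_error(sprintf(
      "length mismatch: subjective has %d components, objective %d",
      length(u), length(v)))
  }
  if (!is.null(names(u)) && !is.null(names(v)) && !identical(names(u), names(v))) {
    ws_validation_error("subjective and objective vectors must share label order")
  }
  if (alpha < 0 || beta < 0 || alpha + beta <= 0) {
    ws_validation_error("trust coefficients must be nonnegative with alpha + beta > 0")
  }
  w <- solve_fusion_qp(as.numeric(u), as.numeric(v), alpha, beta)
  as_weight_vector(w, labels = names(u) %||% names(v), renormalize = TRUE)
}

#' Criterion-level shares of sub-criterion weights
#'
#' Sums fused sub-criterion weights within each parent criterion and reports
#' the result as percentages (summing to 100).
#'
#' @param w sub-criterion weights named by sub-criterion.
#' @param hierarchy a [hierarchy_spec()] with the parent mapping.
#' @return named numeric vector of percentages, one per criterion.
#' @export
grouped_shares <- function(w, hierarchy) {
  if (!inherits(hierarchy, "hierarchy_spec")) {
    ws_validation_error("'hierarchy' must be a hierarchy_spec")
  }
  w <- as_weight_vector(w)
  if (is.null(names(w))) {
    if (length(w) != length(hierarchy$subcriteria)) {
      ws_validation_error("unnamed weights must match the hierarchy's sub-criterion count")
    }
    names(w) <- hierarchy$subcriteria
  }
  missing <- setdiff(hierarchy$subcriteria, names(w))
  if (length(missing) > 0) {
    ws_validation_error(paste0("weights missing for sub-criteria: ",
                               paste(missing, collapse = ", ")))
  }
  shares <- vapply(hierarchy$criteria, function(cr) {
    sum(w[hierarchy$children[[cr]]]) * 100
  }, numeric(1))
  shares
}

#' Assemble a weight bundle table
#'
#' Binds subjective, objective and comprehensive weights into a single table
#' sorted descending by comprehensive weight (the presentation convention for
#' fused rankings).
#'
#' @inheritParams least_squares_combine
#' @param comprehensive optional precomputed fusion; computed if missing.
#' @return `data.frame` with columns `indicator`, `subjective`, `objective`,
#'   `comprehensive`, sorted descending by `comprehensive`.
#' @export
weight_bundle <- function(u, v, comprehensive = NULL, alpha = 1, beta = 1) {
  u <- as_weight_vector(u)
  v <- as_weight_vector(v)
  comprehensive <- comprehensive %||% least_squares_combine(u, v, alpha, beta)
  labels <- names(u) %||% names(v) %||% paste0("V", seq_along(u))
  out <- data.frame(indicator = labels,
                    subjective = as.numeric(u),
                    objective = as.numeric(v),
                    comprehensive = as.numeric(comprehensive),
                    stringsAsFactors = FALSE)
  out[order(-out$comprehensive), , drop = FALSE]
}
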