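# Analytic network process: principal-eigenvector priorities, consistency
# checking, dependency-adjusted criterion weights, global sub-criterion
# weights, and supermatrix synthesis.

# Saaty's mean random consistency index by matrix order.
RI_TABLE <- c(`1` = 0, `2` = 0, `3` = 0.58, `4` = 0.90, `5` = 1.12,
              `6` = 1.24, `7` = 1.32, `8` = 1.41, `9` = 1.45,
              `10` = 1.49, `11` = 1.51)

#' Principal priority vector of a comparison matrix
#'
#' Derives local priorities by solving `A w = lambda_max w`: the normalized
#' principal eigenvector of the positive reciprocal matrix is the weight
#' vector, and the dominant eigenvalue feeds the consistency check. The
#' default solver is power iteration (Perron-Frobenius guarantees a simple
#' dominant eigenvalue with a positive eigenvector for positive matrices);
#' `method = "geometric"` offers the classical geometric-mean-of-rows
#' approximation as a cross-check, with `lambda_max` then estimated as the
#' mean Rayleigh ratio `(A w)_i / w_i`.
#'
#' @param m a [comparison_matrix()].
#' @param method `"power"` (default) or `"geometric"`.
#' @param tol convergence tolerance of the power iteration.
#' @param max_iter iteration cap; exceeding it raises a computation error.
#' @return object of class `priority_result`: list with `weights` (a
#'   [as_weight_vector()]), `lambda_max`, `n`, `method`.
#' @examples
#' m <- comparison_matrix(rbind(c(1, 3, 2), c(1/3, 1, 1/2), c(1/2, 2, 1)),
#'                        labels = c("ES", "IS", "TS"))
#' principal_priority(m)
#' @export
principal_priority <- function(m, method = c("power", "geometric"),
                               tol = 1e-12, max_iter = 10000L) {
  m <- validate_comparison_matrix(m)
  method <- match.arg(method)
  A <- unclass(as.matrix(m))
  n <- nrow(A)
  if (method == "geometric") {
    w <- apply(A, 1, function(r) exp(mean(log(r))))
    w <- w / sum(w)
  } else {
    w <- rep(1 / n, n)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      w_new <- as.numeric(A %*% w)
      w_new <- w_new / sum(w_new)
      if (max(abs(w_new - w)) < tol) {
        w <- w_new
        converged <- TRUE
        break
      }
      w <- w_new
    }
    if (!converged) {
      ws_computation_error(sprintf(
        "power iteration did not converge in %d iterations (tol %g)", max_iter, tol))
    }
  }
  lambda_max <- mean(as.numeric(A %*% w) / w)
  structure(
    list(weights = as_weight_vector(w, labels = rownames(A), renormalize = TRUE),
         lambda_max = lambda_max, n = n, method = method),
    class = "priority_result")
}

#' @export
print.priority_result <- function(x, ...) {
  cat(sprintf("<priority_result> n = %d, lambda_max = %.6f (%s)\n",
              x$n, x$lambda_max, x$method))
  print(x$weights, ...)
  invisible(x)
}

#' Consistency index and ratio of a comparison matrix
#'
#' `CI = (lambda_max - n) / (n - 1)` and `CR = CI / RI(n)`, where `RI` is the
#' mean random consistency index for matrices of order `n`. A matrix is
#' conventionally acceptable when `CR < 0.1`; 1x1 and 2x2 matrices are always
#' consistent (`CR = 0`). By default an inconsistent matrix only flags
#' `acceptable = FALSE` (a library cannot re-elicit judgments); `strict = TRUE`
#' turns that into an error.
#'
#' @param m a [comparison_matrix()].
#' @param result optional precomputed [principal_priority()] result.
#' @param strict error (rather than record) when `CR >= 0.1`.
#' @return object of class `consistency_report`: list with `ci`, `cr`,
#'   `acceptable`, `ri_used`, `lambda_max`, `n`.
#' @export
consistency <- function(m, result = NULL, strict = FALSE) {
  result <- result %||% principal_priority(m)
  n <- result$n
  if (n > length(RI_TABLE)) {
    ws_validation_error(sprintf(
      "no random-index value for n = %d (table covers n <= %d)", n, length(RI_TABLE)))
  }
  ri <- RI_TABLE[[as.character(n)]]
  if (n <= 2) {
    ci <- 0
    cr <- 0
  } else {
    ci <- (result$lambda_max - n) / (n - 1)
    cr <- ci / ri
  }
  acceptable <- cr < 0.1
  if (strict && !acceptable) {
    ws_validation_error(sprintf(
      "consistency ratio %.4f >= 0.1; judgments should be re-elicited", cr))
  }
  structure(list(ci = ci, cr = cr, acceptable = acceptable, ri_used = ri,
                 lambda_max = result$lambda_max, n = n),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("<consistency_report> CI = %.4f, CR = %.4f (RI = %.2f) -> %s\n",
              x$ci, x$cr, x$ri_used,
              if (x$acceptable) "acceptable" else "NOT acceptable"))
  invisible(x)
}

#' Dependency matrix among criteria
#'
#' Encodes how much each criterion's priority is redistributed to the others
#' when interdependence is acknowledged: column `j` holds the relative
#' influence of the other criteria on criterion `j`, so each column sums to 1
#' and the diagonal is 0.
#'
#' @param x square nonnegative matrix with zero diagonal, column sums 1.
#' @param labels criterion names.
#' @param tol tolerance on the column-sum and diagonal constraints.
#' @export
dependency_matrix <- function(x, labels = NULL, tol = 1e-6) {
  x <- as.matrix(x)
  if (nrow(x) != ncol(x)) ws_validation_error("dependency matrix must be square")
  labels <- labels %||% rownames(x) %||% paste0("C", seq_len(nrow(x)))
  dimnames(x) <- list(labels, labels)
  if (any(x < -tol)) ws_validation_error("dependency matrix has negative entries")
  if (any(abs(diag(x)) > tol)) {
    ws_validation_error("dependency matrix must have a zero diagonal")
  }
  cs <- colSums(x)
  if (any(abs(cs - 1) > tol)) {
    j <- which(abs(cs - 1) > tol)[1]
    ws_validation_error(sprintf(
      "dependency matrix column %d ('%s') sums to %.6f; must sum to 1",
      j, labels[j], cs[j]))
  }
  structure(x, class = c("dependency_matrix", "matrix"))
}

#' Interdependence-adjusted criterion weights
#'
#' Multiplies the dependency matrix by the base priority vector: the result is
#' the criterion weighting after feedback among criteria is taken into
#' account. Column-stochasticity of the dependency matrix guarantees the
#' output stays on the simplex.
#'
#' @param dep a [dependency_matrix()].
#' @param base criterion weights (coerced by [as_weight_vector()]).
#' @return a `weight_vector`.
#' @examples
#' dep <- dependency_matrix(rbind(c(0, .25, .25), c(.5, 0, .75), c(.5, .75, 0)),
#'                          labels = c("ES", "IS", "TS"))
#' interdependent_weights(dep, c(ES = 0.5396, IS = 0.1634, TS = 0.2970))
#' @export
interdependent_weights <- function(dep, base) {
  dep <- dependency_matrix(dep)
  base <- as_weight_vector(base)
  if (length(base) != nrow(dep)) {
    ws_validation_error(sprintf(
      "dimension mismatch: dependency matrix is %dx%d but base vector has length %d",
      nrow(dep), ncol(dep), length(base)))
  }
  out <- as.numeric(unclass(dep) %*% as.numeric(base))
  as_weight_vector(out, labels = rownames(dep), renormalize = TRUE)
}

#' Criteria hierarchy with local sub-criterion priorities
#'
#' Describes the two-level structure: ordered criteria, each with an ordered
#' group of sub-criteria and a local priority vector over them. Local
#' priorities may be given directly (e.g. printed values) or as
#' [comparison_matrix()] objects, which are resolved through
#' [principal_priority()].
#'
#' @param children named list: criterion -> character vector of sub-criterion
#'   names (order defines the global ordering).
#' @param local named list: criterion -> local weight vector over its
#'   sub-criteria, or a `comparison_matrix` of the sub-criteria.
#' @return object of class `hierarchy_spec`.
#' @export
hierarchy_spec <- function(children, local = NULL) {
  if (!is.list(children) || is.null(names(children)) ||
      any(!nzchar(names(children)))) {
    ws_validation_error("'children' must be a named list of sub-criterion name vectors")
  }
  subs <- unlist(children, use.names = FALSE)
  if (anyDuplicated(subs)) {
    ws_validation_error("every sub-criterion must have exactly one parent")
  }
  if (any(lengths(children) < 1L)) {
    ws_validation_error("each criterion needs at least one sub-criterion")
  }
  local_w <- NULL
  if (!is.null(local)) {
    missing <- setdiff(names(children), names(local))
    if (length(missing) > 0) {
      ws_validation_error(paste0("missing local priorities for criterion: ",
                                 paste(missing, collapse = ", ")))
    }
    local_w <- lapply(names(children), function(cr) {
      lw <- local[[cr]]
      if (inherits(lw, "comparison_matrix") || (is.matrix(lw) && nrow(lw) > 1)) {
        lw <- principal_priority(comparison_matrix(lw))$weights
      }
      if (abs(sum(lw) - 1) > 1e-2) {
        ws_validation_error(sprintf(
          "local priorities for '%s' sum to %.4f; not a weight vector", cr, sum(lw)))
      }
      # printed priorities are rounded (e.g. to 4 dp); renormalize exactly
      lw <- as_weight_vector(as.numeric(lw), labels = children[[cr]],
                             renormalize = TRUE)
      if (length(lw) != length(children[[cr]])) {
        ws_validation_error(sprintf(
          "local priorities for '%s' have length %d; expected %d",
          cr, length(lw), length(children[[cr]])))
      }
      lw
    })
    names(local_w) <- names(children)
  }
  structure(list(criteria = names(children), children = children,
                 subcriteria = subs, local = local_w),
            class = "hierarchy_spec")
}

#' Global sub-criterion weights under the overall goal
#'
#' Multiplies each sub-criterion's local priority by its parent criterion's
#' weight; the result is ordered by the hierarchy's sub-criterion order and
#' lies on the simplex.
#'
#' @param criteria criterion weights named (or ordered) as in the hierarchy.
#' @param hierarchy a [hierarchy_spec()] carrying local priorities.
#' @return a `weight_vector` over the sub-criteria.
#' @export
global_subcriteria_weights <- function(criteria, hierarchy) {
  if (!inherits(hierarchy, "hierarchy_spec")) {
    ws_validation_error("'hierarchy' must be a hierarchy_spec")
  }
  if (is.null(hierarchy$local)) {
    ws_validation_error("hierarchy has no local priority vectors")
  }
  criteria <- as_weight_vector(criteria)
  if (length(criteria) != length(hierarchy$criteria)) {
    ws_validation_error("criterion weight vector length does not match the hierarchy")
  }
  if (is.null(names(criteria))) names(criteria) <- hierarchy$criteria
  out <- unlist(lapply(hierarchy$criteria, function(cr) {
    unclass(hierarchy$local[[cr]]) * criteria[[cr]]
  }))
  as_weight_vector(out, labels = hierarchy$subcriteria, renormalize = TRUE)
}

#' Supermatrix over the sub-criteria
#'
#' The (unweighted) supermatrix collects the relative-importance vectors of
#' the sub-criteria with respect to each sub-criterion as its columns. It is
#' expected column-stochastic; pass `raw = TRUE` for an unnormalized matrix,
#' in which case products are renormalized back to the simplex.
#'
#' @param x square nonnegative matrix.
#' @param labels sub-criterion names.
#' @param raw flag an unnormalized matrix (skips the column-sum check).
#' @param tol column-stochasticity tolerance.
#' @export
supermatrix <- function(x, labels = NULL, raw = FALSE, tol = 1e-6) {
  x <- as.matrix(x)
  if (nrow(x) != ncol(x)) ws_validation_error("supermatrix must be square")
  labels <- labels %||% rownames(x) %||% paste0("S", seq_len(nrow(x)))
  dimnames(x) <- list(labels, labels)
  if (any(x < -tol)) ws_validation_error("supermatrix has negative entries")
  if (!raw) {
    cs <- colSums(x)
    if (any(abs(cs - 1) > tol)) {
      ws_validation_error(sprintf(
        "supermatrix column '%s' sums to %.6f; must be column-stochastic (or pass raw = TRUE)",
        labels[which(abs(cs - 1) > tol)[1]], cs[which(abs(cs - 1) > tol)[1]]))
    }
  }
  structure(x, raw = raw, class = c("supermatrix", "matrix"))
}

#' Apply a supermatrix to global weights
#'
#' Synthesizes interdependence among sub-criteria as a single multiplication
#' of the supermatrix with the global weight vector (the default here, since a
#' one-step product is what a dependency-adjusted hierarchy prescribes);
#' `limit = TRUE` instead powers the column-stochastic supermatrix to its
#' limit before multiplying, the classical limit-supermatrix variant.
#'
#' @param super a [supermatrix()].
#' @param global_weights sub-criterion weights matching the supermatrix.
#' @param limit use the limit (repeatedly powered) supermatrix.
#' @param tol,max_iter convergence controls for `limit` mode.
#' @return a `weight_vector`.
#' @export
apply_supermatrix <- function(super, global_weights, limit = FALSE,
                              tol = 1e-12, max_iter = 10000L) {
  if (!inherits(super, "supermatrix")) super <- supermatrix(super)
  w <- as_weight_vector(global_weights)
  if (length(w) != nrow(super)) {
    ws_validation_error(sprintf(
      "dimension mismatch: supermatrix is %dx%d but weights have length %d",
      nrow(super), ncol(super), length(w)))
  }
  S <- unclass(as.matrix(super))
  out <- as.numeric(S %*% as.numeric(w))
  if (limit) {
    for (it in seq_len(max_iter)) {
      nxt <- as.numeric(S %*% out)
      if (sum(nxt) > 0) nxt <- nxt / sum(nxt)
      if (max(abs(nxt - out / sum(out))) < tol) {
        out <- nxt
        break
      }
      out <- nxt
      if (it == max_iter) {
        ws_computation_error("limit supermatrix iteration did not converge")
      }
    }
  }
  as_weight_vector(out, labels = rownames(S), renormalize = TRUE)
}
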