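# Independent oracles and random-case generators. Each oracle is a naive
# transliteration kept deliberately separate from the implementation paths it
# checks.

# Dense full-spectrum eigen oracle for the principal priority vector.
oracle_principal <- function(A) {
  e <- eigen(A)
  i <- which.max(Re(e$values))
  w <- Re(e$vectors[, i])
  w <- w / sum(w)
  list(weights = w, lambda_max = Re(e$values[i]))
}

# Naive loop transliteration of the CRITIC chain (min-max normalize, sample
# sd, Pearson r with the identical-column convention, C_j, normalize).
oracle_critic <- function(X) {
  n <- nrow(X); m <- ncol(X)
  S <- matrix(0, n, m)
  for (j in 1:m) {
    lo <- min(X[, j]); hi <- max(X[, j])
    if (hi > lo) S[, j] <- (X[, j] - lo) / (hi - lo)
  }
  sigma <- numeric(m)
  for (j in 1:m) {
    mu <- mean(S[, j])
    sigma[j] <- sqrt(sum((S[, j] - mu)^2) / (n - 1))
  }
  r <- matrix(0, m, m)
  for (j in 1:m) for (k in 1:m) {
    if (all(abs(S[, j] - S[, k]) < 1e-12) && j != k) {
      r[j, k] <- 0
    } else if (sigma[j] == 0 || sigma[k] == 0) {
      r[j, k] <- 0
    } else {
      num <- sum((S[, j] - mean(S[, j])) * (S[, k] - mean(S[, k])))
      den <- sqrt(sum((S[, j] - mean(S[, j]))^2) * sum((S[, k] - mean(S[, k]))^2))
      r[j, k] <- num / den
    }
  }
  C <- numeric(m)
  for (j in 1:m) C[j] <- sigma[j] * sum(1 - r[j, ])
  list(sigma = sigma, r = r, C = C, weights = C / sum(C))
}

# KKT oracle for min alpha||w-u||^2 + beta||w-v||^2 s.t. sum(w) = 1 (equality
# constraint only; valid whenever the unconstrained-in-sign optimum is
# nonnegative, which holds for simplex inputs).
oracle_qp <- function(u, v, alpha = 1, beta = 1) {
  m <- length(u)
  K <- rbind(cbind(diag(2 * (alpha + beta), m), rep(1, m)),
             c(rep(1, m), 0))
  sol <- solve(K, c(2 * (alpha * u + beta * v), 1))
  sol[1:m]
}

# Inverse standard normal CDF by bisection on pnorm (independent of qnorm).
oracle_inv_normal <- function(p, tol = 1e-10) {
  stats::uniroot(function(z) stats::pnorm(z) - p, c(-10, 10),
                 tol = tol)$root
}

# Random positive reciprocal matrix of order n (Saaty-style judgments).
random_reciprocal <- function(n) {
  A <- diag(n)
  vals <- c(1/9, 1/7, 1/5, 1/3, 1/2, 1, 2, 3, 5, 7, 9)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    A[i, j] <- sample(vals, 1)
    A[j, i] <- 1 / A[i, j]
  }
  A
}

# Random column-stochastic matrix with zero diagonal.
random_dependency <- function(n) {
  A <- matrix(stats::runif(n * n), n, n)
  diag(A) <- 0
  sweep(A, 2, colSums(A), "/")
}

random_simplex <- function(n) {
  x <- stats::rexp(n)
  x / sum(x)
}

case_fixture <- case_study_fixture()

expect_simplex <- function(x, tol = 1e-9) {
  expect_true(all(x >= -tol))
  expect_equal(sum(x), 1, tolerance = max(tol, 1e-12))
}

default_names <- function() weightscape:::default_indicators
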