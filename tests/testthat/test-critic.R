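toy42 <- score_matrix(cbind(a = c(1, 3, 5, 9), b = c(10, 8, 2, 4)))

test_that("min-max normalization hits ideal and anti-ideal endpoints", {
  s <- score_matrix(cbind(x = c(2, 6, 10), y = c(0, 5, 10)))
  n <- normalize_scores(s)
  expect_equal(unclass(n)[, "x"], c(0, 0.5, 1), ignore_attr = TRUE)

  cs <- score_matrix(cbind(x = c(7, 7, 7), y = c(0, 5, 10)))
  expect_warning(nc <- normalize_scores(cs), "constant")
  expect_equal(unclass(nc)[, "x"], c(0, 0, 0), ignore_attr = TRUE)
  expect_true(attr(nc, "constant")[["x"]])

  n2 <- normalize_scores(toy42)
  expect_equal(unclass(n2)[, "a"], c(0, 0.25, 0.5, 1), ignore_attr = TRUE)
  expect_equal(unclass(n2)[, "b"], c(1, 0.75, 0, 0.25), ignore_attr = TRUE)

  # cost direction swaps ideal and anti-ideal
  n3 <- normalize_scores(s, direction = c(-1, 1))
  expect_equal(unclass(n3)[, "x"], c(1, 0.5, 0), ignore_attr = TRUE)

  bad <- cbind(c(1, NA), c(2, 3))
  expect_error(score_matrix(bad), "incomplete", class = "ws_validation_error")
})

test_that("contrast and conflict implement the stated correlation conventions", {
  dup <- score_matrix(cbind(a = c(1, 5, 9), b = c(1, 5, 9), c = c(2, 9, 4)))
  d <- contrast_and_conflict(normalize_scores(dup))
  expect_equal(d$conflict["a", "b"], 0)    # identical columns: no correlation
  expect_equal(d$conflict["a", "a"], 1)

  mirror <- score_matrix(cbind(a = c(0, 2.5, 5, 10), b = c(10, 7.5, 5, 0)))
  dm <- contrast_and_conflict(normalize_scores(mirror))
  expect_equal(dm$conflict["a", "b"], -1, tolerance = 1e-12)

  d2 <- contrast_and_conflict(normalize_scores(toy42))
  expect_equal(d2$conflict["a", "b"], -0.7483315, tolerance = 1e-6)

  suppressWarnings({
    const <- score_matrix(cbind(a = c(3, 3, 3), b = c(1, 5, 9)))
    dc <- contrast_and_conflict(normalize_scores(const))
  })
  expect_equal(dc$conflict["a", "b"], 0)
  expect_equal(dc$sigma[["a"]], 0)
})

test_that("standard deviation convention is switchable", {
  n <- normalize_scores(toy42)
  ds <- contrast_and_conflict(n, sd_method = "sample")
  dp <- contrast_and_conflict(n, sd_method = "population")
  expect_equal(unname(dp$sigma), unname(ds$sigma) * sqrt(3 / 4), tolerance = 1e-12)
})

test_that("information content multiplies contrast by summed conflict", {
  mk <- function(sigma, r12) {
    d <- structure(list(sigma = sigma,
                        conflict = rbind(c(1, r12), c(r12, 1)),
                        info = NULL, weights = NULL,
                        labels = c("a", "b"), n = 10),
                   class = "critic_diagnostics")
    information_content(d)$info
  }
  expect_equal(unname(mk(c(0.5, 0.5), 0)), c(0.5, 0.5))
  expect_equal(unname(mk(c(0.5, 0.5), 1)), c(0, 0))

  d <- information_content(contrast_and_conflict(normalize_scores(toy42)))
  o <- oracle_critic(unclass(toy42))
  expect_equal(unname(d$info), o$C, tolerance = 1e-12)
})

test_that("weight normalization matches the published information vector", {
  Cvec <- unlist(case_fixture$information$values)
  d <- structure(list(sigma = NULL, conflict = NULL, info = Cvec,
                      weights = NULL, labels = names(Cvec), n = 2969),
                 class = "critic_diagnostics")
  w <- critic_weights(d)$weights
  published <- unlist(case_fixture$omega_c$values)
  expect_lt(max(abs(unclass(w) - published)), 0.0015)
  expect_gt(w[["I2"]], 0.1200)
  expect_lt(w[["I2"]], 0.1203)

  uniform <- structure(list(info = c(1, 1, 1, 1), labels = letters[1:4]),
                       class = "critic_diagnostics")
  expect_equal(unclass(critic_weights(uniform)$weights), rep(0.25, 4),
               ignore_attr = TRUE)
  prop <- structure(list(info = c(3, 1), labels = c("a", "b")),
                    class = "critic_diagnostics")
  expect_equal(unclass(critic_weights(prop)$weights), c(0.75, 0.25),
               ignore_attr = TRUE)
  degen <- structure(list(info = c(0, 0), labels = c("a", "b")),
                     class = "critic_diagnostics")
  expect_error(critic_weights(degen), class = "ws_degenerate_error")
})

test_that("full pipeline equals the naive transliteration oracle", {
  set.seed(13)
  for (rep in 1:5) {
    X <- matrix(runif(50 * 5, 0, 10), 50, 5)
    d <- critic(score_matrix(X))
    o <- oracle_critic(X)
    expect_equal(unname(d$sigma), o$sigma, tolerance = 1e-12)
    expect_equal(unname(unclass(d$conflict)), o$r, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(unname(d$info), o$C, tolerance = 1e-12)
    expect_equal(unclass(d$weights), o$weights, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_simplex(d$weights)
  }
})

test_that("CRITIC weights are affine-invariant and permutation-equivariant", {
  set.seed(17)
  X <- matrix(runif(40 * 4, 2, 8), 40, 4)
  w0 <- unclass(critic(score_matrix(X))$weights)

  # positive affine map of a column is absorbed by min-max normalization
  Y <- X
  Y[, 2] <- 0.8 * Y[, 2] + 1.5
  expect_equal(unclass(critic(score_matrix(Y))$weights), w0, tolerance = 1e-12)

  # permuting respondents changes nothing
  expect_equal(unclass(critic(score_matrix(X[sample(40), ]))$weights), w0,
               tolerance = 1e-12)

  # permuting indicators permutes weights identically
  perm <- c(3, 1, 4, 2)
  wp <- unclass(critic(score_matrix(X[, perm]))$weights)
  expect_equal(unname(wp), unname(w0[perm]), tolerance = 1e-12)
})

test_that("duplicating an indicator never increases its weight", {
  set.seed(19)
  for (rep in 1:5) {
    X <- matrix(runif(30 * 3, 0, 10), 30, 3)
    w0 <- unclass(critic(score_matrix(X))$weights)
    Xd <- cbind(X, X[, 1])
    wd <- unclass(critic(score_matrix(Xd))$weights)
    expect_lte(wd[1], w0[1] + 1e-12)
  }
})
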