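table1 <- case_fixture$table1$matrix

test_that("comparison matrix validation catches structural defects", {
  expect_s3_class(validate_comparison_matrix(table1), "comparison_matrix")
  expect_error(comparison_matrix(rbind(c(1, 2), c(2, 1))),
               "reciprocity", class = "ws_validation_error")
  expect_error(comparison_matrix(rbind(c(1, -3), c(-1/3, 1))),
               "not positive", class = "ws_validation_error")
  expect_error(comparison_matrix(rbind(c(2, 1), c(1, 2))),
               "diagonal", class = "ws_validation_error")
  expect_error(comparison_matrix(matrix(1, 2, 3)), class = "ws_validation_error")
})

test_that("principal priorities reproduce published and analytic cases", {
  pr <- principal_priority(table1)
  expect_equal(unname(round(unclass(pr$weights), 4)),
               c(0.5396, 0.1634, 0.2970), tolerance = 1e-8)
  expect_gte(pr$lambda_max, 3)

  ones <- comparison_matrix(matrix(1, 3, 3))
  pr1 <- principal_priority(ones)
  expect_equal(unclass(pr1$weights), rep(1/3, 3), ignore_attr = TRUE)
  expect_equal(pr1$lambda_max, 3, tolerance = 1e-9)

  w <- c(0.4, 0.3, 0.2, 0.1)
  consistent <- comparison_matrix(outer(w, w, "/"))
  pr2 <- principal_priority(consistent)
  expect_equal(unclass(pr2$weights), w, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(pr2$lambda_max, 4, tolerance = 1e-9)
})

test_that("geometric-mean mode cross-checks the eigen route at 4 dp", {
  pg <- principal_priority(table1, method = "geometric")
  pe <- principal_priority(table1)
  expect_equal(round(unclass(pg$weights), 4), round(unclass(pe$weights), 4))
})

test_that("power iteration agrees with dense eigen oracle on random matrices", {
  set.seed(42)
  for (n in 3:7) {
    for (rep in 1:5) {
      A <- random_reciprocal(n)
      pr <- principal_priority(comparison_matrix(A))
      o <- oracle_principal(A)
      expect_equal(unclass(pr$weights), o$weights, tolerance = 1e-6,
                   ignore_attr = TRUE)
      expect_equal(pr$lambda_max, o$lambda_max, tolerance = 1e-6)
      expect_gte(pr$lambda_max, n - 1e-9)
      expect_simplex(pr$weights)
    }
  }
})

test_that("consistency index and ratio follow the definitions", {
  rep1 <- consistency(table1)
  expect_lt(abs(rep1$cr - 0.0079), 0.0005)
  expect_equal(rep1$ri_used, 0.58)
  expect_true(rep1$acceptable)

  w <- c(0.5, 0.3, 0.2)
  cons <- consistency(comparison_matrix(outer(w, w, "/")))
  expect_equal(cons$ci, 0, tolerance = 1e-9)
  expect_equal(cons$cr, 0, tolerance = 1e-9)

  # cyclic preferences: circulant rows sum to 6.2, so lambda_max = 6.2 exactly
  cyc <- comparison_matrix(rbind(c(1, 5, 1/5), c(1/5, 1, 5), c(5, 1/5, 1)))
  pr <- principal_priority(cyc)
  expect_equal(pr$lambda_max, 6.2, tolerance = 1e-9)
  rep2 <- consistency(cyc, pr)
  expect_gt(rep2$cr, 0.1)
  expect_false(rep2$acceptable)
  expect_error(consistency(cyc, pr, strict = TRUE), class = "ws_validation_error")

  expect_equal(consistency(comparison_matrix(rbind(c(1, 3), c(1/3, 1))))$cr, 0)
  big <- comparison_matrix(diag(12) + 1 - diag(12))  # 12x12 all-ones off diag
  expect_error(consistency(big), "random-index", class = "ws_validation_error")
})

test_that("interdependent weights multiply the dependency matrix through", {
  dep <- case_fixture$dependency$matrix
  om3 <- interdependent_weights(dep, c(ES = 0.5396, IS = 0.1634, TS = 0.2970))
  expect_lt(max(abs(unclass(om3) - c(0.1151, 0.4926, 0.3924))), 0.0005)

  # doubly stochastic dependency maps uniform to uniform
  ds <- dependency_matrix(rbind(c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0)))
  expect_equal(unclass(interdependent_weights(ds, rep(1/3, 3))), rep(1/3, 3),
               ignore_attr = TRUE)

  set.seed(7)
  for (rep in 1:10) {
    D <- random_dependency(4)
    b <- random_simplex(4)
    out <- interdependent_weights(dependency_matrix(D), b)
    expect_equal(unclass(out), as.numeric(D %*% b), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_simplex(out)
  }

  expect_error(interdependent_weights(dep, c(0.5, 0.5)),
               "mismatch", class = "ws_validation_error")
  bad <- unclass(dep); bad[1, 1] <- 0.5
  expect_error(dependency_matrix(bad), class = "ws_validation_error")
})

test_that("global sub-criterion weights reproduce the published table", {
  fx <- case_fixture
  om3 <- as_weight_vector(fx$omega3$values, labels = fx$labels$criteria,
                          renormalize = TRUE)
  gw <- global_subcriteria_weights(om3, fx$hierarchy)
  published <- unlist(fx$table2$globals)
  expect_lt(max(abs(unclass(gw) - published)), 0.0005)
  expect_lt(abs(gw[["I2"]] - 0.2750), 0.0005)
  expect_simplex(gw, tol = 1e-6)

  single <- hierarchy_spec(list(A = c("a1", "a2")), list(A = c(0.7, 0.3)))
  expect_equal(unclass(global_subcriteria_weights(c(A = 1), single)),
               c(0.7, 0.3), ignore_attr = TRUE)
  expect_error(global_subcriteria_weights(om3, hierarchy_spec(
    list(ES = "E1", IS = "I1", TS = "T1"))), class = "ws_validation_error")
})

test_that("supermatrix application synthesizes and preserves the simplex", {
  w <- as_weight_vector(c(0.5, 0.3, 0.2))
  expect_equal(unclass(apply_supermatrix(supermatrix(diag(3)), w)),
               c(0.5, 0.3, 0.2), ignore_attr = TRUE)

  S <- supermatrix(rbind(c(.2, .5, .3), c(.3, .2, .4), c(.5, .3, .3)))
  expect_equal(unclass(apply_supermatrix(S, w)), c(0.31, 0.29, 0.40),
               tolerance = 1e-12, ignore_attr = TRUE)

  set.seed(11)
  for (rep in 1:10) {
    S <- random_dependency(5)  # column-stochastic works for conservation
    out <- apply_supermatrix(supermatrix(S), random_simplex(5))
    expect_simplex(out)
  }
  expect_error(apply_supermatrix(supermatrix(diag(3)), random_simplex(4)),
               "mismatch", class = "ws_validation_error")
})

test_that("synthetic stand-in supermatrix regresses to the published subjective vector", {
  S <- supermatrix(read_matrix_csv(fixture_path("supermatrix_synthetic.csv")),
                   raw = TRUE)
  omega_p <- as_weight_vector(unlist(case_fixture$table2$globals),
                              renormalize = TRUE)
  omega_y <- apply_supermatrix(S, omega_p)
  published <- unlist(case_fixture$omega_y$values)
  expect_equal(unclass(omega_y), published / sum(published), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("fractions in CSV matrices are parsed exactly", {
  m <- read_matrix_csv(fixture_path("table1_criteria.csv"))
  expect_identical(m["IS", "ES"], 1/3)
  expect_identical(m["TS", "ES"], 1/2)
  expect_error(weightscape:::parse_fraction("3/4/5"), class = "ws_validation_error")
})
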