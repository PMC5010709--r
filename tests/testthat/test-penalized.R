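test_that("a penalty above lambda_max shrinks everything to zero", {
  d <- random_dataset(30, 8, seed = 1, beta = c(1, -2, rep(0, 6)))
  fit <- fit_lasso_cv(d, lambda = 1e6)
  expect_length(fit$selected, 0)
  expect_equal(fit$intercept, 0, tolerance = 1e-8)
})

test_that("the unpenalized limit recovers OLS on an orthonormal toy design", {
  set.seed(2)
  Q <- qr.Q(qr(matrix(rnorm(40), 20, 2)))
  X <- scale(Q)                      # orthogonal, standardized columns
  y <- as.numeric(X %*% c(1.5, -0.8)) + rnorm(20, sd = 0.1)
  d <- bag_dataset(X, y)
  fit <- fit_lasso_cv(d, lambda = 0)
  ols <- qr.coef(qr(cbind(1, d$X)), d$y)
  expect_equal(unname(fit$coefficients[d$var_ids]), unname(ols[-1]),
               tolerance = 1e-6)
})

test_that("CV lasso solution satisfies the KKT conditions and matches a
           coordinate-descent oracle", {
  d <- random_dataset(20, 10, seed = 3, beta = c(2, -1, 1, rep(0, 7)),
                      sigma = 0.5)
  fit <- fit_lasso_cv(d, k = 5, seed = 11)
  b <- setNames(rep(0, 10), d$var_ids)
  b[fit$selected] <- fit$coefficients
  n <- nrow(d$X)
  grad <- -as.numeric(crossprod(d$X, d$y - fit$intercept - d$X %*% b)) / n
  lam <- fit$lambda
  expect_true(all(abs(grad[b == 0]) <= lam + 1e-6))
  expect_true(all(abs(grad[b != 0] + lam * sign(b[b != 0])) < 1e-6))
  ## independent coordinate-descent re-solve at the same lambda
  oracle <- cd_lasso(d$X, d$y, lam)
  expect_equal(unname(b), oracle$beta, tolerance = 1e-6)
  ## local optimality against random perturbations of the solution
  obj0 <- lasso_objective(d$X, d$y, fit$intercept, b, lam)
  set.seed(99)
  worse <- replicate(1000, {
    lasso_objective(d$X, d$y, fit$intercept,
                    b + rnorm(10, sd = 0.01), lam) >= obj0 - 1e-10
  })
  expect_true(all(worse))
})

test_that("initial weights are reciprocal absolute initial coefficients", {
  ## exact design: y = 2 x1 - 0.5 x2 so the OLS coefficients are known
  set.seed(4)
  X <- scale(matrix(rnorm(40), 20, 2))
  y <- as.numeric(X %*% c(2, -0.5))
  d <- bag_dataset(X, y, standardize = FALSE)
  w <- initial_weights(d, scheme = "ols")
  expect_equal(unname(w), c(0.5, 2), tolerance = 1e-10)
  ## P >= n has no full OLS
  d_wide <- random_dataset(10, 15, seed = 5)
  expect_error(initial_weights(d_wide, scheme = "ols"), "ridge")
  ## a zero marginal coefficient gives an infinite weight and exclusion
  yc <- rep(c(1, 1, -1, -1), 5)              # centered response
  x2 <- rep(c(1, -1), 10)                    # exactly orthogonal to yc
  x1 <- yc                                   # perfectly predictive
  d2 <- bag_dataset(cbind(x1, x2), yc, var_ids = c("x1", "x2"),
                    standardize = FALSE)
  w2 <- initial_weights(d2, scheme = "marginal_ols")
  expect_true(is.infinite(w2[2]))
  fit <- fit_adaptive_lasso_cv(d2, weights = w2, seed = 1)
  expect_false("x2" %in% fit$selected)
})

test_that("adaptive lasso with unit weights is exactly the plain lasso", {
  d <- random_dataset(40, 15, seed = 6, beta = c(rep(1, 3), rep(0, 12)))
  w1 <- setNames(rep(1, 15), d$var_ids)
  a <- fit_lasso_cv(d, k = 5, seed = 21)
  b <- fit_adaptive_lasso_cv(d, k = 5, weights = w1, seed = 21)
  expect_identical(a$selected, b$selected)
  expect_equal(a$coefficients, b$coefficients, tolerance = 1e-12)
  expect_equal(a$lambda, b$lambda)
})

test_that("an infinitely weighted variable is excluded and the fit matches
           the reduced design", {
  d <- random_dataset(40, 6, seed = 7, beta = c(1, 1, rep(0, 4)))
  w <- setNames(rep(1, 6), d$var_ids)
  w["x2"] <- Inf
  full <- fit_adaptive_lasso_cv(d, weights = w, seed = 31)
  d_red <- bag_dataset(d$X[, -2], d$y, var_ids = d$var_ids[-2],
                       standardize = FALSE)
  red <- fit_lasso_cv(d_red, seed = 31)
  expect_false("x2" %in% full$selected)
  expect_identical(full$selected, red$selected)
  expect_equal(full$coefficients, red$coefficients, tolerance = 1e-10)
})

test_that("all-infinite weights give an empty model with a warning", {
  d <- random_dataset(20, 4, seed = 8)
  w <- setNames(rep(Inf, 4), d$var_ids)
  expect_warning(fit <- fit_adaptive_lasso_cv(d, weights = w, seed = 1),
                 "infinite")
  expect_length(fit$selected, 0)
})

test_that("a constant response yields an empty selection with a warning", {
  d <- random_dataset(20, 4, seed = 9)
  d$y <- rep(0, 20)
  expect_warning(fit <- fit_lasso_cv(d, seed = 1), "constant")
  expect_length(fit$selected, 0)
})

test_that("OLS refit matches the normal equations and handles edge cases", {
  ## empty set: intercept-only at the (centered) response mean
  d <- random_dataset(10, 3, seed = 10)
  m0 <- refit_ols(character(0), d)
  expect_equal(predict(m0, d), rep(0, 10), tolerance = 1e-12)
  ## single standardized variable: slope = cov(x, y) / var(x)
  m1 <- refit_ols("x1", d)
  expect_equal(unname(m1$coefficients),
               cov(d$X[, 1], d$y) / var(d$X[, 1]), tolerance = 1e-12)
  ## full 10 x 3 system vs brute-force normal equations
  m3 <- refit_ols(c("x1", "x2", "x3"), d)
  Xs <- cbind(1, d$X)
  bb <- solve(t(Xs) %*% Xs, t(Xs) %*% d$y)
  expect_equal(unname(m3$coefficients), unname(bb[-1, 1]), tolerance = 1e-10)
  ## residuals orthogonal to included columns
  r <- d$y - predict(m3, d)
  expect_lt(max(abs(crossprod(d$X, r))), 1e-10)
  ## rank deficiency: duplicated column is dropped with a warning
  X <- matrix(rnorm(30), 10, 3)
  X <- cbind(X, X[, 1])
  dd <- bag_dataset(X, rnorm(10), var_ids = c("a", "b", "c", "adup"))
  expect_warning(mr <- refit_ols(c("a", "b", "c", "adup"), dd), "adup")
  expect_equal(mr$dropped, "adup")
  expect_equal(mr$variables, c("a", "b", "c"))
  ## too many columns for the rows
  expect_error(refit_ols(dd$var_ids, dataset_subset(dd, 1:3)), "fewer")
})

test_that("prediction is the stored affine function of the named columns", {
  X <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2)
  d <- bag_dataset(X, c(0, 0, 0), var_ids = c("u", "v"), standardize = FALSE)
  m <- structure(list(variables = c("u", "v"),
                      coefficients = c(u = 2, v = -1),
                      intercept = 0.5, dropped = character(0)),
                 class = "bag_model")
  expect_equal(predict(m, d), c(0.5 + 2 * 1 - 4, 0.5 + 4 - 5, 0.5 + 6 - 6))
  expect_error(predict(m, bag_dataset(X, rep(0, 3), var_ids = c("u", "w"),
                                      standardize = FALSE)), "missing")
})

test_that("the CV curve is deterministic under a fixed fold seed", {
  d <- random_dataset(50, 30, seed = 12, beta = c(rep(0.8, 4), rep(0, 26)))
  f1 <- fit_lasso_cv(d, seed = 77)
  f2 <- fit_lasso_cv(d, seed = 77)
  expect_identical(f1$cvm, f2$cvm)
  expect_identical(f1$lambda, f2$lambda)
})

test_that("selections and models serialize to JSON and back", {
  d <- random_dataset(40, 10, seed = 13, beta = c(2, -2, rep(0, 8)))
  fit <- fit_lasso_cv(d, seed = 5)
  f <- withr::local_tempfile(fileext = ".json")
  write_selection(fit, f)
  fit2 <- read_selection(f)
  expect_equal(fit2$selected, fit$selected)
  expect_equal(fit2$coefficients, fit$coefficients)
  expect_equal(fit2$lambda, fit$lambda)
  m <- refit_ols(fit$selected, d)
  g <- withr::local_tempfile(fileext = ".json")
  write_model(m, g)
  m2 <- read_model(g)
  expect_equal(m2$coefficients, m$coefficients)
  expect_equal(predict(m2, d), predict(m, d))
})
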