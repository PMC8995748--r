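test_that("linear regression reproduces exact linear structure", {
  ## noiseless linear response: zero residual
  set.seed(1)
  X <- matrix(rnorm(24), 8, 3)
  w <- c(2, -1, 0.5)
  y <- as.numeric(X %*% w) + 1.5
  m <- fit_linear(X, y)
  expect_equal(as.numeric(X %*% m$W + m$b), y, tolerance = 1e-10)

  ## two 1-D points: the line through both
  m2 <- fit_linear(matrix(c(0, 2), 2, 1), c(1, 5))
  expect_equal(m2$W, 2, tolerance = 1e-12)
  expect_equal(m2$b, 1, tolerance = 1e-12)
})

test_that("linear coefficients match the normal-equations oracle", {
  set.seed(2)
  X <- matrix(rnorm(24), 8, 3)
  y <- rnorm(8)
  m <- fit_linear(X, y)
  ## oracle: solve the centered normal equations directly
  Xc <- sweep(X, 2, colMeans(X)); yc <- y - mean(y)
  w_oracle <- solve(crossprod(Xc), crossprod(Xc, yc))
  expect_equal(m$W, as.numeric(w_oracle), tolerance = 1e-8)
  ## minimum-norm solution when underdetermined: fits exactly and has
  ## the smallest norm among least-squares solutions
  Xu <- matrix(rnorm(4 * 9), 4, 9)
  yu <- rnorm(4)
  mu <- fit_linear(Xu, yu)
  expect_equal(as.numeric(Xu %*% mu$W + mu$b), yu, tolerance = 1e-8)
  expect_error(fit_linear(Xu[1, , drop = FALSE], yu[1]), "2 subjects")
})

test_that("lasso shrinks fully, matches least squares at lambda 0", {
  set.seed(3)
  X <- matrix(rnorm(40), 10, 4)
  y <- rnorm(10)
  ## full shrinkage: lambda at least 2 max|X'y|/n on centered data
  Xc <- sweep(X, 2, colMeans(X)); yc <- y - mean(y)
  lam_max <- 2 * max(abs(crossprod(Xc, yc))) / nrow(X)
  m_big <- fit_lasso(X, y, lambda = lam_max * 1.01)
  expect_identical(m_big$beta, rep(0, 4))
  ## lambda = 0 reduces to least squares (solver run to tight
  ## tolerance; coordinate descent converges slowly without penalty)
  m0 <- fit_lasso(X, y, lambda = 0, tol = 1e-14)
  ols <- fit_linear(X, y)
  expect_equal(m0$beta, ols$W, tolerance = 1e-6)
  expect_error(fit_lasso(X, y, lambda = -0.1), "lambda")
})

test_that("orthonormal-design lasso equals the soft-threshold closed form", {
  set.seed(4)
  ## orthonormal columns via QR
  Q <- qr.Q(qr(matrix(rnorm(12 * 4), 12, 4)))
  Q <- sweep(Q, 2, colMeans(Q)) # keep centering harmless
  Q <- qr.Q(qr(Q))
  y <- rnorm(12)
  yc <- y - mean(y)
  n <- nrow(Q)
  for (lambda in c(0.01, 0.05, 0.2)) {
    m <- fit_lasso(Q, y, lambda = lambda)
    z <- as.numeric(crossprod(Q, yc)) # OLS coefficients, X'X = I
    oracle <- sign(z) * pmax(abs(z) - n * lambda / 2, 0)
    expect_equal(m$beta, oracle, tolerance = 1e-6)
  }
})

test_that("lasso objective matches glmnet on a general design", {
  set.seed(5)
  X <- matrix(rnorm(30 * 6), 30, 6)
  y <- as.numeric(X %*% c(1.5, -2, 0, 0, 0.5, 0)) + rnorm(30, sd = 0.3)
  obj <- function(beta, lambda) {
    Xc <- sweep(X, 2, colMeans(X)); yc <- y - mean(y)
    mean((yc - Xc %*% beta)^2) + lambda * sum(abs(beta))
  }
  for (lambda in c(0.05, 0.2)) {
    mine <- fit_lasso(X, y, lambda = lambda)
    ## glmnet minimizes 1/(2n)RSS + lambda_g |beta|; lambda_g = lambda/2
    g <- glmnet::glmnet(X, y, family = "gaussian",
                        lambda = lambda / 2, standardize = FALSE,
                        intercept = TRUE, thresh = 1e-12)
    beta_g <- as.numeric(g$beta)
    expect_equal(obj(mine$beta, lambda), obj(beta_g, lambda),
                 tolerance = 1e-6)
    expect_equal(mine$beta, beta_g, tolerance = 1e-4)
  }
})

test_that("lasso support is non-increasing in lambda", {
  set.seed(6)
  for (rep in 1:3) {
    X <- matrix(rnorm(25 * 8), 25, 8)
    y <- as.numeric(X %*% rnorm(8)) + rnorm(25, sd = 0.5)
    nz <- vapply(c(0.001, 0.01, 0.1, 0.5, 1, 2), function(l)
      sum(fit_lasso(X, y, lambda = l)$beta != 0), numeric(1))
    expect_true(all(diff(nz) <= 0))
  }
})

test_that("PLS recovers rank-1 structure and reduces to least squares", {
  set.seed(7)
  ## rank-1 X with y proportional to the single factor
  t1 <- rnorm(12)
  p1 <- rnorm(5)
  X1 <- outer(t1, p1)
  y1 <- 2 * t1
  m1 <- fit_pls(X1, y1, n_components = 1)
  expect_lt(sqrt(sum(m1$F_res^2)), 1e-8)

  ## full components on full-rank tall X: predictions match OLS
  X <- matrix(rnorm(20 * 4), 20, 4)
  y <- rnorm(20)
  mp <- fit_pls(X, y, n_components = 4)
  ols <- fit_linear(X, y)
  expect_equal(predict(mp, X), predict(ols, X), tolerance = 1e-6)

  ## score vectors are mutually orthogonal
  Tm <- mp$T
  for (a in 1:3) for (b in (a + 1):4)
    expect_lt(abs(sum(Tm[, a] * Tm[, b])),
              1e-8 * sqrt(sum(Tm[, a]^2)) * sqrt(sum(Tm[, b]^2)))

  expect_error(fit_pls(X, y, n_components = 0), "n_components")
  expect_error(fit_pls(X, y, n_components = 25), "n_components")
})

test_that("baseline tuning maximizes validation accuracy deterministically", {
  set.seed(8)
  n <- 40
  X <- matrix(rnorm(n * 5), n, 5)
  y <- ifelse(as.numeric(X %*% c(2, -1, 0, 0, 0)) + rnorm(n, sd = 0.2)
              >= 0, 1, -1)
  tr <- 1:24; va <- 25:40

  ## single-point grid returns that point
  t1 <- tune_baseline("lasso", X[tr, ], y[tr], X[va, ], y[va],
                      grid = data.frame(lambda = 0.3))
  expect_equal(t1$params$lambda, 0.3)

  ## noiseless linear data: a small lambda beats heavy shrinkage
  t2 <- tune_baseline("lasso", X[tr, ], y[tr], X[va, ], y[va])
  small <- min(t2$grid$lambda)
  expect_gte(
    t2$grid$val_accuracy[t2$grid$lambda == small],
    max(t2$grid$val_accuracy[t2$grid$lambda == max(t2$grid$lambda)]))

  ## PLS: selected component count attains the grid maximum
  t3 <- tune_baseline("pls", X[tr, ], y[tr], X[va, ], y[va])
  expect_lte(t3$params$n_components, 5)
  expect_equal(t3$val_accuracy, max(t3$grid$val_accuracy))

  ## all four kinds share the fit/tune/predict contract
  for (kind in c("linear", "lasso", "pls", "svm")) {
    tk <- tune_baseline(kind, X[tr, ], y[tr], X[va, ], y[va])
    sc <- predict(tk$model, X[va, ])
    expect_length(sc, length(va))
    cls <- predict(tk$model, X[va, ], type = "class")
    expect_true(all(cls %in% c(-1, 1)))
    expect_equal(ifelse(sc >= 0, 1, -1), cls)
  }
})

test_that("linear and lasso(0) agree on full-rank problems", {
  set.seed(9)
  X <- matrix(rnorm(30 * 3), 30, 3)
  y <- rnorm(30)
  expect_equal(fit_lasso(X, y, lambda = 0, tol = 1e-14)$beta,
               fit_linear(X, y)$W, tolerance = 1e-6)
})
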