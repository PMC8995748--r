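#' Least-squares linear model (minimum-norm)
#'
#' Fits f(x) = w'x + b by minimizing the residual sum of squares.
#' The intercept is handled by centering; the slope solution is the
#' Moore-Penrose (minimum-norm) least-squares solution, so
#' underdetermined problems (more voxels than subjects) are handled
#' without regularization. Classification is by the sign of f(x).
#'
#' @param X matrix (subjects x features).
#' @param y numeric response (here labels in \{-1, +1\}).
#' @return an \code{rssvm_linear} model with \code{W}, \code{b}.
#' @export
fit_linear <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 subjects")
  xbar <- colMeans(X); ybar <- mean(y)
  Xc <- sweep(X, 2, xbar); yc <- y - ybar
  s <- svd(Xc)
  pos <- s$d > max(dim(Xc)) * .Machine$double.eps * max(s$d, 1)
  W <- s$v[, pos, drop = FALSE] %*%
    ((t(s$u[, pos, drop = FALSE]) %*% yc) / s$d[pos])
  structure(list(W = as.numeric(W), b = ybar - sum(xbar * W)),
            class = "rssvm_linear")
}

#' @export
predict.rssvm_linear <- function(object, newdata,
                                 type = c("score", "class"), ...) {
  type <- match.arg(type)
  f <- as.numeric(as.matrix(newdata) %*% object$W + object$b)
  if (type == "score") f else ifelse(f >= 0, 1, -1)
}

soft_threshold <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

#' Lasso regression by cyclic coordinate descent
#'
#' Minimizes, on centered data,
#' \deqn{\frac1n \|y - X\beta\|_2^2 + \lambda \|\beta\|_1}
#' by cyclic coordinate descent with the closed-form per-coordinate
#' soft-threshold update, to an objective tolerance of 1e-8 (at most
#' 10,000 sweeps). The intercept is recovered from the stored column
#' means. Classification is by the sign of the linear score.
#'
#' @param X matrix (subjects x features).
#' @param y numeric response.
#' @param lambda nonnegative L1 penalty weight.
#' @param tol convergence tolerance on the objective decrease.
#' @param max_sweeps sweep cap.
#' @return an \code{rssvm_lasso} model with \code{beta},
#'   \code{lambda}, \code{xbar}, \code{ybar}, \code{objective}.
#' @export
fit_lasso <- function(X, y, lambda, tol = 1e-8, max_sweeps = 10000) {
  if (lambda < 0) stop("'lambda' must be nonnegative")
  X <- as.matrix(X)
  n <- nrow(X)
  xbar <- colMeans(X); ybar <- mean(y)
  Xc <- sweep(X, 2, xbar); yc <- y - ybar
  ssq <- colSums(Xc^2)
  p <- ncol(Xc)
  beta <- numeric(p)
  r <- yc
  obj <- function() mean(r^2) + lambda * sum(abs(beta))
  prev <- obj()
  for (sweep_i in seq_len(max_sweeps)) {
    max_delta <- 0
    for (j in seq_len(p)) {
      if (ssq[j] == 0) next
      zj <- sum(Xc[, j] * r) + ssq[j] * beta[j]
      bj <- soft_threshold(zj, n * lambda / 2) / ssq[j]
      if (bj != beta[j]) {
        max_delta <- max(max_delta, abs(bj - beta[j]))
        r <- r - Xc[, j] * (bj - beta[j])
        beta[j] <- bj
      }
    }
    cur <- obj()
    ## stop only once both the objective and the coefficients settle
    if (prev - cur < tol && max_delta < sqrt(tol)) break
    prev <- cur
  }
  structure(list(beta = beta, lambda = lambda, xbar = xbar,
                 ybar = ybar, objective = obj()),
            class = "rssvm_lasso")
}

#' @export
predict.rssvm_lasso <- function(object, newdata,
                                type = c("score", "class"), ...) {
  type <- match.arg(type)
  f <- as.numeric(sweep(as.matrix(newdata), 2, object$xbar) %*%
                    object$beta + object$ybar)
  if (type == "score") f else ifelse(f >= 0, 1, -1)
}

#' Partial least squares regression (NIPALS, univariate response)
#'
#' Extracts \code{n_components} latent components by the NIPALS
#' iteration with deflation: each weight vector maximizes the
#' covariance between the X score t and the response, X is deflated
#' by t p' and y by t q after each component, leaving the residual
#' matrices E and F. The X scores are mutually orthogonal by
#' construction. With a full set of components on a full-rank tall X
#' the fitted values coincide with least squares.
#'
#' @param X matrix (subjects x features).
#' @param y numeric response (n x 1; labels here).
#' @param n_components number of latent components.
#' @return an \code{rssvm_pls} model with score matrix \code{T},
#'   loadings \code{P}, \code{W}, y-loadings \code{Q}, residuals
#'   \code{E}, \code{F_res}, regression coefficients \code{B} and
#'   intercept.
#' @export
fit_pls <- function(X, y, n_components) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n_components < 1L || n_components > min(n - 1L, p))
    stop("'n_components' must be in [1, min(n - 1, p)]")
  xbar <- colMeans(X); ybar <- mean(y)
  E <- sweep(X, 2, xbar); f <- y - ybar
  W <- matrix(0, p, n_components); P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components); Q <- numeric(n_components)
  U <- matrix(0, n, n_components)
  for (a in seq_len(n_components)) {
    u <- f                              # univariate y: u = current residual
    w <- as.numeric(crossprod(E, u))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) { W <- W[, seq_len(a - 1L), drop = FALSE]
      P <- P[, seq_len(a - 1L), drop = FALSE]
      Tm <- Tm[, seq_len(a - 1L), drop = FALSE]
      U <- U[, seq_len(a - 1L), drop = FALSE]
      Q <- Q[seq_len(a - 1L)]; break }
    w <- w / nw
    t_a <- as.numeric(E %*% w)
    tt <- sum(t_a^2)
    p_a <- as.numeric(crossprod(E, t_a)) / tt
    q_a <- sum(f * t_a) / tt
    E <- E - tcrossprod(t_a, p_a)
    f <- f - t_a * q_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; Q[a] <- q_a
    U[, a] <- u
  }
  ## B = W (P'W)^-1 Q maps centered x to the fitted score
  B <- as.numeric(W %*% solve(crossprod(P, W), Q))
  structure(list(T = Tm, U = U, P = P, Q = Q, W = W, E = E, F_res = f,
                 B = B, xbar = xbar, ybar = ybar,
                 n_components = ncol(Tm)),
            class = "rssvm_pls")
}

#' @export
predict.rssvm_pls <- function(object, newdata,
                              type = c("score", "class"), ...) {
  type <- match.arg(type)
  f <- as.numeric(sweep(as.matrix(newdata), 2, object$xbar) %*%
                    object$B + object$ybar)
  if (type == "score") f else ifelse(f >= 0, 1, -1)
}

default_baseline_grid <- function(kind) {
  switch(kind,
         linear = data.frame(dummy = NA),
         lasso = data.frame(lambda = c(0.001, 0.005, 0.01, 0.05,
                                       0.1, 0.5, 1)),
         pls = data.frame(n_components = 1:5),
         svm = default_svm_grid(),
         stop("unknown model kind: ", kind))
}

#' Tune a comparison model on a validation set
#'
#' Shared fit/tune/predict contract for the four comparison
#' classifiers. Fits each grid point on the training data, scores
#' sign-thresholded predictions on the validation set, and returns
#' the grid point with the highest validation accuracy; ties go to
#' the smaller penalty / fewer components / canonical SVM order.
#'
#' @param kind one of \code{"linear"}, \code{"lasso"}, \code{"pls"},
#'   \code{"svm"}.
#' @param X_train,y_train,X_val,y_val split data.
#' @param grid hyperparameter data.frame; \code{NULL} for the default
#'   grid of that model kind.
#' @return list with \code{model} (the refitted winner),
#'   \code{params}, \code{val_accuracy} and the scored \code{grid}.
#' @export
tune_baseline <- function(kind, X_train, y_train, X_val, y_val,
                          grid = NULL) {
  kind <- match.arg(kind, c("linear", "lasso", "pls", "svm"))
  if (kind == "svm")
    return(local({
      gs <- grid_search(X_train, y_train, X_val, y_val,
                        if (is.null(grid)) default_svm_grid() else grid)
      model <- train_svm(X_train, y_train,
                         kernel = gs$best_params$kernel,
                         C = gs$best_params$C,
                         gamma = if (is.na(gs$best_params$gamma)) 0.5
                                 else gs$best_params$gamma)
      list(model = model, params = gs$best_params,
           val_accuracy = gs$val_accuracy, grid = gs$grid)
    }))
  if (is.null(grid)) grid <- default_baseline_grid(kind)
  if (nrow(grid) == 0L) stop("'grid' must be non-empty")
  ## canonical order: smaller penalty / fewer components first
  ord_col <- intersect(c("lambda", "n_components"), names(grid))
  if (length(ord_col)) grid <- grid[order(grid[[ord_col[1]]]), ,
                                    drop = FALSE]
  fit_one <- function(row) switch(kind,
    linear = fit_linear(X_train, y_train),
    lasso = fit_lasso(X_train, y_train, lambda = row$lambda),
    pls = fit_pls(X_train, y_train,
                  n_components = min(row$n_components,
                                     nrow(X_train) - 1L,
                                     ncol(X_train))))
  acc <- numeric(nrow(grid))
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    fits[[i]] <- fit_one(grid[i, , drop = FALSE])
    acc[i] <- mean(predict(fits[[i]], X_val, type = "class") == y_val)
  }
  best <- which.max(acc)
  grid$val_accuracy <- acc
  list(model = fits[[best]], params = grid[best, , drop = FALSE],
       val_accuracy = acc[best], grid = grid)
}
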