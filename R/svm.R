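## kernel evaluations between row sets
kernel_matrix <- function(X1, X2, kernel, gamma = 0.5) {
  if (kernel == "linear") return(X1 %*% t(X2))
  ## rbf: exp(-gamma * ||x - x'||^2)
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), `+`) - 2 * X1 %*% t(X2)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

#' Train a soft-margin support vector machine
#'
#' Solves the standard soft-margin problem
#' \deqn{\min \tfrac12\|w\|^2 + C\sum_i \varepsilon_i
#'   \quad s.t.\quad y_i(w^\top\varphi(x_i)+b) \ge 1-\varepsilon_i,\
#'   \varepsilon_i \ge 0}
#' through its dual with a sequential-minimal-optimization solver
#' (maximal-violating-pair selection), for a linear or RBF kernel.
#'
#' @param X numeric matrix (subjects x features).
#' @param y labels in \{-1, +1\}.
#' @param kernel \code{"linear"} or \code{"rbf"}.
#' @param C penalty factor (> 0); default 1.
#' @param gamma RBF width (> 0); default 0.5. Ignored for linear.
#' @param tol KKT-gap convergence tolerance of the SMO solver.
#' @param max_iter iteration cap.
#' @return an \code{rssvm_svm} model with dual coefficients
#'   \code{alpha}, intercept \code{b}, dual \code{objective},
#'   training data and kernel settings.
#' @export
train_svm <- function(X, y, kernel = c("linear", "rbf"), C = 1,
                      gamma = 0.5, tol = 1e-8, max_iter = 1e6) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  if (length(unique(y)) < 2L)
    stop("training data must contain both classes")
  if (!all(y %in% c(-1, 1))) stop("labels must be in {-1, +1}")
  if (C <= 0) stop("'C' must be positive")
  if (kernel == "rbf" && gamma <= 0) stop("'gamma' must be positive")
  K <- kernel_matrix(X, X, kernel, gamma)
  fit <- smo_solve(K, as.numeric(y), C, tol, as.integer(max_iter))
  structure(list(kernel = kernel, C = C,
                 gamma = if (kernel == "rbf") gamma else NA_real_,
                 X = X, y = as.numeric(y),
                 alpha = fit$alpha, b = fit$b,
                 objective = fit$objective,
                 iterations = fit$iterations,
                 support_indices = which(fit$alpha > 1e-10)),
            class = "rssvm_svm")
}

#' @describeIn train_svm decision scores (\code{type = "score"}) or
#'   sign-thresholded class labels (\code{type = "class"}) for new
#'   data.
#' @param object fitted model.
#' @param newdata matrix of new rows.
#' @param type \code{"score"} or \code{"class"}.
#' @param ... unused.
#' @export
predict.rssvm_svm <- function(object, newdata, type = c("score", "class"),
                              ...) {
  type <- match.arg(type)
  K <- kernel_matrix(as.matrix(newdata), object$X, object$kernel,
                     object$gamma)
  f <- as.numeric(K %*% (object$alpha * object$y) + object$b)
  if (type == "score") f else ifelse(f >= 0, 1, -1)
}
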