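## Shared fixtures and independent oracles for the test suite.

## tiny deterministic cohort used across modules
small_cohort <- function(seed = 7, n = 10, dims = c(6, 7, 6),
                         n_informative = 20, effect = 0.3,
                         noise = 0.05, ...) {
  generate_cohort(n, n, dims, n_informative, effect, noise,
                  seed = seed, ...)
}

## group summaries built directly from hand-given voxel vectors
gvv <- function(values, group, dims) {
  structure(list(values = values, group = group, dims = dims,
                 flatten_order = "column-major-0-based"),
            class = "group_voxel_vector")
}

## dense pairwise similarity oracle: direct double loop over rows
dense_similarity_oracle <- function(vm, vn) {
  n <- length(vm)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    S[i, j] <- (vm[i] - vm[j])^2 + (vn[i] - vn[j])^2
  S
}

## independent SVM oracle via quadprog, reported on the scale of the
## dual minimum 0.5 a'Qa - 1'a (what train_svm()$objective stores).
## Linear kernel: solve the PRIMAL in (w, b, eps) -- its Hessian is
## the identity on w, so it stays well conditioned even when the
## rank-deficient linear-kernel dual is numerically degenerate; by
## strong duality primal min = -(dual min). RBF kernel: solve the
## dual directly (K is full rank for distinct points); ridge 1e-8
## keeps quadprog's Cholesky stable while perturbing the objective
## by < 1e-7.
qp_svm_objective <- function(X, y, kernel = "linear", C = 1,
                             gamma = 0.5, ridge = 1e-8) {
  n <- length(y)
  if (kernel == "linear") {
    p <- ncol(X)
    D <- diag(c(rep(1, p), rep(ridge, 1 + n)))
    d <- c(rep(0, p + 1), rep(-C, n))
    ## margin constraints y_i (w'x_i + b) + eps_i >= 1, eps >= 0
    A <- cbind(rbind(t(X * y), y, diag(n)),
               rbind(matrix(0, p + 1, n), diag(n)))
    sol <- quadprog::solve.QP(D, d, A, c(rep(1, n), rep(0, n)))
    v <- sol$solution
    w <- v[seq_len(p)]; eps <- v[p + 1 + seq_len(n)]
    return(-(0.5 * sum(w^2) + C * sum(pmax(eps, 0))))
  }
  K <- exp(-gamma * as.matrix(dist(X))^2)
  Q <- (y %*% t(y)) * K
  sol <- quadprog::solve.QP(
    Dmat = Q + diag(ridge, n), dvec = rep(1, n),
    Amat = cbind(y, diag(n), -diag(n)),
    bvec = c(0, rep(0, n), rep(-C, n)), meq = 1)
  a <- sol$solution
  as.numeric(0.5 * t(a) %*% Q %*% a - sum(a))
}

## rank-statistic AUC oracle: Mann-Whitney U / (P*N), ties counted 1/2
mann_whitney_auc <- function(scores, y_true) {
  sp <- scores[y_true == 1]; sn <- scores[y_true == -1]
  u <- 0
  for (a in sp) for (b in sn)
    u <- u + (a > b) + 0.5 * (a == b)
  u / (length(sp) * length(sn))
}

## random confusion table with all four counts
random_confusion <- function() {
  repeat {
    cts <- as.list(sample.int(20, 4, replace = TRUE))
    names(cts) <- c("TP", "TN", "FP", "FN")
    cts$P <- cts$TP + cts$FN; cts$N <- cts$FP + cts$TN
    return(structure(cts, class = "confusion_counts"))
  }
}

## features + bounds + split for a generated cohort, one call
pipeline_inputs <- function(cohort, g = 10, tol = 1e-12,
                            split_seed = 2) {
  gm <- compute_group_matrices(cohort)
  pairs <- build_voxel_pairs(gm$M, gm$N, tol = tol)
  feats <- assemble_feature_matrix(cohort, pairs)
  bounds <- feature_count_bounds(
    block_similarity(pairs, min(g, nrow(pairs))))
  split <- split_dataset(length(feats$y), feats$y, seed = split_seed)
  list(pairs = pairs, features = feats, bounds = bounds,
       split = split)
}

## planted-voxel recall / precision of a selected survey
survey_recovery <- function(rs_result, cohort) {
  truth0 <- which(as.vector(cohort$truth_mask)) - 1L
  sel <- rs_result$best$voxel_index
  hits <- sum(sel %in% truth0)
  list(recall = hits / max(length(truth0), 1),
       precision = hits / length(sel))
}
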