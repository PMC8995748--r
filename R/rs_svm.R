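#' Draw a random survey of feature columns
#'
#' Samples the survey size l uniformly from the integer interval
#' [C_max, C_min] given by the similarity bounds, then draws l
#' distinct column indices uniformly without replacement. Uses the
#' current RNG state, so a caller that fixes the seed gets a
#' reproducible sequence of surveys.
#'
#' @param n_columns number of available feature columns.
#' @param bounds a \code{feature_bounds}.
#' @return a \code{survey}: list with sorted 1-based column indices
#'   \code{R} and size \code{l}.
#' @export
draw_survey <- function(n_columns, bounds) {
  if (bounds$c_min > n_columns)
    stop("C_min (", bounds$c_min, ") exceeds the number of columns (",
         n_columns, ")")
  l <- as.integer(bounds$c_max) +
    sample.int(as.integer(bounds$c_min) - as.integer(bounds$c_max) + 1L,
               1L) - 1L
  R <- sort(sample.int(n_columns, l))
  structure(list(R = R, l = l), class = "survey")
}

#' Stratified train/validation/test split
#'
#' Splits subjects 6:2:2 within each class; remainder subjects are
#' assigned train-first (then validation, then test).
#'
#' @param n_subjects total subject count (>= 5).
#' @param y labels in \{-1, +1\}.
#' @param ratios split ratios; default \code{c(6, 2, 2)}.
#' @param seed integer seed for the shuffle.
#' @return a \code{split_spec}: list of disjoint, exhaustive index
#'   vectors \code{train_idx}, \code{val_idx}, \code{test_idx} plus
#'   \code{ratios} and \code{seed}.
#' @export
split_dataset <- function(n_subjects, y, ratios = c(6, 2, 2),
                          seed = 1L) {
  if (n_subjects < 5L) stop("need at least 5 subjects to split 6:2:2")
  if (length(y) != n_subjects) stop("'y' must have length 'n_subjects'")
  if (!all(c(-1, 1) %in% y))
    stop("both classes must be present to stratify the split")
  p <- ratios / sum(ratios)
  idx <- list(train = integer(0), val = integer(0), test = integer(0))
  withr::with_seed(as.integer(seed), {
    for (cls in c(-1, 1)) {
      members <- sample(which(y == cls))
      n <- length(members)
      n_tr <- floor(p[1] * n); n_va <- floor(p[2] * n)
      n_te <- floor(p[3] * n)
      rem <- n - n_tr - n_va - n_te
      add <- c(rem >= 1, rem >= 2, rem >= 3) # train-first
      n_tr <- n_tr + add[1]; n_va <- n_va + add[2]; n_te <- n_te + add[3]
      idx$train <- c(idx$train, members[seq_len(n_tr)])
      idx$val <- c(idx$val, members[n_tr + seq_len(n_va)])
      idx$test <- c(idx$test, members[n_tr + n_va + seq_len(n_te)])
    }
  })
  structure(list(train_idx = sort(idx$train), val_idx = sort(idx$val),
                 test_idx = sort(idx$test), ratios = ratios,
                 seed = as.integer(seed), stratified = TRUE),
            class = "split_spec")
}

#' Default SVM hyperparameter grid
#'
#' Linear and RBF kernels, C in \{0.1, 1, 10, 100\}, gamma in
#' \{0.001, 0.01, 0.1, 0.5, 1\} (gamma ignored for linear), so the
#' conventional starting point C = 1, gamma = 0.5 is always included.
#' Rows are ordered by the tie-break convention: smaller C first,
#' then smaller gamma, then linear before rbf.
#'
#' @return data.frame with columns kernel, C, gamma.
#' @export
default_svm_grid <- function() {
  g <- rbind(
    data.frame(kernel = "linear", C = c(0.1, 1, 10, 100), gamma = NA_real_),
    expand.grid(kernel = "rbf", C = c(0.1, 1, 10, 100),
                gamma = c(0.001, 0.01, 0.1, 0.5, 1),
                stringsAsFactors = FALSE))
  g[order(g$C, ifelse(is.na(g$gamma), 0, g$gamma),
          g$kernel != "linear"), , drop = FALSE]
}

#' Grid search for SVM hyperparameters on a validation set
#'
#' Fits each (kernel, C, gamma) point on the training set and scores
#' it by validation accuracy; returns the maximizer. Ties are broken
#' deterministically: smaller C, then smaller gamma, then linear
#' before rbf.
#'
#' @param X_train,y_train,X_val,y_val split data.
#' @param grid data.frame with columns kernel, C, gamma.
#' @return list with \code{best_params} (one-row data.frame),
#'   \code{val_accuracy}, \code{val_metrics} (a
#'   \code{metrics_report}) and the scored \code{grid}.
#' @export
grid_search <- function(X_train, y_train, X_val, y_val,
                        grid = default_svm_grid()) {
  if (nrow(grid) == 0L) stop("'grid' must be non-empty")
  grid <- grid[order(grid$C, ifelse(is.na(grid$gamma), 0, grid$gamma),
                     grid$kernel != "linear"), , drop = FALSE]
  acc <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    m <- train_svm(X_train, y_train, kernel = grid$kernel[i],
                   C = grid$C[i],
                   gamma = if (is.na(grid$gamma[i])) 0.5 else grid$gamma[i])
    acc[i] <- mean(predict(m, X_val, type = "class") == y_val)
  }
  best <- which.max(acc)  # first maximum respects the canonical order
  model <- train_svm(X_train, y_train, kernel = grid$kernel[best],
                     C = grid$C[best],
                     gamma = if (is.na(grid$gamma[best])) 0.5
                             else grid$gamma[best])
  vm <- metrics(confusion_counts(y_val, predict(model, X_val,
                                                type = "class")))
  grid$val_accuracy <- acc
  list(best_params = grid[best, c("kernel", "C", "gamma")],
       val_accuracy = acc[best], val_metrics = vm, grid = grid)
}

#' Run the random-survey SVM feature-selection loop
#'
#' Repeatedly draws a survey of feature columns with size in
#' [C_max, C_min], tunes a kernel SVM on the training/validation
#' split restricted to those columns, and evaluates the tuned model
#' on the held-out test set. The survey with the highest validation
#' accuracy (ties: smaller survey, then earlier survey) is selected
#' as the final feature set R.
#'
#' @param features a \code{feature_matrix}.
#' @param bounds a \code{feature_bounds}.
#' @param split a \code{split_spec}.
#' @param n_surveys number of surveys (default 200).
#' @param seed integer seed driving the survey draws.
#' @param grid hyperparameter grid (see [default_svm_grid()]).
#' @return an \code{rs_svm_result}: list with \code{best} (a
#'   \code{survey_result} carrying the selected columns, the mapped
#'   voxel indices, tuned hyperparameters, validation/test metrics
#'   and test decision scores) and \code{history} (one row per
#'   survey: survey_id, l, val_accuracy, test_accuracy).
#' @export
run_rs_svm <- function(features, bounds, split, n_surveys = 200,
                       seed = 1L, grid = default_svm_grid()) {
  if (n_surveys < 1L) stop("'n_surveys' must be at least 1")
  X <- features$X; y <- features$y
  tr <- split$train_idx; va <- split$val_idx; te <- split$test_idx
  surveys <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_surveys),
           function(i) draw_survey(ncol(X), bounds))
  })
  results <- vector("list", n_surveys)
  history <- data.frame(survey_id = seq_len(n_surveys),
                        l = NA_integer_, val_accuracy = NA_real_,
                        test_accuracy = NA_real_)
  for (i in seq_len(n_surveys)) {
    sv <- surveys[[i]]
    Xs <- X[, sv$R, drop = FALSE]
    gs <- grid_search(Xs[tr, , drop = FALSE], y[tr],
                      Xs[va, , drop = FALSE], y[va], grid)
    model <- train_svm(Xs[tr, , drop = FALSE], y[tr],
                       kernel = gs$best_params$kernel,
                       C = gs$best_params$C,
                       gamma = if (is.na(gs$best_params$gamma)) 0.5
                               else gs$best_params$gamma)
    test_scores <- predict(model, Xs[te, , drop = FALSE])
    test_pred <- ifelse(test_scores >= 0, 1, -1)
    tm <- metrics(confusion_counts(y[te], test_pred))
    results[[i]] <- structure(
      list(survey = sv,
           voxel_index = features$column_index[sv$R],
           best_params = gs$best_params,
           val_metrics = gs$val_metrics, test_metrics = tm,
           val_accuracy = gs$val_accuracy,
           test_accuracy = mean(test_pred == y[te]),
           test_scores = test_scores, test_y = y[te],
           accepted = FALSE),
      class = "survey_result")
    history$l[i] <- sv$l
    history$val_accuracy[i] <- gs$val_accuracy
    history$test_accuracy[i] <- results[[i]]$test_accuracy
  }
  ## argmax validation accuracy; ties -> smaller l, then earlier survey
  ord <- order(-history$val_accuracy, history$l, history$survey_id)
  best <- results[[ord[1]]]
  best$accepted <- TRUE
  structure(list(best = best, history = history, seed = seed,
                 n_surveys = n_surveys, bounds = bounds, split = split),
            class = "rs_svm_result")
}

#' @export
print.rs_svm_result <- function(x, ...) {
  cat(sprintf(
    "rs_svm_result: %d surveys; best l = %d, val acc = %.3f, test acc = %.3f (%s, C = %g%s)\n",
    x$n_surveys, x$best$survey$l, x$best$val_accuracy,
    x$best$test_accuracy, x$best$best_params$kernel,
    x$best$best_params$C,
    if (is.na(x$best$best_params$gamma)) ""
    else sprintf(", gamma = %g", x$best$best_params$gamma)))
  invisible(x)
}
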