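#' Confusion counts for binary labels
#'
#' Counts TP/TN/FP/FN with the positive class fixed as +1 (healthy
#' control under this package's label convention; disease is -1).
#'
#' @param y_true,y_pred label vectors in \{-1, +1\}, equal length.
#' @return a \code{confusion_counts}: list TP, TN, FP, FN, P, N.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("'y_true' and 'y_pred' lengths differ")
  if (!all(c(y_true, y_pred) %in% c(-1, 1)))
    stop("labels must be in {-1, +1}")
  structure(list(
    TP = sum(y_true == 1 & y_pred == 1),
    TN = sum(y_true == -1 & y_pred == -1),
    FP = sum(y_true == -1 & y_pred == 1),
    FN = sum(y_true == 1 & y_pred == -1),
    P = sum(y_true == 1), N = sum(y_true == -1)),
    class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy (TP+TN)/(P+N), precision TP/(TP+FP), recall TP/(TP+FN)
#' and the weighted F-measure
#' \deqn{F = \frac{(\alpha^2+1)\,P\,R}{\alpha^2 (P+R)}}
#' which at the default alpha = 1 reduces to the harmonic mean
#' 2PR/(P+R). (Note this weighting differs from the conventional
#' F_beta denominator for alpha != 1; the two coincide at alpha = 1.)
#' Ratios with a zero denominator are reported as \code{NA} and named
#' in the \code{undefined} field -- never silently coerced to 0.
#'
#' @param counts a \code{confusion_counts}.
#' @param alpha F-measure weight (default 1).
#' @return a \code{metrics_report}: accuracy, precision, recall,
#'   f_measure, alpha, undefined (character vector of metric names
#'   whose denominator was zero).
#' @export
metrics <- function(counts, alpha = 1) {
  with(counts, {
    if (P + N == 0) stop("no samples: P + N = 0")
    undef <- character(0)
    acc <- (TP + TN) / (P + N)
    prec <- if (TP + FP > 0) TP / (TP + FP) else {
      undef <- c(undef, "precision"); NA_real_ }
    rec <- if (TP + FN > 0) TP / (TP + FN) else {
      undef <- c(undef, "recall"); NA_real_ }
    f <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
      (alpha^2 + 1) * prec * rec / (alpha^2 * (prec + rec))
    else { undef <- c(undef, "f_measure"); NA_real_ }
    structure(list(accuracy = acc, precision = prec, recall = rec,
                   f_measure = f, alpha = alpha, undefined = undef),
              class = "metrics_report")
  })
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.3f  precision %s  recall %s  F %s",
              x$accuracy,
              ifelse(is.na(x$precision), "undefined",
                     sprintf("%.3f", x$precision)),
              ifelse(is.na(x$recall), "undefined",
                     sprintf("%.3f", x$recall)),
              ifelse(is.na(x$f_measure), "undefined",
                     sprintf("%.3f", x$f_measure))), "\n")
  invisible(x)
}

#' ROC curve and AUC from decision scores
#'
#' Sweeps thresholds over the unique scores, accumulating TPR/FPR,
#' and integrates by the trapezoidal rule; tied scores are grouped so
#' the curve steps diagonally through ties, which makes the AUC equal
#' to the Mann-Whitney rank statistic U/(P*N) with ties counted 1/2.
#'
#' @param scores numeric decision values (larger = more positive).
#' @param y_true labels in \{-1, +1\}; both classes required.
#' @return a \code{roc_curve}: thresholds, fpr, tpr (non-decreasing),
#'   auc.
#' @export
roc_auc <- function(scores, y_true) {
  if (length(scores) != length(y_true)) stop("length mismatch")
  if (length(unique(y_true)) < 2L)
    stop("both classes must be present to compute a ROC curve")
  P <- sum(y_true == 1); N <- sum(y_true == -1)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yt <- y_true[ord]
  ## group tied scores into single curve vertices
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(yt == 1); fp <- cumsum(yt == -1)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tpr <- c(0, tp[last] / P); fpr <- c(0, fp[last] / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = c(Inf, s[last]), fpr = fpr, tpr = tpr,
                 auc = auc),
            class = "roc_curve")
}

#' Repeated-split comparison of the five classifiers
#'
#' For each repetition a fresh stratified 6:2:2 split is drawn; the
#' random-survey SVM is run to select a feature set, and the four
#' comparison models (linear regression, Lasso, PLS, plain SVM) are
#' tuned on the validation set and evaluated on the test set.
#' Baselines use either the RS-SVM-selected columns
#' (\code{baseline_columns = "selected"}, the default) or all
#' retained voxels (\code{"all"}).
#'
#' @param features a \code{feature_matrix}.
#' @param bounds a \code{feature_bounds}.
#' @param models character subset of
#'   \code{c("linear", "lasso", "pls", "svm", "rs_svm")}.
#' @param n_repetitions number of repeated splits (default 10).
#' @param seed base seed; repetition r uses split seed
#'   \code{seed + r} and survey seed \code{seed + 1000 + r}.
#' @param n_surveys surveys per repetition for the RS-SVM.
#' @param baseline_columns \code{"selected"} or \code{"all"}.
#' @return a \code{comparison_report}: \code{accuracy} (long
#'   data.frame: repetition, model, split, accuracy), \code{metrics}
#'   (per repetition/model/split metric table), \code{roc} (per-model
#'   ROC of the final repetition), \code{auc}, and \code{spread}
#'   (max - min test accuracy per model across repetitions).
#' @export
compare_models <- function(features, bounds,
                           models = c("linear", "lasso", "pls",
                                      "svm", "rs_svm"),
                           n_repetitions = 10, seed = 1L,
                           n_surveys = 200,
                           baseline_columns = c("selected", "all")) {
  baseline_columns <- match.arg(baseline_columns)
  models <- match.arg(models, several.ok = TRUE)
  if (n_repetitions < 1L) stop("'n_repetitions' must be at least 1")
  X <- features$X; y <- features$y
  acc_rows <- list(); met_rows <- list(); roc <- list(); auc <- list()
  rs_results <- vector("list", n_repetitions)
  for (r in seq_len(n_repetitions)) {
    split <- split_dataset(length(y), y, seed = as.integer(seed) + r)
    tr <- split$train_idx; va <- split$val_idx; te <- split$test_idx
    cols <- seq_len(ncol(X))
    if ("rs_svm" %in% models || baseline_columns == "selected") {
      rs <- run_rs_svm(features, bounds, split, n_surveys = n_surveys,
                       seed = as.integer(seed) + 1000L + r)
      rs_results[[r]] <- rs
      if (baseline_columns == "selected") cols <- rs$best$survey$R
    }
    Xb <- X[, cols, drop = FALSE]
    score_one <- function(model_name) {
      if (model_name == "rs_svm") {
        list(val = rs$best$val_metrics, test = rs$best$test_metrics,
             scores = rs$best$test_scores)
      } else {
        fit <- tune_baseline(model_name, Xb[tr, , drop = FALSE], y[tr],
                             Xb[va, , drop = FALSE], y[va])
        val_pred <- predict(fit$model, Xb[va, , drop = FALSE],
                            type = "class")
        ts <- predict(fit$model, Xb[te, , drop = FALSE])
        list(val = metrics(confusion_counts(y[va], val_pred)),
             test = metrics(confusion_counts(y[te],
                                             ifelse(ts >= 0, 1, -1))),
             scores = ts)
      }
    }
    for (m in models) {
      res <- score_one(m)
      acc_rows[[length(acc_rows) + 1L]] <- data.frame(
        repetition = r, model = m,
        split = c("validation", "test"),
        accuracy = c(res$val$accuracy, res$test$accuracy))
      for (sp in c("validation", "test")) {
        mm <- if (sp == "validation") res$val else res$test
        met_rows[[length(met_rows) + 1L]] <- data.frame(
          repetition = r, model = m, split = sp,
          accuracy = mm$accuracy, precision = mm$precision,
          recall = mm$recall, f_measure = mm$f_measure)
      }
      if (r == n_repetitions) {
        rc <- roc_auc(res$scores, y[te])
        roc[[m]] <- data.frame(model = m, fpr = rc$fpr, tpr = rc$tpr)
        auc[[m]] <- rc$auc
      }
    }
  }
  accuracy <- do.call(rbind, acc_rows)
  test_acc <- accuracy[accuracy$split == "test", ]
  spread <- vapply(split(test_acc$accuracy, test_acc$model),
                   function(a) max(a) - min(a), numeric(1))
  structure(list(accuracy = accuracy,
                 metrics = do.call(rbind, met_rows),
                 roc = do.call(rbind, roc),
                 auc = unlist(auc), spread = spread,
                 n_repetitions = n_repetitions, seed = seed,
                 baseline_columns = baseline_columns,
                 rs_results = rs_results),
            class = "comparison_report")
}
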