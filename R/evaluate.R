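#' Rank-based ROC curve and AUC
#'
#' The AUC is computed from ranks (Mann-Whitney form, ties counted half),
#' which equals the trapezoidal area under the ROC curve of sensitivity
#' versus 1 - specificity. Both classes must be present.
#'
#' @param scores Numeric prediction scores (higher = more target-like).
#' @param labels Binary labels (logical, 0/1, or factor with levels 0/1).
#' @return List of class `roc_result`: `auc` and `roc` (data.frame of
#'   `fpr`, `tpr` points, monotone nondecreasing, from (0,0) to (1,1)).
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  stopifnot(length(scores) == length(y), all(is.finite(scores)))
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  grp_end <- cumsum(rle(ss)$lengths)
  tpr <- c(0, cumsum(ys)[grp_end] / n1)
  fpr <- c(0, cumsum(1L - ys)[grp_end] / n0)
  structure(list(auc = auc, roc = data.frame(fpr = fpr, tpr = tpr)),
            class = "roc_result")
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.logical(labels)) labels <- as.integer(labels)
  y <- as.integer(labels)
  if (any(is.na(y)) || !all(y %in% c(0L, 1L))) {
    stop("labels must be binary 0/1 without missing values")
  }
  y
}

#' Positive predictive value among the top-k predictions
#'
#' Fraction of the `top_k` highest-scoring items that are true positives.
#' Ties are broken by stable (input) order. At `top_k = n` the PPV equals
#' the class prevalence.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels.
#' @param top_k Number of top predictions to consider (1..n).
#' @return PPV in [0, 1].
#' @export
ppv <- function(scores, labels, top_k) {
  y <- as_binary_labels(labels)
  n <- length(scores)
  if (!is.numeric(top_k) || length(top_k) != 1L || top_k < 1L || top_k > n) {
    stop("top_k must be between 1 and the number of predictions")
  }
  idx <- order(-scores)[seq_len(top_k)]  # stable for ties
  mean(y[idx])
}

#' Repeated k-fold cross-validated training and evaluation
#'
#' The evaluation protocol of the target-prediction models: the data are
#' randomly split into `folds` equal parts (default two-fold, i.e. half
#' train / half test), the classifier is trained on the training part
#' (features standardised by training-fold statistics only) and scores the
#' held-out part; the AUC is computed per held-out fold. The whole split is
#' repeated `repeats` times and the mean AUC over all held-out folds
#' summarises the model. Splits are seeded and redrawn (up to 100 times) if
#' any fold lacks one of the classes.
#'
#' @param ft A `feature_table` from [assemble_features()].
#' @param repeats Number of random splits (study protocol: 50).
#' @param folds Number of folds per split (study protocol: 2).
#' @param seed Integer seed for the split RNG.
#' @param classifier A classifier contract, default [svm_classifier()].
#' @param min_positives Minimum number of positive genes required
#'   (default 10).
#' @return List of class `eval_result`: `auc` (mean over folds), `per_fold`
#'   data.frame, `per_repeat` mean AUC per repeat, `roc` points and
#'   `auc_pooled` computed from per-gene mean held-out scores, `ppv_topk`
#'   (PPV at k = number of positives), `scores` (per-gene mean held-out
#'   score), `n` and `n_pos`.
#' @export
cv_train_evaluate <- function(ft, repeats = 50L, folds = 2L, seed = 1L,
                              classifier = svm_classifier(),
                              min_positives = 10L) {
  stopifnot(inherits(ft, "feature_table"), inherits(classifier, "ct_classifier"),
            repeats >= 1L, folds >= 2L)
  x <- ft$x; y <- ft$y
  n <- nrow(x)
  n_pos <- sum(y == "1")
  if (n_pos < min_positives) {
    stop(sprintf("too few positives: %d < %d", n_pos, min_positives))
  }
  if (n_pos == n) stop("single-class data: no negatives")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  per_fold <- vector("list", repeats * folds)
  score_sum <- numeric(n); score_cnt <- integer(n)
  k <- 0L
  for (rep_i in seq_len(repeats)) {
    fold_of <- draw_folds(y, folds)
    for (f in seq_len(folds)) {
      test <- which(fold_of == f); train <- which(fold_of != f)
      std <- fold_standardize(x[train, , drop = FALSE], x[test, , drop = FALSE])
      model <- classifier$fit(std$train, droplevels(y[train]))
      sc <- classifier$score(model, std$test)
      k <- k + 1L
      per_fold[[k]] <- data.frame(rep = rep_i, fold = f,
                                  auc = roc_auc(sc, y[test])$auc)
      score_sum[test] <- score_sum[test] + sc
      score_cnt[test] <- score_cnt[test] + 1L
    }
  }
  per_fold <- do.call(rbind, per_fold)
  mean_scores <- score_sum / pmax(score_cnt, 1L)
  pooled <- roc_auc(mean_scores, y)
  structure(list(
    auc = mean(per_fold$auc),
    per_fold = per_fold,
    per_repeat = tapply(per_fold$auc, per_fold$rep, mean),
    auc_pooled = pooled$auc,
    roc = pooled$roc,
    ppv_topk = ppv(mean_scores, y, n_pos),
    scores = stats::setNames(mean_scores, ft$genes),
    n = n, n_pos = n_pos, repeats = repeats, folds = folds, seed = seed
  ), class = "eval_result")
}

draw_folds <- function(y, folds) {
  n <- length(y)
  for (try in seq_len(100L)) {
    fold_of <- sample(rep_len(seq_len(folds), n))
    ok <- all(vapply(seq_len(folds), function(f) {
      yt <- y[fold_of == f]
      length(unique(yt)) == 2L
    }, logical(1L)))
    if (ok) return(fold_of)
  }
  stop("could not draw folds containing both classes (100 attempts)")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "eval_result: mean AUC %.3f over %d x %d-fold CV (n = %d, positives = %d); pooled AUC %.3f, PPV@%d = %.3f\n",
    x$auc, x$repeats, x$folds, x$n, x$n_pos, x$auc_pooled, x$n_pos, x$ppv_topk))
  invisible(x)
}
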