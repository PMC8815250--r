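#' Random-forest configuration
#'
#' Hyperparameters for the signature-ranking classifier. Defaults follow the
#' classical random-forest convention (1000 trees, `mtry = floor(sqrt(p))`,
#' unlimited depth) with the study's 4-fold cross-validation and Brier
#' discard threshold of 1.
#'
#' @param n_trees Trees per forest.
#' @param mtry Features sampled per split; `NULL` means `floor(sqrt(p))`.
#' @param min_leaf Minimum terminal-node size.
#' @param k_folds Cross-validation folds (>= 2).
#' @param brier_threshold Subjects with Brier score strictly greater than
#'   this are discarded; in `(0, 2]`.
#' @param seed Integer RNG seed governing folds, bootstraps and feature
#'   sampling.
#' @return List of class `rf_config`.
#' @export
rf_config <- function(n_trees = 1000, mtry = NULL, min_leaf = 1,
                      k_folds = 4, brier_threshold = 1.0, seed = 1) {
  if (k_folds < 2) stop("k_folds must be >= 2")
  if (brier_threshold <= 0 || brier_threshold > 2)
    stop("brier_threshold must lie in (0, 2]")
  structure(list(n_trees = n_trees, mtry = mtry, min_leaf = min_leaf,
                 k_folds = k_folds, brier_threshold = brier_threshold,
                 seed = as.integer(seed)),
            class = "rf_config")
}

# stratified fold assignment: shuffle within each class, deal round-robin
stratified_folds <- function(labels, k) {
  if (any(table(labels) < k))
    stop("each class needs at least k_folds members for stratified folds")
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

check_features <- function(x, labels) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("feature matrix must have no missing entries")
  labels <- factor(as.character(labels), levels = c("S", "R"))
  if (any(table(labels) < 2)) stop("need >= 2 subjects per class")
  if (is.null(rownames(x))) rownames(x) <- sprintf("subj%03d", seq_len(nrow(x)))
  list(x = x, labels = labels)
}

#' Cross-validated class probabilities and Brier scores
#'
#' Predicts each subject exactly once from a forest trained without its
#' (stratified) fold. The predicted probability of the resistant class is
#' the fraction of trees voting R, and the per-subject Brier score uses the
#' two-class sum form `sum_k (p_k - y_k)^2`, which ranges over `[0, 2]` and
#' equals `2 * (1 - p_true)^2`.
#'
#' @param x Subjects x genes feature matrix (conventionally negative
#'   delta-Ct values); no missing entries.
#' @param labels `"S"`/`"R"` per subject; R is the positive class.
#' @param cfg An [rf_config()].
#' @return `data.frame`: `subject`, `label`, `fold`, `p_R`, `brier`.
#' @export
cv_predict <- function(x, labels, cfg = rf_config()) {
  cl <- check_features(x, labels)
  x <- cl$x; labels <- cl$labels
  set.seed(cfg$seed)
  fold <- stratified_folds(labels, cfg$k_folds)
  mtry <- if (is.null(cfg$mtry)) max(1, floor(sqrt(ncol(x)))) else cfg$mtry
  p_R <- numeric(nrow(x))
  for (f in seq_len(cfg$k_folds)) {
    test <- fold == f
    fit <- randomForest::randomForest(
      x = x[!test, , drop = FALSE], y = droplevels(labels[!test]),
      ntree = cfg$n_trees, mtry = mtry, nodesize = cfg$min_leaf)
    p_R[test] <- predict(fit, x[test, , drop = FALSE], type = "prob")[, "R"]
  }
  y_R <- as.numeric(labels == "R")
  brier <- (p_R - y_R)^2 + ((1 - p_R) - (1 - y_R))^2
  data.frame(subject = rownames(x), label = as.character(labels),
             fold = fold, p_R = p_R, brier = brier,
             stringsAsFactors = FALSE)
}

#' Discard high-uncertainty subjects by Brier score
#'
#' A subject is excluded if and only if its Brier score is strictly greater
#' than the threshold. With the two-class sum form, `brier > 1` is
#' equivalent to a predicted probability of the true class below
#' `1 - 1/sqrt(2)` (about 0.293).
#'
#' @param scores `data.frame` from [cv_predict()].
#' @param threshold Discard threshold (default 1).
#' @return Character vector of retained subject ids.
#' @export
brier_filter <- function(scores, threshold = 1.0) {
  stopifnot(all(c("subject", "brier") %in% names(scores)))
  scores$subject[scores$brier <= threshold]
}

#' Forest variable importance (MDA and MDG)
#'
#' Trains a fresh forest on the supplied subjects and reports, per gene,
#' the permutation importance (mean decrease in out-of-bag accuracy, scaled
#' by its standard error as conventional) and the total Gini impurity
#' decrease attributed to the gene (mean decrease Gini).
#'
#' @param x Subjects x genes matrix (typically the Brier-retained subjects).
#' @param labels `"S"`/`"R"` per subject.
#' @param cfg An [rf_config()].
#' @return List: `importance` (`data.frame` gene, mda, mdg) and `forest`
#'   (the fitted `randomForest` object).
#' @export
rf_importance <- function(x, labels, cfg = rf_config()) {
  cl <- check_features(x, labels)
  set.seed(cfg$seed + 1L)
  mtry <- if (is.null(cfg$mtry)) max(1, floor(sqrt(ncol(cl$x)))) else cfg$mtry
  fit <- randomForest::randomForest(
    x = cl$x, y = cl$labels, ntree = cfg$n_trees, mtry = mtry,
    nodesize = cfg$min_leaf, importance = TRUE)
  imp <- randomForest::importance(fit)
  list(importance = data.frame(gene = rownames(imp),
                               mda = unname(imp[, "MeanDecreaseAccuracy"]),
                               mdg = unname(imp[, "MeanDecreaseGini"]),
                               stringsAsFactors = FALSE),
       forest = fit)
}

#' Normalize importances to a 0-100 scale
#'
#' Linear min-max rescaling so the worst predictor scores 0 and the best
#' scores 100: `100 * (v - min) / (max - min)`. Invariant under positive
#' affine transforms of the input.
#'
#' @param values Numeric vector (>= 2 values, not all equal).
#' @return Vector of percentages in `[0, 100]`.
#' @export
normalize_importance <- function(values) {
  if (length(values) < 2) stop("need at least 2 values to normalize")
  rng <- range(values)
  if (diff(rng) == 0) stop("normalization undefined: all values equal")
  pmin(pmax(((values - rng[1]) / diff(rng)) * 100, 0), 100)
}

#' Mean-percent ranking score
#'
#' The per-gene ranking score is the arithmetic mean of the percent MDA and
#' percent MDG values.
#'
#' @param pct_mda,pct_mdg Percent importances in `[0, 100]`.
#' @return Ranking scores in `[0, 100]`.
#' @export
ranking_score <- function(pct_mda, pct_mdg) {
  if (any(pct_mda < 0 | pct_mda > 100 | pct_mdg < 0 | pct_mdg > 100))
    stop("percent importances must lie in [0, 100]")
  (pct_mda + pct_mdg) / 2
}

#' Classification performance from a confusion matrix
#'
#' Standard derived metrics with the resistant class positive. Percentages:
#' sensitivity `100*TP/(TP+FN)`, specificity `100*TN/(TN+FP)`, precision
#' `100*TP/(TP+FP)`, F1 `100*2TP/(2TP+FP+FN)`, accuracy
#' `100*(TP+TN)/total`; proportions: FPR `FP/(FP+TN)`, FDR `FP/(FP+TP)`,
#' FNR `FN/(FN+TP)`. A zero denominator yields `NA` (undefined), never 0.
#'
#' @param TP,TN,FP,FN Non-negative counts.
#' @return List of class `confusion_report` with the counts and all metrics.
#' @export
confusion_metrics <- function(TP, TN, FP, FN) {
  cts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(cts < 0)) stop("counts must be non-negative")
  div <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(
    TP = TP, TN = TN, FP = FP, FN = FN,
    sensitivity = 100 * div(TP, TP + FN),
    specificity = 100 * div(TN, TN + FP),
    precision   = 100 * div(TP, TP + FP),
    f1          = 100 * div(2 * TP, 2 * TP + FP + FN),
    accuracy    = 100 * div(TP + TN, TP + TN + FP + FN),
    fpr = div(FP, FP + TN),
    fdr = div(FP, FP + TP),
    fnr = div(FN, FN + TP)),
    class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  cat(sprintf("Confusion (R positive): TP %d  TN %d  FP %d  FN %d\n",
              x$TP, x$TN, x$FP, x$FN))
  cat(sprintf("  sensitivity %.2f  specificity %.2f  precision %.2f  F1 %.2f  accuracy %.2f\n",
              x$sensitivity, x$specificity, x$precision, x$f1, x$accuracy))
  cat(sprintf("  FPR %.4f  FDR %.4f  FNR %.4f\n", x$fpr, x$fdr, x$fnr))
  invisible(x)
}

confusion_from_scores <- function(scores) {
  pred_R <- scores$p_R > 0.5              # tie predicts sensitive
  true_R <- scores$label == "R"
  confusion_metrics(TP = sum(pred_R & true_R),
                    TN = sum(!pred_R & !true_R),
                    FP = sum(pred_R & !true_R),
                    FN = sum(!pred_R & true_R))
}

#' Brier-filtered random-forest signature ranking
#'
#' The central fitting function of the classifier stage. Runs stratified
#' k-fold cross-validation to obtain held-out class probabilities and
#' per-subject Brier scores, discards subjects with Brier score above the
#' threshold, re-runs cross-validation on the retained subjects for the
#' primary performance report, retrains a forest on all retained subjects
#' for the variable importances, and converts MDA and MDG to the 0-100
#' mean-percent ranking score.
#'
#' @param x Subjects x genes feature matrix (negative delta-Ct values by
#'   convention); row names are subject ids.
#' @param labels `"S"`/`"R"` per subject (R = resistant = positive class).
#' @param cfg An [rf_config()]; `...` is passed to [rf_config()] when `cfg`
#'   is not supplied.
#' @param ... Convenience hyperparameter overrides, e.g. `seed = 7`.
#' @return Object of class `rf_signature`: list with `scores` (pre-filter
#'   CV subject table with an `excluded` flag), `retained`, `scores_post`
#'   (post-filter CV table), `confusion_pre`, `confusion` (post-filter,
#'   primary), `importance` (gene, mda, mdg, pct_mda, pct_mdg, rank_score;
#'   sorted by rank_score), `forest` (final retrained forest), `config`.
#' @export
rf_signature <- function(x, labels, cfg = rf_config(...), ...) {
  scores <- cv_predict(x, labels, cfg)
  retained <- brier_filter(scores, cfg$brier_threshold)
  scores$excluded <- !(scores$subject %in% retained)
  if (length(retained) < 2 * cfg$k_folds)
    stop("too few subjects retained after Brier filtering")
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- scores$subject
  keep <- rownames(x) %in% retained
  cfg2 <- cfg; cfg2$seed <- cfg$seed + 2L
  scores_post <- cv_predict(x[keep, , drop = FALSE], labels[keep], cfg2)
  imp <- rf_importance(x[keep, , drop = FALSE], labels[keep], cfg)
  itab <- imp$importance
  itab$pct_mda <- normalize_importance(itab$mda)
  itab$pct_mdg <- normalize_importance(itab$mdg)
  itab$rank_score <- ranking_score(itab$pct_mda, itab$pct_mdg)
  itab <- itab[order(-itab$rank_score), ]
  rownames(itab) <- NULL
  structure(list(scores = scores, retained = retained,
                 scores_post = scores_post,
                 confusion_pre = confusion_from_scores(scores),
                 confusion = confusion_from_scores(scores_post),
                 importance = itab, forest = imp$forest, config = cfg),
            class = "rf_signature")
}

#' @export
print.rf_signature <- function(x, ...) {
  cat(sprintf("Random-forest signature: %d genes, %d/%d subjects retained (Brier <= %g)\n",
              nrow(x$importance), length(x$retained), nrow(x$scores),
              x$config$brier_threshold))
  cat("Top genes by mean-percent ranking score:\n")
  print(head(x$importance, 5), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.rf_signature <- function(object, ...) {
  print(object)
  cat("\nHeld-out performance on retained subjects:\n")
  print(object$confusion)
  invisible(object)
}

#' @export
predict.rf_signature <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  p <- predict(object$forest, as.matrix(newdata), type = "prob")[, "R"]
  if (type == "prob") return(p)
  factor(ifelse(p > 0.5, "R", "S"), levels = c("S", "R"))
}

#' @export
plot.rf_signature <- function(x, ...) {
  imp <- x$importance[order(x$importance$rank_score), ]
  barplot(imp$rank_score, names.arg = imp$gene, horiz = TRUE, las = 1,
          xlab = "mean percent (MDA%, MDG%)",
          main = "Gene ranking score", ...)
  invisible(x)
}
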