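# Evaluation: 3x3 confusion matrices, accuracy / precision / recall / F1 with
# macro and support-weighted averaging, and per-class, micro- and
# macro-average one-vs-rest ROC curves with trapezoidal AUC.

#' 3x3 confusion matrix
#'
#' Counts records by true class (rows) versus predicted class (columns), in
#' canonical class order (`normal`, `drusen`, `cnv`).
#'
#' @param truth,predicted Equal-length label vectors over the three classes.
#' @return A 3x3 integer matrix with named dimensions.
#' @export
confusion_matrix3 <- function(truth, predicted) {
  truth <- as_oct_factor(truth)
  predicted <- as_oct_factor(predicted)
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length", call. = FALSE)
  }
  cm <- table(truth = truth, predicted = predicted)
  matrix(as.integer(cm), 3, 3, dimnames = list(truth = OCT_CLASSES, predicted = OCT_CLASSES))
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy plus per-class precision, recall and F1, with both macro
#' (unweighted mean over classes) and support-weighted averages reported
#' explicitly. A zero denominator (no predicted or no true instances of a
#' class) yields 0 for that metric, with a warning; F1 is 0 when precision
#' and recall are both 0.
#'
#' @param cm A 3x3 confusion matrix (rows true, columns predicted).
#' @return A list of class `metrics_report`: `accuracy`, `per_class` (tibble
#'   with precision/recall/f1/support), `macro` and `weighted` (named
#'   vectors over precision/recall/f1).
#' @export
classification_metrics <- function(cm) {
  cm <- as.matrix(cm)
  if (!all(dim(cm) == c(3L, 3L)) || any(cm < 0)) {
    stop("cm must be a 3x3 matrix of non-negative counts", call. = FALSE)
  }
  total <- sum(cm)
  if (total == 0) stop("confusion matrix is empty", call. = FALSE)
  diagv <- diag(cm)
  colsum <- colSums(cm)
  rowsum <- rowSums(cm)
  if (any(colsum == 0) || any(rowsum == 0)) {
    warning("class with zero predicted or true instances: metric set to 0",
            call. = FALSE)
  }
  precision <- ifelse(colsum > 0, diagv / colsum, 0)
  recall <- ifelse(rowsum > 0, diagv / rowsum, 0)
  f1 <- ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
  wts <- rowsum / total
  structure(list(
    accuracy = sum(diagv) / total,
    per_class = tibble::tibble(class = OCT_CLASSES, precision = as.numeric(precision),
                               recall = as.numeric(recall), f1 = as.numeric(f1),
                               support = as.integer(rowsum)),
    macro = c(precision = mean(precision), recall = mean(recall), f1 = mean(f1)),
    weighted = c(precision = sum(wts * precision), recall = sum(wts * recall),
                 f1 = sum(wts * f1))
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> accuracy %.4f | macro P %.4f R %.4f F1 %.4f\n",
              x$accuracy, x$macro["precision"], x$macro["recall"], x$macro["f1"]))
  print(x$per_class)
  invisible(x)
}

# Binary ROC with tie grouping: one operating point per distinct score, so
# uninformative (all-equal) scores give the chance diagonal and AUC is exactly
# the Mann-Whitney statistic with ties counted 1/2.
binary_roc <- function(pos, scores) {
  n_pos <- sum(pos); n_neg <- sum(!pos)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  last <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tie group
  tp <- cumsum(p)[last]; fp <- cumsum(!p)[last]
  fpr <- c(0, fp / n_neg); tpr <- c(0, tp / n_pos)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' Multiclass ROC analysis
#'
#' One-vs-rest ROC per class from the class's probability column, plus a
#' micro-average ROC (all `(record, class)` binary decisions pooled into a
#' single curve) and a macro-average ROC (per-class true-positive rates
#' averaged exactly on the union of all per-class false-positive-rate
#' breakpoints, with trapezoidal AUC). Tied scores are grouped into a single
#' operating point, making each per-class AUC equal to the pairwise
#' Mann-Whitney probability. A class with no positive (or no negative)
#' records has its curve omitted with a warning and the macro average is
#' taken over the remaining classes.
#'
#' @param truth True labels over the three classes.
#' @param proba Probability matrix, one row per record, columns in canonical
#'   class order, rows summing to 1.
#' @return A list of class `roc_result`: `per_class` (named list of
#'   `fpr`/`tpr`/`auc`), `micro`, and `macro`.
#' @export
roc_analysis <- function(truth, proba) {
  truth <- as_oct_factor(truth)
  proba <- as.matrix(proba)
  if (nrow(proba) != length(truth) || ncol(proba) != 3L) {
    stop("proba must be an n x 3 matrix matching truth", call. = FALSE)
  }
  if (any(abs(rowSums(proba) - 1) > 1e-6) || any(proba < -1e-9)) {
    stop("probability rows must be non-negative and sum to 1", call. = FALSE)
  }
  per_class <- stats::setNames(vector("list", 3L), OCT_CLASSES)
  for (k in 1:3) {
    pos <- truth == OCT_CLASSES[k]
    if (sum(pos) == 0L || sum(!pos) == 0L) {
      warning("class '", OCT_CLASSES[k],
              "' has no positives or no negatives; curve omitted", call. = FALSE)
      next
    }
    per_class[[k]] <- binary_roc(pos, proba[, k])
  }
  per_class <- per_class[!vapply(per_class, is.null, logical(1))]
  if (length(per_class) == 0L) stop("no class has both positives and negatives", call. = FALSE)

  onehot <- outer(as.integer(truth), 1:3, "==")
  micro <- binary_roc(as.vector(onehot), as.vector(proba))

  grid <- sort(unique(c(0, 1, unlist(lapply(per_class, `[[`, "fpr")))))
  tprs <- vapply(per_class, function(r) {
    # curves can be set-valued at a breakpoint (vertical segments); the upper
    # envelope is the right value for piecewise-linear averaging
    ymax <- tapply(r$tpr, r$fpr, max)
    xs <- as.numeric(names(ymax))
    stats::approx(xs, as.numeric(ymax), xout = grid, rule = 2)$y
  }, numeric(length(grid)))
  mean_tpr <- rowMeans(tprs)
  macro_auc <- sum(diff(grid) * (utils::head(mean_tpr, -1) + utils::tail(mean_tpr, -1)) / 2)
  if (mean_tpr[1] > 0) {     # vertical segment at fpr 0: anchor the curve at (0,0)
    grid <- c(0, grid)
    mean_tpr <- c(0, mean_tpr)
  }

  structure(list(per_class = per_class, micro = micro,
                 macro = list(fpr = grid, tpr = mean_tpr, auc = macro_auc)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  aucs <- vapply(x$per_class, `[[`, numeric(1), "auc")
  cat("<roc_result> per-class AUC:",
      paste(sprintf("%s %.4f", names(aucs), aucs), collapse = ", "),
      sprintf("| micro %.4f | macro %.4f\n", x$micro$auc, x$macro$auc))
  invisible(x)
}

#' Evaluate a trained classifier on labeled records
#'
#' Convenience wrapper producing hard predictions, the confusion matrix,
#' [classification_metrics()] and [roc_analysis()] in one call.
#'
#' @param model A trained classifier.
#' @param images Named list of images.
#' @param truth True labels.
#' @return List with `confusion`, `metrics`, `roc`, `accuracy`.
#' @export
evaluate_model <- function(model, images, truth) {
  truth <- as_oct_factor(truth)
  proba <- predict_proba(model, images)
  pred <- factor(OCT_CLASSES[max.col(proba, ties.method = "first")], levels = OCT_CLASSES)
  cm <- confusion_matrix3(truth, pred)
  metrics <- classification_metrics(cm)
  roc <- tryCatch(roc_analysis(truth, proba), error = function(e) {
    warning("ROC undefined on this evaluation set: ", conditionMessage(e),
            call. = FALSE)
    NULL
  })
  list(confusion = cm, metrics = metrics, roc = roc, accuracy = metrics$accuracy)
}

# AUC accessor tolerating a degenerate (omitted) ROC result.
roc_auc <- function(roc, which = c("micro", "macro")) {
  which <- match.arg(which)
  if (is.null(roc)) NA_real_ else roc[[which]]$auc
}
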