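# One-vs-rest evaluation: confusion matrix, per-class sensitivity /
# specificity / accuracy / AUC, overall accuracy and macro mean AUC.

#' Confusion matrix of true versus predicted labels
#'
#' @param true_labels,predicted_labels equal-length label vectors over the
#'   class vocabulary.
#' @param classes class vocabulary fixing row/column order; defaults to the
#'   sorted union of observed labels.
#' @return an n_classes x n_classes count matrix, rows = true class,
#'   columns = predicted class.
#' @export
confusion_matrix <- function(true_labels, predicted_labels, classes = NULL) {
  if (length(true_labels) == 0L) stop("label vectors must be non-empty")
  if (length(true_labels) != length(predicted_labels))
    stop("true and predicted label vectors must have equal length")
  if (is.null(classes)) classes <- sort(unique(c(true_labels, predicted_labels)))
  bad <- setdiff(unique(c(true_labels, predicted_labels)), classes)
  if (length(bad))
    stop(sprintf("unknown label(s): %s", paste(bad, collapse = ", ")))
  tt <- table(factor(true_labels, levels = classes),
              factor(predicted_labels, levels = classes))
  m <- matrix(as.integer(tt), nrow = length(classes),
              dimnames = list(true = classes, predicted = classes))
  m
}

# One-vs-rest AUC via the rank statistic (equivalent to trapezoidal
# integration of the ROC curve with midpoint handling of score ties).
auc_ovr <- function(scores, positive) {
  np <- sum(positive); nn <- sum(!positive)
  if (np == 0L || nn == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

#' Per-class one-vs-rest metrics
#'
#' For each class k, treating k as positive and all others as negative:
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), accuracy =
#' (TP+TN)/N, and (when scores are supplied) the one-vs-rest ROC AUC of the
#' class-k probability. AUC for a class absent from the truth is reported as
#' `NA` with a warning; mean AUC is the unweighted mean over classes with a
#' defined AUC.
#'
#' @param confusion a [confusion_matrix()] (rows true, columns predicted).
#' @param scores optional N x n_classes matrix of class probabilities whose
#'   columns follow the confusion-matrix class order.
#' @param true_labels labels aligned with `scores` rows (required with
#'   `scores`).
#' @return a data frame with one row per class: sensitivity, specificity,
#'   accuracy, auc; attributes `overall_accuracy` and `mean_auc`.
#' @export
per_class_metrics <- function(confusion, scores = NULL, true_labels = NULL) {
  classes <- rownames(confusion)
  n <- sum(confusion)
  tp <- diag(confusion)
  fn <- rowSums(confusion) - tp
  fp <- colSums(confusion) - tp
  tn <- n - tp - fn - fp
  out <- data.frame(class = classes,
                    sensitivity = tp / (tp + fn),
                    specificity = tn / (tn + fp),
                    accuracy = (tp + tn) / n,
                    auc = NA_real_, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(scores)) {
    if (is.null(true_labels) || length(true_labels) != nrow(scores))
      stop("true_labels aligned with the score rows are required for AUC")
    for (k in seq_along(classes)) {
      pos <- true_labels == classes[k]
      if (!any(pos)) {
        warning(sprintf("class '%s' absent from truth; AUC undefined",
                        classes[k]))
        next
      }
      out$auc[k] <- auc_ovr(scores[, k], pos)
    }
  }
  attr(out, "overall_accuracy") <- sum(tp) / n
  attr(out, "mean_auc") <- if (all(is.na(out$auc))) NA_real_
                           else mean(out$auc, na.rm = TRUE)
  out
}

#' Evaluate a fitted model on a manifest split
#'
#' Runs a deterministic evaluation-mode pass over the requested split and
#' assembles the confusion matrix, per-class one-vs-rest metrics, overall
#' accuracy and macro mean AUC. Refuses splits whose subjects overlap the
#' training subjects.
#'
#' @param object a fitted `"echo_gcnn"`.
#' @param manifest manifest data frame (with a `split` column if `split` is
#'   given).
#' @param split which split to evaluate (default `"test"`); `NULL` evaluates
#'   every row.
#' @param images optional in-memory image store.
#' @return a list of class `"eval_report"`: `confusion`, `per_class`,
#'   `overall_accuracy`, `mean_auc`, `n`.
#' @export
evaluate_model <- function(object, manifest, split = "test", images = NULL) {
  stopifnot(inherits(object, "echo_gcnn"))
  rows <- if (!is.null(split)) {
    if (!"split" %in% names(manifest)) stop("manifest has no split column")
    manifest[manifest$split == split, , drop = FALSE]
  } else manifest
  if (nrow(rows) == 0L) stop("no images in the requested split")
  if (!identical(split, "train")) {
    overlap <- intersect(unique(rows$subject_id), object$train_subjects)
    if (length(overlap))
      stop(sprintf("evaluation subjects overlap training subjects: %s",
                   paste(overlap, collapse = ", ")))
  }
  attr(rows, "dir") <- attr(manifest, "dir")
  store <- image_store(rows, images, object$net$config$input_size)
  x <- stack_images(rows$image_id, store, object$net$config$input_size)
  probs <- predict_probs(object$net, x)
  colnames(probs) <- object$classes
  pred <- object$classes[max.col(probs, ties.method = "first")]
  conf <- confusion_matrix(rows$view_label, pred, classes = object$classes)
  pc <- per_class_metrics(conf, scores = probs, true_labels = rows$view_label)
  structure(list(confusion = conf, per_class = pc,
                 overall_accuracy = attr(pc, "overall_accuracy"),
                 mean_auc = attr(pc, "mean_auc"), n = nrow(rows)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  cat(sprintf("Evaluation over %d images\n", x$n))
  cat(sprintf("  overall accuracy: %.*f   mean AUC: %.*f\n",
              digits, x$overall_accuracy, digits, x$mean_auc))
  print(format(x$per_class, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Produces three text artifacts: the full report as JSON, the per-class
#' metric table as CSV (Cardiac View, Sensitivity, Specificity, Accuracy,
#' AUC), and the confusion matrix as CSV in row-percent form (each row of
#' true labels normalized to percentages of predicted labels).
#'
#' @param report an `"eval_report"`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_eval_report <- function(report, dir) {
  stopifnot(inherits(report, "eval_report"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop(sprintf("cannot create directory '%s'", dir))
  jp <- file.path(dir, "eval_report.json")
  jsonlite::write_json(list(
    confusion = report$confusion, classes = rownames(report$confusion),
    per_class = report$per_class,
    overall_accuracy = report$overall_accuracy,
    mean_auc = report$mean_auc, n = report$n),
    jp, auto_unbox = TRUE, digits = NA)
  tab <- data.frame(`Cardiac View` = report$per_class$class,
                    Sensitivity = report$per_class$sensitivity,
                    Specificity = report$per_class$specificity,
                    Accuracy = report$per_class$accuracy,
                    AUC = report$per_class$auc, check.names = FALSE)
  mp <- file.path(dir, "per_class_metrics.csv")
  utils::write.csv(tab, mp, row.names = FALSE)
  rp <- report$confusion / pmax(rowSums(report$confusion), 1) * 100
  cp <- file.path(dir, "confusion_row_percent.csv")
  utils::write.csv(as.data.frame(rp), cp, row.names = TRUE)
  invisible(c(jp, mp, cp))
}
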