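# Evaluation: confusion matrix, one-vs-rest precision/recall/F1 per class,
# overall accuracy, and the comparative report for the rule system (scored
# on its non-blank subset, blanks counted separately) versus the ML models
# (scored on the blank test set).
#
# Undefined metrics (empty denominators) are NA, never silently 0, and are
# excluded -- with a count -- from macro averages.

#' Multi-class confusion matrix
#'
#' @param truth,pred Equal-length label vectors (rows = truth, columns =
#'   prediction).
#' @param classes Class list defining row/column order; defaults to the
#'   sorted union of observed labels.  Labels outside `classes` are an
#'   error.
#' @return K x K integer matrix of counts.
#' @export
confusion_matrix <- function(truth, pred, classes = NULL) {
  if (length(truth) != length(pred)) {
    stop("truth and pred must have equal length", call. = FALSE)
  }
  if (length(truth) == 0L) stop("cannot tabulate empty labels", call. = FALSE)
  if (is.null(classes)) classes <- sort(unique(c(truth, pred)))
  bad <- setdiff(unique(c(truth, pred)), classes)
  if (length(bad) > 0L) {
    stop("labels outside the declared class list: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  tab <- table(factor(truth, levels = classes),
               factor(pred, levels = classes))
  m <- matrix(as.integer(tab), nrow = length(classes),
              dimnames = list(truth = classes, pred = classes))
  m
}

#' Per-class precision, recall and F1 from a confusion matrix
#'
#' One-vs-rest counts per class; precision = TP/(TP+FP), recall =
#' TP/(TP+FN), F1 = 2PR/(P+R).  Metrics with an empty denominator are `NA`
#' (undefined), which is distinct from 0.
#'
#' @param confusion K x K count matrix (rows = truth).
#' @return data.frame with one row per class: `class`, `support`, `tp`,
#'   `fp`, `fn`, `tn`, `precision`, `recall`, `f1`.
#' @export
class_metrics <- function(confusion) {
  stopifnot(is.matrix(confusion), nrow(confusion) == ncol(confusion),
            nrow(confusion) >= 2L)
  total <- sum(confusion)
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  tn <- total - tp - fp - fn
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall),
               ifelse(is.na(precision) | is.na(recall), NA_real_, NA_real_))
  # P = R = 0 gives an empty F1 denominator: undefined, not 0
  data.frame(class = rownames(confusion), support = as.integer(tp + fn),
             tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
             tn = as.integer(tn), precision = precision, recall = recall,
             f1 = f1, row.names = NULL, stringsAsFactors = FALSE)
}

#' Overall accuracy of a confusion matrix
#'
#' The multi-class reading of (TP + TN) / (TP + TN + FP + FN): the fraction
#' of series on the diagonal.
#'
#' @param confusion K x K count matrix.
#' @return Proportion in `[0, 1]`.
#' @export
overall_accuracy <- function(confusion) {
  stopifnot(is.matrix(confusion))
  if (sum(confusion) == 0) {
    stop("confusion matrix is empty", call. = FALSE)
  }
  sum(diag(confusion)) / sum(confusion)
}

.macro_average <- function(metrics) {
  avg <- function(v) list(mean = mean(v[!is.na(v)]),
                          n_undefined = sum(is.na(v)))
  list(precision = avg(metrics$precision), recall = avg(metrics$recall),
       f1 = avg(metrics$f1))
}

.micro_average <- function(confusion) {
  tp <- sum(diag(confusion))
  # single-label multi-class: micro precision = micro recall = accuracy
  list(precision = tp / sum(confusion), recall = tp / sum(confusion))
}

.build_report <- function(truth, pred, classes, blank_count = NA_integer_) {
  conf <- confusion_matrix(truth, pred, classes)
  metrics <- class_metrics(conf)
  structure(list(
    confusion = conf,
    per_class = metrics,
    overall_accuracy = overall_accuracy(conf),
    macro = .macro_average(metrics),
    micro = .micro_average(conf),
    support = stats::setNames(metrics$support, metrics$class),
    n = length(truth),
    blank_count = blank_count
  ), class = "seq_eval_report")
}

#' @export
print.seq_eval_report <- function(x, ...) {
  cat(sprintf("<seq_eval_report> n = %d, overall accuracy = %.3f", x$n,
              x$overall_accuracy))
  if (!is.na(x$blank_count)) cat(sprintf(", blanks = %d", x$blank_count))
  cat("\n  (headline averages are macro over defined classes;",
      "micro equals overall accuracy)\n")
  df <- x$per_class[, c("class", "support", "precision", "recall", "f1")]
  df[, 3:5] <- round(df[, 3:5], 3)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Comparative evaluation of the rule system and the ML models
#'
#' Scores the rule-based labeler on its non-blank subset (the blank count is
#' reported separately, never in the denominator) and the ML models on the
#' blank test set.
#'
#' @param truth Ground-truth labels for all series.
#' @param rule_decisions A [label_dataset()] result aligned with `truth`.
#' @param ml_virtual_pred,ml_human_pred Predicted labels for the blank
#'   subset (in blank-index order), or full-length vectors from which the
#'   blank subset is taken.  `ml_human_pred` may be `NULL`.
#' @param classes Optional class list for matrix ordering.
#' @return List of class `seq_eval_comparison` with elements `rule`,
#'   `ml_virtual`, `ml_human` (each a `seq_eval_report`, or `NULL`).
#' @export
evaluate_system <- function(truth, rule_decisions, ml_virtual_pred = NULL,
                            ml_human_pred = NULL, classes = NULL) {
  stopifnot(length(truth) == nrow(rule_decisions))
  part <- attr(rule_decisions, "partition")
  blank <- part$blank
  labeled <- part$labeled

  take_blank <- function(pred) {
    if (is.null(pred)) return(NULL)
    if (length(pred) == length(truth)) return(pred[blank])
    if (length(pred) == length(blank)) return(pred)
    stop("prediction vector length matches neither the full set nor the ",
         "blank subset", call. = FALSE)
  }

  rule_report <- if (length(labeled) > 0L) {
    .build_report(truth[labeled], rule_decisions$label[labeled], classes,
                  blank_count = length(blank))
  } else NULL
  mlv <- take_blank(ml_virtual_pred)
  mlh <- take_blank(ml_human_pred)
  structure(list(
    rule = rule_report,
    ml_virtual = if (!is.null(mlv) && length(blank) > 0L) {
      .build_report(truth[blank], mlv, classes)
    } else NULL,
    ml_human = if (!is.null(mlh) && length(blank) > 0L) {
      .build_report(truth[blank], mlh, classes)
    } else NULL
  ), class = "seq_eval_comparison")
}

#' Write an evaluation report as CSV files
#'
#' Writes `<stem>_per_class.csv` (per-class metrics) and
#' `<stem>_confusion.csv`.
#'
#' @param report A `seq_eval_report`.
#' @param stem Output path stem.
#' @return The per-class CSV path, invisibly.
#' @export
write_report <- function(report, stem) {
  stopifnot(inherits(report, "seq_eval_report"))
  per_class_path <- paste0(stem, "_per_class.csv")
  utils::write.csv(report$per_class, per_class_path, row.names = FALSE)
  conf_wide <- as.data.frame.matrix(report$confusion)
  conf_wide <- cbind(truth = rownames(conf_wide), conf_wide)
  utils::write.csv(conf_wide, paste0(stem, "_confusion.csv"),
                   row.names = FALSE)
  invisible(per_class_path)
}
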