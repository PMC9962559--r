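#' Confusion matrix of oxidation predictions
#'
#' Cross-tabulates true against predicted classes. Rows are true classes,
#' columns predicted classes, both in the fixed order Good, Fair, Bad.
#'
#' @param truth,predicted Label vectors of equal length with values in
#'   [oxidation_levels].
#' @return A 3 x 3 `table` of class `c("confusion_matrix", "table")`.
#' @export
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted) || length(truth) == 0)
    stop_invalid("truth and predicted must have equal, positive length")
  tt <- as_oxidation_factor(truth)
  pp <- as_oxidation_factor(predicted)
  structure(table(true = tt, predicted = pp),
            class = c("confusion_matrix", "table"))
}

#' Per-class precision, recall, F1 and support
#'
#' For each class: precision = TP / (TP + FP), recall = TP / (TP + FN),
#' F1 = 2 * precision * recall / (precision + recall). A class never
#' predicted gets precision 0 (with a warning); a class with zero support
#' gets recall 0 (with a warning); F1 is 0 when precision + recall is 0.
#'
#' @param cm A [confusion()] matrix.
#' @return data.frame with columns `class`, `precision`, `recall`, `f1`,
#'   `support`.
#' @export
class_metrics <- function(cm) {
  cm <- unclass(cm)
  if (any(cm < 0)) stop_invalid("confusion counts must be >= 0")
  tp <- diag(cm)
  pred_pos <- colSums(cm)
  support <- rowSums(cm)
  if (any(pred_pos == 0))
    warning("class(es) never predicted: precision set to 0 for ",
            paste(rownames(cm)[pred_pos == 0], collapse = ", "))
  if (any(support == 0))
    warning("class(es) with zero support: recall set to 0 for ",
            paste(rownames(cm)[support == 0], collapse = ", "))
  precision <- ifelse(pred_pos > 0, tp / pred_pos, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  pr <- precision + recall
  f1 <- ifelse(pr > 0, 2 * precision * recall / pr, 0)
  data.frame(class = rownames(cm), precision = unname(precision),
             recall = unname(recall), f1 = unname(f1),
             support = unname(as.integer(support)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Support-weighted average F1
#'
#' @param metrics A [class_metrics()] data.frame (or a confusion matrix).
#' @return The support-weighted mean of the per-class F1 scores.
#' @export
weighted_f1 <- function(metrics) {
  if (inherits(metrics, "confusion_matrix")) metrics <- class_metrics(metrics)
  if (sum(metrics$support) == 0) stop_invalid("total support is zero")
  sum(metrics$f1 * metrics$support) / sum(metrics$support)
}

# Support-weighted averages of all three metrics.
weighted_metrics <- function(metrics) {
  w <- metrics$support / sum(metrics$support)
  c(precision = sum(metrics$precision * w),
    recall = sum(metrics$recall * w),
    f1 = sum(metrics$f1 * w))
}

#' Evaluation report for one test set
#'
#' Computes the confusion matrix, per-class metrics and overall summaries for
#' one model evaluation. Two overall summaries are reported: the pooled
#' micro-average (`accuracy`, identical for precision and recall) and the
#' support-weighted macro averages of precision, recall and F1.
#'
#' @param truth,predicted Label vectors, as for [confusion()].
#' @return An object of class `"eval_report"`: list with `confusion`,
#'   `per_class` (the [class_metrics()] table), `accuracy`,
#'   `weighted` (named vector: precision, recall, f1), `n`.
#' @export
eval_report <- function(truth, predicted) {
  cm <- confusion(truth, predicted)
  pc <- class_metrics(cm)
  structure(list(confusion = cm, per_class = pc,
                 accuracy = sum(diag(unclass(cm))) / sum(cm),
                 weighted = weighted_metrics(pc),
                 n = sum(cm)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  cat("Evaluation report (n =", x$n, ")\n")
  print(x$confusion)
  df <- x$per_class
  df[2:4] <- lapply(df[2:4], round, digits)
  print(df, row.names = FALSE)
  cat(sprintf("accuracy (micro) %.4f; weighted precision %.4f, recall %.4f, F1 %.4f\n",
              x$accuracy, x$weighted["precision"], x$weighted["recall"],
              x$weighted["f1"]))
  invisible(x)
}

#' Aggregate evaluation reports across training repetitions
#'
#' Combines the reports of repeated, independently trained sessions into
#' per-class medians and interquartile ranges (25th/75th percentiles, linear
#' interpolation) for precision, recall and F1, plus overall medians of the
#' pooled micro-accuracy and of the support-weighted macro metrics.
#' `total_tests` is `n_repetitions * test-set size`.
#'
#' @param reports List of [eval_report()] objects with identical class sets
#'   and supports.
#' @return An object of class `"eval_aggregate"`: list with `per_class`
#'   (data.frame: class, metric, median, q25, q75), `overall_weighted`,
#'   `overall_micro`, `support`, `n_repetitions`, `total_tests`.
#' @export
aggregate_repetitions <- function(reports) {
  if (length(reports) < 1) stop_invalid("need at least one report")
  supports <- vapply(reports, function(r) r$per_class$support,
                     numeric(nrow(reports[[1]]$per_class)))
  supports <- matrix(supports, ncol = length(reports))
  if (any(supports != supports[, 1]))
    stop_invalid("reports have inconsistent per-class supports")
  support <- reports[[1]]$per_class$support
  classes <- reports[[1]]$per_class$class
  iqr3 <- function(v) unname(quantile(v, c(0.5, 0.25, 0.75), type = 7))
  rows <- list()
  for (m in c("precision", "recall", "f1")) {
    vals <- vapply(reports, function(r) r$per_class[[m]],
                   numeric(length(classes)))
    vals <- matrix(vals, ncol = length(reports))
    for (i in seq_along(classes)) {
      q <- iqr3(vals[i, ])
      rows[[length(rows) + 1]] <- data.frame(
        class = classes[i], metric = m, median = q[1], q25 = q[2],
        q75 = q[3], stringsAsFactors = FALSE)
    }
  }
  per_class <- do.call(rbind, rows)
  ow <- vapply(c("precision", "recall", "f1"), function(m) {
    iqr3(vapply(reports, function(r) unname(r$weighted[m]), numeric(1)))
  }, numeric(3))
  om <- iqr3(vapply(reports, function(r) r$accuracy, numeric(1)))
  structure(list(per_class = per_class,
                 overall_weighted = data.frame(
                   metric = c("precision", "recall", "f1"),
                   median = ow[1, ], q25 = ow[2, ], q75 = ow[3, ],
                   row.names = NULL),
                 overall_micro = c(median = om[1], q25 = om[2], q75 = om[3]),
                 support = stats::setNames(support, classes),
                 n_repetitions = length(reports),
                 total_tests = length(reports) * sum(support)),
            class = "eval_aggregate")
}

#' @export
print.eval_aggregate <- function(x, ...) {
  cat(sprintf(
    "Aggregate over %d repetitions (support %s; %d total tests)\n",
    x$n_repetitions,
    paste(sprintf("%s=%d", names(x$support), x$support), collapse = ", "),
    x$total_tests))
  fmt <- function(m, q1, q3) sprintf("%.3f [%.3f, %.3f]", m, q1, q3)
  for (m in c("precision", "recall", "f1")) {
    pc <- x$per_class[x$per_class$metric == m, ]
    ov <- x$overall_weighted[x$overall_weighted$metric == m, ]
    cat(sprintf("  %-9s %s | overall (weighted) %s\n", m,
                paste(sprintf("%s %s", pc$class,
                              fmt(pc$median, pc$q25, pc$q75)),
                      collapse = "  "),
                fmt(ov$median, ov$q25, ov$q75)))
  }
  cat(sprintf("  accuracy (micro, median [IQR]) %s\n",
              fmt(x$overall_micro["median"], x$overall_micro["q25"],
                  x$overall_micro["q75"])))
  invisible(x)
}

#' Write an aggregate report as a performance table
#'
#' Emits the aggregate in the conventional benchmark-table shape: one column
#' per class (Bad, Fair, Good) plus an Overall column (support-weighted), one
#' row each for repetitions, support, total tests and the median \[IQR\] of
#' precision, recall and F1.
#'
#' @param aggregate An [aggregate_repetitions()] result.
#' @param file Output CSV path.
#' @return Invisibly, the table data.frame.
#' @export
report_table <- function(aggregate, file = NULL) {
  cols <- c("Bad", "Fair", "Good")
  fmt <- function(m, q1, q3, pct) {
    if (pct) sprintf("%.0f%% [%.0f%%, %.0f%%]", 100 * m, 100 * q1, 100 * q3)
    else sprintf("%.2f [%.2f, %.2f]", m, q1, q3)
  }
  metric_row <- function(metric, pct) {
    vals <- vapply(cols, function(cl) {
      r <- aggregate$per_class[aggregate$per_class$class == cl &
                                 aggregate$per_class$metric == metric, ]
      fmt(r$median, r$q25, r$q75, pct)
    }, character(1))
    ov <- aggregate$overall_weighted[
      aggregate$overall_weighted$metric == metric, ]
    c(vals, Overall = fmt(ov$median, ov$q25, ov$q75, pct))
  }
  tab <- rbind(
    repetitions = c(rep(aggregate$n_repetitions, 3),
                    aggregate$n_repetitions),
    support = c(aggregate$support[cols], sum(aggregate$support)),
    total_tests = c(aggregate$n_repetitions * aggregate$support[cols],
                    aggregate$total_tests),
    `precision (median [IQR])` = metric_row("precision", TRUE),
    `recall (median [IQR])` = metric_row("recall", TRUE),
    `f1 (median [IQR])` = metric_row("f1", FALSE))
  df <- data.frame(quantity = rownames(tab), tab, row.names = NULL,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("quantity", cols, "Overall")
  if (!is.null(file)) write.csv(df, file, row.names = FALSE)
  invisible(df)
}
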