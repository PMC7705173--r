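#' Sample-by-sample classification metrics
#'
#' Scores a predicted decision stream against ground truth at the
#' decision rate: overall accuracy (trace of the confusion matrix over
#' its total), per-class recall (`n_ii / sum_j n_ij`, also the per-class
#' recognition rate), precision (`n_ii / sum_j n_ji`), F1 (harmonic mean
#' of the two), and their macro (unweighted class mean) and weighted
#' (class-frequency-weighted) averages. A class absent from the true
#' labels has undefined recall/F1 and is reported as `NaN` with a count
#' of 0; macro averages skip undefined entries.
#'
#' @param true_labels,predicted_labels Aligned label vectors.
#' @param classes Class set (default the fused gait classes).
#' @return A `metrics_report`: list with `accuracy`, `per_class`
#'   (data.frame: class, n, recall, precision, f1), `macro`, `weighted`,
#'   `confusion`, `n_windows`, `classes`, `chance_level`.
#' @export
score <- function(true_labels, predicted_labels, classes = GAIT_CLASSES) {
  if (!length(true_labels)) stop("empty label sequence")
  cm <- estimate_confusion(true_labels, predicted_labels, classes)
  n <- sum(cm)
  diagv <- diag(unclass(cm))
  row_tot <- rowSums(cm)
  col_tot <- colSums(cm)
  recall <- ifelse(row_tot > 0, diagv / row_tot, NaN)
  precision <- ifelse(col_tot > 0, diagv / col_tot, NaN)
  f1 <- ifelse(is.nan(recall) | is.nan(precision) | (precision + recall) == 0,
               ifelse(is.nan(recall), NaN, 0),
               2 * precision * recall / (precision + recall))
  per_class <- data.frame(class = classes, n = as.integer(row_tot),
                          recall = recall, precision = precision, f1 = f1,
                          row.names = NULL)
  macro <- c(recall = mean(recall, na.rm = TRUE),
             precision = mean(precision, na.rm = TRUE),
             f1 = mean(f1, na.rm = TRUE))
  wts <- row_tot / n
  weighted <- c(recall = sum(wts * recall, na.rm = TRUE),
                precision = sum(wts * precision, na.rm = TRUE),
                f1 = sum(wts * f1, na.rm = TRUE))
  structure(list(accuracy = sum(diagv) / n, per_class = per_class,
                 macro = macro, weighted = weighted, confusion = cm,
                 n_windows = n, classes = classes,
                 chance_level = 1 / length(classes)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> accuracy %.3f over %d windows (chance %.2f)\n",
              x$accuracy, x$n_windows, x$chance_level))
  print(x$per_class, digits = 3)
  cat(sprintf("macro: recall %.3f, precision %.3f, F1 %.3f\n",
              x$macro["recall"], x$macro["precision"], x$macro["f1"]))
  invisible(x)
}

#' Long-format comparison of decoder x condition reports
#'
#' Flattens a two-level list of [score()] reports (condition, then
#' decoder) into a long table (decoder, regime, level, metric, value) —
#' the layout from which accuracy-vs-degradation curves and per-class
#' recognition-rate curves are drawn. All reports must cover the same
#' test windows.
#'
#' @param reports Named list of conditions; each element a named list of
#'   `metrics_report`s keyed by decoder (e.g. `emg`, `eeg`, `fused`).
#' @param regime Regime label stored in the table (e.g. `"temporary"`).
#' @return A data.frame with columns `decoder`, `regime`, `level`,
#'   `metric`, `class`, `value`.
#' @export
compare_conditions <- function(reports, regime = NA_character_) {
  n_ref <- NULL
  rows <- list()
  for (level in names(reports)) {
    for (decoder in names(reports[[level]])) {
      rep <- reports[[level]][[decoder]]
      if (!inherits(rep, "metrics_report")) next
      if (is.null(n_ref)) n_ref <- rep$n_windows
      if (rep$n_windows != n_ref && length(rep$classes) == 3) {
        stop("reports cover different numbers of test windows")
      }
      rows[[length(rows) + 1L]] <- rbind(
        data.frame(decoder = decoder, regime = regime, level = level,
                   metric = "accuracy", class = NA_character_,
                   value = rep$accuracy),
        data.frame(decoder = decoder, regime = regime, level = level,
                   metric = rep(c("recall", "precision", "f1"),
                                each = nrow(rep$per_class)),
                   class = rep$per_class$class,
                   value = c(rep$per_class$recall, rep$per_class$precision,
                             rep$per_class$f1)),
        data.frame(decoder = decoder, regime = regime, level = level,
                   metric = c("macro_recall", "macro_precision", "macro_f1"),
                   class = NA_character_,
                   value = unname(rep$macro)))
    }
  }
  do.call(rbind, rows)
}
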