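#' Four-class confusion table
#'
#' Rows are the true condition, columns the prediction, both in the fixed
#' [beat_classes()] order. Built either from a 4x4 count matrix or from
#' paired true/predicted label vectors.
#'
#' @param counts 4x4 non-negative integer matrix (rows = true).
#' @param classes class names, defaults to [beat_classes()].
#' @return An object of class `confusion_table`.
#' @export
#' @examples
#' ct <- confusion_table(diag(4) * 10)
#' accuracy(ct)
confusion_table <- function(counts, classes = beat_classes()) {
  counts <- as.matrix(counts)
  k <- length(classes)
  if (!all(dim(counts) == c(k, k))) {
    stop("counts must be a ", k, "x", k, " matrix", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  dimnames(counts) <- list(true = classes, predicted = classes)
  structure(counts, class = c("confusion_table", "matrix"))
}

#' @rdname confusion_table
#' @param true,predicted vectors of class labels (character or factor with
#'   levels in `classes`).
#' @export
confusion_from_labels <- function(true, predicted, classes = beat_classes()) {
  t_f <- factor(as.character(true), levels = classes)
  p_f <- factor(as.character(predicted), levels = classes)
  if (anyNA(t_f) || anyNA(p_f)) {
    stop("labels outside the class set", call. = FALSE)
  }
  confusion_table(unclass(table(t_f, p_f)), classes)
}

#' @export
print.confusion_table <- function(x, ...) {
  cat("<confusion_table> rows = true, columns = predicted\n")
  print(unclass(x))
  invisible(x)
}

#' Read / write a confusion table as CSV
#'
#' Plain CSV with class names as row and column headers.
#'
#' @param path file path.
#' @export
read_confusion_csv <- function(path) {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  confusion_table(m, classes = rownames(m))
}

#' @rdname read_confusion_csv
#' @param ct a [confusion_table()].
#' @export
write_confusion_csv <- function(ct, path) {
  utils::write.csv(as.data.frame(unclass(ct)), path)
  invisible(path)
}

#' Overall accuracy
#'
#' The correct rate of the overall judgment: `trace / total`.
#'
#' @param ct a [confusion_table()].
#' @return Fraction in `[0, 1]`.
#' @export
accuracy <- function(ct) {
  stopifnot(inherits(ct, "confusion_table"))
  tot <- sum(ct)
  if (tot == 0) stop("undefined metric: empty confusion table", call. = FALSE)
  sum(diag(ct)) / tot
}

#' Per-class recall, precision and F1
#'
#' `recall_k = ct[k,k] / rowsum_k` (how many actual positives are judged
#' correctly), `precision_k = ct[k,k] / colsum_k` (proportion of actual
#' positives among positive predictions), and
#' `F1 = 2 * precision * recall / (precision + recall)`. A class with a zero
#' row or column sum gets `NA` for the affected metric (flagged undefined,
#' never reported as 0).
#'
#' @param ct a [confusion_table()].
#' @return data.frame with columns `class`, `recall`, `precision`, `f1`.
#' @export
per_class_metrics <- function(ct) {
  stopifnot(inherits(ct, "confusion_table"))
  if (sum(ct) == 0) stop("undefined metric: empty confusion table", call. = FALSE)
  d <- diag(ct)
  rs <- rowSums(ct)
  cs <- colSums(ct)
  recall <- ifelse(rs > 0, d / rs, NA_real_)
  precision <- ifelse(cs > 0, d / cs, NA_real_)
  f1 <- ifelse(!is.na(recall) & !is.na(precision) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall), NA_real_)
  data.frame(class = rownames(ct), recall = recall, precision = precision,
             f1 = f1, row.names = NULL)
}

#' Macro-averaged recall, precision and F1
#'
#' Macro recall and precision are unweighted means over classes. The macro
#' F1 is, by this package's primary convention, the harmonic mean of macro
#' precision and macro recall; `f1_convention = "mean_per_class"` returns
#' the arithmetic mean of the per-class F1 scores instead.
#'
#' @param ct a [confusion_table()].
#' @param f1_convention `"macro_harmonic"` (default) or `"mean_per_class"`.
#' @return Named list `macro_recall`, `macro_precision`, `macro_f1`.
#' @export
macro_metrics <- function(ct, f1_convention = c("macro_harmonic",
                                                "mean_per_class")) {
  f1_convention <- match.arg(f1_convention)
  pc <- per_class_metrics(ct)
  if (anyNA(pc[c("recall", "precision", "f1")])) {
    stop("undefined metric: a class has a zero row or column sum",
         call. = FALSE)
  }
  mr <- mean(pc$recall)
  mp <- mean(pc$precision)
  mf <- switch(f1_convention,
               macro_harmonic = 2 * mp * mr / (mp + mr),
               mean_per_class = mean(pc$f1))
  list(macro_recall = mr, macro_precision = mp, macro_f1 = mf)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement between prediction and truth:
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement
#' `p_o = trace / total` and chance agreement
#' `p_e = sum_k rowsum_k * colsum_k / total^2`.
#'
#' @param ct a [confusion_table()].
#' @return Value in `[-1, 1]`.
#' @export
cohens_kappa <- function(ct) {
  stopifnot(inherits(ct, "confusion_table"))
  tot <- sum(ct)
  if (tot == 0) stop("undefined metric: empty confusion table", call. = FALSE)
  po <- sum(diag(ct)) / tot
  pe <- sum(rowSums(ct) * colSums(ct)) / tot^2
  if (pe >= 1) {
    stop("undefined metric: degenerate table (chance agreement = 1)",
         call. = FALSE)
  }
  (po - pe) / (1 - pe)
}

#' Full metrics report for a confusion table
#'
#' Bundles accuracy, per-class metrics, macro aggregates and Cohen's kappa.
#' Values are carried at full precision; rounding (e.g. 3 or 5 decimal
#' places) happens only in the print method.
#'
#' @param ct a [confusion_table()].
#' @param f1_convention see [macro_metrics()].
#' @param partial if `TRUE`, report `NA` macro aggregates when a class has a
#'   zero row or column sum instead of raising an undefined-metric error.
#' @return An object of class `metrics_report`.
#' @export
metrics_report <- function(ct, f1_convention = "macro_harmonic",
                           partial = FALSE) {
  mm <- if (partial) {
    tryCatch(macro_metrics(ct, f1_convention),
             error = function(e) list(macro_recall = NA_real_,
                                      macro_precision = NA_real_,
                                      macro_f1 = NA_real_))
  } else {
    macro_metrics(ct, f1_convention)
  }
  structure(list(accuracy = accuracy(ct),
                 per_class = per_class_metrics(ct),
                 macro_recall = mm$macro_recall,
                 macro_precision = mm$macro_precision,
                 macro_f1 = mm$macro_f1,
                 kappa = cohens_kappa(ct),
                 n = sum(ct),
                 f1_convention = f1_convention),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 5, class_digits = 3, ...) {
  cat(sprintf("<metrics_report> n = %d\n", x$n))
  pc <- x$per_class
  pc[-1] <- lapply(pc[-1], round, class_digits)
  print(pc, row.names = FALSE)
  cat(sprintf("accuracy  %.*f\nrecall    %.*f (macro)\nprecision %.*f (macro)\nF1        %.*f (%s)\nkappa     %.*f\n",
              digits, x$accuracy, digits, x$macro_recall,
              digits, x$macro_precision, digits, x$macro_f1,
              x$f1_convention, digits, x$kappa))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(accuracy = x$accuracy, macro_recall = x$macro_recall,
             macro_precision = x$macro_precision, macro_f1 = x$macro_f1,
             kappa = x$kappa, n = x$n)
}
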