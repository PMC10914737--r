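#' Per-class binary classification metrics
#'
#' For each ADL, the prediction probabilities are binarized at `threshold` and
#' compared with the binary labels over the evaluated (labeled) time steps,
#' yielding the confusion counts TP/FP/FN/TN and the derived metrics:
#' precision = TP/(TP+FP), recall (TPR) = TP/(TP+FN), TNR = TN/(TN+FP),
#' balanced accuracy = (TPR + TNR)/2 (the mean per-class recall of the binary
#' task), micro-averaged F1 (precision and recall pooled over the positive and
#' negative class, which for a binary task equals accuracy), macro-averaged F1
#' (the mean of the two per-class F1 scores), and the log loss
#' `-(1/N) sum_i sum_j y_ij log p_ij` over the two classes. A class with no
#' positive labeled step gets `NA` recall (undefined, not 0).
#'
#' @param y `T x C` binary label matrix (columns named by class) or a vector
#'   for a single class.
#' @param p Matching matrix/vector of predicted probabilities.
#' @param weights Optional length-`T` non-negative weights; steps with zero
#'   weight are excluded from evaluation.
#' @param threshold Binarization threshold.
#' @return A tibble of class `"metrics_report"`: one row per class plus an
#'   `"(mean)"` aggregate row, with columns `class`, `tp`, `fp`, `fn`, `tn`,
#'   `precision`, `recall`, `tnr`, `balanced_accuracy`, `f1_micro`,
#'   `f1_macro`, `logloss`.
#' @export
per_class_metrics <- function(y, p, weights = NULL, threshold = 0.5) {
  if (is.null(dim(y))) y <- matrix(y, ncol = 1, dimnames = list(NULL, "class"))
  if (is.null(dim(p))) p <- matrix(p, ncol = 1)
  stopifnot(all(dim(y) == dim(p)))
  if (!is.null(weights)) {
    keep <- weights > 0
    y <- y[keep, , drop = FALSE]
    p <- p[keep, , drop = FALSE]
  }
  classes <- colnames(y) %||% paste0("class", seq_len(ncol(y)))
  eps <- 1e-15
  rows <- lapply(seq_len(ncol(y)), function(c) {
    yc <- y[, c]
    pc <- p[, c]
    yhat <- as.integer(pc >= threshold)
    tp <- sum(yc == 1 & yhat == 1)
    fp <- sum(yc == 0 & yhat == 1)
    fn <- sum(yc == 1 & yhat == 0)
    tn <- sum(yc == 0 & yhat == 0)
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    tnr <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    bal_acc <- mean(c(recall, tnr)) # NA-propagating: undefined stays undefined
    # micro: pool counts over the positive and negative class of this
    # binary task; micro precision = micro recall = accuracy
    n <- tp + fp + fn + tn
    f1_micro <- if (n > 0) (tp + tn) / n else NA_real_
    f1_pos <- if (!is.na(precision) && !is.na(recall) &&
                  precision + recall > 0)
      2 * precision * recall / (precision + recall) else NA_real_
    prec_neg <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
    rec_neg <- tnr
    f1_neg <- if (!is.na(prec_neg) && !is.na(rec_neg) &&
                  prec_neg + rec_neg > 0)
      2 * prec_neg * rec_neg / (prec_neg + rec_neg) else NA_real_
    f1_macro <- mean(c(f1_pos, f1_neg))
    pcl <- pmin(pmax(pc, eps), 1 - eps)
    logloss <- if (n > 0)
      -mean(yc * log(pcl) + (1 - yc) * log(1 - pcl)) else NA_real_
    tibble::tibble(class = classes[c], tp = tp, fp = fp, fn = fn, tn = tn,
                   precision = precision, recall = recall, tnr = tnr,
                   balanced_accuracy = bal_acc, f1_micro = f1_micro,
                   f1_macro = f1_macro, logloss = logloss)
  })
  out <- dplyr::bind_rows(rows)
  agg <- dplyr::summarise(out, class = "(mean)",
                          dplyr::across(c(tp, fp, fn, tn), sum),
                          dplyr::across(c(precision, recall, tnr,
                                          balanced_accuracy, f1_micro,
                                          f1_macro, logloss),
                                        ~ mean(.x, na.rm = TRUE)))
  structure(dplyr::bind_rows(out, agg),
            class = c("metrics_report", class(tibble::tibble())))
}

#' Flatten one time step's prediction and label sets into pairs
#'
#' The multi-label prediction and label sets of a time step are converted to
#' single-prediction/single-label pairs in three steps: (1) activities present
#' in both sets are matched exactly; (2) while both sets still hold unmatched
#' activities, they are matched in seeded-random order (these show up as
#' confused activities off the diagonal); (3) leftover labels pair with the
#' `"false negative"` sentinel and leftover predictions with the
#' `"false positive"` sentinel. The pair count is always
#' `max(|preds|, |labels|)`.
#'
#' @param preds Character vector (set) of predicted ADLs.
#' @param labels Character vector (set) of labeled ADLs.
#' @return A tibble with columns `label` and `pred`.
#' @export
#' @examples
#' set.seed(7)
#' flatten_pairs(c("watching tv", "using phone", "room transition"),
#'               c("watching tv", "toileting", "organizing", "other"))
flatten_pairs <- function(preds, labels) {
  preds <- unique(preds)
  labels <- unique(labels)
  exact <- intersect(labels, preds)
  rest_l <- setdiff(labels, exact)
  rest_p <- setdiff(preds, exact)
  # step 2: arbitrary-order cross matching, seeded by the caller's RNG state
  if (length(rest_l) > 1) rest_l <- sample(rest_l)
  if (length(rest_p) > 1) rest_p <- sample(rest_p)
  m <- min(length(rest_l), length(rest_p))
  out_label <- c(exact, rest_l[seq_len(m)])
  out_pred <- c(exact, rest_p[seq_len(m)])
  if (length(rest_l) > m) {
    out_label <- c(out_label, rest_l[(m + 1):length(rest_l)])
    out_pred <- c(out_pred, rep(.sentinels[["fn"]], length(rest_l) - m))
  }
  if (length(rest_p) > m) {
    out_label <- c(out_label, rep(.sentinels[["fp"]], length(rest_p) - m))
    out_pred <- c(out_pred, rest_p[(m + 1):length(rest_p)])
  }
  tibble::tibble(label = out_label, pred = out_pred)
}

#' Accumulate flattened pairs into the joint 13 x 13 confusion matrix
#'
#' Rows are the 12 labeled ADLs plus a `"false positive"` row (predictions
#' without any label); columns are the 12 predicted ADLs plus a
#' `"false negative"` column (labels without any prediction). The total count
#' equals the sum over time steps of `max(|preds_t|, |labels_t|)`.
#'
#' @param pairs A tibble of pairs from [flatten_pairs()] (rows from many time
#'   steps concatenated).
#' @return A 13 x 13 integer matrix of class `"full_confusion"`.
#' @export
accumulate_confusion <- function(pairs) {
  reg <- adl_registry()
  rn <- c(reg, .sentinels[["fp"]])
  cn <- c(reg, .sentinels[["fn"]])
  m <- matrix(0L, 13, 13, dimnames = list(label = rn, pred = cn))
  if (nrow(pairs) > 0) {
    tab <- table(factor(pairs$label, levels = rn),
                 factor(pairs$pred, levels = cn))
    m <- m + unclass(tab)
  }
  structure(m, class = c("full_confusion", "matrix", "array"))
}

#' Flatten a whole session of multi-label predictions
#'
#' Binarizes the predicted probabilities at `threshold`, restricts to steps
#' with positive label weight, and runs the three-step matching at every step.
#'
#' @param probs `T x 12` predicted probability matrix.
#' @param Y `T x 12` binary label matrix.
#' @param w Length-`T` weights (0 = unlabeled, excluded).
#' @param threshold Binarization threshold.
#' @param seed Seed for the arbitrary-order matching of step 2 (recorded as an
#'   attribute of the result).
#' @return A `"full_confusion"` matrix with attribute `seed`.
#' @export
flatten_session <- function(probs, Y, w, threshold = 0.5, seed = 1) {
  reg <- adl_registry()
  set.seed(seed)
  keep <- which(w > 0)
  pieces <- lapply(keep, function(t) {
    flatten_pairs(reg[probs[t, ] >= threshold], reg[Y[t, ] == 1])
  })
  out <- accumulate_confusion(dplyr::bind_rows(pieces))
  attr(out, "seed") <- seed
  out
}

#' Aggregate per-participant metric reports
#'
#' Mean and standard deviation of every metric across participants, per class.
#' A class missing (NA) for some participant is excluded from that cell's mean
#' with a note in the `n` column.
#'
#' @param reports A list of `"metrics_report"` tibbles, one per participant.
#' @return A tibble with columns `class`, `metric`, `mean`, `sd`, `n`.
#' @export
aggregate_over_participants <- function(reports) {
  if (length(reports) < 2) {
    stop("need at least 2 participants to aggregate", call. = FALSE)
  }
  long <- dplyr::bind_rows(reports, .id = "participant")
  long <- tidyr::pivot_longer(
    long, cols = c("precision", "recall", "tnr", "balanced_accuracy",
                   "f1_micro", "f1_macro", "logloss"),
    names_to = "metric", values_to = "value")
  dplyr::summarise(
    long,
    mean = mean(value[!is.na(value)]),
    sd = stats::sd(value[!is.na(value)]),
    n = sum(!is.na(value)),
    .by = c("class", "metric"))
}

#' @export
print.full_confusion <- function(x, ...) {
  cat("<full_confusion> 13 x 13, total pairs:", sum(x), "\n")
  print(unclass(x))
  invisible(x)
}
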