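# Literal transcriptions of the printed metric definitions, kept deliberately
# naive (explicit loops) and independent of the package implementation.
oracle_metrics <- function(y, p, threshold) {
  yhat <- ifelse(p >= threshold, 1, 0)
  tp <- 0; fp <- 0; fn <- 0; tn <- 0
  for (i in seq_along(y)) {
    if (y[i] == 1 && yhat[i] == 1) tp <- tp + 1
    if (y[i] == 0 && yhat[i] == 1) fp <- fp + 1
    if (y[i] == 1 && yhat[i] == 0) fn <- fn + 1
    if (y[i] == 0 && yhat[i] == 0) tn <- tn + 1
  }
  precision <- tp / (tp + fp)                      # Precision = TP/(TP+FP)
  recall <- tp / (tp + fn)                         # Recall = TP/(TP+FN)
  # per-class precision/recall of the negative class
  precision_neg <- tn / (tn + fn)
  recall_neg <- tn / (tn + fp)
  # micro: precision and recall pooled globally across the two classes
  prec_micro <- (tp + tn) / (tp + tn + fp + fn)
  rec_micro <- (tp + tn) / (tp + tn + fn + fp)
  f1_micro <- 2 * (prec_micro * rec_micro) / (prec_micro + rec_micro)
  # macro: per-class F1 averaged
  f1_pos <- 2 * (precision * recall) / (precision + recall)
  f1_neg <- 2 * (precision_neg * recall_neg) / (precision_neg + recall_neg)
  f1_macro <- (f1_pos + f1_neg) / 2
  # balanced accuracy: mean per-class recall
  bal_acc <- (recall + recall_neg) / 2
  # logloss = -(1/N) sum_i sum_j y_ij log p_ij over the two classes
  eps <- 1e-15
  ll <- 0
  for (i in seq_along(y)) {
    pi1 <- min(max(p[i], eps), 1 - eps)
    ll <- ll + y[i] * log(pi1) + (1 - y[i]) * log(1 - pi1)
  }
  logloss <- -ll / length(y)
  list(precision = precision, recall = recall, tnr = recall_neg,
       balanced_accuracy = bal_acc, f1_micro = f1_micro, f1_macro = f1_macro,
       logloss = logloss)
}

test_that("per-class metrics match hand-derived worked examples", {
  # perfect predictions
  y <- c(1, 0, 1, 1, 0)
  p <- c(0.9, 0.1, 0.8, 0.99, 0.2)
  r <- per_class_metrics(y, p)
  row <- r[r$class != "(mean)", ]
  expect_equal(row$precision, 1)
  expect_equal(row$recall, 1)
  expect_lt(row$logloss, 0.2)
  # counts TP=3, FP=1, FN=2 -> precision 0.75, recall 0.6
  y <- c(1, 1, 1, 0, 1, 1)
  p <- c(1, 1, 1, 1, 0, 0)
  r <- per_class_metrics(y, p)[1, ]
  expect_equal(r$tp, 3); expect_equal(r$fp, 1); expect_equal(r$fn, 2)
  expect_equal(r$precision, 0.75)
  expect_equal(r$recall, 0.6)
  # y = (1, 0), p = (0.5, 0.5) -> logloss = ln 2
  r <- per_class_metrics(c(1, 0), c(0.5, 0.5))[1, ]
  expect_equal(r$logloss, log(2), tolerance = 1e-12)
  # a class with zero positives reports recall as missing, not 0
  r <- per_class_metrics(c(0, 0, 0), c(0.1, 0.2, 0.6))[1, ]
  expect_true(is.na(r$recall))
  expect_true(is.na(r$balanced_accuracy))
  expect_false(is.na(r$tnr))
})

test_that("metrics agree with the literal transcription on random inputs", {
  set.seed(1234)
  worst <- 0
  for (i in 1:1000) {
    n <- sample(3:40, 1)
    y <- stats::rbinom(n, 1, stats::runif(1, 0.2, 0.8))
    if (all(y == 1) || all(y == 0)) y[1:2] <- c(0, 1) # both classes present
    p <- stats::runif(n)
    thr <- stats::runif(1, 0.2, 0.8)
    got <- per_class_metrics(y, p, threshold = thr)[1, ]
    want <- oracle_metrics(y, p, thr)
    for (m in names(want)) {
      if (is.na(want[[m]]) || is.nan(want[[m]])) next
      worst <- max(worst, abs(got[[m]] - want[[m]]))
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("weighted steps outside the mask are excluded", {
  y <- matrix(c(1, 0, 1, 0), ncol = 1)
  p <- matrix(c(0.9, 0.9, 0.1, 0.1), ncol = 1)
  r_all <- per_class_metrics(y, p)
  r_masked <- per_class_metrics(y, p, weights = c(1, 0, 0, 1))
  expect_equal(r_masked$tp[1], 1)
  expect_equal(r_masked$tn[1], 1)
  expect_equal(r_masked$balanced_accuracy[1], 1)
  expect_lt(r_all$balanced_accuracy[1], 1)
})

test_that("flattening reproduces the worked narrative examples", {
  set.seed(7)
  # more labels than predictions: WatchingTV matches exactly; Toileting and
  # Organizing cross-match with UsingPhone and RoomTransition; Other pairs
  # with the false-negative sentinel
  pairs <- flatten_pairs(
    preds = c("watching tv", "using phone", "room transition"),
    labels = c("watching tv", "toileting", "organizing", "other"))
  expect_equal(nrow(pairs), 4)
  expect_true(any(pairs$label == "watching tv" & pairs$pred == "watching tv"))
  crossed <- pairs[pairs$label %in% c("toileting", "organizing"), ]
  expect_setequal(crossed$pred, c("using phone", "room transition"))
  expect_equal(pairs$pred[pairs$label == "other"], "false negative")
  # more predictions than labels: the spare prediction is a false positive
  pairs <- flatten_pairs(preds = c("watching tv", "other"),
                         labels = "watching tv")
  expect_equal(nrow(pairs), 2)
  expect_equal(pairs$label[pairs$pred == "other"], "false positive")
  # empty sets and exact agreement
  expect_equal(nrow(flatten_pairs(character(), character())), 0)
  pairs <- flatten_pairs("eating", "eating")
  expect_equal(pairs, tibble::tibble(label = "eating", pred = "eating"))
})

test_that("pair count equals max(|preds|, |labels|) on random set pairs", {
  set.seed(55)
  reg <- adl_registry()
  res <- vapply(1:10000, function(i) {
    np <- sample(0:5, 1)
    nl <- sample(0:5, 1)
    preds <- sample(reg, np)
    labels <- sample(reg, nl)
    pairs <- flatten_pairs(preds, labels)
    # count property + every intersection ADL in exactly one exact-match pair
    nrow(pairs) == max(np, nl) &&
      all(vapply(intersect(preds, labels), function(a) {
        sum(pairs$label == a & pairs$pred == a) == 1
      }, logical(1)))
  }, logical(1))
  expect_true(all(res))
})

test_that("randomness only permutes cross-matches, never diagonal/sentinels", {
  preds <- c("eating", "walking", "toileting", "showering")
  labels <- c("eating", "organizing", "using phone")
  diags <- integer(); fns <- integer(); fps <- integer()
  for (s in 1:100) {
    set.seed(s)
    pairs <- flatten_pairs(preds, labels)
    diags <- c(diags, sum(pairs$label == pairs$pred))
    fns <- c(fns, sum(pairs$pred == "false negative"))
    fps <- c(fps, sum(pairs$label == "false positive"))
  }
  expect_equal(unique(diags), 1)
  expect_equal(unique(fns), 0)
  expect_equal(unique(fps), 1)
})

test_that("the joint confusion matrix accumulates with sentinel margins", {
  pairs <- tibble::tibble(label = c("eating", "other", "false positive"),
                          pred = c("eating", "false negative", "walking"))
  cm <- accumulate_confusion(pairs)
  expect_equal(dim(unclass(cm)), c(13, 13))
  expect_equal(cm["eating", "eating"], 1)
  expect_equal(cm["other", "false negative"], 1)
  expect_equal(cm["false positive", "walking"], 1)
  expect_equal(sum(cm), 3)
  # totals over a random stream equal the sum of max-cardinalities
  set.seed(66)
  reg <- adl_registry()
  total <- 0
  all_pairs <- list()
  for (t in 1:200) {
    preds <- sample(reg, sample(0:4, 1))
    labels <- sample(reg, sample(0:4, 1))
    total <- total + max(length(preds), length(labels))
    all_pairs <- c(all_pairs, list(flatten_pairs(preds, labels)))
  }
  cm <- accumulate_confusion(dplyr::bind_rows(all_pairs))
  expect_equal(sum(cm), total)
})

test_that("participant aggregation reports mean and sd with missing cells", {
  r1 <- per_class_metrics(c(1, 0, 1), c(1, 0, 1))
  r2 <- per_class_metrics(c(1, 0, 1), c(0, 1, 1))
  agg <- aggregate_over_participants(list(a = r1, b = r2))
  ba <- agg[agg$class != "(mean)" & agg$metric == "balanced_accuracy", ]
  expect_equal(ba$mean, mean(c(1, 0.25)))
  # identical reports -> sd 0
  agg2 <- aggregate_over_participants(list(r1, r1))
  expect_true(all(agg2$sd[agg2$metric == "recall"] == 0))
  # a participant with an undefined cell is excluded from that mean
  r3 <- per_class_metrics(c(0, 0), c(0.2, 0.3)) # no positives: recall NA
  agg3 <- aggregate_over_participants(list(r1, r3))
  rec <- agg3[agg3$class != "(mean)" & agg3$metric == "recall", ]
  expect_equal(rec$n, 1)
  expect_equal(rec$mean, 1)
  expect_error(aggregate_over_participants(list(r1)), "at least 2")
})
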